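# Literal brute-force LBP implementations, written independently of the
# package internals: explicit loops over pixels and bits, nothing shared
# with the vectorized code path. Frozen reference for oracle-equivalence
# tests.

oracle_offsets <- rbind(
  c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
  c(1, 1), c(1, 0), c(1, -1), c(0, -1))

lbp2d_bruteforce <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  code <- matrix(0L, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      v <- 0L
      for (p in 1:8) {
        ni <- i + oracle_offsets[p, 1]
        nj <- j + oracle_offsets[p, 2]
        if (slice[ni, nj] >= slice[i, j]) v <- v + as.integer(2^(p - 1))
      }
      code[i, j] <- v
      valid[i, j] <- TRUE
    }
  }
  list(code = code, valid = valid)
}

lbp_top_bruteforce <- function(vol) {
  d <- dim(vol)
  map_yz <- map_xz <- map_xy <- array(0L, d)
  for (x in seq_len(d[1])) {
    map_yz[x, , ] <- lbp2d_bruteforce(vol[x, , ])$code
  }
  for (y in seq_len(d[2])) {
    map_xz[, y, ] <- lbp2d_bruteforce(vol[, y, ])$code
  }
  for (z in seq_len(d[3])) {
    map_xy[, , z] <- lbp2d_bruteforce(vol[, , z])$code
  }
  valid <- array(FALSE, d)
  valid[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  list(map_yz = map_yz, map_xz = map_xz, map_xy = map_xy, valid = valid)
}
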