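test_that("constant slices code to 255 everywhere valid (ties set the bit)", {
  r <- lbp2d(matrix(7, 5, 5))
  expect_true(all(r$code[r$valid] == 255L))
  expect_true(all(r$code[!r$valid] == 0L))
  expect_false(any(r$valid[c(1, 5), ]) || any(r$valid[, c(1, 5)]))
})

test_that("a fixed 5x5 slice reproduces the frozen brute-force codes", {
  M <- matrix(c(3, 7, 1, 9, 4,
                2, 5, 5, 0, 8,
                6, 3, 7, 2, 1,
                8, 4, 0, 6, 5,
                1, 9, 2, 3, 7), 5, 5, byrow = TRUE)
  r <- lbp2d(M)
  # interior codes computed once with the literal loop oracle and frozen
  expect_identical(as.vector(r$code[2:4, 2:4]),
                   c(90L, 238L, 165L, 165L, 0L, 255L, 255L, 181L, 17L))
  expect_identical(r$code, lbp2d_bruteforce(M)$code)
})

test_that("the code space has exactly 256 achievable labels in [0, 255]", {
  codes <- integer(0)
  for (pattern in 0:255) {
    bits <- as.integer(intToBits(pattern))[1:8]
    # build a 3x3 neighborhood realizing this sign pattern: center 2,
    # neighbor 3 where the bit is on (>= center), 1 where off
    ring <- ifelse(bits == 1L, 3, 1)
    sl <- matrix(2, 3, 3)
    off <- neighborhood_spec()$offsets
    for (p in 1:8) sl[2 + off[p, 1], 2 + off[p, 2]] <- ring[p]
    codes <- c(codes, lbp2d(sl)$code[2, 2])
  }
  expect_identical(sort(codes), 0:255)
})

test_that("lbp_top matches the brute-force oracle on random volumes", {
  set.seed(61)
  for (i in 1:10) {
    d <- sample(3:7, 3, replace = TRUE)
    v <- array(sample.int(40, prod(d), replace = TRUE), dim = d)
    got <- lbp_top(v)
    want <- lbp_top_bruteforce(v)
    expect_identical(got$map_yz, want$map_yz)
    expect_identical(got$map_xz, want$map_xz)
    expect_identical(got$map_xy, want$map_xy)
    expect_identical(got$valid, want$valid)
  }
})

test_that("strictly increasing transforms leave LBP-TOP maps bit-identical", {
  set.seed(62)
  v <- random_tie_free_volume(c(7, 6, 8))
  base <- lbp_top(v)
  for (f in list(function(x) x^2, function(x) 3 * x + 10, exp,
                 function(x) x^0.3)) {
    tr <- lbp_top(f(v - min(v) + 0.5))
    expect_identical(tr$map_yz, base$map_yz)
    expect_identical(tr$map_xz, base$map_xz)
    expect_identical(tr$map_xy, base$map_xy)
  }
})

test_that("swapping the first two axes exchanges the sagittal and coronal maps", {
  set.seed(63)
  v <- random_tie_free_volume(c(5, 6, 7))
  m <- lbp_top(v)
  ms <- lbp_top(aperm(v, c(2, 1, 3)))
  expect_identical(ms$map_yz, aperm(m$map_xz, c(2, 1, 3)))
  expect_identical(ms$map_xz, aperm(m$map_yz, c(2, 1, 3)))
})

test_that("volumes below 3x3x3 and tiny slices are rejected", {
  expect_error(lbp2d(matrix(0, 2, 5)), "3x3")
  expect_error(lbp_top(array(0, dim = c(3, 2, 3))), "3x3")
})

test_that("FWHM-to-sigma follows the Gaussian relation and smoothing conserves mass", {
  # FWHM 4 mm at 2 mm spacing: sigma = 4 / (2 sqrt(2 ln 2)) / 2 voxels
  sig <- 4 / (2 * sqrt(2 * log(2))) / 2
  expect_equal(sig, 0.8493218, tolerance = 1e-6)

  maps <- lbp_top(array(1 + seq_len(15^3) %% 7, dim = c(15, 15, 15)))
  # unit impulse through the same kernel path
  impulse <- array(0, dim = c(15, 15, 15)); impulse[8, 8, 8] <- 1
  maps$map_xy <- impulse
  sm <- smooth_codes(maps, fwhm_mm = 4, spacing_mm = c(2, 2, 2))
  expect_equal(sum(sm$map_xy), 1, tolerance = 1e-6)
  # separable: the peak is the normalized kernel center weight cubed
  w <- stats::dnorm(-4:4, sd = sig); w <- w / sum(w)
  expect_equal(max(sm$map_xy), w[5]^3, tolerance = 1e-10)
})

test_that("zero FWHM is the identity and constants are preserved exactly", {
  v <- array(runif(6^3), dim = c(6, 6, 6))
  maps <- lbp_top(v)
  sm0 <- smooth_codes(maps, fwhm_mm = 0)
  expect_identical(sm0$map_xy, maps$map_xy + 0)
  cmaps <- lbp_top(array(1, dim = c(8, 8, 8)))
  cmaps$map_xy[] <- 255L  # constant field incl. border
  smc <- smooth_codes(cmaps, fwhm_mm = 4, spacing_mm = c(2, 2, 2))
  expect_equal(max(abs(smc$map_xy - 255)), 0, tolerance = 1e-10)
})

test_that("histogram matching to itself is a 256-bin quantization", {
  co <- cohort_null()
  v <- read_volume(co$manifest$path[1], brain_mask = co$template$brain_mask)
  eq <- histogram_equalize(v, v)
  inside <- v$brain_mask
  binw <- diff(range(v$data[inside])) / 256
  expect_lt(max(abs(eq$data[inside] - v$data[inside])), binw)
  expect_true(all(eq$data[!inside] == 0))
})

test_that("matched CDF tracks the template CDF to discretization accuracy", {
  # With a continuous intensity distribution no histogram bin carries more
  # than ~1/256 of the mass, so the matched CDF can deviate from the
  # template CDF by at most one bin of each 256-bin histogram.
  set.seed(71)
  d <- c(20, 20, 20)
  mask <- array(TRUE, d)
  v <- volume(array(runif(prod(d)), d), brain_mask = mask)
  tmpl <- volume(array(rbeta(prod(d), 2, 5), d), brain_mask = mask)
  eq <- histogram_equalize(v, tmpl)
  xt <- tmpl$data[mask]
  xe <- eq$data[mask]
  breaks <- seq(min(xt), max(xt), length.out = 257)
  cdf_t <- cumsum(tabulate(findInterval(xt, breaks, all.inside = TRUE), 256)) /
    length(xt)
  cdf_e <- cumsum(tabulate(findInterval(xe, breaks, all.inside = TRUE), 256)) /
    length(xe)
  expect_lt(max(abs(cdf_t - cdf_e)), 2 / 256)
})

test_that("the histogram-matching map is non-decreasing in input intensity", {
  co <- cohort_null()
  tmpl <- co$template
  v <- read_volume(co$manifest$path[3], brain_mask = tmpl$brain_mask)
  eq <- histogram_equalize(v, tmpl)
  ord <- order(v$data[v$brain_mask])
  expect_true(all(diff(eq$data[v$brain_mask][ord]) >= 0))
})

test_that("feature images dispatch by type with the right plane structure", {
  co <- cohort_null()
  v <- read_volume(co$manifest$path[1], brain_mask = co$template$brain_mask)
  f1 <- feature_image(v, 1)
  expect_identical(f1$planes$intensity, v$data)
  expect_length(f1$planes, 1L)
  f2 <- feature_image(v, 2, template = co$template)
  expect_length(f2$planes, 1L)
  f3 <- feature_image(v, 3)
  expect_setequal(names(f3$planes), c("yz", "xz", "xy"))
  expect_error(feature_image(v, 2), "template")
  expect_error(feature_image(v, 4), "unknown")
})

test_that("type 3 features are identical across gamma variants of one subject", {
  s <- make_subject(spec_exact(), -1, 17)
  v1 <- volume(s$volume$data^0.5, s$volume$spacing, s$volume$brain_mask)
  v2 <- volume(s$volume$data^2.0, s$volume$spacing, s$volume$brain_mask)
  f1 <- feature_image(v1, 3)
  f2 <- feature_image(v2, 3)
  expect_identical(f1$planes, f2$planes)
})

test_that("type 2 features agree across gamma variants up to quantization", {
  co <- cohort_null()
  s <- make_subject(spec_exact(), -1, 18)
  tmpl <- co$template
  mk <- function(g) volume(s$volume$data^g, s$volume$spacing,
                           brain_mask = s$labels > 0)
  f1 <- feature_image(mk(0.5), 2, template = tmpl)
  f2 <- feature_image(mk(2.0), 2, template = tmpl)
  binw <- diff(range(tmpl$data[tmpl$brain_mask])) / 256
  d <- abs(f1$planes$intensity - f2$planes$intensity)
  expect_lte(stats::quantile(d[s$labels > 0], 0.99), 2 * binw + 1e-12)
  expect_lt(max(d), 8 * binw)
})
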