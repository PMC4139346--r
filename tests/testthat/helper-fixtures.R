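# Shared fixtures, generated once per test run and cached in memory.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

# Small noiseless single-scanner spec for exact-property tests.
spec_exact <- function(...) {
  phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2), n_per_group = 3,
               atrophy_fraction = 0.8, ventricle_dilation = 1.2,
               scanner_gammas = 1, noise_sigma = 0, jitter_mm = 0,
               seed = 101L, ...)
}

# Null spec: no group effect, one scanner, mild noise.
spec_null <- function(...) {
  phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2), n_per_group = 10,
               atrophy_fraction = 1, ventricle_dilation = 1,
               scanner_gammas = 1, noise_sigma = 0.05, jitter_mm = 0,
               seed = 202L, ...)
}

# Strong-effect multi-scanner spec for classification tests (small grid so
# the CV loop stays fast); scanner gammas, noise and jitter at the
# generator defaults.
spec_effect <- function(...) {
  phantom_spec(shape = c(32, 32, 32), spacing = c(2, 2, 2), n_per_group = 12,
               atrophy_fraction = 0.6, ventricle_dilation = 1.4,
               seed = 303L, ...)
}

cohort_effect <- function() fixture("cohort_effect", function() {
  make_cohort(spec_effect(), file.path(tempdir(), "lbptop_cohort_effect"))
})

cohort_null <- function() fixture("cohort_null", function() {
  make_cohort(spec_null(), file.path(tempdir(), "lbptop_cohort_null"))
})

features_effect_t3 <- function() fixture("features_effect_t3", function() {
  co <- cohort_effect()
  collect_features(co$manifest, 3, brain_mask = co$template$brain_mask)
})

cv_effect_t3 <- function() fixture("cv_effect_t3", function() {
  co <- cohort_effect()
  run_cv(features_effect_t3(),
         selection_criteria(0.001, co$masks$OVALL),
         cv_config(n_folds = 4, n_repeats = 2, seed = 99))
})

random_tie_free_volume <- function(shape = c(6, 6, 6)) {
  array(sample(seq_len(prod(shape))) + stats::runif(prod(shape), -0.2, 0.2),
        dim = shape)
}
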