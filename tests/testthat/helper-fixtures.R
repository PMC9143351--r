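## Shared fixtures, built once per test run. Small cohorts keep the default
## suite fast; the acceptance tests generate their own full-size cohorts.

## 6 + 6 cohort with a strong, deterministically-coupled effect: large enough
## for 5-fold tuning (>= 10 training rows at w6) and per-class LOOCV minima.
fix_cohort <- generate_cohort(6, 6, effect_size = 2, coupling = 1, seed = 11,
                              acts = c("walk", "stairs_up"))
fix_strides <- segment_cohort(fix_cohort)
fix_labels <- subject_labels(fix_cohort$profiles)
fix_walk_w6 <- training_strides(fix_strides, "walk", "w6_trained")
fix_fm <- suppressWarnings(build_feature_matrix(fix_walk_w6,
                                                fix_cohort$profiles))

## one patient profile reused by trial-level tests
fix_patient <- fix_cohort$profiles[["pat02"]]
fix_control <- fix_cohort$profiles[["ctrl01"]]

## deterministic toy feature matrix helper for classifier tests
toy_matrix <- function(n_per_class = 10, p = 6, shift = 3, seed = 42,
                       sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p, sd = sd), 2 * n_per_class, p)
  X[seq_len(n_per_class), 1:2] <- X[seq_len(n_per_class), 1:2] + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, labels = rep(c("tka", "control"), each = n_per_class))
}
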