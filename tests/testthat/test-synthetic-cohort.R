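test_that("cohort generation is deterministic and seed-sensitive", {
  a <- generate_cohort(2, 2, effect_size = 1, coupling = 1, seed = 5,
                       acts = "walk", n_cycles = 5)
  b <- generate_cohort(2, 2, effect_size = 1, coupling = 1, seed = 5,
                       acts = "walk", n_cycles = 5)
  c <- generate_cohort(2, 2, effect_size = 1, coupling = 1, seed = 6,
                       acts = "walk", n_cycles = 5)
  expect_identical(a, b)
  expect_false(identical(a$trials[[1]]$angles, c$trials[[1]]$angles))
})

test_that("cohort has the study's shape: 20 controls + 19 patients", {
  co <- generate_cohort(20, 19, effect_size = 1.5, coupling = 0.9, seed = 7,
                        acts = "walk", n_cycles = 5)
  groups <- vapply(co$profiles, `[[`, "", "group")
  expect_length(co$profiles, 39L)
  expect_equal(sum(groups == "control"), 20L)
  expect_equal(sum(groups == "patient"), 19L)
  ## controls: one evaluation with zero severity; patients: 5 timepoints
  for (p in co$profiles) {
    if (p$group == "control") {
      expect_identical(names(p$latent_severity), "control_single")
      expect_identical(p$affected_side, "none")
      expect_equal(p$latent_severity$control_single, 0)
    } else {
      expect_identical(names(p$latent_severity),
                       c("pre", "w6", "m3", "m6", "m12"))
      expect_true(p$affected_side %in% c("left", "right"))
    }
  }
  ## dropouts: one after pre, one after m6; trials truncated accordingly
  drops <- vapply(co$profiles, function(p)
    p$dropout_after %||% NA_character_, "")
  expect_equal(sum(drops == "pre", na.rm = TRUE), 1L)
  expect_equal(sum(drops == "m6", na.rm = TRUE), 1L)
  trial_key <- vapply(co$trials, function(t)
    paste(t$subject_id, t$timepoint), "")
  dropped_pre <- names(drops)[which(drops == "pre")]
  expect_false(any(grepl(paste(dropped_pre, "w6"), trial_key, fixed = TRUE)))
  ## a third of patients cannot do stairs at 6 weeks
  incap <- vapply(co$profiles, function(p)
    p$group == "patient" && !isTRUE(p$stairs_capable[["w6"]]), TRUE)
  expect_equal(sum(incap), round(19 / 3))
})

test_that("severity has no effect when effect_size is zero", {
  p <- fix_patient
  p_low <- p; p_low$latent_severity$pre <- 0.1
  p_high <- p; p_high$latent_severity$pre <- 0.9
  t_low <- generate_trial(p_low, "walk", "pre", seed = 3, effect_size = 0)
  t_high <- generate_trial(p_high, "walk", "pre", seed = 3, effect_size = 0)
  expect_identical(t_low$angles, t_high$angles)
  expect_identical(t_low$accel_ap, t_high$accel_ap)
})

test_that("KOOS follows the generative link when coupling = 1", {
  co <- generate_cohort(5, 5, effect_size = 2, coupling = 1, seed = 3,
                        acts = "walk", n_cycles = 5)
  for (pr in co$proms) {
    p <- co$profiles[[pr$subject_id]]
    if (!isTRUE(p$recovering)) next
    tps <- intersect(c("w6", "m3", "m6", "m12"), names(pr$koos_adl))
    koos <- unlist(pr$koos_adl[tps])
    expect_true(all(diff(koos) >= 0))  # severity non-increasing => koos up
    for (tp in tps)
      expect_equal(pr$koos_adl[[tp]], 100 * (1 - p$latent_severity[[tp]]))
  }
})

test_that("KOOS values stay within [0, 100]", {
  co <- generate_cohort(3, 8, effect_size = 1, coupling = 0, seed = 21,
                        acts = "walk", n_cycles = 5, prom_noise_sd = 200)
  koos <- unlist(lapply(co$proms, function(pr) unlist(pr$koos_adl)))
  expect_true(all(koos >= 0 & koos <= 100))
})

test_that("trials plant two steps per cycle and per-leg stride bounds", {
  tr <- generate_trial(fix_control, "walk", "control_single", n_cycles = 6,
                       seed = 9)
  expect_length(tr$true_events$steps, 12L)
  expect_equal(as.vector(table(tr$true_events$step_sides)), c(6L, 6L))
  for (sd in c("left", "right"))
    expect_equal(nrow(tr$true_events$strides[[sd]]), 5L)
  ## all channels share length and sample rate
  expect_equal(nrow(tr$angles$left), nrow(tr$angles$right))
  expect_equal(length(tr$accel_ap), nrow(tr$angles$left))
  expect_equal(length(tr$tibia_accel_x$left), nrow(tr$angles$left))
})

test_that("severity reduces the knee flexion-extension range", {
  p0 <- fix_patient; p0$latent_severity$pre <- 0
  p1 <- fix_patient; p1$latent_severity$pre <- 1
  t0 <- generate_trial(p0, "walk", "pre", seed = 5, effect_size = 2,
                       noise_sd = 0)
  t1 <- generate_trial(p1, "walk", "pre", seed = 5, effect_size = 2,
                       noise_sd = 0)
  side <- fix_patient$affected_side
  r0 <- diff(range(t0$angles[[side]][, "knee_flex_ext"]))
  r1 <- diff(range(t1$angles[[side]][, "knee_flex_ext"]))
  expect_lt(r1, r0)
})

test_that("gait deviation is strictly increasing in latent severity", {
  for (seed in c(2, 7)) {
    devs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
      p <- fix_patient
      p$latent_severity$pre <- s
      gait_deviation(generate_trial(p, "walk", "pre", seed = seed,
                                    effect_size = 2))
    }, 0)
    expect_true(all(diff(devs) > 0))
  }
})

test_that("trial generation validates its inputs", {
  expect_error(generate_trial(fix_patient, "walk", "nonsense", seed = 1),
               "timepoint")
  expect_error(generate_trial(fix_patient, "walk", "pre", n_cycles = 4,
                              seed = 1), "n_cycles")
  expect_error(generate_cohort(1, 5), "at least 2")
  expect_error(generate_cohort(5, 5, coupling = 1.5), "coupling")
  expect_error(generate_cohort(5, 5, effect_size = -1), "effect_size")
})

test_that("cohort CSV round trip writes the documented long format", {
  co <- generate_cohort(2, 2, effect_size = 1, coupling = 1, seed = 2,
                        acts = "walk", n_cycles = 5)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  expect_true(all(file.exists(paths)))
  long <- read.csv(file.path(dir, "trials.csv"))
  expect_identical(names(long),
                   c("subject_id", "activity", "timepoint", "side", "channel",
                     "sample_index", "value"))
  expect_setequal(unique(long$subject_id),
                  vapply(co$profiles, `[[`, "", "subject_id"))
  ## values survive the round trip for one channel of one trial
  tr <- co$trials[[1]]
  sub <- long[long$subject_id == tr$subject_id &
                long$channel == "left_knee_flex_ext" &
                long$timepoint == tr$timepoint, ]
  expect_equal(sub$value[order(sub$sample_index)],
               unname(tr$angles$left[, "knee_flex_ext"]))
})
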