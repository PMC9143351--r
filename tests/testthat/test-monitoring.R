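## small helpers to build trajectory / PROM structures by hand
make_trajs <- function(df, variant = "w6_trained") {
  df$activity <- rep("walk", nrow(df))
  df$in_sample <- df$timepoint == "w6" & variant == "w6_trained"
  structure(df[, c("subject_id", "activity", "timepoint", "p_tka",
                   "in_sample")],
            class = c("recovery_trajectories", "data.frame"),
            variant = variant)
}

make_proms <- function(...) {
  lst <- list(...)
  lapply(lst, function(k)
    structure(list(subject_id = "x", koos_adl = as.list(k)),
              class = "prom_trajectory"))
}

test_that("change scores are simple differences with dropout exclusion", {
  trajs <- make_trajs(data.frame(
    subject_id = c("p1", "p1", "p2"),
    timepoint = c("w6", "m12", "w6"),
    p_tka = c(0.9, 0.3, 0.8)))
  proms <- list(
    p1 = structure(list(subject_id = "p1",
                        koos_adl = list(w6 = 50, m12 = 90)),
                   class = "prom_trajectory"),
    p2 = structure(list(subject_id = "p2",
                        koos_adl = list(w6 = 40)),
                   class = "prom_trajectory"))
  ch <- compute_change_scores(trajs, proms)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$delta_p, -0.6)
  expect_equal(ch$delta_koos, 40)
  expect_identical(attr(ch, "excluded"), "p2")
})

test_that("group correlation is Spearman with a two-sided p", {
  ch <- data.frame(subject_id = letters[1:5],
                   delta_p = c(-0.5, -0.4, -0.3, -0.2, -0.1),
                   delta_koos = c(50, 40, 30, 20, 10))
  g <- group_correlation(ch)
  expect_equal(g$rho, -1)  # probability drops as reported function rises
  ch$delta_koos <- rev(ch$delta_koos)
  expect_equal(group_correlation(ch)$rho, 1)
  expect_error(group_correlation(ch[1:2, ]), ">= 3")
})

test_that("correlation bands partition [-1, 1] at the stated cut-points", {
  expect_identical(correlation_band(c(0, 0.1, -0.2)), rep("weak", 3))
  expect_identical(correlation_band(c(0.25, -0.4)), rep("fair", 2))
  expect_identical(correlation_band(c(0.5, -0.6, 0.74)), rep("moderate", 3))
  expect_identical(correlation_band(c(0.75, -0.9, 1, -1)), rep("strong", 4))
  ## totality: every rho maps to exactly one band
  grid <- seq(-1, 1, by = 0.01)
  bands <- correlation_band(grid)
  expect_false(anyNA(bands))
  expect_setequal(unique(bands), c("weak", "fair", "moderate", "strong"))
  expect_error(correlation_band(1.2), "<= 1")
})

test_that("individual correlations handle monotone, flat and short series", {
  trajs <- make_trajs(data.frame(
    subject_id = rep(c("p1", "p2", "p3"), each = 4),
    timepoint = rep(c("w6", "m3", "m6", "m12"), 3),
    p_tka = c(0.9, 0.7, 0.5, 0.3,   # strictly decreasing
              0.6, 0.5, 0.4, 0.2,
              0.9, 0.8, 0.7, 0.6)))
  trajs <- trajs[!(trajs$subject_id == "p3" &
                     trajs$timepoint %in% c("m6", "m12")), ]
  proms <- list(
    p1 = structure(list(subject_id = "p1",
                        koos_adl = list(w6 = 40, m3 = 60, m6 = 75, m12 = 90)),
                   class = "prom_trajectory"),
    p2 = structure(list(subject_id = "p2",
                        koos_adl = list(w6 = 70, m3 = 70, m6 = 70, m12 = 70)),
                   class = "prom_trajectory"),
    p3 = structure(list(subject_id = "p3",
                        koos_adl = list(w6 = 40, m3 = 60, m6 = 80, m12 = 90)),
                   class = "prom_trajectory"))
  ind <- individual_correlations(trajs, proms)
  p1 <- ind[ind$subject_id == "p1", ]
  expect_equal(p1$rho, -1)
  expect_identical(p1$band, "strong")
  expect_identical(p1$status, "ok")
  expect_equal(p1$n_points, 4L)
  ## constant KOOS: zero rank variance, flagged not banded
  p2 <- ind[ind$subject_id == "p2", ]
  expect_identical(p2$status, "undefined")
  expect_true(is.na(p2$rho))
  ## fewer than 3 shared points: insufficient
  p3 <- ind[ind$subject_id == "p3", ]
  expect_identical(p3$status, "insufficient")
  expect_equal(p3$n_points, 2L)
})

test_that("a rho of -0.6 lands in the moderate band", {
  expect_identical(correlation_band(-0.6), "moderate")
})

test_that("deployment gives identical scores for identical inputs", {
  fm <- suppressWarnings(build_feature_matrix(
    Filter(function(s) s$timepoint %in% c("w6", "m3", "m6", "m12"),
           fix_strides[vapply(fix_strides, function(s)
             s$activity == "walk", TRUE)]),
    fix_cohort$profiles, fix_fm$config, view_defs = fix_fm$view_defs))
  labels <- fix_labels[unique(fix_fm$meta$subject_id)]
  model <- suppressWarnings(tune_and_train(
    fix_fm, fix_labels[fix_fm$meta$subject_id], model_spec(seed = 4),
    view_defs = fix_fm$view_defs))
  trajs <- deploy_over_time(model, fm, "w6_trained")
  expect_true(all(trajs$p_tka >= 0 & trajs$p_tka <= 1))
  expect_true(all(trajs$in_sample == (trajs$timepoint == "w6")))
  ## same feature row, same model -> same probability as predict_probability
  direct <- predict_probability(model, fm)
  direct <- direct[direct$subject_id %in% trajs$subject_id, ]
  key <- function(d) paste(d$subject_id, d$timepoint)
  expect_equal(trajs$p_tka[order(key(trajs))],
               direct$p_tka[order(key(direct))])
  ## view-list mismatch is refused
  fm_bad <- fm
  fm_bad$view_defs <- fm$view_defs[-1]
  expect_error(deploy_over_time(model, fm_bad, "w6_trained"), "view list")
})

test_that("heatmap table renders gaps and deterministic ordering", {
  expect_equal(nrow(export_heatmap_table(make_trajs(data.frame(
    subject_id = character(0), timepoint = character(0),
    p_tka = numeric(0))))), 0L)
  trajs <- make_trajs(data.frame(
    subject_id = c("p2", "p1", "p1"),
    timepoint = c("w6", "m3", "m12"),
    p_tka = c(0.8, 0.6, 0.4)))
  tab <- export_heatmap_table(trajs)
  expect_identical(tab$subject_id, c("p1", "p2"))
  expect_identical(names(tab), c("subject_id", "w6", "m3", "m6", "m12"))
  expect_true(is.na(tab[tab$subject_id == "p1", "w6"]))
  expect_equal(tab[tab$subject_id == "p1", "m3"], 0.6)
  expect_true(all(is.na(tab[, "m6"])))
})

test_that("stairs incapacity at 6 weeks propagates as heatmap gaps", {
  stair_strides <- Filter(function(s) s$activity == "stairs_up", fix_strides)
  tr <- training_strides(stair_strides, "stairs_up", "w6_trained")
  fm_tr <- suppressWarnings(build_feature_matrix(tr, fix_cohort$profiles))
  ## 3 inner folds: the stairs-at-6-weeks training set is small by design
  ## (dropout + stairs-incapable patients)
  model <- suppressWarnings(tune_and_train(
    fm_tr, fix_labels[fm_tr$meta$subject_id],
    model_spec(seed = 6, inner_folds = 3L),
    view_defs = fm_tr$view_defs))
  post <- Filter(function(s) s$timepoint %in% c("w6", "m3", "m6", "m12"),
                 stair_strides)
  fm_post <- suppressWarnings(build_feature_matrix(
    post, fix_cohort$profiles, fm_tr$config, view_defs = fm_tr$view_defs))
  trajs <- deploy_over_time(model, fm_post, "w6_trained")
  tab <- export_heatmap_table(trajs)
  incapable <- names(Filter(function(p)
    p$group == "patient" && !isTRUE(p$stairs_capable[["w6"]]),
    fix_cohort$profiles))
  expect_gt(length(incapable), 0L)
  present <- intersect(incapable, tab$subject_id)
  expect_true(all(is.na(tab[tab$subject_id %in% present, "w6"])))
})
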