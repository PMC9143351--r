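test_that("scaler implements population standard scaling with masking", {
  m <- cbind(a = c(0, 2), b = c(1, 1))
  sc <- fit_scaler(m)
  expect_equal(unname(sc$mean["a"]), 1)
  expect_equal(unname(sc$sd["a"]), 1)  # population std of {0, 2}
  expect_true(sc$zero_variance_mask["b"])
  scaled <- apply_scaler(sc, m)
  expect_identical(colnames(scaled), "a")
  expect_equal(unname(scaled[, "a"]), c(-1, 1))
  expect_error(fit_scaler(m[1, , drop = FALSE]), ">= 2")
})

test_that("scaled training columns are standard to 1e-10", {
  sc <- fit_scaler(fix_fm)
  scaled <- apply_scaler(sc, fix_fm)
  expect_true(all(abs(colMeans(scaled)) < 1e-10))
  expect_true(all(abs(apply(scaled, 2, function(x)
    sqrt(mean((x - mean(x))^2))) - 1) < 1e-10))
})

test_that("evaluation rows are transformed with training statistics only", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sc <- fit_scaler(m)
  ## a row equal to the training mean maps to zero
  expect_equal(unname(apply_scaler(sc, matrix(
    sc$mean, 1, dimnames = list(NULL, names(sc$mean))))[1, ]), rep(0, 4))
  ## shifted evaluation rows stay shifted: no re-centring on themselves
  shifted <- m + 5
  out <- apply_scaler(sc, shifted)
  manual <- sweep(sweep(shifted, 2, sc$mean), 2, sc$sd, `/`)
  expect_equal(out, manual)
  expect_gt(min(colMeans(out)), 1)
  expect_error(apply_scaler(sc, m[, 1:3]), "f4")
})

test_that("the C grid is ten log-spaced values from 0.01 to 1", {
  grid <- model_spec()$C_grid
  expect_length(grid, 10L)
  expect_equal(grid, 0.01 * (10^(2 / 9))^(0:9))
  expect_equal(grid[1], 0.01)
  expect_equal(grid[10], 1)
  ratios <- grid[-1] / grid[-10]
  expect_equal(ratios, rep(10^(2 / 9), 9))
  expect_error(model_spec(C_grid = c(1, 0.5)), "increasing")
})

test_that("probability prediction matches the sigmoid closed form", {
  sc <- structure(list(mean = c(a = 0), sd = c(a = 1),
                       zero_variance_mask = c(a = FALSE)),
                  class = "scaler_params")
  model <- structure(list(scaler = sc, weights = c(a = 1), intercept = 0,
                          spec = model_spec()), class = "trained_model")
  x <- function(v) matrix(v, 1, dimnames = list(NULL, "a"))
  expect_equal(predict_probability(model, x(log(3)))$p_tka, 0.75,
               tolerance = 1e-12)
  ## zero weights, zero intercept -> 0.5, tie classified as control
  model$weights <- c(a = 0)
  p <- predict_probability(model, x(17))
  expect_equal(p$p_tka, 0.5)
  expect_identical(p$predicted_class, "control")
  ## large intercept -> probability approaches 1
  model$intercept <- 50
  expect_gt(predict_probability(model, x(0))$p_tka, 1 - 1e-12)
})

test_that("the coordinate-descent fit agrees with glmnet", {
  library(glmnet)
  set.seed(1)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- ifelse(stats::plogis(X %*% c(1.5, -2, 1, rep(0, p - 3))) > runif(n),
              "tka", "control")
  for (C in c(0.05, 0.3, 1)) {
    fit <- suppressWarnings(fit_l1_logistic(X, y, C))
    lam <- 1 / (n * C)
    ## glmnet solves (1/n) loglik + lambda * ||w||_1: lambda = 1/(n C)
    g <- glmnet(X, factor(y), family = "binomial", alpha = 1,
                standardize = FALSE, thresh = 1e-12,
                lambda = exp(seq(log(max(20 * lam, 0.5)), log(lam),
                                 length.out = 20)))
    ref <- as.numeric(coef(g, s = lam))
    expect_lt(max(abs(fit$weights - ref[-1])), 1e-4)
    expect_lt(abs(fit$intercept - ref[1]), 1e-4)
  }
  expect_error(fit_l1_logistic(X, rep("tka", n), 1), "single class")
})

test_that("AUC is the Mann-Whitney statistic with tie handling", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1),
                         c("tka", "tka", "control", "control")), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9),
                         c("tka", "tka", "control", "control")), 0)
  expect_equal(auc_score(c(0.5, 0.5), c("tka", "control")), 0.5)
  expect_true(is.na(auc_score(c(0.5, 0.6), c("tka", "tka"))))
})

test_that("tuning selects a perfect C on separable data and prefers sparsity", {
  toy <- toy_matrix(n_per_class = 10, shift = 4)
  model <- suppressWarnings(tune_and_train(toy$X, toy$labels,
                                           model_spec(seed = 2)))
  expect_equal(max(model$inner_cv_auc$mean_auc), 1)
  ## ties in AUC resolve to the smallest C (strongest regularisation)
  winners <- model$inner_cv_auc$C[
    model$inner_cv_auc$mean_auc >= max(model$inner_cv_auc$mean_auc) - 1e-12]
  expect_equal(model$chosen_C, min(winners))
  ## L1 path: weaker regularisation never has fewer nonzero weights
  weak <- toy_matrix(n_per_class = 10, shift = 0.4, seed = 9)
  sc <- fit_scaler(weak$X)
  Xs <- apply_scaler(sc, weak$X)
  nnz <- vapply(c(0.01, 1), function(C)
    sum(suppressWarnings(fit_l1_logistic(Xs, weak$labels, C))$weights != 0),
    0L)
  expect_lte(nnz[1], nnz[2])
})

test_that("tune_and_train validates inputs", {
  toy <- toy_matrix(n_per_class = 4)
  expect_error(tune_and_train(toy$X, rep("tka", 8), model_spec()),
               "single class")
  expect_error(tune_and_train(toy$X, toy$labels, model_spec()),
               "too few")
})

test_that("LOOCV refits per fold, scores everyone, and reports accuracy", {
  cv <- suppressWarnings(loocv_evaluate(fix_fm, fix_labels,
                                        model_spec(seed = 3)))
  expect_setequal(cv$scores$subject_id, fix_fm$meta$subject_id)
  expect_true(all(cv$scores$p_tka >= 0 & cv$scores$p_tka <= 1))
  expect_identical(cv$scores$predicted_class,
                   ifelse(cv$scores$p_tka > 0.5, "tka", "control"))
  expect_equal(cv$accuracy, mean(cv$scores$correct))
  ## the arithmetic: 23 of 24 correct is 95.83%
  expect_equal(round(100 * 23 / 24, 2), 95.83)
})

test_that("LOOCV rejects folds that leave a single class", {
  values <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("f1", "f2")))
  fm <- structure(list(
    values = values,
    meta = data.frame(subject_id = c("a1", "c1", "c2", "c3"),
                      activity = "walk", timepoint = "w6",
                      group = c("patient", rep("control", 3)),
                      n_strides = 1L),
    view_defs = list(), config = fusion_config()),
    class = "feature_matrix")
  labels <- c(a1 = "tka", c1 = "control", c2 = "control", c3 = "control")
  expect_error(loocv_evaluate(fm, labels, model_spec()), "single-class")
})

test_that("models survive a JSON round trip", {
  toy <- toy_matrix()
  model <- suppressWarnings(tune_and_train(toy$X, toy$labels,
                                           model_spec(seed = 5),
                                           view_defs = fix_fm$view_defs))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$chosen_C, model$chosen_C)
  expect_equal(back$spec$C_grid, model$spec$C_grid)
  X <- toy$X
  expect_equal(predict_probability(back, X)$p_tka,
               predict_probability(model, X)$p_tka)
})
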