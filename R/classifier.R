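## L1-regularised logistic regression with standard scaling, nested
## hyperparameter tuning on AUC, and leave-one-subject-out evaluation.
##
## The classifier maps a subject's gait features to the probability of
## belonging to the TKA class. Scores near 0 mean control-like gait, near 1
## mean TKA-like gait; the decision boundary is 0.5 (a score of exactly 0.5
## is classified as control).

#' Model specification
#'
#' Houses the fixed hyperparameters of the training procedure: an L1 penalty
#' with ten regularisation values log-spaced on [0.01, 1] (ratio 10^(2/9)),
#' five-fold stratified inner cross-validation tuned on AUC, an optimiser cap
#' of 100 iterations, and a 0.5 decision boundary.
#'
#' @param C_grid Inverse-regularisation grid (strictly increasing).
#' @param inner_folds Inner CV folds (default 5).
#' @param max_iterations Optimiser iteration cap (default 100; hitting the cap
#'   is logged, not fatal).
#' @param decision_boundary Classification threshold (default 0.5).
#' @param seed Seed for the inner CV splits.
#' @return A `model_spec` list.
#' @export
model_spec <- function(C_grid = 10^seq(-2, 0, length.out = 10),
                       inner_folds = 5L, max_iterations = 100L,
                       decision_boundary = 0.5, seed = 1L) {
  if (any(diff(C_grid) <= 0)) stopf("C_grid must be strictly increasing")
  structure(list(C_grid = C_grid, inner_folds = as.integer(inner_folds),
                 max_iterations = as.integer(max_iterations),
                 decision_boundary = decision_boundary,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Class labels from subject profiles
#'
#' @param profiles Named list of subject profiles.
#' @param subjects Subject ids (defaults to all profiles).
#' @return Named character vector, `"control"` or `"tka"`.
#' @export
subject_labels <- function(profiles, subjects = names(profiles)) {
  vapply(stats::setNames(nm = subjects), function(id) {
    if (profiles[[id]]$group == "control") "control" else "tka"
  }, "")
}

fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (is.matrix(x)) x
  else stopf("expected a feature_matrix or numeric matrix")
}

## ---- Standard scaling ------------------------------------------------------

#' Fit a standard scaler on training rows
#'
#' Per-column mean and population standard deviation (divide by n) over the
#' training rows only. Zero-variance columns are masked: they carry no
#' information and would divide by zero; they are dropped from modelling.
#'
#' @param train A `feature_matrix` or numeric matrix of training rows.
#' @return A `scaler_params` list: `mean`, `sd`, `zero_variance_mask`
#'   (all named by feature).
#' @export
fit_scaler <- function(train) {
  m <- fm_values(train)
  if (nrow(m) < 2L)
    stopf("need >= 2 training rows to fit a scaler (got %d)", nrow(m))
  mu <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  mask <- sds <= 1e-12
  structure(list(mean = mu, sd = sds, zero_variance_mask = mask),
            class = "scaler_params")
}

#' Apply a fitted scaler
#'
#' Transforms rows as `(x - train_mean) / train_sd` per retained column, using
#' the training statistics only; evaluation rows are never re-centred on
#' themselves. Masked (zero-variance) columns are dropped.
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param rows A `feature_matrix` or numeric matrix containing all retained
#'   training columns.
#' @return Numeric matrix of scaled values (retained columns only).
#' @export
apply_scaler <- function(params, rows) {
  m <- fm_values(rows)
  keep <- names(params$mean)[!params$zero_variance_mask]
  missing <- setdiff(keep, colnames(m))
  if (length(missing) > 0L)
    stopf("rows are missing required feature column(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  m <- m[, keep, drop = FALSE]
  sweep(sweep(m, 2L, params$mean[keep]), 2L, params$sd[keep], `/`)
}

## ---- Core fit and scoring --------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties.
#'
#' @param scores Numeric scores, higher = more TKA-like.
#' @param labels Labels; `"tka"` (or `TRUE`/1) is the positive class.
#' @return AUC in [0, 1]; `NA` if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == "tka" | labels == TRUE | labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit an L1-penalised logistic regression at a fixed C
#'
#' Minimises `||w||_1 + C * sum(log-loss)` (the LIBLINEAR parameterisation,
#' so larger C means weaker regularisation) by proximal Newton with coordinate
#' descent, capped at `max_iter` outer iterations. Non-convergence within the
#' cap produces a warning and returns the current iterate.
#'
#' @param X Numeric matrix (rows = subjects, columns = scaled features).
#' @param y Binary labels (1/TRUE/"tka" = positive).
#' @param C Inverse regularisation strength (> 0).
#' @param max_iter Outer iteration cap (default 100).
#' @param tol Relative objective tolerance (default 1e-8).
#' @return List: `weights` (named), `intercept`, `iterations`, `converged`.
#' @export
fit_l1_logistic <- function(X, y, C, max_iter = 100L, tol = 1e-8) {
  y01 <- as.numeric(y == "tka" | y == TRUE | y == 1)
  if (length(unique(y01)) < 2L)
    stopf("training labels contain a single class")
  fit <- l1_logistic_cd(X, y01, C, as.integer(max_iter), tol)
  if (!fit$converged)
    warnf("L1 logistic regression did not converge within %d iterations (C = %g)",
          max_iter, C)
  names(fit$weights) <- colnames(X)
  fit
}

sigmoid <- function(z) 1 / (1 + exp(-z))

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune the regularisation parameter and train the final model
#'
#' For each C in the grid, runs stratified `inner_folds`-fold cross-validation
#' on the training rows (scaler refit on each inner training split) and
#' averages the validation AUC; the C with the highest mean AUC wins, ties
#' going to the smaller C (stronger regularisation). The final scaler and
#' model are then fit on all training rows with the chosen C.
#'
#' @param train A `feature_matrix` (or numeric matrix) of training rows.
#' @param labels Labels aligned to the rows (`"control"`/`"tka"`).
#' @param spec A [model_spec()].
#' @param view_defs Optional fused-view definitions to persist with the model.
#' @return A `trained_model`: `scaler`, `weights` (named, over retained
#'   columns), `intercept`, `chosen_C`, `inner_cv_auc` (per-C table), `spec`,
#'   `view_defs`, `feature_names`, `converged`.
#' @export
tune_and_train <- function(train, labels, spec = model_spec(),
                           view_defs = NULL) {
  m <- fm_values(train)
  labels <- as.character(labels)
  if (length(labels) != nrow(m))
    stopf("labels (%d) do not match training rows (%d)",
          length(labels), nrow(m))
  if (length(unique(labels)) < 2L)
    stopf("training labels contain a single class")
  if (nrow(m) < 2L * spec$inner_folds)
    stopf("too few training rows (%d) for %d-fold stratified tuning",
          nrow(m), spec$inner_folds)
  fold <- stratified_folds(labels, spec$inner_folds,
                           derive_seed(spec$seed, "innercv", nrow(m)))
  ## scale each inner fold once (training statistics only), reuse across C
  splits <- lapply(seq_len(spec$inner_folds), function(f) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) return(NULL)
    sc <- fit_scaler(m[tr, , drop = FALSE])
    list(Xtr = apply_scaler(sc, m[tr, , drop = FALSE]),
         Xva = apply_scaler(sc, m[!tr, , drop = FALSE]),
         ytr = labels[tr], yva = labels[!tr])
  })
  cv_auc <- vapply(spec$C_grid, function(C) {
    aucs <- vapply(splits, function(sp) {
      if (is.null(sp)) return(NA_real_)
      fit <- suppressWarnings(
        fit_l1_logistic(sp$Xtr, sp$ytr, C, spec$max_iterations))
      auc_score(sigmoid(drop(sp$Xva %*% fit$weights) + fit$intercept),
                sp$yva)
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  best <- which(cv_auc >= max(cv_auc) - 1e-12)[1L]  # tie -> smaller C
  chosen_C <- spec$C_grid[best]
  scaler <- fit_scaler(m)
  X <- apply_scaler(scaler, m)
  fit <- fit_l1_logistic(X, labels, chosen_C, spec$max_iterations)
  structure(list(scaler = scaler, weights = fit$weights,
                 intercept = fit$intercept, chosen_C = chosen_C,
                 inner_cv_auc = data.frame(C = spec$C_grid,
                                           mean_auc = cv_auc),
                 spec = spec, view_defs = view_defs,
                 feature_names = colnames(X), converged = fit$converged),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "L1 logistic model: C = %.4g, %d/%d nonzero weights, intercept %.3f\n",
    x$chosen_C, sum(x$weights != 0), length(x$weights), x$intercept))
  invisible(x)
}

#' Probability of belonging to the TKA class
#'
#' Scales the rows with the model's training-time scaler and applies the
#' logistic map `1 / (1 + exp(-(w . x + b)))`. The predicted class is `tka`
#' iff the probability strictly exceeds the decision boundary (an exact tie is
#' classified as control).
#'
#' @param model A `trained_model`.
#' @param rows A `feature_matrix` (scores keep subject/activity/timepoint
#'   metadata) or numeric matrix.
#' @return Data frame with `p_tka` and `predicted_class` (plus metadata when
#'   available).
#' @export
predict_probability <- function(model, rows) {
  X <- apply_scaler(model$scaler, rows)
  p <- sigmoid(drop(X %*% model$weights[colnames(X)]) + model$intercept)
  cls <- ifelse(p > model$spec$decision_boundary, "tka", "control")
  if (inherits(rows, "feature_matrix")) {
    cbind(rows$meta[, c("subject_id", "activity", "timepoint")],
          data.frame(p_tka = unname(p), predicted_class = unname(cls)))
  } else {
    data.frame(p_tka = unname(p), predicted_class = unname(cls))
  }
}

## ---- Leave-one-subject-out evaluation --------------------------------------

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' Each fold holds out every row of one subject and refits everything on the
#' remaining subjects — fused-view list (when strides are supplied), scaler,
#' hyperparameter tuning and final model — then scores the held-out subject.
#' Accuracy is the ratio of correct predictions to the total at the 0.5
#' boundary.
#'
#' @param x Either a `feature_matrix` (fixed view list; scaler/tuning refit
#'   per fold) or a list of `stride_window` objects (full refit including the
#'   fused-view list, which requires `profiles`).
#' @param labels Named character vector of per-subject labels
#'   (`"control"`/`"tka"`).
#' @param spec A [model_spec()].
#' @param ... Method-specific arguments.
#' @return List: `scores` (per-row data frame with `p_tka`,
#'   `predicted_class`, `label`, `correct`), `accuracy`, `folds` (per-subject
#'   diagnostics: chosen C, scaler statistics).
#' @export
loocv_evaluate <- function(x, labels, spec = model_spec(), ...) {
  UseMethod("loocv_evaluate")
}

#' @rdname loocv_evaluate
#' @export
loocv_evaluate.feature_matrix <- function(x, labels, spec = model_spec(),
                                          ...) {
  subjects <- unique(x$meta$subject_id)
  if (length(setdiff(subjects, names(labels))) > 0L)
    stopf("labels missing for some subjects")
  loocv_core(subjects, labels, spec, function(held) {
    train <- subset_rows(x, x$meta$subject_id != held)
    test <- subset_rows(x, x$meta$subject_id == held)
    list(train = train, test = test, view_defs = x$view_defs)
  })
}

#' @rdname loocv_evaluate
#' @param profiles Named list of subject profiles (stride-list method only).
#' @param config A [fusion_config()] (stride-list method only).
#' @export
loocv_evaluate.list <- function(x, labels, spec = model_spec(),
                                profiles = NULL, config = fusion_config(),
                                ...) {
  if (is.null(profiles)) stopf("`profiles` is required for stride-level LOOCV")
  subjects <- unique(vapply(x, `[[`, "", "subject_id"))
  loocv_core(subjects, labels, spec, function(held) {
    in_fold <- vapply(x, function(s) s$subject_id != held, TRUE)
    train_fm <- build_feature_matrix(x[in_fold], profiles, config)
    test_fm <- build_feature_matrix(x[!in_fold], profiles, config,
                                    view_defs = train_fm$view_defs)
    list(train = train_fm, test = test_fm, view_defs = train_fm$view_defs)
  })
}

loocv_core <- function(subjects, labels, spec, split_fn) {
  scores <- list()
  folds <- list()
  for (held in subjects) {
    rest <- setdiff(subjects, held)
    if (length(unique(labels[rest])) < 2L)
      stopf("fold holding out %s leaves a single-class training set", held)
    sp <- split_fn(held)
    model <- tune_and_train(sp$train, labels[sp$train$meta$subject_id], spec,
                            view_defs = sp$view_defs)
    pred <- predict_probability(model, sp$test)
    pred$label <- unname(labels[held])
    pred$correct <- pred$predicted_class == pred$label
    scores[[held]] <- pred
    folds[[held]] <- list(chosen_C = model$chosen_C,
                          scaler_mean = model$scaler$mean,
                          scaler_sd = model$scaler$sd)
  }
  scores <- do.call(rbind, c(scores, list(make.row.names = FALSE)))
  list(scores = scores, accuracy = mean(scores$correct), folds = folds)
}

## ---- Model persistence -----------------------------------------------------

#' Save a trained model as JSON
#'
#' Persists scaler arrays, the sparse weights (name -> value for nonzero
#' entries), the intercept, chosen C, the model specification and the fused
#' view list, so evaluation-time feature reconstruction is exact.
#'
#' @param model A `trained_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  nz <- model$weights[model$weights != 0]
  obj <- list(
    scaler = list(mean = as.list(model$scaler$mean),
                  sd = as.list(model$scaler$sd),
                  zero_variance_mask = as.list(model$scaler$zero_variance_mask)),
    weights = as.list(nz), intercept = model$intercept,
    chosen_C = model$chosen_C, feature_names = model$feature_names,
    spec = unclass(model$spec), view_defs = model$view_defs,
    converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trained model saved by [write_model_json()]
#'
#' @param path JSON file path.
#' @return A `trained_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  scaler <- structure(list(
    mean = unlist(obj$scaler$mean),
    sd = unlist(obj$scaler$sd),
    zero_variance_mask = unlist(obj$scaler$zero_variance_mask)),
    class = "scaler_params")
  weights <- stats::setNames(rep(0, length(obj$feature_names)),
                             unlist(obj$feature_names))
  nz <- unlist(obj$weights)
  weights[names(nz)] <- nz
  spec <- do.call(model_spec, c(
    list(C_grid = unlist(obj$spec$C_grid)),
    obj$spec[c("inner_folds", "max_iterations", "decision_boundary", "seed")]))
  view_defs <- lapply(obj$view_defs, function(d)
    list(op = d$op, left = d$left, right = d$right, name = d$name))
  structure(list(scaler = scaler, weights = weights,
                 intercept = obj$intercept, chosen_C = obj$chosen_C,
                 inner_cv_auc = NULL, spec = spec, view_defs = view_defs,
                 feature_names = unlist(obj$feature_names),
                 converged = obj$converged),
            class = "trained_model")
}
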