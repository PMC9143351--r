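## Feature construction: time-series fusion with redundancy pruning and a
## fixed statistical feature bank, aggregated per subject per activity.
##
## Each input channel is a "view" (a named univariate series). New views are
## generated by binary fusion operators (ratio, difference, sum, product) over
## ordered pairs of input views, in a fixed enumeration order; a candidate is
## retained only while its absolute Pearson correlation with every
## already-retained view stays below the threshold (default 0.99). The view
## list is determined once from training data and persisted as part of the
## model artifact so evaluation-time reconstruction is exact.

FUSION_OPS <- c("ratio", "difference", "sum", "product")

#' Fusion configuration
#'
#' @param corr_threshold Redundancy threshold in (0, 1]; a fused candidate is
#'   kept only if its absolute Pearson correlation with every retained view is
#'   strictly below this value (default 0.99).
#' @param operations Ordered subset of `ratio`, `difference`, `sum`,
#'   `product`.
#' @param max_generated Cap on the number of retained fused views
#'   (default 32).
#' @param ratio_eps_factor Ratio candidates whose denominator passes within
#'   `ratio_eps_factor * RMS(denominator)` of zero are skipped (default 1e-6).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(corr_threshold = 0.99, operations = FUSION_OPS,
                          max_generated = 32L, ratio_eps_factor = 1e-6) {
  if (!is_scalar_number(corr_threshold) || corr_threshold <= 0 ||
      corr_threshold > 1)
    stopf("corr_threshold must be in (0, 1]")
  operations <- match.arg(operations, FUSION_OPS, several.ok = TRUE)
  structure(list(corr_threshold = corr_threshold, operations = operations,
                 max_generated = as.integer(max_generated),
                 ratio_eps_factor = ratio_eps_factor),
            class = "fusion_config")
}

view_name <- function(op, left, right) sprintf("%s(%s,%s)", op, left, right)

apply_op <- function(op, x, y, eps_factor = 1e-6) {
  switch(op,
    sum = x + y,
    difference = x - y,
    product = x * y,
    ratio = {
      eps <- eps_factor * sqrt(mean(y^2))
      if (any(abs(y) < eps)) return(NULL)  # near-zero denominator: skip
      x / y
    },
    stopf("unknown fusion operation '%s'", op))
}

## deterministic candidate enumeration: for each operator in config order,
## all ordered pairs (i, j), i != j, of the input views
enumerate_candidates <- function(input_names, operations) {
  out <- list()
  for (op in operations) {
    for (i in input_names) {
      for (j in input_names) {
        if (i == j) next
        out[[length(out) + 1L]] <- list(op = op, left = i, right = j,
                                        name = view_name(op, i, j))
      }
    }
  }
  out
}

#' Fuse views with correlation-redundancy pruning
#'
#' Generates candidate series from the configured binary operators over
#' ordered pairs of the input views and keeps a candidate only if its maximum
#' absolute Pearson correlation with every already-retained view (inputs plus
#' previously retained candidates) is below `config$corr_threshold`. Ratio
#' candidates whose denominator passes near zero, and degenerate
#' (zero-variance or non-finite) candidates, are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param inputs Named list of equal-length numeric series (the input views).
#' @param config A [fusion_config()].
#' @return Named list of views (`inputs` followed by retained candidates) with
#'   attributes `"defs"` (the fused view definitions) and `"skipped"`.
#' @export
fuse_views <- function(inputs, config = fusion_config()) {
  lens <- vapply(inputs, length, 0L)
  if (length(unique(lens)) != 1L)
    stopf("all input views must have the same length")
  cands <- enumerate_candidates(names(inputs), config$operations)
  L <- lens[[1L]]
  retained <- inputs
  ## standardised columns of retained views for fast correlation
  zcol <- function(x) {
    s <- pop_sd(x)
    if (!is.finite(s) || s == 0) return(NULL)
    (x - mean(x)) / (s * sqrt(L))
  }
  Z <- vapply(inputs, function(x) zcol(x) %||% rep(0, L), numeric(L))
  defs <- list()
  skipped <- character(0)
  for (cand in cands) {
    if (length(defs) >= config$max_generated) break
    series <- apply_op(cand$op, inputs[[cand$left]], inputs[[cand$right]],
                       config$ratio_eps_factor)
    if (is.null(series) || !all(is.finite(series))) {
      skipped <- c(skipped, cand$name)
      next
    }
    z <- zcol(series)
    if (is.null(z)) {  # zero variance: redundant by definition
      skipped <- c(skipped, cand$name)
      next
    }
    ## threshold 1.0 is a vacuous filter: every well-defined candidate passes
    if (config$corr_threshold >= 1 ||
        max(abs(crossprod(Z, z))) < config$corr_threshold) {
      retained[[cand$name]] <- series
      defs[[length(defs) + 1L]] <- cand
      Z <- cbind(Z, z)
    }
  }
  attr(retained, "defs") <- defs
  attr(retained, "skipped") <- skipped
  retained
}

#' Determine the fused-view list from training strides
#'
#' Pruning is a property of the dataset, not of a single trial: per-channel
#' series are concatenated across all training strides and [fuse_views()] runs
#' on the concatenation. The returned definitions are reused verbatim for
#' evaluation data.
#'
#' @param strides List of `stride_window` objects (the training strides).
#' @param config A [fusion_config()].
#' @return List of fused view definitions (`op`, `left`, `right`, `name`).
#' @export
determine_view_defs <- function(strides, config = fusion_config()) {
  if (length(strides) == 0L) stopf("no strides to determine views from")
  inputs <- lapply(stats::setNames(nm = angle_channels()), function(ch) {
    unlist(lapply(strides, function(s) s$angles[, ch]), use.names = FALSE)
  })
  attr(fuse_views(inputs, config), "defs")
}

#' Apply persisted view definitions to one stride
#'
#' Rebuilds the full view set (9 input channels plus fused views) for a single
#' stride. At evaluation time a retained ratio view may hit a near-zero
#' denominator on new data; the denominator is then clamped to +/- eps so the
#' feature matrix never contains non-finite values (clamps are counted in the
#' `"clamped"` attribute).
#'
#' @param stride A `stride_window`.
#' @param defs View definitions from [determine_view_defs()].
#' @param eps_factor Denominator clamp scale (default 1e-6 of the RMS).
#' @return Named list of numeric series.
#' @export
apply_view_defs <- function(stride, defs, eps_factor = 1e-6) {
  views <- lapply(stats::setNames(nm = angle_channels()),
                  function(ch) stride$angles[, ch])
  clamped <- 0L
  for (d in defs) {
    x <- views[[d$left]]; y <- views[[d$right]]
    if (d$op == "ratio") {
      eps <- eps_factor * sqrt(mean(y^2))
      if (eps == 0) eps <- .Machine$double.eps
      bad <- abs(y) < eps
      if (any(bad)) {
        clamped <- clamped + 1L
        y[bad] <- eps * ifelse(y[bad] < 0, -1, 1)
      }
      views[[d$name]] <- x / y
    } else {
      views[[d$name]] <- apply_op(d$op, x, y)
    }
  }
  attr(views, "clamped") <- clamped
  views
}

## ---- Statistical feature bank ---------------------------------------------

FEATURE_BANK <- c("mean", "variance", "min", "max", "median", "range", "rms",
                  paste0("fourier_", 1:5),
                  "trend_slope", "trend_intercept", "trend_r")

#' The fixed statistical feature bank
#'
#' Simple statistics (mean, variance, min, max, median, range, RMS),
#' magnitudes of discrete Fourier coefficients 1-5 of the mean-subtracted
#' series (scaled by 2/n so a unit-amplitude sinusoid at a bin frequency has
#' magnitude ~1), and linear-trend statistics of value against normalised time
#' (slope, intercept, Pearson r). 15 features with stable names.
#'
#' @return Character vector of feature names.
#' @export
feature_bank <- function() FEATURE_BANK

#' Extract the feature bank from one series
#'
#' @param series Finite numeric series (a view).
#' @return Named numeric vector of length 15. For a constant series the trend
#'   slope and Pearson r are 0 and variance and Fourier magnitudes are 0.
#' @export
extract_features <- function(series) {
  if (!all(is.finite(series))) stopf("series contains non-finite values")
  drop(extract_features_matrix(matrix(series, ncol = 1L)))
}

## vectorised bank over the columns of a matrix (series in columns); this is
## the hot path when rebuilding features inside every cross-validation fold
extract_features_matrix <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  variance <- colMeans(ctr^2)
  mn <- apply(m, 2L, min)
  mx <- apply(m, 2L, max)
  med <- apply(m, 2L, median)
  rms <- sqrt(colMeans(m^2))
  fo <- Mod(stats::mvfft(ctr)[2:6, , drop = FALSE]) * 2 / n
  tt <- seq(0, 1, length.out = n)
  tc <- tt - mean(tt)
  vt <- mean(tc^2)
  slope <- colMeans(ctr * tc) / vt
  intercept <- mu - slope * mean(tt)
  sy <- sqrt(variance)
  r <- ifelse(sy > 0, slope * sqrt(vt) / sy, 0)
  slope[sy == 0] <- 0
  out <- rbind(mean = mu, variance = variance, min = mn, max = mx,
               median = med, range = mx - mn, rms = rms, fo,
               trend_slope = slope, trend_intercept = intercept, trend_r = r)
  rownames(out) <- FEATURE_BANK
  out
}

## ---- Feature matrix --------------------------------------------------------

#' Build the per subject-activity-timepoint feature matrix
#'
#' Per stride, the persisted views are rebuilt and the feature bank extracted;
#' feature vectors are then averaged per (subject, activity, timepoint).
#' Controls contribute both legs; patients contribute only the affected side
#' (strides from the unaffected side are excluded with a warning). When
#' `view_defs` is `NULL` the fused-view list is first determined from the
#' given (training) strides.
#'
#' @param strides List of `stride_window` objects.
#' @param profiles Named list of subject profiles (for group/affected side).
#' @param config A [fusion_config()].
#' @param view_defs Persisted view definitions; `NULL` to determine them from
#'   `strides` (training mode).
#' @return A `feature_matrix`: numeric matrix `values` (rows in deterministic
#'   order, columns named `view__feature`), data frame `meta`, plus
#'   `view_defs` and `config`.
#' @export
build_feature_matrix <- function(strides, profiles, config = fusion_config(),
                                 view_defs = NULL) {
  for (s in strides) {
    if (is.null(profiles[[s$subject_id]]))
      stopf("stride subject '%s' missing from profiles", s$subject_id)
  }
  ## side rule: controls both legs, patients affected side only
  eligible <- vapply(strides, function(s) {
    p <- profiles[[s$subject_id]]
    p$group == "control" || identical(s$side, p$affected_side)
  }, TRUE)
  if (any(!eligible)) {
    warnf("excluding %d unaffected-side stride(s) of patients",
          sum(!eligible))
    strides <- strides[eligible]
  }
  if (length(strides) == 0L) stopf("no eligible strides")
  if (is.null(view_defs)) view_defs <- determine_view_defs(strides, config)

  all_views <- c(angle_channels(), vapply(view_defs, `[[`, "", "name"))
  feat_names <- as.vector(outer(FEATURE_BANK, all_views,
                                function(f, v) paste0(v, "__", f)))
  per_stride <- vapply(strides, function(s) {
    views <- apply_view_defs(s, view_defs)
    as.vector(extract_features_matrix(
      vapply(all_views, function(v) views[[v]], numeric(nrow(s$angles)))))
  }, numeric(length(feat_names)))
  rownames(per_stride) <- feat_names

  key <- vapply(strides, function(s)
    paste(s$subject_id, s$activity, s$timepoint, sep = "|"), "")
  ord <- sort(unique(key))
  values <- t(vapply(ord, function(k) {
    rowMeans(per_stride[, key == k, drop = FALSE])
  }, numeric(length(feat_names))))
  parts <- do.call(rbind, strsplit(ord, "|", fixed = TRUE))
  meta <- data.frame(subject_id = parts[, 1L], activity = parts[, 2L],
                     timepoint = parts[, 3L],
                     group = vapply(parts[, 1L],
                                    function(id) profiles[[id]]$group, ""),
                     n_strides = as.integer(table(key)[ord]),
                     row.names = NULL)
  structure(list(values = values, meta = meta, view_defs = view_defs,
                 config = config),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d rows x %d features (%d views x %d bank)\n",
              nrow(x$values), ncol(x$values),
              length(angle_channels()) + length(x$view_defs),
              length(FEATURE_BANK)))
  invisible(x)
}

#' Subset the rows of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param rows Logical or integer row index into `fm$meta`.
#' @return A `feature_matrix` with the selected rows.
#' @export
subset_rows <- function(fm, rows) {
  fm$values <- fm$values[rows, , drop = FALSE]
  fm$meta <- fm$meta[rows, , drop = FALSE]
  rownames(fm$meta) <- NULL
  fm
}
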