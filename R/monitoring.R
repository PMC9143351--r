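## Longitudinal deployment of a trained model and its relation to
## patient-reported functioning.
##
## A trained model applied at successive post-operative timepoints yields a
## per-subject trajectory of the probability of belonging to the TKA class.
## Recovery is then related to the KOOS-ADL score via (a) a group-level
## Spearman correlation of 6-week -> 12-month change scores and (b) individual
## Spearman correlations over the post-operative timepoints, banded
## weak/fair/moderate/strong at |rho| cut-points 0.25 / 0.5 / 0.75.

DEPLOY_TIMEPOINTS <- list(pre_trained = c("w6", "m3", "m6", "m12"),
                          w6_trained = c("w6", "m3", "m6", "m12"))

#' Deploy a trained model across post-operative timepoints
#'
#' Scores every patient row of a feature matrix built with the model's
#' persisted view list. For the `w6_trained` variant the 6-week scores are
#' in-sample (the model was trained on them) and flagged as such; true
#' deployment points are the later timepoints. Missing activity-timepoints
#' (dropouts, subjects unable to negotiate stairs) are simply absent and
#' render as gaps downstream — no imputation anywhere.
#'
#' @param model A `trained_model`.
#' @param features A `feature_matrix` with patient rows at post-operative
#'   timepoints (built with `model$view_defs`).
#' @param variant `"pre_trained"` or `"w6_trained"`.
#' @return A `recovery_trajectories` data frame: `subject_id`, `activity`,
#'   `timepoint`, `p_tka`, `in_sample`; attribute `"variant"`.
#' @export
deploy_over_time <- function(model, features, variant = c("w6_trained",
                                                          "pre_trained")) {
  variant <- match.arg(variant)
  if (!identical(
    vapply(features$view_defs, `[[`, "", "name"),
    vapply(model$view_defs, `[[`, "", "name")))
    stopf("feature matrix was not built with the model's persisted view list")
  keep <- features$meta$timepoint %in% DEPLOY_TIMEPOINTS[[variant]] &
    features$meta$group == "patient"
  fm <- subset_rows(features, keep)
  if (nrow(fm$meta) == 0L) stopf("no deployable patient rows in `features`")
  sc <- predict_probability(model, fm)
  sc$in_sample <- variant == "w6_trained" & sc$timepoint == "w6"
  sc <- sc[order(sc$subject_id, match(sc$timepoint, timepoints())), ]
  rownames(sc) <- NULL
  structure(sc[, c("subject_id", "activity", "timepoint", "p_tka",
                   "in_sample")],
            class = c("recovery_trajectories", "data.frame"),
            variant = variant)
}

traj_lookup <- function(trajs, subject, tp) {
  v <- trajs$p_tka[trajs$subject_id == subject & trajs$timepoint == tp]
  if (length(v) == 1L) v else NA_real_
}

prom_lookup <- function(proms, subject, tp) {
  pr <- proms[[subject]]
  if (is.null(pr)) return(NA_real_)
  pr$koos_adl[[tp]] %||% NA_real_
}

#' Change scores between 6 weeks and 12 months
#'
#' Simple differences `p_tka(m12) - p_tka(w6)` and `KOOS(m12) - KOOS(w6)`,
#' computed only for subjects observed at both endpoints; the rest are listed
#' in the `"excluded"` attribute.
#'
#' @param trajs A `recovery_trajectories` data frame.
#' @param proms Named list of PROM trajectories (from a cohort).
#' @return Data frame `subject_id`, `delta_p`, `delta_koos`; attribute
#'   `"excluded"`.
#' @export
compute_change_scores <- function(trajs, proms) {
  subjects <- sort(unique(trajs$subject_id))
  rows <- lapply(subjects, function(id) {
    dp <- traj_lookup(trajs, id, "m12") - traj_lookup(trajs, id, "w6")
    dk <- prom_lookup(proms, id, "m12") - prom_lookup(proms, id, "w6")
    data.frame(subject_id = id, delta_p = dp, delta_koos = dk)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$delta_p) & is.finite(out$delta_koos)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- out$subject_id[!ok]
  res
}

#' Group-level Spearman correlation of change scores
#'
#' @param changes Output of [compute_change_scores()] (>= 3 subjects).
#' @return List `rho`, `p` (two-sided; average ranks for ties), `n`.
#' @export
group_correlation <- function(changes) {
  n <- nrow(changes)
  if (n < 3L) stopf("need >= 3 subjects with both endpoints (got %d)", n)
  ct <- suppressWarnings(
    cor.test(changes$delta_p, changes$delta_koos, method = "spearman",
             exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Strength band of a correlation coefficient
#'
#' Applied to |rho|: weak [0, 0.25), fair [0.25, 0.5), moderate [0.5, 0.75),
#' strong [0.75, 1]. Every rho in [-1, 1] maps to exactly one band.
#'
#' @param rho Correlation coefficient(s) in [-1, 1].
#' @return Character vector of bands.
#' @export
correlation_band <- function(rho) {
  a <- abs(rho)
  if (any(a > 1 + 1e-12, na.rm = TRUE)) stopf("|rho| must be <= 1")
  as.character(cut(pmin(a, 1), breaks = c(0, 0.25, 0.5, 0.75, 1),
                   labels = c("weak", "fair", "moderate", "strong"),
                   include.lowest = TRUE, right = FALSE))
}

#' Individual Spearman correlations of probability against KOOS-ADL
#'
#' Per subject, the Spearman rank correlation between the TKA-class
#' probability and the KOOS-ADL score over the shared post-operative
#' timepoints (at most 4: 6 weeks, 3, 6, 12 months). Subjects with fewer than
#' `min_points` shared points are flagged `insufficient`; subjects whose
#' probability or KOOS has zero rank variance are flagged `undefined`. With
#' n = 4 the support of rho is coarse and p-values are unreliable, so none are
#' reported here.
#'
#' @param trajs A `recovery_trajectories` data frame.
#' @param proms Named list of PROM trajectories.
#' @param tps Timepoints to use (default `w6`, `m3`, `m6`, `m12`).
#' @param min_points Minimum shared points (default 3).
#' @return Data frame `subject_id`, `rho`, `n_points`, `band`, `status`
#'   (`ok`/`insufficient`/`undefined`).
#' @export
individual_correlations <- function(trajs, proms,
                                    tps = c("w6", "m3", "m6", "m12"),
                                    min_points = 3L) {
  subjects <- sort(unique(trajs$subject_id))
  rows <- lapply(subjects, function(id) {
    p <- vapply(tps, function(tp) traj_lookup(trajs, id, tp), 0)
    k <- vapply(tps, function(tp) prom_lookup(proms, id, tp), 0)
    ok <- is.finite(p) & is.finite(k)
    if (sum(ok) < min_points)
      return(data.frame(subject_id = id, rho = NA_real_,
                        n_points = sum(ok), band = NA_character_,
                        status = "insufficient"))
    if (pop_sd(rank(p[ok])) == 0 || pop_sd(rank(k[ok])) == 0)
      return(data.frame(subject_id = id, rho = NA_real_,
                        n_points = sum(ok), band = NA_character_,
                        status = "undefined"))
    rho <- cor(p[ok], k[ok], method = "spearman")
    data.frame(subject_id = id, rho = rho, n_points = sum(ok),
               band = correlation_band(rho), status = "ok")
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full correlation report
#'
#' Bundles the group change-score correlation with the individual
#' longitudinal correlations and the band shares.
#'
#' @param trajs A `recovery_trajectories` data frame.
#' @param proms Named list of PROM trajectories.
#' @return A `correlation_report` list: `group` (rho, p, n), `individual`
#'   (data frame), `band_shares` (fraction of banded subjects per band).
#' @export
correlation_report <- function(trajs, proms) {
  changes <- compute_change_scores(trajs, proms)
  grp <- group_correlation(changes)
  ind <- individual_correlations(trajs, proms)
  banded <- ind$band[ind$status == "ok"]
  shares <- vapply(c("weak", "fair", "moderate", "strong"),
                   function(b) mean(banded == b), 0)
  structure(list(group = grp, individual = ind, band_shares = shares,
                 excluded_from_changes = attr(changes, "excluded")),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("group change-score Spearman rho = %.3f (p = %.3f, n = %d)\n",
              x$group$rho, x$group$p, x$group$n))
  ok <- x$individual$status == "ok"
  cat(sprintf("individual correlations: %d subjects, median rho %.2f\n",
              sum(ok), median(x$individual$rho[ok])))
  cat("band shares:",
      paste(sprintf("%s %.0f%%", names(x$band_shares),
                    100 * x$band_shares), collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap table of probability trajectories
#'
#' Subjects x timepoints matrix of `p_tka` with `NA` as the explicit gap
#' marker (a missing trial never produces a number); subjects ordered by id.
#' This is the tabular form of the recovery heatmap — plotting is left to the
#' caller.
#'
#' @param trajs A `recovery_trajectories` data frame.
#' @param tps Timepoint columns (default `w6`, `m3`, `m6`, `m12`).
#' @return Data frame with `subject_id` and one column per timepoint.
#' @export
export_heatmap_table <- function(trajs, tps = c("w6", "m3", "m6", "m12")) {
  subjects <- sort(unique(trajs$subject_id))
  out <- data.frame(subject_id = subjects)
  for (tp in tps)
    out[[tp]] <- vapply(subjects, function(id) traj_lookup(trajs, id, tp), 0)
  out
}
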