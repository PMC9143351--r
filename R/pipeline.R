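## Reproducible end-to-end pipeline: simulate -> segment -> features ->
## train (2 variants x 3 activities) -> monitor, with a run manifest.

#' Pipeline configuration
#'
#' A fully serialisable nested list of every tunable parameter; its hash is
#' recorded in the run manifest so any output artifact can be traced to the
#' exact configuration. All randomness derives from the single `seed`.
#'
#' @param seed Master seed (default 42).
#' @param cohort Named list of [generate_cohort()] arguments.
#' @param segmentation Named list: `cutoff_hz`, `min_step_interval`,
#'   `min_stride_interval`, `normalize_points`.
#' @param fusion Named list of [fusion_config()] arguments.
#' @param model Named list of [model_spec()] arguments (seed is derived).
#' @param loocv_activities Activities to evaluate leave-one-subject-out
#'   (default `"walk"`; stairs models are trained and deployed but LOOCV on
#'   them is optional because it dominates the runtime).
#' @param write_signals,write_strides Write the (large) raw-signal and stride
#'   CSVs (default `FALSE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, cohort = list(),
                            segmentation = list(), fusion = list(),
                            model = list(), loocv_activities = "walk",
                            write_signals = FALSE, write_strides = FALSE) {
  seg_defaults <- list(cutoff_hz = 6, min_step_interval = 0.4,
                       min_stride_interval = 0.6, normalize_points = 101L)
  structure(list(
    seed = as.integer(seed), cohort = cohort,
    segmentation = modifyList(seg_defaults, segmentation),
    fusion = fusion, model = model,
    loocv_activities = loocv_activities,
    write_signals = isTRUE(write_signals),
    write_strides = isTRUE(write_strides)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Select the training strides for a model variant
#'
#' Variant `pre_trained` trains on controls plus patients pre-operatively;
#' `w6_trained` on controls plus patients at 6 weeks post-TKA.
#'
#' @param strides List of `stride_window` objects.
#' @param activity Activity to model.
#' @param variant `"pre_trained"` or `"w6_trained"`.
#' @return Sub-list of `strides`.
#' @export
training_strides <- function(strides, activity,
                             variant = c("w6_trained", "pre_trained")) {
  variant <- match.arg(variant)
  tp <- if (variant == "pre_trained") "pre" else "w6"
  keep <- vapply(strides, function(s) {
    s$activity == activity && s$timepoint %in% c(tp, "control_single")
  }, TRUE)
  strides[keep]
}

#' Write a feature matrix as CSV plus a JSON sidecar
#'
#' The sidecar carries the fused view list, the fusion configuration, the
#' feature-bank version and the config hash, so the matrix can be
#' reconstructed exactly at evaluation time.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path (`<path>.json` is written alongside).
#' @return Invisibly, the CSV path.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  write.csv(cbind(fm$meta, as.data.frame(fm$values, check.names = FALSE)),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(view_defs = fm$view_defs, config = unclass(fm$config),
         feature_bank = feature_bank()),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage %s: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, segments every trial, and per activity and
#' training variant (pre-operative / 6 weeks post-operative) determines the
#' fused-view list, trains the tuned L1 logistic model, optionally evaluates
#' it leave-one-subject-out, deploys it over the post-operative timepoints and
#' writes the probability heatmap table. For the 6-week walking model — the
#' variant usable for recovery monitoring — the correlation report against
#' KOOS-ADL is produced. All artifacts plus an atomically-written manifest
#' (config hash, file checksums, collected warnings) land in `out_dir`;
#' rerunning with the same config reproduces identical numbers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  outputs <- character(0)

  withCallingHandlers({
    cohort <- stage("simulate", do.call(generate_cohort, modifyList(
      list(seed = derive_seed(config$seed, "cohort")), config$cohort)))
    if (config$write_signals)
      outputs <- c(outputs, write_cohort_csv(cohort, file.path(out_dir, "cohort")))
    else {
      dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE)
      meta <- do.call(rbind, lapply(cohort$profiles, function(p)
        data.frame(subject_id = p$subject_id, group = p$group,
                   affected_side = p$affected_side,
                   dropout_after = p$dropout_after %||% NA_character_)))
      mp <- file.path(out_dir, "cohort", "subjects.csv")
      write.csv(meta, mp, row.names = FALSE)
      pp <- file.path(out_dir, "cohort", "koos_adl.csv")
      write.csv(do.call(rbind, lapply(cohort$proms, function(pr)
        data.frame(subject_id = pr$subject_id, timepoint = names(pr$koos_adl),
                   koos_adl = unlist(pr$koos_adl, use.names = FALSE)))),
        pp, row.names = FALSE)
      outputs <- c(outputs, mp, pp)
    }

    seg <- config$segmentation
    strides <- stage("segment", segment_cohort(
      cohort, cutoff = seg$cutoff_hz, n_points = seg$normalize_points,
      min_step_interval = seg$min_step_interval,
      min_stride_interval = seg$min_stride_interval))
    if (config$write_strides) {
      sp <- file.path(out_dir, "strides.csv")
      long <- do.call(rbind, lapply(strides, function(s)
        data.frame(subject_id = s$subject_id, activity = s$activity,
                   timepoint = s$timepoint, side = s$side,
                   pct = seq(0, 100, length.out = nrow(s$angles)),
                   as.data.frame(s$angles))))
      write.csv(long, sp, row.names = FALSE)
      outputs <- c(outputs, sp)
    }

    fus_cfg <- do.call(fusion_config, config$fusion)
    labels <- subject_labels(cohort$profiles)
    results <- list()
    acts <- intersect(activities(), cohort$params$acts)
    for (act in acts) {
      for (variant in c("pre_trained", "w6_trained")) {
        tag <- sprintf("%s_%s", act, variant)
        tr_strides <- training_strides(strides, act, variant)
        subj <- unique(vapply(tr_strides, `[[`, "", "subject_id"))
        if (length(unique(labels[subj])) < 2L)
          stage(paste0("train/", tag),
                stopf("training set contains a single class"))
        spec <- do.call(model_spec, modifyList(
          list(seed = derive_seed(config$seed, "model", tag)), config$model))
        fm_train <- stage(paste0("features/", tag),
                          build_feature_matrix(tr_strides, cohort$profiles,
                                               fus_cfg))
        outputs <- c(outputs, write_feature_matrix_csv(
          fm_train, file.path(out_dir, sprintf("features_%s.csv", tag))))
        model <- stage(paste0("train/", tag), tune_and_train(
          fm_train, labels[fm_train$meta$subject_id], spec,
          view_defs = fm_train$view_defs))
        mp <- file.path(out_dir, sprintf("model_%s.json", tag))
        write_model_json(model, mp)
        outputs <- c(outputs, mp)

        acc <- NA_real_
        if (act %in% config$loocv_activities) {
          cv <- stage(paste0("evaluate/", tag), loocv_evaluate(
            tr_strides, labels, spec, profiles = cohort$profiles,
            config = fus_cfg))
          acc <- cv$accuracy
          ap <- file.path(out_dir, sprintf("loocv_%s.csv", tag))
          write.csv(cv$scores, ap, row.names = FALSE)
          outputs <- c(outputs, ap)
        }

        post <- vapply(strides, function(s) {
          s$activity == act &&
            s$timepoint %in% c("w6", "m3", "m6", "m12")
        }, TRUE)
        trajs <- NULL
        if (any(post)) {
          fm_post <- stage(paste0("monitor/", tag), build_feature_matrix(
            strides[post], cohort$profiles, fus_cfg,
            view_defs = model$view_defs))
          trajs <- deploy_over_time(model, fm_post, variant)
          hp <- file.path(out_dir, sprintf("heatmap_%s.csv", tag))
          write.csv(export_heatmap_table(trajs), hp, row.names = FALSE,
                    na = "")
          outputs <- c(outputs, hp)
        }
        m12 <- if (!is.null(trajs)) trajs$p_tka[trajs$timepoint == "m12"]
               else numeric(0)
        results[[tag]] <- list(
          accuracy = acc, chosen_C = model$chosen_C,
          n_views = length(angle_channels()) + length(model$view_defs),
          ## share of patients whose gait is classified asymptomatic at 12
          ## months (probability below the 0.5 boundary)
          asymptomatic_m12 = if (length(m12)) mean(m12 < 0.5) else NA_real_)

        if (act == "walk" && variant == "w6_trained" && !is.null(trajs)) {
          rep <- stage("monitor/correlations",
                       correlation_report(trajs, cohort$proms))
          cp <- file.path(out_dir, "correlation_report.json")
          jsonlite::write_json(
            list(group = rep$group,
                 individual = rep$individual,
                 band_shares = as.list(rep$band_shares),
                 excluded_from_changes = rep$excluded_from_changes),
            cp, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
          outputs <- c(outputs, cp)
          results[[tag]]$group_rho <- rep$group$rho
        }
      }
    }
  }, warning = note)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitrecover")),
    config = unclass(config), config_hash = config_hash(config),
    results = results,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))),
    warnings = warnings_log)
  tmp <- file.path(out_dir, ".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))  # atomic at run end
  invisible(manifest)
}
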