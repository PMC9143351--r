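## Seeded synthetic cohort: gait signals + patient-reported outcomes.
##
## No public TKA gait dataset exists (clinical motion data falls under GDPR),
## so the package ships a generator that emulates the statistical structure
## the analysis assumes: smooth periodic joint-angle templates (<= 4 harmonics
## per channel), severity-scaled deviations acting on range, offset, timing
## and left-right asymmetry, acceleration channels with planted gait events,
## and KOOS-ADL trajectories stochastically coupled to the latent gait
## deviation. Ground truth (event indices, noise-free templates) is stored on
## each trial so segmentation and monitoring can be tested against planted
## truth.

SAMPLE_RATE <- 60  # Hz, typical IMU suit output

## per-channel harmonic templates for level walking (degrees);
## amplitudes/offsets are published-plausible, not subject-specific
.template_params <- list(
  spine_lat_bending  = list(a0 = 0,  amp = c(3, 1),        ph = c(0.3, 2.2)),
  spine_flex_ext     = list(a0 = 5,  amp = c(2, 1),        ph = c(1.4, 0.0)),
  spine_rotation     = list(a0 = 0,  amp = c(4, 1.5),      ph = c(2.0, 0.6)),
  hip_flex_ext       = list(a0 = 10, amp = c(20, 4, 1),    ph = c(0.2, 1.0, 2.1)),
  hip_abd_add        = list(a0 = 2,  amp = c(5, 2),        ph = c(0.5, 1.7)),
  hip_rotation       = list(a0 = 0,  amp = c(6, 2),        ph = c(3.0, 0.0)),
  knee_flex_ext      = list(a0 = 25, amp = c(15, 12, 3),   ph = c(2.6, 0.8, 1.5)),
  knee_abd_add       = list(a0 = 1,  amp = c(3, 1.5),      ph = c(1.0, 2.0)),
  ankle_dorsi_plantar = list(a0 = 0, amp = c(8, 6, 2),     ph = c(1.2, 2.9, 0.0))
)

## activity modifiers: stair negotiation uses larger knee/hip excursions
.activity_mods <- list(
  walk       = list(amp = c(knee_flex_ext = 1.0),  off = c(knee_flex_ext = 0)),
  stairs_up  = list(amp = c(knee_flex_ext = 1.6, hip_flex_ext = 1.4,
                            ankle_dorsi_plantar = 1.2),
                    off = c(knee_flex_ext = 10, hip_flex_ext = 8)),
  stairs_down = list(amp = c(knee_flex_ext = 1.4, ankle_dorsi_plantar = 1.5,
                             hip_flex_ext = 0.9),
                     off = c(knee_flex_ext = 5))
)

## how strongly the latent severity deforms each channel
.severity_weights <- c(
  spine_lat_bending = 0.3, spine_flex_ext = 0.3, spine_rotation = 0.3,
  hip_flex_ext = 0.6, hip_abd_add = 0.4, hip_rotation = 0.3,
  knee_flex_ext = 1.0, knee_abd_add = 0.4, ankle_dorsi_plantar = 0.5
)

## deviation scale constants (per unit of effect_size * severity * weight)
.SEV_AMP <- 0.15      # fractional range reduction
.SEV_OFFSET <- 2.0    # degrees of offset shift
.SEV_TIMING <- 0.04   # cycle fraction of timing shift
.CONTRA_W <- 0.4      # contralateral side receives this fraction of the deviation

#' Noise-free joint-angle template
#'
#' Evaluates the class-neutral periodic template (sum of at most 4 harmonics
#' per channel, activity-modified) at the given stride phases, optionally with
#' a subject's stable individual modifications but no severity deviation.
#'
#' @param activity One of [activities()].
#' @param phase Numeric vector of stride phases (1 unit = one gait cycle).
#' @param mods Optional per-subject template modification list with `amp`,
#'   `ph`, `off` (numeric vectors named by channel), as stored in a
#'   [subject profile][generate_cohort].
#' @return Matrix `length(phase)` x 9, columns [angle_channels()], degrees.
#' @export
angle_template <- function(activity, phase, mods = NULL) {
  activity <- match.arg(activity, activities())
  am <- .activity_mods[[activity]]
  out <- vapply(angle_channels(), function(ch) {
    p <- .template_params[[ch]]
    ascale <- (am$amp[ch] %||% NA)
    if (is.na(ascale)) ascale <- 1
    aoff <- am$off[ch] %||% NA
    if (is.na(aoff)) aoff <- 0
    jamp <- if (is.null(mods)) 1 else mods$amp[ch]
    jph <- if (is.null(mods)) 0 else mods$ph[ch]
    joff <- if (is.null(mods)) 0 else mods$off[ch]
    y <- rep(p$a0 + aoff + joff, length(phase))
    for (k in seq_along(p$amp)) {
      y <- y + p$amp[k] * ascale * jamp *
        cos(2 * pi * k * phase + p$ph[k] + jph)
    }
    y
  }, numeric(length(phase)))
  out
}

## smooth (< 6 Hz) additive noise so the kinematic low-pass filter cannot
## trivially remove it
smooth_noise <- function(n, sd_raw, sample_rate = SAMPLE_RATE, cutoff = 5) {
  if (sd_raw <= 0) return(rep(0, n))
  lowpass_filter(rnorm(n, 0, sd_raw), sample_rate, cutoff)
}

gauss_bumps <- function(n, centers, amps, width) {
  y <- rep(0, n)
  t <- seq_len(n)
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-0.5 * ((t - centers[i]) / width)^2)
  }
  y
}

#' Generate one kinematic trial
#'
#' Builds a multichannel 60 Hz recording of one repetition of an activity:
#' nine joint-angle channels (template + severity-scaled deviation + smooth
#' noise), pelvis anterior-posterior and medio-lateral acceleration with one
#' dominant peak per step, and per-leg tibia axial acceleration with a local
#' minimum followed by a local maximum at every stride boundary. Severity
#' reduces channel range, shifts offsets and peak timing, and acts more
#' strongly on the affected side. Ground-truth event indices and the
#' noise-free template are stored for oracle tests.
#'
#' @param profile A subject profile (see [generate_cohort()]).
#' @param activity One of [activities()].
#' @param timepoint A timepoint the profile has severity for.
#' @param n_cycles Number of gait cycles (>= 5 so a middle stride exists;
#'   default 8).
#' @param seed Integer seed; identical arguments and seed give identical
#'   trials.
#' @param effect_size Scale of the class deviation (>= 0).
#' @param noise_sd Raw angle-noise standard deviation in degrees before
#'   low-pass shaping (default 1.5).
#' @return A `kinematic_trial` list: metadata, `angles` (list `left`/`right`
#'   of n x 9 matrices, one per leg), `accel_ap`, `accel_ml`, `tibia_accel_x`
#'   (list left/right), `true_events`, `template` (per-leg noise-free
#'   templates).
#' @export
generate_trial <- function(profile, activity, timepoint, n_cycles = 8L,
                           seed = 1L, effect_size = 1.5, noise_sd = 1.5) {
  activity <- match.arg(activity, activities())
  if (n_cycles < 5L) stopf("n_cycles must be >= 5 (got %d)", n_cycles)
  sev <- profile$latent_severity[[timepoint]]
  if (is.null(sev))
    stopf("profile %s has no timepoint '%s'", profile$subject_id, timepoint)
  set.seed(seed)
  fs <- SAMPLE_RATE
  ## severity slows gait, but only as part of the class effect: at
  ## effect_size = 0 patients must be exchangeable with controls
  cad <- profile$cadence_hz * (1 - clip(0.075 * effect_size * sev, 0, 0.5))
  stride_len <- round(2 * fs / cad)                   # samples per stride
  pad <- round(stride_len / 2)
  n <- 2L * pad + n_cycles * stride_len
  phase <- (seq_len(n) - pad - 1) / stride_len

  ## planted steps: two per cycle, alternating sides, affected side first
  step_idx <- pad + 1L + round((0:(2L * n_cycles - 1L)) * stride_len / 2)
  side0 <- if (profile$affected_side %in% c("left", "right"))
    profile$affected_side else "left"
  side1 <- if (side0 == "left") "right" else "left"
  step_sides <- rep(c(side0, side1), n_cycles)
  stride_bounds <- lapply(c(left = "left", right = "right"), function(sd) {
    si <- step_idx[step_sides == sd]
    cbind(start = si[-length(si)], end = si[-1L])
  })

  ## per-leg joint angles: each leg's channels follow the canonical cycle
  ## relative to that leg's own steps (the contralateral leg is half a cycle
  ## out of phase). The affected leg carries the full severity deviation, the
  ## contralateral leg a fixed fraction of it.
  mods <- profile$template_mods
  am <- .activity_mods[[activity]]
  leg_phase <- list(left = phase, right = phase)
  leg_phase[[side1]] <- phase - 0.5
  leg_w <- c(left = 1, right = 1)
  if (profile$affected_side %in% c("left", "right"))
    leg_w[setdiff(c("left", "right"), profile$affected_side)] <- .CONTRA_W
  template <- lapply(leg_phase, function(ph) angle_template(activity, ph, mods))
  angles <- template
  for (leg in c("left", "right")) {
    if (sev > 0 && effect_size > 0) {
      for (ch in angle_channels()) {
        dev <- effect_size * sev * .severity_weights[[ch]] * leg_w[[leg]]
        p <- .template_params[[ch]]
        ascale <- am$amp[ch] %||% NA; if (is.na(ascale)) ascale <- 1
        aoff <- am$off[ch] %||% NA; if (is.na(aoff)) aoff <- 0
        jamp <- mods$amp[ch] %||% 1; jph <- mods$ph[ch] %||% 0
        joff <- mods$off[ch] %||% 0
        amp_shrink <- clip(.SEV_AMP * dev, 0, 0.8)
        y <- rep(p$a0 + aoff + joff + .SEV_OFFSET * dev, n)
        for (k in seq_along(p$amp)) {
          y <- y + p$amp[k] * ascale * jamp * (1 - amp_shrink) *
            cos(2 * pi * k * (leg_phase[[leg]] - .SEV_TIMING * dev) +
                  p$ph[k] + jph)
        }
        angles[[leg]][, ch] <- y
      }
    }
    for (ch in angle_channels())
      angles[[leg]][, ch] <- angles[[leg]][, ch] + smooth_noise(n, noise_sd)
  }

  ## accelerations with planted events
  amp_jit <- runif(length(step_idx), -0.3, 0.3)
  accel_ap <- 0.3 * sin(2 * pi * phase) +
    gauss_bumps(n, step_idx, 3 + amp_jit, 2) + smooth_noise(n, 0.15)
  ml_sign <- ifelse(step_sides == "right", 1, -1)
  accel_ml <- gauss_bumps(n, step_idx, 1.5 * ml_sign, 3) + smooth_noise(n, 0.1)
  tibia <- lapply(c(left = "left", right = "right"), function(sd) {
    bnd <- step_idx[step_sides == sd]
    0.15 * sin(2 * pi * phase + 1) +
      gauss_bumps(n, bnd - 4L, rep(-3, length(bnd)), 1.5) +
      gauss_bumps(n, bnd, rep(4, length(bnd)), 1.5) +
      smooth_noise(n, 0.08)
  })

  structure(list(
    subject_id = profile$subject_id, activity = activity,
    timepoint = timepoint, side = profile$affected_side,
    sample_rate = fs, angles = angles,
    accel_ap = accel_ap, accel_ml = accel_ml, tibia_accel_x = tibia,
    true_events = list(steps = step_idx, step_sides = step_sides,
                       strides = stride_bounds),
    template = template, severity = sev, n_cycles = n_cycles
  ), class = "kinematic_trial")
}

#' Mean absolute gait deviation of a trial from its template
#'
#' Scalar summary used by generator property tests: the mean absolute
#' difference between the recorded angle channels and the subject's noise-free
#' class-neutral template, averaged over all samples, channels and both legs.
#' Strictly increasing in latent severity for a fixed seed.
#'
#' @param trial A `kinematic_trial`.
#' @return Numeric scalar, degrees.
#' @export
gait_deviation <- function(trial) {
  mean(c(abs(trial$angles$left - trial$template$left),
         abs(trial$angles$right - trial$template$right)))
}

## ---- Cohort ----------------------------------------------------------------

make_profile <- function(subject_id, group, seed, prop_nonrecovering) {
  set.seed(seed)
  affected <- if (group == "patient") sample(c("left", "right"), 1L) else "none"
  cadence <- clip(rnorm(1, 1.8, 0.08), 1.5, 2.1)
  nch <- length(angle_channels())
  mods <- list(
    amp = stats::setNames(1 + rnorm(nch, 0, 0.06), angle_channels()),
    ph = stats::setNames(rnorm(nch, 0, 0.08), angle_channels()),
    off = stats::setNames(rnorm(nch, 0, 1.5), angle_channels())
  )
  if (group == "control") {
    sev <- list(control_single = 0)
    recovering <- NA
  } else {
    recovering <- runif(1) >= prop_nonrecovering
    pre <- runif(1, 0.6, 0.9)
    w6 <- runif(1, 0.6, 0.9)
    if (recovering) {
      m3 <- w6 * runif(1, 0.5, 0.75)
      m6 <- m3 * runif(1, 0.55, 0.8)
      m12 <- m6 * runif(1, 0.55, 0.85)
    } else {
      m3 <- m6 <- m12 <- w6
    }
    sev <- list(pre = pre, w6 = w6, m3 = m3, m6 = m6, m12 = m12)
  }
  structure(list(subject_id = subject_id, group = group,
                 affected_side = affected, latent_severity = sev,
                 cadence_hz = cadence, template_mods = mods,
                 recovering = recovering, dropout_after = NULL,
                 stairs_capable = NULL),
            class = "subject_profile")
}

patient_timepoints_present <- function(profile) {
  tps <- timepoints(patients_only = TRUE)
  if (is.null(profile$dropout_after)) return(tps)
  tps[seq_len(match(profile$dropout_after, tps))]
}

#' Generate a seeded synthetic cohort
#'
#' Emulates the study design the pipeline targets: `n_controls` asymptomatic
#' controls with a single evaluation and `n_patients` people with unilateral
#' knee osteoarthritis evaluated pre-operatively and at 6 weeks, 3, 6 and
#' 12 months after total knee arthroplasty. By default one patient drops out
#' after the pre-operative visit and one before 12 months, and one third of
#' the patients cannot negotiate stairs at 6 weeks. KOOS-ADL is generated as
#' `100 * (1 - latent_severity)` plus Gaussian noise weighted by
#' `1 - coupling` (so `coupling = 1` is a deterministic link), clipped to
#' [0, 100].
#'
#' @param n_controls,n_patients Group sizes (each >= 2).
#' @param effect_size Scale of the patient gait deviation (>= 0; 0 makes the
#'   groups exchangeable up to noise).
#' @param coupling Strength of the PROM-gait link in [0, 1].
#' @param seed Master seed; all trial/profile randomness derives from it.
#' @param acts Activities to generate (default all three).
#' @param n_cycles Gait cycles per trial (default 8).
#' @param stairs_incapable_frac Fraction of patients unable to do stairs at 6
#'   weeks (default 1/3).
#' @param prop_nonrecovering Probability of a constant-severity
#'   (non-recovering) patient profile (default 0).
#' @param n_dropouts Integer vector of length 2: patients dropping out after
#'   the pre-op visit and after 6 months (default `c(1, 1)`; reduced
#'   automatically for tiny cohorts).
#' @param noise_sd Angle noise level in degrees (default 1.5).
#' @param prom_noise_sd KOOS noise scale at `coupling = 0` (default 15
#'   points).
#' @return A `cohort_dataset`: `profiles`, `trials`, `proms`, `seed`,
#'   `params`.
#' @export
generate_cohort <- function(n_controls = 20L, n_patients = 19L,
                            effect_size = 1.5, coupling = 0.9, seed = 1L,
                            acts = activities(), n_cycles = 8L,
                            stairs_incapable_frac = 1 / 3,
                            prop_nonrecovering = 0,
                            n_dropouts = c(1L, 1L), noise_sd = 1.5,
                            prom_noise_sd = 15) {
  if (n_controls < 2L || n_patients < 2L)
    stopf("need at least 2 controls and 2 patients (got %d, %d)",
          n_controls, n_patients)
  if (!is_scalar_number(coupling) || coupling < 0 || coupling > 1)
    stopf("coupling must be in [0, 1]")
  if (!is_scalar_number(effect_size) || effect_size < 0)
    stopf("effect_size must be >= 0")
  acts <- match.arg(acts, activities(), several.ok = TRUE)

  ids_c <- sprintf("ctrl%02d", seq_len(n_controls))
  ids_p <- sprintf("pat%02d", seq_len(n_patients))
  profiles <- c(
    lapply(ids_c, function(id)
      make_profile(id, "control", derive_seed(seed, "profile", id),
                   prop_nonrecovering)),
    lapply(ids_p, function(id)
      make_profile(id, "patient", derive_seed(seed, "profile", id),
                   prop_nonrecovering))
  )
  names(profiles) <- c(ids_c, ids_p)

  ## dropouts and stairs capability (patients only)
  set.seed(derive_seed(seed, "design"))
  if (n_patients < 6L) n_dropouts <- c(0L, 0L)
  dropped <- sample(ids_p, sum(n_dropouts))
  if (n_dropouts[1] > 0)
    for (id in dropped[seq_len(n_dropouts[1])])
      profiles[[id]]$dropout_after <- "pre"
  if (n_dropouts[2] > 0)
    for (id in dropped[n_dropouts[1] + seq_len(n_dropouts[2])])
      profiles[[id]]$dropout_after <- "m6"
  n_incapable <- round(n_patients * stairs_incapable_frac)
  incapable <- sample(ids_p, n_incapable)
  for (id in names(profiles)) {
    p <- profiles[[id]]
    tps <- if (p$group == "control") "control_single"
           else timepoints(patients_only = TRUE)
    cap <- stats::setNames(rep(TRUE, length(tps)), tps)
    if (id %in% incapable && "w6" %in% tps) cap["w6"] <- FALSE
    profiles[[id]]$stairs_capable <- as.list(cap)
  }

  ## trials
  trials <- list()
  for (id in names(profiles)) {
    p <- profiles[[id]]
    tps <- if (p$group == "control") "control_single"
           else patient_timepoints_present(p)
    for (tp in tps) {
      for (act in acts) {
        if (act != "walk" && !isTRUE(p$stairs_capable[[tp]])) next
        trials[[length(trials) + 1L]] <- generate_trial(
          p, act, tp, n_cycles = n_cycles,
          seed = derive_seed(seed, "trial", id, act, tp),
          effect_size = effect_size, noise_sd = noise_sd)
      }
    }
  }

  ## PROMs: KOOS-ADL per patient at the timepoints they attended
  proms <- lapply(ids_p, function(id) {
    p <- profiles[[id]]
    set.seed(derive_seed(seed, "prom", id))
    tps <- patient_timepoints_present(p)
    ## coupling blends the deterministic gait link with unrelated noise:
    ## coupling = 1 -> koos = 100 * (1 - severity) exactly; coupling = 0 ->
    ## koos is independent of gait (centred on a typical mid-recovery score)
    koos <- vapply(tps, function(tp) {
      clip(coupling * 100 * (1 - p$latent_severity[[tp]]) +
             (1 - coupling) * (65 + prom_noise_sd * rnorm(1)), 0, 100)
    }, 0)
    structure(list(subject_id = id, koos_adl = as.list(koos)),
              class = "prom_trajectory")
  })
  names(proms) <- ids_p

  structure(list(profiles = profiles, trials = trials, proms = proms,
                 seed = seed,
                 params = list(n_controls = n_controls,
                               n_patients = n_patients,
                               effect_size = effect_size, coupling = coupling,
                               acts = acts, n_cycles = n_cycles,
                               stairs_incapable_frac = stairs_incapable_frac,
                               prop_nonrecovering = prop_nonrecovering,
                               n_dropouts = n_dropouts, noise_sd = noise_sd,
                               prom_noise_sd = prom_noise_sd)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$profiles, `[[`, "", "group")
  cat(sprintf(
    "synthetic cohort: %d controls + %d patients, %d trials, seed %d\n",
    sum(groups == "control"), sum(groups == "patient"), length(x$trials),
    x$seed))
  cat(sprintf("  effect_size %.2f, coupling %.2f, activities: %s\n",
              x$params$effect_size, x$params$coupling,
              paste(x$params$acts, collapse = ", ")))
  invisible(x)
}

#' @export
print.kinematic_trial <- function(x, ...) {
  cat(sprintf("kinematic trial: %s %s @%s, %d samples @%g Hz, severity %.2f\n",
              x$subject_id, x$activity, x$timepoint, nrow(x$angles$left),
              x$sample_rate, x$severity))
  invisible(x)
}

## ---- Plain-text serialisation ---------------------------------------------

#' Write a cohort to CSV files
#'
#' Long-format trial CSV (`subject_id, activity, timepoint, side, channel,
#' sample_index, value`), a subject metadata CSV and a PROM CSV, plus a JSON
#' file of the generation parameters.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$trials, function(tr) {
    ang <- cbind(tr$angles$left, tr$angles$right)
    colnames(ang) <- c(paste0("left_", angle_channels()),
                       paste0("right_", angle_channels()))
    chans <- cbind(as.data.frame(ang),
                   accel_ap = tr$accel_ap, accel_ml = tr$accel_ml,
                   tibia_accel_x_left = tr$tibia_accel_x$left,
                   tibia_accel_x_right = tr$tibia_accel_x$right)
    n <- nrow(chans)
    data.frame(subject_id = tr$subject_id, activity = tr$activity,
               timepoint = tr$timepoint, side = tr$side,
               channel = rep(names(chans), each = n),
               sample_index = rep(seq_len(n), ncol(chans)),
               value = unlist(chans, use.names = FALSE))
  })
  trials_path <- file.path(dir, "trials.csv")
  write.csv(do.call(rbind, rows), trials_path, row.names = FALSE)
  meta <- do.call(rbind, lapply(cohort$profiles, function(p) {
    data.frame(subject_id = p$subject_id, group = p$group,
               affected_side = p$affected_side, cadence_hz = p$cadence_hz,
               dropout_after = p$dropout_after %||% NA_character_)
  }))
  meta_path <- file.path(dir, "subjects.csv")
  write.csv(meta, meta_path, row.names = FALSE)
  proms <- do.call(rbind, lapply(cohort$proms, function(pr) {
    data.frame(subject_id = pr$subject_id, timepoint = names(pr$koos_adl),
               koos_adl = unlist(pr$koos_adl, use.names = FALSE))
  }))
  prom_path <- file.path(dir, "koos_adl.csv")
  write.csv(proms, prom_path, row.names = FALSE)
  par_path <- file.path(dir, "cohort_params.json")
  jsonlite::write_json(c(cohort$params, list(seed = cohort$seed)), par_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(trials_path, meta_path, prom_path, par_path))
}
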