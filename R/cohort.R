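#' Scanner/centre acquisition profile
#'
#' Describes one PET centre in the multicentre simulation: point-spread
#' blur, noise level, injected-dose scaling, frame schedule and axial
#' field of view.
#'
#' @param name centre label.
#' @param psf_fwhm Gaussian point-spread FWHM in mm.
#' @param noise_sd_fraction per-frame Gaussian noise SD as a fraction of
#'   local (blurred) signal.
#' @param dose_scale global multiplicative activity scale (cancels in
#'   retention ratios).
#' @param frame_schedule two-column matrix of frame `(start, end)` times in
#'   minutes post injection; frames must be ordered and non-overlapping.
#' @param fov_z axial field of view retained, as fractions `c(lo, hi)` of
#'   the template z-extent (template coordinates); `c(0, 1)` = full.
#' @return a `centre_profile` list.
#' @export
centre_profile <- function(name, psf_fwhm, noise_sd_fraction, dose_scale,
                           frame_schedule, fov_z = c(0, 1)) {
  frame_schedule <- matrix(as.numeric(frame_schedule), ncol = 2,
                           dimnames = list(NULL, c("start", "end")))
  stopifnot(all(frame_schedule[, 2] > frame_schedule[, 1]),
            psf_fwhm >= 0, noise_sd_fraction >= 0, dose_scale > 0,
            length(fov_z) == 2, fov_z[1] >= 0, fov_z[2] <= 1, fov_z[1] < fov_z[2])
  if (nrow(frame_schedule) > 1) {
    o <- order(frame_schedule[, 1])
    frame_schedule <- frame_schedule[o, , drop = FALSE]
    if (any(frame_schedule[-1, 1] < frame_schedule[-nrow(frame_schedule), 2] - 1e-9))
      stop("frame schedule has overlapping frames", call. = FALSE)
  }
  structure(list(name = name, psf_fwhm = psf_fwhm,
                 noise_sd_fraction = noise_sd_fraction,
                 dose_scale = dose_scale, frame_schedule = frame_schedule,
                 fov_z = fov_z),
            class = "centre_profile")
}

#' Consecutive 5-min frame schedule
#' @param from,to acquisition window in minutes post injection.
#' @return two-column `(start, end)` matrix.
#' @export
five_min_frames <- function(from, to) {
  starts <- seq(from, to - 5, by = 5)
  cbind(starts, starts + 5)
}

#' Default five-centre acquisition profiles
#'
#' Mirrors the published acquisition listing: centre A acquired six 5-min
#' frames 40-70 min p.i. on an HR+; centres B/C/E acquired 90-min and
#' centre D 60-min dynamic series; injected doses differed (345/230/368/
#' 302/458 MBq), encoded here as `dose_scale` relative to centre A.
#' Reconstruction PSF and noise are plausible per-scanner placeholders
#' (no published per-centre figures exist).
#'
#' @return named list of [centre_profile()] objects A-E.
#' @export
default_centre_profiles <- function() {
  list(
    A = centre_profile("A", psf_fwhm = 6.0, noise_sd_fraction = 0.06,
                       dose_scale = 1.000, frame_schedule = five_min_frames(40, 70)),
    B = centre_profile("B", psf_fwhm = 6.5, noise_sd_fraction = 0.08,
                       dose_scale = 230 / 345, frame_schedule = five_min_frames(0, 90)),
    C = centre_profile("C", psf_fwhm = 6.0, noise_sd_fraction = 0.06,
                       dose_scale = 368 / 345, frame_schedule = five_min_frames(0, 90)),
    D = centre_profile("D", psf_fwhm = 7.0, noise_sd_fraction = 0.07,
                       dose_scale = 302 / 345, frame_schedule = five_min_frames(0, 60)),
    E = centre_profile("E", psf_fwhm = 7.5, noise_sd_fraction = 0.05,
                       dose_scale = 458 / 345, frame_schedule = five_min_frames(0, 90))
  )
}

#' Default diagnosis-specific retention-ratio mixtures
#'
#' Published group summaries: normal-control main cluster 1.26 +/- 0.07
#' with 5/51 positives (the five printed outlier values calibrate the
#' control positive component directly); MCI 1.64 +/- 0.35 with 65 %
#' positive; AD 1.85 +/- 0.32 with 90 % positive. MCI and AD positive
#' components are moment-matched so the mixtures reproduce the printed
#' total mean/SD exactly; their negative components are anchored to the
#' control cluster (AD negatives set slightly higher at 1.30 +/- 0.08).
#'
#' @return named list of mixture parameter lists (`control`, `MCI`, `AD`).
#' @export
default_mixtures <- function() {
  outliers <- c(1.82, 1.70, 1.70, 1.62, 1.53) # printed PIB-positive controls
  list(
    control = list(weight_pos = 5 / 51, neg_mean = 1.26, neg_sd = 0.07,
                   pos_mean = mean(outliers), pos_sd = stats::sd(outliers)),
    MCI = moment_match_mixture(1.64, 0.35, weight_pos = 0.65,
                               neg_mean = 1.26, neg_sd = 0.07),
    AD = moment_match_mixture(1.85, 0.32, weight_pos = 0.90,
                              neg_mean = 1.30, neg_sd = 0.08)
  )
}

# per-group centre allocation of the published cohort (Table-1 counts)
default_centre_counts <- function() {
  list(control = c(A = 0, B = 15, C = 14, D = 6, E = 16),
       MCI = c(A = 14, B = 0, C = 10, D = 19, E = 29),
       AD = c(A = 19, B = 14, C = 10, D = 34, E = 20))
}

#' Generator configuration for the synthetic multicentre cohort
#'
#' All defaults encode the published cohort structure: group sizes 51/72/97
#' (controls/MCI/AD), the diagnosis-specific retention mixtures of
#' [default_mixtures()], ApoE e4 carrier frequencies 10/31, 34/59 and 48/85
#' per group, MCI-carrier enrichment of the positive mixture component
#' (weight 0.80 for carriers, non-carrier weight solved to preserve the
#' 65 % marginal), retention-coupled cognition (group-specific delayed-recall
#' slopes -0.5/-2.34/-0.82 Z per ratio unit; residual SDs calibrated to the
#' pooled r = -0.60 with delayed recall and r = -0.45 with MMSE), follow-up
#' of 28 +/- 15 months clipped to 6-60 available in 64/72 MCI, and an
#' exponential conversion hazard of 0.0445/month confined to PIB-positive
#' MCI. See the methods vignette for the calibration derivations
#' (reproduced by `analysis/00_calibrate_cognition.R`).
#'
#' @param group_sizes named counts for `control`, `MCI`, `AD`.
#' @param centre_profiles named list of [centre_profile()]s.
#' @param mixtures named per-diagnosis mixture parameter lists.
#' @param apoe_carrier_prob named per-diagnosis carrier probabilities.
#' @param apoe_genotyped_frac named per-diagnosis fraction genotyped.
#' @param apoe_mci_pos_weight positive-component weight for MCI e4 carriers.
#' @param cognition_model list of slopes/intercept targets/residual SDs.
#' @param followup_model list: `frac_followed`, `mean`, `sd`, `clip`.
#' @param conversion_hazard monthly conversion hazard for PIB-positive MCI.
#' @param cutoff positivity threshold used for the conversion logic.
#' @param seed default RNG seed for [sample_cohort()].
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(group_sizes = c(control = 51, MCI = 72, AD = 97),
                             centre_profiles = default_centre_profiles(),
                             mixtures = default_mixtures(),
                             apoe_carrier_prob = c(control = 10 / 31, MCI = 34 / 59, AD = 48 / 85),
                             apoe_genotyped_frac = c(control = 31 / 51, MCI = 59 / 72, AD = 85 / 97),
                             apoe_mci_pos_weight = 0.80,
                             cognition_model = default_cognition_model(),
                             followup_model = list(frac_followed = 64 / 72,
                                                   mean = 28, sd = 15, clip = c(6, 60)),
                             conversion_hazard = 0.0445,
                             cutoff = 1.41,
                             seed = 1L) {
  config <- structure(
    list(group_sizes = group_sizes, centre_profiles = centre_profiles,
         mixtures = mixtures, apoe_carrier_prob = apoe_carrier_prob,
         apoe_genotyped_frac = apoe_genotyped_frac,
         apoe_mci_pos_weight = apoe_mci_pos_weight,
         cognition_model = cognition_model, followup_model = followup_model,
         conversion_hazard = conversion_hazard, cutoff = cutoff,
         seed = as.integer(seed),
         age_model = list(control = c(67.4, 6.3), MCI = c(67.5, 8.1), AD = c(69.2, 8.4)),
         male_prob = c(control = 22 / 51, MCI = 37 / 72, AD = 47 / 97),
         centre_counts = default_centre_counts(),
         white_matter_ratio = 1.8),
    class = "generator_config")
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  stopifnot(all(config$group_sizes > 0),
            all(names(config$group_sizes) == c("control", "MCI", "AD")))
  for (mix in config$mixtures) {
    stopifnot(mix$weight_pos >= 0, mix$weight_pos <= 1,
              mix$neg_sd >= 0, mix$pos_sd >= 0)
  }
  probs <- c(config$apoe_carrier_prob, config$apoe_genotyped_frac,
             config$apoe_mci_pos_weight, config$followup_model$frac_followed)
  stopifnot(all(probs >= 0 & probs <= 1), config$conversion_hazard >= 0,
            config$cutoff > 0)
  for (cp in config$centre_profiles) stopifnot(inherits(cp, "centre_profile"))
  invisible(config)
}

#' Default cognition-coupling model
#'
#' Memory Z-scores and MMSE are linear in the true neocortical composite
#' with group-specific intercepts chosen so the group means match the
#' published neuropsychological table, plus Gaussian residuals. Delayed
#' verbal recall uses the published group regression slopes (-0.5 in
#' controls where no significant relation was seen, -2.34 in MCI, -0.82 in
#' AD); its residual SD and the common MMSE slope were calibrated once by
#' closed-form pooled-moment matching (see [calibrate_cognition()]) to give
#' pooled correlations of about -0.60 (delayed recall) and -0.45 (MMSE).
#'
#' @return list of per-score model parameters.
#' @export
default_cognition_model <- function() {
  list(
    mmse = list(group_means = c(control = 29.2, MCI = 27.1, AD = 24.0),
                slopes = c(control = -1.3352, MCI = -1.3352, AD = -1.3352),
                resid_sd = c(control = 1.0831, MCI = 1.9446, AD = 3.1713),
                avail_frac = c(control = 43 / 51, MCI = 72 / 72, AD = 97 / 97),
                clip = c(0, 30), integer = TRUE),
    verbal_del = list(group_means = c(control = 0.9, MCI = -1.2, AD = -2.2),
                      slopes = c(control = -0.5, MCI = -2.34, AD = -0.82),
                      resid_sd = c(control = 1.1339, MCI = 1.1339, AD = 1.1339),
                      avail_frac = c(control = 38 / 51, MCI = 64 / 72, AD = 90 / 97)),
    verbal_imm = list(group_means = c(control = 0.6, MCI = -1.0, AD = -1.9),
                      slopes = c(control = -0.4, MCI = -1.8, AD = -0.7),
                      resid_sd = c(control = 1.3, MCI = 1.3, AD = 1.3),
                      avail_frac = c(control = 36 / 51, MCI = 64 / 72, AD = 90 / 97)),
    nonverbal_del = list(group_means = c(control = 0.7, MCI = -0.8, AD = -1.7),
                         slopes = c(control = -0.4, MCI = -1.5, AD = -0.6),
                         resid_sd = c(control = 1.1, MCI = 1.1, AD = 1.1),
                         avail_frac = c(control = 28 / 51, MCI = 60 / 72, AD = 71 / 97))
  )
}

# run expr under a local RNG state seeded with `seed`; restores global state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mixture total mean and variance
mixture_moments <- function(mix) {
  w <- mix$weight_pos
  m <- w * mix$pos_mean + (1 - w) * mix$neg_mean
  v <- w * mix$pos_sd^2 + (1 - w) * mix$neg_sd^2 +
    w * (mix$pos_mean - m)^2 + (1 - w) * (mix$neg_mean - m)^2
  c(mean = m, var = v)
}

#' Sample a ground-truth cohort
#'
#' Draws one synthetic cohort: diagnosis, centre, demographics, ApoE,
#' a true neocortical composite from the diagnosis mixture (with
#' e4-carrier enrichment in MCI), true regional ratios (all cortical and
#' subcortical amyloid-coupled regions carry the composite; the
#' hippocampus is drawn from the control-like low distribution in every
#' group, the cerebellum is exactly 1, white matter is fixed), cognition,
#' follow-up and conversion status.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`. Fixing it makes the
#'   whole table reproducible.
#' @return data.frame, one row per subject, with true regional ratios in
#'   `ratio_*` columns.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  atlas_names <- c("frontal_L", "frontal_R", "sensorimotor_L", "sensorimotor_R",
                   "parietal_L", "parietal_R", "occipital_L", "occipital_R",
                   "temporal_latbas_L", "temporal_latbas_R",
                   "temporal_medial_L", "temporal_medial_R",
                   "cingulate_ant", "cingulate_post", "precuneus",
                   "hippocampus_L", "hippocampus_R", "caudate_L", "caudate_R",
                   "putamen_L", "putamen_R", "thalamus_L", "thalamus_R",
                   "cerebellum", "white_matter")
  with_seed(seed, {
    groups <- c("control", "MCI", "AD")
    rows <- list()
    sid <- 0L
    for (g in groups) {
      n <- config$group_sizes[[g]]
      mix <- config$mixtures[[g]]

      # centre allocation: exact published counts when the group size
      # matches, otherwise multinomial with the same proportions
      counts <- config$centre_counts[[g]]
      counts <- counts[names(counts) %in% names(config$centre_profiles)]
      counts <- counts[counts > 0]
      if (length(counts) == 0) { # custom centre set: allocate uniformly
        counts <- stats::setNames(rep(1, length(config$centre_profiles)),
                                  names(config$centre_profiles))
      }
      if (sum(counts) == n) {
        centre <- rep(names(counts), counts)
      } else {
        centre <- sample(names(counts), n, replace = TRUE, prob = counts / sum(counts))
      }
      centre <- sample(centre) # shuffle so subject order is not centre-blocked

      age <- stats::rnorm(n, config$age_model[[g]][1], config$age_model[[g]][2])
      sex <- ifelse(stats::runif(n) < config$male_prob[[g]], "M", "F")

      # ApoE: genotyping is unavailable at centre C (as published);
      # remaining subjects are genotyped at random to hit the group fraction
      apoe <- stats::runif(n) < config$apoe_carrier_prob[[g]]
      genotyped <- stats::runif(n) < config$apoe_genotyped_frac[[g]] /
        max(mean(centre != "C"), 1e-9)
      genotyped[centre == "C"] <- FALSE
      apoe[!genotyped] <- NA

      # true composite: MCI carriers get an enriched positive weight, with
      # the non-carrier weight solved to preserve the configured marginal
      if (g == "MCI" && !is.na(config$apoe_mci_pos_weight)) {
        p_carrier <- config$apoe_carrier_prob[["MCI"]]
        w_marg <- mix$weight_pos
        w_car <- config$apoe_mci_pos_weight
        w_non <- (w_marg - p_carrier * w_car) / (1 - p_carrier)
        w_non <- min(max(w_non, 0), 1)
        carrier_eff <- ifelse(is.na(apoe), stats::runif(n) < p_carrier, apoe)
        w_i <- ifelse(carrier_eff, w_car, w_non)
      } else {
        w_i <- rep(mix$weight_pos, n)
      }
      is_pos <- stats::runif(n) < w_i
      composite <- ifelse(is_pos,
                          stats::rnorm(n, mix$pos_mean, mix$pos_sd),
                          stats::rnorm(n, mix$neg_mean, mix$neg_sd))

      # cognition scores, linear in the true composite
      cg <- config$cognition_model
      score <- function(mod) {
        gm <- mixture_moments(mix)[["mean"]]
        intercept <- mod$group_means[[g]] - mod$slopes[[g]] * gm
        y <- intercept + mod$slopes[[g]] * composite +
          stats::rnorm(n, 0, mod$resid_sd[[g]])
        if (!is.null(mod$clip)) y <- pmin(pmax(y, mod$clip[1]), mod$clip[2])
        if (isTRUE(mod$integer)) y <- round(y)
        y[stats::runif(n) >= mod$avail_frac[[g]]] <- NA
        y
      }
      mmse <- score(cg$mmse)
      verbal_del <- score(cg$verbal_del)
      verbal_imm <- score(cg$verbal_imm)
      nonverbal_del <- score(cg$nonverbal_del)

      # follow-up and conversion (MCI only; positives only can convert)
      followup <- rep(NA_real_, n)
      converted <- rep(NA, n)
      conv_month <- rep(NA_real_, n)
      if (g == "MCI") {
        fm <- config$followup_model
        followed <- stats::runif(n) < fm$frac_followed
        fu <- pmin(pmax(stats::rnorm(n, fm$mean, fm$sd), fm$clip[1]), fm$clip[2])
        followup[followed] <- fu[followed]
        converted[followed] <- FALSE
        pib_pos_truth <- composite > config$cutoff
        can_convert <- followed & pib_pos_truth & config$conversion_hazard > 0
        t_event <- stats::rexp(n, rate = max(config$conversion_hazard, 1e-12))
        hit <- can_convert & t_event <= followup
        converted[hit] <- TRUE
        conv_month[hit] <- t_event[hit]
      }

      # regional truth: amyloid-coupled grey matter carries the composite,
      # hippocampus stays control-like low in all groups
      regional <- matrix(rep(composite, times = length(atlas_names)),
                         nrow = n,
                         dimnames = list(NULL, paste0("ratio_", atlas_names)))
      regional[, "ratio_hippocampus_L"] <- stats::rnorm(n, 1.26, 0.07)
      regional[, "ratio_hippocampus_R"] <- stats::rnorm(n, 1.26, 0.07)
      regional[, "ratio_cerebellum"] <- 1.0
      regional[, "ratio_white_matter"] <- config$white_matter_ratio

      rows[[g]] <- data.frame(
        subject_id = sprintf("S%03d", sid + seq_len(n)),
        diagnosis = g, centre = centre, age = age, sex = sex,
        apoe_e4 = apoe, component = ifelse(is_pos, "pos", "neg"),
        true_composite = composite, mmse = mmse,
        verbal_del_z = verbal_del, verbal_imm_z = verbal_imm,
        nonverbal_del_z = nonverbal_del,
        followup_months = followup, converted = converted,
        conversion_month = conv_month,
        stringsAsFactors = FALSE)
      rows[[g]] <- cbind(rows[[g]], regional)
      sid <- sid + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$diagnosis <- factor(out$diagnosis, levels = groups)
    out
  })
}

#' Region names used in `ratio_*` truth columns
#' @keywords internal
truth_region_names <- function(cohort) {
  sub("^ratio_", "", grep("^ratio_", names(cohort), value = TRUE))
}
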