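#' Monte-Carlo recovery of the normative cutoff
#'
#' For each seed, simulates a control arm of `n_cluster` values from the
#' normative control component plus the five published high-retention
#' contaminant values, runs main-cluster trimming and the
#' mean + `multiplier` x SD rule, and records the cutoff.
#'
#' @param n_seeds number of simulated control arms (default 1000).
#' @param seed master seed.
#' @param n_cluster main-cluster size (default 46).
#' @param cluster_mean,cluster_sd normative component (default 1.26, 0.07).
#' @param contaminants inserted high values (default the five published
#'   outlier ratios).
#' @param multiplier SD multiplier (default 1.96).
#' @return list with `cutoffs`, `mean`, `se` (Monte-Carlo SE of the mean),
#'   and `outlier_detection_rate` (fraction of arms where every
#'   contaminant was trimmed).
#' @export
mc_cutoff_study <- function(n_seeds = 1000L, seed = 1L, n_cluster = 46L,
                            cluster_mean = 1.26, cluster_sd = 0.07,
                            contaminants = c(1.82, 1.70, 1.70, 1.62, 1.53),
                            multiplier = 1.96) {
  cutoffs <- numeric(n_seeds)
  all_out <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    vals <- with_seed(derive_seed(seed, k), {
      c(stats::rnorm(n_cluster, cluster_mean, cluster_sd), contaminants)
    })
    mc <- main_cluster(vals)
    cutoffs[k] <- normal_upper_limit(mc$cluster, multiplier = multiplier)$cutoff
    all_out[k] <- all(contaminants %in% mc$outliers)
  }
  list(cutoffs = cutoffs, mean = mean(cutoffs),
       se = stats::sd(cutoffs) / sqrt(n_seeds),
       outlier_detection_rate = mean(all_out))
}

#' End-to-end calibration-recovery study through the image pipeline
#'
#' For each seed, draws group-specific true composites from the default
#' mixtures, renders noisy multicentre phantoms at reduced image size,
#' builds the grey-matter ROI set from fresh probability maps, quantifies
#' every subject and records per-seed mean recovered composites and
#' positivity rates at the fixed cutoff. This is the workhorse behind the
#' calibration-recovery acceptance checks.
#'
#' @param n_seeds number of replicates (default 200).
#' @param seed master seed.
#' @param groups which arms to simulate: subset of
#'   `c("control_cluster", "MCI", "AD")`. The control arm draws
#'   `n_control` subjects from the negative (main-cluster) component only.
#' @param n_control,n_mci,n_ad arm sizes (defaults 46/72/97).
#' @param atlas_dim,atlas_vox_mm reduced rendering grid (default
#'   40 x 40 x 30 at 4.8 mm, preserving the 192 x 192 x 144 mm field).
#' @param cutoff positivity threshold (default 1.41).
#' @param config generator configuration (defaults; mixtures and centre
#'   profiles are taken from it).
#' @return list with per-arm matrices of per-seed statistics and a
#'   `summary` data.frame (`statistic`, `value`, `mc_se`).
#' @export
mc_endtoend_study <- function(n_seeds = 200L, seed = 1L,
                              groups = c("control_cluster", "MCI", "AD"),
                              n_control = 46L, n_mci = 72L, n_ad = 97L,
                              atlas_dim = c(40L, 40L, 30L), atlas_vox_mm = 4.8,
                              cutoff = 1.41, config = generator_config()) {
  atlas <- build_atlas(atlas_dim, atlas_vox_mm)
  mixes <- config$mixtures
  centres <- config$centre_profiles
  counts <- config$centre_counts
  region_names <- atlas$lut$name

  draw_arm <- function(group, n) {
    # true composites for one arm (control arm: negative component only)
    if (group == "control_cluster") {
      comp <- stats::rnorm(n, mixes$control$neg_mean, mixes$control$neg_sd)
      cc <- counts$control
    } else {
      mix <- mixes[[group]]
      comp <- draw_mixture(n, mix)$value
      cc <- counts[[group]]
    }
    cc <- cc[cc > 0]
    centre <- sample(names(cc), n, replace = TRUE, prob = cc / sum(cc))
    list(composite = comp, centre = centre)
  }

  quantify_arm <- function(arm, roiset, seed_q) {
    n <- length(arm$composite)
    out <- numeric(n)
    for (i in seq_len(n)) {
      ratios <- stats::setNames(rep(arm$composite[i], length(region_names)),
                                region_names)
      ratios[c("hippocampus_L", "hippocampus_R")] <-
        stats::rnorm(2, mixes$control$neg_mean, mixes$control$neg_sd)
      ratios["cerebellum"] <- 1.0
      ratios["white_matter"] <- config$white_matter_ratio
      frames <- render_phantom(ratios, centres[[arm$centre[i]]], atlas,
                               seed = derive_seed(seed_q, i), window = c(40, 60))
      rr <- quantify_subject(frames, roiset)
      out[i] <- rr$composite
    }
    out
  }

  res <- lapply(groups, function(g) {
    matrix(NA_real_, n_seeds, 2, dimnames = list(NULL, c("mean", "pos_pct")))
  })
  names(res) <- groups
  truth <- res

  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, k)
    maps <- render_gm_probability_maps(10L, atlas, seed = derive_seed(sk, 1L))
    roiset <- build_roi_set(maps, atlas)
    arms <- with_seed(derive_seed(sk, 2L), {
      stats::setNames(lapply(seq_along(groups), function(j) {
        n <- switch(groups[j], control_cluster = n_control, MCI = n_mci, AD = n_ad)
        draw_arm(groups[j], n)
      }), groups)
    })
    for (g in groups) {
      rec <- with_seed(derive_seed(sk, 3L + match(g, groups)), {
        quantify_arm(arms[[g]], roiset, derive_seed(sk, 10L + match(g, groups)))
      })
      res[[g]][k, ] <- c(mean(rec), 100 * mean(rec > cutoff))
      truth[[g]][k, ] <- c(mean(arms[[g]]$composite),
                           100 * mean(arms[[g]]$composite > cutoff))
    }
  }

  summarize <- function(mat, stat) {
    c(value = mean(mat[, stat]), mc_se = stats::sd(mat[, stat]) / sqrt(n_seeds))
  }
  rows <- list()
  for (g in groups) {
    rows[[paste0(g, "_mean")]] <- summarize(res[[g]], "mean")
    rows[[paste0(g, "_pos_pct")]] <- summarize(res[[g]], "pos_pct")
  }
  summary <- data.frame(statistic = names(rows),
                        value = vapply(rows, `[[`, numeric(1), "value"),
                        mc_se = vapply(rows, `[[`, numeric(1), "mc_se"),
                        row.names = NULL)
  list(per_seed = res, truth_per_seed = truth, summary = summary,
       n_seeds = n_seeds, cutoff = cutoff)
}

#' Monte-Carlo check of the Kaplan-Meier median under exponential
#' conversion
#'
#' Simulates `n_subjects` PIB-positive MCI-like subjects per seed with
#' exponential event times (monthly rate `log(2) / median_months`) and
#' censoring times drawn Normal(28, 15) clipped to 6-60 months, runs
#' [km_estimate()] and records the KM median.
#'
#' @param n_seeds replicates (default 500).
#' @param seed master seed.
#' @param n_subjects group size (default 43, the positive MCI group size).
#' @param median_months true median of the event distribution (default 24).
#' @param censor_mean,censor_sd,censor_clip censoring distribution.
#' @return list with `medians`, `mean`, `se`, `n_defined` (seeds where the
#'   curve reached 0.5).
#' @export
mc_km_study <- function(n_seeds = 500L, seed = 1L, n_subjects = 43L,
                        median_months = 24, censor_mean = 28, censor_sd = 15,
                        censor_clip = c(6, 60)) {
  med <- rep(NA_real_, n_seeds)
  rate <- log(2) / median_months
  for (k in seq_len(n_seeds)) {
    med[k] <- with_seed(derive_seed(seed, k), {
      t_event <- stats::rexp(n_subjects, rate)
      t_cens <- pmin(pmax(stats::rnorm(n_subjects, censor_mean, censor_sd),
                          censor_clip[1]), censor_clip[2])
      times <- pmin(t_event, t_cens)
      events <- t_event <= t_cens
      km_estimate(times, events)$median
    })
  }
  ok <- !is.na(med)
  list(medians = med, mean = mean(med[ok]),
       se = stats::sd(med[ok]) / sqrt(sum(ok)), n_defined = sum(ok))
}
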