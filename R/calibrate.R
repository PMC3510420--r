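#' Closed-form calibration of the cognition-coupling residuals
#'
#' The generator models each cognition score as
#' `score = intercept_g + slope_g * composite + N(0, sigma)`, with the
#' intercepts fixed by the published group means. Pooled (cross-group)
#' correlations with the composite then follow from the mixture moments by
#' the laws of total covariance/variance, so the remaining free constants
#' can be solved in closed form:
#'
#' * `sigma` for delayed verbal recall such that the pooled correlation is
#'   `r_target` (default -0.60), given the published group slopes;
#' * the common MMSE slope such that the pooled correlation is -0.45,
#'   holding the group SDs at their published values (residual SDs then
#'   follow by subtraction).
#'
#' These solved values are frozen as the [default_cognition_model()]
#' constants; `analysis/00_calibrate_cognition.R` reproduces them.
#'
#' @param config a [generator_config()] (mixtures and group sizes are used).
#' @param r_delayed target pooled correlation for delayed recall.
#' @param r_mmse target pooled correlation for MMSE.
#' @param mmse_group_sd published MMSE group SDs.
#' @return list with `sigma_verbal_del`, `mmse_slope`, `mmse_resid_sd`,
#'   and the implied pooled moments.
#' @export
calibrate_cognition <- function(config = generator_config(),
                                r_delayed = -0.60, r_mmse = -0.45,
                                mmse_group_sd = c(control = 1.1, MCI = 2.0, AD = 3.2)) {
  groups <- c("control", "MCI", "AD")
  n_g <- as.numeric(config$group_sizes[groups])
  mom <- vapply(config$mixtures[groups], mixture_moments, numeric(2))
  mx_g <- mom["mean", ]; vx_g <- mom["var", ]

  # published pooled correlations are computed on the tested subset, so the
  # groups are weighted by the per-test availability (n = 38/64/90 for
  # delayed recall, i.e. the printed n = 192)
  del <- config$cognition_model$verbal_del
  w_g <- n_g * del$avail_frac[groups]
  w_g <- w_g / sum(w_g)
  mx <- sum(w_g * mx_g)
  vx <- sum(w_g * vx_g) + sum(w_g * (mx_g - mx)^2)
  b_g <- del$slopes[groups]
  my_g <- del$group_means[groups]
  my <- sum(w_g * my_g)
  cov_xy <- sum(w_g * b_g * vx_g) + sum(w_g * (mx_g - mx) * (my_g - my))
  between_y <- sum(w_g * (my_g - my)^2)
  within_b <- sum(w_g * b_g^2 * vx_g)
  # r = cov / sqrt(vx * (within_b + sigma^2 + between_y))
  vy_needed <- (cov_xy / (r_delayed * sqrt(vx)))^2
  sigma2 <- vy_needed - within_b - between_y
  if (sigma2 <= 0) stop("infeasible delayed-recall calibration", call. = FALSE)

  # MMSE: group SDs fixed at published values, solve the common slope
  # (availability-weighted like above)
  mm <- config$cognition_model$mmse
  wm_g <- n_g * mm$avail_frac[groups]
  wm_g <- wm_g / sum(wm_g)
  mxm <- sum(wm_g * mx_g)
  vxm <- sum(wm_g * vx_g) + sum(wm_g * (mx_g - mxm)^2)
  mmy_g <- mm$group_means[groups]
  mmy <- sum(wm_g * mmy_g)
  between_cov <- sum(wm_g * (mx_g - mxm) * (mmy_g - mmy))
  vy_mmse <- sum(wm_g * mmse_group_sd[groups]^2) + sum(wm_g * (mmy_g - mmy)^2)
  # r = (b * E[varX_g] + between_cov) / sqrt(vx * vy_mmse)
  b_mmse <- (r_mmse * sqrt(vxm * vy_mmse) - between_cov) / sum(wm_g * vx_g)
  resid2 <- mmse_group_sd[groups]^2 - b_mmse^2 * vx_g
  if (any(resid2 <= 0)) stop("infeasible MMSE calibration", call. = FALSE)

  list(sigma_verbal_del = sqrt(sigma2), mmse_slope = b_mmse,
       mmse_resid_sd = sqrt(resid2),
       pooled = list(mean_composite = mx, sd_composite = sqrt(vx),
                     cov_delayed = cov_xy))
}
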