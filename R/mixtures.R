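#' Moment-match the positive component of a two-component normal mixture
#'
#' The generator models each diagnostic group's neocortical retention ratio
#' as a two-component (amyloid-negative / amyloid-positive) normal mixture.
#' Published group summaries give the *total* mean and SD plus the
#' positivity fraction; the negative component is anchored to the normal
#' control cluster. This solves for the positive component so the mixture
#' reproduces the total moments exactly (law of total variance):
#'
#' \deqn{\mu = w\mu_+ + (1-w)\mu_-}
#' \deqn{\sigma^2 = w\sigma_+^2 + (1-w)\sigma_-^2 +
#'       w(\mu_+-\mu)^2 + (1-w)(\mu_--\mu)^2}
#'
#' @param total_mean,total_sd target mixture mean and SD (retention-ratio units).
#' @param weight_pos positive-component weight in (0, 1].
#' @param neg_mean,neg_sd negative component parameters.
#' @return list with `pos_mean`, `pos_sd` (plus the inputs, for records).
#' @export
moment_match_mixture <- function(total_mean, total_sd, weight_pos, neg_mean, neg_sd) {
  stopifnot(weight_pos > 0, weight_pos <= 1, total_sd >= 0, neg_sd >= 0)
  if (weight_pos == 1) {
    return(list(pos_mean = total_mean, pos_sd = total_sd,
                weight_pos = 1, neg_mean = neg_mean, neg_sd = neg_sd))
  }
  w <- weight_pos
  pos_mean <- (total_mean - (1 - w) * neg_mean) / w
  pos_var <- (total_sd^2 - (1 - w) * neg_sd^2 -
                w * (pos_mean - total_mean)^2 -
                (1 - w) * (neg_mean - total_mean)^2) / w
  if (pos_var <= 0) {
    stop("infeasible moments: implied positive-component variance is not positive",
         call. = FALSE)
  }
  list(pos_mean = pos_mean, pos_sd = sqrt(pos_var),
       weight_pos = w, neg_mean = neg_mean, neg_sd = neg_sd)
}

#' Draw from a two-component normal mixture
#' @param n number of draws.
#' @param mix list as returned by [moment_match_mixture()].
#' @return list with `value` (numeric) and `component` (`"pos"`/`"neg"`).
#' @keywords internal
draw_mixture <- function(n, mix) {
  pos <- stats::runif(n) < mix$weight_pos
  value <- ifelse(pos,
                  stats::rnorm(n, mix$pos_mean, mix$pos_sd),
                  stats::rnorm(n, mix$neg_mean, mix$neg_sd))
  list(value = value, component = ifelse(pos, "pos", "neg"))
}

#' Population positivity fraction implied by a mixture at a cutoff
#'
#' Closed-form \eqn{P(X > c)} for the two-component normal mixture; used as
#' an independent check on simulated classification rates.
#'
#' @param mix list as returned by [moment_match_mixture()].
#' @param cutoff classification threshold (strictly-greater convention).
#' @export
mixture_positive_fraction <- function(mix, cutoff) {
  mix$weight_pos * stats::pnorm(cutoff, mix$pos_mean, mix$pos_sd, lower.tail = FALSE) +
    (1 - mix$weight_pos) * stats::pnorm(cutoff, mix$neg_mean, mix$neg_sd, lower.tail = FALSE)
}
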