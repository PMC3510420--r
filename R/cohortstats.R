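#' Classical one-way ANOVA
#'
#' @param values numeric response.
#' @param groups factor-coercible grouping with >= 2 levels, each n >= 2.
#' @return list with `F`, `df_between`, `df_within`, `p`, `group_means`.
#' @export
anova_oneway <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(as.factor(groups[ok]))
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  fit <- stats::lm(values ~ groups)
  a <- stats::anova(fit)
  Fv <- a$`F value`[1]
  if (a$`Mean Sq`[2] == 0) {
    warning("zero within-group variance; F is infinite")
    Fv <- Inf
  }
  list(F = Fv, df_between = a$Df[1], df_within = a$Df[2],
       p = if (is.infinite(Fv)) 0 else a$`Pr(>F)`[1],
       group_means = tapply(values, groups, mean))
}

#' Two-factor variance partition (diagnosis x centre)
#'
#' Fixed-effects GLM with Type II sums of squares (each main effect
#' adjusted for the other; the interaction adjusted for both), which
#' tolerates the unbalanced, incomplete diagnosis-by-centre design.
#' Effect sizes are eta-squared relative to the total sum of squares.
#'
#' @param values numeric response.
#' @param factor_a,factor_b two crossed categorical factors.
#' @return list with per-effect `ss`, `df`, `F`, `p`, `eta_sq`, plus
#'   `eta_ratio` (`eta_sq_a / eta_sq_b`).
#' @export
variance_partition <- function(values, factor_a, factor_b) {
  ok <- !is.na(values) & !is.na(factor_a) & !is.na(factor_b)
  d <- data.frame(y = values[ok],
                  a = droplevels(as.factor(factor_a[ok])),
                  b = droplevels(as.factor(factor_b[ok])))
  one_level_b <- nlevels(d$b) < 2
  if (one_level_b) {
    # degenerate crossing: reduces to one-way ANOVA in factor_a
    ow <- anova_oneway(d$y, d$a)
    sst <- sum((d$y - mean(d$y))^2)
    ssa <- sst - sum(stats::resid(stats::lm(y ~ a, d))^2)
    return(list(a = list(ss = ssa, df = ow$df_between, F = ow$F, p = ow$p,
                         eta_sq = ssa / sst),
                b = list(ss = 0, df = 0, F = NA_real_, p = NA_real_, eta_sq = 0),
                interaction = list(ss = 0, df = 0, F = NA_real_, p = NA_real_,
                                   eta_sq = 0),
                residual = list(ss = sst - ssa, df = ow$df_within),
                eta_ratio = Inf))
  }
  rss <- function(formula) sum(stats::resid(stats::lm(formula, data = d))^2)
  r_a <- rss(y ~ a); r_b <- rss(y ~ b); r_ab <- rss(y ~ a + b)
  full <- stats::lm(y ~ a * b, data = d)
  r_full <- sum(stats::resid(full)^2)
  df_full <- stats::df.residual(full)
  sst <- sum((d$y - mean(d$y))^2)

  ss_a <- r_b - r_ab                 # a | b
  ss_b <- r_a - r_ab                 # b | a
  ss_int <- r_ab - r_full            # a:b | a, b
  df_a <- nlevels(d$a) - 1L
  df_b <- nlevels(d$b) - 1L
  # interaction df from the actually estimable cells
  df_int <- (stats::df.residual(stats::lm(y ~ a + b, data = d))) - df_full
  mse <- r_full / df_full
  eff <- function(ss, df) {
    Fv <- if (df > 0 && mse > 0) (ss / df) / mse else NA_real_
    list(ss = ss, df = df, F = Fv,
         p = if (is.na(Fv)) NA_real_ else stats::pf(Fv, df, df_full, lower.tail = FALSE),
         eta_sq = ss / sst)
  }
  a_eff <- eff(ss_a, df_a); b_eff <- eff(ss_b, df_b); i_eff <- eff(ss_int, df_int)
  list(a = a_eff, b = b_eff, interaction = i_eff,
       residual = list(ss = r_full, df = df_full),
       eta_ratio = if (b_eff$eta_sq > 0) a_eff$eta_sq / b_eff$eta_sq else Inf)
}

#' Pearson correlation with pairwise-complete observations
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p` (two-sided, t transform), `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Simple least-squares regression slope
#'
#' @param x,y numeric vectors (pairwise-complete, n >= 3).
#' @return list with `slope`, `se`, `p` (two-sided), `intercept`, `n`.
#' @export
ols_slope <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  list(slope = co["x", "Estimate"], se = co["x", "Std. Error"],
       p = co["x", "Pr(>|t|)"], intercept = co["(Intercept)", "Estimate"],
       n = length(x))
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction, matching the classical test of differences in
#' distribution.
#'
#' @param counts matrix of counts (e.g. 2 x k).
#' @return list with `chi_sq`, `df`, `p`.
#' @export
chi_squared_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0)) stop("non-positive expected count", call. = FALSE)
  list(chi_sq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
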