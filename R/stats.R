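# Aftereffect-level parametric and Bayesian statistics.

#' Paired t test with effect size and Bayes factor
#'
#' Standard two-tailed paired t test on per-participant differences, with the
#' paired-design Cohen's d (mean of differences over their SD, equal to
#' t / sqrt(n)), a 95% CI from the t distribution, and the JZS Bayes factor.
#'
#' @param diffs per-participant differences (degrees), or the first condition
#'   when `y` is supplied.
#' @param y optional second condition; differences are `diffs - y`.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return a `stat_result` list: `estimate`, `ci95`, `t`, `df`, `p`, `d`,
#'   `bf10`, `n`.
#' @export
paired_t <- function(diffs, y = NULL, prior_scale = sqrt(2) / 2) {
  if (!is.null(y)) diffs <- diffs - y
  n <- length(diffs)
  if (n < 3) stop("need at least 3 paired observations")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero variance of differences")
  m <- mean(diffs)
  t <- m / (s / sqrt(n))
  ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * s / sqrt(n)
  structure(list(estimate = m, ci95 = ci, t = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), n - 1), d = m / s,
                 bf10 = jzs_bf_ttest(t, n, prior_scale), n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "mean difference %.2f, 95%% CI [%.2f %.2f], t(%d) = %.3f, p = %.3g, d = %.2f, BF10 = %.3g\n",
    x$estimate, x$ci95[1], x$ci95[2], x$df, x$t, x$p, x$d, x$bf10))
  invisible(x)
}

#' JZS Bayes factor for a one-sample / paired t test
#'
#' Default-prior Bayes factor of the alternative over the null for a t
#' statistic, with a Cauchy prior of scale `prior_scale` on the standardized
#' effect size. Computed by numerical integration of the noncentral-t
#' likelihood over the prior (relative tolerance 1e-10); invariant to the
#' sign of t.
#'
#' @param t observed t statistic.
#' @param n sample size (pairs); degrees of freedom are `n - 1`.
#' @param prior_scale Cauchy scale, default `sqrt(2)/2` ("medium").
#' @return BF10 (> 0).
#' @examples
#' jzs_bf_ttest(3.75, 44)   # ~53
#' @export
jzs_bf_ttest <- function(t, n, prior_scale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n >= 2, prior_scale > 0)
  df <- n - 1
  r2 <- prior_scale^2
  # marginal likelihood under H1, integrating over g with the inverse-gamma
  # (1/2, r^2/2) mixing density that makes delta ~ Cauchy(0, r)
  lik1 <- function(g) {
    q <- 1 + n * g
    (1 + t^2 / (q * df))^(-(df + 1) / 2) / sqrt(q) *
      sqrt(r2 / (2 * pi)) * g^(-3 / 2) * exp(-r2 / (2 * g))
  }
  m1 <- stats::integrate(lik1, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  m0 <- (1 + t^2 / df)^(-(df + 1) / 2)
  m1 / m0
}

#' Pearson correlation with Bayes factor
#'
#' Two-tailed Pearson correlation test plus a Bayes factor for the presence
#' of a correlation, using the Jeffreys approximate likelihood for r under a
#' uniform (stretched-beta, width 1) prior on the population correlation.
#'
#' @param x,y per-participant values (n >= 4).
#' @return list with `r`, `p`, `bf10`, `n`.
#' @export
correlation_with_bf <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  kern <- function(rho) (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^((3 - 2 * n) / 2)
  bf <- if (abs(r) > 1 - 1e-12) Inf  # likelihood kernel diverges at |r| = 1
        else stats::integrate(kern, -1, 1, rel.tol = 1e-9)$value / 2
  list(r = r, p = ct$p.value, bf10 = bf, n = n)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate within-subject decomposition with the Greenhouse-Geisser
#' sphericity correction applied to the F-test degrees of freedom, partial
#' eta squared, and Bonferroni-corrected pairwise paired t contrasts.
#'
#' @param data participant x condition matrix (complete; >= 2 conditions).
#' @return an `anova_result` list: `F`, `df_num`, `df_den` (GG-corrected),
#'   `epsilon_gg`, `p`, `eta_p_sq`, and a `pairwise` data.frame of contrasts.
#' @export
rm_anova_gg <- function(data) {
  M <- as.matrix(data)
  if (anyNA(M)) stop("missing cells in repeated-measures data")
  n <- nrow(M); k <- ncol(M)
  if (k < 2) stop("need >= 2 conditions")
  grand <- mean(M)
  cond_m <- colMeans(M); subj_m <- rowMeans(M)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(M)
  Sd <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- if (sum(Sd^2) == 0) 1 else sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  if (k == 2) eps <- 1
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  cn <- colnames(M) %||% paste0("c", seq_len(k))
  prs <- utils::combn(k, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    d <- M[, i2] - M[, i1]
    tt <- stats::t.test(d)
    data.frame(contrast = paste(cn[i2], "-", cn[i1]),
               mean_diff = mean(d), ci_lo = tt$conf.int[1],
               ci_hi = tt$conf.int[2],
               p_bonferroni = min(tt$p.value * ncol(prs), 1))
  }))
  structure(list(F = Fv, df_num = df1 * eps, df_den = df2 * eps,
                 epsilon_gg = eps, p = p,
                 eta_p_sq = if (ss_cond == 0) 0 else ss_cond / (ss_cond + ss_err),
                 pairwise = pairwise, n = n, k = k),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F[%.2f, %.1f] = %.2f, p = %.3g, eta_p^2 = %.2f (GG epsilon %.2f)\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_p_sq, x$epsilon_gg))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Random-slope linear mixed model for graded aftereffects
#'
#' Fits `y ~ x` with correlated random intercept and slope per participant by
#' maximum likelihood (falling back to uncorrelated random effects when the
#' fit is singular). The fixed-slope t statistic uses the residual degrees of
#' freedom convention `N_obs - 2`.
#'
#' @param data data.frame with columns `participant`, `x` (e.g. number of
#'   veridical cycles before learning) and `y` (e.g. aftereffect, degrees).
#' @return a `mixed_result` list: fixed `intercept` and `slope` (each with
#'   estimate, se, t, ci95), `df`, `p_slope`, random-effect variances,
#'   `singular` flag and per-participant slopes.
#' @export
mixed_model_slope <- function(data) {
  stopifnot(all(c("participant", "x", "y") %in% names(data)))
  if (any(tapply(data$x, data$participant,
                 function(v) length(unique(v))) < 2))
    stop("each participant needs >= 2 distinct x values")
  fit <- lme4::lmer(y ~ x + (1 + x | participant), data = data, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    fit <- lme4::lmer(y ~ x + (1 + x || participant), data = data, REML = FALSE)
  co <- summary(fit)$coefficients
  df <- nrow(data) - 2
  tcrit <- stats::qt(0.975, df)
  mk <- function(row) list(estimate = co[row, 1], se = co[row, 2],
                           t = co[row, 3],
                           ci95 = co[row, 1] + c(-1, 1) * tcrit * co[row, 2])
  vc <- as.data.frame(lme4::VarCorr(fit))
  ps <- stats::coef(fit)$participant
  structure(list(intercept = mk(1), slope = mk(2), df = df,
                 p_slope = 2 * stats::pt(-abs(co[2, 3]), df),
                 varcorr = vc, singular = singular,
                 participant_slopes = stats::setNames(ps$x, rownames(ps)),
                 fit = fit), class = "mixed_result")
}

#' @export
print.mixed_result <- function(x, ...) {
  cat(sprintf("fixed slope %.3f [%.3f %.3f], t(%d) = %.2f, p = %.3g%s\n",
              x$slope$estimate, x$slope$ci95[1], x$slope$ci95[2], x$df,
              x$slope$t, x$p_slope,
              if (x$singular) " (singular fit; uncorrelated random effects)" else ""))
  invisible(x)
}

#' Sample size for a paired / one-sample t test
#'
#' Smallest n at which the noncentral-t power of the two-tailed test with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom reaches the
#' target power.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.95).
#' @param two_tailed logical (default TRUE).
#' @param n_max search bound.
#' @return integer sample size.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.95,
                                 two_tailed = TRUE, n_max = 1e5) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  pw <- function(n) {
    ncp <- d * sqrt(n)
    if (two_tailed) {
      q <- stats::qt(1 - alpha / 2, n - 1)
      stats::pt(q, n - 1, ncp, lower.tail = FALSE) + stats::pt(-q, n - 1, ncp)
    } else {
      stats::pt(stats::qt(1 - alpha, n - 1), n - 1, ncp, lower.tail = FALSE)
    }
  }
  for (n in 2:n_max) if (pw(n) >= power) return(n)
  stop("target power not reachable within n_max")
}
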