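test_that("paired t returns the textbook quantities", {
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$estimate, 2)
  expect_equal(r$t, 2 * sqrt(3))
  expect_equal(r$d, 2)
  tt <- t.test(c(1, 2, 3))
  expect_equal(r$ci95, as.numeric(tt$conf.int))
  expect_equal(r$p, tt$p.value)
  # paired-design d = t / sqrt(n): the printed t reproduces the printed d
  expect_equal(round(-3.75 / sqrt(44), 2), -0.57)
  expect_error(paired_t(rep(1, 5)), "zero variance")
  expect_error(paired_t(c(1, 2)), "at least 3")
})

test_that("JZS Bayes factor matches an independent noncentral-t integration", {
  # independent route: integrate the noncentral-t likelihood directly over
  # the Cauchy prior on the standardized effect
  jzs_ncp <- function(t, n, r = sqrt(2) / 2) {
    num <- integrate(function(d) suppressWarnings(dt(t, n - 1, ncp = d * sqrt(n))) *
                       dcauchy(d, 0, r), -Inf, Inf, rel.tol = 1e-9)$value
    num / dt(t, n - 1)
  }
  for (tv in c(0.266, 1.5, 3.27, 3.75)) {
    expect_equal(jzs_bf_ttest(tv, 44), jzs_ncp(tv, 44), tolerance = 1e-6)
  }
  # invariant to the sign of t, increasing in |t|, evidence for null at t = 0
  expect_equal(jzs_bf_ttest(-3.75, 44), jzs_bf_ttest(3.75, 44))
  bfs <- vapply(seq(0, 5, by = 0.5), jzs_bf_ttest, 1, n = 20)
  expect_true(all(diff(bfs) > 0))
  expect_lt(jzs_bf_ttest(0, 20), 1)
  expect_lt(jzs_bf_ttest(0, 5), 1)
  # wider prior penalizes small effects more
  expect_lt(jzs_bf_ttest(0.5, 30, prior_scale = 1.4),
            jzs_bf_ttest(0.5, 30, prior_scale = sqrt(2) / 2))
})

test_that("correlation test reports r, p and a null-supporting BF for noise", {
  x <- 1:20 + 0
  expect_equal(correlation_with_bf(x, x * 2 + 1)$r, 1)
  set.seed(99)
  a <- rnorm(44); b <- rnorm(44)
  b <- residuals(lm(b ~ a))  # orthogonalized: r = 0 exactly
  r <- correlation_with_bf(a, b)
  expect_equal(r$r, 0, tolerance = 1e-12)
  expect_lt(r$bf10, 1)
  expect_error(correlation_with_bf(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("repeated-measures ANOVA matches car's GG-corrected univariate test", {
  skip_if_not_installed("car")
  set.seed(5)
  for (k in c(3, 4)) {
    M <- matrix(rnorm(25 * k), 25, k) + outer(rnorm(25), rep(1, k)) +
      matrix(rep(seq(0, 0.8, length.out = k), each = 25), 25, k)
    r <- rm_anova_gg(M)
    fit <- lm(M ~ 1)
    av <- suppressWarnings(summary(car::Anova(
      fit, idata = data.frame(cond = factor(seq_len(k))), idesign = ~cond,
      type = 3), multivariate = FALSE))
    expect_equal(r$F, unname(av$univariate.tests["cond", "F value"]))
    expect_equal(r$epsilon_gg, unname(av$pval.adjustments["cond", "GG eps"]),
                 tolerance = 1e-10)
    expect_equal(r$p, unname(av$pval.adjustments["cond", "Pr(>F[GG])"]),
                 tolerance = 1e-10)
  }
})

test_that("two-condition ANOVA collapses to the squared paired t", {
  set.seed(6)
  M <- matrix(rnorm(40), 20, 2)
  r <- rm_anova_gg(M)
  t2 <- paired_t(M[, 1], M[, 2])
  expect_equal(r$F, t2$t^2, tolerance = 1e-10)
  expect_equal(r$epsilon_gg, 1)
  # identical conditions: no effect
  v <- rnorm(10)
  r2 <- rm_anova_gg(cbind(v, v))
  expect_equal(r2$F, 0)
  expect_equal(r2$eta_p_sq, 0)
  expect_error(rm_anova_gg(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("mixed model recovers a noiseless common slope and known fixed effects", {
  d <- expand.grid(participant = paste0("S", 1:12), x = c(5, 45, 85))
  d$y <- 10 - 0.05 * d$x
  m <- suppressWarnings(suppressMessages(mixed_model_slope(d)))
  expect_equal(m$slope$estimate, -0.05, tolerance = 1e-6)
  expect_equal(m$df, nrow(d) - 2)

  # parameter recovery with realistic noise: estimate within 2 SE of truth
  set.seed(14)
  ok <- 0
  for (rep in 1:20) {
    n <- 30
    slopes <- rnorm(n, -0.04, 0.01)
    ints <- rnorm(n, 10, 2)
    dd <- expand.grid(participant = seq_len(n), x = c(5, 45, 85))
    dd$y <- ints[dd$participant] + slopes[dd$participant] * dd$x + rnorm(nrow(dd))
    m <- suppressWarnings(suppressMessages(mixed_model_slope(dd)))
    if (abs(m$slope$estimate - (-0.04)) < 2 * m$slope$se) ok <- ok + 1
  }
  expect_gte(ok, 17)
  expect_error(mixed_model_slope(data.frame(participant = 1:3, x = 1, y = 1)),
               "distinct x")
})

test_that("required sample size matches noncentral-t power and is monotone", {
  n <- required_sample_size(0.6, 0.05, 0.95)
  # direct power check around the returned n
  pow <- function(n, d = 0.6) {
    q <- qt(0.975, n - 1)
    suppressWarnings(pt(q, n - 1, d * sqrt(n), lower.tail = FALSE) +
                       pt(-q, n - 1, d * sqrt(n)))
  }
  expect_gte(pow(n), 0.95)
  expect_lt(pow(n - 1), 0.95)
  # consistent with stats::power.t.test continuous solution
  ct <- power.t.test(delta = 0.6, sd = 1, sig.level = 0.05, power = 0.95,
                     type = "one.sample")$n
  expect_equal(n, ceiling(ct))
  expect_lt(required_sample_size(1.2), n)
  expect_lt(required_sample_size(0.6, power = 0.5), n)
})
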