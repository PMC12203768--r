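test_that("cycle-wise paired t matches t.test and is translation invariant", {
  set.seed(10)
  A <- matrix(rnorm(8 * 6), 8, 6)
  B <- matrix(rnorm(8 * 6), 8, 6)
  r <- cyclewise_paired_t(A, B)
  for (j in 1:6) {
    tt <- t.test(A[, j], B[, j], paired = TRUE)
    expect_equal(r$t[j], unname(tt$statistic))
    expect_equal(r$p[j], tt$p.value)
  }
  # identical blocks
  r0 <- cyclewise_paired_t(A, A)
  expect_equal(r0$t, rep(0, 6))
  expect_equal(r0$p, rep(1, 6))
  # hand-computed: diffs (1,2,3) -> t = 2*sqrt(3)
  r1 <- cyclewise_paired_t(matrix(c(1, 2, 3)), matrix(0, 3, 1))
  expect_equal(r1$t, 2 * sqrt(3))
  # translation invariance
  r2 <- cyclewise_paired_t(A + 7, B + 7)
  expect_equal(r2$t, r$t)
  expect_error(cyclewise_paired_t(A, B[, 1:3]), "matching shapes")
})

test_that("clusters are maximal sign-homogeneous runs of significant cycles", {
  cl <- form_clusters(c(.5, 3, 2.8, .4), c(.2, .01, .02, .3))
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end, cl$t_sum), c(2, 3, 5.8))
  # alternating signs split clusters
  cl2 <- form_clusters(c(3, -3, 3), c(.01, .01, .01))
  expect_equal(nrow(cl2), 3)
  expect_equal(nrow(form_clusters(c(1, 1), c(.5, .5))), 0)
})

test_that("max cluster statistic agrees with the loop oracle on random input", {
  set.seed(77)
  for (i in 1:50) {
    tv <- rnorm(30, 0, 2)
    pv <- runif(30)
    expect_equal(reclamp:::max_cluster_tsum(tv, pv < 0.05),
                 oracle_max_tsum(tv, pv))
  }
})

test_that("paired cluster test finds overwhelming separation and is seed-stable", {
  set.seed(3)
  A <- matrix(rnorm(10 * 12), 10, 12)
  B <- A + 10
  r <- paired_cluster_test(B, A, n_perm = 500, seed = 9)
  expect_equal(nrow(r$clusters), 1)
  expect_equal(c(r$clusters$start, r$clusters$end), c(1, 12))
  expect_equal(r$clusters$p_cluster, 0)  # resolution floor
  expect_true(r$clusters$significant)
  r2 <- paired_cluster_test(B, A, n_perm = 500, seed = 9)
  expect_identical(r, r2)
  # conservative variant never reports exactly zero
  r3 <- paired_cluster_test(B, A, n_perm = 500, seed = 9, conservative = TRUE)
  expect_equal(r3$clusters$p_cluster, 1 / 501)
  expect_error(paired_cluster_test(B, A, n_perm = 0), "n_perm")
})

test_that("Monte-Carlo cluster p agrees with exhaustive sign-flip enumeration", {
  set.seed(42)
  n <- 6
  A <- matrix(rnorm(n * 8), n, 8) + matrix(rep(c(0, 1.2), c(4, 4)), n, 8,
                                           byrow = TRUE)
  B <- matrix(rnorm(n * 8), n, 8)
  exact <- oracle_exact_cluster_p(A, B)
  mc <- paired_cluster_test(A, B, n_perm = 4000, seed = 1)
  expect_equal(nrow(mc$clusters), nrow(exact))
  for (i in seq_len(nrow(exact))) {
    se <- sqrt(exact$p_exact[i] * (1 - exact$p_exact[i]) / 4000)
    expect_lt(abs(mc$clusters$p_cluster[i] - exact$p_exact[i]),
              3 * se + 1e-12)
  }
})

test_that("scaling the effect never shrinks cluster mass (monotonicity)", {
  set.seed(8)
  A <- matrix(rnorm(12 * 20), 12, 20)
  B <- A - matrix(rep(seq(0, 1.5, length.out = 20), each = 12), 12, 20) -
    rnorm(12 * 20, 0, 0.3)
  base <- paired_cluster_test(A, B, n_perm = 200, seed = 2)
  for (c_scale in c(1.5, 3)) {
    D <- (A - B) * c_scale
    up <- paired_cluster_test(D, matrix(0, 12, 20), n_perm = 200, seed = 2)
    if (nrow(base$clusters) > 0) {
      expect_gte(max(abs(up$clusters$t_sum)), max(abs(base$clusters$t_sum)))
    }
  }
})

test_that("cycle-wise regression equals lm on pooled points", {
  set.seed(12)
  n <- 5; k <- 3; C <- 4
  y <- array(rnorm(n * k * C), c(n, k, C))
  x <- c(5, 45, 85)
  r <- cyclewise_regression(y, x)
  for (j in seq_len(C)) {
    fit <- summary(lm(as.vector(y[, , j]) ~ rep(x, each = n)))
    expect_equal(r$slope[j], unname(fit$coefficients[2, 1]))
    expect_equal(r$t[j], unname(fit$coefficients[2, 3]))
    expect_equal(r$p[j], unname(fit$coefficients[2, 4]))
  }
  # exact line y = 10 - 0.05 x
  y2 <- array(rep(10 - 0.05 * rep(x, each = n), C), c(n, k, C))
  r2 <- cyclewise_regression(y2, x)
  expect_equal(r2$slope, rep(-0.05, C))
  expect_equal(r2$p, rep(0, C))
  # identical conditions -> slope 0
  y3 <- array(rep(rnorm(n), k * C), c(n, k, C))
  expect_equal(cyclewise_regression(y3, x)$slope, rep(0, C))
  expect_error(cyclewise_regression(y, c(1, 1, 1)), "distinct")
})

test_that("regression cluster test flags a perfect monotone condition effect", {
  set.seed(13)
  n <- 12; k <- 3; C <- 15
  x <- c(5, 45, 85)
  eff <- -0.05 * rep(x, each = n)
  y <- array(rnorm(n * k * C, sd = 0.5) + eff, c(n, k, C))
  r <- regression_cluster_test(y, x, n_perm = 500, seed = 4)
  expect_equal(nrow(r$clusters), 1)
  expect_equal(c(r$clusters$start, r$clusters$end), c(1, C))
  expect_lt(r$clusters$t_sum, 0)
  expect_true(r$clusters$significant)
  expect_identical(r, regression_cluster_test(y, x, n_perm = 500, seed = 4))
})

test_that("Bonferroni cluster threshold matches the three-comparison adjustment", {
  adj <- bonferroni_cluster_alpha(0.05, 3)
  expect_equal(round(adj$alpha, 3), 0.017)
  expect_equal(adj$quantile, 0.983, tolerance = 1e-3)
  expect_equal(bonferroni_cluster_alpha(0.05, 1)$alpha, 0.05)
  expect_equal(bonferroni_cluster_alpha(0.05, 5)$alpha, 0.01)
})
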