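# Cluster-based permutation tests with max-statistic family-wise error
# control: a cycle-wise paired-t variant (two within-participant conditions)
# and a cycle-wise regression-slope variant (graded condition covariate).
#
# Conventions: clusters are maximal runs of consecutive cycles whose
# cycle-wise test is significant at the forming threshold AND whose statistic
# has a single sign; the cluster statistic is the sum of the cycle statistics
# (t sum). The null distribution collects, for each permutation, the largest
# absolute t sum over that permutation's clusters (0 when no cluster forms),
# and a cluster's p value is the fraction of null values at or above its
# absolute t sum.

#' Cycle-wise paired t statistics
#'
#' @param A,B participant x cycle matrices of matched shape (>= 3 rows).
#' @return list with `t`, `p` (two-tailed), `df` and `mean_diff` per cycle.
#'   Cycles with zero variance of the differences get `t = sign(mean) * Inf`
#'   (p = 0) or `t = 0, p = 1` when the differences are identically zero.
#' @export
cyclewise_paired_t <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have matching shapes")
  n <- nrow(A)
  if (n < 3) stop("need at least 3 participants")
  D <- A - B
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), n - 1))
  p[t == 0 & s == 0] <- 1
  list(t = as.numeric(t), p = as.numeric(p), df = n - 1, mean_diff = as.numeric(m))
}

#' Form clusters of consecutive significant cycles
#'
#' Maximal runs of consecutive cycles with `p < forming_alpha` and a constant
#' sign of the statistic; the cluster statistic is the sum of the cycle
#' statistics over the run.
#'
#' @param t,p cycle-wise statistics and p values (aligned vectors).
#' @param forming_alpha cluster-forming threshold (default 0.05).
#' @return data.frame with `start`, `end`, `t_sum` (possibly zero rows).
#' @export
form_clusters <- function(t, p, forming_alpha = 0.05) {
  stopifnot(length(t) == length(p))
  code <- ifelse(p < forming_alpha & t != 0, sign(t), 0)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(), t_sum = numeric()))
  data.frame(start = starts[keep], end = ends[keep],
             t_sum = vapply(which(keep), function(i)
               sum(t[starts[i]:ends[i]]), 1))
}

# Largest |t_sum| over sign-homogeneous significant runs of one t vector;
# `sig` = logical significance per cycle. Returns 0 when no cluster forms.
max_cluster_tsum <- function(t, sig) {
  code <- ifelse(sig & t != 0, sign(t), 0)
  r <- rle(code)
  keep <- r$values != 0
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(abs(t)))
  max(cs[ends[keep] + 1L] - cs[starts[keep]])
}

#' Bonferroni-adjusted cluster significance threshold
#'
#' @param family_alpha family-wise alpha (default 0.05).
#' @param n_comparisons number of cluster tests in the family.
#' @return list with `alpha` (`family_alpha / n_comparisons`) and `quantile`
#'   (the corresponding null-distribution quantile `1 - alpha`).
#' @examples
#' bonferroni_cluster_alpha(0.05, 3)  # alpha 0.0167, quantile 0.983
#' @export
bonferroni_cluster_alpha <- function(family_alpha = 0.05, n_comparisons) {
  stopifnot(n_comparisons >= 1)
  a <- family_alpha / n_comparisons
  list(alpha = a, quantile = 1 - a)
}

cluster_result <- function(clusters, t, p, null_max, n_perm, forming_alpha,
                           cluster_alpha, seed, type, conservative) {
  p_cl <- vapply(abs(clusters$t_sum), function(ts) {
    # tolerance so algebraically tied permutations count as "at or above"
    eps <- if (is.finite(ts)) 1e-8 * max(1, ts) else 0
    if (conservative) (sum(null_max >= ts - eps) + 1) / (n_perm + 1)
    else mean(null_max >= ts - eps)
  }, 1)
  clusters$p_cluster <- p_cl
  clusters$significant <- p_cl < cluster_alpha
  structure(list(clusters = clusters, t = t, p = p,
                 null_max_tsums = null_max, n_perm = n_perm,
                 forming_alpha = forming_alpha, cluster_alpha = cluster_alpha,
                 threshold = stats::quantile(null_max, 1 - cluster_alpha,
                                             names = FALSE),
                 seed = seed, type = type), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$type, "variant,", length(x$t), "cycles,",
      x$n_perm, "permutations\n")
  if (nrow(x$clusters) == 0) cat("no clusters at forming alpha",
                                 x$forming_alpha, "\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Paired cluster-based permutation test
#'
#' Cycle-wise paired t tests between two within-participant condition
#' matrices; clusters of consecutive significant cycles are evaluated against
#' a max-statistic permutation null in which each participant's condition
#' assignment is independently flipped (equivalently, the sign of their
#' difference series), with the largest absolute cluster t sum recorded per
#' permutation.
#'
#' @param A,B participant x cycle matrices (e.g. learning block 1 vs 2).
#' @param n_perm number of permutations (default 10000).
#' @param forming_alpha cluster-forming threshold (default 0.05).
#' @param cluster_alpha cluster-level significance threshold (default 0.05;
#'   use [bonferroni_cluster_alpha()] for families of comparisons).
#' @param seed integer seed; results are reproducible given it.
#' @param conservative if `TRUE`, use the (+1)/(+1) permutation p value that
#'   counts the observed statistic in the null set; the default matches the
#'   plain "fraction of null t sums at or above" convention.
#' @return a `cluster_result`: observed clusters with p values and
#'   significance flags, cycle-wise statistics, and the null max-t-sum
#'   distribution.
#' @export
paired_cluster_test <- function(A, B, n_perm = 10000, forming_alpha = 0.05,
                                cluster_alpha = 0.05, seed = NULL,
                                conservative = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  A <- as.matrix(A); B <- as.matrix(B)
  obs <- cyclewise_paired_t(A, B)
  clusters <- form_clusters(obs$t, obs$p, forming_alpha)
  D <- A - B
  n <- nrow(D)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    perm_null_paired(S, D, forming_alpha)
  })
  cluster_result(clusters, obs$t, obs$p, null_max, n_perm, forming_alpha,
                 cluster_alpha, seed, "paired", conservative)
}

# Null max |t sum| for each row of sign matrix S applied to difference
# matrix D (n x C). Vectorized: under sign flips the column sums of squares
# are invariant, so all permuted t vectors come from one matrix product.
perm_null_paired <- function(S, D, forming_alpha) {
  n <- nrow(D)
  tcrit <- stats::qt(1 - forming_alpha / 2, n - 1)
  M <- (S %*% D) / n                           # n_perm x C means
  SS <- colSums(D^2)
  V <- sweep(-n * M^2, 2, SS, "+") / (n - 1)   # per-cell variances
  V[V < 0] <- 0
  Tm <- M / sqrt(V / n)
  Tm[is.nan(Tm)] <- 0           # 0/0: identically zero differences
  Tm[is.infinite(Tm)] <- sign(M[is.infinite(Tm)]) * .Machine$double.xmax / 1e6
  sig <- abs(Tm) > tcrit
  vapply(seq_len(nrow(Tm)), function(i) max_cluster_tsum(Tm[i, ], sig[i, ]), 1)
}

#' Cycle-wise regression of reach angle on a condition covariate
#'
#' For each cycle, ordinary least squares (with intercept) of the pooled
#' (participant, condition) observations on the condition covariate, e.g. the
#' number of veridical-feedback cycles preceding learning.
#'
#' @param y participant x condition x cycle array.
#' @param x condition covariate (length = number of conditions), or a
#'   participant x condition matrix when the covariate-to-condition mapping
#'   differs across participants.
#' @return list with `slope`, `t`, `p` (two-tailed) and `df` per cycle.
#' @export
cyclewise_regression <- function(y, x) {
  stopifnot(length(dim(y)) == 3)
  n <- dim(y)[1]; k <- dim(y)[2]; C <- dim(y)[3]
  X <- if (is.matrix(x)) x else matrix(x, n, k, byrow = TRUE)
  if (length(unique(as.vector(X))) < 2) stop("need >= 2 distinct covariate values")
  N <- n * k
  xv <- as.vector(X)                     # participant-major flattening
  Y <- matrix(y, N, C)                   # rows ordered (participant, condition)
  xc <- xv - mean(xv)
  Sxx <- sum(xc^2)
  Sxy <- as.numeric(crossprod(xc, Y))
  b1 <- Sxy / Sxx
  Syy <- colSums(Y^2) - N * colMeans(Y)^2
  rss <- pmax(Syy - Sxy^2 / Sxx, 0)
  se <- sqrt(rss / (N - 2) / Sxx)
  t <- ifelse(se == 0, ifelse(b1 == 0, 0, sign(b1) * Inf), b1 / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), N - 2))
  p[t == 0 & se == 0] <- 1
  list(slope = b1, t = as.numeric(t), p = as.numeric(p), df = N - 2)
}

#' Regression-slope cluster-based permutation test
#'
#' Clusters of consecutive cycles in which the regression slope of reach
#' angle on a condition covariate differs from zero, evaluated against a
#' max-statistic null in which the condition labels are shuffled
#' independently within each participant (preserving the within-subject
#' structure).
#'
#' @inheritParams cyclewise_regression
#' @inheritParams paired_cluster_test
#' @return a `cluster_result` with slope-t based clusters.
#' @export
regression_cluster_test <- function(y, x, n_perm = 10000, forming_alpha = 0.05,
                                    cluster_alpha = 0.05, seed = NULL,
                                    conservative = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- dim(y)[1]; k <- dim(y)[2]; C <- dim(y)[3]
  obs <- cyclewise_regression(y, x)
  clusters <- form_clusters(obs$t, obs$p, forming_alpha)
  X <- if (is.matrix(x)) x else matrix(x, n, k, byrow = TRUE)
  N <- n * k
  Y <- matrix(y, N, C)
  xc_all <- as.vector(X) - mean(X)
  Sxx <- sum(xc_all^2)
  Syy <- colSums(Y^2) - N * colMeans(Y)^2
  tcrit <- stats::qt(1 - forming_alpha / 2, N - 2)
  perms <- perm_index_matrix(k)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      pi_idx <- perms[sample.int(nrow(perms), n, replace = TRUE), , drop = FALSE]
      # permute each participant's covariate values across their conditions
      W <- matrix(X[cbind(rep(seq_len(n), k),
                          as.vector(pi_idx))], n, k) - mean(X)
      Sxy <- as.numeric(crossprod(as.vector(W), Y))
      b1 <- Sxy / Sxx
      rss <- pmax(Syy - Sxy^2 / Sxx, 0)
      se <- sqrt(rss / (N - 2) / Sxx)
      t <- ifelse(se == 0, 0, b1 / se)
      max_cluster_tsum(t, abs(t) > tcrit)
    }, 1)
  })
  cluster_result(clusters, obs$t, obs$p, null_max, n_perm, forming_alpha,
                 cluster_alpha, seed, "regression", conservative)
}

# all permutations of 1..k as rows (k small)
perm_index_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_index_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= k - 1L) sub[, pos:(k - 1L), drop = FALSE]
    cbind(left, k, right)
  }))
}
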