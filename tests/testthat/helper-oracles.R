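# Independent reference implementations used as oracles. These deliberately
# use plain loops and base building blocks, not the package's vectorized
# paths.

# single-pass exclusion rule, literal reading
oracle_exclude <- function(a, dev = 100, delta = 20) {
  out <- logical(length(a))
  for (t in seq_along(a)) {
    if (abs(a[t]) > dev) out[t] <- TRUE
    if (t > 1 && abs(a[t] - a[t - 1]) > delta) out[t] <- TRUE
  }
  out
}

# max |t sum| over sign-homogeneous runs of significant cycles, loop version
oracle_max_tsum <- function(tv, pv, alpha = 0.05) {
  best <- 0; run <- 0; run_sign <- 0
  for (j in seq_along(tv)) {
    if (pv[j] < alpha && tv[j] != 0) {
      s <- sign(tv[j])
      if (s == run_sign) run <- run + tv[j]
      else { run <- tv[j]; run_sign <- s }
      best <- max(best, abs(run))
    } else { run <- 0; run_sign <- 0 }
  }
  best
}

# exhaustive sign-flip null of the paired cluster test for n <= 12
oracle_exact_cluster_p <- function(A, B, forming_alpha = 0.05) {
  D <- A - B
  n <- nrow(D)
  tp <- function(M) {
    tv <- numeric(ncol(M)); pv <- numeric(ncol(M))
    for (j in seq_len(ncol(M))) {
      tt <- stats::t.test(M[, j])
      tv[j] <- unname(tt$statistic); pv[j] <- tt$p.value
    }
    list(t = tv, p = pv)
  }
  obs <- tp(D)
  null <- numeric(2^n)
  for (m in seq_len(2^n)) {
    bits <- as.integer(intToBits(m - 1))[1:n]
    s <- ifelse(bits == 1, -1, 1)
    pr <- tp(D * s)
    null[m] <- oracle_max_tsum(pr$t, pr$p, forming_alpha)
  }
  # p value for each observed cluster
  cl <- reclamp::form_clusters(obs$t, obs$p, forming_alpha)
  cl$p_exact <- vapply(abs(cl$t_sum), function(ts) mean(null >= ts), 1)
  cl
}

# deterministic state-space learning curve (per trial), cycle-averaged
oracle_learning_curve <- function(a_f, u, scale, n_cycles, tpc) {
  x <- 0; xs <- numeric(n_cycles * tpc)
  for (t in seq_len(n_cycles * tpc)) {
    xs[t] <- x
    x <- a_f * x + scale * u
  }
  colMeans(matrix(xs, tpc))
}

quick_protocol <- function(...) clamp_protocol("E1", clamp_sign = -1, ...)
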