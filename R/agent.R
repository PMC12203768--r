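# Context-tagged state-space learner used to generate synthetic cohorts.
#
# Each movement context c carries an adaptation state x_c (degrees, signed in
# screen coordinates) and a count P_c of prior trials with feedback whose
# contingency is discrepant from the learning clamp. Updates from a trial's
# feedback are scaled by an interference multiplier 1 / (1 + kappa * P_c) and
# generalize to neighboring contexts with a Gaussian falloff over the angular
# distance between context centers.

#' Generative parameters of the synthetic learner
#'
#' @param a_f retention factor per feedback trial (0-1).
#' @param a_n retention factor per no-feedback trial (0-1, close to 1).
#' @param u clamp-driven update magnitude (degrees/trial).
#' @param b error-proportional learning rate for contingent feedback (0-1).
#' @param sigma_m motor noise SD (degrees).
#' @param kappa interference coefficient per discrepant-feedback trial.
#' @param sigma_g generalization width across context centers (degrees).
#' @param mt_median,mt_sdlog lognormal movement-time parameters (ms, log-SD).
#' @return an `agent_params` list.
#' @details With `kappa = 0` and a constant clamp the state's fixed point is
#'   `u / (1 - a_f)` in the adaptive direction; the defaults put it at 20
#'   degrees, reached over roughly 80 cycles of four reaches.
#' @export
agent_params <- function(a_f = 0.98, a_n = 0.998, u = 0.4, b = 0.15,
                         sigma_m = 4, kappa = 0.003, sigma_g = 20,
                         mt_median = 180, mt_sdlog = 0.25) {
  stopifnot(a_f > 0, a_f <= 1, a_n > 0, a_n <= 1, u >= 0,
            b >= 0, b < 1, sigma_m > 0, kappa >= 0, sigma_g > 0)
  structure(list(a_f = a_f, a_n = a_n, u = u, b = b, sigma_m = sigma_m,
                 kappa = kappa, sigma_g = sigma_g, mt_median = mt_median,
                 mt_sdlog = mt_sdlog), class = "agent_params")
}

#' Interference multiplier from discrepant-feedback exposure
#'
#' @param P_c count of prior discrepant-feedback trials in the context.
#' @param kappa interference coefficient.
#' @return multiplier in (0, 1]: `1 / (1 + kappa * P_c)`, equal to 1 with no
#'   prior exposure and strictly decreasing in `P_c`.
#' @examples
#' interference_scale(100, 0.01)  # 0.5
#' @export
interference_scale <- function(P_c, kappa) {
  stopifnot(all(P_c >= 0), kappa >= 0)
  1 / (1 + kappa * P_c)
}

# circular mean of target angles (degrees)
context_center <- function(targets) {
  r <- targets * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

# K x K matrix of generalization factors between context centers
generalization_matrix <- function(contexts, sigma_g) {
  centers <- vapply(contexts, context_center, 1)
  K <- length(centers)
  G <- diag(1, K)
  if (K > 1) {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      d <- abs(wrap_angle(centers[i] - centers[j]))
      G[i, j] <- G[j, i] <- exp(-d^2 / (2 * sigma_g^2))
    }
  }
  dimnames(G) <- list(names(contexts), names(contexts))
  G
}

#' Initial agent state for a protocol
#'
#' @param protocol a [clamp_protocol()].
#' @param params an [agent_params()].
#' @return an `agent_state` list: per-context adaptation state `x` (all zero),
#'   discrepant-feedback exposure counts `P` (all zero) and the context
#'   generalization matrix.
#' @export
agent_state <- function(protocol, params = agent_params()) {
  K <- length(protocol$contexts)
  structure(list(
    x = stats::setNames(numeric(K), names(protocol$contexts)),
    P = stats::setNames(integer(K), names(protocol$contexts)),
    G = generalization_matrix(protocol$contexts, params$sigma_g)),
    class = "agent_state")
}

#' One state-transition of the learner
#'
#' Applies the feedback of a single trial to the agent state. Clamped feedback
#' drives a fixed-size update opposite the clamp direction; veridical and
#' rotated feedback drive an error-proportional correction; with no feedback
#' the state decays. The update is scaled by [interference_scale()] and
#' generalizes to other contexts via the Gaussian context kernel. The exposure
#' count `P` increments on every trial with a visible cursor whose contingency
#' differs from the learning clamp (veridical, rotated, or reversed clamp).
#'
#' @param state an [agent_state()].
#' @param trial list with `context`, `target_deg`, `kind` (feedback kind),
#'   `cursor_deg` (NA when `kind = "none"`), `clamp_sign`.
#' @param params an [agent_params()].
#' @return the updated `agent_state`.
#' @export
agent_update <- function(state, trial, params) {
  cx <- trial$context
  if (!cx %in% names(state$x)) stop("unknown context: ", cx)
  kind <- trial$kind
  if (!kind %in% c("none", "veridical", "clamped", "rotated"))
    stop("unknown feedback kind: ", kind)
  if (kind == "none") {
    state$x[cx] <- params$a_n * state$x[cx]
    return(state)
  }
  err <- wrap_angle(trial$cursor_deg - trial$target_deg)
  s <- interference_scale(state$P[[cx]], params$kappa)
  inc <- if (kind == "clamped") -s * params$u * sign(err) else -s * params$b * err
  state$x[cx] <- params$a_f * state$x[cx]
  state$x <- state$x + state$G[, cx] * inc
  discrepant <- kind %in% c("veridical", "rotated") ||
    (kind == "clamped" && sign(err) != trial$clamp_sign)
  if (discrepant) state$P[cx] <- state$P[[cx]] + 1L
  state
}

#' Simulate one participant in closed loop
#'
#' Runs the learner through a protocol trial by trial: the hand angle is
#' emitted from the current state plus motor noise, the cursor is computed by
#' the protocol's feedback policy from that hand angle, and the state is
#' updated from the experienced feedback. The adaptive washout transition is
#' driven by the simulated behavior (magnitude of the median direction error
#' within the criterion window for the required consecutive cycles, with a
#' cap so that a minimum veridical phase always remains), and the
#' gradual-rotation washout magnitude is initialized to the participant's own
#' mean reach angle over the first aftereffect block, exactly as the
#' individualized experimental procedure prescribes.
#'
#' @param protocol a [clamp_protocol()].
#' @param params an [agent_params()].
#' @param participant participant identifier.
#' @param seed integer seed; the full trial table is reproducible from it.
#' @return data.frame of trial records: identifiers, geometry, feedback and
#'   movement time, one row per reach in chronological order.
#' @export
simulate_participant <- function(protocol, params = agent_params(),
                                 participant = "S01", seed = NULL) {
  stopifnot(inherits(protocol, "clamp_protocol"), inherits(params, "agent_params"))
  with_seed(seed, {
    sched <- make_schedule(protocol, seed = NULL)
    n <- nrow(sched)
    noise <- stats::rnorm(n, 0, params$sigma_m)
    mt <- stats::rlnorm(n, log(params$mt_median), params$mt_sdlog)

    cxn <- names(protocol$contexts)
    K <- length(cxn)
    ctx_i <- match(sched$context, cxn)
    G <- generalization_matrix(protocol$contexts, params$sigma_g)
    x <- numeric(K); P <- numeric(K)
    cs <- protocol$clamp_sign
    # hot-path copies (plain vectors; data.frame access is too slow per trial)
    sk_kind <- sched$kind; sk_tgt <- sched$target_deg
    sk_off <- sched$clamp_offset; sk_cyc <- sched$cycle
    a_f <- params$a_f; a_n <- params$a_n; u <- params$u; b <- params$b
    kap <- params$kappa

    hand <- numeric(n); cursor <- rep(NA_real_, n)
    feedback <- character(n); rot <- rep(NA_real_, n)
    block_out <- sched$block

    # adaptive washout bookkeeping, per context
    reversed <- rep(TRUE, K)           # still in reversed-clamp phase?
    medians <- vector("list", K)       # per-cycle |error| medians so far
    # gradual washout (E3): magnitude schedule filled in when the block starts
    grad_mag <- NULL; grad_block_start <- NA_integer_

    cyc_counts <- tabulate(sched$cycle, nbins = protocol$total_cycles)
    row0 <- 1L
    for (cy in seq_len(protocol$total_cycles)) {
      if (cyc_counts[cy] == 0L) next
      idx <- row0:(row0 + cyc_counts[cy] - 1L)
      row0 <- row0 + cyc_counts[cy]
      for (i in idx) {
        k <- ctx_i[i]; kind <- sk_kind[i]
        if (kind == "adaptive") {
          kind <- if (reversed[k]) "clamped" else "veridical"
          block_out[i] <- if (reversed[k]) "washout_reversed_clamp" else "washout_veridical"
        } else if (kind == "gradual") {
          if (is.null(grad_mag)) {
            ae <- which(block_out == "aftereffect1" & seq_len(n) < i)
            m0 <- mean(wrap_angle(hand[ae] - sk_tgt[ae]))
            blk <- context_block_at(protocol, cxn[k], cy)
            grad_block_start <- blk$start_cycle
            grad_mag <- gradual_rotation_schedule(
              abs(m0), protocol$gradual_decrement,
              blk$end_cycle - blk$start_cycle + 1L) * -sign(m0)
          }
          r <- grad_mag[cy - grad_block_start + 1L]
          kind <- if (r == 0) "veridical" else "rotated"
          rot[i] <- r
        }
        tgt <- sk_tgt[i]
        h <- tgt + x[k] + noise[i]
        hand[i] <- h
        feedback[i] <- kind
        if (kind == "none") {
          x[k] <- a_n * x[k]
          next
        }
        cur <- if (kind == "veridical") h
               else if (kind == "rotated") h + rot[i]
               else tgt + cs * sk_off[i]
        cursor[i] <- cur
        err <- wrap_angle(cur - tgt)
        s <- 1 / (1 + kap * P[k])
        inc <- if (kind == "clamped") -s * u * sign(err) else -s * b * err
        x[k] <- a_f * x[k]
        x <- x + G[, k] * inc
        if (kind != "clamped" || sign(err) != cs) P[k] <- P[k] + 1
      }
      # end-of-cycle: adaptive washout monitors
      for (k in which(reversed)) {
        ki <- idx[ctx_i[idx] == k]
        if (length(ki) == 0 || sk_kind[ki[1]] != "adaptive") next
        blk <- context_block_at(protocol, cxn[k], cy)
        cyc_in_washout <- cy - blk$start_cycle + 1L
        med <- abs(stats::median(wrap_angle(hand[ki] - sk_tgt[ki])))
        medians[[k]] <- c(medians[[k]], med)
        if (washout_transition_reached(medians[[k]], protocol$washout_window,
                                       protocol$washout_consecutive) ||
            cyc_in_washout >= protocol$reversed_cap)
          reversed[k] <- FALSE
      }
    }

    out <- data.frame(
      participant = participant, experiment = protocol$experiment,
      context = sched$context, block = block_out, cycle = sched$cycle,
      trial = sched$trial, trial_in_cycle = sched$trial_in_cycle,
      target_deg = sched$target_deg, hand_deg = hand, cursor_deg = cursor,
      feedback = feedback, clamp_sign = cs, rotation_deg = rot,
      movement_time_ms = mt, too_slow = mt > protocol$movement_time_limit,
      stringsAsFactors = FALSE)
    if (protocol$experiment == "E4") {
      role <- stats::setNames(names(protocol$context_roles),
                              unname(protocol$context_roles))
      out$context_role <- unname(role[out$context])
    } else if (protocol$experiment == "E5") {
      out$veridical_cycles <- unname(protocol$context_roles[out$context])
    }
    out
  })
}

# counterbalancing cells per design
cohort_cells <- function(experiment, n) {
  cells <- switch(experiment,
    E1 = , E2 = , E3 = data.frame(clamp_sign = c(-1, 1)),
    E4 = expand.grid(clamp_sign = c(-1, 1), relearn = c("ctxA", "ctxB"),
                     stringsAsFactors = FALSE),
    E5 = expand.grid(clamp_sign = c(-1, 1), rot = 0:2))
  if (n %% nrow(cells) != 0)
    stop("n_participants (", n, ") must be divisible by the ",
         nrow(cells), " counterbalancing cells of ", experiment)
  cells[rep(seq_len(nrow(cells)), each = n / nrow(cells)), , drop = FALSE]
}

#' Simulate a counterbalanced cohort
#'
#' Clamp direction is split into exact halves; in E4 the context-role
#' assignment and in E5 the context-to-exposure assignment (cyclic rotations
#' of 85/45/5 veridical cycles) are counterbalanced exactly. Per-participant
#' seeds are derived deterministically from `seed`.
#'
#' @param experiment experiment id (`"E1"` ... `"E5"`).
#' @param n_participants cohort size; must be divisible by the design's
#'   counterbalancing cells (2 for E1-E3, 4 for E4, 6 for E5).
#' @param params an [agent_params()].
#' @param seed master integer seed.
#' @param ... passed on to [clamp_protocol()].
#' @return long trial table (one row per reach) for the whole cohort, with
#'   attributes `params`, `master_seed` and `participant_seeds`.
#' @export
simulate_cohort <- function(experiment, n_participants,
                            params = agent_params(), seed = 1, ...) {
  cells <- cohort_cells(experiment, n_participants)
  pseeds <- with_seed(seed, sample.int(2147483646L, n_participants))
  exposures <- list(c(85, 45, 5), c(45, 5, 85), c(5, 85, 45))
  tabs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    roles <- if (experiment == "E4") {
      rc <- cells$relearn[i]
      stats::setNames(c(rc, setdiff(c("ctxA", "ctxB"), rc)),
                      c("relearn", "long_baseline"))
    } else if (experiment == "E5") {
      stats::setNames(exposures[[cells$rot[i] + 1L]], c("ctx1", "ctx2", "ctx3"))
    } else NULL
    prot <- clamp_protocol(experiment, clamp_sign = cells$clamp_sign[i],
                           context_roles = roles, ...)
    tabs[[i]] <- simulate_participant(prot, params,
                                      participant = sprintf("S%02d", i),
                                      seed = pseeds[i])
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "master_seed") <- seed
  attr(out, "participant_seeds") <- pseeds
  out
}

#' Refit the learner to observed learning-curve data
#'
#' Least-squares fit of the retention factor `a_f` and update size `u` to the
#' cohort-mean cycle series of a clamped learning block (the deterministic
#' trajectory `x[t+1] = a_f x[t] + s u` started from zero, averaged within
#' cycles), followed by a motor-noise estimate from the trial-level residuals
#' around the fitted trajectory. Used for parameter-recovery validation of the
#' generator.
#'
#' @param trials cohort trial table (as from [simulate_cohort()]).
#' @param block learning block to fit (default `"learning1"`).
#' @param scale interference multiplier in force during the block (from
#'   [interference_scale()]; supply the true exposure count when validating
#'   recovery with `kappa` fixed at its generating value).
#' @return list with elements `a_f`, `u`, `sigma_m`, the fitted per-cycle
#'   trajectory and the observed cohort-mean cycle series.
#' @export
fit_state_space <- function(trials, block = "learning1", scale = 1) {
  tr <- trials[trials$block == block, ]
  if (nrow(tr) == 0) stop("no trials in block ", block)
  signed <- sign_align(wrap_angle(tr$hand_deg - tr$target_deg), tr$clamp_sign)
  cyc <- tr$cycle - min(tr$cycle) + 1L
  tpc <- max(table(tr$participant, tr$cycle))
  pos <- stats::ave(seq_along(signed), tr$participant, FUN = seq_along)
  obs <- tapply(signed, cyc, mean)
  n_cyc <- length(obs)
  traj <- function(a, u) {
    xs <- numeric(n_cyc * tpc)
    for (t in seq_len(n_cyc * tpc - 1)) xs[t + 1] <- a * xs[t] + scale * u
    xs
  }
  sse <- function(p) {
    xs <- traj(p[1], p[2])
    sum((colMeans(matrix(xs, tpc)) - obs)^2)
  }
  fit <- stats::optim(c(0.9, 1), sse, method = "L-BFGS-B",
                      lower = c(0.5, 1e-4), upper = c(0.9999, 10))
  xs <- traj(fit$par[1], fit$par[2])
  sigma <- stats::sd(signed - xs[pmin(pos, length(xs))])
  list(a_f = fit$par[1], u = fit$par[2], sigma_m = sigma,
       fitted_cycle_means = colMeans(matrix(xs, tpc)),
       observed_cycle_means = as.numeric(obs))
}
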