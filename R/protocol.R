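# Protocol construction for the five error-clamp experiment designs.
#
# A protocol is a per-context timeline of blocks. Cycle indices are absolute
# (1-based, shared across contexts of an experiment); within a cycle each
# active target is reached exactly once, in pseudorandom order.

#' Feedback policy for a block of trials
#'
#' @param kind one of `"none"`, `"veridical"`, `"clamped"`, `"rotated"`.
#' @param clamp_offset unsigned clamp offset in degrees (used when
#'   `kind = "clamped"`); the cursor path is fixed at
#'   `target + clamp_sign * clamp_offset`, independent of the hand.
#'   A negative value encodes a reversed clamp.
#' @param rotation hand-contingent rotation in degrees (used when
#'   `kind = "rotated"`).
#' @return a `feedback_policy` list.
#' @export
feedback_policy <- function(kind = c("none", "veridical", "clamped", "rotated"),
                            clamp_offset = 15, rotation = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, clamp_offset = clamp_offset, rotation = rotation),
            class = "feedback_policy")
}

#' Cursor angle produced by a feedback policy
#'
#' Clamped feedback follows an invariant path with respect to the target:
#' `target + clamp_sign * clamp_offset`, regardless of where the hand went.
#' Veridical feedback mirrors the hand; rotated feedback adds a fixed
#' hand-contingent rotation; with no feedback the cursor is absent (`NA`).
#'
#' @param policy a [feedback_policy()].
#' @param hand_angle hand direction in degrees.
#' @param target_angle target direction in degrees.
#' @param clamp_sign +1 for a counter-clockwise clamp, -1 for clockwise.
#' @return cursor angle in degrees, or `NA_real_` for no feedback.
#' @examples
#' feedback_angle(feedback_policy("clamped"), 90, 45, -1)  # 30
#' @export
feedback_angle <- function(policy, hand_angle, target_angle, clamp_sign = -1) {
  stopifnot(inherits(policy, "feedback_policy"),
            is.finite(hand_angle) || policy$kind == "none",
            clamp_sign %in% c(-1, 1))
  switch(policy$kind,
         none      = NA_real_,
         veridical = hand_angle,
         rotated   = hand_angle + policy$rotation,
         clamped   = target_angle + clamp_sign * policy$clamp_offset)
}

#' Has the adaptive washout criterion been met?
#'
#' During the reversed-clamp phase of a standard washout block, the transition
#' to veridical feedback occurs once the magnitude of the per-cycle median
#' direction error has been strictly within `window` degrees of the target
#' for `n_consecutive` consecutive cycles. With fewer than `n_consecutive`
#' cycles of history the criterion is not met.
#'
#' @param recent_cycle_medians magnitudes of the per-cycle median direction
#'   error (degrees), oldest first.
#' @param window criterion window in degrees (default 5).
#' @param n_consecutive required run length in cycles (default 5).
#' @return logical.
#' @export
washout_transition_reached <- function(recent_cycle_medians, window = 5,
                                       n_consecutive = 5) {
  m <- recent_cycle_medians
  if (length(m) < n_consecutive) return(FALSE)
  all(utils::tail(m, n_consecutive) < window)
}

#' Per-cycle rotation magnitudes for a gradual washout
#'
#' The rotation starts at the participant's final adaptation level and is
#' decreased by `decrement` degrees on each successive cycle until it reaches
#' zero, after which feedback is veridical.
#'
#' @param initial_magnitude starting rotation magnitude in degrees (>= 0).
#' @param decrement decrease per cycle in degrees (> 0).
#' @param n_cycles length of the returned schedule.
#' @return numeric vector of non-negative magnitudes, one per cycle.
#' @examples
#' gradual_rotation_schedule(2.5, 1, 6)  # 2.5 1.5 0.5 0 0 0
#' @export
gradual_rotation_schedule <- function(initial_magnitude, decrement = 1,
                                      n_cycles = 110) {
  if (initial_magnitude < 0) stop("initial_magnitude must be >= 0")
  if (decrement <= 0) stop("decrement must be > 0")
  pmax(initial_magnitude - (seq_len(n_cycles) - 1) * decrement, 0)
}

experiment_ids <- c("E1", "E2", "E3", "E4", "E5")

# One timeline row per (context, block). `kind` is the block's feedback kind;
# "adaptive" marks the reversed-clamp -> veridical washout whose split is
# determined online; "gradual" washouts are rotated until the individual
# schedule reaches zero, then veridical.
timeline_row <- function(context, block, start, end, kind,
                         clamp_offset = NA_real_, adaptive = FALSE) {
  data.frame(context = context, block = block, start_cycle = start,
             end_cycle = end, kind = kind, clamp_offset = clamp_offset,
             adaptive = adaptive, stringsAsFactors = FALSE)
}

#' Build the protocol for one of the five experiment designs
#'
#' @param experiment `"E1"` (relearning after reversed-clamp + veridical
#'   washout), `"E2"` (no-feedback washout), `"E3"` (gradual-rotation washout),
#'   `"E4"` (two contexts: relearning vs. extended veridical baseline) or
#'   `"E5"` (three contexts with 5/45/85 veridical cycles before learning).
#' @param clamp_sign +1 for a counter-clockwise learning clamp, -1 clockwise.
#' @param context_roles counterbalancing slot assignment. For E4 a named
#'   character vector `c(relearn = , long_baseline = )` over contexts
#'   `"ctxA"` (targets 30, 60) and `"ctxB"` (210, 240). For E5 a named numeric
#'   vector giving the number of veridical cycles (a permutation of 85, 45, 5)
#'   for contexts `"ctx1"` (10, 40), `"ctx2"` (130, 160), `"ctx3"` (250, 280).
#'   `NULL` selects the default assignment.
#' @param seed default seed for [make_schedule()].
#' @param clamp_deg clamp offset magnitude in degrees (default 15).
#' @param movement_time_limit "too slow" threshold in ms (default 300).
#' @param washout_window,washout_consecutive adaptive-transition criterion
#'   (median error strictly within `washout_window` degrees for
#'   `washout_consecutive` consecutive cycles).
#' @param gradual_decrement rotation decrease per washout cycle in E3 (deg).
#' @return a `clamp_protocol` object: contexts (target sets), the block
#'   timeline, counterbalancing fields and adaptive-washout parameters.
#' @examples
#' p <- clamp_protocol("E1", clamp_sign = -1, seed = 7)
#' p$total_cycles  # 300
#' @export
clamp_protocol <- function(experiment, clamp_sign = -1, context_roles = NULL,
                           seed = NULL, clamp_deg = 15,
                           movement_time_limit = 300,
                           washout_window = 5, washout_consecutive = 5,
                           gradual_decrement = 1) {
  if (!experiment %in% experiment_ids)
    stop("unknown experiment id: ", experiment)
  if (!clamp_sign %in% c(-1, 1)) stop("clamp_sign must be -1 or +1")
  off <- clamp_deg  # learning clamp offset; sign applied via clamp_sign

  if (experiment %in% c("E1", "E2", "E3")) {
    contexts <- list(main = c(45, 135, 225, 335))
    wk <- switch(experiment, E1 = "adaptive", E2 = "none", E3 = "gradual")
    wb <- switch(experiment, E1 = "washout", E2 = "washout_no_feedback",
                 E3 = "washout_gradual")
    tl <- rbind(
      timeline_row("main", "no_feedback_baseline", 1, 5, "none"),
      timeline_row("main", "veridical_baseline", 6, 10, "veridical"),
      timeline_row("main", "learning1", 11, 90, "clamped", off),
      timeline_row("main", "aftereffect1", 91, 100, "none"),
      timeline_row("main", wb, 101, 210, wk,
                   if (experiment == "E1") -off else NA_real_,
                   adaptive = experiment == "E1"),
      timeline_row("main", "learning2", 211, 290, "clamped", off),
      timeline_row("main", "aftereffect2", 291, 300, "none"))
    total <- 300
    reversed_cap <- 40  # ensures >= 70 veridical washout cycles
    roles <- NULL
  } else if (experiment == "E4") {
    contexts <- list(ctxA = c(30, 60), ctxB = c(210, 240))
    roles <- context_roles %||% c(relearn = "ctxA", long_baseline = "ctxB")
    if (!setequal(names(roles), c("relearn", "long_baseline")) ||
        !setequal(unname(roles), names(contexts)))
      stop("E4 context_roles must assign 'relearn' and 'long_baseline' to ctxA/ctxB")
    rc <- unname(roles[["relearn"]]); lb <- unname(roles[["long_baseline"]])
    tl <- rbind(
      timeline_row(rc, "no_feedback_baseline", 1, 5, "none"),
      timeline_row(rc, "veridical_baseline", 6, 10, "veridical"),
      timeline_row(rc, "learning1", 11, 50, "clamped", off),
      timeline_row(rc, "aftereffect1", 51, 60, "none"),
      timeline_row(rc, "washout", 61, 100, "adaptive", -off, adaptive = TRUE),
      timeline_row(rc, "learning2", 101, 140, "clamped", off),
      timeline_row(rc, "aftereffect2", 141, 150, "none"),
      timeline_row(lb, "no_feedback_baseline", 1, 5, "none"),
      timeline_row(lb, "veridical_baseline", 6, 55, "veridical"),
      timeline_row(lb, "no_feedback_insert", 56, 65, "none"),
      timeline_row(lb, "veridical_baseline", 66, 100, "veridical"),
      timeline_row(lb, "learning1", 101, 140, "clamped", off),
      timeline_row(lb, "aftereffect1", 141, 150, "none"))
    total <- 150
    reversed_cap <- 15  # 40-cycle washout: keep >= 25 veridical cycles
  } else { # E5
    contexts <- list(ctx1 = c(10, 40), ctx2 = c(130, 160), ctx3 = c(250, 280))
    roles <- context_roles %||% c(ctx1 = 85, ctx2 = 45, ctx3 = 5)
    if (!setequal(names(roles), names(contexts)) ||
        !setequal(unname(roles), c(85, 45, 5)))
      stop("E5 context_roles must assign veridical exposures 85/45/5 to ctx1/ctx2/ctx3")
    ver_start <- function(exposure) 91 - exposure  # veridical block ends at cycle 90
    tl <- do.call(rbind, c(
      lapply(names(contexts), function(cx)
        timeline_row(cx, "no_feedback_baseline", 1, 5, "none")),
      lapply(names(contexts), function(cx)
        timeline_row(cx, "veridical_baseline", ver_start(roles[[cx]]), 90,
                     "veridical")),
      lapply(names(contexts), function(cx)
        timeline_row(cx, "learning1", 91, 130, "clamped", off)),
      lapply(names(contexts), function(cx)
        timeline_row(cx, "aftereffect1", 131, 140, "none"))))
    total <- 140
    reversed_cap <- NA_integer_
  }

  structure(list(
    experiment = experiment, clamp_sign = clamp_sign, clamp_deg = clamp_deg,
    contexts = contexts, context_roles = roles, timeline = tl,
    total_cycles = total, movement_time_limit = movement_time_limit,
    washout_window = washout_window, washout_consecutive = washout_consecutive,
    gradual_decrement = gradual_decrement, reversed_cap = reversed_cap,
    seed = seed), class = "clamp_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.clamp_protocol <- function(x, ...) {
  cat("<clamp_protocol>", x$experiment, "-", x$total_cycles, "cycles,",
      length(x$contexts), "context(s), clamp",
      if (x$clamp_sign > 0) "CCW" else "CW", paste0(x$clamp_deg, "deg\n"))
  print(x$timeline, row.names = FALSE)
  invisible(x)
}

# Block label + feedback kind for context `cx` at cycle `cy`; NULL if inactive.
context_block_at <- function(protocol, cx, cy) {
  tl <- protocol$timeline
  i <- which(tl$context == cx & tl$start_cycle <= cy & tl$end_cycle >= cy)
  if (length(i) == 0) return(NULL)
  tl[i[1], ]
}

#' Expand a protocol into a per-trial schedule
#'
#' One trial per active target per cycle; within each cycle the order of the
#' active targets is drawn pseudorandomly from a seeded generator, so the
#' schedule is reproducible.
#'
#' @param protocol a [clamp_protocol()].
#' @param seed integer seed (defaults to the protocol's own seed).
#' @return data.frame with columns `cycle`, `trial` (chronological),
#'   `context`, `target_deg`, `block`, `kind`, `clamp_offset`, `adaptive`.
#' @export
make_schedule <- function(protocol, seed = protocol$seed) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  tl <- protocol$timeline
  nrep <- tl$end_cycle - tl$start_cycle + 1L
  # one row per active (context, cycle), then per target
  cyc <- unlist(lapply(seq_len(nrow(tl)),
                       function(i) tl$start_cycle[i]:tl$end_cycle[i]))
  ctx <- rep(tl$context, nrep)
  ntg <- vapply(protocol$contexts[ctx], length, 1L)
  j <- rep(seq_along(ctx), ntg)
  tgt <- unlist(protocol$contexts[ctx], use.names = FALSE)
  row_of <- rep(seq_len(nrow(tl)), nrep)[j]
  # pseudorandom order within each cycle: random sort keys, stable by cycle
  key <- with_seed(seed, stats::runif(length(tgt)))
  o <- order(cyc[j], key)
  cyc_s <- cyc[j][o]
  out <- data.frame(
    cycle = cyc_s, trial = seq_along(o),
    trial_in_cycle = sequence(rle(cyc_s)$lengths),
    context = ctx[j][o], target_deg = tgt[o], block = tl$block[row_of][o],
    kind = tl$kind[row_of][o], clamp_offset = tl$clamp_offset[row_of][o],
    adaptive = tl$adaptive[row_of][o], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
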