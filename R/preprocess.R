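# Trial-table preprocessing: signed reach angles, outlier exclusion,
# cycle averaging and aftereffect measures.

#' Sign-align reach angles to the adaptive direction
#'
#' Participants who experienced a counter-clockwise clamp have the sign of
#' their reach angle flipped, so that positive always means movement opposite
#' the perturbed feedback (the adaptive direction).
#'
#' @param raw_angle raw reach angle(s) in degrees (CCW positive).
#' @param clamp_sign +1 for a CCW clamp, -1 for CW; vectorized.
#' @return sign-aligned angle(s).
#' @export
sign_align <- function(raw_angle, clamp_sign) {
  if (!all(clamp_sign %in% c(-1, 1))) stop("clamp_sign must be -1 or +1")
  ifelse(clamp_sign > 0, -raw_angle, raw_angle)
}

#' Outlier-trial exclusion mask
#'
#' A trial is excluded if its (sign-aligned) reach angle deviates from the
#' target by more than `deviation_limit` degrees, or if the absolute change
#' from the immediately preceding trial's raw (pre-exclusion) angle exceeds
#' `delta_limit` degrees. Both rules are applied in a single chronological
#' pass; the first trial is exempt from the delta rule. Comparisons are
#' strict (ties are kept).
#'
#' @param signed_angles reach angles in chronological order (one participant).
#' @param deviation_limit absolute-deviation threshold (default 100 degrees).
#' @param delta_limit trial-to-trial change threshold (default 20 degrees).
#' @return logical vector, `TRUE` = exclude.
#' @examples
#' exclude_trials(c(150, 0, 0))  # TRUE TRUE FALSE
#' @export
exclude_trials <- function(signed_angles, deviation_limit = 100,
                           delta_limit = 20) {
  a <- signed_angles
  abs(a) > deviation_limit | c(FALSE, abs(diff(a)) > delta_limit)
}

#' Preprocess a trial table into cycle series and aftereffect measures
#'
#' Computes signed reach angles (hand direction relative to target, flipped
#' for CCW-clamp participants), applies the exclusion rules chronologically
#' within participant, averages retained trials within each participant x
#' context x cycle cell, linearly interpolates cells left empty by exclusion
#' from neighboring cycles of the same block (endpoints take the nearest
#' value; interpolated cells are flagged), and extracts aftereffect measures
#' (mean over each 10-cycle aftereffect block).
#'
#' @param trials trial table with at least `participant`, `context`, `block`,
#'   `cycle`, `trial`, `target_deg`, `hand_deg`, `clamp_sign`; extra columns
#'   are tolerated.
#' @param deviation_limit,delta_limit see [exclude_trials()].
#' @return list with `cycles` (participant, context, block, cycle, reach_deg,
#'   n_trials, interpolated), `aftereffects` (one row per participant x
#'   aftereffect block, plus design covariates where present), and
#'   `exclusion` (counts and percentage excluded).
#' @export
preprocess_trials <- function(trials, deviation_limit = 100, delta_limit = 20) {
  req <- c("participant", "context", "block", "cycle", "trial",
           "target_deg", "hand_deg", "clamp_sign")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  tr <- trials[order(trials$participant, trials$trial), ]
  tr$signed_deg <- sign_align(wrap_angle(tr$hand_deg - tr$target_deg),
                              tr$clamp_sign)
  excl <- unlist(tapply(tr$signed_deg, tr$participant, exclude_trials,
                        deviation_limit = deviation_limit,
                        delta_limit = delta_limit, simplify = FALSE),
                 use.names = FALSE)
  # tapply groups by factor level order; reorder rows to match
  tr <- tr[order(factor(tr$participant)), ]
  tr$excluded <- excl

  keep <- tr[!tr$excluded, ]
  cells_all <- unique(tr[, c("participant", "context", "block", "cycle")])
  agg <- stats::aggregate(keep$signed_deg,
                          by = keep[, c("participant", "context", "cycle")],
                          FUN = mean)
  names(agg)[4] <- "reach_deg"
  cnt <- stats::aggregate(keep$signed_deg,
                          by = keep[, c("participant", "context", "cycle")],
                          FUN = length)
  names(cnt)[4] <- "n_trials"
  cyc <- merge(cells_all, merge(agg, cnt,
                                by = c("participant", "context", "cycle"),
                                all = TRUE),
               by = c("participant", "context", "cycle"), all.x = TRUE)
  cyc$n_trials[is.na(cyc$n_trials)] <- 0L
  cyc$interpolated <- is.na(cyc$reach_deg)
  cyc <- cyc[order(cyc$participant, cyc$context, cyc$cycle), ]

  # within-block linear interpolation of empty cells
  key <- interaction(cyc$participant, cyc$context, cyc$block, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    v <- cyc$reach_deg[i]
    if (!anyNA(v)) next
    if (all(is.na(v)))
      stop("participant with an entirely empty block: ", k)
    cyc$reach_deg[i] <- stats::approx(cyc$cycle[i][!is.na(v)], v[!is.na(v)],
                                      xout = cyc$cycle[i], rule = 2)$y
  }
  rownames(cyc) <- NULL

  ae_blocks <- grep("^aftereffect", unique(cyc$block), value = TRUE)
  ae <- do.call(rbind, lapply(ae_blocks, function(b) {
    s <- cyc[cyc$block == b, ]
    a <- stats::aggregate(s$reach_deg,
                          by = s[, c("participant", "context")], FUN = mean)
    names(a)[3] <- "aftereffect_deg"
    a$block <- b
    a
  }))
  if (!is.null(ae)) {
    for (col in intersect(c("context_role", "veridical_cycles", "clamp_sign"),
                          names(tr))) {
      m <- unique(tr[, c("participant", "context", col)])
      ae <- merge(ae, m, by = c("participant", "context"), all.x = TRUE)
    }
    ae <- ae[order(ae$participant, ae$block, ae$context), ]
    rownames(ae) <- NULL
  }

  list(cycles = cyc[, c("participant", "context", "block", "cycle",
                        "reach_deg", "n_trials", "interpolated")],
       aftereffects = ae,
       exclusion = list(n_total = nrow(tr), n_excluded = sum(tr$excluded),
                        pct_excluded = 100 * mean(tr$excluded)))
}

#' Cycle-averaged series for explicit trial/mask inputs
#'
#' Lower-level counterpart of [preprocess_trials()] for a single participant:
#' averages non-excluded angles within cycles and interpolates cycles left
#' empty within a block.
#'
#' @param angles signed reach angles, chronological.
#' @param cycle cycle index per trial.
#' @param excluded logical exclusion mask (e.g. from [exclude_trials()]).
#' @param block optional block label per trial (single block assumed if NULL).
#' @return data.frame with `cycle`, `reach_deg`, `n_trials`, `interpolated`.
#' @export
cycle_average <- function(angles, cycle, excluded = rep(FALSE, length(angles)),
                          block = NULL) {
  if (is.null(block)) block <- rep("b", length(angles))
  cyc_levels <- unique(cycle)
  blk <- block[match(cyc_levels, cycle)]
  kept <- !excluded
  reach <- vapply(cyc_levels, function(cy) {
    v <- angles[kept & cycle == cy]
    if (length(v)) mean(v) else NA_real_
  }, 1)
  n_tr <- vapply(cyc_levels, function(cy) sum(kept & cycle == cy), 1L)
  out <- data.frame(cycle = cyc_levels, reach_deg = reach, n_trials = n_tr,
                    interpolated = is.na(reach))
  for (b in unique(blk)) {
    i <- which(blk == b)
    v <- out$reach_deg[i]
    if (!anyNA(v)) next
    if (all(is.na(v))) stop("entirely empty block: ", b)
    out$reach_deg[i] <- stats::approx(out$cycle[i][!is.na(v)], v[!is.na(v)],
                                      xout = out$cycle[i], rule = 2)$y
  }
  out
}

#' Aftereffect measure per participant
#'
#' Unweighted mean of the cycle means over a 10-cycle aftereffect block.
#'
#' @param cycles cycle series (as `$cycles` from [preprocess_trials()]).
#' @param block aftereffect block label (e.g. `"aftereffect1"`).
#' @param context optional context filter.
#' @return data.frame `participant`, `aftereffect_deg`.
#' @export
aftereffect <- function(cycles, block, context = NULL) {
  s <- cycles[cycles$block == block, ]
  if (!is.null(context)) s <- s[s$context %in% context, ]
  if (nrow(s) == 0) stop("no cycles in block ", block)
  a <- stats::aggregate(s$reach_deg, by = list(participant = s$participant),
                        FUN = mean)
  names(a)[2] <- "aftereffect_deg"
  a
}

#' Retention ratio: first aftereffect cycle over late learning
#'
#' Ratio of the first aftereffect-cycle mean to the mean of the last 10
#' learning-block cycles, per participant. Participants whose late-learning
#' mean is within 0.5 degrees of zero are flagged as undefined (`NA` ratio).
#'
#' @param cycles cycle series (as `$cycles` from [preprocess_trials()]).
#' @param learning_block,aftereffect_block block labels.
#' @return data.frame `participant`, `ratio`, `undefined`.
#' @export
retention_ratio <- function(cycles, learning_block = "learning1",
                            aftereffect_block = "aftereffect1") {
  out <- lapply(split(cycles, cycles$participant), function(s) {
    lrn <- s[s$block == learning_block, ]
    lrn <- lrn[order(lrn$cycle), ]
    if (nrow(lrn) < 10) stop("learning block has fewer than 10 cycles")
    late <- mean(utils::tail(lrn$reach_deg, 10))
    ae <- s[s$block == aftereffect_block, ]
    first_ae <- ae$reach_deg[which.min(ae$cycle)]
    undef <- abs(late) < 0.5
    data.frame(participant = s$participant[1],
               ratio = if (undef) NA_real_ else first_ae / late,
               undefined = undef)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
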