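# End-to-end wiring: trial-table I/O, per-design analysis dispatch, and the
# synthetic reproduction pipeline.

#' Write / read a trial table
#'
#' CSV interchange with a JSON sidecar (`<path>.json`) holding the generating
#' parameters and seeds when present as attributes.
#'
#' @param trials trial table (as from [simulate_cohort()]).
#' @param path CSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   trial table (extra columns are tolerated, schema is validated).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  meta <- list(params = unclass(attr(trials, "params")),
               master_seed = attr(trials, "master_seed"),
               participant_seeds = attr(trials, "participant_seeds"))
  if (!is.null(meta$params))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "context", "block", "cycle", "trial",
           "target_deg", "hand_deg", "clamp_sign")
  miss <- setdiff(req, names(tr))
  if (length(miss)) stop("trial CSV lacks columns: ", paste(miss, collapse = ", "))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(tr, "params") <- meta$params
    attr(tr, "master_seed") <- meta$master_seed
  }
  tr
}

#' Write a cycle series and aftereffect table
#'
#' @param pre result of [preprocess_trials()].
#' @param dir output directory.
#' @return invisible character vector of written paths.
#' @export
write_preprocessed <- function(pre, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cycle_series.csv")
  p2 <- file.path(dir, "aftereffects.csv")
  p3 <- file.path(dir, "exclusion.json")
  utils::write.csv(pre$cycles, p1, row.names = FALSE)
  utils::write.csv(pre$aftereffects, p2, row.names = FALSE)
  jsonlite::write_json(pre$exclusion, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

# participant x cycle matrix for one block sequence (cycles ordered within
# block, blocks concatenated in the order given)
cycles_matrix <- function(cycles, blocks, context = NULL) {
  s <- cycles[cycles$block %in% blocks, ]
  if (!is.null(context)) s <- s[s$context %in% context, ]
  s$block <- factor(s$block, levels = blocks)
  s <- s[order(s$participant, s$block, s$cycle), ]
  parts <- unique(s$participant)
  ncol <- nrow(s) / length(parts)
  if (ncol != round(ncol)) stop("unbalanced cycle series")
  matrix(s$reach_deg, nrow = length(parts), ncol = ncol, byrow = TRUE,
         dimnames = list(parts, NULL))
}

#' Analyze a preprocessed experiment
#'
#' Dispatches the design-appropriate statistics. E1-E3: paired cluster test
#' over the concatenated learning + aftereffect cycles of blocks 1 vs 2, and
#' a paired t test (with Cohen's d and JZS BF10) on the aftereffect
#' difference. E4: the three between-block cluster comparisons at the
#' Bonferroni-adjusted cluster threshold, and a Greenhouse-Geisser
#' repeated-measures ANOVA over the three aftereffect conditions. E5: the
#' regression-slope cluster test over learning + aftereffect cycles against
#' the number of veridical cycles, and the random-slope mixed model on the
#' aftereffect.
#'
#' @param pre result of [preprocess_trials()].
#' @param experiment experiment id (`"E1"` ... `"E5"`).
#' @param n_perm permutations for the cluster tests (default 10000).
#' @param seed seed for the permutation draws.
#' @return list of results; components depend on the design.
#' @export
analyze_experiment <- function(pre, experiment, n_perm = 10000, seed = NULL) {
  cyc <- pre$cycles
  ae <- pre$aftereffects
  if (experiment %in% c("E1", "E2", "E3")) {
    A <- cycles_matrix(cyc, c("learning1", "aftereffect1"))
    B <- cycles_matrix(cyc, c("learning2", "aftereffect2"))
    ae1 <- aftereffect(cyc, "aftereffect1")
    ae2 <- aftereffect(cyc, "aftereffect2")
    stopifnot(identical(ae1$participant, ae2$participant))
    list(cluster = paired_cluster_test(B, A, n_perm = n_perm, seed = seed),
         aftereffect_diff = paired_t(ae2$aftereffect_deg, ae1$aftereffect_deg),
         aftereffects = data.frame(participant = ae1$participant,
                                   aftereffect1 = ae1$aftereffect_deg,
                                   aftereffect2 = ae2$aftereffect_deg))
  } else if (experiment == "E4") {
    stopifnot(!is.null(ae), "context_role" %in% names(ae))
    key <- function(role, blk) {
      s <- ae[ae$context_role == role & ae$block == blk, ]
      s[order(s$participant), "aftereffect_deg"]
    }
    M <- cbind(aftereffect1 = key("relearn", "aftereffect1"),
               aftereffect2 = key("relearn", "aftereffect2"),
               long_baseline = key("long_baseline", "aftereffect1"))
    adj <- bonferroni_cluster_alpha(0.05, 3)
    # context roles are counterbalanced, so filter per (participant, context)
    role_map <- unique(ae[, c("participant", "context", "context_role")])
    cm <- function(blocks, role) {
      keep_key <- paste(role_map$participant, role_map$context)[
        role_map$context_role == role]
      cycles_matrix(cyc[paste(cyc$participant, cyc$context) %in% keep_key, ],
                    blocks)
    }
    L1 <- cm(c("learning1", "aftereffect1"), "relearn")
    L2 <- cm(c("learning2", "aftereffect2"), "relearn")
    LB <- cm(c("learning1", "aftereffect1"), "long_baseline")
    list(clusters = list(
           L2_vs_LB = paired_cluster_test(L2, LB, n_perm = n_perm,
                                          cluster_alpha = adj$alpha, seed = seed),
           L1_vs_L2 = paired_cluster_test(L2, L1, n_perm = n_perm,
                                          cluster_alpha = adj$alpha, seed = seed),
           L1_vs_LB = paired_cluster_test(LB, L1, n_perm = n_perm,
                                          cluster_alpha = adj$alpha, seed = seed)),
         cluster_alpha = adj,
         anova = rm_anova_gg(M),
         aftereffects = M)
  } else if (experiment == "E5") {
    stopifnot(!is.null(ae), "veridical_cycles" %in% names(ae))
    parts <- sort(unique(ae$participant))
    ctxs <- sort(unique(ae$context))
    k <- length(ctxs)
    Xv <- t(vapply(parts, function(p)
      ae$veridical_cycles[ae$participant == p][order(ae$context[ae$participant == p])],
      numeric(k)))
    blocks <- c("learning1", "aftereffect1")
    Ys <- lapply(ctxs, function(cx)
      cycles_matrix(cyc[cyc$context == cx, ], blocks))
    C <- ncol(Ys[[1]])
    y <- array(NA_real_, c(length(parts), k, C))
    for (j in seq_len(k)) y[, j, ] <- Ys[[j]][parts, ]
    long <- ae[ae$block == "aftereffect1",
               c("participant", "veridical_cycles", "aftereffect_deg")]
    names(long) <- c("participant", "x", "y")
    list(cluster = regression_cluster_test(y, Xv, n_perm = n_perm, seed = seed),
         mixed = mixed_model_slope(long),
         aftereffects = long)
  } else stop("unknown experiment id: ", experiment)
}

#' Run the full synthetic pipeline for one or more designs
#'
#' Simulates a counterbalanced cohort, preprocesses it, runs the
#' design-appropriate analysis, and collects headline numbers (aftereffect
#' difference and its t/BF/d, significant clusters, exclusion rate, and the
#' design-specific ANOVA or mixed-model results). All randomness derives
#' from `seed`.
#'
#' @param experiments character vector of experiment ids.
#' @param n_participants cohort size per design; defaults to the study sizes
#'   (44 for E1-E4, 60 for E5).
#' @param params an [agent_params()].
#' @param seed master seed.
#' @param n_perm permutations for cluster tests.
#' @return named list per experiment with `trials_n`, `exclusion_pct`,
#'   `analysis` and a compact `summary` data.frame row.
#' @export
reproduce_study <- function(experiments = c("E1", "E2", "E3", "E4", "E5"),
                            n_participants = NULL, params = agent_params(),
                            seed = 1, n_perm = 2000) {
  out <- list()
  for (i in seq_along(experiments)) {
    ex <- experiments[i]
    n <- n_participants %||% if (ex == "E5") 60 else 44
    trials <- simulate_cohort(ex, n, params, seed = seed + i)
    pre <- preprocess_trials(trials)
    an <- analyze_experiment(pre, ex, n_perm = n_perm, seed = seed + i)
    sm <- if (ex %in% c("E1", "E2", "E3")) {
      st <- an$aftereffect_diff
      data.frame(experiment = ex, n = n,
                 estimate = st$estimate, t = st$t, p = st$p, d = st$d,
                 bf10 = st$bf10,
                 n_significant_clusters = sum(an$cluster$clusters$significant),
                 exclusion_pct = pre$exclusion$pct_excluded)
    } else if (ex == "E4") {
      data.frame(experiment = ex, n = n,
                 estimate = an$anova$F, t = NA, p = an$anova$p,
                 d = an$anova$eta_p_sq, bf10 = NA,
                 n_significant_clusters = sum(vapply(
                   an$clusters, function(cl) sum(cl$clusters$significant), 1L)),
                 exclusion_pct = pre$exclusion$pct_excluded)
    } else {
      data.frame(experiment = ex, n = n,
                 estimate = an$mixed$slope$estimate, t = an$mixed$slope$t,
                 p = an$mixed$p_slope, d = NA, bf10 = NA,
                 n_significant_clusters = sum(an$cluster$clusters$significant),
                 exclusion_pct = pre$exclusion$pct_excluded)
    }
    out[[ex]] <- list(trials_n = nrow(trials),
                      exclusion_pct = pre$exclusion$pct_excluded,
                      analysis = an, summary = sm)
  }
  out$summary <- do.call(rbind, lapply(out, `[[`, "summary"))
  rownames(out$summary) <- NULL
  out
}
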