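#' Classify a sample pair into an ecological assembly process
#'
#' Applies the standard two-stage decision rule. Selection first:
#' `bnti < -2` is homogeneous selection (less turnover than chance under a
#' constant environment), `bnti > 2` heterogeneous selection (more turnover
#' under divergent environments). Pairs inside the stochastic band
#' (`-2 < bnti < 2`) are split by RC-bray: `< -0.95` homogenizing
#' dispersal, `> 0.95` dispersal limitation acting with drift, otherwise
#' drift alone. Values exactly at a threshold fall to the interior
#' (stochastic) side: `|bnti| = 2` proceeds to the RC-bray test and
#' `|rc_bray| = 0.95` is drift alone.
#'
#' @param bnti betaNTI value(s).
#' @param rc_bray RC-bray value(s); may be `NA` for pairs where
#'   `|bnti| > 2` (it is not consulted there), but must be present whenever
#'   the stochastic band is reached.
#' @return Character vector of process labels among
#'   `homogeneous_selection`, `heterogeneous_selection`,
#'   `homogenizing_dispersal`, `dispersal_limitation_drift`, `drift_alone`.
#' @export
classify_process <- function(bnti, rc_bray = NA_real_) {
  n <- max(length(bnti), length(rc_bray))
  bnti <- rep_len(bnti, n); rc_bray <- rep_len(rc_bray, n)
  out <- character(n)
  for (k in seq_len(n)) {
    b <- bnti[k]
    if (is.na(b)) stop("betaNTI is NA", call. = FALSE)
    if (b < -2) out[k] <- "homogeneous_selection"
    else if (b > 2) out[k] <- "heterogeneous_selection"
    else {
      r <- rc_bray[k]
      if (is.na(r))
        stop("rc_bray required when |betaNTI| <= 2", call. = FALSE)
      if (r < -0.95) out[k] <- "homogenizing_dispersal"
      else if (r > 0.95) out[k] <- "dispersal_limitation_drift"
      else out[k] <- "drift_alone"
    }
  }
  out
}

#' Relative contribution of assembly processes over a set of pairs
#'
#' Counts each process among the selected pairwise comparisons and divides
#' by the number of selected pairs, giving the relative-contribution profile
#' reported for "all" versus within-group comparison sets.
#'
#' @param results `data.frame` of pairwise records with columns `sample_a`,
#'   `sample_b` and `process` (as produced by [assembly_analysis()]).
#' @param subset Either `"all"` (every pair) or `"within-group"` (only
#'   pairs whose two samples share a group label).
#' @param groups Named character vector mapping sample name to group label;
#'   required for `subset = "within-group"`.
#' @param subset_label Text recorded on the profile (defaults to `subset`).
#' @return List with `fractions` (named numeric over the five processes,
#'   summing to 1), `n_comparisons`, and `subset_label`.
#' @export
process_profile <- function(results, subset = c("all", "within-group"),
                            groups = NULL, subset_label = NULL) {
  subset <- match.arg(subset)
  keep <- rep(TRUE, nrow(results))
  if (subset == "within-group") {
    if (is.null(groups))
      stop("'groups' required for within-group profiles", call. = FALSE)
    keep <- groups[results$sample_a] == groups[results$sample_b]
    keep[is.na(keep)] <- FALSE
  }
  sel <- results[keep, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no pairwise comparisons selected; cannot form a profile",
         call. = FALSE)
  counts <- table(factor(sel$process, levels = PROCESS_LEVELS))
  list(fractions = setNames(as.numeric(counts) / nrow(sel), PROCESS_LEVELS),
       n_comparisons = nrow(sel),
       subset_label = if (is.null(subset_label)) subset else subset_label)
}

#' Full pairwise assembly-process analysis
#'
#' Runs the complete inference for every pair of samples: observed betaMNTD,
#' its tip-randomization null (one shared permutation per iteration across
#' pairs), betaNTI, RC-bray for pairs in the stochastic band, and the
#' five-way process classification.
#'
#' @param comm Sample x taxon count matrix (ideally rarefied to equal
#'   depths).
#' @param tree Rooted phylogeny covering all nonzero taxa.
#' @param n_reps Null-model iterations for both the betaMNTD and RC-bray
#'   nulls (default 999).
#' @param seed Optional integer seed controlling both nulls.
#' @param abundance_weighted Weight betaMNTD by relative abundance?
#' @param rc_always Also compute RC-bray for pairs outside the stochastic
#'   band (slower; off by default since classification never consults it
#'   there).
#' @param pairs Optional two-column matrix/data.frame of sample-name pairs
#'   to evaluate; the null model and RC-bray metacommunity still use the
#'   full table (see [null_bmntd()]).
#' @return `data.frame` with one row per pair: `sample_a`, `sample_b`,
#'   `bmntd`, `null_mean`, `null_sd`, `bnti`, `rc_bray` (`NA` where not
#'   computed) and `process`.
#' @export
assembly_analysis <- function(comm, tree, n_reps = 999, seed = NULL,
                              abundance_weighted = TRUE, rc_always = FALSE,
                              pairs = NULL) {
  comm <- .check_comm(comm)
  nb <- null_bmntd(comm, tree, n_reps = n_reps, seed = seed,
                   abundance_weighted = abundance_weighted, pairs = pairs)
  b <- bnti(nb$obs, nb)
  res <- data.frame(nb$pairs, bmntd = nb$obs, null_mean = nb$mean,
                    null_sd = nb$sd, bnti = b, rc_bray = NA_real_,
                    process = NA_character_, stringsAsFactors = FALSE)
  need_rc <- abs(b) <= 2 | rc_always
  for (k in which(need_rc)) {
    res$rc_bray[k] <- raup_crick_bray(
      comm, c(res$sample_a[k], res$sample_b[k]),
      n_reps = n_reps, seed = seed)
  }
  res$process <- classify_process(res$bnti, res$rc_bray)
  res
}
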