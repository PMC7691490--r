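#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))`; 0 for identical
#' communities, 1 for disjoint supports.
#'
#' @param a,b Nonnegative count (or abundance) vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("counts must be nonnegative", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0)
    stop("both communities are empty; Bray-Curtis undefined", call. = FALSE)
  1 - 2 * sum(pmin(a, b)) / (sa + sb)
}

# Core nearest-taxon turnover between two sparse samples.
# ia/ib: integer taxon indices present in each sample (into D);
# wa/wb: matching weights summing to 1. D: tip x tip patristic matrix.
.bmntd_core <- function(ia, wa, ib, wb, D) {
  da <- .row_mins(D[ia, ib, drop = FALSE])
  db <- .row_mins(D[ib, ia, drop = FALSE])
  0.5 * (sum(wa * da) + sum(wb * db))
}

# Decompose a community matrix into per-sample index/weight lists keyed by
# position in `taxa`.
.sample_support <- function(comm, taxa, abundance_weighted) {
  lapply(seq_len(nrow(comm)), function(s) {
    idx <- which(comm[s, ] > 0)
    if (!length(idx)) stop("sample '", rownames(comm)[s], "' is empty",
                           call. = FALSE)
    w <- if (abundance_weighted) comm[s, idx] / sum(comm[s, idx])
         else rep(1 / length(idx), length(idx))
    list(idx = match(colnames(comm)[idx], taxa), w = unname(w))
  })
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Phylogenetic turnover between two communities: the mean patristic
#' distance from each taxon in one community to its closest relative in the
#' other, averaged over both directions. With `abundance_weighted = TRUE`
#' (the default) each taxon's nearest-relative distance is weighted by its
#' relative abundance; otherwise all present taxa weigh equally. A taxon
#' shared by both samples is its own closest relative (distance 0).
#'
#' @param comm Sample x taxon count matrix.
#' @param pair Length-2 vector of sample names (or row indices).
#' @param tree Rooted phylogeny whose tips cover all nonzero taxa.
#' @param abundance_weighted Weight by relative abundance?
#' @return Nonnegative scalar in branch-length units; symmetric in the pair.
#' @export
bmntd <- function(comm, pair, tree, abundance_weighted = TRUE) {
  comm <- .check_comm(comm)
  .check_taxa_on_tree(comm, tree)
  sub <- comm[pair, , drop = FALSE]
  D <- patristic_matrix(tree)
  sup <- .sample_support(sub, rownames(D), abundance_weighted)
  .bmntd_core(sup[[1]]$idx, sup[[1]]$w, sup[[2]]$idx, sup[[2]]$w, D)
}

#' betaMNTD for every pair of samples
#'
#' @inheritParams bmntd
#' @return A symmetric sample x sample matrix of betaMNTD values
#'   (zero diagonal).
#' @export
bmntd_all <- function(comm, tree, abundance_weighted = TRUE) {
  comm <- .check_comm(comm)
  .check_taxa_on_tree(comm, tree)
  D <- patristic_matrix(tree)
  sup <- .sample_support(comm, rownames(D), abundance_weighted)
  n <- nrow(comm)
  out <- matrix(0, n, n, dimnames = list(rownames(comm), rownames(comm)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- .bmntd_core(sup[[i]]$idx, sup[[i]]$w, sup[[j]]$idx, sup[[j]]$w, D)
    out[i, j] <- out[j, i] <- v
  }
  out
}

#' Tip-randomization null distribution of betaMNTD
#'
#' For each of `n_reps` iterations one random permutation of the assignment
#' between taxa and tree tips is drawn (a single shared permutation across
#' all sample pairs per iteration, covering every taxon in the table), and
#' betaMNTD is recomputed for every pair. The resulting per-pair
#' distributions describe phylogenetic turnover expected when taxon
#' identities carry no phylogenetic information.
#'
#' @inheritParams bmntd
#' @param n_reps Number of randomizations (default 999).
#' @param seed Optional integer seed.
#' @param pairs Optional two-column matrix or data.frame of sample-name
#'   pairs to evaluate (default: every pair). The randomized taxon pool is
#'   always the full table, so restricting `pairs` changes only which
#'   comparisons are reported, not the null model.
#' @return List with elements `pairs` (two-column data.frame of sample
#'   names), `values` (`n_reps` x n_pairs matrix of null betaMNTD), `mean`
#'   and `sd` (per-pair null summaries), and `obs` (observed betaMNTD per
#'   pair).
#' @export
null_bmntd <- function(comm, tree, n_reps = 999, seed = NULL,
                       abundance_weighted = TRUE, pairs = NULL) {
  comm <- .check_comm(comm)
  .check_taxa_on_tree(comm, tree)
  if (n_reps < 2) stop("'n_reps' must be >= 2", call. = FALSE)
  taxa <- colnames(comm)[colSums(comm) > 0]
  if (length(taxa) < 2)
    stop("need at least 2 taxa with nonzero abundance", call. = FALSE)
  comm <- comm[, taxa, drop = FALSE]
  D <- patristic_matrix(tree)
  ord <- match(taxa, rownames(D))
  D <- D[ord, ord, drop = FALSE]  # rows/cols now in table taxon order
  sup <- .sample_support(comm, taxa, abundance_weighted)
  n <- nrow(comm)
  if (is.null(pairs)) {
    pr <- t(combn(n, 2L))
  } else {
    pairs <- as.matrix(pairs)
    pr <- cbind(match(pairs[, 1L], rownames(comm)),
                match(pairs[, 2L], rownames(comm)))
    if (anyNA(pr)) stop("unknown sample names in 'pairs'", call. = FALSE)
  }
  npair <- nrow(pr)
  pair_names <- data.frame(sample_a = rownames(comm)[pr[, 1L]],
                           sample_b = rownames(comm)[pr[, 2L]],
                           stringsAsFactors = FALSE)
  obs <- vapply(seq_len(npair), function(k) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    .bmntd_core(sup[[i]]$idx, sup[[i]]$w, sup[[j]]$idx, sup[[j]]$w, D)
  }, numeric(1))
  vals <- .with_seed(seed, {
    v <- matrix(NA_real_, n_reps, npair)
    nt <- length(taxa)
    for (r in seq_len(n_reps)) {
      p <- sample.int(nt)
      Dp <- D[p, p, drop = FALSE]
      for (k in seq_len(npair)) {
        i <- pr[k, 1L]; j <- pr[k, 2L]
        v[r, k] <- .bmntd_core(sup[[i]]$idx, sup[[i]]$w,
                               sup[[j]]$idx, sup[[j]]$w, Dp)
      }
    }
    v
  })
  list(pairs = pair_names, values = vals,
       mean = colMeans(vals), sd = apply(vals, 2L, sd), obs = obs)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Deviation of observed betaMNTD from its tip-randomization null, in null
#' standard-deviation units: `(obs - mean(null)) / sd(null)`. Values below
#' -2 indicate less phylogenetic turnover than expected by chance
#' (homogeneous selection); values above +2 indicate more (heterogeneous
#' selection); the interior band is attributed to stochastic processes.
#'
#' A degenerate null (sd = 0) is an error, with one documented exception:
#' when the observed value also coincides with the null point mass (as for
#' two samples with identical taxon support, where betaMNTD is 0 under
#' every tip relabeling) the standardized deviation is defined as 0, so the
#' pair falls to the stochastic band and RC-bray decides its process.
#'
#' @param bmntd_obs Observed betaMNTD value(s).
#' @param null Either a numeric vector of null betaMNTD values or a list
#'   with `mean` and `sd` components (as returned by [null_bmntd()]).
#' @param tol Absolute tolerance for the observed-equals-point-mass case.
#' @return betaNTI value(s).
#' @export
bnti <- function(bmntd_obs, null, tol = 1e-12) {
  if (is.list(null)) { m <- null$mean; s <- null$sd }
  else { m <- mean(null); s <- sd(null) }
  degen <- s == 0
  if (any(degen & abs(bmntd_obs - m) > tol))
    stop("degenerate null distribution (sd = 0) with observed away from ",
         "the null point mass; betaNTI undefined", call. = FALSE)
  out <- ifelse(degen, 0, (bmntd_obs - m) / s)
  out
}

#' Abundance-based Raup-Crick metric on Bray-Curtis (RC-bray)
#'
#' Positions the observed Bray-Curtis dissimilarity of a sample pair within
#' a null distribution of probabilistically reassembled communities. Each
#' null community preserves the observed richness and total individual count
#' of its sample: taxon identities are drawn without replacement with
#' probability proportional to metacommunity occupancy (number of samples in
#' which each taxon occurs), each drawn taxon receives one individual, and
#' the remaining individuals are allocated multinomially with probability
#' proportional to metacommunity relative abundance. The metric is
#' `2 * (fraction of null values below the observed, ties counted half) - 1`,
#' so it lies in \[-1, 1\]: +1 means the pair is more dissimilar than every
#' null assembly (consistent with dispersal limitation), -1 less dissimilar
#' than every null (consistent with homogenizing dispersal).
#'
#' @param comm Sample x taxon count matrix; all samples define the
#'   metacommunity.
#' @param pair Length-2 vector of sample names (or row indices).
#' @param n_reps Number of null assemblies (default 999).
#' @param seed Optional integer seed. The pair's Monte-Carlo stream is
#'   derived from the seed and the sorted sample names, so results do not
#'   depend on the order pairs are processed in.
#' @param tie_tol Absolute tolerance for counting a null Bray-Curtis value
#'   as tied with the observed one.
#' @return RC-bray value in \[-1, 1\].
#' @export
raup_crick_bray <- function(comm, pair, n_reps = 999, seed = NULL,
                            tie_tol = 1e-12) {
  comm <- .check_comm(comm)
  sub <- comm[pair, , drop = FALSE]
  sub <- sub[order(rownames(sub)), , drop = FALSE]  # orientation-invariant
  occ <- colSums(comm > 0)
  relab <- colSums(comm); relab <- relab / sum(relab)
  obs <- bray_curtis(sub[1L, ], sub[2L, ])
  rich <- rowSums(sub > 0)
  tot <- rowSums(sub)
  if (any(rich == 0)) stop("empty sample in pair", call. = FALSE)
  if (any(rich > sum(occ > 0)))
    stop("sample richness exceeds number of occupied taxa", call. = FALSE)
  pseed <- if (is.null(seed)) NULL
           else .pair_seed(seed, rownames(sub)[1L], rownames(sub)[2L])
  nt <- length(occ)
  .with_seed(pseed, {
    below <- 0; ties <- 0
    for (r in seq_len(n_reps)) {
      x1 <- .rc_assemble(rich[1L], tot[1L], occ, relab, nt)
      x2 <- .rc_assemble(rich[2L], tot[2L], occ, relab, nt)
      bc <- 1 - 2 * sum(pmin(x1, x2)) / (tot[1L] + tot[2L])
      if (bc < obs - tie_tol) below <- below + 1
      else if (abs(bc - obs) <= tie_tol) ties <- ties + 1
    }
    2 * (below + 0.5 * ties) / n_reps - 1
  })
}

# One null community: richness-constrained identity draw by occupancy,
# then abundance-weighted filling. Returns a count vector of length nt.
.rc_assemble <- function(richness, total, occ, relab, nt) {
  drawn <- sample.int(nt, richness, prob = occ)
  x <- numeric(nt)
  x[drawn] <- 1
  if (total > richness) {
    p <- relab[drawn]
    if (sum(p) == 0) p <- rep(1, length(drawn))
    x[drawn] <- x[drawn] +
      rmultinom(1L, total - richness, p)[, 1L]
  }
  x
}
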