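#' Abundance-weighted environmental optima per taxon
#'
#' Approximates each taxon's niche position on an environmental variable as
#' the abundance-weighted mean of that variable over the samples where the
#' taxon occurs: `optimum_i = sum_s(count_is * env_s) / sum_s(count_is)`.
#' Being a convex combination, every optimum lies within the observed range
#' of the variable.
#'
#' @param comm Sample x taxon count matrix.
#' @param env `data.frame` of environmental variables, one row per sample
#'   (rownames or a `sample` column matching `rownames(comm)`).
#' @param variables Which columns of `env` to use (default: all numeric
#'   columns).
#' @return Taxon x variable matrix of optima. Taxa with zero total
#'   abundance are dropped with a warning.
#' @export
niche_optima <- function(comm, env, variables = NULL) {
  comm <- .check_comm(comm)
  env <- .align_env(env, rownames(comm))
  if (is.null(variables))
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  bad <- variables[!vapply(env[variables], function(x) all(is.finite(x)),
                           logical(1))]
  if (length(bad))
    stop("non-finite environmental values in: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tot <- colSums(comm)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0),
            " taxa with zero total abundance", call. = FALSE)
    comm <- comm[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  E <- as.matrix(env[variables])
  opt <- crossprod(comm, E) / tot
  rownames(opt) <- colnames(comm)
  opt
}

# Align an environment table with the community samples by rowname or a
# 'sample' column; errors on samples without metadata.
.align_env <- function(env, samples) {
  env <- as.data.frame(env)
  if ("sample" %in% names(env)) {
    rownames(env) <- env$sample
    env$sample <- NULL
  }
  missing <- setdiff(samples, rownames(env))
  if (length(missing))
    stop("samples missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  env[samples, , drop = FALSE]
}

#' Between-taxon optima distances for one variable
#'
#' Manhattan distance on a single variable, i.e. the absolute difference
#' between taxon optima.
#'
#' @param optima Taxon x variable optima matrix (from [niche_optima()]) or
#'   a named numeric vector of optima.
#' @param variable Column to use when `optima` is a matrix.
#' @return Symmetric taxon x taxon distance matrix with zero diagonal.
#' @export
optima_distance <- function(optima, variable = NULL) {
  x <- if (is.matrix(optima)) {
    if (is.null(variable)) stop("'variable' required", call. = FALSE)
    setNames(optima[, variable], rownames(optima))
  } else optima
  if (any(!is.finite(x))) stop("optima must be finite", call. = FALSE)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(x), names(x))
  d
}

#' Combined between-taxon optima distance over all variables
#'
#' Euclidean distance across log-transformed optima of all variables
#' (log10). Variables containing nonpositive optima are additively shifted
#' so their minimum becomes 1 before the log; applied shifts are recorded in
#' the `"shifts"` attribute of the result.
#'
#' @param optima Taxon x variable optima matrix.
#' @param log_base Base of the log transform (default 10).
#' @param shift `"auto"` (shift nonpositive variables, the default) or
#'   `"none"` (error on nonpositive optima).
#' @return Symmetric taxon x taxon distance matrix with zero diagonal;
#'   attribute `"shifts"` gives the additive shift used per variable.
#' @export
combined_optima_distance <- function(optima, log_base = 10,
                                     shift = c("auto", "none")) {
  shift <- match.arg(shift)
  if (!is.matrix(optima)) stop("'optima' must be a matrix", call. = FALSE)
  shifts <- numeric(ncol(optima))
  names(shifts) <- colnames(optima)
  L <- optima
  for (j in seq_len(ncol(L))) {
    if (any(L[, j] <= 0)) {
      if (shift == "none")
        stop("nonpositive optima in variable '", colnames(L)[j],
             "' and no shift configured", call. = FALSE)
      shifts[j] <- 1 - min(L[, j])
      L[, j] <- L[, j] + shifts[j]
    }
    L[, j] <- log(L[, j], base = log_base)
  }
  d <- as.matrix(stats::dist(L, method = "euclidean"))
  dimnames(d) <- list(rownames(optima), rownames(optima))
  attr(d, "shifts") <- shifts
  d
}

#' Patristic (tip-to-tip) distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree Rooted phylogeny with branch lengths on all edges.
#' @return Symmetric tip x tip distance matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  ape::cophenetic.phylo(tree)
}

#' Mantel correlogram of ecological versus phylogenetic distance
#'
#' Bins phylogenetic distances into `n_classes` equal-width classes over
#' `[0, max]`, and for each class computes the Mantel statistic (Pearson
#' correlation over unordered tip pairs) between the ecological distance
#' matrix and the binary class-membership indicator. The sign is oriented so
#' that a POSITIVE value means pairs inside the class are more ecologically
#' similar than expected by chance (the field's plotting convention).
#' Two-sided p-values come from `n_perm` simultaneous row/column
#' permutations of the ecological matrix; a progressive Holm correction is
#' applied, i.e. the p-value of class k is Holm-adjusted within the set of
#' testable classes 1..k.
#'
#' @param d_eco,d_phylo Symmetric distance matrices over the same taxa
#'   (zero diagonal), in the same taxon order.
#' @param n_classes Number of equal-width phylogenetic distance classes
#'   (default 50).
#' @param n_perm Permutations for the Mantel test (default 999).
#' @param alpha Significance level for the `significant` flag.
#' @param seed Optional integer seed.
#' @return `data.frame` with one row per class: `class_index`,
#'   `class_midpoint`, `n_pairs`, `mantel_r`, `p_raw`, `p_corrected`,
#'   `significant`. Classes with fewer than 2 pairs are untestable: their
#'   statistics are `NA` and they are excluded from the progressive
#'   correction.
#' @export
mantel_correlogram <- function(d_eco, d_phylo, n_classes = 50, n_perm = 999,
                               alpha = 0.05, seed = NULL) {
  d_eco <- as.matrix(d_eco); d_phylo <- as.matrix(d_phylo)
  if (!isTRUE(all.equal(dim(d_eco), dim(d_phylo))))
    stop("distance matrices must have the same dimensions", call. = FALSE)
  for (m in list(d_eco, d_phylo)) {
    if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-12))
      stop("distance matrices must be symmetric with zero diagonal",
           call. = FALSE)
  }
  n <- nrow(d_eco)
  ut <- upper.tri(d_eco)
  x <- d_eco[ut]
  dp <- d_phylo[ut]
  breaks <- seq(0, max(dp), length.out = n_classes + 1L)
  cls <- findInterval(dp, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mids <- (breaks[-1L] + breaks[-(n_classes + 1L)]) / 2
  n_pairs <- tabulate(cls, nbins = n_classes)
  npair <- length(x)
  xbar <- mean(x)
  sxx <- sqrt(sum((x - xbar)^2))
  # r for class k from the within-class sum: closed form of the Pearson
  # correlation with a binary indicator (negated for the similarity
  # orientation). The pair-value multiset is permutation-invariant, so xbar
  # and sxx are constants across permutations.
  r_from_sums <- function(sums) {
    denom <- sxx * sqrt(n_pairs * (1 - n_pairs / npair))
    r <- -(sums - n_pairs * xbar) / denom
    r[n_pairs < 2] <- NA_real_
    r
  }
  obs_sums <- as.numeric(rowsum(x, cls, reorder = FALSE))
  # rowsum drops empty classes; rebuild full-length sums
  full_sums <- function(v, cl) {
    s <- numeric(n_classes)
    t <- rowsum(v, cl)
    s[as.integer(rownames(t))] <- t[, 1L]
    s
  }
  r_obs <- r_from_sums(full_sums(x, cls))
  exceed <- integer(n_classes)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      xp <- d_eco[p, p][ut]
      rp <- r_from_sums(full_sums(xp, cls))
      exceed <- exceed + as.integer(!is.na(rp) & !is.na(r_obs) &
                                      abs(rp) >= abs(r_obs) - 1e-12)
    }
  })
  p_raw <- ifelse(is.na(r_obs), NA_real_, (1 + exceed) / (n_perm + 1))
  testable <- which(!is.na(p_raw))
  p_corr <- rep(NA_real_, n_classes)
  for (i in seq_along(testable)) {
    k <- testable[seq_len(i)]
    p_corr[testable[i]] <- p.adjust(p_raw[k], method = "holm")[i]
  }
  data.frame(class_index = seq_len(n_classes), class_midpoint = mids,
             n_pairs = n_pairs, mantel_r = r_obs, p_raw = p_raw,
             p_corrected = p_corr,
             significant = !is.na(p_corr) & p_corr <= alpha)
}
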