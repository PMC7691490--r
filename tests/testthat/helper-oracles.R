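# Independent oracles used to validate the package's core statistics.
# These deliberately use naive, explicit algorithms (loops, enumeration)
# rather than the vectorized implementations under test.

# Brute-force betaMNTD: explicit double loop over taxa, explicit minimum.
brute_bmntd <- function(comm, pair, D, abundance_weighted = TRUE) {
  a <- comm[pair[1], ]; b <- comm[pair[2], ]
  ta <- names(a)[a > 0]; tb <- names(b)[b > 0]
  wa <- if (abundance_weighted) a[ta] / sum(a[ta]) else rep(1 / length(ta), length(ta))
  wb <- if (abundance_weighted) b[tb] / sum(b[tb]) else rep(1 / length(tb), length(tb))
  s <- 0
  for (i in seq_along(ta)) {
    best <- Inf
    for (j in seq_along(tb)) best <- min(best, D[ta[i], tb[j]])
    s <- s + wa[i] * best
  }
  for (j in seq_along(tb)) {
    best <- Inf
    for (i in seq_along(ta)) best <- min(best, D[tb[j], ta[i]])
    s <- s + wb[j] * best
  }
  unname(s / 2)
}

# Naive patristic distances: climb parent pointers from each tip to the
# root and join paths, independent of ape::cophenetic.
path_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  plen <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- ntip + 1L
  to_root <- function(i) {
    nodes <- i; d <- 0
    while (i != root) { d <- c(d, d[length(d)] + plen[i]); i <- parent[i]; nodes <- c(nodes, i) }
    list(nodes = nodes, dist = d)
  }
  paths <- lapply(seq_len(ntip), to_root)
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) for (j in seq(i + 1, ntip)) {
    pi <- paths[[i]]; pj <- paths[[j]]
    k <- which(pi$nodes %in% pj$nodes)[1]
    lca <- pi$nodes[k]
    D[i, j] <- D[j, i] <- pi$dist[k] + pj$dist[which(pj$nodes == lca)]
  }
  D
}

# All permutations of 1..n (for exhaustive tip-shuffle expectations).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# Exact Raup-Crick null distribution by exhaustive enumeration, for tiny
# communities. Returns P(null BC < obs), P(null BC == obs), and exact RC.
rc_exact <- function(comm, pair, tie_tol = 1e-12) {
  occ <- colSums(comm > 0)
  relab <- colSums(comm); relab <- relab / sum(relab)
  nt <- ncol(comm)
  obs <- bray_curtis(comm[pair[1], ], comm[pair[2], ])

  # probability of drawing each richness-r identity SET under sequential
  # weighted sampling without replacement (sum over orderings)
  set_probs <- function(r) {
    sets <- combn(which(occ > 0), r, simplify = FALSE)
    pr <- vapply(sets, function(s) {
      tot <- 0
      for (o in all_perms(length(s))) {
        seqs <- s[unlist(o)]
        p <- 1
        avail <- occ
        for (t in seqs) {
          p <- p * avail[t] / sum(avail[avail > 0])
          avail[t] <- 0
        }
        tot <- tot + p
      }
      tot
    }, numeric(1))
    list(sets = sets, probs = pr)
  }

  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (k in 0:total) {
      sub <- compositions(total - k, parts - 1)
      out <- rbind(out, cbind(k, sub))
    }
    out
  }

  # distribution over full count vectors for one sample
  sample_dist <- function(r, N) {
    sp <- set_probs(r)
    vecs <- list(); probs <- numeric(0)
    for (si in seq_along(sp$sets)) {
      s <- sp$sets[[si]]
      q <- relab[s]
      if (sum(q) == 0) q <- rep(1, length(s))
      q <- q / sum(q)
      comps <- compositions(N - r, length(s))
      for (ci in seq_len(nrow(comps))) {
        add <- comps[ci, ]
        pmult <- dmultinom(add, prob = q)
        x <- numeric(nt); x[s] <- 1 + add
        vecs[[length(vecs) + 1L]] <- x
        probs <- c(probs, sp$probs[si] * pmult)
      }
    }
    list(vecs = vecs, probs = probs)
  }

  r1 <- sum(comm[pair[1], ] > 0); n1 <- sum(comm[pair[1], ])
  r2 <- sum(comm[pair[2], ] > 0); n2 <- sum(comm[pair[2], ])
  d1 <- sample_dist(r1, n1); d2 <- sample_dist(r2, n2)
  p_below <- 0; p_tie <- 0
  for (i in seq_along(d1$vecs)) for (j in seq_along(d2$vecs)) {
    bc <- 1 - 2 * sum(pmin(d1$vecs[[i]], d2$vecs[[j]])) / (n1 + n2)
    w <- d1$probs[i] * d2$probs[j]
    if (bc < obs - tie_tol) p_below <- p_below + w
    else if (abs(bc - obs) <= tie_tol) p_tie <- p_tie + w
  }
  list(p_below = p_below, p_tie = p_tie,
       rc = 2 * (p_below + 0.5 * p_tie) - 1, obs = obs)
}

# Small random fixture: tree plus community with guaranteed nonzero samples.
random_instance <- function(n_taxa, n_samples = 2, max_count = 9, seed = 1) {
  tr <- simulate_tree(n_taxa, 1, 0, seed = seed)
  set.seed(seed + 5000)
  repeat {
    m <- matrix(rbinom(n_samples * n_taxa, max_count, 0.4),
                n_samples, n_taxa,
                dimnames = list(paste0("s", seq_len(n_samples)), tr$tip.label))
    if (all(rowSums(m) > 0)) break
  }
  list(tree = tr, comm = m)
}
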