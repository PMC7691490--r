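#' Simulate a rooted birth-death phylogeny
#'
#' Generates an ultrametric birth-death tree with exactly `n_taxa` tips, used
#' as the evolutionary scaffold for simulated communities. Tips are labelled
#' `t1 ... tn`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate,death_rate Per-lineage speciation and extinction rates.
#' @param seed Optional integer seed; the same seed gives a byte-identical
#'   tree.
#' @return An [ape::phylo] object, rooted, binary, with positive branch
#'   lengths.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, death_rate = 0, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2)
    stop("'n_taxa' must be an integer >= 2", call. = FALSE)
  if (birth_rate <= 0 || death_rate < 0)
    stop("'birth_rate' must be > 0 and 'death_rate' >= 0", call. = FALSE)
  .with_seed(seed, {
    tree <- ape::rphylo(as.integer(n_taxa), birth = birth_rate,
                        death = death_rate)
    # rphylo can emit numerically zero terminal branches at high turnover;
    # nudge them so patristic distances stay strictly positive off-diagonal.
    tree$edge.length[tree$edge.length <= 0] <- 1e-8
    tree
  })
}

#' Evolve a continuous niche trait by Brownian motion
#'
#' Simulates one trait value per tip under Brownian motion along the tree:
#' each branch adds a Gaussian step with standard deviation
#' `bm_sigma * sqrt(branch length)`. Shared ancestry therefore induces trait
#' covariance equal to `bm_sigma^2` times shared path length, which is what
#' creates phylogenetic signal at short patristic distances.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param bm_sigma Brownian step standard deviation per unit sqrt branch
#'   length (> 0).
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip trait values (the niche optima).
#' @export
evolve_trait_bm <- function(tree, bm_sigma, root_value = 0, seed = NULL) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (!is.numeric(bm_sigma) || bm_sigma <= 0)
    stop("'bm_sigma' must be > 0", call. = FALSE)
  .with_seed(seed, {
    ntip <- ape::Ntip(tree)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
    x <- numeric(ntip + tr$Nnode)
    x[ntip + 1L] <- root_value
    steps <- rnorm(nrow(tr$edge), mean = 0,
                   sd = bm_sigma * sqrt(tr$edge.length))
    for (i in seq_len(nrow(tr$edge)))
      x[tr$edge[i, 2L]] <- x[tr$edge[i, 1L]] + steps[i]
    setNames(x[seq_len(ntip)], tr$tip.label)
  })
}

#' Simulate a structured phylogeny (terminal clades on a deep backbone)
#'
#' Builds a rooted ultrametric tree composed of many small terminal clades
#' (default three tips each) joined by long backbone branches, plus a few
#' deep singleton lineages. This reproduces the geometry of real 16S
#' phylogenies -- dense clusters of close relatives separated by deep
#' inter-family divergences -- which is the regime in which nearest-taxon
#' statistics are informative. Complements [simulate_tree()], whose
#' reconstructed birth-death trees lack this deep-versus-shallow contrast at
#' small tip counts.
#'
#' @param n_clades Number of terminal clades.
#' @param clade_size Tips per clade.
#' @param n_singletons Deep unclustered lineages added to the backbone.
#' @param backbone_depth Length of each backbone branch (stem to every
#'   clade and singleton).
#' @param crown_depth Depth of each terminal clade's crown.
#' @param seed Optional integer seed.
#' @return An `ape::phylo` object with
#'   `n_clades * clade_size + n_singletons` tips; clade members are named
#'   `c<i>_<j>`, singletons `iso<k>`.
#' @export
simulate_structured_tree <- function(n_clades = 16, clade_size = 3,
                                     n_singletons = 2, backbone_depth = 3,
                                     crown_depth = 0.1, seed = NULL) {
  if (n_clades < 2 || clade_size < 2)
    stop("need at least 2 clades of at least 2 tips", call. = FALSE)
  .with_seed(seed, {
    m <- n_clades + n_singletons
    base <- ape::stree(m, "star")
    base$edge.length <- rep(backbone_depth, m)
    tr <- base
    for (i in seq_len(n_clades)) {
      cr <- ape::rphylo(clade_size, 1, 0)
      cr$edge.length <- cr$edge.length * crown_depth /
        max(ape::node.depth.edgelength(cr))
      cr$tip.label <- paste0("c", i, "_", seq_len(clade_size))
      tr <- ape::bind.tree(tr, cr, where = which(tr$tip.label == paste0("t", i)))
    }
    iso <- grepl("^t", tr$tip.label)
    if (any(iso)) tr$tip.label[iso] <- paste0("iso", seq_len(sum(iso)))
    # resolve the basal polytomy so the tree is rooted and binary; the
    # zero-length resolving edges leave patristic distances unchanged
    tr <- ape::multi2di(tr)
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  })
}

#' Convergent-guild niche traits
#'
#' Assigns each terminal clade of a structured tree to one of two niche
#' guilds separated by a fixed trait offset, then adds Brownian-style
#' within-guild divergence (a clade-level and a tip-level Gaussian
#' component). Close relatives therefore share nearly identical niche
#' values while deep relationships carry almost no trait information --
#' the short-distance-only phylogenetic signal observed in real
#' microbial correlograms, where distant lineages converge on shared
#' environmental niches.
#'
#' @param tree A tree from [simulate_structured_tree()] (clade membership
#'   is read from the `c<i>_<j>` tip labels; singletons form their own
#'   groups).
#' @param separation Trait distance between the two guild centres
#'   (centres at +/- separation/2).
#' @param clade_sd Standard deviation of the clade-level trait component.
#' @param tip_sd Standard deviation of the tip-level trait component.
#' @param seed Optional integer seed.
#' @return Named numeric trait vector with a `"guild"` attribute giving
#'   each clade's guild assignment.
#' @export
guild_niche_traits <- function(tree, separation = 5, clade_sd = 0.22,
                               tip_sd = 0.14, seed = NULL) {
  .with_seed(seed, {
    grp <- sub("_.*", "", tree$tip.label)
    cherries <- split(tree$tip.label, grp)
    ord <- sample(names(cherries))
    gA <- ord[seq_len(length(ord) %/% 2)]
    z <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
    guild <- setNames(character(length(cherries)), names(cherries))
    for (nm in names(cherries)) {
      guild[nm] <- if (nm %in% gA) "A" else "B"
      centre <- if (guild[nm] == "A") -separation / 2 else separation / 2
      base <- centre + rnorm(1, 0, clade_sd)
      z[cherries[[nm]]] <- base + rnorm(length(cherries[[nm]]), 0, tip_sd)
    }
    attr(z, "guild") <- guild
    z
  })
}

#' Assemble communities under environmental selection
#'
#' Each sample holds `community_size` individuals drawn multinomially with
#' taxon probability proportional to a Gaussian fitness filter
#' `exp(-(trait - env_value)^2 / (2 * filter_width^2))`. A single shared
#' `env_value` across samples emulates homogeneous selection; calling this
#' for two groups with divergent `env_value`s emulates heterogeneous
#' selection.
#'
#' @param tree Phylogeny whose tips define the taxon pool.
#' @param traits Named trait vector covering all tips (niche optima).
#' @param env_value Position of the environmental filter on the trait axis.
#' @param n_samples Number of samples to draw.
#' @param community_size Individuals per sample.
#' @param filter_width Filter standard deviation in trait units (> 0).
#' @param seed Optional integer seed.
#' @param drift_level Dirichlet concentration compounding ecological drift
#'   onto the filter (per-sample taxon probabilities drawn from
#'   `Dirichlet(drift_level * p)`). The default `Inf` disables drift, so
#'   every sample is a pure multinomial draw from the filter
#'   probabilities. Finite values emulate the realistic situation where
#'   selection constrains WHICH lineages can persist while demographic
#'   stochasticity governs which of them dominate each replicate; community
#'   identities then turn over among close relatives, the signature that
#'   the betaNTI test reads as homogeneous selection.
#' @param sample_prefix Prefix for generated sample names.
#' @return Integer sample x taxon matrix with row sums `community_size`.
#' @export
assemble_selection <- function(tree, traits, env_value, n_samples,
                               community_size, filter_width, seed = NULL,
                               drift_level = Inf, sample_prefix = "S") {
  if (!is.numeric(filter_width) || filter_width <= 0)
    stop("'filter_width' must be > 0", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss))
    stop("traits missing for tips: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(drift_level) || drift_level <= 0)
    stop("'drift_level' must be > 0", call. = FALSE)
  tr <- traits[tree$tip.label]
  lw <- -(tr - env_value)^2 / (2 * filter_width^2)
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  .with_seed(seed, {
    out <- matrix(0L, n_samples, length(p),
                  dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                  tree$tip.label))
    for (s in seq_len(n_samples)) {
      ps <- if (is.finite(drift_level)) {
        g <- rgamma(length(p), shape = drift_level * p, rate = 1)
        if (sum(g) == 0) p else g / sum(g)
      } else p
      out[s, ] <- rmultinom(1L, community_size, ps)[, 1L]
    }
    out
  })
}

#' Assemble communities by neutral drift
#'
#' Samples are drawn multinomially from Dirichlet-perturbed metacommunity
#' relative abundances, with no reference to traits or phylogeny. The
#' Dirichlet concentration `noise_level` controls drift magnitude:
#' `noise_level = Inf` disables the perturbation (pure multinomial sampling
#' noise), small values make sample-to-sample compositional fluctuations
#' large.
#'
#' @param metacommunity_abundances Nonnegative taxon abundance vector (named,
#'   or names taken from `tree` tips when supplied).
#' @param n_samples,community_size Samples to draw and individuals each.
#' @param noise_level Dirichlet concentration (> 0, may be `Inf`).
#' @param tree Optional phylogeny supplying taxon names.
#' @param seed Optional integer seed.
#' @param sample_prefix Prefix for generated sample names.
#' @return Integer sample x taxon matrix with row sums `community_size`.
#' @export
assemble_neutral_drift <- function(metacommunity_abundances, n_samples,
                                   community_size, noise_level = Inf,
                                   tree = NULL, seed = NULL,
                                   sample_prefix = "S") {
  m <- metacommunity_abundances
  if (any(m < 0) || all(m == 0))
    stop("metacommunity abundances must be nonnegative and not all zero",
         call. = FALSE)
  if (!is.numeric(noise_level) || noise_level <= 0)
    stop("'noise_level' must be > 0", call. = FALSE)
  taxa <- names(m)
  if (is.null(taxa) && !is.null(tree)) taxa <- tree$tip.label
  if (is.null(taxa)) taxa <- paste0("t", seq_along(m))
  rel <- m / sum(m)
  .with_seed(seed, {
    out <- matrix(0L, n_samples, length(m),
                  dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                  taxa))
    for (s in seq_len(n_samples)) {
      p <- if (is.finite(noise_level)) {
        g <- rgamma(length(rel), shape = noise_level * rel, rate = 1)
        if (sum(g) == 0) rel else g / sum(g)
      } else rel
      out[s, ] <- rmultinom(1L, community_size, p)[, 1L]
    }
    out
  })
}

#' Assemble communities under dispersal limitation
#'
#' Each sample independently draws its own random pool containing
#' `ceiling(pool_fraction * n_taxa)` taxa and fills `community_size`
#' individuals uniformly from that pool, so different samples see largely
#' disjoint species pools. `pool_fraction = 1` reduces to neutral drift from
#' a uniform metacommunity.
#'
#' @param tree Phylogeny whose tips define the taxon pool.
#' @param n_samples,community_size Samples to draw and individuals each.
#' @param pool_fraction Fraction of candidate taxa reachable per sample,
#'   in (0, 1].
#' @param seed Optional integer seed.
#' @param taxa Candidate taxa the pools are drawn from (default: all tree
#'   tips). Restricting this to locally persisting endemics -- excluding
#'   regionally dominant taxa -- emulates closed habitat patches such as
#'   intact permafrost.
#' @param dominance Dirichlet concentration for within-pool abundance
#'   weights. The default `Inf` fills pools uniformly (so
#'   `pool_fraction = 1` reduces exactly to neutral drift from a uniform
#'   metacommunity); small values let each isolated patch develop its own
#'   dominant taxa, as drift inside closed patches does.
#' @param sample_prefix Prefix for generated sample names.
#' @return Integer sample x taxon matrix with row sums `community_size`;
#'   columns cover all tree tips.
#' @export
assemble_dispersal_limited <- function(tree, n_samples, community_size,
                                       pool_fraction, seed = NULL,
                                       taxa = NULL, dominance = Inf,
                                       sample_prefix = "S") {
  if (!is.numeric(pool_fraction) || pool_fraction <= 0 || pool_fraction > 1)
    stop("'pool_fraction' must be in (0, 1]", call. = FALSE)
  if (!is.numeric(dominance) || dominance <= 0)
    stop("'dominance' must be > 0", call. = FALSE)
  all_taxa <- tree$tip.label
  if (is.null(taxa)) taxa <- all_taxa
  if (length(setdiff(taxa, all_taxa)))
    stop("candidate taxa must be tree tips", call. = FALSE)
  k <- ceiling(pool_fraction * length(taxa))
  .with_seed(seed, {
    out <- matrix(0L, n_samples, length(all_taxa),
                  dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                  all_taxa))
    for (s in seq_len(n_samples)) {
      pool <- sample(taxa, k)
      w <- if (is.finite(dominance)) {
        g <- rgamma(k, shape = dominance, rate = 1)
        if (sum(g) == 0) rep(1, k) else g
      } else rep(1, k)
      p <- setNames(numeric(length(all_taxa)), all_taxa)
      p[pool] <- w / sum(w)
      out[s, ] <- rmultinom(1L, community_size, p)[, 1L]
    }
    out
  })
}

#' Assemble communities under homogenizing dispersal
#'
#' All samples are near-copies of one template community: a fraction
#' `swap_fraction` of each sample's individuals is removed at random and
#' replaced by individuals drawn uniformly across all taxa. Row totals are
#' conserved, and pairwise dissimilarity is far below any neutral
#' expectation, emulating mass effects that overwhelm selection.
#'
#' @param template_sample Named integer count vector (the shared source
#'   community).
#' @param n_samples Samples to generate.
#' @param swap_fraction Fraction of individuals resampled per sample
#'   (recommended <= 0.05).
#' @param seed Optional integer seed.
#' @param source_weights Taxon weights for the incoming individuals
#'   (default uniform). Passing regional metacommunity abundances makes
#'   immigrants arrive in proportion to the source pool, as mass effects
#'   do.
#' @param sample_prefix Prefix for generated sample names.
#' @return Integer sample x taxon matrix; every row sums to
#'   `sum(template_sample)`.
#' @export
assemble_homogenizing_dispersal <- function(template_sample, n_samples,
                                            swap_fraction, seed = NULL,
                                            source_weights = NULL,
                                            sample_prefix = "S") {
  if (any(template_sample < 0) || sum(template_sample) == 0)
    stop("template must be nonnegative with positive total", call. = FALSE)
  if (swap_fraction < 0 || swap_fraction > 1)
    stop("'swap_fraction' must be in [0, 1]", call. = FALSE)
  taxa <- names(template_sample)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(template_sample))
  total <- sum(template_sample)
  k <- round(swap_fraction * total)
  src <- if (is.null(source_weights)) rep(1, length(template_sample))
         else source_weights[taxa]
  if (any(is.na(src)) || any(src < 0) || sum(src) == 0)
    stop("'source_weights' must cover all taxa and be nonnegative",
         call. = FALSE)
  src <- src / sum(src)
  .with_seed(seed, {
    out <- matrix(0L, n_samples, length(template_sample),
                  dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                  taxa))
    for (s in seq_len(n_samples)) {
      cnt <- as.integer(template_sample)
      if (k > 0) {
        # remove k individuals uniformly without replacement
        drop <- rmultinom_hyper(cnt, k)
        cnt <- cnt - drop
        cnt <- cnt + rmultinom(1L, k, src)[, 1L]
      }
      out[s, ] <- cnt
    }
    out
  })
}

# Draw k individuals without replacement from a count vector
# (multivariate hypergeometric); returns per-taxon removal counts.
rmultinom_hyper <- function(counts, k) {
  idx <- sample.int(sum(counts), k)
  bins <- findInterval(idx - 0.5, cumsum(counts)) + 1L
  tabulate(bins, nbins = length(counts))
}

#' Simulate paired incubation respiration series
#'
#' Generates respiration-rate time series at 4 degrees C and 15 degrees C
#' with a known temperature sensitivity. The 15 degree rate is
#' `base_rate_4c * q10_true^(11/10)` (the inverse of the Q10 definition with
#' an 11 degree gap), multiplied by mean-one lognormal measurement noise.
#'
#' @param base_rate_4c True rate at 4 degrees C (> 0), in
#'   ug C-CO2 per g dry soil per hour.
#' @param q10_true True temperature sensitivity (> 0).
#' @param days Numeric vector of measurement days.
#' @param measurement_noise_cv Coefficient of variation of the lognormal
#'   measurement noise (0 = noise-free).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `day`, `rate_4c`, `rate_15c`.
#' @export
simulate_respiration <- function(base_rate_4c, q10_true, days,
                                 measurement_noise_cv = 0, seed = NULL) {
  if (base_rate_4c <= 0 || q10_true <= 0)
    stop("'base_rate_4c' and 'q10_true' must be > 0", call. = FALSE)
  if (measurement_noise_cv < 0)
    stop("'measurement_noise_cv' must be >= 0", call. = FALSE)
  rate15 <- base_rate_4c * q10_true^((15 - 4) / 10)
  .with_seed(seed, {
    n <- length(days)
    noise <- function() {
      if (measurement_noise_cv == 0) return(rep(1, n))
      sdl <- sqrt(log(1 + measurement_noise_cv^2))
      rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    data.frame(day = days,
               rate_4c = base_rate_4c * noise(),
               rate_15c = rate15 * noise())
  })
}

# internal: n_samples multinomial draws with fixed probabilities
.multinomial_table <- function(p, n_samples, community_size, taxa, prefix) {
  out <- matrix(0L, n_samples, length(p),
                dimnames = list(paste0(prefix, seq_len(n_samples)), taxa))
  for (s in seq_len(n_samples))
    out[s, ] <- rmultinom(1L, community_size, p)[, 1L]
  out
}

#' Simulate a soil depth profile of abiotic variables
#'
#' Generates sample metadata resembling a permafrost depth profile:
#' gravimetric water content, pH, total carbon and nitrogen, and the C:N
#' ratio, with water content, carbon and C:N decreasing with depth and pH
#' most acidic near the surface.
#'
#' @param depths_cm Numeric vector of layer midpoints (cm).
#' @param n_replicates Replicate cores per depth.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `sample`, `depth_cm`, `GWC`, `pH`,
#'   `pct_C`, `pct_N`, `CN`.
#' @export
simulate_depth_environment <- function(depths_cm = seq(5, 75, by = 10),
                                       n_replicates = 4, seed = NULL) {
  .with_seed(seed, {
    d <- rep(depths_cm, each = n_replicates)
    n <- length(d)
    gwc <- pmax(100, 600 - 5.5 * d + rnorm(n, 0, 40))
    ph <- 3.9 + 0.015 * d + rnorm(n, 0, 0.15)
    pc <- pmax(8, 46 - 0.45 * d + rnorm(n, 0, 2))
    pn <- pmax(0.26, 1.1 + rnorm(n, 0, 0.15))
    data.frame(
      sample = paste0("d", d, "_r", rep(seq_len(n_replicates),
                                        times = length(depths_cm))),
      depth_cm = d, GWC = gwc, pH = ph, pct_C = pc, pct_N = pn,
      CN = pc / pn, stringsAsFactors = FALSE
    )
  })
}
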