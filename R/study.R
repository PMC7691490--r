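#' Simulate a complete community-assembly recovery study
#'
#' Generates one synthetic study in which every ecological assembly process
#' of the five-way classification acts on a known group of samples, so the
#' whole inference chain (betaMNTD, tip-shuffle nulls, betaNTI, RC-bray,
#' classification) can be validated by parameter recovery.
#'
#' The study comprises, on one structured phylogeny
#' ([simulate_structured_tree()]) with convergent-guild niche traits
#' ([guild_niche_traits()]):
#' \describe{
#'   \item{SELA, SELB}{two groups filtered at the two guild niche centres
#'     (a two-environment selection experiment). Within-group pairs
#'     experience homogeneous selection, between-group pairs heterogeneous
#'     selection.}
#'   \item{DR}{neutral-drift samples from a lognormal regional
#'     metacommunity.}
#'   \item{DL}{dispersal-limited samples: each draws its own endemic
#'     species pool (excluding the regionally dominant taxa) and develops
#'     its own within-pool dominance structure.}
#'   \item{HD}{homogenizing-dispersal samples: near-copies of one template
#'     community with a small fraction of individuals exchanged.}
#'   \item{REF}{regional reference communities (additional drift samples)
#'     that establish metacommunity occupancy and abundance structure for
#'     the null models, playing the role the full sample collection plays
#'     in field studies.}
#' }
#'
#' @param n_clades,clade_size,n_singletons Structured-tree shape (defaults
#'   give 50 taxa).
#' @param n_samples_per_group Samples per assembly regime.
#' @param n_reference Regional reference samples.
#' @param selection_size Individuals per sample in the selection groups
#'   (small relative to the guild pool, so replicate communities turn over
#'   in membership among close relatives).
#' @param community_size Individuals per sample in the stochastic groups.
#' @param filter_width Gaussian selection filter width (trait units).
#' @param guild_separation Distance between the two guild niche centres.
#' @param meta_decay Geometric decay of the regional rank-abundance
#'   series (relative abundance of rank k is `meta_decay^k`; the classic
#'   niche-preemption model). Ranks are assigned to taxa at random.
#' @param n_commons Number of regionally dominant taxa excluded from
#'   endemic dispersal pools.
#' @param pool_fraction Endemic-pool fraction per dispersal-limited sample.
#' @param dominance Within-pool Dirichlet concentration for
#'   dispersal-limited samples.
#' @param swap_fraction Individuals exchanged per homogenizing-dispersal
#'   sample.
#' @param noise_level Dirichlet concentration of drift perturbation.
#' @param seed Integer seed; fully determines the study.
#' @return List with `tree`, `traits`, `comm` (all groups row-bound),
#'   `metadata` (`sample`, `group`), and `metacommunity` (regional
#'   abundances).
#' @export
simulate_assembly_study <- function(n_clades = 16, clade_size = 3,
                                    n_singletons = 2,
                                    n_samples_per_group = 8,
                                    n_reference = 24,
                                    selection_size = 28,
                                    community_size = 250,
                                    filter_width = 0.5,
                                    guild_separation = 5,
                                    meta_decay = 0.7,
                                    n_commons = 8,
                                    pool_fraction = 0.6,
                                    dominance = 0.6,
                                    swap_fraction = 0.02,
                                    noise_level = 100,
                                    seed = 1) {
  .with_seed(seed, {
    tree <- simulate_structured_tree(n_clades, clade_size, n_singletons)
    traits <- guild_niche_traits(tree, separation = guild_separation)
    ns <- n_samples_per_group
    sela <- assemble_selection(tree, traits, -guild_separation / 2, ns,
                               selection_size, filter_width,
                               sample_prefix = "SELA")
    selb <- assemble_selection(tree, traits, guild_separation / 2, ns,
                               selection_size, filter_width,
                               sample_prefix = "SELB")
    meta_ab <- meta_decay^(seq_along(tree$tip.label) - 1L)
    names(meta_ab) <- sample(tree$tip.label)
    commons <- names(sort(meta_ab, decreasing = TRUE))[seq_len(n_commons)]
    endemics <- setdiff(tree$tip.label, commons)
    dr <- assemble_neutral_drift(meta_ab, ns, community_size, noise_level,
                                 sample_prefix = "DR")
    dl <- assemble_dispersal_limited(tree, ns, community_size,
                                     pool_fraction, taxa = endemics,
                                     dominance = dominance,
                                     sample_prefix = "DL")
    template <- assemble_neutral_drift(meta_ab, 1, community_size, Inf)[1, ]
    hd <- assemble_homogenizing_dispersal(template, ns, swap_fraction,
                                          source_weights = meta_ab,
                                          sample_prefix = "HD")
    ref <- assemble_neutral_drift(meta_ab, n_reference, community_size,
                                  noise_level, sample_prefix = "REF")
    comm <- rbind(sela, selb, dr, dl, hd, ref)
    metadata <- data.frame(
      sample = rownames(comm),
      group = rep(c("selection_a", "selection_b", "drift",
                    "dispersal_limited", "homogenizing_dispersal",
                    "reference"),
                  times = c(ns, ns, ns, ns, ns, n_reference)),
      stringsAsFactors = FALSE
    )
    list(tree = tree, traits = traits, comm = comm, metadata = metadata,
         metacommunity = meta_ab)
  })
}

#' Recover assembly processes from a simulated study
#'
#' Runs the full inference on a study from [simulate_assembly_study()],
#' mirroring how field studies score within-group comparisons against a
#' larger analyzed table: the two selection groups are analyzed together
#' (their union is the taxon pool for the tip-shuffle null); each
#' stochastic regime is analyzed with the sample set that defines its
#' metacommunity (dispersal-limited samples together with the regional
#' reference group; drift and homogenizing-dispersal groups on their own).
#'
#' @param study Output of [simulate_assembly_study()].
#' @param n_reps Null-model iterations (default 999).
#' @param seed Integer seed for the null models.
#' @return List with `fractions` -- named recovery summaries
#'   (`homogeneous_selection`, `heterogeneous_selection`,
#'   `drift_stochastic`, `drift_alone`,
#'   `dispersal_limitation_among_stochastic`, `homogenizing_dispersal`) --
#'   and `results`, the per-experiment pairwise tables.
#' @export
recover_processes <- function(study, n_reps = 999, seed = 1) {
  md <- study$metadata
  by_group <- split(md$sample, md$group)
  pairs_within <- function(s) t(combn(s, 2L))
  tidy <- function(m) m[, colSums(m) > 0, drop = FALSE]

  # Selection experiment: both groups form one table; within-group pairs
  # test homogeneous selection, between-group pairs heterogeneous.
  sel <- tidy(study$comm[c(by_group$selection_a, by_group$selection_b), ,
                         drop = FALSE])
  wg <- rbind(pairs_within(by_group$selection_a),
              pairs_within(by_group$selection_b))
  bg <- as.matrix(expand.grid(by_group$selection_a, by_group$selection_b,
                              stringsAsFactors = FALSE))
  sel_res <- assembly_analysis(sel, study$tree, n_reps = n_reps,
                               seed = seed, pairs = rbind(wg, bg))
  sel_res$comparison <- rep(c("within", "between"), c(nrow(wg), nrow(bg)))

  dr <- tidy(study$comm[by_group$drift, , drop = FALSE])
  dr_res <- assembly_analysis(dr, study$tree, n_reps = n_reps, seed = seed)

  dl <- tidy(study$comm[c(by_group$dispersal_limited, by_group$reference), ,
                        drop = FALSE])
  dl_res <- assembly_analysis(dl, study$tree, n_reps = n_reps, seed = seed,
                              pairs = pairs_within(by_group$dispersal_limited))

  hd <- tidy(study$comm[by_group$homogenizing_dispersal, , drop = FALSE])
  hd_res <- assembly_analysis(hd, study$tree, n_reps = n_reps, seed = seed)

  w <- sel_res[sel_res$comparison == "within", ]
  b <- sel_res[sel_res$comparison == "between", ]
  dl_stoch <- dl_res[abs(dl_res$bnti) <= 2, ]
  fractions <- c(
    homogeneous_selection =
      mean(w$process == "homogeneous_selection"),
    heterogeneous_selection =
      mean(b$process == "heterogeneous_selection"),
    drift_stochastic = mean(abs(dr_res$bnti) <= 2),
    drift_alone = mean(dr_res$process == "drift_alone"),
    dispersal_limitation_among_stochastic =
      if (nrow(dl_stoch)) mean(dl_stoch$process ==
                                 "dispersal_limitation_drift") else NA_real_,
    homogenizing_dispersal =
      mean(hd_res$process == "homogenizing_dispersal")
  )
  list(fractions = fractions,
       results = list(selection = sel_res, drift = dr_res,
                      dispersal_limited = dl_res,
                      homogenizing_dispersal = hd_res))
}
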