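#' Read a rooted newick phylogeny
#'
#' Parses a newick file and validates that the tree is rooted, has unique
#' tip labels, and carries a branch length on every edge.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e)
                     stop("newick parse error in '", path, "': ",
                          conditionMessage(e), call. = FALSE),
                   warning = function(w)
                     stop("newick parse error in '", path, "': ",
                          conditionMessage(w), call. = FALSE))
  if (is.null(tree))
    stop("newick parse error in '", path, "'", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)
      || anyNA(tree$edge.length))
    stop("tree is missing branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a sample x taxon count table
#'
#' Reads a TSV with samples as rows (first column = sample identifier) and
#' taxa as columns. Counts must be nonnegative integers and identifiers
#' unique. When a tree is supplied, taxa are checked against its tips and
#' mismatches reported by name.
#'
#' @param path Path to a tab-separated table.
#' @param tree Optional phylogeny to validate taxa against.
#' @return Integer sample x taxon matrix.
#' @export
read_community <- function(path, tree = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample identifiers in '", path, "'", call. = FALSE)
  rn <- as.character(df[[1L]])
  df <- df[-1L]
  if (anyDuplicated(names(df)))
    stop("duplicate taxon identifiers in '", path, "'", call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- rn
  if (!is.null(tree)) .check_taxa_on_tree(m, tree)
  m
}

#' Write a sample x taxon count table to TSV
#'
#' @param comm Sample x taxon matrix.
#' @param path Output path.
#' @param id_column Name of the leading identifier column.
#' @export
write_community <- function(comm, path, id_column = "sample") {
  df <- data.frame(rownames(comm), comm, check.names = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV with one row per sample. The first column is the sample
#' identifier; remaining columns are group labels and abiotic variables.
#'
#' @param path Path to a tab-separated metadata file.
#' @param samples Optional character vector of required sample identifiers;
#'   missing samples raise an error.
#' @return `data.frame` with sample identifiers as rownames.
#' @export
read_metadata <- function(path, samples = NULL) {
  if (!file.exists(path))
    stop("metadata file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample identifiers in '", path, "'", call. = FALSE)
  rownames(df) <- as.character(df[[1L]])
  df <- df[-1L]
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(df))
    if (length(missing))
      stop("samples missing from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's individuals uniformly WITHOUT replacement to
#' exactly `depth` (multivariate hypergeometric draw). Samples whose total
#' falls below the depth are dropped and reported in the `"dropped"`
#' attribute; taxa left with all-zero columns are removed.
#'
#' @param comm Sample x taxon count matrix.
#' @param depth Target depth (>= 1).
#' @param seed Optional integer seed.
#' @return Rarefied integer matrix with attribute `"dropped"` naming the
#'   removed samples.
#' @export
rarefy <- function(comm, depth, seed = NULL) {
  comm <- .check_comm(comm)
  if (depth < 1) stop("'depth' must be >= 1", call. = FALSE)
  tot <- rowSums(comm)
  dropped <- rownames(comm)[tot < depth]
  keep <- comm[tot >= depth, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("all samples fall below rarefaction depth ", depth, call. = FALSE)
  out <- .with_seed(seed, {
    r <- keep
    for (s in seq_len(nrow(keep))) {
      if (sum(keep[s, ]) == depth) next
      r[s, ] <- rmultinom_hyper(as.integer(keep[s, ]), depth)
    }
    r
  })
  out <- out[, colSums(out) > 0, drop = FALSE]
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Run the full inference pipeline from a configuration
#'
#' Orchestrates reading inputs, rarefaction, and the requested analysis
#' stages, writing tab-separated outputs and a JSON run manifest recording
#' the seed, parameters, dropped samples and numerical conventions so that
#' identical configurations yield byte-identical outputs.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `tree`, `table`, `metadata` (input paths), `out_dir`,
#'   `rarefaction_depth`, `seed`, `reps`, `stages` (subset of
#'   `"assembly"`, `"signal"`), `group_column` (for within-group profiles),
#'   `signal_variables` (metadata columns for the correlogram stage), and
#'   optional `abundance_weighted`, `n_classes`.
#' @return Invisible list with the loaded inputs and per-stage results;
#'   outputs are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  req <- c("tree", "table", "out_dir")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("configuration missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stages <- config$stages %||% "assembly"
  seed <- config$seed %||% 1L
  reps <- config$reps %||% 999L
  if (reps < 2) stop("'reps' must be >= 2", call. = FALSE)
  depth <- config$rarefaction_depth
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  tree <- read_tree(config$tree)
  comm <- read_community(config$table, tree = tree)
  meta <- if (!is.null(config$metadata))
    read_metadata(config$metadata, samples = rownames(comm)) else NULL

  dropped <- character(0)
  if (!is.null(depth)) {
    comm <- rarefy(comm, depth, seed = seed)
    dropped <- attr(comm, "dropped")
  }
  results <- list(tree = tree, comm = comm, metadata = meta)
  manifest <- list(
    package = "ecoassembly",
    seed = seed, reps = reps, stages = stages,
    rarefaction_depth = depth, dropped_samples = dropped,
    n_samples = nrow(comm), n_taxa = ncol(comm),
    conventions = list(
      abundance_weighted = isTRUE(config$abundance_weighted %||% TRUE),
      boundary = "threshold values fall to the stochastic/interior side",
      combined_optima_log = "log10 with additive shift to min 1 when needed"
    )
  )

  if ("assembly" %in% stages) {
    res <- assembly_analysis(
      comm, tree, n_reps = reps, seed = seed,
      abundance_weighted = isTRUE(config$abundance_weighted %||% TRUE))
    write.table(res, file.path(config$out_dir, "pairwise_assembly.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profiles <- list(all = process_profile(res, "all"))
    gcol <- config$group_column
    if (!is.null(gcol) && !is.null(meta)) {
      groups <- setNames(as.character(meta[[gcol]]), rownames(meta))
      for (g in unique(groups)) {
        sel <- res[groups[res$sample_a] == g & groups[res$sample_b] == g, ,
                   drop = FALSE]
        if (nrow(sel) == 0) next
        profiles[[g]] <- process_profile(sel, "all", subset_label = g)
      }
    }
    ptab <- do.call(rbind, lapply(profiles, function(p)
      data.frame(subset = p$subset_label, n_comparisons = p$n_comparisons,
                 t(p$fractions), check.names = FALSE)))
    write.table(ptab, file.path(config$out_dir, "process_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$assembly <- res
    results$profiles <- profiles
  }

  if ("signal" %in% stages) {
    if (is.null(meta))
      stop("signal stage requires a metadata table", call. = FALSE)
    vars <- config$signal_variables %||%
      names(meta)[vapply(meta, is.numeric, logical(1))]
    opt <- niche_optima(comm, meta, variables = vars)
    dphy <- patristic_matrix(tree)
    dphy <- dphy[rownames(opt), rownames(opt)]
    sig <- list()
    for (v in vars) {
      cg <- mantel_correlogram(optima_distance(opt, v), dphy,
                               n_classes = config$n_classes %||% 50,
                               n_perm = reps, seed = seed)
      cg$variable <- v
      sig[[v]] <- cg
    }
    cmb <- mantel_correlogram(combined_optima_distance(opt), dphy,
                              n_classes = config$n_classes %||% 50,
                              n_perm = reps, seed = seed)
    cmb$variable <- "combined"
    sig$combined <- cmb
    stab <- do.call(rbind, sig)
    write.table(stab, file.path(config$out_dir, "correlograms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$signal <- sig
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
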