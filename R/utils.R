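# Internal helpers shared across modules.

# Run expr with a locally seeded RNG without clobbering the caller's stream.
# seed = NULL leaves the global stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a sample pair, invariant to pair order, so
# per-pair Monte-Carlo streams do not depend on iteration order.
.pair_seed <- function(seed, a, b) {
  nm <- paste(sort(c(as.character(a), as.character(b))), collapse = "\r")
  v <- utf8ToInt(nm)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(seed) + h * 7919) %% 2147483647)
}

# Row-wise minima of a numeric matrix; faster than apply() for the small
# dense blocks used in the nearest-taxon computations.
.row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Validate a sample x taxon count matrix; returns it with dimnames enforced.
.check_comm <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm) || !is.numeric(comm))
    stop("community table must be a numeric sample x taxon matrix", call. = FALSE)
  if (any(comm < 0)) stop("community table has negative entries", call. = FALSE)
  if (is.null(rownames(comm)))
    rownames(comm) <- paste0("S", seq_len(nrow(comm)))
  if (is.null(colnames(comm)))
    stop("community table must have taxon (column) names", call. = FALSE)
  comm
}

# Check every taxon with nonzero abundance is a tip of the tree.
.check_taxa_on_tree <- function(comm, tree) {
  used <- colnames(comm)[colSums(comm) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
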