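test_that("niche optima are abundance-weighted means bounded by the data", {
  comm <- rbind(s1 = c(t1 = 1, t2 = 3), s2 = c(t1 = 1, t2 = 1))
  env <- data.frame(pH = c(4, 6), row.names = c("s1", "s2"))
  opt <- niche_optima(comm, env)
  expect_equal(unname(opt["t1", "pH"]), 5)   # equal counts -> plain mean
  comm2 <- rbind(s1 = c(t1 = 3), s2 = c(t1 = 1))
  env2 <- data.frame(pH = c(4, 8), row.names = c("s1", "s2"))
  expect_equal(unname(niche_optima(comm2, env2)["t1", "pH"]), 5)  # (12+8)/4

  single <- rbind(s1 = c(t1 = 0, t2 = 2), s2 = c(t1 = 5, t2 = 0))
  expect_equal(unname(niche_optima(single, env)["t2", "pH"]), 4)

  # convexity over random instances
  set.seed(1)
  for (k in 1:10) {
    m <- matrix(rpois(30, 2), 5, 6,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:6)))
    m[, 1] <- pmax(m[, 1], 1L)
    e <- data.frame(v = runif(5, -3, 9), row.names = rownames(m))
    keep <- colSums(m) > 0
    op <- suppressWarnings(niche_optima(m, e))
    expect_true(all(op >= min(e$v) - 1e-12 & op <= max(e$v) + 1e-12))
  }

  dead <- rbind(s1 = c(t1 = 1, t2 = 0), s2 = c(t1 = 2, t2 = 0))
  expect_warning(niche_optima(dead, env), "zero total")
})

test_that("single-variable optima distances are absolute differences", {
  opt <- cbind(pH = c(a = 3, b = 7, c = 7))
  d <- optima_distance(opt, "pH")
  expect_equal(d["a", "b"], 4)
  expect_equal(d["b", "c"], 0)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  # triangle inequality on random optima
  set.seed(2)
  x <- runif(8); dd <- optima_distance(setNames(x, letters[1:8]))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
})

test_that("combined optima distance is Euclidean on log10 optima", {
  opt <- rbind(a = c(v1 = 1, v2 = 5), b = c(v1 = 10, v2 = 5))
  d <- combined_optima_distance(opt)
  expect_equal(d["a", "b"], 1)           # one variable, factor 10, log10
  expect_equal(unname(diag(d)), c(0, 0))

  shuffled <- combined_optima_distance(opt[, c("v2", "v1")])
  expect_equal(unname(d["a", "b"]), unname(shuffled["a", "b"]))

  neg <- rbind(a = c(v1 = -1, v2 = 2), b = c(v1 = 3, v2 = 2))
  expect_error(combined_optima_distance(neg, shift = "none"), "nonpositive")
  shifted <- combined_optima_distance(neg)
  expect_equal(unname(attr(shifted, "shifts")["v1"]), 2)  # min becomes 1
})

test_that("patristic distances agree with a naive path-walk oracle", {
  cherry <- ape::read.tree(text = "((x:0.3,y:0.5):0.2,z:1.0);")
  expect_equal(patristic_matrix(cherry)["x", "y"], 0.8)

  tr <- simulate_tree(12, 1, 0.3, seed = 13)
  D <- patristic_matrix(tr)
  expect_equal(D, path_patristic(tr)[rownames(D), colnames(D)],
               tolerance = 1e-12)
  # tree metric: triangle inequality
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)

  noel <- ape::read.tree(text = "((a,b),c);")
  expect_error(patristic_matrix(noel), "branch lengths")
})

test_that("the Mantel correlogram recovers self-correlation structure", {
  tr <- simulate_tree(40, 1, 0, seed = 17)
  D <- patristic_matrix(tr)
  cg <- mantel_correlogram(D, D, n_classes = 12, n_perm = 199, seed = 3)
  tst <- cg[!is.na(cg$p_corrected), ]
  expect_gt(tst$mantel_r[1], 0)
  expect_true(tst$significant[1])
  expect_lt(tail(tst$mantel_r, 1), 0)
  # progressive correction can only raise p-values
  expect_true(all(tst$p_corrected >= tst$p_raw - 1e-12))
  # untestable classes are flagged NA
  expect_true(all(is.na(cg$mantel_r[cg$n_pairs < 2])))
})

test_that("the correlogram matches vegan at shared break points", {
  skip_if_not_installed("vegan")
  tr <- simulate_tree(35, 1, 0, seed = 19)
  z <- evolve_trait_bm(tr, 1, seed = 20)
  deco <- optima_distance(z)
  dphy <- patristic_matrix(tr)
  n_classes <- 8
  breaks <- seq(0, max(dphy[upper.tri(dphy)]), length.out = n_classes + 1)
  mine <- mantel_correlogram(deco, dphy, n_classes = n_classes,
                             n_perm = 99, seed = 1)
  ref <- suppressWarnings(vegan::mantel.correlog(
    as.dist(deco), as.dist(dphy), break.pts = breaks, nperm = 0,
    cutoff = FALSE))$mantel.res
  ok <- which(!is.na(mine$mantel_r) & !is.na(ref[, "Mantel.cor"]))
  expect_gt(length(ok), 3)
  expect_equal(unname(mine$mantel_r[ok]), unname(ref[ok, "Mantel.cor"]),
               tolerance = 1e-10)
})

test_that("permutation p-values are calibrated under label shuffling", {
  tr <- simulate_tree(50, 1, 0, seed = 23)
  z <- evolve_trait_bm(tr, 1, seed = 24)
  dphy <- patristic_matrix(tr)
  set.seed(9)
  ps <- vapply(1:60, function(r) {
    zs <- setNames(sample(z), names(z))
    cg <- mantel_correlogram(optima_distance(zs), dphy, n_classes = 20,
                             n_perm = 99, seed = 7000 + r)
    cg$p_raw[!is.na(cg$p_raw)][1]
  }, numeric(1))
  # roughly uniform: not a hard gate, just a calibration sanity band
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})
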