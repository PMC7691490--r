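test_that("simulate_tree produces rooted binary trees with the forced topology facts", {
  tr <- simulate_tree(8, 1, 0, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 8)
  expect_equal(tr$Nnode, 7)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))

  tr2 <- simulate_tree(2, 1, 0, seed = 3)
  D <- patristic_matrix(tr2)
  expect_equal(D[1, 2], sum(tr2$edge.length))

  expect_identical(ape::write.tree(simulate_tree(50, 1, 0, seed = 7)),
                   ape::write.tree(simulate_tree(50, 1, 0, seed = 7)))
  expect_error(simulate_tree(1), "n_taxa")
})

test_that("Brownian traits have the BM variance structure", {
  tr <- simulate_tree(8, 1, 0, seed = 4)
  # degenerate limit: vanishing step size pins every tip at the root value
  z0 <- evolve_trait_bm(tr, 1e-12, root_value = 2.5, seed = 1)
  expect_true(all(abs(z0 - 2.5) < 1e-9))
  expect_error(evolve_trait_bm(tr, 0), "bm_sigma")

  # zero-length terminal pair inherits identical values
  tr0 <- ape::read.tree(text = "((a:0,b:0):1,c:2);")
  z <- evolve_trait_bm(tr0, 1, seed = 2)
  expect_identical(unname(z["a"]), unname(z["b"]))

  # Monte-Carlo check of Var(tip) = sigma^2 * root-to-tip depth
  sigma <- 0.8
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  tip <- which.max(depths)
  vals <- vapply(seq_len(500), function(r)
    evolve_trait_bm(tr, sigma, seed = 10000 + r)[tip], numeric(1))
  expect_lt(abs(var(vals) / (sigma^2 * depths[tip]) - 1), 0.15)
})

test_that("selection filter behaves across its width limits and separates groups", {
  tr <- simulate_tree(12, 1, 0, seed = 5)
  z <- evolve_trait_bm(tr, 1, seed = 6)

  # flat-filter limit: all taxa near-equally likely
  wide <- assemble_selection(tr, z, 0, 200, 60, filter_width = 1e6, seed = 1)
  shares <- colSums(wide) / sum(wide)
  expect_true(all(abs(shares - 1 / 12) < 0.02))

  # delta-filter limit: the taxon nearest the optimum dominates
  narrow <- assemble_selection(tr, z, z[3], 5, 100, filter_width = 1e-4, seed = 2)
  expect_true(all(narrow[, 3] == 100))

  # divergent environments push between-group turnover above within-group
  a <- assemble_selection(tr, z, min(z), 6, 200, 0.5, seed = 3)
  b <- assemble_selection(tr, z, max(z), 6, 200, 0.5, seed = 4)
  bc <- function(x, y) bray_curtis(x, y)
  within <- c(apply(combn(6, 2), 2, function(ij) bc(a[ij[1], ], a[ij[2], ])),
              apply(combn(6, 2), 2, function(ij) bc(b[ij[1], ], b[ij[2], ])))
  between <- as.vector(outer(1:6, 1:6, Vectorize(function(i, j) bc(a[i, ], b[j, ]))))
  expect_gt(mean(between), mean(within))
  expect_error(assemble_selection(tr, z, 0, 2, 10, filter_width = 0), "filter_width")
})

test_that("neutral drift matches the metacommunity in expectation", {
  meta <- c(t1 = 5, t2 = 3, t3 = 2)
  out <- assemble_neutral_drift(meta, 200, 100, noise_level = Inf, seed = 1)
  expect_true(all(rowSums(out) == 100))
  expect_identical(out, assemble_neutral_drift(meta, 200, 100,
                                               noise_level = Inf, seed = 1))
  expected <- 100 * meta / sum(meta)
  expect_true(all(abs(colMeans(out) / expected - 1) < 0.10))
  expect_error(assemble_neutral_drift(c(0, 0), 2, 10), "nonnegative")
})

test_that("dispersal limitation restricts pools and raises turnover", {
  tr <- simulate_tree(20, 1, 0, seed = 8)
  lim <- assemble_dispersal_limited(tr, 10, 80, pool_fraction = 0.2, seed = 1)
  expect_true(all(rowSums(lim > 0) <= ceiling(0.2 * 20)))
  expect_true(all(rowSums(lim) == 80))
  expect_error(assemble_dispersal_limited(tr, 2, 10, 0), "pool_fraction")
  expect_error(assemble_dispersal_limited(tr, 2, 10, 1.2), "pool_fraction")

  mean_bc <- function(m) {
    mean(apply(combn(nrow(m), 2), 2,
               function(ij) bray_curtis(m[ij[1], ], m[ij[2], ])))
  }
  d_lim <- vapply(1:20, function(r)
    mean_bc(assemble_dispersal_limited(tr, 10, 80, 0.2, seed = r)), numeric(1))
  d_full <- vapply(1:20, function(r)
    mean_bc(assemble_dispersal_limited(tr, 10, 80, 1, seed = 100 + r)),
    numeric(1))
  expect_gt(mean(d_lim), mean(d_full))
})

test_that("homogenizing dispersal conserves totals and collapses dissimilarity", {
  template <- c(a = 40, b = 30, c = 20, d = 10)
  same <- assemble_homogenizing_dispersal(template, 5, swap_fraction = 0, seed = 1)
  expect_true(all(apply(same, 1, function(x) identical(as.integer(x),
                                                       as.integer(template)))))
  swapped <- assemble_homogenizing_dispersal(template, 8, 0.05, seed = 2)
  expect_true(all(rowSums(swapped) == sum(template)))
})

test_that("respiration simulator inverts exactly at zero noise", {
  rs <- simulate_respiration(2, q10_true = 2, days = c(30, 60, 90),
                             measurement_noise_cv = 0)
  expect_equal(q10(mean(rs$rate_15c), mean(rs$rate_4c)), 2)
  flat <- simulate_respiration(1.5, q10_true = 1, days = 1:5,
                               measurement_noise_cv = 0)
  expect_equal(flat$rate_4c, flat$rate_15c)
})

test_that("the depth-profile environment has the expected gradients", {
  env <- simulate_depth_environment(seed = 4)
  expect_equal(nrow(env), 8 * 4)
  expect_true(all(env$GWC >= 100))
  expect_true(all(env$pH > 0))
  expect_equal(env$CN, env$pct_C / env$pct_N)
  # shallow layers wetter and more carbon-rich than deep layers on average
  shallow <- env$depth_cm <= 25; deep <- env$depth_cm >= 55
  expect_gt(mean(env$GWC[shallow]), mean(env$GWC[deep]))
  expect_gt(mean(env$CN[shallow]), mean(env$CN[deep]))
  expect_identical(env, simulate_depth_environment(seed = 4))
})

test_that("the assembly study is seed-deterministic with conserved row sums", {
  st <- simulate_assembly_study(seed = 3)
  st2 <- simulate_assembly_study(seed = 3)
  expect_identical(st$comm, st2$comm)
  expect_identical(st$metadata, st2$metadata)
  expect_setequal(rownames(st$comm), st$metadata$sample)
  sizes <- tapply(rowSums(st$comm), st$metadata$group[
    match(rownames(st$comm), st$metadata$sample)], unique)
  expect_true(all(st$comm >= 0))
  expect_true(all(st$comm == round(st$comm)))
  expect_true(all(colnames(st$comm) %in% st$tree$tip.label))
})
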