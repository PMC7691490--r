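test_that("Bray-Curtis matches its closed form", {
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 4)), 0.5)
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(1, 2), c(2, 1)), bray_curtis(c(2, 1), c(1, 2)))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
})

test_that("betaMNTD handles the forced small cases", {
  tr <- ape::read.tree(text = "((x:0.3,y:0.5):0.2,z:0.9);")
  comm <- rbind(s1 = c(x = 3, y = 0, z = 0), s2 = c(x = 0, y = 2, z = 0))
  expect_equal(bmntd(comm, c("s1", "s2"), tr), 0.8)

  shared <- rbind(s1 = c(x = 3, y = 1, z = 2), s2 = c(x = 1, y = 5, z = 1))
  expect_equal(bmntd(shared, c("s1", "s2"), tr), 0)

  # symmetry
  inst <- random_instance(7, seed = 11)
  expect_equal(bmntd(inst$comm, c("s1", "s2"), inst$tree),
               bmntd(inst$comm, c("s2", "s1"), inst$tree))
  # missing taxon named in the error
  bad <- cbind(inst$comm, ghost = c(1L, 1L))
  expect_error(bmntd(bad, c("s1", "s2"), inst$tree), "ghost")
})

test_that("betaMNTD agrees with brute force and with picante", {
  skip_if_not_installed("picante")
  for (k in 1:10) {
    inst <- random_instance(sample(4:10, 1), seed = 40 + k)
    D <- path_patristic(inst$tree)
    mine <- bmntd(inst$comm, c("s1", "s2"), inst$tree)
    expect_equal(mine, brute_bmntd(inst$comm, c("s1", "s2"), D),
                 tolerance = 1e-12)
    ref <- as.matrix(picante::comdistnt(inst$comm,
                                        ape::cophenetic.phylo(inst$tree),
                                        abundance.weighted = TRUE))["s1", "s2"]
    expect_equal(mine, unname(ref), tolerance = 1e-12)
  }
})

test_that("the tip-shuffle null enumerates correctly on tiny trees", {
  # two taxa: a permutation either fixes or swaps the tips, so the null of
  # a single-taxon pair takes at most the values {0, d(x,y)}
  tr <- simulate_tree(2, 1, 0, seed = 2)
  d <- patristic_matrix(tr)[1, 2]
  comm <- rbind(s1 = c(5L, 0L), s2 = c(0L, 4L))
  colnames(comm) <- tr$tip.label
  nb <- null_bmntd(comm, tr, n_reps = 200, seed = 1)
  expect_true(all(vapply(nb$values[, 1], function(v)
    isTRUE(all.equal(v, 0)) || isTRUE(all.equal(v, d)), logical(1))))

  # seed determinism
  nb2 <- null_bmntd(comm, tr, n_reps = 200, seed = 1)
  expect_identical(nb$values, nb2$values)

  # six taxa: 999-rep mean within 3 SE of the exact all-permutation mean
  inst <- random_instance(6, seed = 77)
  D <- patristic_matrix(inst$tree)
  exact <- vapply(all_perms(6), function(p) {
    Dp <- D[unlist(p), unlist(p)]
    dimnames(Dp) <- dimnames(D)
    brute_bmntd(inst$comm, c("s1", "s2"), Dp)
  }, numeric(1))
  nb <- null_bmntd(inst$comm, inst$tree, n_reps = 999, seed = 9)
  se <- sd(exact) / sqrt(999)
  expect_lt(abs(nb$mean[1] - mean(exact)), 3 * se)
})

test_that("betaNTI is the null-standardized deviation with guarded degeneracy", {
  null <- list(mean = 2, sd = 0.5)
  expect_equal(bnti(2, null), 0)
  expect_equal(bnti(3, null), 2)
  expect_error(bnti(1, list(mean = 2, sd = 0)), "degenerate")
  # observed sitting exactly on a point-mass null standardizes to zero
  expect_equal(bnti(2, list(mean = 2, sd = 0)), 0)
})

test_that("betaNTI is invariant under uniform branch-length rescaling", {
  inst <- random_instance(8, seed = 21)
  tr2 <- inst$tree
  tr2$edge.length <- tr2$edge.length * 3.7
  nb1 <- null_bmntd(inst$comm, inst$tree, n_reps = 299, seed = 5)
  nb2 <- null_bmntd(inst$comm, tr2, n_reps = 299, seed = 5)
  expect_lt(abs(bnti(nb1$obs[1], nb1) - bnti(nb2$obs[1], nb2)), 1e-9)
})

test_that("RC-bray stays in bounds and ignores pair orientation", {
  inst <- random_instance(6, n_samples = 4, seed = 31)
  rc <- raup_crick_bray(inst$comm, c("s1", "s2"), n_reps = 199, seed = 4)
  expect_gte(rc, -1); expect_lte(rc, 1)
  expect_identical(rc, raup_crick_bray(inst$comm, c("s2", "s1"),
                                       n_reps = 199, seed = 4))
})

test_that("the process classifier implements the two-stage rule", {
  expect_equal(classify_process(-3), "homogeneous_selection")
  expect_equal(classify_process(2.5), "heterogeneous_selection")
  expect_equal(classify_process(0.5, 0.99), "dispersal_limitation_drift")
  expect_equal(classify_process(1.0, 0.2), "drift_alone")
  expect_equal(classify_process(-1.5, -0.99), "homogenizing_dispersal")
  # boundary convention: threshold values fall to the interior side
  expect_equal(classify_process(-2, -0.99), "homogenizing_dispersal")
  expect_equal(classify_process(2, 0.99), "dispersal_limitation_drift")
  expect_equal(classify_process(0, 0.95), "drift_alone")
  expect_equal(classify_process(0, -0.95), "drift_alone")
  expect_error(classify_process(1.5), "rc_bray")
  # the plane is covered: every combination yields a label
  grid <- expand.grid(b = seq(-4, 4, by = 0.5), r = seq(-1, 1, by = 0.25))
  labs <- classify_process(grid$b, grid$r)
  expect_true(all(labs %in% c("homogeneous_selection", "heterogeneous_selection",
                              "homogenizing_dispersal",
                              "dispersal_limitation_drift", "drift_alone")))
})

test_that("process profiles count comparisons correctly", {
  res <- data.frame(
    sample_a = c("a", "a", "b", "c"), sample_b = c("b", "c", "c", "d"),
    process = c("homogeneous_selection", "homogeneous_selection",
                "dispersal_limitation_drift", "drift_alone"),
    stringsAsFactors = FALSE)
  pr <- process_profile(res)
  expect_equal(sum(pr$fractions), 1)
  expect_equal(unname(pr$fractions["homogeneous_selection"]), 0.5)
  expect_equal(unname(pr$fractions["drift_alone"]), 0.25)
  expect_equal(pr$n_comparisons, 4)

  uni <- res; uni$process <- "drift_alone"
  expect_equal(unname(process_profile(uni)$fractions["drift_alone"]), 1)

  groups <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  expect_error(process_profile(res[res$sample_a == "a" & res$sample_b == "c", ],
                               "within-group", groups = groups), "no pairwise")
})
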