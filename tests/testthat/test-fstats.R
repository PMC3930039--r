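test_that("theta hits the degenerate anchors", {
  expect_equal(pairwise_fst(c(48, 0, 0), c(0, 0, 48), n_perm = 0)$theta, 1)
  # same-allele monomorphic pair: undefined, reported as NA
  expect_true(is.na(pairwise_fst(c(30, 0, 0), c(20, 0, 0),
                                 n_perm = 0)$theta))
  # equal-frequency large samples: theta near zero
  a <- simulate_population(300, 0.3, seed = 1)$sample
  b <- simulate_population(300, 0.3, seed = 2)$sample
  expect_lt(abs(pairwise_fst(a, b, n_perm = 0)$theta), 0.02)
  expect_error(pairwise_fst(c(1, 0, 0), c(5, 5, 5), n_perm = 0), "n >= 2")
})

test_that("island-model F_ST is recovered without bias over replicates", {
  # two demes with frequencies drawn so E[F_ST] = 0.10
  fst_target <- 0.10
  pbar <- 0.5
  shape <- pbar * (1 / fst_target - 1)
  th <- vapply(1:100, function(s) {
    set.seed(400 + s)
    p_demes <- stats::rbeta(2, shape, shape)
    a <- simulate_population(100, p_demes[1], seed = 800 + s)$sample
    b <- simulate_population(100, p_demes[2], seed = 900 + s)$sample
    pairwise_fst(a, b, n_perm = 0)$theta
  }, numeric(1))
  se <- stats::sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - fst_target), 3 * se + 0.01)
})

test_that("inbreeding F is recovered by the hierarchical decomposition", {
  pops <- lapply(1:6, function(i)
    simulate_population(150, 0.4, f = 0.3, site_id = paste0("s", i),
                        region = if (i <= 3) "A" else "B",
                        seed = 40 + i)$sample)
  fs <- hierarchical_fstats(pops, n_perm = 0)
  expect_lt(abs(fs$F[["F_IS"]] - 0.3), 0.08)
  # panmictic pops: F_IS near zero
  pops0 <- lapply(1:6, function(i)
    simulate_population(150, 0.4, f = 0, site_id = paste0("s", i),
                        region = if (i <= 3) "A" else "B",
                        seed = 70 + i)$sample)
  fs0 <- hierarchical_fstats(pops0, n_perm = 0)
  expect_lt(abs(fs0$F[["F_IS"]]), 0.08)
})

test_that("identical populations give null F_CT with large permutation p", {
  pops <- lapply(1:4, function(i)
    population_sample(paste0("s", i), 40, 40, 20,
                      region = if (i %% 2) "A" else "B"))
  fs <- hierarchical_fstats(pops, n_perm = 200, seed = 5)
  expect_lt(abs(fs$F[["F_CT"]]), 1e-6)
  expect_gt(fs$p[["F_CT"]], 0.5)
})

test_that("fixed-vs-segregating groups give positive, significant F_CT", {
  # 5 populations per group: the population-label permutation null has
  # C(10,5) = 252 distinct splits, fine enough to resolve p < 0.05
  pops <- c(
    lapply(1:5, function(i) population_sample(paste0("m", i), 100, 0, 0,
                                              region = "fixed")),
    lapply(1:5, function(i) {
      sim <- simulate_population(100, 0.5, site_id = paste0("e", i),
                                 region = "seg", seed = 50 + i)
      sim$sample
    }))
  fs <- hierarchical_fstats(pops, n_perm = 300, seed = 9)
  expect_gt(fs$F[["F_CT"]], 0.2)
  expect_lt(fs$p[["F_CT"]], 0.05)
})

test_that("survey counts show regional structure and heterozygote deficit", {
  pops <- survey_pops()
  fs <- hierarchical_fstats(pops[c(as.character(1:5), as.character(7:16))],
                            n_perm = 300, seed = 17)
  # direction-only checks: among-region differentiation and within-region
  # inbreeding are both positive and significant
  expect_gt(fs$F[["F_CT"]], 0)
  expect_lt(fs$p[["F_CT"]], 0.05)
  expect_gt(fs$F[["F_IS"]], 0)
  expect_lt(fs$p[["F_IS"]], 0.05)
  expect_gt(fs$F[["F_ST"]], fs$F[["F_SC"]])
})

test_that("permutation p is uniform under the exchangeable null", {
  set.seed(99)
  res <- lapply(1:200, function(s) {
    a <- simulate_population(30, 0.3, seed = 2000 + s)$sample
    b <- simulate_population(30, 0.3, seed = 3000 + s)$sample
    pairwise_fst(a, b, n_perm = 99, seed = 4000 + s, return_null = TRUE)
  })
  pvals <- vapply(res, `[[`, numeric(1), "p_perm")
  # the reported tie-inclusive p is valid (sub-uniform at usual levels)
  expect_true(all(pvals >= 1 / 100 & pvals <= 1))
  expect_lt(mean(pvals <= 0.05), 0.05 + 0.04)
  expect_lt(mean(pvals <= 0.20), 0.20 + 0.07)
  # the tie-randomized p built from the same null is exactly uniform
  p_rand <- vapply(res, function(r) {
    gt <- sum(r$null > r$theta, na.rm = TRUE)
    eq <- sum(abs(r$null - r$theta) < 1e-12, na.rm = TRUE)
    (gt + stats::runif(1) * (eq + 1)) / (r$n_perm + 1)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_rand, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pairwise matrix covers every unordered site pair", {
  pops <- survey_pops()[as.character(c(4, 7, 8))]
  m <- pairwise_fst_matrix(pops, n_perm = 50, seed = 2)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$theta[m$site_a == "4"] > 0))
})
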