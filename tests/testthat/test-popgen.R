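test_that("observed heterozygosity is the heterozygote frequency", {
  expect_equal(round(observed_heterozygosity(c(18, 13, 0)), 3), 0.419)
  expect_equal(observed_heterozygosity(c(48, 0, 0)), 0)
  expect_equal(observed_heterozygosity(c(0, 12, 0)), 1)
  expect_error(population_sample("x", 0, 0, 0), "at least one")
})

test_that("unbiased H_E matches the printed site values and its identity", {
  expect_equal(round(unbiased_expected_heterozygosity(c(60, 17, 11)), 3), 0.347)
  expect_equal(round(unbiased_expected_heterozygosity(c(37, 6, 5)), 3), 0.281)
  expect_equal(round(unbiased_expected_heterozygosity(c(42, 6, 0)), 3), 0.118)
  expect_equal(unbiased_expected_heterozygosity(c(30, 0, 0)), 0)
  # (2n-1)/2n * H_E == 2pq exactly; invariant under allele swap
  set.seed(8)
  for (k in 1:20) {
    cnt <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    if (sum(cnt) < 2) next
    n <- sum(cnt)
    p <- (2 * cnt[3] + cnt[2]) / (2 * n)
    he <- unbiased_expected_heterozygosity(cnt)
    expect_equal((2 * n - 1) / (2 * n) * he, 2 * p * (1 - p),
                 tolerance = 1e-12)
    expect_equal(unbiased_expected_heterozygosity(rev(cnt)), he)
  }
})

test_that("exact HWE enumeration reproduces the printed p-values", {
  expect_equal(round(hwe_exact(c(21, 2, 1))$p, 3), 0.126)
  expect_equal(round(hwe_exact(c(5, 2, 3))$p, 3), 0.082)
  expect_equal(round(hwe_exact(c(17, 5, 2))$p, 3), 0.152)
  # a single minor-allele copy admits one configuration
  expect_equal(hwe_exact(c(16, 1, 0))$p, 1)
  expect_equal(hwe_exact(c(10, 0, 0))$p, 1)
})

test_that("the conditional distribution sums to 1 and is swap-invariant", {
  set.seed(12)
  for (k in 1:25) {
    cnt <- c(sample(0:40, 1), sample(0:40, 1), sample(0:40, 1))
    if (sum(cnt) < 1) next
    res <- hwe_exact(cnt)
    expect_equal(sum(res$distribution$prob), 1, tolerance = 1e-9)
    expect_equal(hwe_exact(rev(cnt))$p, res$p, tolerance = 1e-12)
  }
})

test_that("the Markov chain converges to the enumeration oracle", {
  set.seed(3)
  for (k in 1:12) {
    n <- sample(10:100, 1)
    nez <- sample(0:floor(n / 2), 1)
    nee <- sample(0:(n - nez), 1)
    cnt <- c(n - nez - nee, nez, nee)
    p_exact <- hwe_exact(cnt)$p
    p_mc <- hwe_markov_chain(cnt, steps = 4e4, seed = 100 + k)$p
    expect_lt(abs(p_mc - p_exact), 0.04)
  }
  # determinism contract: same seed, identical estimate
  a <- hwe_markov_chain(c(21, 2, 1), steps = 2e4, seed = 7)$p
  b <- hwe_markov_chain(c(21, 2, 1), steps = 2e4, seed = 7)$p
  expect_identical(a, b)
  expect_equal(hwe_markov_chain(c(30, 0, 0), seed = 1)$p, 1)
  expect_error(hwe_markov_chain(c(5, 2, 3), steps = 10, burnin = 10),
               "exceed")
})

test_that("count reconstruction inverts printed tables uniquely", {
  expect_equal(reconstruct_counts(24, 0.083, 0.156),
               c(n_zz = 21L, n_ez = 2L, n_ee = 1L))
  expect_equal(reconstruct_counts(88, 0.193, 0.347),
               c(n_zz = 60L, n_ez = 17L, n_ee = 11L))
  expect_equal(reconstruct_counts(10, 0.000, NA),
               c(n_zz = 10L, n_ez = 0L, n_ee = 0L))
  # printed H_E off by one in the last decimal is still inverted
  expect_equal(reconstruct_counts(10, 0.200, 0.506),
               c(n_zz = 5L, n_ez = 2L, n_ee = 3L))
  expect_error(reconstruct_counts(24, 0.083, 0.9), "no consistent")
  # round trip against the brute-force oracle for random true counts
  set.seed(19)
  for (k in 1:15) {
    cnt <- c(sample(5:40, 1), sample(0:10, 1), sample(0:4, 1))
    cnt <- c(max(cnt[1], cnt[3]), cnt[2], min(cnt[1], cnt[3]))
    n <- sum(cnt)
    ho <- round(cnt[2] / n, 3)
    he <- round(unbiased_expected_heterozygosity(cnt), 3)
    oracle <- oracle_reconstruct(n, ho, he)
    got <- tryCatch(reconstruct_counts(n, ho, he), error = function(e) e)
    if (inherits(got, "error")) {
      # only acceptable failure: the printed pair is genuinely ambiguous
      expect_match(conditionMessage(got), "ambiguous")
      canon <- unique(lapply(oracle, function(x)
        if (x[3] > x[1]) rev(x) else x))
      expect_gt(length(canon), 1L)
    } else {
      expect_equal(unname(got), cnt)
    }
  }
})

test_that("B-Y thresholds follow the harmonic-sum formula", {
  expect_equal(by_threshold(0.05, 1), 0.05)
  expect_equal(by_threshold(0.05, 3), 0.05 / (1 + 1 / 2 + 1 / 3))
  expect_equal(round(by_threshold(0.05, 55), 4), 0.0109)
  expect_error(by_threshold(0.05, 0), "at least 1")
})

test_that("survey site summary reproduces the printed per-site statistics", {
  pops <- survey_pops()
  s <- site_summary(pops[as.character(1:16)])
  tab <- pgfar_survey()[1:16, ]
  expect_equal(round(s$H_O, 3), tab$H_O)
  expect_true(all(abs(round(s$H_E[!s$monomorphic], 3) -
                      tab$H_E[!is.na(tab$H_E)]) <= 0.001 + 1e-9))
  expect_true(all(is.na(s$p_hwe[s$monomorphic])))
  # printed exact p-values (enumeration-reproducible rows)
  expect_equal(round(s$p_hwe[s$site_id == "6"], 3), 0.126)
  expect_equal(round(s$p_hwe[s$site_id == "12"], 3), 0.082)
  expect_equal(round(s$p_hwe[s$site_id == "10"], 3), 0.152)
  expect_equal(s$p_hwe[s$site_id == "13"], 1.000)
})

test_that("regional means match the printed sympatric-zone summary", {
  pops <- survey_pops()
  s <- site_summary(pops[as.character(1:16)])
  east <- heterozygosity_summary(s, as.character(6:16))
  expect_equal(round(east$mean, 3), 0.154)
  expect_equal(round(east$sd, 3), 0.110)
  expect_equal(east$n_sites, 11L)
  one <- heterozygosity_summary(s, "8")
  expect_true(is.na(one$sd))
  mono <- heterozygosity_summary(s, as.character(1:5))
  expect_equal(mono$mean, 0)
  expect_equal(mono$sd, 0)
})
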