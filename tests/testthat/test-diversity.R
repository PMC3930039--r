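test_that("pairwise distance matches hand-computed examples", {
  expect_equal(mean_pairwise_distance(aligned_panel(c("ACGT", "ACGT")))$d, 0)
  expect_equal(mean_pairwise_distance(aligned_panel(c("ACGT", "ACGA")))$d,
               0.25)
  expect_error(mean_pairwise_distance(aligned_panel("ACGT")),
               "insufficient|one sequence")
  # pairwise deletion: the gapped column is excluded for the gapped pair
  p <- aligned_panel(c("ACG-", "ACGA", "ACGA"))
  pc <- mean_pairwise_distance(p)
  expect_equal(pc$d, 0)
})

test_that("pi equals the six-pair hand enumeration and is reorder-invariant", {
  p <- aligned_panel(c("AA", "AA", "AT", "TT"))
  expect_equal(nucleotide_diversity(p), 3.5 / 6, tolerance = 1e-12)
  perm <- aligned_panel(c("TT", "AA", "AT", "AA"))
  expect_equal(nucleotide_diversity(perm), nucleotide_diversity(p))
  expect_equal(nucleotide_diversity(aligned_panel(c("ACGT", "ACGT"))), 0)
  expect_error(nucleotide_diversity(p, integer(0)), "empty")
})

test_that("segregating sites ignore gaps and ambiguity", {
  expect_equal(segregating_sites(aligned_panel(c("ACGT", "ACGA", "TCGA"))), 2L)
  expect_equal(segregating_sites(aligned_panel(c("AAA", "A-A", "AAA"))), 0L)
  expect_equal(segregating_sites(aligned_panel(c("ANA", "ATA", "ATA"))), 0L)
  expect_equal(segregating_sites(aligned_panel(c("AAAA", "AAAA"))), 0L)
})

test_that("Tajima's D agrees with a brute-force oracle on small panels", {
  expect_true(is.na(tajimas_d(aligned_panel(c("ACGT", "ACGT", "ACGT")))))
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:8, 1)
    L <- sample(20:60, 1)
    # low-diversity panels: mutate a few sites off a common ancestor
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- anc
      hit <- sample(L, sample(0:5, 1))
      for (h in hit) s[h] <- sample(setdiff(c("A", "C", "G", "T"), s[h]), 1)
      paste(s, collapse = "")
    }, character(1))
    expect_equal(tajimas_d(aligned_panel(seqs)), oracle_tajimas_d(seqs),
                 tolerance = 1e-10)
  }
})

test_that("neutral coalescent panels give near-zero D and few |D| > 2 flags", {
  d <- vapply(1:150, function(s)
    tajimas_d(simulate_neutral_panel(10, length = 300, theta = 4,
                                     seed = 1000 + s)),
    numeric(1))
  d <- d[!is.na(d)]
  expect_gt(length(d), 140)
  expect_lt(abs(mean(d)), 0.2)          # E[D] ~ 0 under neutrality
  expect_lt(mean(abs(d) > 2), 0.10)     # extreme windows are rare
})

test_that("window coordinates follow the 100/25 scheme and partitions sum", {
  p <- random_panel(6, 150, seed = 42)
  sc <- sliding_window_scan(p, width = 100, step = 25)
  expect_equal(sc$start, c(1L, 26L, 51L))
  expect_equal(sc$end, c(100L, 125L, 150L))
  expect_false(any(sc$truncated))
  # leftover columns produce one marked truncated terminal window
  p2 <- random_panel(6, 160, seed = 43)
  sc2 <- sliding_window_scan(p2, width = 100, step = 25)
  expect_equal(tail(sc2$end, 1), 160L)
  expect_true(tail(sc2$truncated, 1))
  expect_false(any(head(sc2$truncated, -1)))
  # step = width partitions columns exactly once; S adds up
  p3 <- random_panel(5, 200, seed = 44)
  sc3 <- sliding_window_scan(p3, width = 50, step = 50)
  expect_equal(sum(sc3$S), segregating_sites(p3))
  expect_error(sliding_window_scan(p, width = 0), "positive")
  expect_error(sliding_window_scan(p, width = 200), "exceeds")
})

test_that("flagged windows localize a planted divergent block", {
  sim <- simulate_panel(n_e = 10, n_z = 10, length = 600,
                        divergent_block = list(start = 301, end = 420,
                                               density = 0.25),
                        seed = 7)
  sc <- sliding_window_scan(sim$panel, width = 100, step = 25,
                            threshold = 2)
  reg <- divergent_regions(sc)
  expect_equal(nrow(reg), 1L)
  expect_lte(reg$start, 420)
  expect_gte(reg$end, 301)
  # flagged region covers the block core
  expect_lte(reg$start, 330)
  expect_gte(reg$end, 400)
})

test_that("fixed differences apply the strict two-sided definition", {
  # identical groups: nothing fixed
  p0 <- aligned_panel(rep("ACGT", 4), groups = c("E", "E", "Z", "Z"))
  expect_equal(nrow(fixed_differences(p0)), 0L)
  # polymorphic in Z: not reported
  p1 <- aligned_panel(c("AA", "AA", "AA", "GA"), groups = c("E", "E", "Z", "Z"))
  expect_equal(nrow(fixed_differences(p1)), 0L)
  # gap in a labelled sequence excludes the column
  p2 <- aligned_panel(c("AC", "AC", "G-", "GC"), groups = c("E", "E", "Z", "Z"))
  fd2 <- fixed_differences(p2)
  expect_equal(fd2$column, 1L)
  expect_equal(fd2$allele_e, "A")
  expect_equal(fd2$allele_z, "G")
  expect_error(fixed_differences(
    aligned_panel(c("AA", "AA"), groups = c("E", "E"))), "labelled Z")
})

test_that("codon annotation distinguishes synonymous changes", {
  # frame starts at 1; GAA->GAG (Glu/Glu) synonymous at codon pos 3,
  # CAA->GAA (Gln/Glu) nonsynonymous at codon pos 1
  p <- aligned_panel(c("GAACAA", "GAACAA", "GAGGAA", "GAGGAA"),
                     groups = c("E", "E", "Z", "Z"))
  fd <- fixed_differences(p, cds = c(1, 6))
  expect_equal(fd$position, c(3L, 4L))
  expect_equal(fd$codon_position, c(3L, 1L))
  expect_equal(fd$synonymous, c(TRUE, FALSE))
})

test_that("diversity partitions report within-E, within-Z and between", {
  sim <- simulate_panel(n_e = 6, n_z = 6, length = 400,
                        within_diversity = 0.01, n_plain_snps = 4, seed = 3)
  parts <- distance_partitions(sim$panel)
  expect_equal(parts$partition, c("within_E", "within_Z", "between"))
  # between-group distance dominates the within-group ones
  expect_gt(parts$d[3], parts$d[1])
  expect_gt(parts$d[3], parts$d[2])
  # within-group d tracks the generating target (loose, stochastic)
  expect_lt(abs(parts$d[1] - 0.01), 0.006)
})
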