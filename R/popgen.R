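#' Genotype counts for one collection site
#'
#' Because the three diagnostic SNP markers are in perfect linkage
#' disequilibrium in the survey data (identical genotypes across markers at
#' every site), the package treats them as a single effective biallelic
#' locus by default; per-marker analyses just build one sample per marker.
#'
#' @param site_id site identifier.
#' @param n_zz,n_ez,n_ee genotype counts (pgfar-z/z homozygote,
#'   heterozygote, pgfar-e/e homozygote).
#' @param region optional region label (e.g. `"Midwest"`, `"EastCoast"`).
#' @param n_male,n_female optional sex split of the total.
#' @return object of class `population_sample`.
#' @export
population_sample <- function(site_id, n_zz, n_ez, n_ee, region = NA,
                              n_male = NA, n_female = NA) {
  counts <- c(n_zz, n_ez, n_ee)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  if (sum(counts) < 1L) stop("sample must contain at least one individual")
  structure(list(site_id = as.character(site_id), region = region,
                 n_zz = as.integer(n_zz), n_ez = as.integer(n_ez),
                 n_ee = as.integer(n_ee),
                 n_male = n_male, n_female = n_female),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("%s: n = %d (zz %d / ez %d / ee %d), p_e = %.4f\n",
              x$site_id, sample_size(x), x$n_zz, x$n_ez, x$n_ee,
              allele_freq_e(x)))
  invisible(x)
}

as_pop <- function(x) {
  if (inherits(x, "population_sample")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(population_sample("pop", x[1L], x[2L], x[3L]))
  stop("expected a population_sample or a (n_zz, n_ez, n_ee) triple")
}

sample_size <- function(pop) pop$n_zz + pop$n_ez + pop$n_ee
allele_freq_e <- function(pop) (2 * pop$n_ee + pop$n_ez) / (2 * sample_size(pop))
is_monomorphic <- function(pop) {
  p <- allele_freq_e(pop)
  p == 0 || p == 1
}

#' Observed heterozygosity
#'
#' The heterozygote frequency `n_ez / n`; in a hybrid zone between two
#' pheromone races this doubles as the per-site hybridization frequency.
#'
#' @param pop a [population_sample()] or `(n_zz, n_ez, n_ee)` triple.
#' @return numeric H_O.
#' @export
observed_heterozygosity <- function(pop) {
  pop <- as_pop(pop)
  n <- sample_size(pop)
  if (n < 1L) stop("empty sample")
  pop$n_ez / n
}

#' Nei unbiased expected heterozygosity
#'
#' For a biallelic locus, `H_E = 2n/(2n - 1) * 2 p q` with allele
#' frequencies from the genotype counts; `(2n-1)/(2n) * H_E` equals `2pq`
#' exactly.
#'
#' @inheritParams observed_heterozygosity
#' @return numeric H_E.
#' @export
unbiased_expected_heterozygosity <- function(pop) {
  pop <- as_pop(pop)
  n <- sample_size(pop)
  if (n < 2L) stop("need at least 2 individuals")
  p <- allele_freq_e(pop)
  (2 * n) / (2 * n - 1) * 2 * p * (1 - p)
}

# log-probabilities of every heterozygote count compatible with the
# observed allele counts, under the exact conditional HWE distribution
hwe_distribution <- function(pop) {
  n <- sample_size(pop)
  ne <- 2 * pop$n_ee + pop$n_ez
  nz <- 2 * pop$n_zz + pop$n_ez
  m <- min(ne, nz)
  hets <- seq.int(m %% 2L, m, by = 2L)
  logp <- vapply(hets, function(h) {
    nzz <- (nz - h) / 2
    nee <- (ne - h) / 2
    lfactorial(n) - lfactorial(nzz) - lfactorial(h) - lfactorial(nee) +
      h * log(2) + lfactorial(ne) + lfactorial(nz) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp)
  stopifnot(abs(sum(prob) - 1) < 1e-9)   # enumeration must be exhaustive
  data.frame(n_ez = hets, prob = prob)
}

#' Exact conditional Hardy-Weinberg test by enumeration
#'
#' Enumerates every genotype configuration compatible with the observed
#' allele counts; the conditional probability of a configuration with `h`
#' heterozygotes is `n! / (n_zz! h! n_ee!) * 2^h * n_e! n_z! / (2n)!`. The
#' p-value sums the probabilities of all configurations no more probable
#' than the observed one, the observed configuration (and exact ties)
#' included. Monomorphic samples admit a single configuration and return
#' p = 1.
#'
#' @inheritParams observed_heterozygosity
#' @return list of class `hwe_result` with `p`, `method`,
#'   `observed_config`, and the full conditional `distribution`.
#' @export
hwe_exact <- function(pop) {
  pop <- as_pop(pop)
  dist <- hwe_distribution(pop)
  p_obs <- dist$prob[dist$n_ez == pop$n_ez]
  p <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)])
  structure(list(p = min(p, 1), method = "enumeration",
                 observed_config = c(n_zz = pop$n_zz, n_ez = pop$n_ez,
                                     n_ee = pop$n_ee),
                 distribution = dist),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("exact HWE test (%s): config (%d, %d, %d), p = %.4g\n",
              x$method, x$observed_config[1L], x$observed_config[2L],
              x$observed_config[3L], x$p))
  invisible(x)
}

#' Markov-chain exact Hardy-Weinberg test
#'
#' Metropolis random walk over the heterozygote counts compatible with the
#' observed allele counts, proposing moves of +/- 2 heterozygotes and
#' accepting with the conditional probability ratio. The estimated p-value
#' is the post-burn-in fraction of visited configurations no more probable
#' than the observed one; it converges to [hwe_exact()]'s p as the chain
#' lengthens. Provided to mirror the Markov-chain testing tradition of the
#' field's software and as the extension point for multi-allelic loci; the
#' enumeration test is the package default.
#'
#' @inheritParams observed_heterozygosity
#' @param steps chain length after burn-in.
#' @param burnin discarded initial steps.
#' @param seed integer seed; same seed, same estimate.
#' @return list of class `hwe_result` with a Monte-Carlo standard error
#'   `se`.
#' @export
hwe_markov_chain <- function(pop, steps = 1e5, burnin = 1000, seed = 1L) {
  pop <- as_pop(pop)
  if (steps <= burnin) stop("steps must exceed burnin")
  dist <- hwe_distribution(pop)
  k <- nrow(dist)
  obs_idx <- match(pop$n_ez, dist$n_ez)
  extreme <- dist$prob <= dist$prob[obs_idx] * (1 + 1e-12)
  if (k == 1L) {   # monomorphic or single-configuration sample
    return(structure(list(p = 1, se = 0, method = "markov_chain",
                          observed_config = c(n_zz = pop$n_zz,
                                              n_ez = pop$n_ez,
                                              n_ee = pop$n_ee),
                          distribution = dist),
                     class = "hwe_result"))
  }
  hits <- 0L
  with_seed(seed, {
    state <- obs_idx
    prop <- sample(c(-1L, 1L), steps + burnin, replace = TRUE)
    u <- stats::runif(steps + burnin)
    for (t in seq_len(steps + burnin)) {
      cand <- state + prop[t]
      if (cand >= 1L && cand <= k &&
          u[t] < dist$prob[cand] / dist$prob[state])
        state <- cand
      if (t > burnin && extreme[state]) hits <- hits + 1L
    }
  })
  p <- hits / steps
  structure(list(p = p, se = sqrt(p * (1 - p) / steps),
                 method = "markov_chain",
                 observed_config = c(n_zz = pop$n_zz, n_ez = pop$n_ez,
                                     n_ee = pop$n_ee),
                 distribution = dist),
            class = "hwe_result")
}

#' Reconstruct genotype counts from printed summary statistics
#'
#' Inverts a site row of a published summary table: given the sample size
#' and the 3-decimal printed H_O and unbiased H_E, finds the unique
#' nonnegative integer triple `(n_zz, n_ez, n_ee)` (up to allele-label
#' swap) with `n_ez = round(H_O * n)` and matching H_E. The H_E match uses
#' a tolerance of `he_tol` (default 0.0015) rather than strict 3-decimal
#' equality, accommodating one-off rounding in printed tables. Monomorphic
#' rows (`H_O = 0`, no H_E) return `(n, 0, 0)`. The returned orientation
#' has `n_ee <= n_zz` (the pgfar-e allele is the minor allele throughout
#' the sympatric survey).
#'
#' @param n total individuals.
#' @param H_O printed observed heterozygosity (3 decimals).
#' @param H_E printed unbiased expected heterozygosity, or `NA` for a
#'   monomorphic site.
#' @param he_tol tolerance on the H_E match.
#' @return integer vector `c(n_zz, n_ez, n_ee)`.
#' @export
reconstruct_counts <- function(n, H_O, H_E = NA, he_tol = 0.0015) {
  n <- as.integer(n)
  n_ez <- as.integer(round(H_O * n))
  if (round(n_ez / n, 3) != round(H_O, 3))
    stop("no consistent counts: H_O = ", H_O,
         " is not a multiple of 1/", n, " to 3 decimals")
  if (is.na(H_E)) {
    if (n_ez != 0L) stop("no consistent counts: monomorphic site with H_O > 0")
    return(c(n_zz = n, n_ez = 0L, n_ee = 0L))
  }
  cand <- list()
  for (n_ee in 0:(n - n_ez)) {
    n_zz <- n - n_ez - n_ee
    he <- unbiased_expected_heterozygosity(c(n_zz, n_ez, n_ee))
    if (abs(he - H_E) <= he_tol)
      cand[[length(cand) + 1L]] <- c(n_zz = n_zz, n_ez = n_ez, n_ee = n_ee)
  }
  if (!length(cand)) stop("no consistent counts for n = ", n, ", H_O = ",
                          H_O, ", H_E = ", H_E)
  # allele-label swaps (a,b,c) <-> (c,b,a) are the same solution
  canon <- lapply(cand, function(x)
    if (x[3L] > x[1L]) c(n_zz = unname(x[3L]), n_ez = unname(x[2L]),
                         n_ee = unname(x[1L])) else x)
  uniq <- unique(canon)
  if (length(uniq) > 1L)
    stop("ambiguous: ", length(uniq), " distinct count triples match")
  uniq[[1L]]
}

#' Benjamini-Yekutieli significance threshold
#'
#' The modified alpha for m dependent tests: `alpha / sum(1/i, i = 1..m)`.
#'
#' @param alpha nominal significance level.
#' @param m number of tests.
#' @return adjusted alpha.
#' @export
by_threshold <- function(alpha, m) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1")
  alpha / sum(1 / seq_len(m))
}

#' Per-site heterozygosity and HWE summary
#'
#' One row per site with H_O, unbiased H_E and the exact HWE p-value;
#' monomorphic sites are retained with H_E = 0 and the p-value reported as
#' `NA` (printed "Monomorphic"), matching the convention of excluding them
#' from HWE testing.
#'
#' @param pops list of [population_sample()] objects.
#' @return data.frame with `site_id`, `region`, `n`, `n_zz`, `n_ez`,
#'   `n_ee`, `p_e`, `H_O`, `H_E`, `p_hwe`, `monomorphic`.
#' @export
site_summary <- function(pops) {
  out <- do.call(rbind, lapply(pops, function(pop) {
    mono <- is_monomorphic(pop)
    data.frame(site_id = pop$site_id,
               region = if (is.na(pop$region)) NA_character_
                        else as.character(pop$region),
               n = sample_size(pop), n_zz = pop$n_zz, n_ez = pop$n_ez,
               n_ee = pop$n_ee, p_e = allele_freq_e(pop),
               H_O = observed_heterozygosity(pop),
               H_E = if (sample_size(pop) >= 2L)
                 unbiased_expected_heterozygosity(pop) else NA_real_,
               p_hwe = if (mono) NA_real_ else hwe_exact(pop)$p,
               monomorphic = mono, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Unweighted regional mean and SD of per-site heterozygosity
#'
#' @param summary output of [site_summary()].
#' @param sites site ids to include; default all.
#' @param statistic column to summarise (default `"H_O"`).
#' @return list with `mean`, `sd` (sample SD, `NA` for a single site) and
#'   `n_sites`.
#' @export
heterozygosity_summary <- function(summary, sites = summary$site_id,
                                   statistic = "H_O") {
  v <- summary[[statistic]][summary$site_id %in% sites]
  list(mean = mean(v), sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
       n_sites = length(v))
}
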