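# Evaluate code under a fixed seed without disturbing the caller's RNG
# stream. All generators are pure functions of their arguments (seed
# included); no global state leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  code
}

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

concrete_site <- function(recognition) {
  # first base of each IUPAC code: a concrete instance of the site
  vapply(strsplit(recognition, "")[[1L]],
         function(ch) substr(Biostrings::IUPAC_CODE_MAP[[ch]], 1L, 1L),
         character(1))
}

covering_site_exists <- function(seqc, pos, enzymes) {
  for (enz in enzymes) {
    k <- nchar(enz$recognition)
    lo <- max(1L, pos - k + 1L); hi <- min(nchar(seqc), pos + k - 1L)
    starts <- iupac_match_starts(enz$recognition, substr(seqc, lo, hi))
    starts <- starts + lo - 1L
    if (any(starts <= pos & starts + k - 1L >= pos)) return(TRUE)
  }
  FALSE
}

#' Simulate a group-labelled alignment panel with planted structure
#'
#' Generates a random ancestral coding-like sequence and plants, with full
#' ground truth: diagnostic SNPs whose one allele completes a restriction
#' site (one per supplied enzyme, flanked by monomorphic context so the
#' candidate screen can fire), plain fixed inter-group differences outside
#' any restriction context, an optional block of dense fixed differences
#' (balanced divergence, for sliding-window calibration), and independent
#' within-group mutation noise at rate `within_diversity / 2` per site so
#' the expected within-group pairwise distance matches the target.
#'
#' @param n_e,n_z sequences per race.
#' @param length alignment columns.
#' @param within_diversity target within-group mean pairwise distance
#'   (scalar, applied to both groups).
#' @param diagnostic_enzymes list of [enzyme()] objects; one diagnostic SNP
#'   is planted per enzyme (the cut allele is assigned to the E group).
#' @param n_plain_snps fixed inter-group SNPs planted outside restriction
#'   contexts.
#' @param divergent_block optional `list(start, end, density)`: columns of
#'   the block receive fixed inter-group differences at the given density.
#' @param seed integer seed; same spec + seed, same panel.
#' @return list with `panel` (an [aligned_panel()]) and `truth` (lists
#'   `diagnostic`, `plain`, `block` describing every planted feature).
#' @export
simulate_panel <- function(n_e = 5L, n_z = 5L, length = 600L,
                           within_diversity = 0,
                           diagnostic_enzymes = list(),
                           n_plain_snps = 0L, divergent_block = NULL,
                           seed = 1L) {
  n_diag <- length(diagnostic_enzymes)
  with_seed(seed, {
    anc <- rand_bases(length)
    protected <- logical(length)
    all_enz <- if (n_diag) diagnostic_enzymes else default_enzymes()

    # space planted SNPs evenly along the sequence, away from the block
    n_snp <- n_diag + n_plain_snps
    slots <- if (n_snp) round(length * seq_len(n_snp) / (n_snp + 1L)) else integer(0)
    if (!is.null(divergent_block)) {
      inblk <- slots >= divergent_block$start - 8L &
               slots <= divergent_block$end + 8L
      if (any(inblk)) stop("contradictory spec: planted SNP collides with block")
    }
    if (anyDuplicated(slots)) stop("contradictory spec: planted SNPs collide")

    diag_truth <- list()
    for (i in seq_len(n_diag)) {
      enz <- diagnostic_enzymes[[i]]
      k <- nchar(enz$recognition)
      site <- concrete_site(enz$recognition)
      pos <- slots[i]
      s <- pos                       # SNP at the first base of the site
      if (s + k - 1L + (k - 1L) > length || s - (k - 1L) < 1L)
        stop("length too short for diagnostic footprint")
      ok <- FALSE
      for (flank in c("C", "A", "G", "T")) {
        anc[(s - k + 1L):(s - 1L)] <- flank
        anc[(s + k):(s + 2L * k - 2L)] <- flank
        anc[s:(s + k - 1L)] <- site
        alts <- setdiff(BASES, site[1L])
        for (alt in alts) {
          test <- anc; test[s] <- alt
          cut_seq <- paste(anc, collapse = "")
          alt_seq <- paste(test, collapse = "")
          n_cut <- sum(vapply(all_enz, function(e2)
            covering_site_exists(cut_seq, s, list(e2)), logical(1)))
          if (n_cut == 1L && !covering_site_exists(alt_seq, s, all_enz)) {
            diag_truth[[i]] <- data.frame(
              position = s, enzyme = enz$name, allele_e = site[1L],
              allele_z = alt, allele_cut = site[1L], race_cut = "pgfar-e",
              stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not plant a clean diagnostic site for ", enz$name)
      protected[(s - k + 1L):(s + 2L * k - 2L)] <- TRUE
    }

    plain_truth <- list()
    for (j in seq_len(n_plain_snps)) {
      pos <- slots[n_diag + j]
      ok <- FALSE
      for (flank in c("C", "A", "G", "T")) {
        anc[max(1L, pos - 3L):(pos - 1L)] <- flank
        anc[(pos + 1L):min(length, pos + 3L)] <- flank
        combos <- utils::combn(BASES, 2L)
        for (cb in seq_len(ncol(combos))) {
          a_e <- combos[1L, cb]; a_z <- combos[2L, cb]
          t1 <- anc; t1[pos] <- a_e
          t2 <- anc; t2[pos] <- a_z
          if (!covering_site_exists(paste(t1, collapse = ""), pos, all_enz) &&
              !covering_site_exists(paste(t2, collapse = ""), pos, all_enz)) {
            plain_truth[[j]] <- data.frame(position = pos, allele_e = a_e,
                                           allele_z = a_z,
                                           stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not plant a plain SNP outside restriction context")
      protected[max(1L, pos - 3L):min(length, pos + 3L)] <- TRUE
    }

    block_cols <- integer(0)
    if (!is.null(divergent_block)) {
      cand <- divergent_block$start:divergent_block$end
      cand <- cand[!protected[cand]]
      block_cols <- cand[stats::runif(length(cand)) < divergent_block$density]
      protected[block_cols] <- TRUE
    }

    seq_e <- anc; seq_z <- anc
    dt <- do.call(rbind, diag_truth)
    pt <- do.call(rbind, plain_truth)
    if (!is.null(dt)) {
      seq_e[dt$position] <- dt$allele_e
      seq_z[dt$position] <- dt$allele_z
    }
    if (!is.null(pt)) {
      seq_e[pt$position] <- pt$allele_e
      seq_z[pt$position] <- pt$allele_z
    }
    for (cl in block_cols)
      seq_z[cl] <- sample(setdiff(BASES, seq_e[cl]), 1L)

    noisy <- function(base_seq, n) {
      m <- within_diversity / 2
      do.call(rbind, lapply(seq_len(n), function(i) {
        s <- base_seq
        if (m > 0) {
          hit <- which(stats::runif(length) < m & !protected)
          for (cl in hit) s[cl] <- sample(setdiff(BASES, s[cl]), 1L)
        }
        s
      }))
    }
    mat <- rbind(noisy(seq_e, n_e), noisy(seq_z, n_z))
    seqs <- apply(mat, 1L, paste, collapse = "")
    panel <- aligned_panel(seqs,
                           groups = c(rep("E", n_e), rep("Z", n_z)),
                           ids = c(paste0("E", seq_len(n_e)),
                                   paste0("Z", seq_len(n_z))))
    list(panel = panel,
         truth = list(diagnostic = dt, plain = pt,
                      block = if (length(block_cols))
                        list(start = divergent_block$start,
                             end = divergent_block$end,
                             columns = sort(block_cols)) else NULL))
  })
}

#' Simulate a neutral panmictic panel under the coalescent
#'
#' Standard neutral coalescent for a panmictic sample: exponential waiting
#' times between coalescences, Poisson mutations on branches at rate
#' `theta / 2` per lineage per unit (2N generations) of time, each mutation
#' at a distinct column (infinite-sites on a finite column set).
#' `theta` is the expected number of pairwise differences over the whole
#' panel. Used to calibrate the null behaviour of Tajima's D, which the
#' star-shaped mutation sprinkling of [simulate_panel()] cannot emulate.
#'
#' @param n sequences.
#' @param length alignment columns.
#' @param theta population-scaled mutation rate for the whole locus.
#' @param seed integer seed.
#' @return an [aligned_panel()] (all records unlabeled).
#' @export
simulate_neutral_panel <- function(n, length = 500L, theta = 5, seed = 1L) {
  with_seed(seed, {
    sets <- as.list(seq_len(n))
    blen <- numeric(n)
    branches <- list()
    while (length(sets) > 1L) {
      k <- length(sets)
      dt <- stats::rexp(1L, k * (k - 1) / 2)
      blen <- blen + dt
      pair <- sample(k, 2L)
      for (p in pair)
        branches[[length(branches) + 1L]] <-
          list(len = blen[p], tips = sets[[p]])
      sets[[pair[1L]]] <- c(sets[[pair[1L]]], sets[[pair[2L]]])
      blen[pair[1L]] <- 0
      sets[[pair[2L]]] <- NULL
      blen <- blen[-pair[2L]]
    }
    anc <- rand_bases(length)
    mat <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
    free <- sample.int(length)
    used <- 0L
    for (br in branches) {
      nm <- stats::rpois(1L, br$len * theta / 2)
      nm <- min(nm, length(free) - used)
      if (nm < 1L) next
      cols <- free[used + seq_len(nm)]
      used <- used + nm
      for (cl in cols)
        mat[br$tips, cl] <- sample(setdiff(BASES, anc[cl]), 1L)
    }
    aligned_panel(apply(mat, 1L, paste, collapse = ""),
                  ids = paste0("seq", seq_len(n)))
  })
}

#' Simulate genotype counts for one population
#'
#' Genotypes are drawn multinomially from `(q^2 + Fpq, 2pq(1 - F),
#' p^2 + Fpq)` for pgfar-e frequency `p = p_e` and inbreeding coefficient
#' `F`, or, when `admixture` is given, from an equal-weight two-deme
#' mixture with per-deme Hardy-Weinberg proportions (a Wahlund heterozygote
#' deficit then emerges without any explicit F).
#'
#' @param n individuals.
#' @param p_e pgfar-e allele frequency.
#' @param f inbreeding coefficient in `[-1, 1]`; probabilities must remain
#'   nonnegative.
#' @param admixture optional `list(p = c(p1, p2), weight)`: each individual
#'   comes from deme 1 with probability `weight`, deme 2 otherwise.
#' @param site_id,region labels for the resulting sample.
#' @param seed integer seed.
#' @return list with `sample` (a [population_sample()]) and `genotypes`
#'   (character vector of `"zz"`/`"ez"`/`"ee"` per individual).
#' @export
simulate_population <- function(n, p_e, f = 0, admixture = NULL,
                                site_id = "sim", region = NA, seed = 1L) {
  with_seed(seed, {
    if (!is.null(admixture)) {
      deme <- ifelse(stats::runif(n) < admixture$weight, 1L, 2L)
      p <- admixture$p[deme]
      g1 <- stats::rbinom(n, 1L, p)
      g2 <- stats::rbinom(n, 1L, p)
      geno <- c("zz", "ez", "ee")[g1 + g2 + 1L]
    } else {
      p <- p_e; q <- 1 - p_e
      probs <- c(zz = q^2 + f * p * q, ez = 2 * p * q * (1 - f),
                 ee = p^2 + f * p * q)
      if (any(probs < -1e-12))
        stop("negative genotype probability under F = ", f)
      probs <- pmax(probs, 0)
      geno <- sample(c("zz", "ez", "ee"), n, replace = TRUE, prob = probs)
    }
    list(sample = population_sample(site_id, sum(geno == "zz"),
                                    sum(geno == "ez"), sum(geno == "ee"),
                                    region = region),
         genotypes = geno)
  })
}

rtrunc_norm <- function(n, mean, sd, lower = 0, upper = 100) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate GC pheromone phenotypes from genotypes
#'
#' %E11-14:OAc values are drawn per genotype class from normal
#' distributions truncated to `[0, 100]` (inverse-CDF sampling, so the
#' draws are proper truncated normals, not clamped); a fraction
#' `unresolved_rate` of records is set to unresolved (`NA`), emulating
#' glands with insufficient pheromone for detection.
#'
#' @param genotypes character vector of `"EE"`/`"EZ"`/`"ZZ"` (lowercase
#'   accepted).
#' @param class_means,class_sds named numeric vectors (`EE`, `EZ`, `ZZ`)
#'   of the class-conditional %E mean and SD. Defaults are the published
#'   class-conditional estimates (98.02 +/- 4.24, 67.58 +/- 8.92,
#'   2.74 +/- 6.24).
#' @param unresolved_rate fraction of unresolved records.
#' @param seed integer seed.
#' @return data.frame with `individual_id`, `genotype`, `pct_e`,
#'   `pheno_class`.
#' @export
simulate_phenotypes <- function(genotypes,
                                class_means = c(EE = 98.02, EZ = 67.58,
                                                ZZ = 2.74),
                                class_sds = c(EE = 4.24, EZ = 8.92,
                                              ZZ = 6.24),
                                unresolved_rate = 0, seed = 1L) {
  genotypes <- toupper(as.character(genotypes))
  if (!all(genotypes %in% c("EE", "EZ", "ZZ")))
    stop("genotypes must be EE/EZ/ZZ")
  with_seed(seed, {
    pct <- numeric(length(genotypes))
    for (g in unique(genotypes)) {
      sel <- genotypes == g
      pct[sel] <- rtrunc_norm(sum(sel), class_means[[g]], class_sds[[g]])
    }
    if (unresolved_rate > 0)
      pct[stats::runif(length(pct)) < unresolved_rate] <- NA_real_
    data.frame(individual_id = paste0("F", seq_along(genotypes)),
               genotype = genotypes, pct_e = pct,
               pheno_class = classify_phenotype(pct))
  })
}

#' Simulate observed fragment patterns for a genotyped cohort
#'
#' Noise-free band patterns per marker from each individual's true
#' genotype, with an optional planted discordance: a fraction
#' `discordance_rate` of individuals has one randomly chosen marker's
#' pattern replaced by a different genotype's pattern.
#'
#' @param genotypes character vector of true genotypes (`"EE"`/`"EZ"`/
#'   `"ZZ"`).
#' @param markers named list of [build_marker()] results.
#' @param discordance_rate fraction of individuals made discordant.
#' @param seed integer seed.
#' @return named list (by individual) of named lists (by marker) of
#'   fragment-length vectors, as consumed by [genotype_cohort()].
#' @export
simulate_marker_patterns <- function(genotypes, markers,
                                     discordance_rate = 0, seed = 1L) {
  genotypes <- toupper(as.character(genotypes))
  pattern_of <- function(marker, g)
    switch(g, EE = marker$pattern_e, ZZ = marker$pattern_z,
           EZ = marker$bands_het)
  with_seed(seed, {
    out <- lapply(seq_along(genotypes), function(i) {
      pats <- lapply(markers, pattern_of, g = genotypes[i])
      if (discordance_rate > 0 && stats::runif(1L) < discordance_rate) {
        mk <- sample(length(markers), 1L)
        wrong <- sample(setdiff(c("EE", "EZ", "ZZ"), genotypes[i]), 1L)
        pats[[mk]] <- pattern_of(markers[[mk]], wrong)
      }
      pats
    })
    names(out) <- paste0("ind", seq_along(genotypes))
    out
  })
}
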