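# Individual-level allele table: one row per individual, columns a1/a2 in
# {0,1} with 1 = pgfar-e. Used by the AMOVA and permutation machinery.
pop_to_individuals <- function(pop, group = NA) {
  pop <- as_pop(pop)
  g <- c(rep("zz", pop$n_zz), rep("ez", pop$n_ez), rep("ee", pop$n_ee))
  data.frame(pop = pop$site_id, group = group,
             a1 = ifelse(g == "zz", 0L, 1L),
             a2 = ifelse(g == "ee", 1L, 0L))
}

# Hierarchical AMOVA variance components for diploid data at one biallelic
# locus, three nesting levels (groups / populations / individuals), with the
# within-population variance partitioned between and within individuals.
# Unbalanced-design coefficients follow the standard gene-copy formulation.
amova_components <- function(ind) {
  N <- nrow(ind)
  ind_mean <- (ind$a1 + ind$a2) / 2                # per-individual mean, row order
  pops <- unique(ind$pop)
  grps <- unique(ind$group)
  P <- length(pops); G <- length(grps)
  pop_idx <- match(ind$pop, pops)
  pop_mean <- vapply(seq_len(P),
                     function(p) mean(ind_mean[pop_idx == p]), numeric(1))
  c_pop <- 2 * tabulate(pop_idx, P)                # gene copies per pop
  pop_grp <- vapply(seq_len(P),
                    function(p) ind$group[match(p, pop_idx)], character(1))
  grp_idx_pop <- match(pop_grp, grps)
  c_grp <- vapply(seq_len(G),
                  function(g) sum(c_pop[grp_idx_pop == g]), numeric(1))
  grp_mean <- vapply(seq_len(G), function(g)
    sum(pop_mean[grp_idx_pop == g] * c_pop[grp_idx_pop == g]) /
      c_grp[g], numeric(1))
  C <- 2 * N
  grand <- sum(ind_mean) / N

  ssd_wi <- 0.5 * sum(ind$a1 != ind$a2)            # copies about ind means
  ssd_ai <- sum(2 * (ind_mean - pop_mean[pop_idx])^2)
  ssd_ap <- sum(c_pop * (pop_mean - grp_mean[grp_idx_pop])^2)
  ssd_ag <- sum(c_grp * (grp_mean - grand)^2)

  df <- c(ag = G - 1L, ap = P - G, ai = N - P, wi = N)
  ms <- c(ag = if (df[["ag"]] > 0) ssd_ag / df[["ag"]] else NA_real_,
          ap = if (df[["ap"]] > 0) ssd_ap / df[["ap"]] else NA_real_,
          ai = ssd_ai / df[["ai"]], wi = ssd_wi / df[["wi"]])

  sum_c2_within <- vapply(seq_len(G), function(g) {
    v <- c_pop[grp_idx_pop == g]
    sum(v^2) / sum(v)
  }, numeric(1))
  n1 <- (C - sum(sum_c2_within)) / max(df["ap"], 1L)
  n2 <- (sum(sum_c2_within) - sum(c_pop^2) / C) / max(df["ag"], 1L)
  n3 <- (C - sum(c_grp^2) / C) / max(df["ag"], 1L)

  s4 <- ms[["wi"]]
  s3 <- (ms[["ai"]] - s4) / 2
  s2 <- if (df["ap"] > 0) (ms[["ap"]] - s4 - 2 * s3) / n1 else 0
  s1 <- if (df["ag"] > 0) (ms[["ag"]] - s4 - 2 * s3 - n2 * s2) / n3 else 0
  list(sigma = c(among_groups = unname(s1),
                 among_pops_within_groups = unname(s2),
                 among_individuals_within_pops = unname(s3),
                 within_individuals = unname(s4)),
       ssd = c(ag = ssd_ag, ap = ssd_ap, ai = ssd_ai, wi = ssd_wi),
       df = df, ms = ms)
}

fstats_from_sigma <- function(sigma) {
  s1 <- sigma[1L]; s2 <- sigma[2L]; s3 <- sigma[3L]; s4 <- sigma[4L]
  tot <- s1 + s2 + s3 + s4
  c(F_CT = unname(if (tot != 0) s1 / tot else NA_real_),
    F_SC = unname(if (s2 + s3 + s4 != 0) s2 / (s2 + s3 + s4) else NA_real_),
    F_IS = unname(if (s3 + s4 != 0) s3 / (s3 + s4) else NA_real_),
    F_ST = unname(if (tot != 0) (s1 + s2) / tot else NA_real_))
}

#' Hierarchical F-statistics and AMOVA with permutation tests
#'
#' Weir-Cockerham-style variance components at three nested levels (among
#' regional groups, among populations within groups, within populations,
#' the last partitioned between and within individuals), from genotype
#' counts at one biallelic locus. F-ratios are formed from the component
#' sums: `F_CT` (among groups), `F_SC` (among populations within groups),
#' `F_IS` (inbreeding within populations), `F_ST` (total). Significance is
#' evaluated by seeded permutation, 1000 permutations by default:
#' populations permuted among groups for `F_CT`; individuals permuted among
#' populations within groups for `F_SC`; alleles permuted among individuals
#' within populations for `F_IS` (the within-population Hardy-Weinberg
#' null). Permutation p is `(#\{perm >= obs\} + 1) / (n_perm + 1)`.
#'
#' @param pops list of [population_sample()] objects.
#' @param grouping named character vector mapping site ids to groups; when
#'   `NULL`, each sample's `region` field is used. Whether an intermediate
#'   site belongs to either group is the caller's explicit choice, never a
#'   silent default.
#' @param n_perm permutations per statistic (0 skips testing).
#' @param seed integer seed for the permutation stream.
#' @return list of class `fstat_result`: `F` (the four statistics),
#'   `sigma` (variance components), `p` (permutation p-values), `df`,
#'   `ssd`, `n_perm`.
#' @export
hierarchical_fstats <- function(pops, grouping = NULL, n_perm = 1000,
                                seed = 1L) {
  inds <- do.call(rbind, lapply(pops, function(pop) {
    g <- if (!is.null(grouping)) grouping[[pop$site_id]] else pop$region
    if (is.null(g) || is.na(g)) stop("no group for site ", pop$site_id)
    pop_to_individuals(pop, g)
  }))
  if (length(unique(inds$group)) < 2L) stop("need at least 2 groups")
  comp <- amova_components(inds)
  Fs <- fstats_from_sigma(comp$sigma)
  pvals <- c(F_CT = NA_real_, F_SC = NA_real_, F_IS = NA_real_)
  if (n_perm > 0 && !all(is.na(Fs))) {
    pop_group <- tapply(inds$group, inds$pop, `[`, 1L)
    with_seed(seed, {
      exceed <- c(F_CT = 0L, F_SC = 0L, F_IS = 0L)
      for (b in seq_len(n_perm)) {
        # (a) permute populations among groups
        d <- inds
        pg <- sample(pop_group)
        names(pg) <- names(pop_group)
        d$group <- pg[d$pop]
        f <- fstats_from_sigma(amova_components(d)$sigma)
        if (!is.na(f["F_CT"]) && f["F_CT"] >= Fs["F_CT"])
          exceed["F_CT"] <- exceed["F_CT"] + 1L
        # (b) permute individuals among populations within groups
        d <- inds
        for (g in unique(d$group)) {
          sel <- d$group == g
          d$pop[sel] <- sample(d$pop[sel])
        }
        f <- fstats_from_sigma(amova_components(d)$sigma)
        if (!is.na(f["F_SC"]) && f["F_SC"] >= Fs["F_SC"])
          exceed["F_SC"] <- exceed["F_SC"] + 1L
        # (c) permute alleles among individuals within populations
        d <- inds
        for (p in unique(d$pop)) {
          sel <- which(d$pop == p)
          al <- sample(c(d$a1[sel], d$a2[sel]))
          d$a1[sel] <- al[seq_along(sel)]
          d$a2[sel] <- al[length(sel) + seq_along(sel)]
        }
        f <- fstats_from_sigma(amova_components(d)$sigma)
        if (!is.na(f["F_IS"]) && f["F_IS"] >= Fs["F_IS"])
          exceed["F_IS"] <- exceed["F_IS"] + 1L
      }
      pvals <- (exceed + 1L) / (n_perm + 1L)
    })
  }
  structure(list(F = Fs, sigma = comp$sigma, p = pvals, df = comp$df,
                 ssd = comp$ssd, n_perm = n_perm),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat("hierarchical F-statistics (AMOVA)\n")
  for (nm in names(x$F)) {
    cat(sprintf("  %s = %s", nm, formatC(x$F[[nm]], digits = 4,
                                         format = "f")))
    if (nm %in% names(x$p) && !is.na(x$p[[nm]]))
      cat(sprintf("  (perm p = %.4g)", x$p[[nm]]))
    cat("\n")
  }
  invisible(x)
}

wc_theta_counts <- function(n_i, p_i, h_i) {
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

theta_from_pops <- function(a, b) {
  wc_theta_counts(c(sample_size(a), sample_size(b)),
                  c(allele_freq_e(a), allele_freq_e(b)),
                  c(observed_heterozygosity(a), observed_heterozygosity(b)))
}

#' Pairwise Weir-Cockerham theta between two samples
#'
#' The two-population, single-locus theta of Weir and Cockerham (1984),
#' with significance from permuting whole individuals (genotypes) between
#' the two samples. Theta is undefined (reported `NA`) when both samples
#' are monomorphic for the same allele.
#'
#' The reported `p_perm` is `(#\{perm >= obs\} + 1) / (n_perm + 1)`:
#' tie-inclusive and hence valid but conservative on the discrete null
#' (genotype counts admit only finitely many theta values). With
#' `return_null = TRUE` the permuted theta values are returned so that the
#' tie-randomized p-value — which is exactly uniform under the null — can
#' be formed when calibration is being checked.
#'
#' @param a,b [population_sample()] objects (each n >= 2).
#' @param n_perm number of permutations (default 1000; 0 skips the test).
#' @param seed integer seed.
#' @param return_null also return the vector of permuted theta values.
#' @return list with `theta`, `p_perm`, `n_perm` (and `null` when
#'   requested).
#' @export
pairwise_fst <- function(a, b, n_perm = 1000, seed = 1L,
                         return_null = FALSE) {
  a <- as_pop(a); b <- as_pop(b)
  if (sample_size(a) < 2L || sample_size(b) < 2L)
    stop("both samples need n >= 2")
  theta <- theta_from_pops(a, b)
  if (is.na(theta))
    return(list(theta = NA_real_, p_perm = NA_real_, n_perm = 0L))
  p_perm <- NA_real_
  null <- NULL
  if (n_perm > 0) {
    geno <- c(rep("zz", a$n_zz), rep("ez", a$n_ez), rep("ee", a$n_ee),
              rep("zz", b$n_zz), rep("ez", b$n_ez), rep("ee", b$n_ee))
    na <- sample_size(a)
    with_seed(seed, {
      null <- vapply(seq_len(n_perm), function(k) {
        perm <- sample(geno)
        ga <- perm[seq_len(na)]; gb <- perm[-seq_len(na)]
        pa <- population_sample("a", sum(ga == "zz"), sum(ga == "ez"),
                                sum(ga == "ee"))
        pb <- population_sample("b", sum(gb == "zz"), sum(gb == "ez"),
                                sum(gb == "ee"))
        theta_from_pops(pa, pb)
      }, numeric(1))
      p_perm <- (sum(null >= theta, na.rm = TRUE) + 1L) / (n_perm + 1L)
    })
  }
  out <- list(theta = theta, p_perm = p_perm, n_perm = n_perm)
  if (return_null) out$null <- null
  out
}

#' All pairwise theta estimates among a set of samples
#'
#' @param pops list of [population_sample()] objects.
#' @inheritParams pairwise_fst
#' @return data.frame with `site_a`, `site_b`, `theta`, `p_perm` for every
#'   unordered pair.
#' @export
pairwise_fst_matrix <- function(pops, n_perm = 1000, seed = 1L) {
  ids <- vapply(pops, function(p) p$site_id, character(1))
  pairs <- utils::combn(length(pops), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    fst <- pairwise_fst(pops[[i]], pops[[j]], n_perm = n_perm,
                        seed = seed + k)
    data.frame(site_a = ids[i], site_b = ids[j], theta = fst$theta,
               p_perm = fst$p_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
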