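#' Classify female pheromone phenotype from GC %E
#'
#' Phenotype classes follow the gas-chromatography coding: >= 90% E11-14:OAc
#' is class 1 (E-type), <= 5% is class 3 (Z-type), everything in between is
#' class 2 (hybrid-type). Boundary values belong to classes 1 and 3. An
#' unresolved reading (`NA`, insufficient pheromone for detection) stays
#' `NA` ("U").
#'
#' @param pct_e numeric vector of %E11-14:OAc in `[0, 100]`; `NA` =
#'   unresolved.
#' @return numeric vector of classes 1/2/3, `NA` for unresolved.
#' @export
classify_phenotype <- function(pct_e) {
  pct_e <- as.numeric(pct_e)
  ok <- !is.na(pct_e)
  if (any(pct_e[ok] < 0 | pct_e[ok] > 100))
    stop("pct_e must lie in [0, 100]")
  out <- rep(NA_real_, length(pct_e))
  out[ok] <- ifelse(pct_e[ok] >= 90, 1, ifelse(pct_e[ok] <= 5, 3, 2))
  out
}

#' Pearson product-moment correlation
#'
#' Plain Pearson r with input validation: paired vectors of length >= 3 and
#' nonzero variance in both. The genotype-phenotype association is computed
#' in two codings by [association_summary()]; this is the shared core.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson correlation coefficient.
#' @export
pmcc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("degenerate input")
  stats::cor(x, y)
}

e_allele_count <- function(genotype) {
  unname(c(EE = 2, EZ = 1, ZZ = 0)[as.character(genotype)])
}

#' Genotype-phenotype association, per family and pooled
#'
#' Two codings are reported side by side because the published analysis is
#' ambiguous between them:
#' * `r_allele` — continuous %E against the pgfar-e allele count (0/1/2);
#'   this coding reproduces the printed pooled correlation (~0.97).
#' * `r_class` — phenotype class code (1/2/3) against genotype dosage
#'   (0/0.5/1); exactly 1 in magnitude whenever class and dosage are fully
#'   concordant, since the codes are then affinely related.
#'
#' The class coding flips both axes relative to the continuous coding
#' (class 1 = E-type while dosage 1.0 = ZZ), so the two signed r values
#' agree in sign even though each coding runs opposite to %E; absolute
#' values are reported alongside signed ones so either convention can be
#' read off. Per-family values are combined as an unweighted mean and SD
#' across families.
#'
#' @param pct_e numeric %E values (`NA` = unresolved, excluded).
#' @param genotype character vector of consensus genotypes
#'   (`"EE"`/`"EZ"`/`"ZZ"`; anything else excluded).
#' @param family optional family/replicate labels for per-family rows.
#' @return list with `per_family` (data.frame: family, n, r_allele, r_class,
#'   p_allele), `pooled` (same columns for all records), and `combined`
#'   (mean and SD of per-family r values).
#' @export
association_summary <- function(pct_e, genotype, family = NULL) {
  genotype <- as.character(genotype)
  keep <- !is.na(pct_e) & genotype %in% c("EE", "EZ", "ZZ")
  pct_e <- pct_e[keep]; genotype <- genotype[keep]
  family <- if (is.null(family)) rep("all", sum(keep)) else
    as.character(family)[keep]
  one <- function(p, g, label) {
    x <- e_allele_count(g)
    cls <- classify_phenotype(p)
    dos <- 1 - x / 2
    r_a <- pmcc(p, x)
    r_c <- tryCatch(pmcc(cls, dos), error = function(e) NA_real_)
    pv <- stats::cor.test(p, x)$p.value
    data.frame(family = label, n = length(p), r_allele = r_a,
               abs_r_allele = abs(r_a), r_class = r_c,
               abs_r_class = abs(r_c), p_allele = pv,
               stringsAsFactors = FALSE)
  }
  fams <- sort(unique(family))
  per_family <- do.call(rbind, lapply(fams, function(f)
    one(pct_e[family == f], genotype[family == f], f)))
  pooled <- one(pct_e, genotype, "pooled")
  combined <- data.frame(
    statistic = c("r_allele", "r_class"),
    mean = c(mean(per_family$r_allele), mean(per_family$r_class)),
    sd = c(stats::sd(per_family$r_allele), stats::sd(per_family$r_class)))
  list(per_family = per_family, pooled = pooled, combined = combined)
}

#' Per-genotype summary of %E
#'
#' Sample mean and SD (n-1 denominator) of %E per consensus genotype class,
#' with unresolved records excluded. Empty classes are reported with n = 0
#' and undefined statistics.
#'
#' @inheritParams association_summary
#' @return data.frame with `genotype`, `n`, `mean`, `sd`.
#' @export
genotype_class_summary <- function(pct_e, genotype) {
  genotype <- as.character(genotype)
  keep <- !is.na(pct_e) & genotype %in% c("EE", "EZ", "ZZ")
  pct_e <- pct_e[keep]; genotype <- genotype[keep]
  do.call(rbind, lapply(c("EE", "EZ", "ZZ"), function(g) {
    v <- pct_e[genotype == g]
    data.frame(genotype = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  }))
}

#' Chi-square goodness-of-fit for genotype counts
#'
#' `sum((O - E)^2 / E)` against supplied expected counts, with the p-value
#' from the upper chi-square tail.
#'
#' @param observed,expected numeric count vectors over the same categories.
#' @param df degrees of freedom; default `length(observed) - 1`.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_genotypes <- function(observed, expected,
                                 df = length(observed) - 1L) {
  if (length(observed) != length(expected))
    stop("observed and expected must cover the same categories")
  if (any(expected <= 0)) stop("expected counts must be positive")
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
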