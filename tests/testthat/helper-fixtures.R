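# Small in-code fixtures shared across test files.

# random gap-free panel for property loops
random_panel <- function(n, L, seed, groups = NULL) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                             collapse = ""))
  aligned_panel(seqs, groups = groups)
}

# independent brute-force Tajima's D straight from the definition:
# explicit pairwise difference loop and textbook coefficients
oracle_tajimas_d <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  seg <- sum(apply(mat[, , drop = FALSE], 2, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2
  }))
  k_sum <- 0; n_pair <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    both <- mat[i, ] %in% c("A", "C", "G", "T") &
            mat[j, ] %in% c("A", "C", "G", "T")
    k_sum <- k_sum + sum(mat[i, both] != mat[j, both])
    n_pair <- n_pair + 1
  }
  if (seg == 0) return(NA_real_)
  k <- k_sum / n_pair
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - seg / a1) / sqrt(e1 * seg + e2 * seg * (seg - 1))
}

# brute-force count reconstruction: every triple summing to n, matched on
# the 3-decimal printed statistics
oracle_reconstruct <- function(n, H_O, H_E) {
  hits <- list()
  for (nez in 0:n) for (nee in 0:(n - nez)) {
    nzz <- n - nez - nee
    ho <- round(nez / n, 3)
    p <- (2 * nee + nez) / (2 * n)
    he <- round(2 * n / (2 * n - 1) * 2 * p * (1 - p), 3)
    if (ho == round(H_O, 3) && abs(he - round(H_E, 3)) <= 0.001 + 1e-9)
      hits[[length(hits) + 1]] <- c(nzz, nez, nee)
  }
  hits
}

survey_pops <- function() pgfar_survey_samples()
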