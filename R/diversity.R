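BASES <- c("A", "C", "G", "T")

resolve_columns <- function(panel, columns) {
  if (is.null(columns)) return(seq_len(panel$width))
  columns <- as.integer(columns)
  if (length(columns) == 2L && columns[2L] >= columns[1L])
    columns <- columns[1L]:columns[2L]
  if (!length(columns)) stop("empty column range")
  if (any(columns < 1L | columns > panel$width)) stop("columns out of range")
  columns
}

# per-pair mismatch/compared-site counts under pairwise deletion
pair_counts <- function(mat, columns) {
  n <- nrow(mat)
  pairs <- utils::combn(n, 2L)
  sub <- mat[, columns, drop = FALSE]
  ok <- matrix(sub %in% BASES, nrow = n)
  diffs <- integer(ncol(pairs))
  comp <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    both <- ok[i, ] & ok[j, ]
    comp[k] <- sum(both)
    diffs[k] <- sum(sub[i, both] != sub[j, both])
  }
  list(diffs = diffs, compared = comp)
}

#' Mean pairwise p-distance of a panel
#'
#' Nucleotide diversity *d*: the mean, over all unordered sequence pairs, of
#' the proportion of mismatching sites, comparing only columns where both
#' sequences carry an unambiguous base (pairwise deletion of gaps and N).
#' The standard error is the analytical binomial variance of the p-distance,
#' `p(1-p)/L`, averaged over pairs and square-rooted.
#'
#' @param panel an [aligned_panel()].
#' @param group optional race filter passed to [subset_panel()].
#' @param columns optional column range (`c(start, end)` or explicit vector).
#' @return list with `d`, `se` and `n_pairs`.
#' @export
mean_pairwise_distance <- function(panel, group = NULL, columns = NULL) {
  panel <- subset_panel(panel, group)
  if (n_sequences(panel) < 2L) stop("insufficient sequences")
  pc <- pair_counts(panel$mat, resolve_columns(panel, columns))
  if (any(pc$compared == 0L)) stop("a sequence pair shares no comparable sites")
  p <- pc$diffs / pc$compared
  list(d = mean(p), se = sqrt(mean(p * (1 - p) / pc$compared)),
       n_pairs = length(p))
}

#' Diversity partitions within and between races
#'
#' Reports all three partitions of the mean pairwise distance: within the E
#' group, within the Z group, and between groups (pairs with one member in
#' each).
#'
#' @inheritParams mean_pairwise_distance
#' @return data.frame with columns `partition`, `d`, `se`, `n_pairs`.
#' @export
distance_partitions <- function(panel, columns = NULL) {
  within_e <- mean_pairwise_distance(panel, "E", columns)
  within_z <- mean_pairwise_distance(panel, "Z", columns)
  e <- subset_panel(panel, "E"); z <- subset_panel(panel, "Z")
  cols <- resolve_columns(panel, columns)
  diffs <- numeric(0)
  for (i in seq_len(n_sequences(e))) {
    for (j in seq_len(n_sequences(z))) {
      a <- e$mat[i, cols]; b <- z$mat[j, cols]
      both <- a %in% BASES & b %in% BASES
      diffs <- c(diffs, sum(a[both] != b[both]) / sum(both))
    }
  }
  data.frame(
    partition = c("within_E", "within_Z", "between"),
    d = c(within_e$d, within_z$d, mean(diffs)),
    se = c(within_e$se, within_z$se, NA_real_),
    n_pairs = c(within_e$n_pairs, within_z$n_pairs, length(diffs)))
}

#' Nucleotide diversity (pi) over a column range
#'
#' Average per-site pairwise difference: the mean over all sequence pairs of
#' (mismatches / compared sites) within the range, with pairwise deletion of
#' gaps and ambiguous bases.
#'
#' @inheritParams mean_pairwise_distance
#' @return a single numeric value.
#' @export
nucleotide_diversity <- function(panel, columns = NULL) {
  if (n_sequences(panel) < 2L) stop("insufficient sequences")
  pc <- pair_counts(panel$mat, resolve_columns(panel, columns))
  mean(ifelse(pc$compared > 0L, pc$diffs / pc$compared, NA_real_))
}

#' Count of segregating sites
#'
#' A column segregates when at least two distinct unambiguous bases occur
#' among the included sequences; gaps and N are ignored (a column holding
#' only `A,-,A` is not segregating).
#'
#' @inheritParams mean_pairwise_distance
#' @return integer count S.
#' @export
segregating_sites <- function(panel, columns = NULL) {
  cols <- resolve_columns(panel, columns)
  sub <- panel$mat[, cols, drop = FALSE]
  sum(apply(sub, 2L, function(col) length(unique(col[col %in% BASES])) >= 2L))
}

tajima_coefficients <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' The standard statistic contrasting the mean pairwise difference count with
#' the segregating-site estimator of theta:
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with `k` the mean number of
#' pairwise differences (pairwise deletion) over the column range and the
#' usual coefficients computed from the number of sequences. Returns `NA`
#' (undefined) when `S = 0`, since the denominator vanishes.
#'
#' @inheritParams mean_pairwise_distance
#' @return numeric D, or `NA_real_` when no site segregates.
#' @export
tajimas_d <- function(panel, columns = NULL) {
  n <- n_sequences(panel)
  if (n < 2L) stop("insufficient sequences")
  cols <- resolve_columns(panel, columns)
  S <- segregating_sites(panel, cols)
  if (S == 0L) return(NA_real_)
  pc <- pair_counts(panel$mat, cols)
  k <- mean(pc$diffs)
  cf <- tajima_coefficients(n)
  (k - S / cf$a1) / sqrt(cf$e1 * S + cf$e2 * S * (S - 1))
}

#' Sliding-window Tajima's D scan
#'
#' Windows of `width` columns start at 1, 1+step, ...; windows are full-width
#' while they fit, and if columns remain past the last full window a single
#' terminal truncated window (marked in the output) covers them. Windows with
#' defined D above `threshold` are flagged, and overlapping flagged windows
#' are merged into divergent regions (see [divergent_regions()]).
#'
#' @param panel an [aligned_panel()].
#' @param width window width in columns.
#' @param step increment between window starts.
#' @param threshold numeric cutoff on D above which a window is flagged.
#'   This is a plain cutoff, not a formal test.
#' @return data.frame of class `window_scan` with columns `start`, `end`,
#'   `S`, `pi`, `tajimas_d`, `flagged`, `truncated`.
#' @export
sliding_window_scan <- function(panel, width = 100L, step = 25L,
                                threshold = 2.0) {
  if (width <= 0L || step <= 0L) stop("width and step must be positive")
  L <- panel$width
  if (width > L) stop("window width exceeds alignment length")
  starts <- seq(1L, L - width + 1L, by = step)
  ends <- starts + width - 1L
  truncated <- rep(FALSE, length(starts))
  last <- starts[length(starts)]
  if (last + width - 1L < L) {   # leftover columns -> one truncated window
    starts <- c(starts, last + step)
    ends <- c(ends, L)
    truncated <- c(truncated, TRUE)
  }
  res <- data.frame(start = starts, end = ends, S = NA_integer_,
                    pi = NA_real_, tajimas_d = NA_real_,
                    flagged = FALSE, truncated = truncated)
  for (k in seq_len(nrow(res))) {
    cols <- res$start[k]:res$end[k]
    res$S[k] <- segregating_sites(panel, cols)
    res$pi[k] <- nucleotide_diversity(panel, cols)
    res$tajimas_d[k] <- tajimas_d(panel, cols)
  }
  res$flagged <- !is.na(res$tajimas_d) & res$tajimas_d > threshold
  class(res) <- c("window_scan", "data.frame")
  attr(res, "threshold") <- threshold
  res
}

#' Merge flagged windows into divergent regions
#'
#' Flagged windows sharing any column are merged; each region spans from the
#' first to the last column of its constituent windows.
#'
#' @param scan output of [sliding_window_scan()].
#' @return data.frame with `start`, `end`, `n_windows`, `max_d`.
#' @export
divergent_regions <- function(scan) {
  fl <- scan[scan$flagged, , drop = FALSE]
  if (!nrow(fl))
    return(data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0), max_d = numeric(0)))
  fl <- fl[order(fl$start), ]
  out <- list()
  cur <- fl[1L, ]
  cur_n <- 1L; cur_max <- fl$tajimas_d[1L]
  for (k in seq_len(nrow(fl))[-1L]) {
    if (fl$start[k] <= cur$end) {   # overlap on any column
      cur$end <- max(cur$end, fl$end[k])
      cur_n <- cur_n + 1L
      cur_max <- max(cur_max, fl$tajimas_d[k])
    } else {
      out[[length(out) + 1L]] <- data.frame(start = cur$start, end = cur$end,
                                            n_windows = cur_n, max_d = cur_max)
      cur <- fl[k, ]; cur_n <- 1L; cur_max <- fl$tajimas_d[k]
    }
  }
  out[[length(out) + 1L]] <- data.frame(start = cur$start, end = cur$end,
                                        n_windows = cur_n, max_d = cur_max)
  do.call(rbind, out)
}

#' Export flagged regions as 0-based half-open intervals
#'
#' Explicit conversion from the package's 1-based inclusive alignment columns
#' to BED-like coordinates.
#'
#' @param regions output of [divergent_regions()].
#' @param name region name stem.
#' @return data.frame with `chrom_start` (0-based) and `chrom_end`
#'   (exclusive).
#' @export
regions_to_bed <- function(regions, name = "divergent") {
  data.frame(name = paste0(name, "_", seq_len(nrow(regions))),
             chrom_start = regions$start - 1L,
             chrom_end = regions$end)
}

#' Fixed differences between the E and Z groups
#'
#' Columns at which every E-labelled sequence carries one base, every
#' Z-labelled sequence carries a different single base, and no labelled
#' sequence has a gap or N. Codon position and synonymy are annotated
#' against a supplied reading frame given in consensus (cDNA) coordinates:
#' synonymy compares the amino acid encoded by the E-group codon with that
#' of the Z-group codon (each group's consensus over the codon).
#'
#' @param panel an [aligned_panel()] with at least two sequences per race.
#' @param cds optional `c(start, end)` of the coding region in consensus
#'   coordinates; when `NULL`, codon position and synonymy are `NA`.
#' @return data.frame with `column`, `position` (consensus coordinate, `NA`
#'   when the consensus is gapped there), `allele_e`, `allele_z`,
#'   `codon_position` (1/2/3 or `NA` for noncoding) and `synonymous`.
#' @export
fixed_differences <- function(panel, cds = NULL) {
  stopifnot(inherits(panel, "aligned_panel"))
  for (g in c("E", "Z"))
    if (sum(panel$groups == g) < 2L)
      stop("need at least 2 sequences labelled ", g)
  e <- panel$mat[panel$groups == "E", , drop = FALSE]
  z <- panel$mat[panel$groups == "Z", , drop = FALSE]
  fixed_base <- function(m) apply(m, 2L, function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% BASES) u else NA_character_
  })
  be <- fixed_base(e); bz <- fixed_base(z)
  hit <- which(!is.na(be) & !is.na(bz) & be != bz)
  if (!length(hit))
    return(data.frame(column = integer(0), position = integer(0),
                      allele_e = character(0), allele_z = character(0),
                      codon_position = integer(0), synonymous = logical(0)))
  cons <- panel_consensus(panel)
  out <- data.frame(column = hit, position = cons$position[hit],
                    allele_e = be[hit], allele_z = bz[hit],
                    codon_position = NA_integer_, synonymous = NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(cds) && nrow(out)) {
    stopifnot(length(cds) == 2L, cds[2L] >= cds[1L])
    group_base <- function(m, col) {   # majority unambiguous base in a group
      tab <- table(factor(m[, col], levels = BASES))
      if (sum(tab) == 0L) NA_character_ else BASES[which.max(tab)]
    }
    aa <- function(codon) {
      if (is.na(codon) || grepl("[^ACGT]", codon)) return(NA_character_)
      unname(Biostrings::GENETIC_CODE[codon])
    }
    n_pos <- length(cons$column)
    for (k in seq_len(nrow(out))) {
      pos <- out$position[k]
      if (is.na(pos) || pos < cds[1L] || pos > cds[2L]) next
      off <- pos - cds[1L]
      out$codon_position[k] <- off %% 3L + 1L
      codon_start <- cds[1L] + (off %/% 3L) * 3L
      idx <- codon_start:(codon_start + 2L)
      if (max(idx) > n_pos) next
      codon <- function(m) {   # group-consensus codon
        b <- vapply(cons$column[idx], function(cl) group_base(m, cl),
                    character(1))
        if (anyNA(b)) NA_character_ else paste(b, collapse = "")
      }
      aae <- aa(codon(e)); aaz <- aa(codon(z))
      out$synonymous[k] <- if (is.na(aae) || is.na(aaz)) NA else aae == aaz
    }
  }
  out
}
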