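#' Restriction enzyme specification
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (IUPAC codes allowed), length
#'   >= 4.
#' @param cut_offset top-strand cut position within the recognition
#'   sequence: the enzyme cuts after `cut_offset` bases of the site (0 means
#'   it cuts immediately before the site's first base).
#' @return object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  cut_offset <- as.integer(cut_offset)
  if (nchar(recognition) < 4L) stop("recognition sequence must be >= 4 bases")
  if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                   collapse = "")), recognition))
    stop("recognition sequence must use IUPAC nucleotide codes")
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition sequence")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  site <- x$recognition
  cat(sprintf("%s: %s^%s\n", x$name,
              substr(site, 1L, x$cut_offset),
              substr(site, x$cut_offset + 1L, nchar(site))))
  invisible(x)
}

is_palindromic <- function(enz) {
  rec <- Biostrings::DNAString(enz$recognition)
  as.character(Biostrings::reverseComplement(rec)) == enz$recognition
}

#' The three race-diagnostic enzymes
#'
#' TaqI (T^CGA), NdeII (^GATC) and MseI (T^TAA): the enzymes whose
#' recognition palindromes are completed by one allele of the diagnostic
#' pgfar SNPs. The table is user-extensible via [enzyme()] or
#' [read_enzyme_table()].
#'
#' @return named list of [enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(TaqI  = enzyme("TaqI",  "TCGA", 1L),
       NdeII = enzyme("NdeII", "GATC", 0L),
       MseI  = enzyme("MseI",  "TTAA", 1L))
}

#' Read an enzyme table from CSV
#'
#' Expects columns `name,recognition,cut_offset`.
#'
#' @param file CSV path.
#' @return named list of [enzyme()] objects.
#' @export
read_enzyme_table <- function(file) {
  tab <- read_csv_checked(file, c("name", "recognition", "cut_offset"))
  enz <- lapply(seq_len(nrow(tab)), function(i)
    enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i]))
  names(enz) <- tab$name
  enz
}

iupac_match_starts <- function(pattern, subject, max_mismatch = 0L) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch, fixed = FALSE)
  Biostrings::start(m)
}

#' Find restriction cut positions in a sequence
#'
#' Every occurrence of the recognition sequence (IUPAC-expanded) is reported
#' as the 1-based position of the last base before the top-strand cut, i.e.
#' `site_start + cut_offset - 1` (0 means the cut falls before base 1).
#' Palindromic enzymes need only the top-strand scan; for non-palindromic
#' enzymes, sites on the bottom strand are scanned as well and their cut is
#' mapped back to top-strand coordinates.
#'
#' @param sequence gap-free DNA string.
#' @param enz an [enzyme()].
#' @return sorted integer vector of cut positions (possibly empty).
#' @export
find_sites <- function(sequence, enz) {
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE)) stop("sequence must be gap-free")
  k <- nchar(enz$recognition)
  starts <- iupac_match_starts(enz$recognition, sequence)
  cuts <- starts + enz$cut_offset - 1L
  if (!is_palindromic(enz)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enz$recognition)))
    starts2 <- iupac_match_starts(rc, sequence)
    # bottom-strand cut after (k - cut_offset) bases from the site's 3' end
    cuts <- c(cuts, starts2 + (k - enz$cut_offset) - 1L)
  }
  sort(unique(as.integer(cuts)))
}

#' In-silico restriction digestion
#'
#' Fragment lengths induced by the top-strand cut positions of `enz` in the
#' amplicon; an uncut amplicon yields one full-length fragment. Recognition
#' sites whose footprint starts within `min_end_distance` bases of either
#' fragment terminus are not scored: restriction endonucleases cleave
#' end-proximal sites inefficiently, and the sub-gel-resolution terminal
#' fragments such cuts would produce are never observed on the 3% agarose
#' gels the assay is scored on. Set `min_end_distance = 0` for a literal
#' digest. Fragment lengths always sum to the amplicon length.
#'
#' @param amplicon an [amplicon] object from [insilico_pcr()], or a plain
#'   DNA string.
#' @param enz an [enzyme()].
#' @param min_end_distance minimum distance (bases) between a scored site's
#'   start and the nearer amplicon end; default 3.
#' @return integer vector of fragment lengths, descending; class
#'   `fragment_pattern`.
#' @export
digest <- function(amplicon, enz, min_end_distance = 3L) {
  seqc <- if (inherits(amplicon, "amplicon")) amplicon$sequence
          else toupper(as.character(amplicon))
  len <- nchar(seqc)
  k <- nchar(enz$recognition)
  cuts <- find_sites(seqc, enz)
  if (min_end_distance > 0L && length(cuts)) {
    # recover plausible site starts for each cut (top or bottom strand)
    site_start_top <- cuts - enz$cut_offset + 1L
    near_end <- function(s) s <= min_end_distance |
                            s + k - 1L > len - min_end_distance
    drop <- near_end(site_start_top)
    if (!is_palindromic(enz)) {
      site_start_bot <- cuts - (k - enz$cut_offset) + 1L
      drop <- drop | near_end(site_start_bot)
    }
    cuts <- cuts[!drop]
  }
  cuts <- cuts[cuts > 0L & cuts < len]
  frags <- diff(c(0L, cuts, len))
  structure(sort(as.integer(frags), decreasing = TRUE),
            class = "fragment_pattern")
}

#' @export
print.fragment_pattern <- function(x, ...) {
  cat(format_fragments(x), "\n")
  invisible(x)
}

#' Serialize fragment lengths as `118+32`-style text
#'
#' @param fragments integer fragment lengths.
#' @return single string with lengths joined by `+`.
#' @export
format_fragments <- function(fragments) {
  paste(sort(as.integer(fragments), decreasing = TRUE), collapse = "+")
}
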