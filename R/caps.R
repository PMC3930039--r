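#' Primer pair
#'
#' Both primers are given 5'->3': the forward primer on the sense strand and
#' the reverse primer on the antisense strand. IUPAC degeneracy codes are
#' allowed (e.g. the `W` in pgFAR-mnr matches A or T).
#'
#' @param name pair name.
#' @param forward,reverse primer sequences, length >= 15.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(gsub("\\s", "", forward))
  reverse <- toupper(gsub("\\s", "", reverse))
  iupac <- paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15L) stop("primers must be at least 15 nt")
    if (grepl(sprintf("[^%s]", iupac), p))
      stop("primers must use IUPAC nucleotide codes only")
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' The published pgfar assay primer pairs
#'
#' `pgFAR-t` (pgFAR-tf/pgFAR-tr) primes the TaqI-assayed fragment containing
#' the G/T(857) SNP; `pgFAR-mn` (pgFAR-mnf/pgFAR-mnr) primes the single
#' fragment carrying both the G/T(995) (NdeII) and G/T(1005) (MseI) SNPs.
#'
#' @return named list of [primer_pair()] objects.
#' @export
pgfar_primers <- function() {
  list(
    `pgFAR-t` = primer_pair("pgFAR-t",
                            "TTCGATTCGGGAACCCATA",
                            "AGGTTCGCAACGTGGTCTAC"),
    `pgFAR-mn` = primer_pair("pgFAR-mn",
                             "GGGCAACAAAGGAGTCAAGGT",
                             "CCAAAATATTTCCTGTATTTTAWGCA"))
}

#' Read primer pairs from CSV
#'
#' Expects columns `name,forward,reverse`.
#'
#' @param file CSV path.
#' @return named list of [primer_pair()] objects.
#' @export
read_primer_table <- function(file) {
  tab <- read_csv_checked(file, c("name", "forward", "reverse"))
  pp <- lapply(seq_len(nrow(tab)), function(i)
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i]))
  names(pp) <- tab$name
  pp
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' In-silico PCR
#'
#' Finds the unique product primed by a pair under IUPAC-degenerate exact
#' matching (no mismatches by default, no thermodynamics): the forward
#' primer must match the product's 5' end on the sense strand and the
#' reverse-complement of the reverse primer its 3' end. Both orientations of
#' the template are searched; the amplicon is returned 5'->3' from the
#' forward primer, with both primer footprints included.
#'
#' @param template gap-free DNA string (e.g. a panel consensus).
#' @param primers a [primer_pair()].
#' @param max_products maximum acceptable number of products (default 1);
#'   any other count is an error naming the count.
#' @param max_mismatch mismatches tolerated per primer (default 0).
#' @param template_id identifier stored on the amplicon.
#' @return object of class `amplicon`: list with `sequence`, `template_id`,
#'   `start`, `end` (1-based inclusive template coordinates, primers
#'   included) and `strand` (`"+"` if the amplicon reads along the template,
#'   `"-"` if along its reverse complement).
#' @export
insilico_pcr <- function(template, primers, max_products = 1L,
                         max_mismatch = 0L, template_id = "template") {
  template <- toupper(as.character(template))
  if (grepl("-", template, fixed = TRUE)) stop("template must be gap-free")
  len <- nchar(template)
  scan_strand <- function(seqc) {
    f <- iupac_match_starts(primers$forward, seqc, max_mismatch)
    r <- iupac_match_starts(revcomp(primers$reverse), seqc, max_mismatch)
    rends <- r + nchar(primers$reverse) - 1L
    out <- list()
    for (fs in f) for (re in rends)
      if (re >= fs + nchar(primers$forward))
        out[[length(out) + 1L]] <- c(fs, re)
    out
  }
  plus <- scan_strand(template)
  minus <- scan_strand(revcomp(template))
  n_prod <- length(plus) + length(minus)
  if (n_prod == 0L || n_prod > max_products)
    stop("in-silico PCR returned ", n_prod, " products for primer pair ",
         primers$name)
  if (length(plus)) {
    fs <- plus[[1L]][1L]; re <- plus[[1L]][2L]
    amp <- substr(template, fs, re)
    coords <- c(fs, re); strand <- "+"
  } else {
    fs <- minus[[1L]][1L]; re <- minus[[1L]][2L]
    amp <- substr(revcomp(template), fs, re)
    coords <- c(len - re + 1L, len - fs + 1L); strand <- "-"
  }
  structure(list(sequence = amp, template_id = template_id,
                 start = coords[1L], end = coords[2L], strand = strand),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon: %d bp from %s:%d-%d (%s)\n",
              nchar(x$sequence), x$template_id, x$start, x$end, x$strand))
  invisible(x)
}

substitute_base <- function(sequence, position, base) {
  substr(sequence, position, position) <- base
  sequence
}

#' Candidate CAPS sites among fixed SNPs
#'
#' A fixed inter-race SNP is a CAPS candidate for an enzyme when
#' substituting one allele into the consensus context creates a recognition
#' site covering the SNP that is absent under the other allele, and the rest
#' of the recognition footprint is monomorphic (no base change, gap or N)
#' across every labelled sequence in the panel — so that the presence or
#' absence of the cut depends on the diagnostic allele alone. A SNP whose
#' two alleles both complete sites of the same enzyme is not diagnostic and
#' is not emitted.
#'
#' @param panel an [aligned_panel()].
#' @param snps data.frame from [fixed_differences()] on the same panel.
#' @param enzymes list of [enzyme()] objects, default [default_enzymes()].
#' @return data.frame with one row per (SNP, enzyme) candidate: `position`
#'   (consensus), `column`, `enzyme`, `recognition`, `allele_cut` (the base
#'   completing the site), `race_cut` (`"pgfar-e"` or `"pgfar-z"`),
#'   `site_start` (consensus coordinate of the created site).
#' @export
diagnostic_caps_sites <- function(panel, snps = fixed_differences(panel),
                                  enzymes = default_enzymes()) {
  cons <- panel_consensus(panel)
  labelled <- panel$mat[panel$groups %in% c("E", "Z"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$position[i]
    if (is.na(pos)) next
    for (enz in enzymes) {
      k <- nchar(enz$recognition)
      lo <- max(1L, pos - k + 1L)
      hi <- min(nchar(cons$sequence), pos + k - 1L)
      ctx <- substr(cons$sequence, lo, hi)
      rel <- pos - lo + 1L
      covering <- function(allele) {
        starts <- iupac_match_starts(enz$recognition,
                                     substitute_base(ctx, rel, allele))
        starts[starts <= rel & starts + k - 1L >= rel]
      }
      site_e <- covering(snps$allele_e[i])
      site_z <- covering(snps$allele_z[i])
      if ((length(site_e) > 0L) == (length(site_z) > 0L)) next
      cut_is_e <- length(site_e) > 0L
      site_rel <- if (cut_is_e) site_e[1L] else site_z[1L]
      site_pos <- lo + site_rel - 1L
      foot_cols <- cons$column[site_pos:(site_pos + k - 1L)]
      flank_cols <- setdiff(foot_cols, snps$column[i])
      mono <- all(vapply(flank_cols, function(cl) {
        u <- unique(labelled[, cl])
        length(u) == 1L && u %in% BASES
      }, logical(1)))
      if (!mono) next
      out[[length(out) + 1L]] <- data.frame(
        position = pos, column = snps$column[i], enzyme = enz$name,
        recognition = enz$recognition,
        allele_cut = if (cut_is_e) snps$allele_e[i] else snps$allele_z[i],
        race_cut = if (cut_is_e) "pgfar-e" else "pgfar-z",
        site_start = site_pos, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(position = integer(0), column = integer(0),
                      enzyme = character(0), recognition = character(0),
                      allele_cut = character(0), race_cut = character(0),
                      site_start = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a CAPS marker from a diagnostic SNP
#'
#' Substitutes each allele into the panel consensus, PCR-amplifies both
#' templates in silico, digests both amplicons, and stores the per-allele
#' fragment patterns with race labels attached. If the amplicon carries a
#' constitutive site of the same enzyme the marker is flagged (`flagged =
#' TRUE`) but still emitted, as the two alleles' patterns remain distinct;
#' identical patterns for both alleles are an error.
#'
#' @param panel an [aligned_panel()].
#' @param snp one row of [fixed_differences()] output (the diagnostic SNP).
#' @param enz the [enzyme()] whose site the cut allele completes.
#' @param primers a [primer_pair()] flanking the SNP.
#' @param name marker name; defaults to `<enzyme>_<position>`.
#' @param max_mismatch passed to [insilico_pcr()].
#' @return object of class `caps_marker`: name, primers, enzyme, SNP
#'   coordinates and alleles, per-allele fragment patterns `pattern_e` /
#'   `pattern_z`, the heterozygote band set `bands_het`, `cut_allele`,
#'   `cut_race`, `amplicon_length`, `flagged`.
#' @export
build_marker <- function(panel, snp, enz, primers, name = NULL,
                         max_mismatch = 0L) {
  cons <- panel_consensus(panel)
  pos <- snp$position
  if (is.na(pos)) stop("SNP has no consensus position")
  if (is.null(name)) name <- paste0(enz$name, "_", pos)
  amp_for <- function(allele) {
    tmpl <- substitute_base(cons$sequence, pos, allele)
    insilico_pcr(tmpl, primers, max_mismatch = max_mismatch,
                 template_id = "consensus")
  }
  amp_e <- amp_for(snp$allele_e)
  amp_z <- amp_for(snp$allele_z)
  if (nchar(amp_e$sequence) != nchar(amp_z$sequence))
    stop("allele substitution changed the amplicon length")
  pat_e <- digest(amp_e, enz)
  pat_z <- digest(amp_z, enz)
  if (identical(as.integer(pat_e), as.integer(pat_z)))
    stop("non-diagnostic: both alleles yield pattern ", format_fragments(pat_e))
  cut_is_e <- length(pat_e) > length(pat_z)
  structure(list(
    name = name, primers = primers, enzyme = enz,
    position = pos, column = snp$column,
    allele_e = snp$allele_e, allele_z = snp$allele_z,
    pattern_e = as.integer(pat_e), pattern_z = as.integer(pat_z),
    bands_het = sort(unique(c(pat_e, pat_z)), decreasing = TRUE),
    cut_allele = if (cut_is_e) snp$allele_e else snp$allele_z,
    cut_race = if (cut_is_e) "pgfar-e" else "pgfar-z",
    amplicon_length = nchar(amp_e$sequence),
    flagged = min(length(pat_e), length(pat_z)) > 1L),
    class = "caps_marker")
}

#' @export
print.caps_marker <- function(x, ...) {
  cat(sprintf("CAPS marker %s: SNP %s/%s at cDNA %d, %s (%s+ = %s)\n",
              x$name, x$allele_e, x$allele_z, x$position, x$enzyme$name,
              x$enzyme$name, x$cut_race))
  cat(sprintf("  pgfar-e amplicon: %s | pgfar-z amplicon: %s\n",
              format_fragments(x$pattern_e), format_fragments(x$pattern_z)))
  invisible(x)
}

#' Design all CAPS markers for a panel
#'
#' Convenience wrapper: finds fixed differences, screens them against the
#' enzyme list, and builds a marker for every candidate whose SNP falls
#' inside a product of one of the supplied primer pairs.
#'
#' @inheritParams diagnostic_caps_sites
#' @param primers named list of [primer_pair()] objects.
#' @param cds optional coding range for SNP annotation.
#' @return named list of [build_marker()] results.
#' @export
design_markers <- function(panel, primers, enzymes = default_enzymes(),
                           cds = NULL) {
  snps <- fixed_differences(panel, cds = cds)
  cands <- diagnostic_caps_sites(panel, snps, enzymes)
  cons <- panel_consensus(panel)
  markers <- list()
  for (i in seq_len(nrow(cands))) {
    snp <- snps[match(cands$position[i], snps$position), ]
    enz_names <- vapply(enzymes, function(e) e$name, character(1))
    enz <- enzymes[[match(cands$enzyme[i], enz_names)]]
    for (pp in primers) {
      amp <- tryCatch(insilico_pcr(cons$sequence, pp),
                      error = function(e) NULL)
      if (is.null(amp)) next
      if (cands$position[i] >= amp$start && cands$position[i] <= amp$end) {
        mk <- build_marker(panel, snp, enz, pp)
        markers[[mk$name]] <- mk
        break
      }
    }
  }
  markers
}

#' Marker report table
#'
#' One row per marker with `+`-joined fragment patterns, suitable for CSV
#' export.
#'
#' @param markers list of `caps_marker` objects.
#' @return data.frame.
#' @export
marker_report <- function(markers) {
  do.call(rbind, lapply(markers, function(m) data.frame(
    name = m$name, enzyme = m$enzyme$name, position = m$position,
    allele_e = m$allele_e, allele_z = m$allele_z,
    cut_allele = m$cut_allele, cut_race = m$cut_race,
    amplicon_bp = m$amplicon_length,
    pattern_e = format_fragments(m$pattern_e),
    pattern_z = format_fragments(m$pattern_z),
    flagged = m$flagged, stringsAsFactors = FALSE)))
}
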