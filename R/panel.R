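#' Aligned, group-labelled sequence panel
#'
#' Container for a gapped multiple alignment of cDNA sequences in which each
#' record carries a pheromone-race label (`"E"`, `"Z"`, or `"unlabeled"`).
#' Alignment coordinates are 1-based inclusive columns throughout the package;
#' ungapped "cDNA" coordinates refer to positions in the panel consensus (see
#' [panel_consensus()]).
#'
#' @param sequences character vector of equal-length gapped DNA strings
#'   (alphabet `A C G T N -`, case-insensitive), or a
#'   [Biostrings::DNAStringSet].
#' @param groups character vector of race labels, recycled `"unlabeled"` when
#'   `NULL`. Any value other than `"E"`/`"Z"` is stored as `"unlabeled"`.
#' @param ids sequence identifiers; defaults to `names(sequences)` or
#'   `seq1, seq2, ...`.
#'
#' @return An object of class `aligned_panel`: a list with elements `ids`,
#'   `groups`, `mat` (an `n x L` character matrix of single bases) and
#'   `width` (the number of alignment columns).
#' @export
aligned_panel <- function(sequences, groups = NULL, ids = NULL) {
  if (inherits(sequences, "DNAStringSet")) {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- as.character(sequences)
  }
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 1L) stop("panel needs at least one sequence")
  if (is.null(ids)) ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length; got widths ",
         paste(unique(widths), collapse = ", "))
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = " "))
  if (is.null(groups)) groups <- rep("unlabeled", n)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must have one label per sequence")
  groups[!groups %in% c("E", "Z")] <- "unlabeled"
  structure(list(ids = as.character(ids), groups = groups, mat = mat,
                 width = widths[1L]),
            class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat(sprintf("aligned_panel: %d sequences x %d columns (E: %d, Z: %d, unlabeled: %d)\n",
              nrow(x$mat), x$width,
              sum(x$groups == "E"), sum(x$groups == "Z"),
              sum(x$groups == "unlabeled")))
  invisible(x)
}

#' Read an aligned FASTA panel with race labels
#'
#' Labels come either from a two-column CSV (`id,group`) or from a
#' `group=E`/`group=Z` token anywhere in the FASTA header. FASTA parsing
#' (wrapped lines, mixed case) is delegated to Biostrings.
#'
#' @param fasta path to an aligned multi-FASTA file.
#' @param groups_file optional path to an `id,group` CSV; overrides header
#'   tokens.
#' @return an [aligned_panel()].
#' @export
read_alignment <- function(fasta, groups_file = NULL) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop("failed to parse FASTA file '",
                                            fasta, "': ", conditionMessage(e)))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  groups <- rep("unlabeled", length(seqs))
  tok <- regmatches(headers, regexpr("group=[EZez]", headers))
  has_tok <- grepl("group=[EZez]", headers)
  groups[has_tok] <- toupper(sub("group=", "", tok))
  if (!is.null(groups_file)) {
    tab <- read_csv_checked(groups_file, c("id", "group"))
    idx <- match(ids, tab$id)
    if (anyNA(idx))
      stop("groups file '", groups_file, "' is missing ids: ",
           paste(ids[is.na(idx)], collapse = ", "))
    groups <- toupper(as.character(tab$group[idx]))
  }
  aligned_panel(as.character(seqs), groups = groups, ids = ids)
}

#' Restrict a panel to one race
#'
#' @param panel an [aligned_panel()].
#' @param group `"E"`, `"Z"` or `"unlabeled"`; `NULL` keeps everything.
#' @return an [aligned_panel()] with the selected records.
#' @export
subset_panel <- function(panel, group = NULL) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (is.null(group)) return(panel)
  keep <- panel$groups %in% group
  if (!any(keep)) stop("no sequences with group ", paste(group, collapse = "/"))
  structure(list(ids = panel$ids[keep], groups = panel$groups[keep],
                 mat = panel$mat[keep, , drop = FALSE], width = panel$width),
            class = "aligned_panel")
}

#' Ungapped consensus and column/position maps
#'
#' The consensus base of a column is its most frequent symbol (gap included;
#' ties broken alphabetically with `-` sorting last, so a base wins a tie
#' against a gap). Columns whose consensus is a gap have no consensus
#' position. cDNA positions used elsewhere in the package (e.g. the
#' diagnostic SNPs at 857/995/1005) are positions in this ungapped consensus.
#'
#' @param panel an [aligned_panel()].
#' @return list with `sequence` (ungapped consensus string), `column`
#'   (alignment column of each consensus position) and `position` (consensus
#'   position of each alignment column, `NA` for consensus-gap columns).
#' @export
panel_consensus <- function(panel) {
  stopifnot(inherits(panel, "aligned_panel"))
  lev <- c("A", "C", "G", "T", "N", "-")
  cons <- apply(panel$mat, 2L, function(col) {
    tab <- table(factor(col, levels = lev))
    lev[which.max(tab)]  # which.max takes the first maximum => base beats gap
  })
  keep <- cons != "-"
  position <- rep(NA_integer_, panel$width)
  position[keep] <- cumsum(keep)[keep]
  list(sequence = paste(cons[keep], collapse = ""),
       column = which(keep),
       position = position)
}

n_sequences <- function(panel) nrow(panel$mat)

#' Map consensus positions to alignment columns (and back)
#'
#' @param panel an [aligned_panel()].
#' @param position consensus (cDNA) positions.
#' @return integer alignment columns.
#' @export
consensus_to_column <- function(panel, position) {
  cons <- panel_consensus(panel)
  if (any(position < 1L | position > length(cons$column)))
    stop("consensus position out of range")
  cons$column[position]
}

#' @rdname consensus_to_column
#' @param column alignment columns.
#' @return for `column_to_consensus`, consensus positions (`NA` where the
#'   consensus is gapped).
#' @export
column_to_consensus <- function(panel, column) {
  cons <- panel_consensus(panel)
  if (any(column < 1L | column > panel$width)) stop("column out of range")
  cons$position[column]
}
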