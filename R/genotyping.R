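match_band_sets <- function(observed, expected, tolerance) {
  observed <- sort(as.numeric(observed))
  expected <- sort(as.numeric(expected))
  all(vapply(observed, function(o) any(abs(o - expected) <= tolerance),
             logical(1))) &&
  all(vapply(expected, function(e) any(abs(observed - e) <= tolerance),
             logical(1)))
}

#' Call a genotype from an observed fragment pattern
#'
#' Band sets (unique fragment lengths, as resolved on a gel) are compared
#' against the marker's expectations: the pgfar-e allele pattern alone means
#' homozygous `"EE"`, the pgfar-z pattern alone `"ZZ"`, the union of both
#' patterns a heterozygote `"EZ"`, and anything else is `NA` (missing /
#' unresolvable). An observed band matches an expected one when their
#' lengths differ by at most `tolerance` bp, reflecting sizing against a
#' 50-bp ladder.
#'
#' @param pattern numeric vector of observed fragment lengths (bp).
#' @param marker a [build_marker()] result.
#' @param tolerance sizing tolerance in bp; default 5.
#' @return `"EE"`, `"EZ"`, `"ZZ"` or `NA_character_`.
#' @export
call_marker <- function(pattern, marker, tolerance = 5) {
  if (identical(sort(unique(as.integer(marker$pattern_e))),
                sort(unique(as.integer(marker$pattern_z)))))
    stop("marker has indistinct per-allele patterns")
  if (!length(pattern) || anyNA(pattern)) return(NA_character_)
  bands <- unique(as.numeric(pattern))
  is_e <- match_band_sets(bands, unique(marker$pattern_e), tolerance)
  is_z <- match_band_sets(bands, unique(marker$pattern_z), tolerance)
  is_h <- match_band_sets(bands, marker$bands_het, tolerance)
  if (is_h && !is_e && !is_z) return("EZ")
  if (is_e && !is_z) return("EE")
  if (is_z && !is_e) return("ZZ")
  NA_character_
}

#' Consensus diploid genotype across markers
#'
#' All non-missing per-marker calls must agree for a consensus; otherwise
#' the individual is reported `"discordant"` with its full per-marker
#' vector, never silently resolved (the `"majority"` rule, which resolves
#' 2-of-3 splits, must be requested explicitly). Genotype dosage counts
#' pgfar-z alleles / 2 by default (`ZZ` = 1.0, `EZ` = 0.5, `EE` = 0.0);
#' `dosage_allele = "e"` flips the orientation. Dosage is defined only for
#' concordant calls.
#'
#' @param calls named character vector or list of per-marker calls
#'   (`"EE"`/`"EZ"`/`"ZZ"`/`NA`).
#' @param resolve `"strict"` (default) or `"majority"`.
#' @param dosage_allele which allele the dosage counts: `"z"` (default) or
#'   `"e"`.
#' @return list with `consensus` (`"EE"`, `"EZ"`, `"ZZ"`, `"discordant"` or
#'   `"missing"`), `dosage` (0/0.5/1 or `NA`), and `per_marker`.
#' @export
consensus_genotype <- function(calls, resolve = c("strict", "majority"),
                               dosage_allele = c("z", "e")) {
  resolve <- match.arg(resolve)
  dosage_allele <- match.arg(dosage_allele)
  calls <- unlist(calls)
  obs <- calls[!is.na(calls)]
  bad <- setdiff(unique(obs), c("EE", "EZ", "ZZ"))
  if (length(bad)) stop("unknown genotype call: ", paste(bad, collapse = " "))
  if (!length(obs))
    return(list(consensus = "missing", dosage = NA_real_, per_marker = calls))
  u <- unique(obs)
  consensus <-
    if (length(u) == 1L) u
    else if (resolve == "majority") {
      tab <- sort(table(obs), decreasing = TRUE)
      if (length(tab) > 1L && tab[1L] == tab[2L]) "discordant"
      else names(tab)[1L]
    } else "discordant"
  dosage <- if (consensus %in% c("EE", "EZ", "ZZ")) {
    z <- c(EE = 0, EZ = 0.5, ZZ = 1)[[consensus]]
    if (dosage_allele == "z") z else 1 - z
  } else NA_real_
  list(consensus = consensus, dosage = dosage, per_marker = calls)
}

#' Genotype a cohort of individuals across markers
#'
#' @param patterns named list: one element per individual, each a named list
#'   of observed fragment-length vectors keyed by marker name.
#' @param markers named list of [build_marker()] results.
#' @param tolerance sizing tolerance in bp.
#' @param resolve,dosage_allele passed to [consensus_genotype()].
#' @return data.frame with `individual_id`, one column per marker,
#'   `consensus` and `dosage`.
#' @export
genotype_cohort <- function(patterns, markers, tolerance = 5,
                            resolve = "strict", dosage_allele = "z") {
  rows <- lapply(names(patterns), function(id) {
    calls <- vapply(names(markers), function(mk) {
      obs <- patterns[[id]][[mk]]
      if (is.null(obs)) NA_character_
      else call_marker(obs, markers[[mk]], tolerance)
    }, character(1))
    cg <- consensus_genotype(calls, resolve, dosage_allele)
    cbind(data.frame(individual_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(calls), stringsAsFactors = FALSE),
          data.frame(consensus = cg$consensus, dosage = cg$dosage))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
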