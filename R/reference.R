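#' Published site summary of the pgfar survey
#'
#' The per-site summary statistics of the published U.S. light-trap survey
#' of *Ostrinia nubilalis* genotyped at the three pgfar CAPS markers: 16
#' field sites (1-5 Midwest, historically pure Z-race; 6-16 East Coast,
#' sympatric) plus the pure E-race BENY laboratory colony. H_O is identical
#' across the three markers at every site (the SNPs are in perfect linkage
#' disequilibrium), so one column carries it. `p_printed` is the published
#' HWE p-value as printed (`"Monomorphic"` for fixed sites, `"<0.001"` where
#' censored). These printed values are inputs: genotype counts are
#' recoverable from them with [reconstruct_counts()].
#'
#' @return data.frame with `site_id`, `site`, `state`, `region`, `n_male`,
#'   `n_female`, `n`, `H_O`, `H_E`, `p_printed`.
#' @export
pgfar_survey <- function() {
  tab <- data.frame(
    site_id = c(as.character(1:16), "C"),
    site = c("Mead", "Brookings", "Kanawha", "Crawfordsville", "Lexington",
             "Snyder Co.", "Beltsville", "Newark", "Cohansey",
             "Sergentsville", "Little York", "Yates", "Aurora", "Spencer",
             "Freeville", "Hartford", "BENY colony"),
    state = c("NE", "SD", "IA", "IA", "KY", "PA", "MD", "DE", "NJ", "NJ",
              "NJ", "NY", "NY", "NY", "NY", "NY", "NY"),
    region = c(rep("Midwest", 5), rep("EastCoast", 11), "Colony"),
    n_male = c(24, 12, 24, 24, 10, 13, 17, 44, 24, 11, 24, 3, 10, 9, 5, 6, NA),
    n_female = c(24, 12, 24, 24, 14, 11, 14, 44, 24, 13, 24, 7, 7, 11, 6, 4, NA),
    H_O = c(0, 0, 0, 0, 0, 0.083, 0.419, 0.193, 0.125, 0.208, 0.125, 0.200,
            0.059, 0.100, 0.182, 0.000, 0),
    H_E = c(NA, NA, NA, NA, NA, 0.156, 0.337, 0.347, 0.281, 0.311, 0.118,
            0.506, 0.059, 0.097, 0.173, NA, NA),
    p_printed = c(rep("Monomorphic", 5), "0.126", "0.295", "<0.001",
                  "<0.001", "0.152", "1.000", "0.082", "1.000", "1.000",
                  "1.000", "Monomorphic", "Monomorphic"),
    stringsAsFactors = FALSE)
  tab$n <- ifelse(is.na(tab$n_male), 44, tab$n_male + tab$n_female)
  tab
}

#' Reconstruct the survey's genotype counts
#'
#' Applies [reconstruct_counts()] to every row of [pgfar_survey()] and
#' returns the corresponding [population_sample()] objects. The BENY colony
#' is fixed for the pgfar-e allele, so its monomorphic counts sit in `n_ee`.
#'
#' @param sites site ids to include; default all.
#' @return named list of [population_sample()] objects.
#' @export
pgfar_survey_samples <- function(sites = NULL) {
  tab <- pgfar_survey()
  if (!is.null(sites)) tab <- tab[tab$site_id %in% as.character(sites), ]
  samples <- lapply(seq_len(nrow(tab)), function(i) {
    cnt <- reconstruct_counts(tab$n[i], tab$H_O[i], tab$H_E[i])
    if (tab$site_id[i] == "C")   # E-race colony: fixed for pgfar-e
      cnt <- c(n_zz = unname(cnt["n_ee"]), n_ez = 0L,
               n_ee = unname(cnt["n_zz"]))
    population_sample(tab$site_id[i], cnt["n_zz"], cnt["n_ez"], cnt["n_ee"],
                      region = tab$region[i], n_male = tab$n_male[i],
                      n_female = tab$n_female[i])
  })
  names(samples) <- tab$site_id
  samples
}
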