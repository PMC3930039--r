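read_csv_checked <- function(file, required) {
  if (!file.exists(file)) stop("input file not found: ", file)
  tab <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("failed to parse CSV '", file, "': ",
                             conditionMessage(e)))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("CSV '", file, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Read a compact genotype-counts table
#'
#' Expects columns `site_id, region, n_zz, n_ez, n_ee`.
#'
#' @param file CSV path.
#' @return named list of [population_sample()] objects.
#' @export
read_counts <- function(file) {
  tab <- read_csv_checked(file, c("site_id", "region", "n_zz", "n_ez",
                                  "n_ee"))
  pops <- lapply(seq_len(nrow(tab)), function(i)
    population_sample(tab$site_id[i], tab$n_zz[i], tab$n_ez[i],
                      tab$n_ee[i], region = tab$region[i]))
  names(pops) <- tab$site_id
  pops
}

round_cols <- function(df, cols, digits = 3L) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

write_report <- function(df, path, digits_cols = character(0)) {
  # rounded human-facing CSV plus a full-precision sidecar
  utils::write.csv(round_cols(df, digits_cols), path, row.names = FALSE,
                   na = "NA")
  side <- sub("\\.csv$", "_full.csv", path)
  if (length(digits_cols))
    utils::write.csv(df, side, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Thin orchestration over the package's functions: executes the requested
#' stage and writes CSV reports plus a JSON run manifest (inputs,
#' parameters, seed, package version) into `out_dir`. Stages:
#'
#' * `"scan"` — sliding-window diversity scan of an aligned panel
#'   (`alignment`, `groups`; `width`, `step`, `threshold`).
#' * `"design"` — fixed differences, CAPS candidates and marker report
#'   (`alignment`, `groups`, optional `enzymes`, `primers` CSVs).
#' * `"popgen"` — site summary, hierarchical F-statistics and pairwise
#'   theta from a counts CSV (`counts`; `grouping`, `n_perm`, `alpha`,
#'   `correction`).
#' * `"assoc"` — genotype-phenotype association from a phenotype CSV
#'   (`phenotypes` with columns individual_id, family, pct_E and a
#'   genotype column).
#'
#' Every stochastic step receives an explicit seed (default 1, recorded in
#' the manifest); a rerun with the same config reproduces the outputs.
#'
#' @param config named list of parameters (see stages above).
#' @return invisibly, a list of the computed result objects.
#' @export
run_pipeline <- function(config) {
  stage <- match.arg(config$stage, c("scan", "design", "popgen", "assoc"))
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  results <- list()

  if (stage %in% c("scan", "design")) {
    panel <- read_alignment(config$alignment, config$groups)
    results$panel <- panel
  }
  if (stage == "scan") {
    width <- if (is.null(config$width)) 100L else as.integer(config$width)
    step <- if (is.null(config$step)) 25L else as.integer(config$step)
    thr <- if (is.null(config$threshold)) 2.0 else as.numeric(config$threshold)
    scan <- sliding_window_scan(results$panel, width, step, thr)
    regions <- divergent_regions(scan)
    write_report(as.data.frame(scan), file.path(out_dir, "windows.csv"),
                 c("pi", "tajimas_d"))
    write_report(regions, file.path(out_dir, "divergent_regions.csv"))
    results$scan <- scan
    results$regions <- regions
  }
  if (stage == "design") {
    enzymes <- if (is.null(config$enzymes)) default_enzymes()
               else read_enzyme_table(config$enzymes)
    primers <- if (is.null(config$primers)) pgfar_primers()
               else read_primer_table(config$primers)
    cds <- config$cds
    snps <- fixed_differences(results$panel, cds = cds)
    cands <- diagnostic_caps_sites(results$panel, snps, enzymes)
    markers <- design_markers(results$panel, primers, enzymes, cds = cds)
    write_report(snps, file.path(out_dir, "fixed_differences.csv"))
    write_report(cands, file.path(out_dir, "caps_candidates.csv"))
    if (length(markers))
      write_report(marker_report(markers), file.path(out_dir, "markers.csv"))
    results$snps <- snps
    results$candidates <- cands
    results$markers <- markers
  }
  if (stage == "popgen") {
    pops <- read_counts(config$counts)
    n_perm <- if (is.null(config$n_perm)) 1000L else as.integer(config$n_perm)
    alpha <- if (is.null(config$alpha)) 0.05 else as.numeric(config$alpha)
    summ <- site_summary(pops)
    write_report(summ, file.path(out_dir, "site_summary.csv"),
                 c("p_e", "H_O", "H_E", "p_hwe"))
    grouping <- config$grouping
    polymorphic_groups <- length(unique(stats::na.omit(
      vapply(pops, function(p) as.character(p$region), character(1))))) >= 2L
    if (!is.null(grouping) || polymorphic_groups) {
      fs <- hierarchical_fstats(pops, grouping, n_perm = n_perm, seed = seed)
      amova <- data.frame(level = names(fs$sigma), sigma = fs$sigma,
                          row.names = NULL)
      write_report(amova, file.path(out_dir, "amova.csv"))
      write_report(data.frame(statistic = names(fs$F), value = fs$F,
                              p_perm = c(fs$p["F_CT"], fs$p["F_SC"],
                                         fs$p["F_IS"], NA),
                              row.names = NULL),
                   file.path(out_dir, "fstats.csv"))
      results$fstats <- fs
    }
    fst <- pairwise_fst_matrix(pops, n_perm = n_perm, seed = seed)
    m <- nrow(fst)
    fst$significant <- !is.na(fst$p_perm) &
      fst$p_perm <= if (identical(config$correction, "none")) alpha
                    else by_threshold(alpha, m)
    write_report(fst, file.path(out_dir, "pairwise_fst.csv"),
                 c("theta", "p_perm"))
    results$site_summary <- summ
    results$pairwise_fst <- fst
  }
  if (stage == "assoc") {
    tab <- read_csv_checked(config$phenotypes,
                            c("individual_id", "family", "pct_E",
                              "genotype"))
    summ <- genotype_class_summary(tab$pct_E, tab$genotype)
    assoc <- association_summary(tab$pct_E, tab$genotype, tab$family)
    write_report(summ, file.path(out_dir, "genotype_class_summary.csv"),
                 c("mean", "sd"))
    write_report(rbind(assoc$per_family, assoc$pooled),
                 file.path(out_dir, "association.csv"),
                 c("r_allele", "abs_r_allele", "r_class", "abs_r_class"))
    results$class_summary <- summ
    results$association <- assoc
  }

  manifest <- list(stage = stage, parameters = config, seed = seed,
                   package = "racecaps",
                   version = as.character(utils::packageVersion("racecaps")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(results)
}
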