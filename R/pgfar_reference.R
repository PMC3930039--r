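#' Synthetic surrogate of the pgfar cDNA reference panel
#'
#' A fully synthetic aligned cDNA panel that reproduces the *published
#' geometry* of the three pgfar CAPS assays, for offline testing and
#' demonstration: the real accession panel is not redistributed and is not
#' emulated base-by-base. The surrogate embeds, at the published cDNA
#' coordinates, the published primer footprints and diagnostic restriction
#' contexts, so that against it:
#' * the pgFAR-t primer pair amplifies a 150-bp product containing the
#'   G/T(857) SNP, with TaqI patterns 150 (pgfar-e) vs 118+32 (pgfar-z);
#' * the pgFAR-mn primer pair amplifies a single 145-bp product containing
#'   both the G/T(995) (NdeII, 83+62 when cut) and G/T(1005) (MseI, 93+52
#'   when cut) SNPs — the product reads antisense to cDNA numbering, the
#'   only orientation consistent with both published fragment patterns;
#' * `fixed_differences()` recovers exactly the three diagnostic SNPs with
#'   E alleles G857/T995/T1005 and Z alleles T857/G995/G1005.
#'
#' Everything outside these constrained features is seeded random fill,
#' scrubbed so no stray recognition site of the three assay enzymes
#' confounds the diagnostics. E-race records carry a 9-column gap
#' (columns 500-508), mirroring the length difference between the races'
#' coding regions and exercising gap handling; both races are internally
#' monomorphic. The reading frame starts at consensus position 1, placing
#' 857 and 995 at second and 1005 at third codon positions.
#'
#' @param n_e,n_z number of E- and Z-race records (defaults 10 and 11, a
#'   21-sequence panel).
#' @param seed integer seed for the random fill.
#' @return list with `panel` (an [aligned_panel()]), `cds` (`c(1, 1317)`),
#'   and `truth` (data.frame of the three planted SNPs).
#' @export
synthetic_pgfar_panel <- function(n_e = 10L, n_z = 11L, seed = 1L) {
  L <- 1607L
  primers <- pgfar_primers()
  tf <- primers[["pgFAR-t"]]$forward
  tr <- primers[["pgFAR-t"]]$reverse
  mnf <- primers[["pgFAR-mn"]]$forward
  mnr <- primers[["pgFAR-mn"]]$reverse
  mnr_concrete <- sub("W", "T", mnr)   # W resolved to T: A would plant an
                                       # internal MseI site the assay forbids
  with_seed(seed, {
    fill <- rand_bases(L)
    e <- fill; z <- fill
    fixed <- logical(L)
    put <- function(at, s) {
      idx <- at + seq_len(nchar(s)) - 1L
      both <- strsplit(s, "")[[1L]]
      e[idx] <<- both; z[idx] <<- both; fixed[idx] <<- TRUE
      invisible(NULL)
    }
    put(740L, tf)                       # forward footprint, sense
    put(870L, revcomp(tr))              # reverse footprint, sense
    put(858L, "CGA")                    # TaqI context: SNP completes TCGA
    put(914L, mnr_concrete)             # mn product is antisense to cDNA
    put(1038L, revcomp(mnf))
    put(993L, "GA"); put(996L, "C")     # NdeII context GA[T]C
    put(1004L, "T"); put(1006L, "AA")   # MseI context T[T]AA
    snps <- data.frame(position = c(857L, 995L, 1005L),
                       enzyme = c("TaqI", "NdeII", "MseI"),
                       allele_e = c("G", "T", "T"),
                       allele_z = c("T", "G", "G"),
                       race_cut = c("pgfar-z", "pgfar-e", "pgfar-e"),
                       stringsAsFactors = FALSE)
    e[snps$position] <- snps$allele_e
    z[snps$position] <- snps$allele_z
    fixed[snps$position] <- TRUE

    # stray recognition sites of the assay enzymes are scrubbed from the
    # random fill so only the designed contexts are cut / diagnostic
    allowed <- list(TaqI = list(e = c(741L), z = c(741L, 857L)),
                    NdeII = list(e = c(993L), z = integer(0)),
                    MseI = list(e = c(1004L), z = integer(0)))
    enzymes <- default_enzymes()
    for (iter in 1:200) {
      dirty <- FALSE
      for (enz in enzymes) {
        k <- nchar(enz$recognition)
        for (v in c("e", "z")) {
          seqv <- if (v == "e") e else z
          starts <- iupac_match_starts(enz$recognition,
                                       paste(seqv, collapse = ""))
          bad <- setdiff(starts, allowed[[enz$name]][[v]])
          for (s in bad) {
            foot <- s:(s + k - 1L)
            free <- foot[!fixed[foot]]
            if (!length(free))
              stop("stray ", enz$name, " site at ", s, " in fixed context")
            pos <- free[1L]
            repl <- setdiff(BASES, c(e[pos], z[pos]))[1L]
            e[pos] <- repl; z[pos] <- repl
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
    }

    gap_cols <- 500:508                 # E coding region is 9 bp shorter
    e_aln <- e; e_aln[gap_cols] <- "-"
    seqs <- c(replicate(n_e, paste(e_aln, collapse = "")),
              replicate(n_z, paste(z, collapse = "")))
    panel <- aligned_panel(seqs,
                           groups = c(rep("E", n_e), rep("Z", n_z)),
                           ids = c(sprintf("synE%02d", seq_len(n_e)),
                                   sprintf("synZ%02d", seq_len(n_z))))
    list(panel = panel, cds = c(1L, 1317L), truth = snps)
  })
}
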