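---
title: "Methods: race-diagnostic CAPS markers and hybrid-zone inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-diagnostic CAPS markers and hybrid-zone inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racecaps)
```

## The problem

The European corn borer *Ostrinia nubilalis* occurs as two pheromone
races: E-race females blend roughly 99:1 E:Z-Δ11-tetradecenyl acetate,
Z-race females roughly 3:97, and the ratio is controlled by the pheromone
gland fatty-acyl reductase locus *pgfar* with codominant alleles *pgfar-e*
and *pgfar-z*. Because the races are morphologically identical, measuring
hybridization in the field historically required gas-chromatography (GC)
analysis of dissected pheromone glands — impractical at population scale.
A molecular diagnostic changes that: SNPs fixed between the races inside
*pgfar*, each completing (or breaking) a restriction-enzyme palindrome,
can be assayed as CAPS (PCR-RFLP) markers on any light-trapped adult, and
the heterozygote frequency at such a marker is a direct estimate of the
hybridization frequency at a site.

`racecaps` implements that whole chain as testable code: alignment
diversity and divergence scans, CAPS marker design by in-silico PCR and
digestion, fragment-pattern genotype calling, genotype–phenotype
association, and the population genetics of the hybrid zone.

## Diversity statistics and the divergence scan

All distances are p-distances with pairwise deletion: a pair of sequences
is compared only at columns where both carry an unambiguous base, so gaps
and N never count as differences. Nucleotide diversity π is the mean
per-site pairwise difference over a column range; `distance_partitions()`
reports within-E, within-Z and between-race distances separately, since a
panel pooled across diverged races has a between-group component that
dwarfs the within-group ones.

Tajima's D is computed in its standard form,
$D = (\hat{k} - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$, with $\hat{k}$ the
mean pairwise difference count and $S$ the segregating-site count over
the range. When $S = 0$ the denominator vanishes and D is reported as
undefined (`NA`), never as 0; undefined windows are excluded from
flagging. The divergence scan uses 100-column windows advanced in
25-column steps — the resolution at which the *pgfar* divergence between
races was originally localized — with a plain numeric flagging cutoff of
D > 2. This is deliberately not a formal test: between-race balanced
divergence inflates D, and the cutoff simply marks where. Flagged windows
that share columns are merged into divergent regions. A terminal window
shorter than the full width is reported but marked truncated.

Windows start at columns 1, 26, 51, …; coordinates are 1-based inclusive
alignment columns everywhere, and cDNA positions (such as the diagnostic
SNPs at 857, 995, 1005) are positions in the ungapped panel consensus,
with `column_to_consensus()` / `consensus_to_column()` as the explicit
mapping. A BED-style export is provided as an explicit 0-based half-open
conversion, never silently.

Fixed differences require strict two-sided fixation: every E record one
base, every Z record a different single base, no gap or N in any labelled
record at the column, and at least two records per race. Synonymy is
annotated by translating each race's consensus codon — not by
substituting a single base into a shared codon — so a SNP that travels
with a second difference in the same codon is classified by the codons
the races actually carry.

## CAPS marker design

Marker design is purely combinatorial; no thermodynamics. Primer matching
is exact under IUPAC degeneracy (the `W` in pgFAR-mnr matches A or T,
with zero mismatches by default), both template orientations are
searched, and anything other than exactly one product is an error naming
the count. A SNP is a CAPS candidate for an enzyme when one allele
completes a recognition site covering the SNP, the other allele leaves no
covering site, and the rest of the recognition footprint is monomorphic
across the panel — so the cut is attributable to the diagnostic allele
alone. A SNP whose two alleles complete sites of the same enzyme is not
diagnostic and is never emitted.

Digestion scores top-strand cut positions (palindromic enzymes need one
strand; non-palindromic ones are scanned on both) and reports fragment
lengths that always sum to the amplicon length. One deliberate deviation
from a literal digest: recognition sites whose footprint starts within 3
bases of a fragment terminus are not scored by default. Restriction
endonucleases cleave end-proximal sites inefficiently, and the ≤2-bp
terminal fragments such cuts would yield are invisible on the 3% agarose
gels the assay is read on. The choice is forced by the assay itself: the
published TaqI forward primer contains a TCGA four bases into the
amplicon, yet the validated uncut product is the full 150 bp. With the
default `min_end_distance = 3` the package reproduces the published
fragment tables exactly; `min_end_distance = 0` restores the literal
digest.

### The synthetic reference panel

The real cDNA accession panel is not redistributed. Instead,
`synthetic_pgfar_panel()` builds a fully synthetic 21-record, 1607-column
panel that embeds the *published geometry* of the assays at the published
coordinates: primer footprints, the three diagnostic SNPs (E alleles
G857/T995/T1005, Z alleles T857/G995/G1005), and their enzyme contexts.
Two details of that geometry are themselves reconstructions. First, the
NdeII/MseI amplicon must read antisense to cDNA numbering: that is the
only orientation in which the published cut patterns (83+62 at the SNP
10 bp from 93+52) are simultaneously consistent. Second, the degenerate
`W` in pgFAR-mnr is fixed to T, because A would plant an internal MseI
site that contradicts the published uncut 145-bp product. Everything else
is seeded random fill, scrubbed of stray assay-enzyme sites. E records
carry a 9-column gap, mirroring the races' coding-length difference and
exercising gap handling. Against this surrogate the package reproduces
every published marker prediction (150 vs 118+32; 145 vs 83+62; 145 vs
93+52). Panel-wide diversity summaries of the real accessions (π, whole-
locus Tajima's D) depend on the real sequences and are *not* emulated or
asserted.

## Genotype calling

An observed gel pattern is compared as a band set against the marker's
expectations: the cut-allele pattern alone, the uncut pattern alone, or
the union (heterozygote). Band matching uses a ±5 bp default tolerance —
the sizing precision of a 50-bp ladder on a 3% gel — and anything
unresolvable is missing, never an error. The consensus across markers is
strict: all non-missing calls must agree, otherwise the individual is
`discordant` and reported with its full per-marker vector. A 2-of-3
majority rule exists but must be requested explicitly
(`resolve = "majority"`), because the study system itself produced five
females homozygous at the TaqI-assayed SNP but heterozygous at the other
two markers, and silently adjudicating such conflicts would hide exactly
the biology of interest. Discordant individuals carry no dosage and are
excluded from downstream population summaries by default. Genotype dosage
counts *pgfar-z* alleles / 2 (ZZ = 1, EZ = 0.5, EE = 0), with
`dosage_allele = "e"` flipping the orientation.

## Genotype–phenotype association

Phenotype classes follow the GC coding with closed boundaries: %E ≥ 90 is
class 1, ≤ 5 is class 3, everything between is class 2, and unreadable
chromatograms are unresolved (U). Two correlation codings are reported
side by side because the study's description is ambiguous between them:
(a) continuous %E against *pgfar-e* allele count 0/1/2, and (b) class
code 1/2/3 against dosage 0/0.5/1. Coding (a) is the package default
because it reproduces the published pooled r ≈ 0.97 under the published
class-conditional distributions; coding (b) equals ±1 exactly whenever
class and dosage are fully concordant (the codes are then affinely
related) and is attenuated otherwise — notably by Z-homozygote females
whose %E draws land just above the 5% class boundary. Both codings flip
an axis relative to %E (class 1 is the E phenotype; dosage 1 is the Z
homozygote), so their signed values agree and absolute values are
reported alongside. Per-family coefficients are combined as an unweighted
mean ± SD across families.

## Population genetics

Observed heterozygosity is the heterozygote frequency and doubles as the
hybridization-frequency estimate. Expected heterozygosity is Nei's
unbiased $\frac{2n}{2n-1} 2pq$; comparisons with printed tables are made
after rounding to 3 decimals.

The Hardy–Weinberg test is the exact conditional test. For one biallelic
locus the configurations compatible with the observed allele counts are
indexed by the heterozygote count alone, so full enumeration is feasible
for any realistic sample and is the package default; the enumerator
verifies on every call that its probabilities sum to 1, and the p-value
sums configurations no more probable than the observed one, ties
included. A Metropolis Markov-chain variant (`hwe_markov_chain()`)
mirrors the field's software tradition and is the extension point for
multi-allelic loci; it is tested for convergence against the enumerator.
Monomorphic samples are excluded from HWE testing (reported as such) but
retained in AMOVA, where they still carry information.

Because the three markers are in perfect linkage disequilibrium in the
survey data (identical genotype columns at every site), the package
treats them as a single effective locus by default.

`reconstruct_counts()` inverts printed summary rows (n, H~O~, H~E~) back
to integer genotype counts, requiring uniqueness up to allele-label swap.
The H~E~ match uses a ±0.0015 tolerance rather than strict 3-decimal
equality: printed tables occasionally carry a one-off in the final
decimal (one sympatric site prints 0.506 where the direct computation
gives 0.505), and the spec of the inversion must absorb exactly that.

Hierarchical F-statistics come from a three-level AMOVA on gene copies
(among regional groups, among populations within groups, within
populations split between and within individuals), with
unbalanced-design coefficients in the standard gene-copy formulation and
F-ratios from component sums. Significance uses seeded permutation, 1000
by default, with the scheme matched to each statistic's null: populations
among groups for F~CT~, individuals among populations within groups for
F~SC~, and alleles among individuals within populations for F~IS~ (the
within-population Hardy–Weinberg null; permuting whole individuals would
leave F~IS~ invariant). Pairwise differentiation is the two-population
Weir–Cockerham θ with whole-individual permutation. Permutation p-values
are $(\#\{perm \ge obs\} + 1)/(n_{perm} + 1)$ — tie-inclusive, hence
valid but conservative on a discrete null; `return_null = TRUE` exposes
the permuted values so the tie-randomized, exactly-uniform p can be
formed when calibration itself is under test. The Benjamini–Yekutieli
threshold $\alpha / \sum_{i=1}^m 1/i$ handles multiplicity across a
pairwise matrix.

Grouping for the hierarchical analysis follows the survey's printed
regional sets (Midwest sites 1–5 vs East Coast 7–16); whether the
intermediate site 6 joins a group is always the caller's explicit choice.

## What the generators emulate — and what they do not

`simulate_panel()` plants known structure (diagnostic SNPs inside enzyme
contexts, plain fixed differences outside them, an optional dense
divergent block) on a random ancestor and adds independent per-site
mutation noise at rate d/2 per sequence to hit a target within-group
distance in expectation. That star-shaped noise is exactly what detection
tests need (truth records score every call) but it is *not* a coalescent:
it produces a singleton excess and strongly negative Tajima's D. Null
calibration of D therefore uses `simulate_neutral_panel()`, a small
Hudson-style neutral coalescent (exponential coalescence times, Poisson
mutations on branches, infinite sites on finite columns), under which
mean D across replicates is near 0 and |D| > 2 is rare.

`simulate_population()` draws genotypes from inbreeding-adjusted
Hardy–Weinberg proportions $(q^2 + Fpq,\; 2pq(1-F),\; p^2 + Fpq)$ or
from an explicit two-deme admixture, under which the Wahlund heterozygote
deficit emerges without any F — the mechanism that makes pooled hybrid-
zone samples reject HWE. `simulate_phenotypes()` draws %E per genotype
class from normal distributions truncated to [0, 100] by inverse-CDF
sampling (proper truncated normals, not clamping, so no artificial point
mass at 0 or 100); defaults are the published class-conditional
estimates 98.02 ± 4.24, 67.58 ± 8.92 and 2.74 ± 6.24. Truncation shifts
the extreme class means inward (the Z class from 2.74 to about 6.1),
which is why the pooled simulated correlation averages ≈ 0.972 rather
than the untruncated closed-form 0.970 — a systematic offset far inside
the sampling noise of any single cohort. All generators are pure
functions of their arguments including the seed, and they restore the
caller's RNG state.

Passing tests on these generators show the machinery is correct under
the stated models; they do not certify behaviour under features real
data may add (genotyping error correlated across markers, gel-sizing
bias, population structure beyond two levels, selection within races).

## Problem sizes and numerical choices

The test suite and acceptance script run entirely from synthetic or
printed inputs at deliberately modest sizes, chosen to estimate each
quantity well: 200 phenotype cohorts of 244 females for the pooled
correlation; 150–200 replicates for coalescent D, Wahlund rejection and
permutation-uniformity checks; 40,000-step chains for Markov–exact HWE
agreement (Monte-Carlo tolerance 0.04); 60–100 replicates for θ and
inbreeding recovery, compared at 3 standard errors plus a small absolute
slack. Brute-force oracles (full enumeration of count triples,
direct-definition Tajima's D, closed-form chi-square) back every derived
expectation. Ties in enumeration p-values are compared with a relative
1e-12 guard; printed-value comparisons use the table's own 3-decimal
precision.

## Known limitations

* Single biallelic locus throughout popgen; the Markov-chain test is the
  designed extension point for multi-allelic data, but multi-locus
  haplotype inference, LD decay and coalescent estimation are out of
  scope.
* In-silico PCR is exact-match (optionally with a mismatch budget); no
  melting temperature, no amplification efficiency, no multi-product
  resolution.
* The synthetic reference panel reproduces assay geometry, not the real
  accessions' diversity; whole-locus π and D of the real panel are
  outside what this package can verify offline.
* The class-coded correlation is sensitive to the 5% class boundary
  interacting with the Z-class %E distribution; the continuous coding is
  the stable default.
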