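---
title: "Methods: quantifying selective mRNA splicing and export phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selective mRNA splicing and export phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrquant)
```

`ddrquant` re-implements, as tested and reusable functions, the
quantification procedures used to characterise RNA-processing factors that
selectively splice and export DNA-damage-response (DDR) transcripts:
nuclear/cytoplasmic (N/C) RNA-FISH ratio imaging, per-nucleus DNA-repair
focus scoring, two-channel splicing-reporter scoring, qRT-PCR
standard-curve quantification with splicing/export indices, transcript-set
filtering and overlap arithmetic, 3′-UTR k-mer over-representation, and
CDS codon arithmetic for nonsense variants.  No experimental data ship
with the package: every input is produced by a synthetic-data generator
that records its own ground truth, so each downstream stage can be tested
against known answers.  This vignette explains the models, the parameters
that matter, the numerical choices, and what the synthetic conditions do
and do not establish about real data.

## Imaging model

### Synthetic fields

A field of view is a pair (or triple) of numeric matrices on a 16-bit
intensity scale, `(row, col)` indexed (0-based in output tables).  Nuclei
are filled ellipses with jittered semi-axes, placed by rejection sampling
with a minimum centre separation that guarantees (i) nuclei never overlap
and (ii) no cell's cytoplasm covers another cell's nucleus.  The cytoplasm
of a cell is the Chebyshev annulus of `cytoplasm_extent_px` (default 36)
around its nucleus.  The signal channel is piecewise constant — background
outside cells, `signal_base` on cytoplasm, `signal_base × true ratio` on
the nucleus — so the noiseless per-cell N/C mean ratio over the
generator's own masks equals the spec ratio *exactly*, which is what makes
the generator usable as an oracle.  The only noise source is additive
Gaussian noise on a constant background; Poisson shot noise, point-spread
blur (other than on the DAPI channel, which is smoothed so segmentation
has realistic soft edges) and 3-D structure are deliberately not modelled.
Consequently, passing recovery tests demonstrates that the measurement
geometry and arithmetic are correct — not that segmentation or focus
detection would meet the same tolerances on real micrographs, where
texture, intensity gradients and out-of-focus light dominate the error
budget.

### Segmentation and the ring geometry

`segment_nuclei()` uses Gaussian smoothing (σ = 2 px), a global Otsu
threshold, hole filling, a minimum-area filter, and optionally a
distance-transform watershed to split touching nuclei.  The original
analysis used an in-house plugin whose parameters are not public, so no
claim of pixel-level agreement with the original masks is made; the
algorithm here is chosen to be standard and reproducible.

The measurement regions follow the published geometry: the nuclear region
is the nucleus *eroded by 2 px*, and the cytoplasmic region is a *30 px
wide ring surrounding the nucleus*.  Two conventions had to be fixed:

* "2 pixels subtracted from the perimeter" is implemented as binary
  erosion on the Chebyshev (8-connected, 3×3-square) metric, matching the
  default binary-erosion semantics of common image tools and keeping
  square-fixture arithmetic exact (a 20×20 square erodes to 16×16 = 256
  px).
* The ring starts after a 2 px gap *outside* the original nucleus
  boundary and extends 30 px: ring = pixels whose Chebyshev distance to
  the nucleus lies in `(gap, gap + width]`, with all nuclear pixels
  excluded and contested pixels assigned to the nearest nucleus (ties to
  the smaller label).  Whether the original ring began at the original or
  the shrunk boundary is ambiguous; the gap-outside convention is our
  declared choice and is configurable (`ring_gap_px`, `ring_width_px`).

Both operations are hand-written and verified pixel-for-pixel against
brute-force per-pixel oracles on fixtures up to 64×64.  Cells whose ring
band reaches the image border, whose nucleus vanishes under erosion, or
whose ring mean is not positive are flagged and excluded from condition
means by default.  No background subtraction is applied before the ratio
(none was applied originally); ratios are invariant under positive
rescaling of the signal channel.

### Focus scoring

No focus detector was published, so `score_foci()` declares one: a white
top-hat transform (grayscale opening with a disc of twice the expected
focus radius), a per-nucleus robust threshold (median + 5·MAD of the
top-hat signal inside the nucleus), and connected-component counting with
a minimum spot area of 2 px.  It is tested only against synthetic ground
truth, where planted counts are recovered exactly on high-contrast
fields.  Scoring uses the inclusive convention — a cell is positive when
it has **at least** `min_foci` (default 5) foci — because every quantified
figure in this assay family uses "≥ 5"; the threshold is configurable, and
the positive fraction is monotone non-increasing in it.

### Reporter ratios

`reporter_ratio()` measures per-cell mean intensities in two channels and
their ratio, excluding cells whose denominator mean falls below
`min_denominator` (untransfected cells).  The ratio is equivariant under
per-channel positive scalars.  `mean_nuclear_signal()` returns the mean of
per-nucleus means ± SEM, the readout of nuclear fluorescent
recombination-reporter assays.

## Transcript sets

`differential_cytoplasmic()` compares one knockdown against the control in
the cytoplasmic fraction: the fold-change is the ratio of mean abundances,
and the p-value is a two-sided two-sample t-test on log2 replicate values
with Benjamini–Hochberg adjustment (`bh_adjust()` delegates to the
standard step-up implementation and is property-tested against the
definition).  The filter retains genes down-regulated by more than
1.5-fold (`fold_change < 1/1.5`, strictness configurable) that pass the
significance rule: FDR-adjusted p < 0.01 for single knockdowns, with raw
p < 0.05 available as the double-knockdown rule — the two rules appear in
different statements of the published analysis and the choice is a
configuration switch.

**Choice of t-test.** The default is Student's pooled-variance test rather
than Welch.  Two reasons.  First, the only statistic named anywhere in
this assay family's quantification is "Student's two-tailed t-test", and
the package follows that convention throughout (`two_tailed_t()` defaults
to `student`; `welch` is available everywhere).  Second, with triplicate
groups the Welch–Satterthwaite degrees of freedom can fall to 2 regardless
of effect size, which places a hard floor on attainable p-values; under a
genome-scale FDR threshold of 0.01 this makes even huge, noiseless-in-
expectation effects undetectable.  The pooled test at df = 4 does not
suffer from this floor and is exact here because the generator gives both
groups the same replicate noise.  On real data with heteroscedastic
groups, Welch (or moderated-variance machinery, which is out of scope
because the module consumes pre-normalised tables) is the safer choice.

**Generator conditions.**  The planted-recovery experiment plants 100
genes at a true fold-change of 0.4 (2.5-fold down) among ~5000 nulls with
3 replicates per condition.  Replicate noise is Gaussian on the log2 scale
with s.d. 0.05 — the "low noise" regime of a well-normalised array
experiment with technical-quality replicates.  Under these conditions the
filter attains sensitivity ≈ 1 with an observed false-discovery proportion
of ≈ 0 across seeds.  Real biological replicates are noisier (0.2–0.5 on
log2) and would require either more replicates or moderated statistics to
reach comparable operating points; the experiment validates the filtering
arithmetic, not a power claim about any real study.

Overlap reports (`overlap_stats()`, `overlap_pct_from_counts()`) print the
intersection as a percent of the union, rounded half-up to one decimal to
match the printed-report style — note 191 shared genes out of sets of 849
and 749 give 191/1407 = 13.6 % of the union, which is how the published
percentage is reproduced.  `fraction_of_universe()` does the analogous
set-over-universe arithmetic (e.g. 2538/26501 = 9.6 %).

## Motif over-representation

The published motif analysis used PWM/EM discovery (MEME); this package
deliberately replaces it with a fully specified exhaustive k-mer scanner,
because an EM search is not oracle-testable and the acceptance surface
here is recovery of a planted exact consensus.  `scan_kmers()` counts, for
every width 8–20, the number of sequences containing each k-mer at least
once (ambiguity codes break windows), computes the expected count under an
order-0 background (`background_model()`, pseudocount 1 per base), and
scores each k-mer supported by ≥ 5 sequences with the one-sided binomial
tail of its sequence count.  Scores are computed on the log scale
(`pbinom(..., log.p = TRUE)`), so a motif present in all of 200 sequences
gets a finite score (~10²–10³) rather than underflowing to zero.

The per-sequence occurrence probability uses the independent-window
approximation `1 − (1 − p)^(L − k + 1)`.  An exact dynamic program over
the KMP prefix automaton serves as the test oracle: for
non-self-overlapping words the approximation is accurate to well below
0.1 %; for self-overlapping words (homopolymers) occurrences cluster and
the approximation *over*estimates the null probability, i.e. scoring is
conservative there.

Multiple testing uses Bonferroni with the family size equal to **every
distinct k-mer observed in the scan**, not just those passing the support
filter.  The support filter is a selection step; correcting only over the
selected k-mers understates the family and admits spurious hits on null
input, whereas the observed-k-mer family keeps null scans clean (no
significant hit in 10/10 seeded null runs) without costing the planted
consensus, whose tail probability is smaller by hundreds of orders of
magnitude.  Ties in score are broken lexicographically; significant hits
contained in a longer significant hit are annotated (`nested_in`), which
is how a 10-mer core relates to the 12-mer consensus when both surface.
Scanning is strand-specific: mRNA is single-stranded, so reverse
complements are never collapsed.

## qPCR quantification

`fit_standard_curve()` fits the in-run dilution series of each primer by
least squares (`Cq ~ log10 concentration`); the amplification efficiency
is `10^(−1/slope)`, so a perfect 10-fold series spaced by log2(10) ≈
3.3219 cycles yields efficiency 2.000.  `quantify()` inverts the curve;
`normalize_to_reference()` divides by the reference gene within the same
sample; `purity_check()` gates fractionation on the cytoplasmic/nuclear
ratio of a nuclear-retained marker transcript (default threshold 0.1,
configurable — none was published); `rt_minus_check()` fails any primer
whose RT-minus well amplified.  The proprietary instrument algorithm is
not reproduced; textbook standard-curve quantification is what its
description implies, and the noiseless generate→fit→quantify→normalise
chain recovers true relative concentrations to ≤ 10⁻⁶ relative error.
Technical replicates are averaged on the concentration scale by default
(the instrument convention was not published; Cq-scale averaging is
available, and the two differ by a Jensen gap).  All derived indices are
invariant under a common rescaling of every true concentration, as
relative quantification must be.

`splicing_export_indices()` assembles, per transcript and condition, the
reference-normalised pre-spliced (exon–intron) and post-spliced
(exon–exon) levels in each compartment and the N/C ratio of each splice
form; a missing compartment yields a flagged `NA` ratio rather than a
guess.

## Codon arithmetic

`codon_of()` maps a 1-based coding nucleotide position (A of ATG = 1) to
`codon_index = ⌊(pos − 1)/3⌋ + 1` and `position_in_codon`; positions 301
and 2509 map to codons 101 and 837, matching the R101*/R837* nonsense
nomenclature.  `annotate_substitution()` classifies substitutions via the
standard genetic code and reports, for nonsense changes, a
`truncated_length` of `codon_index − 1` residues — the stop *replaces* the
affected residue, so an R101* protein retains 100 residues.  Descriptions
elsewhere that count the mutated codon into the product length ("a 101 aa
protein") differ by exactly this off-by-one convention; the package states
its convention and keeps it.

## Statistics and reporting

`mean_sem()` uses the n−1 standard deviation and flags the SEM undefined
for n = 1.  `star_annotation()` implements the figure-legend tiers * p <
0.05, ** p < 0.005, *** p < 0.0005; the tier set is configurable because
some legends use ** p < 0.001 — the default follows the majority
convention.  No correction across assay panels is applied (none was
applied originally).  `surviving_fraction()` is
`(colonies/seeded)/plating efficiency`, so the untreated point of every
treatment arm is exactly 1 by self-normalisation.

## Pipeline, formats, and determinism

All I/O is plain: multi-page 16-bit TIFF for images and masks, CSV for
tables, FASTA for sequences, YAML for configuration, JSON for reports;
pixel coordinates are 0-based, CDS coordinates 1-based.  `run_pipeline()`
executes simulate → quantify → sets → motif → qpcr → annotate → report,
reading every stage's inputs from disk (so each format round-trips), and
writes a provenance record with the resolved configuration and its
checksum.  Seeded pseudo-random streams are part of the public interface:
identical spec + seed reproduce bit-identical images, tables and summary
files, and any stage failure halts with a stage-tagged error instead of a
partial result.  The numbered scripts under `analysis/` are thin drivers
over these stages.

## Problem sizes used by the test suite

The suite exercises the study conditions at desk scale, chosen once:
twenty seeded noiseless FISH fields of 50 cells each (896×896 px) plus
eight fields with Gaussian noise at 5 % of the nuclear signal for the
condition-mean check; ten seeded focus fields of 8 nuclei; twenty seeded
expression tables of 5100 genes; ten planted and ten null UTR sets of 200
× 300 nt; and 1000 random fixtures for the statistical oracles.  Morphology
oracles run exhaustively on fixtures up to 64×64, where per-pixel
brute-force checks are cheap.

## Known limitations

* Synthetic imaging omits shot noise, PSF blur, uneven illumination and
  3-D structure; absolute agreement with the original plugin's figure
  values is not claimable (its parameters are unknown).
* The k-mer scanner finds exact consensus words, not degenerate PWMs; it
  will fragment a strongly degenerate motif into several related hits.
* The expression module consumes already-normalised tables; array
  preprocessing, probe mapping and moderated statistics are out of scope.
* The qPCR module starts from Cq values; raw amplification-curve and
  melt-curve processing are out of scope, as is the ΔΔCq method (not used
  here).
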