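---
title: "Chromatin fragment size and ChIP-seq quality: models and methods"
author: "sonichip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin fragment size and ChIP-seq quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonichip)
```

## The problem

Sonication of fixed chromatin is one of the few fully user-controlled
steps of a ChIP-seq experiment, and the average length of the sheared,
*unenriched* chromatin is strongly associated with whether the
experiment succeeds.  Over-shearing (very short fragments) destroys
binding sites and degrades experiments for every factor; the effect of
under-shearing (long fragments) is factor-specific — CTCF-class targets
tolerate long chromatin, while TAL1-class targets lose enrichment,
plausibly because their epitopes are increasingly sequestered inside
long fragments.  Chromatin averaging 200–250 bp gives the highest
frequency of success for sequence-specific factors.

`sonichip` implements the full analysis chain around that observation:
fragment sizing from electropherogram traces, the sonication decay
model, strand cross-correlation metrics (NSC/RSC), FRiP and FRiP-hc,
motif-based direct/indirect peak classification, metapeak profiling,
and rule-based assessment — plus a generative simulator of the
mechanism so that every stage can be validated offline.

## Measuring chromatin length

`average_fragment_length()` computes the intensity-weighted mean
fragment size of an electropherogram within an inclusive window,
100–500 bp by default.  Material outside the window — notably large
molecular-weight heterochromatin — is excluded entirely rather than
down-weighted, so it cannot skew the average; fragments outside this
range are also unlikely to be sequenced on short-read platforms.

Bioanalyzer-style fluorescence is proportional to DNA *mass*, so the
default weighting treats intensity as mass.  Whether an instrument's
own "region average" is mass- or molarity-weighted varies by export and
setting, so a `weighting = "molar"` switch divides intensity by size
first (recovering the fragment-count mean).  On simulated traces the
two differ by the factor `1 + cv^2` of the length distribution —
about 9 bp at a 250 bp mean with cv 0.15 — which is worth knowing when
comparing numbers across instruments.

## The sonication decay model

Average fragment length decays exponentially with cycle number towards
an asymptote:

$$L(c, n) = L_\infty + (L_0\,g(n) - L_\infty)\,e^{-k c / g(n)},
\qquad g(n) = (n / n_{\mathrm{ref}})^{\gamma}.$$

* `L0` (default 1500 bp): effective unsheared size at the reference
  cell count.  Chromatin entering sonication is much longer, but the
  first cycles fragment it very rapidly; `L0` is the effective
  intercept of the exponential regime in the 100–500 bp measurement
  window.
* `Linf` (default 150 bp): asymptotic size — continued sonication
  cannot shear protected/nucleosomal chromatin much below this.
* `k` (default 0.15 per cycle): decay rate.
* `cell_factor` γ (default 0.35), `n_ref` (2×10⁷ cells): samples with
  more cells shear more slowly, so at fixed cycles more cells mean
  longer chromatin.  The power-law factor is the simplest monotone map
  with that property; the observation it encodes is qualitative
  (ordering), not a calibrated physical law.

These defaults are plausible bench-scale values chosen once for the
simulator; real instruments, fixation chemistry and cell types shift
all of them, which is why `fit_decay()` exists: it estimates
$(L_\infty, A, k)$ per cell-count group from measured
(cycles, average length) points by nonlinear least squares
(Levenberg–Marquardt), optionally with a shared asymptote, and
`cycles_for_target()` inverts the fitted curve to the smallest integer
cycle count reaching a target size — the planning question a bench
scientist actually asks.  Fits need at least three distinct cycle
values per group; starting values come from a log-linear regression on
the range-shifted lengths, so convergence is robust on
noiseless-to-moderately-noisy data.

## Strand cross-correlation, NSC and RSC

`strand_cc_profile()` correlates per-position forward-strand 5′-end
counts with reverse-strand counts shifted left by $d$, for
$d = 0 \ldots$ `max_shift`, chromosome by chromosome, pooling the
per-shift sufficient statistics so no cross-chromosome position pairs
form.  `nsc_rsc()` then locates two peaks: the fragment-length peak and
the "phantom" peak at the read length, excluded by a ±10 bp zone
(configurable) when searching for the fragment peak.  With `ccmin` the
profile minimum:

$$\mathrm{NSC} = \frac{cc_{\mathrm{frag}}}{cc_{\min}},\qquad
\mathrm{RSC} = \frac{cc_{\mathrm{frag}} - cc_{\min}}
                    {cc_{\mathrm{phantom}} - cc_{\min}}.$$

RSC uses the background-subtracted form throughout: a plain ratio of
raw correlations cannot reproduce the familiar RSC ≈ 2 scale of clean
transcription-factor data, and the subtracted form is the standard
definition in the quality-metrics literature this package follows.
RSC > 0.8 is the conventional success floor; clean TF datasets
typically fall between 1.5 and 2.5.

Two numerical choices matter.  First, peak *location* is read from a
running-mean smoothed copy of the profile (half-width 15 bp by
default): the fragment peak is broad, and the argmax of the raw
profile wobbles by tens of bp under sampling noise, while smoothing
holds the estimate within about ±15 bp of truth at the read depths
used here; reported correlation *values* always come from the raw
profile, with plateau ties resolved by the raw maximum so that sharp
synthetic spikes are located exactly.  Second, on the small, perfectly
uniform genomes the simulator builds, the background correlation at
irrelevant shifts fluctuates around zero and `ccmin` can be ≤ 0; NSC
is then reported with a diagnostic rather than clamped.  Real genomes
give positive background correlation (coverage structure, mappability)
and well-behaved NSC; this is a small-genome artifact, and it is one
reason assessment rules here use RSC — whose subtracted form is immune
— and not NSC, matching the observation that NSC does not separate
good from bad experiments consistently.  Duplicate reads are retained.

## FRiP and FRiP-hc

`frip()` is the fraction of mapped reads whose interval overlaps any
peak by ≥ 1 bp, after merging peaks so overlapping calls cannot
double-count; a `five_prime` containment rule is available as a
config switch.  `frip_hc()` composes `frip()` with `overlap_peaks()`:
FRiP over only those of the dataset's peaks that overlap a
high-confidence reference set, which makes enrichment comparable
across datasets with very different peak counts.  The conventional 1%
FRiP guideline for sequence-specific TFs is drawn on report figures
and anchors the assessment rule; it is not meaningful for factors with
very few (or exceptionally many) occupied sites.

`call_peaks_simple()` exists so synthetic end-to-end runs can exercise
peak-dependent metrics: fragment-center estimates are counted in
non-overlapping windows and tested against Poisson(λ), with λ the
larger of the genome-wide rate and a depth-scaled control-window rate,
and adjacent significant windows merged.  It is deliberately minimal
and makes no claim to match production callers' peak counts — those
depend on model-building and parameter choices that published peak
counts rarely pin down.

## Motif scanning with exact p-value thresholds

Peaks are classified as direct (≥ 1 significant motif match anywhere in
the peak, both strands scanned) or indirect, at a per-position-strand
p-value cutoff of 10⁻⁴ — the conventional scanning threshold.  The
threshold-from-p-value computation is exact: the null distribution of
the total log-odds score of a background-distributed word is built by
dynamic programming over floor-discretized per-position scores
(10⁴ bins over the total score range by default).  Scanning reuses the
same discretized matrix for hit selection, so the realized type-I rate
is provably ≤ α; the floor binning makes reported p-values
conservative, never anti-conservative, and for every motif of width
≤ 6 the DP reproduces exhaustive enumeration to within the bin width.
If even the best achievable word has null probability above α (short
or weak motifs), the threshold is reported as unattainable and the
scan returns zero hits rather than silently passing everything.

Background defaults to uniform 0.25 per base — the near-uniform
background shipped in common motif-database exports — with a
constructor for sequence-estimated zero-order backgrounds.  Count
matrices get a pseudocount of 10⁻⁴ of the position total before
normalization.  Per-peak significance is "any single position-level
hit", with no multiple-testing correction across positions: that is
the established usage this analysis mirrors, and peaks are scanned
over their full reported interval without summit trimming.  Ambiguous
bases score −∞ at their position.

## Metapeak profiles

`signal_matrix()` centers a ±1000 bp window (default) on each peak
interval's midpoint, bins it at 10 bp, and fills cells with summed
read coverage, optionally after extending reads to the estimated
fragment length from the cross-correlation step — the usual ChIP-seq
signal convention.  Windows clipped at chromosome ends are zero-padded
and flagged.  `zscore_normalize()` standardizes all cells of a
dataset's matrix (global scope) by default; per-row scope is available
since the appropriate scope for cross-dataset figures is genuinely
ambiguous.  `aggregate_profile()` gives per-class (with/without motif)
bin means, and `render_heatmap()` orders rows by decreasing total
signal within class with a deterministic lexicographic tie-break, so
re-renders are byte-identical.

## Assessment and binned testing

The subjective pass/low-pass/fail calls of real studies are codified
in `assess()` as an explicit heuristic: **Fail** when FRiP < 1%;
otherwise **Pass** when RSC lies in [1.5, 2.5] and average chromatin
length in [190, 290] bp (criteria whose metric is missing are skipped
and noted); otherwise **LowPass**.  The POL2-class rule omits RSC — no
consistent RSC trend separates good from bad polymerase datasets — and
bounds size only above (< 290 bp).  `bin_and_test()` bins datasets by
chromatin length (`<200`, `200–250`, `>250` bp for TF-class factors;
`<290`, `≥290` for POL2-class; ties at the first edge go up, at later
edges down, matching those labels) and compares FRiP between adjacent
bins with equal-variance Student's t-tests — Welch's form is a flag —
reporting raw p-values without multiple-testing correction.  Adjacent
pairs are the default because the scientific contrasts of interest are
neighbouring size ranges; an all-pairs flag exists.

## The simulator: what it emulates, and what it does not

`simulate_chip_reads()` implements the mechanism under study as a
generative model:

* **Fragments** are log-normal in length (positive support and a right
  tail consistent with real trace shapes; the field reports no
  canonical law), truncated below at the read length.
* **Signal vs background**: each read's fragment is background
  (uniform placement) with probability `background_fraction`, else it
  covers a binding site (site chosen by relative strength; the site
  center falls uniformly within the fragment).
* **IP efficiency** is where fragment length couples to quality
  (`ip_profile()`): a site-bearing fragment is recovered with a
  logistic occlusion probability that decays above a factor-specific
  midpoint (300 bp TAL1-like — sensitive; effectively off for
  CTCF-like; 450 bp POL2-like), and any fragment shorter than
  `min_len` = 170 bp is lost outright — a fragment shorter than the
  protein's footprint no longer carries an intact site, which is what
  makes over-sonication fail for *every* factor.  A rejected signal
  fragment is replaced by a background fragment: sequencing depth is
  fixed, so length-dependent IP efficiency shows up as reduced
  enrichment, exactly as in the data the model emulates.  The
  occlusion midpoints and `min_len` are stated assumptions — the
  mechanism is a published conjecture, not a measured curve — chosen
  once to place failures below ~190 bp and TAL1-like failures above
  ~250 bp.
* **Reads**: each accepted fragment emits one single-end read from a
  uniformly chosen end (forward at the fragment start, or reverse with
  its 5′ end at the fragment end), which is what creates the
  strand-separated 5′-end pattern that cross-correlation measures.
* **Electropherograms** are histograms of the pre-IP fragment lengths
  with mass-proportional intensity and optional clipped Gaussian
  noise, so the trace is consistent with the chromatin the reads came
  from.

`simulate_experiment_grid()` builds one genome with embedded truth
sites per factor profile (90 direct, 60 indirect sites on 300 kb by
default — a direct fraction between the ~97% of CTCF and ~58% of TAL1
peak sets), then one dataset per scenario row (20 000 reads of 36 bp,
70% background, fragment sd 50 bp by default), with the achieved mean
fragment length given directly or predicted from cycles and cell count
through the decay model.  Every stochastic step is seeded and
reproducible.

Deliberately *not* modelled: sequencing errors and quality scores,
duplicates, mappability and repeat structure, GC bias, paired-end
reads, and sonicator physics (including the acoustic-wavelength effect
at very low cell numbers).  Consequently, passing the simulator-based
checks demonstrates internal consistency of the estimators and the
qualitative mechanism — not calibration against any particular
instrument or genome; in particular the uniform small genomes make
absolute peak counts, NSC values and FRiP magnitudes incomparable to
mammalian-scale data.

## Problem sizes and reproducibility

The test-suite and acceptance computations use 150–300 kb genomes,
5 000–25 000 reads per dataset, six replicates per chromatin-size
level, five seeds for recovery checks, and 10⁶ bp for scanner
calibration — sizes at which every check's statistical power is
adequate and a full run stays comfortably interactive.  The
`scripts/acceptance.R` entry point re-derives all headline numbers
from scratch from a single master seed.

The one check that cannot run self-contained is the integration
comparison against the published ENCODE/HOCOMOCO motif-split counts
(25 984 / 2 651 for the CTCF high-confidence set — note these sum to
28 635, one short of the set's stated 28 636 records, a discrepancy in
the published counts themselves that we surface rather than absorb —
and 1 783 / 1 550 for TAL1): it needs the mm10 genome, the ENCODE bed
files and HOCOMOCO v11 matrices as local downloads, and the
corresponding test states exactly which files it wants and where
(`options(sonichip.reference_dir = ...)`).

## Known limitations

* The assessment rule is a codified heuristic; it reproduces the
  anchored examples but cannot capture the judgment calls of visual
  track inspection, and its FRiP floor is inappropriate for factors
  with very few occupied sites.
* `fit_decay()` treats the cell-count groups as separate fits (with an
  optional shared asymptote); it does not estimate the cell-factor
  exponent γ jointly, since two or three group levels cannot
  identify it.
* The internal peak caller is a calibration-grade stand-in; peak
  *counts* from it should never be compared with production callers.
* FIMO-compatibility of the motif stage is to the documented scanning
  convention (p < 10⁻⁴, both strands, zero-order background), not to
  any specific FIMO version's defaults for priors or q-values.
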