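---
title: "Detecting metabolic subpopulations by differential isotope labelling"
author: "dilac authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metabolic subpopulations by differential isotope labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilac)
```

## The problem and the model

Microbial populations can divide labour metabolically: some cells
synthesise an amino acid (producers) while others import it from the
environment (consumers). Bulk measurements of label incorporation cannot
distinguish this from a homogeneous population in which every cell does
a bit of both — the population-average import fraction is the same.

The method implemented here resolves the two scenarios with peptides
that carry **two (or three) copies of one amino acid** — by default
lysine. Cells grow on fully ¹³C-labelled glucose with unlabelled
(¹²C) lysine supplied in the medium, so a residue synthesised de novo is
heavy and an imported residue is light. If a single cell imports each
residue independently with probability $P$, the number $k$ of imported
residues per two-lysine peptide follows a binomial law,

$$ r_k = \binom{n}{k} P^k (1-P)^{\,n-k}, \qquad k = 0, \dots, n , $$

so at $P = 1/2$ the mixed state ($k = 1$, one heavy and one light
residue) is exactly twice as abundant as either pure state. If instead
the population splits into distinct producers ($P \approx 0$) and
consumers ($P \approx 1$), peptides are almost always uniformly
labelled and the mixed states are depleted. The package's
`depletion_test()` estimates $P$ from the observed state fractions
($\hat P = \sum_k k f_k / n$), computes the binomial expectation, and
reports the **depletion ratio** expected-mixed / observed-mixed. For
the colony condition whose observed profile is (producer, mixed,
consumer) = (0.300, 0.150, 0.550), $\hat P = 0.625$, the expected mixed
fraction is $2 \hat P (1-\hat P) = 0.469$ and the ratio is $3.1$:

```{r headline}
depletion_test(c(0.30, 0.15, 0.55))
```

The detection is deliberately ratio-based; to make verdicts
reproducible the test adds a declared threshold (default ratio > 2
calls "heterogeneous") and an optional chi-square goodness-of-fit
against the fitted binomial (df $= n - 1$) when the caller supplies an
effective observation count `m`. Fractions alone carry no sample size,
so without `m` the output is ratio-only. Both knobs are reported
alongside the raw numbers, never instead of them.

## The isotope mass model

All masses are monoisotopic and derive from a shipped plain-text residue
composition table plus CODATA element masses; the
¹³C–¹²C difference is fixed at 1.0033548378 Da. A
`label_scheme()` names one *target* residue (variable label, per-site)
and a set of *fixed-labelled* residues (all carbons heavy wherever they
occur); the default scheme models ¹³C-glucose growth: every residue
except lysine fixed-heavy, lysine variable. Peptide, free-amino-acid
and y/b fragment masses follow the standard conventions (y: C-terminal
chain + water; b: bare N-terminal chain; ions singly protonated per
charge). Nominal m/z uses round-half-away-from-zero and is only used
for MRM-style transition tables; the free-lysine check reproduces the
147→84 (unlabelled) and 153→89 (labelled) transitions:

```{r lysine}
free_lysine_transitions()
```

Carbamidomethyl-cysteine and other derivatisation carbons are never
labelled (the label enters by biosynthesis, not chemistry); a custom
scheme can be supplied where that assumption is wrong.

## Candidate peptides and fragment specificity

`digest()` performs in-silico proteolysis (gluC after E by default,
optionally E+D; trypsin after K/R, optional proline suppression — off by
default). `select_candidates()` keeps peptides with exactly the
required number of target residues and no cysteine/methionine, and
marks a peptide proteotypic when its sequence occurs in exactly one
protein (exact substring counting; I/L ambiguity is ignored and
documented as such). The geometry score prefers target sites far apart
with the last one near the C terminus — the configuration that
maximises the number of fragments covering exactly one site — via
`separation/(L-1) + 1 - dist_C/(L-1)`. Only the ordering of scores is
meaningful; abundance and identification-consistency criteria require
measured data and are left to the caller as optional ranking inputs.

The two mixed states of a two-lysine peptide share a precursor mass, so
they are resolved at the fragment level: a y or b ion covering exactly
one target site is mass-unique to that site's labelling state
(`fragment_specificity()`). Quantification uses only such diagnostic
fragments, retains the top three by mean abundance rank across all
samples (average ranks within ties; lexicographic fragment name at the
cut), normalises state areas per fragment first, and then averages
unweighted across fragments, peptides and replicates, reporting the
s.d. at the replicate level. Unweighted means are used at every level
because no weighting is defensible without an error model for the
upstream integration. A state absent from a fragment's rows is treated
as area 0 with a warning (configurable to dropping the fragment).
Precursor-level (MS1) profiles use the same cascade over the $n+1$ mass
states, with the two single-site mixed states inherently merged.

## Proteome deconvolution from heavy/light pairs

With a single C-terminal target residue per (tryptic) peptide, producer-
and consumer-derived molecules form a heavy/light precursor pair in a
DIA report. The pipeline keeps proteotypic precursors with exactly one
lysine at the C terminus and `Quantity.Quality` strictly above 0.7,
pairs records by (run, stripped sequence, charge) — requiring exactly
one record per side — and computes the heavy/light ratio. Per-sample QC
excludes runs with fewer than half the cohort-median pair count or a
log2 median ratio more than 1 from the cohort median (declared defaults
behind a narrative description of outlier removal). Ratios are divided
by the sample median and log2-transformed, tested per precursor against
0 with a two-sided one-sample t-test (precursors in ≥ 3 runs),
BH-corrected once across all tested precursors, and aggregated per
gene: a hit needs at least one significant precursor, |mean of
per-precursor median log2 FC| > 0.75, and sign concordance across all
its precursors. Pairs with a zero or missing side are excluded, not
imputed. Zero-variance precursors with nonzero mean are reported as
p = 0 with a degeneracy flag rather than dropped.

## Spectral-library relabelling

`relabel_library()` rewrites an OpenSWATH-style long-format library to
the differential labelling state: precursors outside charge {2, 3} or
length 7–30 are dropped; every retained precursor is expanded into its
heavy/light target variants; precursor and fragment m/z are recomputed
from the mass model; modified sequences carry bracketed mass deltas at
four decimals; retention-time columns pass through untouched (labels of
type "label" do not shift retention). `ExcludeFromAssay` is set by the
general rule — exclude any fragment not covering exactly one target
site — which for C-terminal-target tryptic peptides reduces exactly to
"b excluded, y included".

## The population simulator

`sim_config()` fixes the study conditions the analysis modules are
validated against. Defaults are chosen to mirror the colony experiment
the method was developed on: a two-point producer/consumer mixture with
producer fraction 0.375 (reproducing an overall imported-residue
fraction of 0.625), two biological replicates for transition reports
and six runs for DIA reports, five two-lysine peptides,
log-normal intensity noise with $\sigma = 0.2$ (natural-log scale,
≈ 20 % CV — typical for targeted peak areas), $10^4$ cells and
100 molecules per rate-1 cell. Producers are modelled as site-heavy
(import probability 0) because ¹³C glucose feeds synthesis.
Synthesis-rate multipliers weight each subpopulation's contribution to
bulk signal, reproducing the caveat that labelling ratios quantify
signal shares, not cell numbers: at $f = 0.5$ with a consumer rate
multiplier of 2 the consumer signal share is $2/3$, not $1/2$.
Fragment response factors are drawn once per fragment (log-normal,
s.d. 0.5) so top-3 ranking is non-trivial. Generated peptides keep
their target sites at least two residues apart, with one at the C
terminus — the same geometry the candidate scorer rewards — because
adjacent sites admit no single-site fragment and would be flagged
unquantifiable rather than measured, which is not how peptides are
chosen in practice. Beta-mixture populations are
available for gradual heterogeneity, with state expectations computed
in closed form from Beta moments.

What the simulator does *not* emulate: chromatographic interference,
missingness correlated with abundance, isotopic envelope overlap,
retention-time drift, and search-engine scoring artefacts. Passing
recovery tests therefore demonstrates correctness of the statistical
pipeline, not robustness to every failure mode of real acquisitions.

## Numerical choices and test scale

Profile fractions must sum to 1 within $10^{-6}$ and are renormalised
after noise; observed-mixed = 0 yields an `Inf` depletion ratio with a
degeneracy flag rather than an error; rank ties use average ranks with
lexicographic tie-break at the cut; BH is applied once per analysis.
Validation sizes were picked to make Monte-Carlo checks sharp yet
quick: binomial round-trips on a 101-point $P$ grid at $10^{-12}$;
noisy round-trip recovery over 20 seeds compared at 3 standard errors;
population-law checks at $10^4$ cells (homogeneous depletion ratio
within 5 % of 1; two-point mixed fraction below 1 %); gene-recovery
calibration pooled across the 30 simulated genes (3 seeds × 6 runs),
with sensitivity ≥ 0.9 required at |log2 FC| = 1.5. Pooling the
gene-level calibration (rather than testing each gene against its own
3-precursor standard error) is deliberate: a d.f.-2 variance estimate
is too unstable to standardise against.

## Known limitations

Gradual subpopulation structure (Beta-distributed import) depresses but
does not abolish mixed states; the depletion ratio detects it weakly
and the package makes no attempt to deconvolute Beta components
parametrically. Manual integration review has no algorithmic
counterpart. Identification counts and pair counts per run depend on
upstream search settings and are reported, not asserted.
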