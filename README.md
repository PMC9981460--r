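# dilac

Detection and deconvolution of metabolic producer/consumer
subpopulations from differential stable-isotope incorporation into
peptides.

## The scientific problem

When microbes grow on fully ¹³C-labelled glucose with an unlabelled
amino acid (lysine by default) supplied in the medium, every residue of
that amino acid in every protein records a decision: synthesised de
novo (heavy) or imported (light). A bulk import fraction *P* is
compatible with two very different populations — homogeneous cells that
each import a fraction *P* of their residues, or distinct **producer**
(*P* ≈ 0) and **consumer** (*P* ≈ 1) subpopulations.

Peptides carrying *n* = 2 (or 3) copies of the amino acid distinguish
the two. Under homogeneity the number *k* of imported residues per
peptide is binomial,

    r_k = C(n, k) · P^k · (1 − P)^(n−k),

so at *P* = 0.5 the mixed state (one heavy, one light residue) is twice
as abundant as either pure state. Distinct subpopulations deplete the
mixed states instead. The package quantifies this as a **depletion
ratio** (expected mixed / observed mixed) with a reproducible verdict,
and — because producer- and consumer-derived peptides differ in mass —
deconvolutes the two subpopulations' proteomes from bulk DIA
measurements via heavy/light precursor pairs, one-sample t-tests with
Benjamini–Hochberg correction, and gene-level hit rules.

Modules: isotope mass model under per-residue ¹³C labelling · in-silico
digestion and candidate selection · fragment-specific labelling-state
quantification · binomial heterogeneity test · heavy/light
deconvolution · spectral-library relabelling · a seeded population
simulator emitting the same report formats · a CLI
(`inst/cli/dilac.R`).

## Worked example

The headline colony analysis: an observed labelling-state profile of
(producer, mixed, consumer) = (0.30, 0.15, 0.55) for two-lysine
peptides.

```r
library(dilac)
depletion_test(c(0.30, 0.15, 0.55))
#> Mixed-state depletion test
#>   import probability P = 0.6250
#>   mixed fraction: expected 0.4688, observed 0.1500
#>   depletion ratio = 3.125
#>   verdict: heterogeneous
```

The overall import fraction is 62.5%, so a homogeneous population would
show 46.9% mixed-labelling peptides; the observed 15.0% is 3.1-fold
lower — single cells either produce or consume, they do not mix.

The same analysis end-to-end from simulated instrument data — a
two-point population (37.5% producers), log-normal noise, five
two-lysine peptides, two replicates — through the fragment-level
quantifier:

```r
cfg <- sim_config(model = "two_point", f_producer = 0.375,
                  sigma = 0.2, seed = 42)
sim  <- write_transition_report(cfg)
prof <- state_fractions(sim$report)
prof
#> Labelling-state profile (2 target sites)
#>  condition k state_class  fraction         sd
#>        sim 0    producer 0.3690000 0.01724862
#>        sim 1       mixed 0.0000000 0.00000000
#>        sim 2    consumer 0.6310001 0.01724862
depletion_test(prof)
#> Mixed-state depletion test
#>   import probability P = 0.6310
#>   mixed fraction: expected 0.4657, observed 0.0000
#>   depletion ratio = Inf (no mixed signal observed)
#>   verdict: heterogeneous
```

A true producer/consumer mixture yields no mixed-state signal: the
recovered producer fraction (0.369 ± 0.017) matches the simulated
0.375, and the depletion ratio diverges.

The same pipeline from a shell:

```sh
Rscript inst/cli/dilac.R simulate --out-dir sim --seed 5
Rscript inst/cli/dilac.R quantify-states --report sim/transitions.csv \
        --out sim/profile.tsv
Rscript inst/cli/dilac.R test-heterogeneity --profiles sim/profile.tsv \
        --out sim/verdict.tsv
```

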