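# doseimpact

Dose-response analytics for isothermal thermal proteome profiling
(ITDR-TPP) and phosphoproteomics, built for kinase-inhibitor target
deconvolution.

## The problem

In an ITDR-TPP experiment cells are treated with a compound across a dose
ladder (here a 9-dose ladder from 0 to 10 µM) at two temperatures: 37 °C,
where the soluble protein fraction reflects constitutive abundance, and a
heat challenge (52 °C), where it reflects thermal stability and hence
ligand binding. In parallel, enriched phosphopeptides report signalling
changes. Each protein or phosphosite yields a dose-response trace of
reporter intensities, normalized to fold changes relative to the untreated
dose.

Many genuine drug responses are not sigmoidal, so `doseimpact` does not fit
sigmoid models or gate hits on R². Instead every curve is smoothed with a
Gaussian (Nadaraya–Watson) kernel on ordinal dose positions
*x* = 1, …, *n*:

    d_k  = (x_k − x_i) / b
    wt_k = exp(−d_k² / 2) / √(2π)
    ŷ_i  = Σ_k wt_k y_k / Σ_k wt_k

and summarised by its **average slope** — the mean tangent between adjacent
fitted points — plus run-length statistics of the fitted curve. Phosphosite
curves are classified with four user-set thresholds (defaults T = 0.3,
C = 5, B = 3, E = 0.45):

1. fitted range ≤ T → **non-responsive (NR)**;
2. upward and downward runs both long enough and ends within E × range →
   **biphasic**;
3. positive slope with upward run ≥ B → **hyper-phosphorylation**;
4. negative slope with downward run ≥ C → **hypo-phosphorylation**;
5. otherwise NR.

A site gets a responsive final call only when both biological replicates
agree; its summary slope is always the replicate mean. Proteins are placed
on the **proteome impact** map (mean slope at 37 °C vs 52 °C) and flagged
as hits when either slope exceeds 0.5 in magnitude; hit lists can be tested
for gene-set over-representation with the upper-tail hypergeometric
probability.

A synthetic-data generator emits datasets in the same MaxQuant-like table
schema with known ground-truth labels, so the whole pipeline is testable
without raw mass-spectrometry data.

## Worked example

```r
library(doseimpact)

# one synthetic experiment: 50 sites per response pattern, 5% noise
spec  <- synth_spec(n_per_category = c(hyper = 50, hypo = 50,
                                       biphasic = 50, flat = 50),
                    noise_sigma = 0.05, seed = 42)
d     <- make_dataset(spec)
cfg   <- run_config()                      # b=1, T=0.3, C=5, B=3, E=0.45
sites <- read_site_table(d$site_table, spec$design)
res   <- analyze_phospho(sites, cfg)
res
#> Phospho-response analysis: 200 sites
#>    hyper     hypo biphasic       NR
#>       50       50       50       50
```

All 200 generated labels are recovered. Single curves are ordinary model
objects:

```r
tr  <- normalize_first_dose(dose_trace(c(100, 104, 112, 125, 141,
                                         155, 163, 168, 170)))
fit <- fit_dose_curve(tr, cfg)
fit
#> Gaussian-kernel dose-response fit
#>   9 dose positions, bandwidth b = 1
#>   average slope: 0.08274 (fold change per dose position)
#>   fitted range: 0.6619; end difference: 0.6619
#>   longest runs: 8 up, 0 down
classify_curve(fit, cfg)
#> [1] "hyper"
```

The fitted range (0.66) exceeds T = 0.3 and the curve rises through all 8
adjacent intervals, so the site is called hyper-phosphorylated with a mean
gain of 0.083 fold-change units per dose step. The protein arm works the
same way:

```r
prot <- analyze_proteome(read_protein_table(d$protein_table, spec$design), cfg)
prot
#> Proteome impact analysis: 48 proteins,  24 hit(s)
head(prot$impact[prot$impact$is_hit, c("protein_id", "slope_37", "slope_52")], 3)
#>   protein_id     slope_37 slope_52
#> 1   PROT0001  0.009648792 0.640240
#> 2   PROT0002 -0.001586042 0.598521
#> 3   PROT0003  0.003679602 0.665216
```

The hits are the thermally stabilized and abundance-responsive proteins:
near-zero abundance slope with a 52 °C slope above 0.5, or vice versa.
`plot_proteome_impact()`, `plot_phospho_response()` and
`plot_curve_panel()` draw the corresponding figures;
`hypergeom_enrichment()` tests hit lists against gene sets. A command-line
front end covering the whole workflow ships in
`inst/cli/doseimpact.R` (subcommands `simulate`, `phospho`, `proteome`,
`enrich`, `plot`).

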