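# nmrmetab

Chemometrics for 1D ¹H NMR metabolic profiling of cell extracts and culture
media, built for the comparison of isogenic cell-line panels (e.g. KRAS
point-mutant colorectal cancer lines against their wild-type parent). The
package covers the full analysis path from a processed spectrum matrix to
annotated metabolite calls and pathway enrichment, and ships a forward
simulator with known ground truth so every stage can be validated by
parameter recovery.

## What it does

Given spectra on a common chemical-shift grid (samples × ppm) with genotype
annotation, the pipeline runs:

1. **Region exclusion** — drop signal-free and artifact regions (defaults:
   keep 0.8–10 ppm, drop the residual water band δ 4.7–5.2).
2. **Probabilistic quotient normalization (PQN)** — correct per-sample
   dilution: after integral normalization, each sample's dilution factor is
   the median of the quotients `x_iv / r_v` against the median reference
   spectrum `r`.
3. **Recursive segment-wise peak alignment (RSPA)** — correct small
   chemical-shift drifts by recursively bisecting each spectrum and
   shifting segments to maximize Pearson correlation with a reference
   sample.
4. **Log transformation** — `y = ln(x + c)`, turning multiplicative
   intensity noise into additive noise; the default offset sits 20× above
   the estimated noise floor so baseline cells stay numerically tame.
5. **Pattern recognition** — PCA for structure, then a supervised
   **maximum margin criterion (MMC)** projection maximizing
   `tr(Pᵀ(S_b − S_w)P)` (between- minus within-class scatter, computed in a
   PCA basis so no scatter matrix is inverted), validated by leave-one-out
   cross-validation with a regularized **quadratic discriminant (QDA)**
   classifier (class covariances shrunk toward the spherical pooled
   variance, `Σ_g = (1−γ)S_g + γσ̄²I`, uniform priors).
6. **Differential analysis** — per-variable one-way ANOVA on the log-scale
   data, Benjamini–Hochberg q-values at FDR 0.1, the pFDR threshold
   (largest raw p declared significant), per-variable log₂ fold changes on
   the normalized unlogged data, and assignment of significant variables to
   metabolites via a packaged multiplet library (31 metabolites keyed by
   HMDB accession); ambiguous matches are flagged, never dropped.
7. **Enrichment** — one-sided hypergeometric over-representation of the
   called metabolites against GMT metabolite sets, with BH correction and
   fold enrichment `(k/n)/(K/N)`.

The synthetic-data module renders spectra from the peak library with
Lorentzian multiplets (binomial line weights, `J`-splittings in Hz/MHz),
per-class log₂ concentration effects, per-metabolite chemical-shift jitter,
log-normal sample dilution and additive noise — and returns the exact
ground truth (concentrations, dilutions, shifts) for recovery tests. Two
presets emulate an isogenic panel: `"g13d_vs_wt"` (two classes × 5
replicates) and `"codon12_13"` (wild type + seven mutants × 5 replicates).

## Worked example

```r
library(nmrmetab)

design <- presetDesign("g13d_vs_wt", seed = 1)
sim <- simulateDataset(design)
sim$set
#> SpectrumSet: 10 samples x 6000 points, 0.800-10.000 ppm
#> genotypes: G13D(5) WT(5)

pp <- preprocessSpectra(sim$set)          # exclude -> PQN -> RSPA -> log
cv <- looCv(pp$set)
cv
#> CVResult: 10 samples, correct rate 100.0%

dr <- differentialAnalysis(pp$set, pp$unlogged, c("G13D", "WT"))
dr
#> DifferentialResult: G13D vs WT, 5674 variables, 375 significant (FDR 0.1)
#> pFDR = 0.00657; 27 metabolite calls

head(metaboliteCalls(dr)[order(metaboliteCalls(dr)$q),
     c("name", "representative_ppm", "direction", "log2_fc", "q")], 6)
#>                  name representative_ppm direction log2_fc        q
#> 13 Creatine phosphate               3.95      down  -1.074 3.75e-05
#> 18            Inosine               8.35        up   1.736 5.24e-05
#> 12           Creatine               3.05      down  -0.944 1.52e-04
#> 27                ATP               8.27      down  -0.964 1.76e-04
#> 14     Phosphocholine               4.17      down  -0.797 3.71e-04
#> 26                AMP               8.61      down  -1.518 5.13e-04
```

The run reads as follows: every held-out sample is classified to its
genotype (100% leave-one-out rate); 375 spectral variables differ at FDR
0.1, the largest significant raw p-value (pFDR) being 0.0066; and the calls
recover the injected truth — the simulated G13D class carries a +1.739 log₂
inosine effect and the estimate at the inosine 8.35-ppm singlet is +1.736,
while AMP (injected −1.435) and creatine phosphate (−1.060) come out down.
Creatine appears alongside creatine phosphate because their 3.041/3.045
singlets sit closer than the 0.01-ppm matching tolerance — such calls carry
`ambiguous = TRUE` rather than being silently resolved.

The same stages run config-driven from `runPipeline()` (or the thin wrapper
in `inst/scripts/run-pipeline.R`), writing scores tables, per-comparison
differential tables (`*_table2.tsv`, `table1_summary.tsv`, ANOVA traces,
median-centered heat-map matrices), enrichment tables and a manifest with
parameter echo and per-file checksums.

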