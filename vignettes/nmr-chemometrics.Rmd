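---
title: "Models and methods behind the nmrmetab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the nmrmetab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmetab)
```

# Scope

`nmrmetab` implements the chemometric analysis path used in NMR-based
metabolic profiling of isogenic cell-line panels: spectral preprocessing,
supervised multivariate classification, FDR-controlled univariate
differential analysis with metabolite annotation, and metabolite-set
over-representation. The package starts from processed spectra (phased,
baseline-corrected, referenced, on a common ppm grid); free-induction-decay
processing, 2D-NMR-based identification and vendor formats are out of
scope. A forward simulator with exact ground truth stands in for real
acquisitions so that every stage is testable by parameter recovery.

# The forward model of the simulator

A spectrum is a sum of Lorentzian multiplets. For metabolite $m$ at
concentration $c_m$, each library multiplet (center $\delta_0$, coupling
$J$ in Hz, relative intensity $a$) contributes lines at offsets fixed by
first-order coupling rules — Pascal weights $1$, $1\!:\!1$, $1\!:\!2\!:\!1$,
$1\!:\!3\!:\!3\!:\!1$ for s/d/t/q, four equal lines at
$\pm J/2 \pm J'/2$ with $J' = 0.6\,J$ for dd, and a single line for
unresolved multiplets — each with shape
$L(x;\gamma) = \gamma^2/(x^2+\gamma^2)$, $\gamma$ being the half-linewidth
in ppm, `linewidthHz / (2 freqMhz)`. The model is linear in every $c_m$.

Sample $i$ of class $g$ observes

$$x_i = d_i \, \mathrm{render}\!\left(c_{im}\right) + \varepsilon, \qquad
c_{im} = b_m 2^{\beta_{gm}},$$

with log-normal dilution $d_i = e^{N(0,\sigma_d)}$, per-metabolite
chemical-shift jitter $N(0, \sigma_\delta)$ applied coherently to all of a
metabolite's multiplets (emulating pH/ionic-strength-driven movement), and
additive Gaussian noise with sd `noiseSd` relative to the maximum clean
intensity. Negative noisy values are kept: real processed spectra have
them, and the preprocessing must cope.

Defaults: 600 MHz, grid 0.8–10 ppm at 6000 points, linewidth 1.5 Hz,
$\sigma_d = 0.1$, noise 0.005, jitter $\sigma_\delta = 0.00025$ ppm, five
replicates per class. The packaged presets add a realistic abundance
profile (`defaultBaselineConc()`): abundant lactate, taurine, glutamate and
myo-inositol; low-abundance free nucleotides and nucleosides. Two defaults
deserve their own sections below (jitter and the baseline profile), because
they were genuinely open design choices.

What the simulator does **not** emulate: baseline distortions, imperfect
water suppression, ¹³C satellites, T₂/NOE amplitude effects, peak-shape
asymmetry, and rounding of real multiplet structure beyond the library's
codes. Passing recovery tests on these simulations therefore demonstrates
the correctness and calibration of the *algorithms* under the stated noise
model, not robustness to every artifact of real spectra.

# Preprocessing

**Region exclusion** keeps $[0.8, 10]$ ppm and drops $\delta$ 4.7–5.2
(water). Exclusion is closed-interval and idempotent.

**PQN.** Spectra are first integral-normalized to the median positive-part
row sum, the reference is the element-wise median spectrum, and each
sample's residual factor is the median quotient against the reference over
variables where both are positive; fewer than 10 usable quotients is an
error. The *returned* dilution factor is the total (integral × quotient)
factor, so `output = input / d` holds exactly and recovered factors are
directly proportional to simulated truth. PQN's model is a pure sample-wise
scalar; it is exact for noiseless dilution and degrades gracefully with
additive noise.

**RSPA.** The reference is the sample with the highest mean Pearson
correlation to all others (ties to the lowest sample id). Each test
spectrum is aligned by recursive bisection: find the integer shift within
the window maximizing correlation to the reference segment (ties toward
smaller $|s|$, zero-variance segments defined as correlation 0), fill
vacated points with the segment edge value, and — while the correlation is
below `stopCorr` (0.98), the segment is at least `2 * minSegmentPoints`
(2×30) long and the window is at least one point — split at the
minimum-intensity point of the segment's middle third and recurse with a
halved window. Two guarantees are enforced on top: the child window is
capped by the remaining budget `w0 - |cumulative shift|`, so no point ever
moves further than the initial window (0.02 ppm by default); and a sample
whose overall correlation to the reference would drop is restored
unshifted, so alignment can never hurt.

A structural property of this recursion is worth recording: the window and
the segment length both halve at each level, so their ratio is fixed by
`maxShiftPpm / span` regardless of grid resolution. Shifts comparable to
the window are recovered at the top level (the isolated-peak tests), but
*independent per-metabolite* shifts can only be corrected down to the
segment scale at which the window is still ≥ 1 point — about a third of the
recursion depth. Drift larger than roughly a grid step that differs
metabolite-by-metabolite is therefore not fully correctable by this
variant; this motivates the jitter calibration below.

**Log transform.** $y = \ln(x + c)$. Besides a numeric offset, three
automatic modes exist: `"auto"` (smallest positive intensity — errors on
non-positive cells, per contract), `"auto-shift"` (always-positive shift),
and the pipeline default `"noise-floor"`, $c = 20\hat\sigma$ with
$\hat\sigma$ the RMS of the negative baseline cells (half-normal
estimator). The offset choice matters more than it looks: with a near-zero
offset the log's pole turns thousands of baseline cells into variables with
0.2–1 log-units of pure noise, which dominates the scatter matrices and
destroys the downstream classification; $c = 20\hat\sigma$ caps baseline
log-noise at about 0.05 while peaks, far above the noise floor, keep their
multiplicative-to-additive conversion. This is the same reasoning that
motivates generalized-log transforms in metabolomics.

# Pattern recognition

**PCA** is the centered SVD with a deterministic sign convention (the
largest-magnitude loading element is positive); explained variance ratios
are against total centered variance.

**MMC.** With class-share-weighted scatter matrices
$S_b = \sum_g (n_g/n)(\mu_g-\mu)(\mu_g-\mu)^\top$ and
$S_w = \sum_g (n_g/n)\hat\Sigma_g$ (MLE class covariances), the projection
is the top-$k$ eigenvectors of the symmetric $S_b - S_w$, computed in the
PCA basis of rank $\min(n-1, p)$ and mapped back to variable space. Unlike
LDA nothing is inverted, so $p \gg n$ poses no singularity problem; the
trace criterion of the returned projection dominates random orthonormal
projections on every tested instance. Default $k$ = number of classes − 1.

**Regularized QDA.** Class Gaussians with uniform priors and
$\Sigma_g = (1-\gamma)\hat\Sigma_g + \gamma\bar\sigma^2 I + \text{ridge}\,I$,
where $\bar\sigma^2$ is the mean diagonal of the pooled covariance. With
five replicates per class the raw $\hat\Sigma_g$ are singular in $k \ge 5$
dimensions; $\gamma = 0.5$ (default, configurable) keeps the discriminants
defined while preserving class-specific shape. $\gamma = 1$ recovers
nearest-centroid-like behavior. Exact ties go to the lexicographically
lowest label.

**Leave-one-out CV** refits *both* the MMC projection and the QDA on every
fold — projecting held-out samples with a full-data model is information
leakage, and the test suite demonstrates the leaky variant's optimism on
label-randomized data. Every class needs at least three samples.

# Differential analysis

One-way ANOVA runs per spectral variable on the log-scale data
($F = \mathrm{MSB}/\mathrm{MSW}$, upper-tail p from the F distribution;
degenerate conventions: all-equal groups give $F=0, p=1$; zero within-group
variance with a real difference gives $p$ floored at $10^{-300}$).
Benjamini–Hochberg q-values use the standard step-up rule; the **pFDR**
threshold reported alongside is the largest raw p declared significant at
the nominal level (0.1 by default), so "significant" can be read off as
$p \le p_{FDR}$ or $q \le$ level interchangeably.

Fold changes are $\log_2$ ratios of group means computed on the
PQN-normalized *unlogged* data — ratio-scale quantities on the measurement
scale, kept deliberately separate from the log-scale test statistics.
Variables with a non-positive group mean are flagged, not fatal.

Significant variables are assigned to metabolites when they fall within
`tolPpm` (default 0.01, intended for aligned spectra — about half a typical
multiplet spacing at 600 MHz) of a library multiplet center. The
representative ppm of a call is the matched variable with the largest
absolute log-scale group difference; its sign gives the call direction.
Variables matching two or more metabolites (e.g. the creatine 3.041 /
creatine phosphate 3.045 singlets) are listed under every match with an
ambiguity flag — in practice such collisions are resolved by 2D NMR, which
is out of scope, so the package never resolves them silently.

A note on what recovery means here: the quotient normalization estimates
dilution from the median quotient, and when one class shifts an
appreciable share of total intensity the normalization reabsorbs a small
part of every true fold change. With the packaged abundance profile this
attenuation is a few percent of the largest effects — visible as a
recovered inosine effect slightly below the injected +1.739, and bounded
within ±0.1 by the validation suite. With a flat (all-equal) abundance
profile the attenuation roughly triples; realistic dynamic range is not
cosmetic.

# Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ with BH correction across tested pathways and fold enrichment
$(k/n)/(K/N)$. The background is the packaged peak library's metabolome —
the detectable universe of a targeted NMR panel — not all of HMDB;
it is configurable. The packaged GMT file is a small demonstration fixture
whose memberships are drawn from the packaged library (protein
biosynthesis, urea cycle, RNA transcription, ammonia recycling and related
sets); it is synthetic and makes no claim about any curated database.

# Calibrated defaults and open choices

Three defaults were genuinely open and are recorded here with their
rationale.

* **Jitter sd 0.00025 ppm.** The simulator's noise defaults are presets
  chosen so that effects of the magnitude carried by the packaged presets
  are recoverable from five replicates — they are not estimates of any real
  acquisition. Chemical-shift jitter interacts with the aligner's
  structural limit described above: at 0.8× the linewidth
  (0.002 ppm), per-metabolite drift leaves ~0.45 log-units of apex noise
  after alignment at any grid resolution, and eight-class classification
  collapses to 25–35%. At 0.00025 ppm (0.15 Hz; the coherent residual
  plausible in pH 7.4 phosphate-buffered extracts) jitter stays below the
  default digital resolution, alignment holds every multiplet to within a
  point, and classification is perfect across seeds. Users simulating
  stronger drift should raise `maxShiftPpm` and expect the structural
  limit.
* **Baseline abundance profile.** See the attenuation note above.
* **Pipeline stage order** is exclusion → PQN → RSPA → log; exclusion
  first removes the water artifact before it can bias the quotient
  median, and alignment precedes the log so that correlations are computed
  on ratio-scale peaks. The order is recorded in the preprocessing report.

Problem sizes in the validation suite are the package's own choices:
the eight-genotype panel at 6000 grid points with five replicates
(40 samples) for classification; 200 replicates of 1000-variable two-group
datasets for FDR calibration; 200 simulated panels for fold-change
recovery; brute-force enumeration up to $N = 12$ for the hypergeometric
oracle; 1000 random projections for the MMC optimality check.

# Known limitations

* The RSPA variant's window/segment scale invariance (above) — the
  bisection recursion cannot correct per-peak drift much beyond one grid
  step; published segment-detection variants do better on real data.
* PQN attenuates fold changes in proportion to the changed share of total
  intensity; reported fold changes are post-normalization quantities.
* The enrichment background is the library metabolome; p-values are not
  comparable to web-tool results computed against larger universes, and
  with 20+ of 31 metabolites called significant the test has little room
  to flag any set.
* `m`-coded multiplets are rendered as singlets; real unresolved envelopes
  spread intensity more broadly.
* Printed reference tables from real isogenic-panel studies (per-metabolite
  p/q values and fold changes) derive from deposited raw spectra plus
  manual 2D-NMR assignment; the package treats such values as effect-size
  anchors and output schema, and validates itself by parameter recovery
  instead.
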