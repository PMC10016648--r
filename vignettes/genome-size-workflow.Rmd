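---
title: "Methods: genome size and GC content from internal-standard flow cytometry"
author: "gsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome size and GC content from internal-standard flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsflow)
```

# The measurement model

Flow-cytometric genome sizing stains nuclei of a sample together with nuclei
of an internal reference standard of known DNA content, and records a
fluorescence histogram in which each population forms a peak. Because dye
binding is proportional to DNA amount within a run, the sample's diploid
(2C) DNA content follows from a single ratio:

$$
2C_\text{sample} \;=\; 2C_\text{standard} \times
  \frac{\mu_\text{sample}}{\mu_\text{standard}},
$$

where $\mu$ are the fitted peak positions in channel units. The model
assumes (i) both populations experience the same staining kinetics and
instrument gain — this is why the standard is *internal*, homogenized and
stained with the sample; (ii) peaks are approximately Gaussian, so their
position is well estimated by local least squares; and (iii) run quality is
adequate, summarized by each peak's coefficient of variation
(CV = 100·sd/mean) and by the number of recorded particles.

`gsflow` defaults to the plant standard *Pisum sativum* 'Ctirad'
(2C = 9.09 pg, GC 38.50%), the reference used in insect surveys whose
2C values straddle it on both sides. Haploid values use the convention
1C = 2C/2 for every specimen regardless of sex; in XX/X0 insects the male
soma carries one X, so male 2C (hence 1C) is genuinely smaller and the
female-minus-male 1C difference estimates the X chromosome's DNA content.
Masses convert to base pairs with 1 pg = 0.978 Gbp.

## Peak fitting

Instrument software usually performs peak fitting; `fit_peaks()` makes that
step reproducible. Counts are smoothed by a centered moving average (default
5 bins), candidate peaks are local maxima of the smoothed counts at least
10% of the global maximum (`min_height_frac`), and candidates closer than
`min_separation` (default 3 smoothing windows, i.e. 15 bins of 1024) are
merged into the taller one — Poisson ripple on a single peak must not be
read as two populations. Each retained peak is refined by Gaussian least
squares (`nls`) on a window of ±3 initial standard deviations, the initial
sd taken from the half-width at half maximum; if `nls` fails to converge the
window's rank moments are used instead. Windows of neighbouring peaks are
split at their midpoint so fits never share bins. Two peaks closer than the
merge distance are not resolvable by this design; at 1024 channels that
corresponds to a size difference under ~1.5% at typical gains, which is far
inside measurement noise anyway.

Which peak is the standard is **not** decided by order — sample genomes may
be smaller or larger than the standard — but by a configured channel window
(`standard_window`) in which the instrument gain places the standard. A run
where zero or both fitted peaks fall in the window is rejected as
ambiguous rather than guessed.

## Quality control

`qc_check()` flags `HIGH_CV_SAMPLE`/`HIGH_CV_STANDARD` above
`max_cv_percent = 5` and `LOW_PARTICLES` below `min_particles = 3000`.
Reference runs in this workflow record 3,500–5,000 particles with median
CVs of 2.31% (DAPI) and 3.81% (PI); the thresholds accept such runs and
flag clearly degraded ones. Flags annotate rather than abort: exclusion is
the analyst's decision.

# GC content from two dyes

An intercalating dye (propidium iodide) binds DNA irrespective of base
composition, so its sample/standard ratio $r_\text{int}$ estimates relative
genome size. An AT-selective dye (DAPI) needs a run of $n$ consecutive AT
base pairs per binding site, making its signal proportional to genome size
times $p^n$, with $p$ the genome's AT fraction. The quotient of the two
ratios therefore depends only on base composition:

$$
\frac{r_\text{AT}}{r_\text{int}} = \left(\frac{p_s}{p_{st}}\right)^{n}
\quad\Longrightarrow\quad
p_s = p_{st}\left(\frac{r_\text{AT}}{r_\text{int}}\right)^{1/n},
\qquad \text{GC}\% = 100\,(1 - p_s).
$$

The binding length defaults to $n = 4$, the conventional value for DAPI,
and is configurable because other values are in use. The exact functional
form used by individual laboratories' spreadsheet tools is rarely published;
the power-law binding model above is the standard one, and
`forward_dye_ratio()` exposes the forward direction so the inversion can be
property-tested (forward→invert is the identity to numerical precision).
Noisy ratios can push $p_s$ outside $(0,1)$; such results are clipped and
flagged `OUT_OF_RANGE` instead of raised, since they are legitimate data
needing human review. Specimens measured with the AT-selective dye alone
carry size information confounded with base composition: they are tagged
`RELATIVE` and excluded from GC estimation.

# Comparative statistics

`aggregate_species()` reduces specimens to per-species per-sex arithmetic
means (1C) and a per-species GC mean. Group comparisons follow the
conventions of genome-size surveys:

* **Genome size vs chromosome number** — Kruskal–Wallis (tie-corrected H,
  chi-square approximation on $k-1$ df) across male 2n groups, male values
  because males are the better-sampled sex, followed by pairwise
  Mann–Whitney tests over all groups with more than one record. Pairwise
  p-values are Bonferroni-corrected by the number of pairs actually tested
  (the family size is reported as an attribute, since published tables
  rarely print it). Exact Mann–Whitney p-values are used when both groups
  have ≤ 8 tie-free observations, the tie-corrected normal approximation
  otherwise; tool-exact replication of other software is approximated, not
  byte-matched.
* **Sex differences** — per-species F − M differences
  (`sex_differences()`), interpretable as X-chromosome size under XX/X0;
  records mixing studies or methods carry a provenance tag but are computed
  identically.
* **GC contrasts** — one-way ANOVA across families plus the pairwise
  Mann–Whitney matrix and a per-family N/max/min/mean ± sd summary
  (`gc_family_contrasts()`); Pearson's r (`pearson_test()`) serves the
  size–GC and size–sex-difference correlations.

# Ancestral genome size under Brownian motion

With trait values $x$ at the tips of a rooted tree, Brownian motion implies
$x \sim \mathcal{N}(a\mathbf{1}, \sigma^2 C)$ where $C_{ij}$ is the shared
root-to-tip path length of tips $i,j$. The ML root state is the GLS mean

$$
\hat a = (\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}\mathbf{1}^\top C^{-1}x,
\qquad
\hat\sigma^2 = \frac{(x-\hat a\mathbf 1)^\top C^{-1}(x-\hat a\mathbf 1)}{N},
$$

and each internal node's ML estimate is the same GLS mean with the tree
re-rooted at that node. `bm_asr()` realises the re-rooting through path
lengths — the covariance seen from node $j$ is
$V_j[i,k] = (d_{ji} + d_{jk} - d_{ik})/2$ — which handles polytomies
natively and needs no edge surgery. Node variances are
$\hat\sigma^2 (\mathbf 1^\top V_j^{-1}\mathbf 1)^{-1}$ with 95% intervals
at ±1.96 sd, the usual ML-ASR convention. The test suite checks the
estimates against an algorithmically disjoint route (the joint-ML linear
system on the weighted graph Laplacian) and against an established
independent implementation.

Design choices where the field leaves room:

* Trees are used with their substitution-scaled (non-ultrametric) branch
  lengths as supplied; BM ASR does not require ultrametricity. Analysts who
  prefer clock-like trees can transform branch lengths upstream and pass
  the result in — no smoothing is applied internally.
* Tip values are species means over *all* available 1C measurements,
  pooling sexes.
* Zero-length terminal branches would make $C$ singular; they are replaced
  by $10^{-8}\times$ tree height with a warning.
* Name matching between tree and table normalizes case and
  space/underscore variants before pruning unmatched tips.

# What the generators emulate — and what they do not

The synthetic module exists so every stage is testable against known truth.

* `simulate_histogram()` draws two normal peaks (configurable means, CVs,
  particle counts; defaults 4,000 particles and CV 2.31%) over an
  exponential debris background decaying from channel 0 — a deliberately
  coarse debris model. It does **not** emulate S/G2 cell-cycle populations,
  doublets, stain drift within a run, or heavy-tailed debris; passing
  round-trip tests therefore demonstrates correctness of peak fitting and
  calibration under clean two-population runs, not robustness to every
  pathology of real cytometry.
* `simulate_dye_pair()` applies the same binding-length forward model the
  estimator inverts, plus lognormal ratio noise — it validates the
  inversion and its noise sensitivity, not the chemistry of the model
  itself.
* `simulate_tree_and_tips()` grows pure-birth (Yule) trees via `ape` and
  evolves the trait by exact normal increments per branch. The optional
  `total_height` rescaling exists because pure-birth tree height grows with
  the number of tips: comparisons of estimator precision across tree sizes
  are made at a common root depth, otherwise increasing depth confounds
  (and can reverse) the gain from added tips.
* `make_species_table()` draws group-shifted normal genome sizes truncated
  at 0.1 pg for calibration and power studies of the group statistics.

All generators are deterministic given their seed.

# Numerical and experimental choices

* The ASR sample-size experiment in the acceptance suite uses tree sizes
  8–128 at common height 1, $\sigma^2 = 1$, with 2,000 replicates per
  size: a pre-study power analysis showed that a few hundred replicates
  cannot resolve strict monotone decrease of the root RMSE against the
  between-tree variability of random basal splits (bootstrap pass
  probability ≈ 0.55 at 200 replicates vs > 0.99 at 2,000). The root-only
  mode of `bm_asr()` keeps this experiment fast.
* Simulation studies elsewhere use 100–1,000 seeded replicates — enough to
  hold binomial error well inside the asserted margins (e.g. the 5%
  type-I check uses a 99% binomial band around the nominal rate at 1,000
  replicates).
* Kruskal–Wallis identical-group edge cases return H = 0, p = 1; single
  groups, all-zero histograms, off-scale peaks, non-positive ratios and
  malformed trees raise classed errors (`insufficient-groups`,
  `empty-histogram`, `off-scale`, `invalid-ratios`, `parse-error`, ...) so
  callers can trap them precisely.

# Known limitations

* Histogram input is two-column channel/count text; binary instrument
  formats should be exported to text (or binned) upstream.
* GC estimation assumes the power-law binding model; laboratory-specific
  macro corrections beyond it, where they exist unpublished, cannot be
  reproduced.
* Reproducing survey-wide statistics (e.g. a chromosome-number
  Kruskal–Wallis over a completed multi-study dataset, or ancestral
  estimates on a specific mitogenomic tree) requires that dataset and tree;
  the package ships only the species-level summary table it documents, so
  such numbers are recomputed on whatever dataset the user supplies.
* No phylogenetic regression (PGLS), OU models, rate shifts, or B-chromosome
  handling; the ASR is plain single-rate Brownian motion.
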