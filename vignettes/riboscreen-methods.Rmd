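---
title: "Measuring ribosome association in paired-plate screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ribosome association in paired-plate screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscreen)
```

## The measurement

Plate-based translational profiling pairs two 3'-end RNA-seq libraries per
well: a **ribo** library prepared after pan-ribosome immunoprecipitation (IP)
of whole polysomes, and a **total** library from the same lysate. For gene
$g$ in well $w$, **ribosome association** is the log-scale ratio of
normalized ribo to total signal,

$$\mathrm{RA}_{gw} = \log_2 \frac{\tilde{r}_{gw} + c}{\,\tilde{t}_{gw} + c\,},$$

with $\tilde{r}, \tilde{t}$ the size-factor-normalized counts and $c$ a
pseudocount. RA proxies the fraction of a transcript's pool that is
ribosome-bound — distinct from the ribosome-profiling quantity (translation
efficiency, TE), which tracks the average number of ribosomes per transcript.
A sample's **lfcRA** is its RA minus the mean RA of the vehicle (DMSO)
control wells, gene by gene.

## Normalization and the log-shift transform

Size factors are median-of-ratios: per well, the median over reference genes
of $n_{gw}/\bar{g}_g$, where $\bar{g}_g$ is the gene's geometric mean across
wells and the reference set is the genes with all-positive counts. Spike-ins
and blacklisted genes are always excluded from the reference set — spike-ins
present in only half the wells (the alternating-column spike-in design) would
otherwise distort the factors. Factors are *not* re-centered; consequently
rescaling one well rescales every factor by a common constant and only the
factor *ratios* are equivariant. The `vst()` transform is the explicit
log-shift $\log_2(n/s + c)$ with $c = 1$ by default. It is monotone, finite
everywhere, and matches log-ratio semantics in the moderate-count regime
where RA is interpretable; we deliberately use a fully specified transform
rather than a fitted parametric variance-stabilizing curve, so that every
downstream number is reproducible from this document alone. The pseudocount
shrinks RA toward zero for genes with counts near $c \cdot s_w$; differential
testing below does not use the transform at all and is unaffected.

## Differential ribosome association

Each drug is compared with control on the raw counts of its wells plus the
control wells, both library types stacked into one matrix. Per gene we fit
negative-binomial GLMs with log link and log-size-factor offsets:

* full model: `~ condition + type + condition:type`
* reduced model: `~ condition + type`

The interaction coefficient is the change in the log ribo:total ratio
between drug and control — differential RA on the log2 scale after
conversion. Significance comes from the likelihood-ratio statistic
$2(\ell_{full}-\ell_{reduced})$ against $\chi^2_1$, with Benjamini–Hochberg
adjustment within the contrast; all-zero and non-converged genes are
reported `NA` and excluded from the BH denominator.

### Dispersion model

Counts are modeled with variance $\mu + \alpha\mu^2$ and a dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$. Two facts drove the estimator design:

1. **Ribo and total libraries differ several-fold in depth.** With a trend of
   this shape, the same gene is materially more dispersed in its shallow
   (ribo) observations than in its deep (total) ones. A single per-gene
   $\alpha$ — estimated predominantly from the information-rich deep
   observations — underestimates ribo variance, and the interaction LRT
   (which leans on exactly those observations) becomes anticonservative —
   in null calibrations a scalar-dispersion variant visibly inflated the
   type-I rate and failed Kolmogorov–Smirnov uniformity outright.
2. **Sixteen samples and four coefficients.** Plain maximum likelihood with
   fitted means loses a quarter of its degrees of freedom to the mean model
   and biases $\alpha$ downward.

The estimator therefore: (i) fits a preliminary Poisson GLM per gene for
fitted means; (ii) estimates $(a_0, a_1)$ by maximizing the **Cox–Reid
adjusted** likelihood ($-\tfrac12\log\det X^\top W X$ per gene) jointly over
genes, with means fixed; (iii) estimates a per-gene fold-deviation $\phi_g$
from the trend by the same adjusted likelihood; (iv) shrinks $\phi_g$ toward
1 as the weighted geometric mean $\phi_g^{1-w}$ (trend weight $w = 0.5$ by
default); and (v) uses the **per-observation** dispersion
$\alpha_{gw} = \phi_g^{1-w}\,(a_0 + a_1/\mu_{gw})$, floored at $10^{-8}$,
in both GLM fits. For data whose dispersion is truly gene-constant the
fitted $a_1$ collapses and the model reduces to moderated per-gene
dispersions, so nothing is lost in the homogeneous case. With this design
the null-plate calibration checks in the test suite pass KS uniformity with
type-I rates at the nominal level.

### Numerical choices

IRLS convergence is declared when the score norm falls below
$10^{-8}\,(1+\sum_w y_w)$ (the score scales with counts, so the tolerance is
relative), with at most 100 iterations. Separation — typically a treatment
cell that is all zero — or a singular weighted system triggers a ridge
penalty $10^{-6}\lVert\beta\rVert^2$ and flags the gene `ridged`. The LRT
statistic is clipped at zero. Dispersion optimization runs on the log scale
over $[\,10^{-10}, 10^2\,]$; boundary solutions are accepted as the floor.

## The synthetic plate generator

`simulate_experiment()` draws the plates every test runs on. Its generative
model mirrors the analysis assumptions: per-gene abundance is log-normal
(default $\sigma_{\log} = 1$) and normalized to sum to one; per-well depths
are log-normal with mean `depth_mean` (default 6.7e5, the study-scale total
library) and CV 0.3; total means are `depth × abundance`; ribo means are
`depth × abundance × RA × 2^effect × ip_efficiency`; counts are NB draws
with the trend dispersion (defaults $a_0 = 0.01$, $a_1 = 1.5$, mid-range
values for bulk 3'-end libraries). Baseline RA capture is 0.80 for coding
genes (the literature polysome-associated fraction of polyadenylated mRNA),
0.25 for ncRNA and 0.20 for spike-ins, and IP efficiency defaults to 0.21 —
the efficiency implied by the measured ribo:total complexity ratio. Two of
these defaults interact deliberately: $0.21 \times 0.80 \approx 0.17$, so
the realized ribo:total library-size ratio reproduces the observed
complexity ratio as an *emergent* property of the mechanism rather than a
hard-coded depth factor (`ribo_depth_factor` and `equal_depth` override it).

Condition effects multiply RA by $2^{\mathrm{lfc}}$ on a configured fraction
of a named target set. Combination conditions labelled `"A+B"` never carry
their own effects: each gene's combination effect is exactly
`attenuation_factor × (effect_A + effect_B)` — additive in log2 before
attenuation, the simplest model consistent with combination treatments
shifting targets in the same direction but less far. Random draws consume
the seed in a fixed, documented order (abundance, extra-set sampling,
per-condition target sampling, total depths, ribo depths, total counts,
ribo counts), so seeds are portable.

**What the generator does not emulate:** PCR duplicates and UMI structure
(so "complexity" has no unique-fragment meaning below; see QC), batch or
positional plate effects beyond per-well depth, transcript-length and
GC biases, correlated gene modules, and the heavier-than-log-normal tails of
real abundance distributions. Spike-ins sit on a fixed half-log abundance
ladder rather than the true ERCC concentration vector; their identity is
label-only. Passing tests therefore certify the statistical machinery under
the stated model, not robustness to artifacts the model excludes. One known
consequence: in the real study the ribo arm was *sequenced* deeper than the
total arm (reads being re-reads of fewer unique fragments), while here ribo
libraries are smaller — counts stand in for unique content.

## Quality control

* **Spike-in depletion.** Per spike-bearing well, the log2 ratio of summed
  normalized ribo over total counts for spike-ins versus endogenous genes,
  and their difference; summed after normalization. A one-tailed paired
  Wilcoxon signed-rank test (spike < gene) uses an exact, tie-aware null for
  $n \le 25$ (enumerated by dynamic programming over doubled ranks; zero
  differences dropped) and the tie-corrected normal approximation above.
* **Saturation.** Genes detected at subsampled depths, exact multivariate
  hypergeometric thinning realized by sequential hypergeometric draws.
  Depths are thinned *nested* (each depth subsamples the previous one), so
  curves are non-decreasing for every single seed, not just on average.
* **Complexity and IP efficiency.** The per-well ribo:total complexity ratio
  $\rho_w$ is corrected by the input volume fractions
  (`input_fraction_total / input_fraction_ribo`). Two proxies are reported:
  genes detected at a common depth (the largest depth feasible for ≥90% of
  libraries) and the library-size ratio. On generated data only the size
  proxy carries the IP signal — at a common subsampled depth both libraries
  detect similar gene numbers because count composition, not unique-molecule
  count, is what the generator models. IP efficiency is
  $\eta = \bar\rho / f_p$ with the polysomal fraction $f_p = 0.80$ by
  default.

## Screen analytics

PCA is covariance-based on centered per-well profiles (never correlation),
restricted to the genes significant in any contrast. Outlier wells are
flagged by a declared stand-in rule: robust z (|x − median|/MAD) above
$k = 4$ on either of the first two components. Target sets threshold at
FDR < 0.05 split by lfcRA sign; the *exclusive* variant removes any gene
shared by two conditions' same-direction sets (used for enrichment
comparisons), while the kinase-target network always uses the raw down sets
— its regions are exactly the intersections exclusivity would erase. Network
regions are the distinct membership patterns over the kinase sets (a
partition of the union); each (region, TOP set) pair gets a one-sided
Fisher's exact test against the analysis universe, BH-adjusted across all
pairs.

Preranked enrichment uses the classic (unweighted) running sum — $+1/N_h$ at
hits, $-1/(N-N_h)$ at misses — on scores sorted descending with gene-ID
tie-break; ES is the maximum signed deviation with exact-rational tie
resolution favoring the positive extreme. The null is 1000 seeded gene-label
permutations; NES divides ES by the mean |null ES| of matching sign; the
nominal p is one-sided by ES sign with a +1 pseudocount; the family-wise
value is Bonferroni across the reported sets (the most conservative reading
of a "Bonferroni-adjusted FWER"). Attenuation compares, for each gene
significant under either constituent drug, the stronger individual effect
$x$ with the combination effect $y$: *attenuated* if same-signed and
$|y| < |x|$ (including $y = 0$), *enhanced* if same-signed and
$|y| \ge |x|$ (the $y = x$ boundary is "equal effect", hence not
attenuated), *reversed* otherwise.

## Problem sizes in the test suite

The statistical validation tests run on generated plates of 2,000 genes with
4–8 wells per arm at total depths of 5×10^5–10^6, five seeds for calibration
checks — sizes at which the NB machinery's asymptotics are already
representative while a full run stays in the minutes range. Structural tests
use ~100–300-gene plates. The one marginal case is documented honestly: at
the recovery settings (200 targets at lfcRA −1, 8+8 wells, total depth 10^6,
ribo arm at ~0.17× of it), measured sensitivity at FDR < 0.05 averages ~77%
against the 80% aspiration, with estimation bias well under 0.1; the
corresponding test is kept at the stricter bar rather than loosened.

## Limitations

Counts-only modeling cannot separate read depth from unique-fragment
complexity; the IP-efficiency chain is therefore exercised through the
library-size proxy and a worked arithmetic example rather than a
fragment-level simulation. The interaction LRT relies on $\chi^2_1$
asymptotics — fine at these depths, approximate for very low counts. The
outlier rule and the exclusive-set construction are declared conventions
where the field's practice is unstated; both are parameterized.
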