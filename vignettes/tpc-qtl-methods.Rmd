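---
title: "Methods: behavioral TPCs as function-valued traits and their QTL dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral TPCs as function-valued traits and their QTL dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcmap)
```

## The problem and the model

Small ectotherms such as *Caenorhabditis* nematodes change their locomotory
activity as ambient temperature changes. Scored over a temperature ramp, an
individual's activity traces a thermal performance curve (TPC): near-peak
movement at benign temperatures and a steep decline toward the hot extreme.
`tpcmap` treats each monotone limb of the TPC as a **function-valued
trait**: instead of analyzing activity at every temperature separately, it
fits a three-parameter logistic

$$\mathrm{LI}(T) = \frac{\alpha}{1 + e^{-\beta (T - \tau)}}$$

to strain-mean locomotion and treats the parameters as heritable
phenotypes: `alpha` is the asymptote (baseline activity, locomotion-index
units), `beta` the slope (per °C; negative on the hot limb), and `tau` the
inflection temperature where activity has fallen to half the asymptote.
Peak behavior, which the logistic cannot express, is summarized separately
by a Gaussian peak fit
$\mathrm{LI}(T) = P_{max} e^{-0.5((T - T_{opt})/c)^2}$
over the low-skew central window of the curve. Breadth and position of the
whole TPC derive from the two limb fits as $\Delta\tau = \tau_H - \tau_C$
and midpoint $(\tau_H + \tau_C)/2$; we define the midpoint as the
arithmetic mean of the two inflection points, a choice the package records
prominently because it is a definition, not an estimate.

The genetic layer maps these fitted parameters (and any other per-line
phenotype, such as PCA scores of a large trait table) in a panel of
recombinant inbred lines (RILs): fully homozygous mosaic genomes descended
from two parents. The package implements the full interval-mapping stack
itself: hidden-Markov genotype probabilities on a marker + pseudomarker
grid, multiple imputation, Haley-Knott regression scans, permutation-based
genome-wide thresholds, Bayes credible intervals, QTL heritability
($H^2 = 1 - 10^{-2\,\mathrm{LOD}/n}$), conditional scans, and
two-dimensional scans with an epistasis LOD
(`lod_int = lod_full - lod_add`).

## The locomotion index

The behavioral primitive is a changed-pixel score between two binary worm
masks a fixed frame lag apart (1 frame for LI1, 7 for LI7 at 15 fps). A
verbal definition of "fraction of overlapping pixels" with endpoints 0 = no
movement and 1 = complete displacement admits several denominators; we use
the Jaccard distance $1 - |A \cap B| / |A \cup B|$, which satisfies both
endpoints, is symmetric, and is invariant to joint translation. The
alternative normalization by $\max(|A|, |B|)$ is available via
`method = "maxarea"`. Per temperature step the score is the mean over all
lagged frame pairs in the recording window; the aggregation over pairs is a
package choice, as is the center-of-mass definition of the displacement
metric.

Raw series never quite reach zero for immobile animals because of residual
pixel noise (typically a floor around 0.06–0.12). Each individual's series
is therefore normalized by subtracting its own minimum before any fitting;
this is idempotent and preserves all within-series differences. Proportion
moving binarizes normalized LI7 at a threshold of 0.1 — the threshold is
not derivable from first principles and is exposed in configuration.

Quality control drops any (strain, temperature) cell observed in fewer
than 25 usable individuals and any strain with fewer than 40 distinct
individuals overall, with a per-strain exception list for panels that
retain a deliberately smaller strain; every exclusion is enumerated with a
reason code.

## The synthetic-data generator

The generator stands in for the wet-lab assay so every downstream stage is
exercised at desk scale. Its defaults are the study conditions the
pipeline is designed around:

* **Panel**: 153 RILs from two inbred parents; six chromosomes; a marker
  panel of ~172 markers per chromosome emulating a ~1030-SNP map;
  reciprocal cross directions alternate line by line and determine two
  mitochondrial pseudo-markers on their own non-recombining linkage group
  (`"mt"`, positions 0 and 1 cM).
* **Breeding design**: F1 × F1 sib-intercross for 10 generations, then
  fixation sampled directly — a final meiotic product is doubled, which
  resolves residual heterozygosity along a haplotype-coherent path.
  Crossovers are Poisson with no interference (Haldane). The real panel's
  pedigree is not reconstructed; fidelity is to advanced-intercross map
  expansion, not to a specific pedigree.
* **Transmission-ratio distortion** is available as biased retention of
  lines carrying a favored allele at a focal position; the decay of the
  allele-frequency excess along the chromosome arises from linkage rather
  than from an explicit decay model. The cytonuclear epistatic mechanism
  suspected in the real panel is *not* modeled; only its marginal
  signature (distortion plus cross-direction effects) can be emulated.
* **Phenotypes**: per line, logistic parameters are baseline
  (`alpha = 0.6`, `beta = -0.9` per °C, `tau = 35` °C) plus allele-coded
  additive QTL effects plus Gaussian between-line noise (defaults 0.04,
  0.08, 0.5 in parameter units); per individual and temperature, the
  line's curve plus Gaussian within-line noise (SD 0.05 LI units) plus a
  floor offset of 0.08 — inside the observed 0.06–0.12 band — clipped to
  [0, 1]. The assay grid is 25–41 °C in 1 °C steps with 45 individuals
  per line, matching the hot-limb assay design. Companion metrics (LI7 as
  a saturating amplification of the same latent curve, displacements
  proportional to LI, pixel areas around 2500 px) exist to give the trait
  table realistic structure, not to model optics.

What passing tests on these data do **not** show: robustness to
non-Gaussian residuals, temporally correlated noise within a ramp,
condensation artifacts at temperature extremes, segmentation failures, or
real linkage disequilibrium structure — none of which the generator
emulates.

## Numerical choices

* **Curve fitting** is Levenberg–Marquardt nonlinear least squares
  (`minpack.lm::nlsLM`) from an analytic start ($\alpha_0 = \max y$,
  $\tau_0$ at the first crossing of $\alpha_0/2$,
  $\beta_0 = \pm 4/\mathrm{span}$), with up to five jittered restarts; a
  fit is flagged unconverged when the optimizer fails or $|\beta|$ reaches
  its bound. Uncertainty is Wald: SEs from the Jacobian-based covariance,
  95% CIs as estimate $\pm\, t_{n-3,0.975}\cdot$SE. Strain pairs are
  declared different on a parameter exactly when these 95% CIs do not
  overlap; a profile-likelihood CI would make marginal calls differently.
  Fits are to strain-mean series by default (per-individual fitting is
  available). The Gaussian-peak window is 18–32.5 °C by default and
  configurable.
* **Trait table**: per temperature step, mean and SD of five metrics, plus
  mean pixel area and the three logistic estimates with SEs. The assay
  ramp contains 17 one-degree points, but the first is the acclimation
  point at the 25 °C start; dropping it leaves 16 steps and
  $16 \times 5 \times 2 + 1 + 3 + 3 = 167$ columns. The step list is an
  argument.
* **PCA** is correlation-matrix PCA (column mean imputation for missing
  cells, zero-variance columns dropped with a warning), with a
  deterministic sign convention — the largest-magnitude loading of each
  component is positive. Covariance-matrix PCA (`scale = FALSE`) is
  available; its spectrum, unlike the scaled one, is rotation invariant.
* **HMM**: two states (AA/BB), recombination fraction
  $r = 0.5(1 - e^{-2kd/100})$ between positions $d$ cM apart. The
  map-expansion factor $k$ defaults to 3, calibrated once against the
  generator's default breeding design by fitting the observed
  marker-discordance decay at short range; it is a configuration switch
  for panels with other designs. Genotyping error rate defaults to 1e-4.
* **Scans**: LOD $= (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$,
  computed through the correlation identity for single-locus models, with
  the RSS ratio floored at $10^{-12}$ (a documented LOD ceiling) when a
  locus fits exactly. The imputation estimator averages $10^{\mathrm{LOD}}$
  across imputations and takes $\log_{10}$. Peak ties break to the
  smallest cM position. Bayes credible intervals normalize
  $10^{\mathrm{LOD}}$ with trapezoid weights along the chromosome and
  report the narrowest contiguous peak-containing window reaching the
  coverage, expanded outward to the nearest typed markers; a flat profile
  returns the whole chromosome with a warning. Permutation thresholds use
  the empirical $1-\alpha$ quantile of genome-wide maxima with the
  phenotype permuted and genotypes fixed; one seed governs the whole
  permutation set. The default $\alpha = 0.05/12$ mirrors a Bonferroni
  correction for a twelve-phenotype mapping family (8 PCA scores, 3 fit
  parameters, 1 univariate trait).
* **Two-dimensional scans** use Haley-Knott regression only, on positions
  thinned to a 5 cM minimum separation; singular pairs are skipped. The
  epistasis LOD is the difference of full and additive LODs by
  construction, and permutation thresholds are computed per statistic.

## Design decisions taken where the design was open

* The interface is the R package itself — exported functions, a
  configuration-driven `run_pipeline()`, and this vignette; no shell
  entry point is shipped, since the intended users work inside R.
* `scanone` supports both the multiple-imputation estimator (the
  pipeline's default, 128 imputations at 0.5 cM spacing) and Haley-Knott
  regression; permutation thresholds always use Haley-Knott for speed,
  which is conservative in the sense that the two agree at typed markers
  exactly and differ between markers only through the smoothing of
  expected genotypes.
* Between-line and within-line noise are Gaussian because nothing in the
  assay pins down a residual family; clipping to [0, 1] introduces slight
  floor/ceiling censoring at extreme temperatures, which the fits tolerate.
* Parental strains are not scanned; mapping uses RILs only.

## Problem sizes used by the test suite and acceptance script

Simulation-based checks run on: a 153-line, six-chromosome panel with 172
markers per 50 cM chromosome and a 0.5 cM grid (scan correctness, null
calibration at 200 replicates × 500 permutations, planted-QTL detection
and localization over 100 replicates with an effect explaining 20% of
between-line variance in `tau`); 200 synthetic strains for fit-quality
bands; 50 replicates for epistasis power with an interaction contributing
roughly 20% of phenotypic variance; and a 120-line, three-chromosome panel
for unit-level properties. These sizes are the package's own choices for
desk-scale reproducibility.

## Known limitations

* The HMM's expanded-Haldane transition model is an approximation to the
  true advanced-intercross transmission process; between-marker
  probabilities (not marker-level ones) inherit the approximation.
* Bayes credible intervals are known to undercover slightly at modest QTL
  effect sizes; the planted-QTL acceptance check therefore requires 88%
  empirical coverage at nominal 95%.
* No multiple-QTL model selection, composite interval mapping, or
  X-dosage models; the panel is treated as fully homozygous throughout.
* CI-overlap strain comparison is conservative relative to a formal test
  of parameter equality.
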