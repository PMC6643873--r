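# tpcmap

Behavioral thermal performance curves (TPCs) as function-valued traits,
and their genetic dissection by QTL mapping in recombinant inbred line
(RIL) panels.

## What it is for

Nematode locomotion scored over a temperature ramp traces a thermal
performance curve: near-peak activity at benign temperatures and a steep
decline toward the hot extreme. `tpcmap` is for quantitative geneticists
who want to (i) summarize such reaction norms with a few biologically
interpretable parameters and (ii) map natural variation in those
parameters onto the genome in a homozygous biallelic RIL panel. A
synthetic-data generator replaces the wet-lab assay so that every stage —
behavioral metrics, curve fitting, trait tables, PCA, genome scans — runs
and is testable at desk scale, and the same machinery accepts real
long-format assay tables and genotype/map CSVs.

## The models at its core

The locomotion index between two video-frame worm masks is the
changed-pixel (Jaccard) distance `1 − |A∩B|/|A∪B|` (0 = immobile,
1 = complete displacement; 1-frame lag gives LI1, 7-frame LI7). After
per-individual normalization, each monotone limb of a strain-mean TPC is
fitted with the three-parameter logistic

    LI(T) = α / (1 + exp(−β (T − τ)))

(α: asymptote / baseline activity; β: slope per °C, negative on the hot
limb; τ: inflection temperature), and the central peak with a Gaussian
`LI(T) = Pmax · exp(−0.5 ((T − Topt)/c)²)`. The fitted parameters are the
phenotypes. QTL mapping of any per-line phenotype is built from first
principles: a two-state hidden-Markov model yields genotype probabilities
on a marker + 0.5 cM pseudomarker grid (with mitochondrial pseudo-markers
from the reciprocal cross direction), scans use multiple imputation or
Haley-Knott regression with `LOD = (n/2) log10(RSS0/RSS1)`, significance
comes from permutation-based genome-wide thresholds (default
α = 0.05/12), localization from 95% Bayes credible intervals, QTL
heritability from `H² = 1 − 10^(−2·LOD/n)`, and epistasis from
two-dimensional scans with `lod_int = lod_full − lod_add`.

## Worked example

Simulate a 153-line panel with one QTL shifting the hot-limb inflection
temperature τ by +1 °C on chromosome V at 25 cM, fit every strain, and
scan:

```r
library(tpcmap)

map  <- simulate_map(n_chromosomes = 6, chromosome_lengths_cM = 50,
                     markers_per_chromosome = 25, seed = 1)
ril  <- simulate_ril_genotypes(map, n_lines = 153, seed = 2)
spec <- qtl_spec(data.frame(chrom = "V", pos_cM = 25, param = "tau", effect = 1),
                 sd_line = c(alpha = 0.04, beta = 0.08, tau = 1),
                 sd_within = 0.05)
assay <- normalize_assay(simulate_tpc_phenotypes(ril, map, spec, seed = 3))
fits  <- fit_strains(qc_filter(assay)$table, metric = "li7", half = "hot")
fits[["RIL001"]]
#> logistic TPC fit [hot half] (n = 17, R^2 = 0.9965, converged)
#>           alpha    beta     tau
#> estimate 0.8377 -0.7229 33.9291
#> se       0.0103  0.0398  0.0901
#> lower    0.8156 -0.8083 33.7359
#> upper    0.8597 -0.6375 34.1223

summ <- attr(fits, "summary")
gp   <- genotype_probabilities(ril, map, build_grid(map, step = 0.5))
tau  <- setNames(summ$tau, summ$strain)
prof <- scanone(tau, gp)
peak_lod(prof)
#>     chrom   pos_cM marker    lod
#> 466     V 24.77968 V_m014 8.8172
permutation_threshold(tau, gp, n_perm = 1000, seed = 4)$threshold
#> [1] 3.97
bayes_interval(prof, "V")[c("lo", "hi")]   # 24.2–29.9 cM
heritability_from_lod(8.8172, 153)
#> [1] 0.233
```

The strain fit shows the hot limb of RIL001's TPC declining with slope
−0.72 per °C through an inflection at 33.9 °C (the planted architecture
draws each line's τ from 35 ± 1 °C plus the +1 °C allele effect). The
scan recovers the planted locus: a LOD peak of 8.8 at 24.8 cM on
chromosome V, far above the 0.05/12 genome-wide permutation threshold of
3.97, localized to a 95% credible interval of 24.2–29.9 cM spanning the
true position, with the peak regression explaining H² ≈ 23% of
between-line variance.

`run_pipeline(default_config(seed = 1), "out/")` runs the whole chain
(simulate → normalize → QC → fits → 167-column trait table → scaled PCA →
scans with thresholds, intervals and heritability) and writes every
intermediate table plus a JSON manifest; `report_run()` renders TPC-fit
and LOD-profile figures from a run directory.

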