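# finesgs

Fine-scale spatial genetic structure (FSGS) and contemporary gene-flow
analysis for georeferenced SNP data, built for within-population surveys of
long-lived plants — the motivating case is the relict tree *Tetracentron
sinense*, sampled as mapped patches of genotyped individuals spanning three
DBH-defined age classes (sapling < 7.5 cm ≤ adult < 22.5 cm ≤ mature).

The package takes a VCF of biallelic SNPs plus a sample metadata table
(id, population, patch, coordinates, DBH) and provides, as both plain R
functions and one configuration-driven pipeline:

- **Site filtering** — GATK-style hard filters (FS ≤ 60, HaplotypeScore ≤
  13, MQ ≥ 40, QD ≥ 2, ReadPosRankSum ≥ −8, MQRankSum > −12.5) and a
  strict MAF > 0.05 screen.
- **Diversity** — per-patch H<sub>O</sub>, unbiased H<sub>E</sub>, Fis, and
  the pooled-variance t-test of patch H<sub>O</sub> vs H<sub>E</sub>.
- **SGS** — pairwise Loiselle kinship F<sub>ij</sub>, the regression slope
  *b<sub>F</sub>* of kinship on ln(distance), first-class kinship
  F<sub>(1)</sub>, the intensity statistic

  &nbsp;&nbsp;&nbsp;&nbsp;*Sp* = −*b<sub>F</sub>* / (1 − F<sub>(1)</sub>),

  and 999-permutation envelopes under the random-spatial-arrangement null,
  at population, age-class and patch levels.
- **Spatial autocorrelation** — the Smouse–Peakall multilocus coefficient
  *r* per distance class with permutation envelopes, bootstrap errors and
  the correlogram x-intercept.
- **Parentage** — categorical allocation by trio LOD with a genotyping-
  error kernel (ε = 0.01), delta thresholds calibrated by simulation
  (candidate proportion 0.9, 80% confidence), and conversion of confident
  trios into seed (offspring→mother) and pollen (mother→father) dispersal
  events; the combined effective gene-dispersal distance is
  σ<sub>g</sub> = √(σ<sub>s</sub>² + σ<sub>p</sub>²/2).
- **Indirect dispersal** — the cubic decay fit
  F(r) = a + b ln r + c ln² r + d ln³ r, its roots, and the (min, max)
  gene-dispersal range combining root and x-intercept.
- **A spatially explicit forward simulator** with separate Gaussian seed
  and pollen kernels, partial selfing, genotyping error and missingness,
  writing VCF + metadata + pedigree truth so every estimator above is
  validated by parameter recovery.

## Worked example

Recompute the published population-level *Sp* values from their reported
slopes and first-class kinship, and one patch's effective gene-dispersal
distance from its reported seed/pollen means:

```r
library(finesgs)

ref <- reference_table("sgs_population")
data.frame(population = ref$population,
           Sp = round(sp_statistic(ref$bF, ref$F1), 4))
#>   population     Sp
#> 1       BMXS 0.0215
#> 2       MGFD 0.0076
#> 3       SXFP 0.0137
#> 4       GLGS 0.0125

disp <- reference_table("dispersal_direct")
ya <- disp[disp$patch == "YA", ]
effective_gene_dispersal(ya$seed_mean, ya$pollen_mean)
#> [1] 221.1296   # printed value: 221.13 m
```

The *Sp* values match the published table (0.021, 0.0076, 0.013, 0.012) at
their printed precision; small deviations in the re-derived digits come
from the inputs themselves being rounded.

End to end on simulated data — a population with strongly restricted seed
dispersal (5 m kernel) shows significant positive SGS in the first
distance class:

```r
ds <- simulate_population(sim_config(
  n_founders = 30, n_patches = 1, patch_size = 500, sigma_seed = 5,
  sigma_pollen = 50, n_loci = 100, n_generations = 2,
  offspring_per_generation = 30, genotyping_error = 0, missing_rate = 0,
  rng_seed = 1))
gm  <- maf_filter(ds$genotypes)
K   <- kinship_loiselle(gm)
D   <- pairwise_distance(ds$samples)
res <- sgs_permutation(K, D, distance_classes(n_classes = 8),
                       n_perm = 999, seed = 1)
sprintf("bF = %.4f, F(1) = %.4f, Sp = %.4f (first class significant: %s)",
        res$bF, res$F1, res$Sp, res$per_class$signif[1])
#> "bF = -0.0444, F(1) = 0.0999, Sp = 0.0493 (first class significant: TRUE)"
```

A kinship that high in the first class (~0.10, approaching half-sib
expectation) with a steeply negative slope is exactly what a 5 m seed
kernel inside a 500 m patch should produce.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/06_dispersal.R` run the whole study
design as numbered drivers over the package functions: simulate the
survey-scale population (96 trees × 1,000 loci, pedigree truth on disk),
filter and summarize diversity, profile SGS by stratum with 999
permutations, build patch correlograms with intercepts, allocate
parentage and summarize direct dispersal, and fit the indirect cubic
curves. Each stage prints what it found and writes its tables under
`results/`. `run_pipeline()` performs the same chain from a single
`pipeline_config()`, with provenance headers and byte-identical seeded
reruns.

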