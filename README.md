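# clinezone

Maximum-likelihood cline and disequilibrium analysis of hybrid zones,
for population geneticists studying contact zones between differentiated
taxa sampled as georeferenced, individually genotyped animals or plants.
The motivating setting is a narrow salamander contact zone (two taxa,
here labelled E and K, fixed for alternative alleles at three diploid
nuclear loci and one mitochondrial marker), but every analysis applies
to any set of diagnostic biallelic markers scored on individuals with
coordinates.

## What it computes

* **Transect orientation.** Individuals are projected onto a straight
  transect whose compass heading is itself estimated by maximum
  likelihood: at each heading the best *monotone* allele-frequency cline
  is fitted per locus by the pool-adjacent-violators algorithm (weighted
  isotonic regression, which maximises the binomial likelihood), and the
  summed log-likelihood is profiled over headings with two-unit support
  limits.
* **Sigmoid clines.** Allele frequencies follow the tanh cline
  `p(x) = (1 + tanh[2(x − c)/w]) / 2`, with centre `c` and width `w`
  (the inverse of the maximum slope). Fits are by bounded quasi-Newton
  ML with deterministic multistarts; profile likelihoods give two-unit
  support limits (the likelihood analogue of 95% confidence intervals).
  Cline coincidence (shared centre) and concordance (shared width)
  across loci are tested with `G = 2ΔLL` against the chi-square
  distribution with `(n_loci − 1) × n_shared` df.
* **Hybrid-index concordance.** Barton's individual × locus analysis:
  `HI_loc = HI + He[α + β(2HI − 1)]` with `He = 2HI(1 − HI)`, fitted by
  binomial ML per locus. `α` (directionality) measures a shift toward
  one genetic background, `β` (abruptness) a steeper or shallower
  transition than the equal-introgression diagonal.
* **Disequilibria in a sliding window** (200 m window, 100 m steps by
  default): within-locus heterozygote deficit `P(hom) − p²`, gametic
  disequilibrium `D` between nuclear loci (EM over unphased diploid
  genotypes under random union of gametes), and cytonuclear `D`
  (closed-form ML), each averaged over loci or pairs, all bounded in
  `[−0.25, 0.25]`.
* **Hybrid classification.** Threshold calls from an admixture
  proportion (printed 0.1/0.9 thresholds or the midpoint formula
  `(0 + 1/(2L+1))/2`, `(1 + 2L/(2L+1))/2`), and exact
  genotype-frequency-class posteriors over {pure E, pure K, F1, F2,
  backcross-E, backcross-K} for fully diagnostic loci.
* **Habitat analyses.** Chi-square genotype–vegetation association,
  per-class elevation summaries with one-way ANOVA, and a
  habitat-and-cline versus cline-only likelihood-ratio test (the
  habitat model shifts the cline centre with vegetation class or
  elevation).
* **Synthetic data.** `simulate_zone()` generates zones with known
  clines, tension-zone-style parental mixing (the joint source of
  heterozygote deficit, inter-locus and cytonuclear disequilibrium),
  asymmetric mitochondrial inheritance, and habitat covariates
  confounded with position — so every estimator can be validated
  against ground truth.

## Worked example

```r
library(clinezone)

d <- simulate_zone(sim_config(seed = 1))
d
#> Genotype dataset: 335 individuals, 3 nuclear loci (CXCR4, SLC8A3, RAG1) + ND4 (mtDNA)

o <- fit_orientation(d)
o
#> ML transect heading: 206.8 deg (two-unit support 201, 207)
#> logLik -392.011 over 4 loci; per-locus directions agree

pr <- project_positions(d, o$heading)
summary(fit_cline(pr))
#> Tanh cline fit (CXCR4, SLC8A3, RAG1, ND4)
#>        estimate   lower  upper
#> center  -0.0313 -0.0640 0.0018
#> width    0.7729  0.7018 0.8513
#> Maximum slope (at center): 1.2938 per km

fit_shared_and_test(pr, "width")
#> Cline concordance test: shared width across 4 loci
#>   G = 1.900, df = 3, p = 0.5934

fit_concordance(d, "ND4")
#> Concordance fit for ND4:
#>   alpha (directionality) = 1.033
#>   beta  (abruptness)     = -1.106
#>   G = 53.519 (df 2), p = 2.391e-12 vs equal introgression

sc <- ld_scan(pr)
max(sc$D_between, na.rm = TRUE)
#> [1] 0.126   # peaking at -0.19 km, on the E flank
```

The generator's defaults place four tanh clines of width 0.72–0.80 km
across a 3.5 × 1.75 km strip at heading 207°, with the mitochondrial
centre offset 0.105 km toward the E flank and strongly asymmetric
mitochondrial inheritance in admixed individuals. The fitted heading
(206.8°), shared width (0.77 km), non-significant shared-width test,
strongly positive mitochondrial `α`, and the between-locus `D` profile
peaking on the E flank all recover that injected structure. A single
configured run of the whole pipeline — orientation, per-locus and
shared fits, coincidence tests, concordance, the disequilibrium scan,
classification and habitat tests, written to disk with a manifest — is

```r
run_all(sim = sim_config(), out_dir = "zone-report", seed = 1)
```

Field data are read from a tab-separated per-individual table (two
allele columns per nuclear locus coded `E`/`K`, `-9` for missing; see
`?read_genotypes` and `?default_schema` for adapting column names) with
`run_all(input = "table.tsv", ...)`.

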