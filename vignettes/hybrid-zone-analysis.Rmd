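---
title: "Methods: maximum-likelihood hybrid-zone analysis with clinezone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-likelihood hybrid-zone analysis with clinezone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinezone)
```

## The setting and the model

A hybrid zone is a region where two differentiated taxa meet and
produce admixed offspring. When the markers are *diagnostic* — each
parental taxon fixed for an alternative allele — the ancestry of every
allele copy is unambiguous, and the spatial transition of each marker
can be summarised by a one-dimensional cline in the frequency of one
taxon's alleles (here, "K" alleles). Tension-zone theory predicts that
such clines are maintained by a balance between dispersal into the zone
and selection against hybrids, that clines at unlinked markers should
be narrow and mutually coincident, and that the continual arrival of
unrecombined parental genotypes generates heterozygote deficit,
inter-locus gametic disequilibrium, and (when a maternally inherited
marker is included) cytonuclear disequilibrium, all concentrated where
dispersers accumulate.

`clinezone` implements the full likelihood workflow for such data: a
model-free monotone cline used to orient the transect, a parametric
sigmoid cline for widths and centres, concordance analysis on the
hybrid-index scale, sliding-window disequilibrium estimation, hybrid
classification, and habitat-model comparison.

### Transect projection and orientation

Sampling coordinates are mapped to a local planar frame by an
equirectangular projection (`east = R cos(lat₀) Δlon`,
`north = R Δlat`, `R = 6371.0088` km). For a study area a few
kilometres across, the projection error is below a metre, so geodesic
machinery would add nothing. The position of an individual on a
transect with compass heading θ is `east·sin θ + north·cos θ`,
centred on the planar centroid by default, so positions (and hence
cline centres) are expressed in km relative to the sample centroid.
Centres are therefore origin-dependent; only centre *differences*
(e.g. mitochondrial minus nuclear) are comparable across analyses.

The heading itself is estimated by maximum likelihood. For a candidate
heading, each locus's observations `(position, k successes of n allele
copies)` are fitted with the best *monotone* frequency sequence — the
weighted pool-adjacent-violators algorithm, which maximises the
binomial likelihood over all monotone clines without committing to a
parametric shape. Each locus picks the better of an increasing or
decreasing direction, log-likelihoods are summed over loci, and the
heading is scanned on a 1° grid (period 180°, since reversing the
axis only relabels directions) with golden-section refinement around
the grid argmax. The profile is piecewise constant in θ (PAVA depends
only on the ordering of positions), so the refinement can only sharpen
the argmax within one grid cell; the default 1° grid is finer than the
support limits it feeds. Because the profile is also locally jagged,
the two-unit support *set* can be non-contiguous; the reported support
limits are the range of that set around the MLE, which is how such
limits are conventionally printed.

### The tanh cline and its likelihood

Allele frequencies follow

> p(x) = (1 + tanh[2(x − c)/w]) / 2,

with centre `c` (where p = 1/2) and width `w` equal to the inverse of
the maximum slope. The likelihood is binomial per individual-locus:
two trials for a diploid locus (Hardy–Weinberg within site), one for
the mitochondrial marker, with p clamped to `[1e-12, 1 − 1e-12]` to
keep flank observations finite. No site-level inbreeding parameter is
included: departures from Hardy–Weinberg are the *object of study* of
the disequilibrium module, not a nuisance to absorb into the cline
likelihood. Stepped or tail-introgression cline shapes are deliberately
out of scope; they are only identifiable with dense sampling in the
tails.

Optimisation is bounded quasi-Newton (L-BFGS-B) on `(c, log w)` from
six deterministic starts (centre at the 0.25/0.5/0.75 position
quantiles crossed with widths of one-eighth and one-half the position
span), with `w` bounded in `[1e-3 km, 4 × span]`. Profile likelihoods
re-optimise the other parameter(s) at each point; two-unit support
limits are located by geometric expansion followed by bisection to
`1e-5` km. When several loci share parameters, the shared MLE is found
by one joint optimisation over the shared parameter plus per-locus
nuisance parameters (identical to maximising the summed profile, but
cheaper), and the summed profile defines the support limits.
Coincidence (shared centre) and concordance (shared width) are tested
with `G = 2(LL_free − LL_shared)` on `(n_loci − 1) × n_shared` df.

### Barton's concordance analysis

Each individual's hybrid index HI is its fraction of K alleles over all
scored copies (two per nuclear locus, one mitochondrial); the same
fraction restricted to one locus gives HI_loc. Under equal
introgression, E[HI_loc] = HI; deviations are modelled as

> HI_loc = HI + He·[α + β(2HI − 1)],  He = 2·HI·(1 − HI),

and fitted per locus by binomial ML on the locus's K-copy counts, with
the prediction clamped to `[1e-6, 1 − 1e-6]` (unclamped predictions
can leave [0, 1] for large |α|, |β|). A 2-df G-test compares against
α = β = 0. ML fitting (rather than least squares on the scatter) is
used because it weights haploid and diploid loci correctly and degrades
gracefully at the HI endpoints, where He = 0 and individuals carry no
information about (α, β). The regressor HI includes the focal locus by
default — the concordance plot is conventionally drawn that way — and a
`leave_one_out` flag removes it. He is taken literally as
2·HI·(1 − HI) per individual, not smoothed.

### Disequilibria in a sliding window

Three components are estimated in windows of 200 m moved in 100 m
steps (defaults; a window is `[centre − w/2, centre + w/2)`, half-open
so that step = window/2 tiles the transect cleanly):

* within-locus heterozygote deficit: the single-locus analogue of D,
  `D_within = P(hom K) − p²`, whose ML estimate is the plug-in of the
  observed genotype proportions;
* between-nuclear gametic D: for each locus pair, the ML of
  `D = h_KK − p_A p_B` under random union of gametes, with the
  double-heterozygote phase ambiguity resolved by EM on the four
  haplotype frequencies. The EM runs from seven deterministic starts
  (D₀ = 0, ±0.02, ±0.1, ±0.2, clipped to the admissible range) because
  linkage equilibrium is a stationary point of the EM map; convergence
  is declared when the log-likelihood moves by less than 1e-10, and a
  tie (within 1e-6) between maxima at ±D̂ is reported as D = 0 with a
  degeneracy flag;
* cytonuclear D: the association between the mitotype and a random
  nuclear allele copy, `D = P(K, K) − p_mt p_nuc`, whose ML estimate is
  closed-form because the haploid marker leaves no phase ambiguity.

All three are bounded in [−0.25, 0.25] and checked against the
allele-frequency bounds in every window. Components are unweighted
means over loci or pairs; windows with fewer than 5 complete
individuals for a component (a floor the source analyses leave
unstated) omit that component, and monomorphic margins yield no
estimate. Sign convention: D > 0 when K alleles co-occur across
markers. Gametic (EM-resolved) D is used rather than the composite
Burrows estimator, matching the ML framing of the analysis.

### Hybrid classification

Two classifiers are provided. The threshold rule calls an individual a
pure parental when its admixture proportion q falls outside
`(lower, upper)`: the printed convention (0.1, 0.9) is the default,
and a "formula" mode uses the midpoints between 0 resp. 1 and the
nearest attainable ancestry fraction with L diploid diagnostic loci
plus the mitochondrial copy — `(0 + 1/(2L+1))/2` and
`(1 + 2L/(2L+1))/2`, i.e. (1/14, 13/14) for L = 3. The two conventions
disagree (0.1 ≠ 1/14 ≈ 0.071), so both are exposed and the mode is
recorded. q can be supplied externally (e.g. from an MCMC admixture
analysis read with the input table) or proxied by the nuclear hybrid
index; the proxy choice is logged.

For fully diagnostic loci, the six early-generation genotype-frequency
classes have exact per-locus genotype probabilities (pure E (1,0,0),
pure K (0,0,1), F1 (0,1,0), F2 (¼,½,¼), backcrosses (½,½,0)/(0,½,½)),
so the class posterior is a closed-form product over scored loci times
a prior. This is a stand-in for MCMC classifiers, valid only for
diagnostic markers; it does not model allele-frequency uncertainty.
Note that an all-homozygous genotype does *not* identify a parental
with certainty: with three loci, pure E gets posterior 64/73 against
8/73 for backcross-E and 1/73 for F2. MAP calls recover parentals and
F1s almost perfectly while F2 and backcross calls remain diffuse —
exactly the behaviour expected from three diagnostic loci.

### Habitat analyses

The association between class labels and vegetation series is a
Pearson chi-square on the contingency table (no continuity
correction); per-class elevations get descriptive summaries and a
one-way ANOVA omnibus F (post-hoc structure is not used downstream and
is omitted). The habitat-and-cline comparison augments the shared tanh
cline with a centre shift: `c + δ·1[veg = MWP]` (km) or
`c + γ·(elev − mean elev)` (km per metre), each adding one parameter,
fitted on the same individuals and compared by a 1-df LRT. A
centre-offset is the minimal nesting of a habitat effect into the
cline model (the source analyses cite an external approach without
printing a parameterisation); a width effect could be added the same
way but is not fitted by default. The richer model is accepted only on
a significant likelihood increase.

## The synthetic-data generator

`sim_config()` defaults define the study conditions the package is
validated under: 335 individuals uniform on a 3.5 × 1.75 km strip
crossed at heading 207°; three diploid nuclear clines of widths 0.770,
0.799 and 0.725 km centred at 0, plus a mitochondrial cline of width
0.718 km centred at −0.105 km (toward the E flank); parental mixing
with amplitude 0.6 decaying as a Laplacian kernel with 0.5 km scale
from −0.2 km; K-mitotype probability 0.9 for admixed individuals; a
logistically blurred vegetation boundary at the zone centre (0.3 km
blur) and an elevation field of 1420 m + 50 m/km with 60 m Gaussian
noise. Strip, widths, offset, sample size and the mitotype asymmetry
mirror the observed zone these analyses target; the mixing amplitude
and scale were chosen once so that sliding-window D peaks around
0.1–0.15 on the E flank, and the habitat parameters so that vegetation
and elevation are confounded with transect position, as observed.

The generative mechanism is deliberately minimal. With probability
`m(x) = mix_amplitude·exp(−|x − mix_center|/mix_scale)` an individual
is an unrecombined parental — all nuclear loci and the mitotype jointly
K-type with the local cline probability, else all E-type — which
injects heterozygote deficit, inter-locus D and cytonuclear D
*simultaneously*, the tension-zone signature. Otherwise all allele
copies are independent draws from their clines (Hardy–Weinberg and
linkage equilibrium), and individuals that come out carrying both E
and K nuclear alleles take the K mitotype with probability
`mt_asymmetry` (modelling asymmetric hybridisation) instead of their
clinal mitotype. The kernel is centred off the cline centre by default
because a symmetric kernel cannot concentrate disequilibrium on one
flank. Two caveats follow. First, the kernel centre, not any dynamical
process, decides where disequilibrium peaks — the generator emulates
the *pattern*, not dispersal dynamics: no forward-in-time simulation,
mate choice or selection coefficients. Second, with strong mitotype
asymmetry the *fitted* mitochondrial–nuclear centre offset exceeds the
injected −0.105 km (about −0.23 km under the defaults), because
asymmetric inheritance itself displaces the mitochondrial cline;
recovery of the injected geometric offset is therefore validated with
`mix_amplitude = 0, mt_asymmetry = 0`.

What passing tests on these data do and do not show: they demonstrate
that the estimators recover known clines, support limits have close to
their nominal coverage, the LRTs have near-nominal size, and the
disequilibrium scan localises mixing — under binomial sampling on a
uniform strip. Real data add spatial clustering along creeks, drift in
allele frequencies over sampling years, non-diagnostic variation and
genotyping error, none of which the generator emulates.

## Numerical choices, in one place

* Kilometres are the canonical length unit; window/step arguments
  documented in metres are stored as km.
* Binomial coefficients are omitted from all log-likelihoods
  (parameter-free), and `0·log 0 = 0`.
* Cline p clamped at `1e-12`, concordance prediction at `1e-6`.
* Optimiser: L-BFGS-B, `factr = 1e4` (≈ 1e-12 relative tolerance);
  1-D profiles via `optimize` with `tol = 1e-9`.
* Support-limit bisection to `1e-5` in the parameter; when the profile
  never drops two units before a bound, the bound itself is reported.
* EM convergence at `1e-10` in log-likelihood, 10 000 iteration cap;
  the EM trace is checked non-decreasing.
* Ties in position are pooled before PAVA (isotonic regression is
  defined on distinct abscissae).
* Positions, vegetation and elevation are deterministic functions of
  the seed; `run_all()` output is byte-reproducible.

## Problem sizes used in validation

The test suite validates the primitives against brute-force oracles
(exhaustive monotone-sequence search for PAVA; 0.001-grid likelihood
scans for gametic and cytonuclear D on tables of up to 30 individuals)
and the pipeline against ground truth: support-limit coverage on 100
replicate zones of 300 individuals, mitochondrial-offset recovery on
50 replicates of 335, concordance null recovery on 50 replicates of
500, and null calibration of the coincidence and habitat LRTs on 500
replicates each of 300 individuals. Consistency of the tanh fit is
checked at n = 10 000. `scripts/acceptance.R` re-runs the pipeline and
the first three calibration studies (with 200 coincidence-null
replicates) from a single command-line seed.

## Known limitations

* Straight transects only: no curved centreline or 2-D cline surface.
* No estimation of dispersal or selection intensity from widths and
  disequilibria; the quantities needed for those inferences are
  reported, the inference itself is out of scope.
* No variance estimates for sliding-window D (point profiles only).
* The genotype-class posterior assumes perfectly diagnostic loci and
  no genotyping error.
* Support limits are likelihood-based; they are calibrated by
  simulation here but carry no small-sample guarantee.
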