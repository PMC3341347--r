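---
title: "Models and methods in seedshadow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in seedshadow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshadow)
set.seed(1)
```

`seedshadow` estimates seed and pollen dispersal kernels and seedling
parentage for mapped stands of nut-bearing, wind-pollinated trees
(red oaks are the motivating system), and provides the surrounding
machinery a study of this kind needs: a forward simulator for complete
synthetic datasets, a pedigree-relatedness simulator of spatial genetic
structure (SGS) under alternative stand histories, multilocus spatial
autocorrelation, and asymptotic migration-speed arithmetic. This
vignette documents the models, their assumptions, and the design
choices a maintainer or reviewer would want spelled out.

## The 2D-t dispersal kernel

All dispersal in the package is governed by the one-parameter 2D-t
kernel with shape fixed at 1,

$$K(r) = \frac{u}{\pi\,(u + r^2)^2},$$

a radially symmetric density per unit area at distance $r$ (m) from the
source, with a single scale parameter $u$ (m²). It is convex at the
source and fat-tailed ($K \sim r^{-4}$), matching the shape of both
seed-trap and genetic dispersal estimates in trees better than a
Gaussian, and it admits closed forms for everything the analysis needs:
the mean distance is $(\pi/2)\sqrt{u}$ (`expected_distance()`), the
radial CDF is $r^2/(u+r^2)$, and exact sampling uses the inverse CDF
$R^2 = u(1/(1-q) - 1)$ (`sample_distances()`). The shape exponent is a
frozen constant of the family, not a tuning knob: every parameter value
the package quotes (priors, simulation grids, published comparisons)
assumes it. Note the distance *variance* is infinite; sample means of
draws converge slowly, which the tests account for by using empirical
standard errors.

## The hierarchical parentage-and-dispersal model

For each seedling $k$ at location $x_k$ inside a mapped plot, the
candidate mothers and fathers are the mapped adults (each with
coordinates, a genotype, and a fecundity posterior) plus an explicit
*out-of-plot* slot. The pedigree prior is the two-stage law of seed and
pollen rain:

* the mother is tree $i$ with probability equal to $i$'s share
  $f_i K(d_{ik}; u_s) / A_k$ of the total seed rain $A_k$ at $x_k$,
  where $A_k$ sums over all mapped adults and the integrated exterior;
* given the mother, the father is tree $i'$ with probability equal to
  $i'$'s share $c_{i'} K(d_{i'i}; u_p) / B_i$ of the total pollen rain
  $B_i$ at the mother (self excluded — the model assumes
  self-incompatibility, so a tree is never both parents of one
  seedling). Pollen output $c_{i'}$ is taken proportional to seed
  production.

The normalising totals $A_k$ and $B_i$ depend on $(u_s, u_p)$, so they
appear in the dispersal-parameter likelihood, not only in the pedigree
conditional. This is the reading of the model under which it is a
proper generative distribution — it is exactly the law the package's
own forward simulator draws from — and in simulation studies it is what
makes posterior credible intervals calibrated; dropping the normalisers
biases the pollen parameter low (it rewards concentrating the kernel on
the nearest neighbours) and is detectable by likelihood profiling at
the true pedigree.

**Genotype likelihood.** The probability that a candidate pair produces
the observed offspring genotype is a product over loci (loci are
treated as unlinked) of Mendelian transmission convolved with a
two-channel genotyping-error model:

* *allelic dropout* (rate $e_2$ per locus): a heterozygote is recorded
  as a homozygote for one of its alleles, equal split;
* *mistyping* (rate $e_1$ per locus): each recorded allele
  independently moves one motif step along the allele-size ladder
  (equal split up/down; at a ladder boundary the whole mistype mass
  moves inward). Dropout composes first, then mistyping.

The "adjacent size bin" neighbourhood is the minimal faithful reading
of stutter-type mistyping; rates in the 0.02–0.08 (dropout) and
0.02–0.18 (mistyping) ranges per locus are typical of the
microsatellite panels this targets and are the simulator defaults.
Because *adult* genotypes are themselves typed with error, a known
parent's transmission distribution integrates over its true genotype —
posterior proportional to a Hardy–Weinberg prior times the observation
model — rather than taking the observed genotype at face value
(`offspring_genotype_prob(..., parent_error = TRUE)`, the default).
Taking parents at face value makes true parents look incompatible
whenever one of their calls is corrupted, and measurably inflates the
seed-dispersal estimate. Unmapped parents transmit alleles from the
population allele frequencies (pooled over all mapped adults: the
stands are treated as a single interbreeding population because the
co-occurring red-oak species hybridise; `subset_species()` provides the
no-hybridisation single-species mode). Loci with a missing offspring
call are skipped; a parent's missing call falls back to population
frequencies.

**Out-of-plot integration.** Both stands are assumed embedded in
continuous forest with the same adult density and mean fecundity as the
mapped plot. Dispersal from outside is integrated over a regular grid
of virtual-parent cells tiling the annulus between the plot boundary
and a cutoff radius (`build_exterior_grid()`). Defaults are 10 m
spacing and a 500 m cutoff; the examples and tests use coarser grids
(25–40 m, 150–250 m) because the exterior field is smooth at those
scales — the grid is a quadrature, and its resolution is a numerical
choice, reported with the results it produces. Cells carry the mean
fecundity everywhere, including inside their pollen-rain normalisers;
this keeps the expensive exterior cross-term independent of the
per-iteration fecundity draws. A warning is issued if the cutoff is
less than twice the expected seed dispersal distance (tail
truncation).

**Priors.** Truncated normals chosen for *Quercus* from the
literature: seed prior centred at $u_s = 253$ (mean distance 25 m)
with SD 1000, truncated at the parameter values corresponding to mean
distances of 5 m and 157 m; pollen centred at $u_p = 2000$ (70.2 m)
with SD 1500, truncated at 5 m and 192 m (conversion via
`param_from_distance()`). The SDs are interpreted on the
*mean-distance* scale, where they dwarf the truncation windows: the
priors are weakly informative and the truncations carry the real
constraint. This is a deliberate design choice: were the SDs read on
the $u$ scale, posterior means more than a few thousand m² above the
prior centres would be unreachable at realistic sample sizes (the
Fisher information of the 2D-t scale from $n$ parent–offspring
distances gives a likelihood SD of about $u\sqrt{3/n}$), yet analyses
of this model class report exactly such posteriors. `mcmc_config()`
accepts `scale = "u"` in either prior for the strongly-informative
alternative. The density over $u$ includes the distance-transform
Jacobian.

**Sampler.** Gibbs-within-Metropolis (`run_mcmc()`). Each sweep:

1. draw every tree's fecundity from a zero-truncated normal with its
   posterior mean and SD (mixing over fecundity uncertainty);
2. redraw every seedling's (mother, father) pair from its full
   conditional — a categorical over $(N+1)^2$ slots whose weights
   multiply the seed-rain share, pollen-rain share and genotype
   probability (the inner loop is compiled C++; the genotype factor is
   precomputed once per dataset as one $(N{+}1)\times(N{+}1)$ matrix
   per seedling, since it does not depend on $u$ or fecundities);
3. update $u_s$ then $u_p$ by Gaussian random-walk proposals on
   $\log u$, accepted by kernel likelihood × truncated-normal prior ×
   the $u'/u$ Jacobian. Proposal scales adapt toward ~30% acceptance
   during burn-in only, so the post-burn-in kernel is fixed.

The reference schedule is 50,000 sweeps, 30,000 burn-in, every 20th
draw retained (1,000 samples). Maternity and paternity are never
assumed from proximity: both orderings of every pair are enumerated,
so the model mixes over maternity-versus-paternity uncertainty. With
zero seedlings the sampler reproduces the prior, which the tests use
as a correctness check. Kernel matrices are memoised (two slots per
parameter) so rejected proposals cost only the selective likelihood
terms.

**Degenerate inputs.** A seedling all of whose parent-pair weights are
zero (possible when error rates are set to exactly zero against a
mismatching genotype) raises an error naming the seedling rather than
silently assigning it outside. An isolated mother with no possible
father contributes zero weight.

## The synthetic-data generator

`simulate_dataset()` is the forward mirror of the inference model and
defines the study conditions under which the package tests itself:

* 7.5-ha rectangular plot (250 × 300 m) at 26.5 adults/ha (~199
  adults), the denser of the two stand archetypes; density 9.8/ha on
  ~12 ha reproduces the sparser one;
* per-tree fecundity means from a Gamma with mean 948 seeds/yr (shape
  3, putting maxima for ~200 trees near 2,800–3,000); each tree's
  *realised* fecundity is one draw from its stated (mean, SD = 0.3 ×
  mean) posterior, so inference that mixes over fecundity uncertainty
  is coherent with the data;
* six microsatellite loci, 16 alleles each on a 2-bp ladder,
  frequencies from a Dirichlet(0.5) — uneven spectra within the 14–35
  alleles/locus range typical of these markers;
* dropout 0.02–0.08 and mistyping 0.02–0.18 across loci;
* seed and pollen dispersal by exact 2D-t draws; mothers sampled
  proportional to realised fecundity among all trees in the plot plus
  a surrounding forest belt (the edge-distance annulus to 250 m, same
  density and fecundity distribution), seeds kept only if they land in
  the plot, fathers sampled proportional to pollen output × pollen
  kernel at the mother, self excluded. Exterior parents give the OUT
  parentage categories realistic frequencies.

What it deliberately does **not** emulate: masting time series,
seedling mortality after establishment, species-assortative mating,
null alleles, and spatial aggregation of adults (locations are
uniform). Passing recovery tests therefore demonstrates correctness of
the inference under the model's own assumptions — not robustness to
clustered stands or demographic structure in real data.

## SGS scenario simulator

`run_scenario()` implements the pedigree-relatedness simulation used to
interpret observed spatial genetic structure. A scenario specifies the
founding seed sources: *distant* (recolonisation from several source
populations outside the stand — the ploughed-field history), *scattered*
(source trees at 1.5/ha, alternative 0.5/ha, within and around the
stand — the selective-logging history), or *mixed* (distant pools plus
a few local trees). Three "generations" stand in for large adults,
small adults and seedlings; generation $g$ receives a mother
proportional to the seed kernel from the candidate set (sources plus
all older generations) and a father proportional to the pollen kernel
at the mother. Relatedness is the additive (numerator-relationship)
recursion — full sibs 0.5, half sibs 0.25, higher under inbreeding —
and profiles are means over pairs in 10-m distance classes from 0 to
100 m, aggregated over 100 replicates (mean, min, max). The seed
parameter sweep {20, 100, 800, 3500, 7000} corresponds to mean
distances {7, 16, 44, 93, 131} m, with pollen fixed at $u_p = 9000$
(149 m).

The original analysis used the actual stand maps, which are not
distributed; by default cohort locations are drawn uniformly in the
plot each replicate (100 per generation on the 7.5-ha default plot,
about the mapped cohort sizes), and `cohort_xy` accepts user-supplied
maps. The distant pools' geometry is not printed anywhere, so it is
config: 4 pools of 25 unrelated founders centred 250 m beyond the plot
boundary with 30 m spread. The qualitative contrasts the simulator must
reproduce (flat ≈ 0 profiles from distant sources at every dispersal
scale; short-range structure rising as scattered-source density falls;
steeper decline with distance for shorter dispersal) are insensitive to
the pool geometry — they are asserted as quantitative checks in the
test suite — but absolute relatedness levels in the distant scenario do
scale with pool number and size, which is worth remembering when
comparing to any specific published figure.

Genotypes are *not* simulated for scenario trees; the comparison with
the empirical autocorrelation below is qualitative by design (the
coefficient of relatedness and the genetic correlation $r$ are
different statistics).

## Empirical spatial autocorrelation

`autocorrelation_r()` computes the multiallelic codominant
autocorrelation used for the three empirical cohorts (large adults,
small adults by median-DBH split — ties to small, `partition_cohorts()`
— and seedlings). Squared genotypic distances per locus follow the
standard codominant table (0, 1, 2, 3, 4 for identical, one-shared-het,
disjoint-het, hom-vs-disjoint-het, opposite-hom; equivalently
$\tfrac12\lVert y_i-y_j\rVert^2$ on allele counts), summed over loci,
Gower-centred to a covariance matrix $C$, and for class $h$

$$r(h) = \frac{\sum_{i<j \in h} c_{ij}}{\sum_{i<j \in h}
 (c_{ii}+c_{jj})/2}.$$

Confidence intervals bootstrap the pairs within each class; the
significance reference is a permutation envelope from shuffling
genotypes across locations (999 by default). The two answer different
questions — the bootstrap is uncertainty in $r$, the permutation is the
null around 0 — and both are reported. Individuals with any missing
call are excluded (the estimator's centring is not defined piecewise
here); with the package's simulated data missingness is absent unless
configured.

## Migration speed

For range-shift arithmetic under the fat-tailed kernel, the asymptotic
front speed from jumps by the furthest-forward individual is

$$V = \frac{\sqrt{(\pi/2)\,u\,R_0}}{T},$$

with generation time $T$ (yr) and expected lifetime reproduction
$R_0$ = seeds/yr × reproductive years × survival-to-adulthood
(`wave_speed()`, `lifetime_R0()`). Two populations sharing demography
differ in speed by exactly $\sqrt{u_1/u_2}$ (`speed_ratio()`). Standard
oak-like numbers ($T = 20$, 800 seeds/yr over 80 years, 99.9%
pre-adult mortality, so $R_0 = 64$) give speeds of a few to a few tens
of m/yr across the $u$ range this package estimates — the point being
that even the long-dispersal estimates fall far short of the hundreds
of m/yr that latitudinal climate tracking would require. Stochasticity
in $R_0$, which can slow fronts by orders of magnitude, is out of
scope.

## Problem sizes used in the checks

The test suite runs everything end to end at deliberately reduced but
honest sizes, chosen for accuracy per unit compute and stated here as
the package's own methodological choices: the schedule check runs the
full 50,000-step reference chain on a ~50-adult stand; the
prior-recovery check uses 10,000 retained draws with an
autocorrelation-aware (batch-means) standard error; sampler-vs-
enumeration equivalence uses a 4-adult, 2-seedling, single-locus
instance with 10⁵ Gibbs draws; and parameter recovery runs 20
replicates of the full-size stand (~199 adults, 200 seedlings,
$u_s = 800$, $u_p = 5000$, 2% error rates) with 1,500-sweep chains
(500 burn-in, thin 5) and a 40 m / 240 m exterior grid, requiring 95%
credible intervals to cover truth in at least 90% of replicates for
each parameter. Chains of this length pass standard trace inspection
for this posterior (the adaptive burn-in reaches the stationary region
within a few hundred sweeps at these data sizes); the reference
schedule remains the default for real analyses.

## Known limitations

* The exterior is a quadrature over virtual parents; posterior
  sensitivity to the cutoff and spacing should be checked per dataset
  (halving the spacing is a cheap refinement test).
* Loci are assumed unlinked and in Hardy–Weinberg proportions for
  unmapped parents; null alleles are not modelled.
* Two seedlings sharing an *unmapped* parent are treated as
  independent draws from the population — cryptic sibship outside the
  plot is not modelled.
* The mistyping neighbourhood is exactly one motif step; panels with
  frequent two-step artefacts would need a wider neighbourhood.
* Interspecific pollination is all-or-nothing (pooled vs
  single-species analysis); no partial weighting is estimated.
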