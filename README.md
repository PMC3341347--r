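# seedshadow

Hierarchical Bayesian estimation of **seed and pollen dispersal
kernels** and **seedling parentage** for mapped stands of nut-bearing,
wind-pollinated trees (red oaks are the motivating system), where
scatter-hoarding animals make seed movement invisible to seed traps and
genetic data are the only window on effective dispersal.

The package is aimed at forest geneticists and ecologists who have, for
one mapped stand: adult coordinates and DBH, per-tree fecundity
estimates (posterior mean and SD), seedling coordinates, diploid
microsatellite genotypes for all individuals, and per-locus genotyping
error rates from repeat typing. It returns posterior distributions for
the dispersal parameters, a full posterior over each seedling's parent
pair (including *out-of-plot* mother and/or father), and the derived
quantities a study of this kind reports.

## The model

Dispersal follows the fat-tailed one-parameter 2D-t kernel

    K(r) = u / (π (u + r²)²),      mean distance  E[r] = (π/2) √u

for seed (parameter `u_s`) and pollen (`u_p`) separately. For a
seedling *k*, mother *i* and father *i′*, the pedigree prior is the
two-stage law of seed and pollen rain — the mother is tree *i* with
probability equal to her share `f_i K(d_ik; u_s)` of the total seed
rain at the seedling, and the father is *i′* with probability equal to
his share `c_i′ K(d_i′i; u_p)` of the total pollen rain at the mother
(self excluded). Dispersal from beyond the mapped stand is integrated
over a grid of virtual parents at the in-plot density and mean
fecundity. The genotype likelihood multiplies Mendelian transmission
across loci through a two-channel genotyping-error model (allelic
dropout `e2`, adjacent-size mistyping `e1`), integrating over error in
the parents' own observed genotypes as well. Truncated-normal priors on
`u_s` and `u_p` complete the model; inference is Gibbs (pedigrees,
fecundities) within Metropolis (dispersal parameters) — see
`vignette("parentage-dispersal-methods")`.

Companion modules: a forward simulator producing complete synthetic
datasets with known truth (`simulate_dataset()`); a pedigree-based
simulator of spatial genetic structure under stand-history scenarios
(`run_scenario()`); multilocus spatial autocorrelation *r* with
bootstrap CIs and permutation envelopes (`autocorrelation_r()`); and
asymptotic migration wave speeds for the fat-tailed kernel
(`wave_speed()`, `speed_ratio()`).

## Worked example

Simulate a 3-ha stand with restricted seed dispersal (`u_s = 253`,
mean 25 m) and extensive pollen flow (`u_p = 2000`, mean 70.2 m), then
re-estimate both from the noisy genotypes:

```r
library(seedshadow)
cfg <- sim_config(poly = cbind(c(0, 150, 150, 0), c(0, 0, 200, 200)),
                  density_ha = 20, n_seedlings = 60,
                  u_s = 253, u_p = 2000)
sim <- simulate_dataset(cfg, seed = 42)
fit <- run_mcmc(sim$data,
                mcmc_config(n_steps = 4000, burnin = 2000, thin = 10,
                            grid_cutoff = 200, grid_spacing = 25,
                            progress_every = 0),
                seed = 1)
summarize_posterior(fit)
```

```
Posterior summary (200 samples)
 parameter   mean     sd ci_lower ci_upper mean_distance_m dist_ci_lower_m
       u_s  156.4  52.83    75.55    275.9           19.65           13.65
       u_p 1969.0 601.52   976.35   3076.9           69.70           49.08
 dist_ci_upper_m
           26.09
           87.13

Parentage categories (modal assignment):
             category seedlings percent
                in_in        32    53.3
 in_father_out_mother         0     0.0
 in_mother_out_father        25    41.7
              out_out         3     5.0
```

Both true parameters sit inside their 95% credible intervals: the seed
kernel's implied mean distance is estimated at 19.7 m (CI 13.7–26.1 m,
truth 25 m) and the pollen kernel's at 69.7 m (CI 49.1–87.1 m, truth
70.2 m). The category table is the posterior's answer to "where were
the parents?": here most seedlings keep an in-plot mother while 42%
have an unmapped father — the classic wind-pollination signature. For
real analyses use the default reference schedule
(`mcmc_config()`: 50,000 sweeps, 30,000 burn-in, thin 20 → 1,000
retained samples).

Derived migration arithmetic:

```r
wave_speed(20, 92, lifetime_R0(800, 80, 0.001))   # 4.8 m/yr
expected_distance(c(92, 6300))                    # 15, 125 m
```

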