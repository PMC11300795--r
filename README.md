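# cryoreweight

Bayesian reweighting of pre-computed structural ensembles against cryo-EM
density maps.

A single-particle cryo-EM map averages over every conformational and
compositional state in the sample, so dynamic systems — hinged enzymes,
ribosome-bound nascent chains, partially occupied auxiliary factors — are
poorly described by any single fitted model. Given an ensemble of aligned
atomic structures (typically from molecular dynamics) and a map,
`cryoreweight` adjusts the per-structure statistical weights so that the
weighted average of the simulated densities matches the map, yielding state
populations, per-residue fluctuations and principal motions consistent with
the data. It is aimed at structural biologists and simulators who already
have an ensemble and want the experiment to arbitrate its populations.

## The model

With member weights $w_i$ ($i = 1..M$), reference density $\rho^0_n$ on the
selected voxels ($n = 1..N$) and per-member simulated densities
$\rho^i_n(\sigma)$, the method minimises the negative log posterior

$$
\theta \sum_i w_i \ln\frac{w_i}{w_i^0}
 \;+\; \sum_n \frac{\bigl[\rho^0_n - \alpha \sum_i w_i \rho^i_n(\sigma)\bigr]^2}{2\sigma_L^2}
$$

over gauge-fixed log-weights (BFGS with analytic gradients). The map scale
$\alpha$ is profiled analytically, the likelihood variance $\sigma_L^2$ is
estimated from the solvent region, and the kernel width $\sigma$ can be
scanned on a grid. The confidence parameter $\theta$ is chosen
automatically at the knee of the misfit–entropy L-curve (Kneedle with a
misfit-band guard). An iterative mode repeatedly keeps the
$\lceil N_\mathrm{eff} M \rceil$ top-weight members and reweights from a
fresh uniform prior until the misfit $\chi^2$ rises, returning a minimal
sub-ensemble. Synthetic benchmark generators (discrete two-state mixtures,
continuous-ensemble subsets, compositional mixtures) with exact ground
truth are included, as are MRC I/O, a Gaussian forward model, and the
evaluation metrics CC, SMOC, Jensen–Shannon divergence, weighted RMSF and
weighted PCA. See the methods vignette
(`vignettes/ensemble-reweighting.Rmd`) for assumptions, parameter defaults
and numerical choices.

## Worked example

Recover the state populations of a discrete two-state mixture from a noisy
6 Å map:

```r
library(cryoreweight)

ens   <- make_two_state_ensemble(M = 100, seed = 11)      # open/closed toy ensemble
bench <- make_mixture_reference(ens, c(0.3, 0.7),          # 30% open, 70% closed
                                resolution = 6, noise_fraction = 0.01, seed = 42)

res <- reweight_standard(bench$map, model_maps = bench$model_maps,
                         resolution = 6, noise = bench$noise)
res
#> Bayesian map reweighting (standard mode)
#>   M = 100 members, N = 1076 voxels, kernel sigma = 1.35 A
#>   selected theta = 10000, alpha = 19.69, sigma_L2 = 0.0001078
#>   chi2 = 1552, S_KL = 0.07392 nats, Neff = 0.929
#>   map CC (selection): prior 0.9518 -> posterior 0.9977

sum(res$weights[ens$labels == "open"])
#> [1] 0.3105844
```

The knee-selected posterior puts 31% of the weight on the open state
(truth 30%), and the correlation between the posterior average map and the
reference rises from 0.952 to 0.998. `iterative_reweight()` runs the
shrinking variant and returns the round-by-round trace; `weighted_rmsf()`
and `weighted_pca()` profile the dynamics of the reweighted ensemble.

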