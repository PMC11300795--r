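---
title: "Bayesian reweighting of structural ensembles against cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian reweighting of structural ensembles against cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoreweight)
```

## The problem

A single-particle cryo-EM map is an average over the conformational (and
sometimes compositional) states present in the sample. When the imaged
system is dynamic — a hinged enzyme switching between open and closed
forms, a nascent chain flailing outside the ribosomal exit tunnel, an
auxiliary factor only partially occupying its binding site — no single
atomic model explains the density. A molecular-dynamics simulation can
propose a pool of plausible conformations, but its populations reflect the
force field, not the experiment.

`cryoreweight` adjusts the statistical weights of such a pre-computed,
pre-aligned ensemble so that the weighted average of the per-structure
simulated densities matches the experimental map, without generating any
new conformations. The output is a posterior ensemble: the same structures,
new weights, and with them populations, per-residue fluctuations and
principal motions that are consistent with the density.

## The model

Let $w_i$ be the weight of ensemble member $i$ ($i = 1..M$), $\rho^0_n$ the
reference density in selected voxel $n$ ($n = 1..N$), and $\rho^i_n(\sigma)$
the density simulated from member $i$ with a Gaussian kernel of width
$\sigma$. Bayes' theorem combines a Gaussian likelihood over voxels with a
maximum-entropy prior on the weights; minus the log posterior, up to a
constant, is

$$
\mathcal{L}(w) \;=\; \theta \sum_{i=1}^{M} w_i \ln\frac{w_i}{w_i^0}
\;+\; \sum_{n=1}^{N}
\frac{\left[\rho^0_n - \alpha \sum_i w_i \rho^i_n(\sigma)\right]^2}
     {2\sigma_L^2}.
$$

The first term is the Kullback–Leibler divergence $S_{KL}$ from the prior
weights $w^0$ (uniform unless stated otherwise): it penalises departures
from the simulation's populations, with the confidence hyperparameter
$\theta$ setting how much the prior is trusted. The second term is the
misfit; we report it as $\chi^2 = \sum_n r_n^2 / \sigma_L^2$ (without the
$\tfrac12$, which only the objective carries).

Three nuisance parameters appear:

* $\alpha$ — the scale between simulated and experimental density. It has a
  least-squares closed form at fixed weights,
  $\alpha^\ast = \sum_n \rho^0_n \bar\rho_n / \sum_n \bar\rho_n^2$, and is
  profiled out analytically inside every objective evaluation (same optimum
  as treating it as a free coordinate, better conditioning). The sign is
  unconstrained; a non-positive $\alpha$ triggers a warning because it
  indicates a pathological voxel selection.
* $\sigma_L^2$ — the variance of the Gaussian likelihood, playing the role
  of the experimental error. It is estimated once per dataset as the
  variance of the reference density over the solvent region (voxels where
  every model map is below its own $3\sigma_\text{map}$ threshold), with a
  floor of $10^{-6} \max(\rho^0)^2$ so that noiseless synthetic maps do not
  blow up the data term.
* $\sigma$ — the kernel width of the model densities. Because changing it
  requires rebuilding the whole $N \times M$ density matrix, it is handled
  by a discrete grid scan (`scan_sigma_kernel`), not by gradient descent;
  the width minimising the knee-selected posterior $\chi^2$ wins, ties going
  to the smaller width. For synthetic work the generating width
  $0.225 \times \text{resolution}$ is known and a scan is unnecessary.

### Optimisation in log-weight space

Weights must stay positive and normalised, so the optimisation runs over
log-weight parameters $g$ with
$w_i = w^0_i e^{g_i} / \sum_j w^0_j e^{g_j}$ and the gauge $g_M \equiv 0$
removing the normalisation degeneracy. The gradient is analytic (the
envelope theorem removes $\alpha$'s implicit dependence), and a BFGS
quasi-Newton drives it, warm-started along the $\theta$ scan.

Two numerical points deserve mention. First, convergence is declared at
$\lVert\nabla\rVert_\infty \le 10^{-8}\max(1, |\mathcal{L}|)$ — a relative
criterion, because with $\chi^2$ of order $10^3$–$10^5$ an absolute
$10^{-8}$ is below the float resolution of the objective. Second, at small
$\theta$ the optimum can sit on the simplex boundary (some $w_i \to 0$),
which is at infinity in $g$: the gradient never vanishes there, but the
objective and the weights stop moving, so stationarity of the objective
across a BFGS restart (relative $10^{-8}$) is also accepted. In standard
mode weights therefore never become exactly zero; in the KL term the limit
$x \ln x \to 0$ is enforced by clamping at $10^{-300}$.

## Selecting the confidence parameter

The scan covers $\theta \in \{0\} \cup \{10^{-2}, \dots, 10^{7}\}$ by
default, descending so each solve warm-starts the next. Along the scan
$S_{KL}$ is non-increasing and $\chi^2$ non-decreasing in $\theta$ — a
proper trade-off curve. The working point is its knee, found by the Kneedle
construction: sort the points by $S_{KL}$, min–max normalise both axes
(which makes the selection invariant to affine rescaling of either axis),
and take the point maximising the difference $d = (1 - y) - x$ —
equivalently, the point farthest below the corner-to-corner chord.

Two refinements were added after examining the geometry of real scans:

* **Grid refinement.** A decade-spaced grid localises the knee only to
  within a factor of ten. After a provisional knee is found, three extra
  log-spaced $\theta$ values are inserted between it and each grid
  neighbour, the scan is repeated once on the enriched grid, and the knee
  re-detected.
* **Misfit-band guard.** When the prior is far from the data (a two-state
  mixture at population 0.1 against a 50/50 prior, say), $\chi^2$ spans
  orders of magnitude along the scan and the geometric corner of the
  *linearly* normalised curve sits one decade too high in $\theta$,
  returning visibly under-fitted weights. The guard requires the selected
  point to deliver low misfit in absolute terms: its normalised misfit must
  lie within 1% of the scan's misfit range above the achievable floor;
  otherwise the selection moves to the largest-$N_\text{eff}$ point inside
  that band. Operating on the normalised axes keeps the affine invariance.

A $\theta = 0$ point whose effective sample fraction falls below $1/M$ is
excluded from knee candidacy (degenerate overfit), and a curve with no
knee at all (a straight trade-off line) falls back to the most-regularised
point whose $\chi^2$ is within 5% of the minimum, flagged as such.

The effective sample fraction is $N_\text{eff} = \exp(-S_{KL}) \in (0, 1]$:
the fraction of the ensemble effectively carrying weight. (Printed formulas
elsewhere sometimes carry the opposite sign, which would make
$N_\text{eff} \ge 1$ and the iterative selection below a no-op; the
standard effective-fraction convention is used throughout.)

## Iterative mode

Standard-mode weights never vanish, so a minimal explanatory sub-ensemble
requires iteration: after a standard run, keep the
$\lceil N_\text{eff} M \rceil$ members with the largest weights (never
fewer than 2; ties resolve to the lower member index), reset them to a
uniform prior, rebuild the voxel selection for the kept model maps, and
rerun the full scan. Rounds continue until the knee-selected $\chi^2$
increases — the previous round is returned — or until the selection stops
shrinking. Each round's sub-ensemble is treated as a fresh prior rather
than inheriting the posterior: inherited weights would double-count the
data. The ceiling (not floor or round) keeps selections non-empty.

## The forward model

Each atom contributes a normalised 3D Gaussian. Amplitudes are per-element,
from single-Gaussian collapses of the standard electron atomic scattering
factor parameterisations (H, C, N, O, P, S; unlisted elements fall back to
an amplitude proportional to atomic number, scaled to carbon). The width is
shared: $0.225 \times \text{resolution}$ for reference synthesis (matching
the common molmap convention) and the nuisance $\sigma$ for model maps. The
per-element intrinsic widths from the scattering-factor fits are tabulated
but do not modulate $\sigma$ ($\sigma_e^2 = \sigma^2 + b_e^2$ would be a
plausible alternative; with a single shared width the nuisance scan absorbs
the difference, so the simpler convention was kept and is stated here for
users).

Gaussians are truncated at $4\sigma$ per axis (truncation error below 0.4%
of an atom's mass), making map synthesis $O(\text{atoms})$. Total simulated
density equals the summed amplitudes to within 2% whenever the grid covers
$4\sigma$ around every atom, and integer-voxel translations shift the map
exactly — both properties are tested.

Maps are normalised before use: negative voxels zeroed, then divided by the
maximum ("rescaled to a molecular density of 1" is read as max $\to$ 1; the
alternative reading — rescaling so a contour threshold equals 1 — is noted
but not implemented). Voxels enter the reweighting dataset if the reference
exceeds $3\sigma_\text{noise}$ (or a user-supplied absolute threshold, for
experimental maps with a published contour level, or
$3\sqrt{\sigma_L^2}$ when the noise level is unknown) **or** any model map
exceeds $3\times$ its own standard deviation. The union keeps voxels where
models predict density the map lacks, which the likelihood must penalise;
an intersection would let spurious model density escape unpunished.
Anisotropic voxels are rejected rather than resampled.

## The synthetic benchmarks

The package ships generators that emulate the benchmark designs used to
validate this class of method, with exact ground truth:

* **Discrete two-state** (`make_two_state_ensemble` +
  `make_mixture_reference`): a two-domain hinged polymer of 30 CA-style
  pseudo-atoms whose end states differ by a 0.9 rad hinge rotation
  (end-state RMSD ≈ 6 Å, comfortably map-separable at 6 Å resolution);
  $M/2$ members jitter around each end state with 0.4 Å coordinate noise.
  References mix the two state-mean maps at populations 0 to 1 in 0.1
  steps; the full design crosses 11 populations × {3, 6, 10} Å × {1%, 10%}
  noise (66 maps), with a reduced default grid (3 populations × {6, 10} Å ×
  1%) for routine runs.
* **Continuous subset** (`make_continuous_ensemble` +
  `make_subset_reference`): 100 members with hinge angles drawn uniformly
  over [0, 1.2] rad; a seeded random 10-member subset defines the
  reference, and ground truth is uniform weight on the subset.
* **Compositional** (`make_compositional_ensemble`): two ensembles of
  different composition sharing a frame, mixed at a stated fraction;
  species labels ride through the reweighting so the recovered species mass
  can be read off the posterior.

Noise is Gaussian, added after normalisation, with standard deviation a
stated fraction (1% or 10%) of the clean map's maximum — defining the noise
on the normalised scale is what makes the $3\sigma_\text{noise}$ threshold
consistent with those fractions. Every generator is a pure function of its
seed, and each ground-truth object stores the clean map and the
normalisation scale so that `average_map(model_maps, truth$weights)`
reproduces it exactly (a tested invariant).

What the toys do not emulate: real secondary structure and side chains,
B-factor variation, solvent contrast, CTF/envelope effects, map
anisotropy, and alignment error (structures are generated in the map
frame). Passing the benchmarks therefore demonstrates the statistical
machinery — population recovery, target identification, fit improvement —
not robustness to experimental pathologies; for real maps the quality of
the prior ensemble and of the rigid alignment dominate.

Problem sizes for the routine runs were chosen at desk scale: ~20–40k voxel
grids (2 Å voxels at 6 Å resolution), $M = 100$ members, $N$ on the order
of a few thousand selected voxels, for seconds per standard run.

## Evaluation metrics

* `map_cc` — Pearson correlation over a voxel set; reported over the
  reweighting selection (matching the fitted objective's support), with the
  whole-box value alongside. The about-zero overlap variant is available,
  as the two conventions differ on background-dominated boxes.
* `smoc` — per-residue Manders overlap between reference and simulated
  density over a 5 Å zone around each residue's atoms: local fit quality,
  in [0, 1].
* `jensen_shannon` / `ensemble_js_divergence` — symmetric, ln 2-bounded
  divergence between weighted ensembles via histograms of a scalar feature;
  the default feature is RMSD to a fixed reference structure with
  Freedman–Diaconis bins, a declared choice (the feature space such
  comparisons use is rarely stated).
* `weighted_rmsf` / `weighted_pca` — fluctuations and principal motions of
  the weighted ensemble, computed on representative atoms (CA when present,
  else residue centroids) after two passes of weighted-mean superposition.
  PCA eigenvector signs are fixed (largest-magnitude entry positive);
  variance fractions are relative to the covariance trace. `fit = FALSE`
  skips superposition for ensembles already in a common frame.

## Known limitations

* The method reweights; it cannot create conformations missing from the
  prior, and a prior far from the data (low posterior correlation) needs
  better sampling, not a larger $\theta$ scan.
* A single global $\sigma_L^2$ ignores local resolution variation;
  pre-filtering the map (or splitting it) is the intended workaround.
* The rigid-fit helper is a coarse convenience search on a small
  translation/rotation grid, not a substitute for a dedicated fitting tool;
  structures should arrive aligned.
* Memory scales as $N \times M$ doubles for the density matrix plus one
  grid per member; clustering near-duplicate structures before reweighting
  is the practical mitigation for large ensembles.
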