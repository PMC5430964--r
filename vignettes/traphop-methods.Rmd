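---
title: "Trap-hop analysis of polymer transport in micropost arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trap-hop analysis of polymer transport in micropost arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traphop)
```

# The scientific problem

A long, flexible macromolecule (a dye-labeled DNA coil with contour length
around 21 µm and in-slit radius of gyration $R_g \approx 0.84$ µm) diffuses
in a nanoslit containing a hexagonal array of cylindrical microposts to
which it is weakly attracted. Its center-of-mass (COM) trajectory shows
*trap–hop* dynamics: long dwells near one post punctuated by rapid jumps of
roughly one $R_g$ toward a neighbouring post. Because imaging frame rates
cannot resolve the jump itself, the hop statistics must be inferred from
coarse, regularly sampled displacement series. `traphop` implements the
full computational tool-chain for this problem:

* a coarse-grained Langevin dynamics simulator for a Gaussian bead-spring
  chain in the slit-confined post array (`sim_config()`, `run_sim()`);
* trajectory statistics — MSD, windowed diffusivities, displacement
  distributions and their exponential / stretched-exponential /
  shifted-Gaussian fits (`msd()`, `fit_diffusivity()`,
  `fit_exponentials()`, `fit_trap_width()`);
* a hidden-Markov trap-hop decoder that infers the per-frame trapping
  probability $P^*_{\mathrm{trap}}$ and the apparent barrier
  $\Delta G = -\ln(1 - P^*_{\mathrm{trap}})$ by Viterbi iteration
  (`viterbi_iterate()`, `scan_step_size()`);
* the analytic conformational-fluctuation barrier model and
  potential-of-mean-force (PMF) maps from COM histograms
  (`barrier_height()`, `pmf_from_samples()`);
* synthetic trajectory generators that stand in for unavailable
  experimental tracks (`synth_traphop()`, `synth_brownian()`,
  `synth_trapped()`).

# The Langevin model

The chain is $N = 160$ beads of diameter $\sigma$ (one Kuhn segment,
mapped to 134 nm), joined by FENE springs with $k_s = 30\,k_BT/\sigma^2$
and maximum extension $r_o = 1.5\sigma$, plus a WCA core between *bonded*
neighbours only — non-bonded beads do not interact, so the chain is
Gaussian. Each bead obeys underdamped Langevin dynamics with mass
$m = 1$, friction $\gamma = 0.1$ and thermal energy $k_BT = 1$,
integrated by velocity Verlet with $\Delta t = 0.01$ time units
($0.1\,t_D$, where $t_D = \sigma^2/D_0$ and $D_0 = k_BT/m\gamma$ is the
bead diffusivity). Posts of radius $R = 16\sigma$ on a triangular lattice
with surface-to-surface gap $d$ act on every bead through a Lennard-Jones
potential in the distance $s$ from the post surface,
$U_{PA}(s)/k_BT = 4\varepsilon[(\sigma/s)^{12} - (\sigma/s)^6]$, truncated
and shifted at $s = 2.5\sigma$ (attractive wells of depth
$\approx\varepsilon$) or at $s = 1.12\sigma$ (purely repulsive). Walls at
$z = 0$ and $z = H = 3\sigma$ reflect specularly; the slit plane is
periodic.

Numerical conventions worth stating:

* **FENE argument.** The standard Kremer–Grest form
  $-\tfrac12 k_s r_o^2 \ln[1 - (r/r_o)^2]$ is the default; a `fene_form =
  "literal"` switch exposes the variant with an unsquared argument for
  comparison. The quoted parameters are the canonical Kremer–Grest ones.
* **Random-force convention.** The per-component random force has standard
  deviation $(2 m \gamma k_BT/\Delta t)^{1/2}$, the unique choice that
  satisfies fluctuation–dissipation at $k_BT = 1$. The package verifies
  this two ways: a single bead reproduces $D_0 = k_BT/m\gamma$ within
  ~1%, and its position samples reproduce exact Boltzmann shell weights
  around an attractive post to ~2%.
* **Energy shift at the cutoff** is applied in both modes so the force is
  continuous; it changes the attractive well depth by ~1.6% of
  $\varepsilon$.
* **Inertia matters for fitting.** With $\gamma = 0.1$ the velocity
  autocorrelation time is $1/\gamma = 100\,t_D$, so diffusivities are read
  from MSD slopes with a free intercept at lags of several hundred $t_D$,
  never through the origin at short lags.
* **Initial states** are rejection-grown random walks at the mechanical
  equilibrium bond length (~0.96 σ), kept inside the slit and at least one
  diameter away from post surfaces, followed by thermostatted
  equilibration.

## The adsorption threshold and the $\varepsilon = 0.6$ regime

With the fluctuation–dissipation-consistent thermostat the ideal chain
does **not** adsorb to the posts at $\varepsilon = 0.6$: its COM is
depleted near the surface (the entropic correlation hole wins), and the
gap PMF is barrierless at every gap size. Chain adsorption sets in between
$\varepsilon = 0.6$ and $1.0$ and is strong at $\varepsilon \ge 1$, where
the package shows the trap-hop phenomenology this model family is used
for: COM density peaked along the post perimeter and gap barriers that
grow with $d/R_g$. Legacy implementations of this model family sometimes
treat the quantity $(2 m \gamma k_BT/\Delta t)^{1/2}$ as the random-force
*variance* rather than its standard deviation; that convention runs the
system at $k_BT_{\mathrm{eff}} \approx 0.22$, i.e. an effective
attraction of $\approx 2.7\,k_BT$ at nominal $\varepsilon = 0.6$, which
does trap — but it is dimensionally inconsistent and breaks the Rouse
diffusivity $D_{\mathrm{Rouse}} = D_0/N = 0.00625\,\sigma^2/t_D$ that the
free-chain simulation must (and here does) reproduce. The test suite
therefore exercises adsorption physics at $\varepsilon \ge 1$ and records
the $\varepsilon = 0.6$ barrier contrast as a known, documented
discrepancy rather than tuning the thermostat toward it.

# Trajectory statistics

`msd()` computes the sliding-window (all overlapping pairs) MSD with a
per-lag uncertainty equal to the difference between the two half-ensembles
of pairs. Diffusivities are `slope/(2 dim)` over a stated lag window —
`dim = 2` for slit-plane tracks. Displacement distributions $P(r^2,
\Delta t)$ are fitted on $\ln P$ vs $r^2$ weighted by bin counts (the
variance-correct weighting in log space, and the numerical analogue of
ruler fits on semilog axes): single exponentials give
$\lambda = 4D\Delta t$ for Brownian motion; double exponentials separate
around-post ($\lambda_1$) from cross-post ($\lambda_2$) transport, with the
tail scale seeded from bins beyond $3\lambda_1$; the stretched variant
reports $\beta$ with $\beta = 1$ as the simple-diffusion limit. The
shifted-Gaussian trap-width fit uses the convention
$A\exp[-(r-c)^2/w^2]$ — no factor 2 — so that the fitted $w$ is exactly the
emission width `w_trap` of the decoder; it is solved as a count-weighted
quadratic regression of the log bin mass, which is closed-form and robust
at the ~1000-frame sample sizes typical of one long-term trajectory.

# The trap-hop decoder

The displacement series $r(t) = |\vec r(t) - \vec r(0)|$ is modelled by a
ladder of trapped levels at $r_0(j) = j g$ ($g \approx 0.84$ µm, one $R_g$)
with Gaussian emission weights $\exp[-(r - jg)^2/w_{\mathrm{trap}}^2]$,
$w_{\mathrm{trap}} = 0.31$ µm (the exponent is necessarily negative: a
positive one would make distant levels infinitely likely). Transitions
form a tridiagonal row-stochastic matrix: diagonal
$P_{\mathrm{trap}}$, interior off-diagonals $P_{\mathrm{hop}}/2$, full
$P_{\mathrm{hop}}$ on the single neighbour of the boundary levels.

One iteration decodes the maximum-probability level path (log-space
Viterbi, uniform prior, ties to the lower level), counts the observed
transition matrix $T^*$, and refits $P_{\mathrm{trap}}$ by minimizing
$|T^* - T(P_{\mathrm{trap}})|$ over visited rows; iteration stops when
$P_{\mathrm{trap}}$ moves less than `tol` ($10^{-3}$, at most 100
iterations). Two numerical choices deserve explanation:

* **Row weighting.** The row residuals are weighted by the row visit
  counts. An observed row's sampling variance scales inversely with its
  visits, and an unweighted norm lets levels crossed once or twice during
  a ladder excursion dominate: at $P_{\mathrm{trap}} = 0.7$ and 1000
  frames the unweighted fit is biased low by about 0.07, while the
  weighted fit recovers the generator value within ±0.05 across
  $P_{\mathrm{trap}} \in [0.3, 0.9]$. Uniform weights remain available in
  `fit_p_trap()`.
* **Fit-quality scale.** The Pearson statistic is computed on transition
  *counts* ($O$ = observed counts, $E = n_i T_{ij}$, denominator the
  observed entry, $\nu$ = non-zero observed entries − 3): on
  self-generated data this sits near 1 independent of trajectory length,
  which is the scale on which a fit criterion of $\chi^2/\nu = 1$ is
  meaningful. The same statistic on raw probability matrices decays
  toward zero as sampling grows; it is kept as `chi2_prob` for
  comparability.

A greedy nearest-level baseline (`decoder = "greedy"`) decodes each frame
independently. On idealized synthetic data with independent Gaussian
emission noise, its level-flicker is largely absorbed by the refitted
$P_{\mathrm{trap}}$, so its $\chi^2/\nu$ is only moderately worse than the
Viterbi fit while its $P_{\mathrm{trap}}$ estimate is visibly biased low;
very poor greedy fit qualities arise on real trajectories through data
features the idealized generator omits, chiefly temporally correlated
within-trap fluctuations.

The number of levels defaults to $\lceil \max r / g\rceil$ — an output of
the analysis, not an input. `scan_step_size()` reruns the iteration over a
grid of $g$ and flags local minima of $\chi^2/\nu$; a mixture of two hop
scales produces two flagged optima. `detection_floor()` gives the smallest
resolvable $P_{\mathrm{trap}}$, $\exp(-\Delta t\, f_{\mathrm{Nyq}})$, from
the frame interval and acquisition rate; fits below it are flagged.

# Free-energy barriers

Two independent barrier estimates frame the analysis. From the decoder,
$\Delta G = -\ln(1 - P^*_{\mathrm{trap}})$ in $k_BT$. From conformational
statistics, a one-dimensional transition path between two posts a gap $d$
apart: each post contributes a half-Gaussian well of variance
$\langle x^2\rangle_0 = \langle R_{EE}^2\rangle_0/3 = 2R_g^2$, so
$\beta F(x) = [x^2 + (x-d)^2]/(2\langle x^2\rangle_0)$ and the barrier at
$x = d/2$ is $\beta F^* = d^2/8R_g^2$. (This sum formula is convex with a
single minimum at $d/2$, even though the two-well intuition behind it
would place minima at $x = 0$ and $x = d$; the package evaluates the
formula as written, whose midpoint value gives 0.45, 0.85 and 1.6 $k_BT$
for $d$ = 1.6, 2.2, 3.0 µm at $R_g = 0.84$ µm.)

Simulation PMFs are Boltzmann inversions $U_{\mathrm{eff}}/k_BT =
-\ln P(r_{\mathrm{COM}})$ of COM histograms folded into one primitive cell
using lattice translations only (no point-group averaging — finite
sampling need not respect reflection symmetry). Unpopulated bins are `NA`,
never infinite; landscapes are gauge-fixed to zero at their minimum; the
uncertainty surface is the difference between half-ensemble maps; the gap
transect runs along the line joining nearest-neighbour post centers,
reported against distance from the post surface.

# The synthetic generators and what they do (not) emulate

`synth_traphop()` inverts the decoder's observation model: a latent level
ladder that stays with probability $p_{\mathrm{trap}}$, hops ±1 otherwise
(reflecting at zero; optional ceiling; optional two-scale hop mixture),
observed through Gaussian noise of standard deviation
$w_{\mathrm{trap}}/\sqrt2$ — the value that makes the fitted
shifted-Gaussian width return exactly $w_{\mathrm{trap}}$, keeping
generator and decoder conventions bit-consistent. Defaults follow the
long-term observation settings (one frame per 3 s for 3000 s; the
short-term settings are 0.5 s for 100 s), $g = 0.84$ µm,
$w_{\mathrm{trap}} = 0.31$ µm. `synth_brownian()` (2-D Gaussian
increments, variance $2D\Delta t$ per axis) and `synth_trapped()`
(i.i.d. shifted-Gaussian displacements) are the null models for the
estimator round-trips. All generators are pure functions of their
arguments and seed.

These generators emulate the *statistical* structure the analysis assumes
— they contain no photophysics, no localization error, no within-trap
temporal correlation, and no continuous approach/departure during hops.
Passing round-trip tests therefore certifies the estimators under the
model's own assumptions, not the behaviour of the full imaging pipeline on
real movies.

# Problem sizes used by the tests

The packaged checks run at desk scale, chosen as the smallest sizes at
which the targeted quantities are statistically resolvable: free-chain
runs of $5 \times 1.5\times10^6$ steps ($5\times150{,}000\,t_D$) for the
Rouse diffusivity and projected $R_g$ (both to within 10%); PMF runs of
$3 \times 1.5\times10^6$ steps per gap size with samples every $10\,t_D$;
decoder recovery on 1000-frame synthetic series, five seeds per condition.
Production-scale studies of this system run $10^7$–$10^8\,t_D$ per trial
with of order ten trials per parameter set; the package exposes the same
machinery, so longer runs are a matter of configuration.

# Known limitations

* No hydrodynamic interactions, excluded volume between non-bonded beads,
  or electrostatics; attraction is phenomenological through ε.
* The ε = 0.6 adsorption discrepancy described above.
* The decoder assumes a single step scale g per run (the scan handles
  multi-scale data only diagnostically) and a displacement ladder starting
  at zero.
* PMF transects interpolate nothing: unpopulated bins stay undefined, so
  deeply trapped, short runs can report an effectively unsampled barrier.

# A worked example

```{r example, eval = FALSE}
library(traphop)

# synthetic long-term displacement trajectory at the study conditions
traj <- synth_traphop(p_trap = 0.6, step_size_g = 0.84, w_trap = 0.31,
                      frame_interval = 3, duration = 3000, seed = 1)

fit <- viterbi_iterate(traj, step_model(0.84, 0.31))
fit
#> Trap-hop HMM fit (viterbi): p_trap* = 0.6303, chi2/nu = 0.872,
#> dG = 0.995 kT (N = 39, 4 iterations)

# the analytic barrier for the d = 2.2 um array
barrier_height(barrier_model(2.2, 0.84))
#> [1] 0.8574263
```
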