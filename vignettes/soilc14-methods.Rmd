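---
title: "Modelling soil carbon turnover with bomb radiocarbon: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil carbon turnover with bomb radiocarbon: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the estimation machinery, the numerical
choices, and the design decisions behind `soilc14`, in the spirit of the
methods sections of compartmental-modelling packages. Nothing here reports
a number that the test suite or `scripts/acceptance.R` does not itself
compute.

## The compartmental model and its assumptions

Topsoil organic carbon is represented as two pools in series. All plant
inputs $I(t)$ (Mg C ha$^{-1}$ yr$^{-1}$) enter the fast pool; each pool
loses carbon by first-order decay, and a fraction $a_{21}$ of the fast
pool's loss flux is transferred to the slow pool instead of being respired:

$$\frac{dC}{dt} = I(t) + A\,C, \qquad
A = \begin{pmatrix} -k_1 & 0 \\ a_{21} k_1 & -k_2 \end{pmatrix}.$$

A note on the off-diagonal entry: the transfer *flux* is $k_1 a_{21} C_1$,
so the matrix entry is the product $a_{21} k_1$ — $a_{21}$ alone is a
dimensionless fraction, not a rate. `build_system_matrix()` implements
this convention, which is the one consistent with reporting transfer as a
percentage of the fast-pool stock moved per year.

Each pool carries a $^{14}$C/$^{12}$C ratio relative to the standard
("fraction modern", $F = 1 + \Delta^{14}\mathrm{C}/1000$). The tracer
moves with the carbon and decays radioactively:

$$\frac{d(F \circ C)}{dt} = F_{atm}(t)\, I(t) + A\,(F \circ C)
  - \lambda\,(F \circ C).$$

Assumptions worth making explicit:

* **First-order, time-invariant rates within a window.** Environmental
  effects (moisture, nutrient status) are absorbed into the fitted $k$'s;
  there are no explicit rate modifiers. Management-era drift is handled by
  fitting two overlapping windows (1958–1992 and 1985–2010 in the
  motivating application) with independent parameters.
* **All inputs to the fast pool.** Root and shoot litter are not split
  between pools.
* **$\lambda = 1/8267$ yr$^{-1}$**, the true mean life of $^{14}$C
  (half-life 5730 yr), the convention of compartmental soil-radiocarbon
  modelling. Over a 25–35 yr window radioactive decay is a second-order
  effect next to the bomb transient.
* **No year-of-measurement age correction.** Observed and atmospheric
  $\Delta^{14}$C are assumed reported on a common convention; all
  comparisons are internal to one record.

## Parameters

| parameter  | meaning                                   | units     | typical range |
|------------|-------------------------------------------|-----------|---------------|
| `k1`       | fast-pool decomposition rate              | yr$^{-1}$ | 0.1–0.3       |
| `k2`       | slow-pool decomposition rate              | yr$^{-1}$ | 0.005–0.02    |
| `a21`      | fraction of fast-pool loss transferred    | –         | 0.05–0.25     |
| `slowProp` | slow-pool fraction of stock at window start | –       | 0.45–0.8      |

MCMC bounds default to $k_1 \in [0.01, 1]$, $k_2 \in [10^{-4}, 0.05]$,
$a_{21}, \mathrm{slowProp} \in [0, 1]$ — wide brackets around all published
estimates for these systems, with $k_1 > k_2$ enforced so the pool labels
cannot swap. The optional third (passive) pool used for model comparison
adds $k_3 \in [10^{-5}, 10^{-3}]$ ($k_3 < k_2$) and a transfer fraction
$a_{32}$; its share of the initial slow stock is split evenly with pool 2,
since no data constrain that split.

## Initial conditions

Initial pool sizes come from `slowProp` and a total stock estimated by a
least-squares polynomial (degree 2 by default; the degree is configurable)
fitted to the whole stock series and evaluated at the window start. This
weights all years equally instead of trusting the first observation.
Because observations are compared at the mid-point of their sampling year
(sampling dates being unknown), the regression is run on mid-year times so
its value at the window start refers to the window-start instant.

Initial pool $\Delta^{14}$C values cannot be measured on bulk archives, so
they are modelled: a one-pool system held at steady-state stock is spun up
for 12,000 years under the flat-extended atmosphere,
$dF/dt = k F_{atm}(t) - (k+\lambda) F$, and its ratio at the window start
is used. For the second window both pools use this spin-up at the
proposed $k_1$ and $k_2$ of each MCMC step. For the first window the slow
pool is pinned at $-42.0$ ‰ (the assumed 1958 value for every trial) and
the fast pool either uses the per-step spin-up or a fixed value obtained
by `estimate_initial_fast_delta()`, which alternates fitting and
recomputation until the value stabilises.

## Fitting

The cost is the sum of squared SD-weighted residuals over every stock and
every $\Delta^{14}$C observation in the window, and the likelihood is
$\propto e^{-\mathrm{cost}/2}$ under flat priors inside the bounds.
Default observation SDs are 1.5 Mg C ha$^{-1}$ for stocks and 8.9 ‰ for
$\Delta^{14}$C (4 ‰ analytical accuracy and 8 ‰ spatial variability in
quadrature); both travel inside the observation table and can be set per
observation.

`run_mcmc()` is a random-walk Metropolis sampler: 20 % of the chain is an
adaptive burn-in (discarded) during which the proposal starts diagonal,
its scalar scale tracking a ~30 % acceptance rate, and is then replaced by
the empirical covariance of the post-descent burn-in draws scaled by
$2.38^2/d$. The proposal is frozen when the burn-in ends, so the retained
chain is Markovian. Proposals outside the bounds are rejected. Given the
same seed the chain is bitwise reproducible.

Goodness of fit is reported as unweighted RMSEs in native units (so they
are comparable across datasets) and a least-squares AIC,
$n \ln(\mathrm{RSS}/n) + 2p$ on the weighted residuals, used to compare
the two- and three-pool structures. Uncertainty in derived quantities
(median/mean transit time, steady-state stocks) uses percentile bootstrap
over parameter sets resampled from the posterior (1000 draws, 99 %
intervals by default).

## Transit times

With all inputs entering pool 1, the transit-time density is
hypoexponential:

$$f(t) = (1-a_{21}) k_1 e^{-k_1 t}
  + a_{21} \frac{k_1 k_2}{k_1 - k_2} \left(e^{-k_2 t} - e^{-k_1 t}\right),$$

equal to the general matrix form $-\mathbf{1}^T A e^{At} \beta$ with input
distribution $\beta = (1,0)^T$. The survival function, quantiles (bracketed
root-finding to $10^{-10}$) and mean ($1/k_1 + a_{21}/k_2$) follow
analytically; the mass-weighted form scales the density by the constant
input flux. These computations hold $I$ and $A$ constant and do **not**
assume the stocks are at steady state; system *age* distributions, which
would require that assumption, are deliberately not computed. The
degenerate case $k_1 = k_2$ switches to the confluent limit
($a_{21} k^2 t e^{-kt}$ branch) when $|k_1 - k_2|/k_1 < 10^{-8}$.

The test suite validates the analytic forms against an independent
stochastic oracle that simulates individual particle paths (exponential
residence times, Bernoulli transfer) and against numerical integration.

## Steady state

Steady-state stocks are the closed forms $C_1^\ast = I/k_1$,
$C_2^\ast = a_{21} I / k_2$ (checked against a direct solve of
$-A^{-1}I$). Time for the fast pool to reach 95 % of its steady state has
a closed form; for the whole system the exact matrix-exponential solution
of the triangular system is scanned forward and bisected to 0.1 yr. Both
assume constant inputs and rates from the evaluation point onward.

## The synthetic-data generator

`synth_atmosphere()` produces a deterministic bomb-pulse-shaped record:
flat at $-20$ ‰ before 1955, a logistic rise to $+670$ ‰ at 1965.5, then
exponential relaxation toward $+50$ ‰ with a 16-yr e-folding time, on
annual knots. It emulates the *shape* of the Southern Hemisphere record —
sharp rise through the 1960s, slow decline — not its exact values.

`truth_scenario()` bundles known parameters with production statistics and
noise levels emulating a productive fertilized pasture trial: aboveground
production $\mathcal{N}(4.8, 0.79^2)$ Mg ha$^{-1}$ yr$^{-1}$ truncated at
zero, constant belowground production 2.3 (no interannual SD is reported
for root production in these systems), conversion factors
$\theta_{AG} = 0.29$ (grazing return) and $\theta_{BG} = 0.70$ (share of
0–20 cm root production in the top 7.5 cm), observation noise 1.5
Mg C ha$^{-1}$ and 8.9 ‰, and ~8 $\Delta^{14}$C observation years always
including both window ends (mirroring the constraint rule that a
radiocarbon point anchor each end of a fitted window). The default
initial stock (40 Mg C ha$^{-1}$ with `slowProp` 0.55 and inputs ≈ 3.0)
places the fast pool near its steady state at the window start, consistent
with the systems emulated, whose fast pools had equilibrated by the second
modelling window.

What the generator does *not* emulate: spatial correlation between field
replicates, autocorrelated measurement error, bulk-density dynamics,
depth-resolved structure, or real interannual weather forcing of
production. Passing recovery tests therefore demonstrates the estimation
machinery is correct and well calibrated under the stated noise model, not
that real archives carry equivalent information.

`recovery_experiment()` repeats generate-then-fit with derived seeds
(replicate $i$ uses seed $+ i$) and reports bias and RMSE of the posterior
means. By default each fit is conditioned on the scenario's known initial
stock, so the experiment isolates recovery of the four fitted parameters;
with `use_true_initial_stock = FALSE` the initial stock is re-estimated
from the noisy series as a real-data fit would, which adds that
regression's error to the recovery error and measurably inflates the
$k_1$ RMSE. A related, deliberate caveat: with flat priors the
$k_1$–$a_{21}$–`slowProp` ridge gives the $k_1$ marginal a heavier upper
tail, so posterior means carry a small upward skew even on noise-free
data; the suite's bias tolerances account for this.

## Numerical choices

* **Integrator**: fixed-step classical Runge–Kutta (RK4), $dt = 1/12$ yr,
  implemented in C++. Annual inputs are held constant within each step, so
  steps never straddle the calendar-year discontinuities and the scheme
  keeps its full order between them; the atmosphere is interpolated
  linearly and extended flat outside its record. The rates involved
  ($\le 1$ yr$^{-1}$) make the system non-stiff at this step; halving
  $dt$ moves final stocks by far less than 0.1 %.
* **Spin-up**: the flat pre-record segment of the 12,000-yr one-pool
  spin-up is propagated with the exact constant-forcing solution of the
  scalar linear ODE, then the record years are integrated with RK4 at a
  step capped at $0.25/k$ so very fast pools stay accurate. This is
  mathematically identical to stepping the whole spin-up and orders of
  magnitude cheaper, which matters because the second-window convention
  runs two spin-ups per cost evaluation.
* **Observation timing**: model values are taken at the mid-point of each
  sampling year (sampling dates unknown); the simulation therefore runs to
  `end_year + 0.5`.
* **Degenerate inputs**: zero total stock makes bulk $\Delta^{14}$C
  undefined (error); pool stocks crossing zero by round-off are clamped;
  non-finite states abort the integration with the offending step;
  windows without a radiocarbon observation near both ends are rejected —
  stock data alone cannot separate decomposition from transfer.
* **Problem sizes** used by the validation suite were chosen to keep the
  full run comfortable on a laptop: recovery experiments use 10
  replicates of 10,000 MCMC iterations over a 26-yr window; the particle
  oracle uses $10^6$ paths per parameter set; bootstrap checks use a few
  hundred to 2000 resamples.

## Design decisions at genuinely open points

* **Capture efficiency** is computed as
  $100 \times \mathrm{SOC\ increase} / \mathrm{inputs}$ — the orientation
  consistent with every published per-trial value, although the prose
  caption accompanying those values states the inverted ratio.
* **Polynomial degree** for the initial-stock regression defaults to 2;
  the published analysis says only "polynomial". Degree 2 follows the
  visible curvature of the stock series without chasing noise at the
  window edges.
* **Three-pool initial conditions** (even slow-stock split, spin-up
  $\Delta^{14}$C for the passive pool) are the minimal extension of the
  two-pool conventions; nothing in the data constrains them, which is
  part of why the extra pool is penalised by AIC.
* **No decay correction between sampling and measurement year** (archived
  soils measured decades later): no correction formula is published for
  these archives, and all model-data comparisons are internal.
* **CLI**: the package's R functions are the primary interface; a thin
  Rscript (`inst/scripts/soilc14.R`) maps shell subcommands 1:1 onto them
  for pipeline use.

## Known limitations

* Two pools in series is a structural choice; fitted rates are only
  interpretable within it. The AIC comparison justifies parsimony against
  a three-pool alternative, not structural truth.
* The bomb-curve emulation is shape-faithful but synthetic; fits to real
  archives must use a real atmospheric compilation (CSV reader provided).
* Fitted windows assume constant parameters; slow drift inside a window
  biases the estimates (this motivates the two-window design, and the
  test suite demonstrates the effect on a drifting synthetic truth).
* Transit-time summaries assume constant $I$ and $A$ going forward;
  they describe the fate of *new* inputs, not the age of standing stocks.
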