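---
title: "Duplex hybridization thermodynamics by WHAM: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex hybridization thermodynamics by WHAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whamtherm)
```

## The estimation problem

Umbrella sampling holds a molecular system near successive values of a
reaction coordinate with a harmonic restraint; here the coordinate is the
distance $r$ between the centres of mass of the two strands of a nucleic-acid
duplex. Each window $i$ (bias centre $r_i$, spring constant $K$, temperature
$T$) yields samples of $r$ whose distribution is the unbiased one skewed by
the Boltzmann factor of the bias $w_i(r)$. The weighted histogram analysis
method (WHAM) reconstructs the unbiased distribution $p(r)$ by coupling all
windows through self-consistent per-window free-energy shifts $f_i$:

$$p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i \exp\!\big((f_i - w_i(r_b))/RT\big)},
\qquad
f_i = -RT \ln \sum_b p(b)\, \exp\!\big(-w_i(r_b)/RT\big),$$

where $n_i(b)$ are per-window bin counts, $N_i$ in-grid totals, and $r_b$ bin
centres. The potential of mean force is $\mathrm{PMF}(b) = -RT\ln p(b)$, up
to an irrelevant constant.

Downstream, the thermodynamics of duplex formation follow a two-state
picture: only the bound duplex and the fully dissociated strands matter.

* $\Delta G^\circ(T) = \mathrm{PMF}(r_{\min}) - \mathrm{PMF}(r_{\max})$, the
  drop from the dissociation barrier into the bound well (negative for a
  stable duplex);
* $\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$ fitted by OLS across
  the simulated temperatures (van't Hoff, assuming
  $\Delta C_p \approx 0$ over the 60 K range);
* $T_m = 1000\,\Delta H^\circ \,/\, (\Delta S^\circ + R \ln (C_t/m))$ with
  $\Delta H^\circ$ in kcal/mol, $\Delta S^\circ$ in cal/(mol·K), total strand
  concentration $C_t$, and molecularity factor $m$.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_bins` | 150 | – | free-energy profiles plateau for ≥ 100 bins on strand-separation data; 150 adds margin without noise blow-up |
| `tol` | 1e-6 | kcal/mol | largest per-iteration change of any shift $f_i$; well below every quantity of interest |
| `max_iter` | 1e5 | – | plain iteration converges in 10³–10⁵ steps at these problem sizes |
| window spacing | 0.5 | Å | with $K = 10$ this keeps adjacent-histogram overlap near 0.3, safely above the 20 % rule of thumb |
| `bias_constant` K | 10 | kcal/(mol·Å²) | strong enough to pin windows 0.5 Å apart, weak enough to overlap |
| `half_factor` | `TRUE` | – | bias convention, see below |
| `burn_in` | 0 | fraction | leading fraction of each series discarded; 0 because exact samplers need no equilibration — raise it for real MD windows |
| `ct` | 1e-5 | mol/L | 10 μM, a typical experimental strand concentration |
| `self_complementary` | `FALSE` | – | molecularity $m=4$ for two distinct strands, $m=1$ for self-complementary |
| temperatures | 273–333 K step 10 | K | bounded below by freezing water, above by in-simulation duplex denaturation; wide enough for a stable van't Hoff slope |

### The bias convention

Two conventions coexist for a "harmonic potential with constant $K$":
$w = K(r-r_i)^2$ (the AMBER restraint energy) and $w = \tfrac12 K(r-r_i)^2$
(the convention of the classic WHAM programs). The choice matters: it sets
the window width $\sigma = \sqrt{RT/K}$ vs $\sqrt{RT/2K}$, a factor of
$\sqrt2$ in every histogram. `whamtherm` defaults to the **half-factor
convention** because it is the one under which the canonical spacing rules
reproduce: at $K = 10$ and 310 K it gives $\sigma \approx 0.25$ Å, so
0.5 Å spacing yields ~0.3 overlap (≥ 20 % everywhere) and 0.7 Å spacing sits
right at the 20 % boundary — exactly the regime in which this protocol is
operated. Under the no-half convention, 0.5 Å spacing would fall *below*
20 % overlap. Both the generator and the solver take `half_factor`, and the
two must agree; set `half_factor = FALSE` when ingesting data biased with
the raw AMBER restraint energy.

## The synthetic generator

Real umbrella data for this problem are molecular-dynamics trajectories; the
generator replaces them with draws from an analytic free-energy surface so
that recovery can be checked against an exact ground truth. The surface is

$$G(\xi) = W e^{-\xi/\lambda}
 - d\, e^{-(\xi-c)^2/2\sigma^2}
 + h\, e^{-(\xi-b)^2/2\sigma_b^2}
 + s\,(\xi-b)\,\Phi\!\big((\xi-b)/\tau\big)$$

— a steep repulsive wall, a single bound-state well at $c = 6$ Å, a small
dissociation barrier near $b = 13$ Å, and a plateau declining with slope
$s = -0.01$ kcal/(mol·Å) (the post-barrier profile of a dissociating duplex
falls slightly as the strands stop interacting; the true magnitude of that
decline is not well constrained, so it is small and configurable). For a
ground truth $(\Delta H^\circ, \Delta S^\circ)$ the well amplitude $d$ is
calibrated by root finding at each temperature so that the analytic
well-to-barrier difference equals $\Delta H^\circ - T\Delta S^\circ/1000$
to ~1e-10 kcal/mol, with all other shape parameters fixed across
temperatures. Defaults $\Delta H^\circ = -60$ kcal/mol,
$\Delta S^\circ = -160$ cal/(mol·K) are physically typical for an 8-mer
(ratio ≈ 375 K) and are synthetic values, not literature ones.

Window sampling is **exact**: the biased marginal
$p(\xi) \propto e^{-(G+w)/RT}$ is tabulated on ≥ 10⁴ grid points and drawn by
linear-interpolated inverse CDF. `mode = "ar1"` keeps the same marginal but
imposes a lag-1 autocorrelation through a Gaussian copula, to exercise error
estimation under the serial correlation real MD produces.

What passing tests therefore show: the estimator chain (histograms → WHAM →
extraction → van't Hoff → Tm) is correct and well-calibrated on data whose
marginals are exactly Boltzmann. What they cannot show: force-field accuracy,
sampling convergence of real MD, slow orthogonal degrees of freedom, or
heat-capacity effects — none of which exist in the generator.

## Numerical choices

* **Iteration scheme.** Plain self-consistent iteration, no acceleration:
  deterministic, simple, and fast enough at ~100 windows × 150 bins
  (seconds per solve). Convergence is measured on mean-centred shifts, which
  also makes the solve invariant to window order.
* **Convergence metric.** The tolerance applies to free-energy shifts in
  kcal/mol (the natural scale of the output), not to probabilities.
* **Bin assignment.** Half-open bins $[e_k, e_{k+1})$ with the last bin
  closed; samples outside the grid are dropped and counted per window.
* **Empty bins** get $p = 0$ and $\mathrm{PMF} = +\infty$ and are excluded
  from every minimum/maximum search and from the report alignment.
* **PMF reference.** Profiles are shifted so the last 5 % of finite bins
  (the dissociated plateau) average zero — purely cosmetic, since
  $\Delta G$ extraction is shift-invariant.
* **Default grid: last window centre + 2σ.** Bins further out are reached
  only by the outermost window's extreme tail, where the bias changes by
  several $RT$ across one bin; with bin-centre weights those bins acquire a
  systematic error of ~0.2 kcal/mol at the default bin width. Averaging the
  Boltzmann weight over each bin removes that edge artifact but introduces a
  worse bias on the steep well walls (where the *unbiased* density varies
  within a bin), so the standard bin-centre weights are kept and the grid
  simply stops where single-window tail coverage begins.
* **Extraction tie-breaks.** The global minimum takes the first (smallest-
  coordinate) bin on exact ties; the barrier search is restricted to
  coordinates beyond the minimum so the repulsive wall can never be chosen.
  A profile with no finite bin beyond its minimum (monotone; coordinate
  range too short) is an error asking for a longer range.
* **Bootstrap.** Each replicate redraws every window's histogram
  multinomially (equivalent to resampling its in-grid samples with
  replacement), re-solves warm-started from the full-data shifts, and is
  aligned by the common plateau reference; per-bin errors are standard
  deviations across replicates, and per-replicate $\Delta G$ values give the
  $\Delta G$ standard error. Replicates that fail to solve are dropped and
  counted; more than 10 % failures is an error.
* **Degenerate inputs.** Samplers refuse target densities with essentially
  all mass in one grid cell; the well calibration refuses targets too
  shallow for the surface to keep an interior minimum (including
  "unstable duplex" targets $\Delta G \ge 0$, which are flagged first);
  `melting_temperature()` refuses near-zero denominators and
  $\Delta H^\circ > 0$ with $\Delta S^\circ < 0$.

## Design choices where the design was open

* **$\Delta G^\circ_{37}$ comes from the fitted line** at 310.15 K, not from
  any single-temperature profile: 310.15 K is not on the simulated grid, and
  the fitted value uses all temperatures.
* **Linear calibration acts on $\Delta H^\circ$ and $\Delta S^\circ$ only**
  (per-parameter OLS of experimental on calculated, ≥ 3 pairs);
  $\Delta G^\circ_{37}$ and $T_m$ are always recomputed from the corrected
  pair, never corrected independently, and a second correction of already
  corrected parameters is refused.
* **Molecularity.** The exact printed form of the two-state $T_m$ formula
  varies across sources ($C_t$, $C_t/2$, $C_t/4$); the package uses
  $C_t/m$ with $m = 4$ for a bimolecular duplex of distinct strands
  (the standard result for total strand concentration) and $m = 1$ for
  self-complementary sequences, both configurable.
* **Overlap failures warn, not abort** (unless `strict_overlap`): the 20 %
  criterion is a design check on window spacing, not a runtime gate; WHAM
  remains well-defined at lower overlap, just noisier.
* **Equilibration burn-in** is exposed (`burn_in`, default 0) because real
  MD windows usually need it even though exact samplers do not.
* **Interface.** All operations are plain R functions over tibbles (with
  `tidy()`/`glance()`/`autoplot()` methods); `run_pipeline()` +
  `run_config()` orchestrate the end-to-end protocol and write TSV/JSON
  outputs plus a manifest. No shell executable is shipped; the functions and
  this vignette are the interface.

## Problem sizes used in validation

The shipped tests validate the estimator at deliberately modest sizes chosen
by the package: the full-layout checks use 91 windows × 10⁴ exact samples per
window at seven temperatures (recovery of each $\Delta G^\circ(T)$ to
< 0.3 kcal/mol and of $\Delta H^\circ$, $\Delta S^\circ$ to well under 10 %),
bootstrap calibration uses 20 regenerated datasets, and unit tests run on
shorter coordinate ranges. Exact sampling makes these sizes statistically
equivalent to far longer correlated MD trajectories.

## Known limitations

* Samples are treated as statistically independent; for correlated input
  use `mode = "ar1"` data to gauge the optimism of the bootstrap, or stride
  the series before analysis.
* One-dimensional, non-periodic reaction coordinates only; no MBAR.
* No heat-capacity ($\Delta C_p$) modelling: the van't Hoff line assumes
  temperature-independent $\Delta H^\circ$, $\Delta S^\circ$.
* The synthetic surface is a stylised stand-in; nothing in the package
  validates a force field or an MD protocol.
* Experimental comparison values for calibration are user-supplied; the
  package contains no nearest-neighbour prediction model.

```{r example, eval = FALSE}
# a complete synthetic study
truth <- ground_truth(delta_h = -60, delta_s = -160)
plan <- simulation_plan(centers = seq(0, 45, 0.5), n_per_window = 1e4, seed = 42)
res <- run_pipeline(run_config(plan = plan, truth = truth,
                               out_dir = "study", n_boot = 20))
glance(res$fit)
autoplot(res$profiles$T313)
autoplot(res$fit)
```
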