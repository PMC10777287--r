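# whamtherm

Hybridization thermodynamics of oligonucleotide duplexes from
umbrella-sampling simulations, in R.

## The problem

The stability of a DNA (or modified nucleic-acid) duplex is summarised by the
thermodynamics of its formation: the enthalpy ΔH°, the entropy ΔS°, the Gibbs
free energy at 37 °C (ΔG°₃₇), and the melting temperature Tm. For chemically
modified oligonucleotides these numbers often cannot be predicted from
sequence rules, but they *can* be computed from molecular simulations: bias
the distance r between the two strands' centres of mass with a harmonic
umbrella potential at a ladder of positions, and reconstruct the free-energy
profile (potential of mean force, PMF) along r.

`whamtherm` implements the analysis half of that protocol:

1. **WHAM** — the weighted histogram analysis method combines the biased
   per-window histograms into one unbiased distribution p(r) by
   self-consistently estimating per-window free-energy shifts fᵢ:

   ```
   p(b)  =  Σᵢ nᵢ(b)  /  Σᵢ Nᵢ exp((fᵢ − wᵢ(r_b))/RT)
   fᵢ    =  −RT ln Σ_b p(b) exp(−wᵢ(r_b)/RT),      wᵢ(r) = ½K(r − rᵢ)²
   ```

   iterated until the shifts change by less than a tolerance (10⁻⁶ kcal/mol
   by default). The PMF is −RT ln p(r).
2. **ΔG°(T)** — the formation free energy at each simulated temperature is
   the drop from the dissociation barrier into the bound-state well:
   ΔG°(T) = PMF(r_min) − PMF(r_max), with the maximum searched only beyond
   the minimum so the short-range repulsive wall is never mistaken for the
   barrier.
3. **van't Hoff decomposition** — ΔG°(T) = ΔH° − T·ΔS° fitted by ordinary
   least squares across temperatures (273–333 K in 10 K steps by default)
   gives ΔH° (intercept) and ΔS° (−slope); ΔG°₃₇ is the fitted line at
   310.15 K.
4. **Melting temperature** — two-state bimolecular model at total strand
   concentration Ct (10 μM default):
   `Tm(K) = 1000·ΔH° / (ΔS° + R ln(Ct/m))`, m = 4 for two distinct strands.
5. **Diagnostics & calibration** — adjacent-window histogram overlap (≥ 20 %
   rule), bootstrap PMF uncertainties, bin-count convergence scans, and
   linear calibration of computed ΔH°/ΔS° against experimental values.

Because no public umbrella-sampling dataset accompanies this problem, the
package ships a first-class synthetic generator: an analytic model PMF with
the characteristic duplex shape (repulsive wall, bound well near 6 Å,
dissociation barrier, gently declining plateau) whose well-to-barrier depth
is exactly ΔH° − T·ΔS° of a chosen ground truth. Windows are sampled exactly
(inverse-CDF, optionally AR(1)-correlated), so every pipeline stage is
testable by parameter recovery.

## Worked example

```r
library(whamtherm)

# ground truth for a synthetic short duplex
truth <- ground_truth(delta_h = -60, delta_s = -160)

# one temperature: simulate windows, check overlap, solve WHAM
windows <- simulate_windows(truth, temperature = 313,
                            centers = seq(0, 20, 0.5),
                            n_per_window = 5000, seed = 1)
hists <- build_histograms(windows)
attr(adjacent_overlap(hists), "min_overlap")
#> [1] 0.275                      # every adjacent pair overlaps >= 20 %

profile <- solve_wham(hists)
profile
#> <pmf_profile> T = 313.0 K, 150 bins, 41 windows, 4541 iterations (converged)
extract_delta_g(profile)
#> # A tibble: 1 × 5
#>   delta_g xi_min xi_max pmf_min pmf_max
#>     <dbl>  <dbl>  <dbl>   <dbl>   <dbl>
#> 1   -9.94   5.94   13.6   -8.87    1.07
```

The bound state sits near 6 Å, the barrier near 13.6 Å, and the formation
free energy at 313 K is −9.94 kcal/mol (the generating truth is
−60 + 313·0.160 = −9.92). The whole seven-temperature study is one call:

```r
plan <- simulation_plan(centers = seq(0, 20, 0.5), n_per_window = 5000, seed = 1)
cfg <- run_config(plan = plan, truth = truth, out_dir = tempfile(), n_boot = 10)
res <- run_pipeline(cfg)
res$fit
#> <vanthoff_fit> duplex
#>   ΔH° = -60.65 kcal/mol,  ΔS° = -162.0 cal/(mol K)
#>   ΔG°37 = -10.40 kcal/mol,  Tm = 50.1 °C,  R² = 0.9998  (7 temperatures)
```

The fit recovers the generating ΔH° = −60 kcal/mol and ΔS° =
−160 cal/(mol K) within ~1 %. `run_pipeline()` also writes one PMF table per
temperature, a thermodynamic report (ΔH°/ΔG°₃₇ in kcal/mol, ΔS° in
cal/(mol K), Tm in °C) and a manifest sufficient to reproduce the run.
`autoplot()` methods are provided for PMF profiles, van't Hoff fits and
model surfaces; `tidy()`/`glance()` return tibbles for all fitted objects.

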