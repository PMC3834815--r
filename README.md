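# stackprobe

Quantifying DNA conformational change from 2-aminopurine (2AP)
spectroscopy: global iterative-reconvolution fitting of TCSPC
fluorescence decays, low-energy exciton-coupled CD processing, and
conformational-population reporting — plus a seeded synthetic-data
generator so the whole pipeline runs and is tested without instrument
data.

## Who this is for

Nucleic-acid biophysicists using 2AP as a local probe of base
stacking — e.g. to detect duplex unpairing in a protein active site
such as a flap endonuclease — who need a reproducible, scriptable
replacement for instrument-vendor fitting software.

## The model

A TCSPC histogram is the instrument response $p$ convolved with a
multi-exponential decay.  For curve $j$ (emission wavelength $j$) the
expected counts in channel $k$ are

$$M_k^{(j)} = b_j + \sum_{m\le k} p_m(s_j) \sum_{i=1}^n \alpha_{ij}\,
  e^{-(k-m)\Delta t/\tau_i},$$

with lifetimes $\tau_i$ **shared across wavelengths** (global
analysis) and amplitudes $\alpha_{ij}$, background $b_j$ and channel
shift $s_j$ free per curve.  The fit minimises Poisson-weighted least
squares $\sum w_k (C_k - M_k)^2$, $w_k = 1/\max(C_k,1)$, by
Levenberg–Marquardt on log-lifetimes with the linear parameters
profiled out (variable projection).  Fractional amplitudes
$A_{ij} = \alpha_{ij}/\sum_i\alpha_{ij}$ are the populations of the
conformational states: $\tau \approx 50$ ps means 2AP stacked in the
helix, $\tau \approx 10$ ns means extrahelical, intermediates are
partially stacked.  In parallel, the red lobe (320–330 nm) of the
exciton CD couplet of an adjacent 2AP dimer measures the mutual
stacking of the two probes; its fractional loss
$100(1 - \Delta\varepsilon_{330}^{\rm sample}/\Delta\varepsilon_{330}^{\rm ref})$
quantifies unpairing between conditions.

## Worked example

Simulate a three-wavelength decay set of a double-flap substrate
(2AP at the duplex terminus), fit it globally, and classify the
populations:

```r
library(stackprobe)

grid <- make_time_grid(4096, 50)                  # 12.2 ps bins
irf  <- make_irf(irf_spec(fwhm = 80, t0 = 2), grid)
substrate <- simulate_global_set(get_preset("double_flap"), irf,
                                 wavelengths = c(370, 380, 390),
                                 peak_counts = 1e4, seed = 42)
fit <- fit_global(substrate, irf, n_components = 4)
fit
#> <global_fit_result> 4 component(s), 3 curve(s), chi2_r(global) = 1.082, converged in 6 iter
#> <decay_model> 4 components, 3 curve(s)
#>   tau1 = 0.05983 ns   A = 0.746 0.748 0.748
#>   tau2 = 0.2922 ns   A = 0.172 0.170 0.170
#>   tau3 = 1.955 ns   A = 0.062 0.061 0.062
#>   tau4 = 9.947 ns   A = 0.020 0.020 0.020

classify_components(fit)
#> <state_report>
#>   tau1 =  0.05983 ns  A = 0.747  stacked
#>   tau2 =   0.2922 ns  A = 0.171  partially_stacked_fast
#>   tau3 =    1.955 ns  A = 0.062  partially_stacked_slow
#>   tau4 =    9.947 ns  A = 0.020  extrahelical
#>   populations: stacked = 0.747, partially_stacked_fast = 0.171, ...
```

The recovered lifetimes (60 ps, 290 ps, 2.0 ns, 9.9 ns) and the
dominant 75% stacked population match the generating preset: 2AP at a
double-flap terminus is almost as well stacked as inside a duplex.
Binding by a mutant enzyme shifts the decay toward the unpaired
signature — longer short lifetimes, population moved from the stacked
into the partially stacked states:

```r
complex_fit <- fit_global(simulate_global_set(get_preset("y40a_substrate"),
  irf, c(370, 380, 390), 1e4, seed = 43), irf, 4)
percent_param_change(complex_fit, fit)[, c("component", "delta_tau_pct", "delta_a_pct")]
#>   component delta_tau_pct delta_a_pct
#> 1         1     34.957130   -21.70219
#> 2         2     37.949355    72.19208
#> 3         3      1.292262    62.64367
```

i.e. tau1 and tau2 lengthen by ~35% while A1 drops by ~22% and
A2/A3 grow — the duplex-to-single-strand "unpairing fingerprint".

The full pipeline (simulate → fit → CD metrics → state report) runs
from a JSON config, reproducibly under one master seed:

```sh
inst/cli/stackprobe all --config inst/extdata/example-config.json \
    --outdir out --seed 1234
```

or `run_pipeline(read_config(...), "all")` from R.

## Layout

- `R/` — simulation (`simulate-decay.R`, `cd-spectrum.R`, `presets.R`),
  fitting (`reconvolve.R`, `fit-global.R`, `model-order.R`,
  `uncertainty.R`, `diagnostics.R`), CD processing (`cd-process.R`),
  reporting (`report.R`), I/O + pipeline (`io.R`, `config.R`,
  `pipeline.R`)
- `vignettes/stackprobe-methods.Rmd` — models, conventions, and the
  reasoning behind every tunable default
- `tests/testthat/` — unit + property tests with independent
  brute-force oracles, and `test-acceptance.R` with the acceptance
  criteria
- `inst/cli/stackprobe` — subcommand CLI (exit codes: 0 ok,
  2 configuration, 3 data format, 4 fit failure)
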