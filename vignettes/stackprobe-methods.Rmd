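---
title: "Models and methods behind stackprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stackprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackprobe)
```

# The scientific problem

2-aminopurine (2AP) is a fluorescent adenine analogue that base-pairs
with thymine without grossly perturbing a duplex.  Its photophysics
report on the *stacking microenvironment* of the probe: 2AP well
stacked in a helix is quenched by inter-base electron transfer within
~50 ps, an extrahelical (flipped-out) 2AP decays unquenched over ~10 ns,
and partially stacked geometries fall in between.  A TCSPC fluorescence
decay of a 2AP-containing DNA is therefore a mixture of exponentials
whose fractional amplitudes (A factors) measure the populations of the
underlying conformational states.  A second, independent observable is
the exciton-coupled circular dichroism of *adjacent* 2AP dimers: the
coupled transition dipoles produce a bisignate CD couplet whose
red-shifted lobe (maximal near 320--330 nm, where protein and
unmodified DNA are transparent) collapses when the two bases lose their
mutual stacking, e.g. on local unpairing of a duplex terminus in a
protein active site.  stackprobe implements the quantitative machinery
for both observables, plus a synthetic-data generator so that every
stage is testable without an instrument.

# The TCSPC forward model

A measured decay is the convolution of the molecular decay law with the
instrument response function (IRF).  With uniform bins of width
$\Delta t$ and a unit-area discretised IRF $p_j$, the expectation in
channel $k$ of curve $j$ is

$$ M_k^{(j)} = b_j + \sum_{m \le k} p_m(s_j)\,
   \sum_{i=1}^n \alpha_{ij}\, e^{-(k-m)\Delta t/\tau_i} , $$

with per-curve background $b_j$, channel shift $s_j$ (linear
interpolation for fractional shifts) and non-negative amplitudes
$\alpha_{ij}$.  A factors are $A_{ij}= \alpha_{ij}/\sum_i
\alpha_{ij}$.  Internally the per-component convolution is evaluated by
the exact recursion $c_k = e^{-\Delta t/\tau} c_{k-1} + p_k$
(`stats::filter`, O(N)); the test-suite oracle is the literal
O(N$^2$) double sum, an independent code path.

The decay is sampled relative to the first channel rather than
integrated over bins; at the default 12.2 ps bin width this
mid-vs-integrated distinction is far below the other conventions and
both the generator and the fitter use the identical rule, so fits are
exact on synthetic data.

# Global fitting

`fit_global()` minimises the Poisson-weighted least squares
$\sum_{j,k} w_k (C_k - M_k)^2$ with Neyman weights
$w_k = 1/\max(C_k, 1)$ (Pearson weighting is available), lifetimes
*shared* across curves and everything else free per curve.  The
problem is separable: for fixed $\{\tau_i, s_j\}$ the amplitudes and
background are linear and are profiled out at every objective
evaluation by weighted linear least squares with an active-set clamp
keeping $\alpha_{ij} \ge 0$ (variable projection).  A
Levenberg--Marquardt loop with forward-difference derivatives then
drives only the log-lifetimes (positivity by construction) and the
shifts.  Components are sorted by ascending lifetime on return.

Numerical choices that matter:

* **Convergence** -- relative $\chi^2$ decrease below `reltol`
  (default 1e-10) on a step accepted in the near-Gauss-Newton regime
  ($\lambda \le 1$), or three successive such stagnant steps (the
  $\chi^2$ floor of noiseless data is only reachable under damping);
  cap 500 iterations, returning `converged = FALSE` rather than
  raising.
* **Dead components** -- if the clamp sets an amplitude to zero its
  lifetime column of the Jacobian vanishes; the damping diagonal is
  floored at 1e-8 of its largest element so the live parameters keep
  taking full steps.
* **Initialisation** -- log-spaced lifetimes between $5\Delta t$ and a
  third of the window, zero shift.  This is deliberately generic; all
  five shipped presets converge from it at both the test and the full
  grid.
* **Fit range** -- 10 channels before the IRF peak to the last channel
  above the pre-rise background estimate, per curve; configurable.
* **Weighting caveat** -- Neyman weights are exact only where counts
  are moderately large.  In sparsely populated tail bins the statistic
  acquires a positive bias of order $1/\mu$ per bin; with the full
  4096-channel window and $10^4$ peak counts a perfectly specified
  model typically shows $\chi^2_r \approx 1.05$--$1.1$.  Parameter
  estimates are unaffected; the $\chi^2_r$ calibration tests therefore
  restrict themselves to well-populated ranges.

Model order is chosen by `select_model_order()`: accept $n+1$ over $n$
when the F statistic of the $\chi^2$ decrease is significant (default
$\alpha = 0.05$) *and* every component of the larger model carries
$A \ge 0.005$ somewhere -- a statistically significant component that
carries no population is treated as overfitting.  Uncertainties come
from a parametric bootstrap (Poisson replicates of the fitted
expectations, warm-started refits, relative SD per parameter), chosen
over the asymptotic covariance because multi-exponential parameters are
strongly correlated.  Residual structure is summarised per curve by the
two-sided Wald--Wolfowitz runs test on residual signs.

Because the published tables report one A-factor set per sample while
the fit yields one per wavelength, the per-sample summary is the
intensity-weighted average of the per-curve A factors (weights: total
fitted decay counts); whether the source values were averaged this way
or taken at 380 nm is not documented, so both forms are retained.

# The CD chain

Processing follows the standard acquisition protocol exactly: average
the five 0.5 nm scans, subtract the matched no-DNA blank, smooth with
the "Means--Movement" filter, and convert millidegrees to molar CD per
mol 2AP residue,
$\Delta\varepsilon = \theta_\mathrm{mdeg} / (32980\, c\, l)$ with $c$
the 2AP *residue* concentration (strand concentration x residues per
strand).  The 32980 factor is the standard ellipticity relation; it is
a convention of this package, not a documented instrument constant.
Means--Movement is interpreted as a centred moving average over
`width` points (the JASCO manual's description); at the edges the
window shrinks symmetrically so the grid length is preserved.  The
exact instrument edge behaviour is undocumented; for signals supported
away from the grid edges (the only case that matters here) the choice
is immaterial and the filter conserves the integral exactly.

The exciton metrics are the smoothed $\Delta\varepsilon$ at 330 nm (the
published convention), the 320--330 nm band mean (robustness
alternative), and the location of the absolute extremum in 300--360 nm.
Signal changes between conditions are
$100\,(1 - \mathrm{sample}/\mathrm{reference})$, so 83 means 17% of
the reference amplitude survives.

# Conformational reporting

Components are classed by lifetime -- stacked ($\tau \le 0.15$ ns),
partially stacked fast/slow (split at 1 ns) and extrahelical
($\tau \ge 5$ ns).  The boundaries are anchored to the ~50 ps and
~10 ns landmarks of 2AP photophysics but are conventions, and are
configurable.  Class populations are per-sample A factors summed by
class.  Between-condition changes are reported per rank-matched
component as percentages of the reference value, components 1--3 only
(component 4 is always a minor fraction).  2AP senses stacking, not
hydrogen bonding, so all outputs are stated as stacking-environment
populations, never as base-pairing per se.

The two-state mixture estimate treats a complex's decay as a
population-weighted blend of a paired (duplex-like) and an unpaired
(single-strand-like) reference: the complex is refitted with lifetimes
fixed to the union of the two reference sets (coalescing lifetimes
within 2% -- a purely linear problem, so any union size is allowed),
and $f$ is the projection of its A vector onto the segment between the
two reference A vectors, clipped to $[0,1]$.  Fixing the lifetimes is
an identifiability choice; a free-lifetime variant is out of scope.
The residual distance of the projection is reported so a poor two-state
description is visible.  Note that a "50:50 mixture" means equal
*molecular populations*: synthetic mixtures must blend per-molecule
(unit-total-amplitude) expectations, not curves separately scaled to
equal peak counts, which would weight the states by their peak shapes.

# The synthetic world

The generator emulates what the analysis assumes: four-component
decays with lifetimes from ~50 ps to ~10 ns under an 80 ps FWHM
Gaussian IRF at 370/380/390 nm, independent Poisson counting noise,
and CD couplets of which only the red lobe (default centre 326 nm,
sigma 12 nm) is observable above 300 nm.  Stated-protocol values are
defaults (wavelengths, IRF width, 10 uM DNA, 0.5 nm / five-scan CD,
smoothing width five).  Values the protocol does not state were fixed
once at field-typical magnitudes and are not tuned: 4096 channels over
50 ns (bins of ~12 ps resolve the 50 ps component; the window is 5x
the longest lifetime), $10^4$ peak counts, zero simulated background
(the fitter still always estimates one), CD noise SD 5% of the lobe
amplitude, and a gentle polynomial baseline removed by the blanks.
Pulse wrap-around at the ~210 ns repetition period is neglected (the
longest component decays by >9 orders of magnitude per period).

The preset library pins the printed parameter regimes: `duplex`
(A1 = 0.85 at ~50 ps), `double_flap` (A = 0.75/0.17/0.06 with tau1 =
60 ps, tau2 = 300 ps), `y40a_substrate` (0.58/0.30/0.10; 80 ps,
400 ps), `y40a_product` (40% at 9 ns, 18% short-lived) and a
`single_strand` unpaired reference (population shifted from A1 into
A2/A3 with lengthened tau1/tau2).  Entries the source never prints
(the small A4 of unbound DNAs, some intermediate lifetimes) are
field-typical choices, so presets are parameter *regimes*, not
published tables.

What a green test establishes is parameter recovery and internal
consistency under this stated world; what it cannot establish is
anything the generator does not model -- anisotropy, pile-up, detector
afterpulsing, wavelength-dependent IRFs, scattered excitation, or real
instrument baselines.  Reproducibility is a contract: every stochastic
stage draws from a substream hashed from one master seed, and all
writers format deterministically, so a pipeline run is a pure function
of its configuration.

# Known limitations

* Weighted least squares, not Poisson maximum likelihood; no lifetime
  distributions or maximum-entropy analysis.
* The F-test model-order rule shares the usual caveats of nested
  chi-square tests on binned data; the A-factor floor guards the common
  failure mode (significant-but-empty components).
* The mixture fraction is an artifact-level construct: the source work
  establishes the paired/unpaired equilibrium qualitatively and never
  quantifies it, so there is no published value to compare against.
* The CD couplet is a phenomenological two-Gaussian stand-in for a
  proper exciton calculation, which is explicitly out of scope.
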