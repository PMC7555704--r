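---
title: "Electron transport in pyridine: the cross-section set, sampling models, and the virtual transmission experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron transport in pyridine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrxs)
```

## Why pyridine, and why 0.1-100 eV

Pyridine (C5H5N, 79 amu) is a widely used structural prototype for the DNA
bases, so electron-impact data for it feed directly into track-structure
models of radiation damage in biomolecular media.  Most of the damage done
by ionizing radiation is mediated by secondary electrons born below 100 eV,
which is exactly the regime where event-by-event Monte Carlo simulation
needs *complete* input: an integral cross section for every open channel at
every energy, an angular distribution for every channel, and an energy-loss
distribution for every inelastic channel.  `pyrxs` packages such a complete,
self-consistent set for gaseous pyridine between 0.1 and 100 eV, together
with the simulation machinery that consumes it.

## The integral cross-section set

The recommended set covers six channels: elastic scattering, rotational,
vibrational and electronic excitation, ionization, and dissociative electron
attachment (DEA).  Its provenance mixes ab initio theory (R-matrix below
10 eV and an independent-atom screening-corrected additivity calculation
above it for the elastic channel; dipole-Born theory for rotations; R-matrix
shape resonances for attachment), experimental ionization averages, and two
closure rules that make the set self-consistent with measured total cross
sections (TCS):

* the total inelastic cross section is the reference TCS minus the integral
  elastic cross section, split into ionization and electronic excitation by
  a theoretical ratio (`split_inelastic()`); and
* whatever then remains unaccounted for is attributed to vibrational
  excitation (`close_vibrational()`), floored at zero when the channel sum
  overshoots.

Because transmission-measured TCS undercount electrons scattered into the
detector's forward acceptance cone, the package also implements the
missing-angle machinery used to build the reference TCS:
`acceptance_angle()` converts a detector model into an energy-dependent
acceptance half-angle (for a magnetically confined apparatus the acceptance
is linked to the energy resolution, `acos(sqrt(1 - dE_res/E))`, the pitch
angle whose axial-energy decrement equals the resolution), and
`missing_angle_correction()` integrates a channel's differential cross
section (DCS) over that cone by adaptive quadrature (relative tolerance
1e-8, with a domain split at a tenth of the acceptance angle to resolve
forward peaks).

### Storage and interpolation choices

The tables are stored as plain CSV exactly as printed, including cells given
only as the upper bound `"<0.1"`; the loader encodes those as the interval
midpoint 0.05 (1e-20 m^2) with a flag, which preserves channel-onset
continuity while keeping the printed bound recoverable
(`write_xs_csv()` round-trips every cell character-exactly).  Blank cells
are absent grid points, not zeros: below a threshold channel's first
tabulated energy (its onset) the channel contributes zero, and above the
vibrational channel's last tabulated point (3.2 eV) the data give no basis
for a nonzero value, so queries return 0 there; that gap is a documented
limitation of the compiled set, not of the interpolator.

Between grid points interpolation is log-log linear, since the channels span
four orders of magnitude.  Two exceptions are interpolated linearly: the
densely tabulated attachment resonance windows (0.71-0.935 and 1.01-1.2 eV),
where a log transform would distort the sharp peaks, and the
Schwinger-multichannel (SMC) elastic table's spike at 0.9 eV (81.96 between
32.47 and 34.43), which is retained verbatim for fidelity to the published
calculation.  The recommended elastic and rotational grids start at 0.11 eV
while the set's declared range starts at 0.1 eV; queries in between clamp to
the first grid value.  Outside 0.1-100 eV no extrapolation is performed —
electrons below 0.1 eV are culled by the transport rules instead.

```{r}
xs <- load_pyridine_xs()
xs_sigma(xs, "elastic", 20)
xs_channel_probs(xs, 15)
```

## Angular models

**Elastic.**  The published elastic DCS curves are not tabulated, so the
default shape is a screened-Rutherford form
`dcs(E, theta) = C(E) / (1 + 2*eta(E) - cos(theta))^2` with `eta(E) =
eta0/E` and `C(E)` fixed so the full-sphere integral equals the tabulated
elastic integral cross section.  `eta0 = 0.5` makes the 10 eV shape strongly
forward peaked (forward/backward ratio about 440), consistent with
scattering off a strongly polar target at these energies; users with
digitized DCS curves can substitute a tabulated model
(`elastic_dcs_model(kind = "tabulated")`), which is bilinearly interpolated
and renormalized to the same integral.

**Rotational.**  Pyridine's permanent dipole moment (2.2 D) makes rotational
excitation dominant and sharply forward peaked at low energy.  The
dipole-Born angular shape `1/K^2` (momentum transfer
`K^2 = k^2 + k'^2 - 2kk'cos(theta)`, momenta taken nonrelativistically for a
mean excitation energy of 0.00109 eV) is normalized to the tabulated
rotational integral cross section rather than to an ab initio Born integral,
which avoids inventing constants while preserving both published facts about
these curves: the energy-independent shape and the ~1/E fall-off of the
magnitude.  Octave-spaced energy pairs above 1 eV reproduce 1/E within 2%;
over the full two-decade span the tabulated Born integral itself falls
slightly faster (log(E)/E), so the scaling is local, not global.

**Inelastic.**  For vibrational, electronic and ionizing collisions the
package uses the semi-empirical family in which the inelastic
double-differential cross section (DDCS) is the elastic DCS raised to a
loss-dependent power:

* original form: exponent `1 - dE/E`;
* improved form: exponent `(1 - dE/E)^k`, with `k = 1.3` the best fit to
  measured 90 eV ionization DDCS.

This exponent reading is a deliberate interpretation choice: it is the only
algebra under which the improved form reduces to the original at small
energy loss, is identical at `k = 1`, and is *flatter* at large loss for
`k > 1` — the three behaviours the formula is meant to capture.  Note that
the rate of convergence between the two forms at small `dE/E` is governed by
the dynamic range of the elastic DCS (the pointwise deviation is
`dp * |ln dcs|` with `dp = (1-f) - (1-f)^k`), so for a strongly
forward-peaked DCS the two forms agree to 1% only for loss fractions below
about 0.006, even though the sampled angular *distributions* agree far
sooner.

Angle sampling uses exact closed-form inverse CDFs for the whole
screened-Rutherford family (elastic, its powers, and the `1/K^2` rotational
shape); the generic grid-based `sample_theta()` (inverse CDF on a 4096-point
discretization) is the fallback for tabulated shapes.

## Energy-loss models

Per collision the energy bookkeeping is exact: incident energy equals
outgoing primary energy plus locally deposited energy plus (for ionization)
the secondary electron's kinetic energy.

* rotational: fixed 0.00109 eV loss (mean rotational excitation at 300 K);
* elastic: recoil only, `dE = [4 me M/(me+M)^2] E (1-cos(theta))/2`
  (about 2.8 meV for a 100 eV backscatter off 79 amu);
* vibrational / electronic: the measured angle-averaged loss spectra are
  not tabulated, so the defaults are parametric stand-ins — a discrete
  mixture at 0.1/0.2/0.4 eV (weights 0.5/0.3/0.2) and a two-Gaussian
  mixture at 4.8 and 7.0 eV (sd 0.5 eV) — chosen to sit in the right bands
  of the loss spectrum; `load_spectrum()` +
  `spectrum_to_channel_models()` is the faithful path when a measured
  two-column spectrum is available, splitting it at the electronic onset
  (3.5 eV, from the tabulated set) and the ionization binding energy;
* ionization: loss `B + W` with binding energy `B = 9.6 eV` — a choice
  inside the bracket implied by the tabulated onset (below 0.1 above 10 eV,
  first full value at 12 eV) — and secondary energy `W` drawn from a
  Lorentzian-tailed density `1/(W^2 + w^2)` (`w = 10 eV`) truncated to
  `[0, (E-B)/2]` so the secondary is the slower electron.  The secondary
  spectrum's form is a modelling decision, exposed for sensitivity
  analysis;
* attachment: resonant capture absorbs the electron and deposits its whole
  kinetic energy.

Electrons below 0.1 eV are culled and their residual energy deposited
locally.

## The transport engine and the virtual transmission experiment

`run_beam()` is an event-by-event Monte Carlo: exponential free paths from
the local mean free path `1/(n sigma_tot)`, channel choice proportional to
the channel cross sections, angle and loss from the models above, explicit
3-D direction rotation (no small-angle approximation), secondaries
transported with the same physics up to generation 3.  The gas density
comes from the ideal-gas law at the geometric-mean temperature
`sqrt(T_C * T_m)` of chamber and gauge (the standard thermal-transpiration
correction).  Runs are bit-reproducible under a fixed seed, and every run
closes a global energy ledger (injected = exited + backscattered +
deposited + culled) to rounding error.

Under strong axial magnetic confinement (0.1 T confines the gyro-radius to
microns) scattering shows up only as loss of *axial* kinetic energy
`E_par = E dz^2`, which a retarding potential analyzer (RPA) measures:
`rpa_curve()` gives the transmitted intensity above each barrier voltage.
In vacuum this curve is the beam's complementary energy CDF (the beam is
Gaussian, FWHM 0.45 eV — the midpoint of the source's natural 0.4-0.5 eV
spread — truncated at the cull energy); with gas it lies below the vacuum
curve at every barrier, which is the qualitative signature the real
experiment checks.  Backscattered electrons are removed and logged by
default ("lost"); a specular "reflected" policy is available since the real
source-plane behaviour is apparatus-specific.  The confined cell length is
not published; the default is 0.14 m (configurable), while the linear
spectrometer's 50 mm cell is the `gas_conditions()` default for attenuation
work.  A hook for imperfect confinement at high energy (pitch-dependent
loss) was considered and deliberately not shipped: the published evidence
only indicates that ideal confinement fails above ~90 eV, not how.

`virtual_tcs()` closes the loop with the dataset-construction module: it
measures a Beer-Lambert effective cross section `ln(I0/I)/(nL)` from a thin
run, counting as "unscattered" any primary the detector cannot discriminate.
With perfect discrimination it recovers the full total cross section within
stochastic error; with a finite acceptance cone it is reduced by exactly the
missing-angle contribution that `missing_angle_correction()` computes.

## The exponent fit

`fit_k()` estimates `k` from relative DDCS curves at several energy losses
by joint weighted least squares in log space,
`ln ddcs = ln scale_dE + (1-dE/E)^k * ln dcs_el(theta)`, with one free scale
per curve (the absolute DDCS scale carries a ~20% normalization uncertainty
in the real experiment, so only shapes are fit), the scales profiled out in
closed form and `k` found by 1-D minimization; standard errors come from the
Gauss-Newton Jacobian.  Angles below 1 degree are excluded (dipole-like
forward divergence).  `generate_synthetic_ddcs()` emulates the
reaction-microscope data (90 eV, losses 30/40/50 eV, 1-degree grid,
multiplicative lognormal noise) for parameter-recovery studies: with 5%
noise and 200 replicates the mean recovered exponent is within 0.05 of the
generating value, and the ±2 SE intervals cover it at better than 90%.

```{r}
em <- elastic_dcs_model(xs)
set.seed(1)
dd <- generate_synthetic_ddcs(em, 90, c(30, 40, 50), k_true = 1.3,
                              noise = 0.05)
fit_k(dd, em)
```

## Problem sizes and test design

The test suite regenerates all fixtures in code.  Stochastic checks use
sizes chosen to make their oracles sharp at modest cost: Beer-Lambert
survival uses 1e5 electrons per pressure point against a 3-binomial-SE
band; the vacuum RPA identity uses 1e5 electrons against a 0.5% quantile
band; angle samplers are checked by Kolmogorov-Smirnov distance at 1e5
draws (< 0.01); the exponent-recovery study uses 200 replicates.  The
synthetic-data paths emulate the *statistical* structure of the real
measurements (noise type, angular grids, loss grids) but not their physical
systematics (detector efficiency, absolute normalization, ion-channel
branching), so passing tests validate the estimation and transport
machinery, not the underlying ab initio data.

## Known limitations

* Vibrational data end at 3.2 eV in the compiled table; above that the
  channel contributes zero even though it is physically open.
* The parametric loss spectra and the ionization secondary spectrum are
  stand-ins; use measured spectra via the CSV readers where available.
* The elastic DCS default is a one-parameter screened-Rutherford shape; it
  has the right normalization and forward peaking but none of the
  diffraction structure of the ab initio curves.
* Ion fragmentation is not resolved: attachment and ionization are tracked
  energetically, not chemically.
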