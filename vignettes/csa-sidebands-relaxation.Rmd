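---
title: "CSA tensors, spinning sidebands and relaxation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSA tensors, spinning sidebands and relaxation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csarelax)
```

`csarelax` analyses site-resolved solid-state NMR data of crystalline
small molecules along three connected axes: the chemical shift
anisotropy (CSA) tensor of each carbon site, the slow-MAS
spinning-sideband pattern that tensor produces, and the spin-lattice
relaxation behaviour that links the tensor to molecular motion. This
vignette is the package's account of the underlying models, the
numerical decisions taken where the design was genuinely open, and what
the validation on synthetic data does and does not demonstrate.

## Tensor conventions

A chemical shift tensor is characterized by three principal components.
Two labelling conventions coexist in the literature and the package
implements both explicitly rather than leaving the choice implicit:

* **Frequency ordering** (Herzfeld-Berger / IUPAC):
  $\delta_{11} \ge \delta_{22} \ge \delta_{33}$, with span
  $\Omega = \delta_{11} - \delta_{33}$ and skew
  $\kappa = 3(\delta_{22} - \delta_{iso})/\Omega \in [-1, 1]$.
* **Haeberlen ordering**:
  $|\delta_{zz} - \delta_{iso}| \ge |\delta_{xx} - \delta_{iso}| \ge
  |\delta_{yy} - \delta_{iso}|$, giving the signed reduced anisotropy
  $\Delta\delta = \delta_{zz} - (\delta_{xx} + \delta_{yy})/2$ and
  asymmetry $\eta = (\delta_{yy} - \delta_{xx})/(\delta_{zz} -
  \delta_{iso}) \in [0, 1]$.

The sign of $\Delta\delta$ says on which side of the isotropic shift the
powder pattern extends farthest; $\eta \le 0.3$ corresponds to a nearly
axially symmetric pattern, $\eta \ge 0.8$ to a highly asymmetric one.

**Tie-break.** When $\delta_{iso}$ coincides with $\delta_{22}$ the
Haeberlen rule is ambiguous: $|\delta_{11} - \delta_{iso}| =
|\delta_{33} - \delta_{iso}|$ and both assignments are admissible, with
opposite anisotropy signs ($\eta = 1$ either way). The package breaks
the tie toward $\delta_{zz} = \delta_{33}$, the negative branch. This is
the assignment used in the packaged dexamethasone reference table, whose
only exactly tied row (C7: 44.5/30.8/17.1 ppm) is printed with a
negative anisotropy; adopting it keeps the package's output reproducing
the reference without a special case.

**Degenerate tensors.** A fully isotropic tensor ($\Omega = 0$) returns
0 for span, skew, anisotropy and asymmetry rather than NaN, so that
tabulated pipelines stay total. This is a convention, not a claim that
skew is defined there.

**Comparison tolerances.** Regression against printed tables uses
absolute tolerances of 0.15 ppm for ppm-valued fields and 0.06 for
dimensionless ones. The reference table prints one decimal but mixes
round-half-up with truncation (e.g. a skew of -0.751 printed as "-0.7"),
so a half-ulp tolerance of 0.05 would reject correct arithmetic.

**Known inconsistencies in the reference table.** Recomputing every
derived cell from the printed principal components shows the printed
derived values for C16 (all five) and C22 (all but skew) cannot be
produced from the printed components of those rows - for C22 everything
is consistent with a single digit slip in $\delta_{33}$ (38 for 38.9) -
and the C1, C13 and C7 spans are 0.1-ppm off exact arithmetic. These
cells are recorded in `table2_inconsistencies()` with a severity grade
and are excluded from the regression pass-rate rather than silently
matched; no attempt is made to decide which printed number is the typo
source.

## Sideband simulation

Under magic-angle spinning at rotor frequency $\nu_r$ below the static
linewidth, each site's spectrum is a comb at $\delta_{iso} + N\nu_r$.
For a crystallite whose rotor-axis direction in the tensor frame is
$(\beta, \gamma)$, the instantaneous anisotropic frequency is

$$\nu(t) = C_1\cos\omega_r t + S_1\sin\omega_r t +
           C_2\cos 2\omega_r t + S_2\sin 2\omega_r t,$$

with coefficients obtained by rotating the traceless tensor into the
rotor frame and projecting onto the lab axis tilted at the magic angle
(the constant term vanishes exactly at the magic angle). The phase
$\psi(t) = 2\pi\int_0^t \nu\,dt'$ is therefore known in closed form, and
the order-$N$ sideband amplitude for that crystallite is the Fourier
coefficient $A_N$ of $e^{i\psi(t)}$ over one rotor period. Averaging
over the rotor phase (the third Euler angle) analytically turns the
powder signal into $\sum_N \langle|A_N|^2\rangle e^{iN\omega_r t}$:
intensities are real, nonnegative, and sum to exactly 1 by Parseval's
theorem, which is why the simulator's normalization holds to machine
precision rather than to a quadrature tolerance.

Numerical choices:

* **Powder grid**: a spherical Fibonacci (golden-spiral) lattice,
  default 4181 points, equal weights. It is deterministic (bit-identical
  reruns, no seed), low-discrepancy, and at the default size leaves
  grid-doubling changes below $10^{-3}$ in every intensity. A seeded
  random scheme is available for cross-checks.
* **Time discretization**: 256 slices per rotor period by default,
  comfortably above twice the default maximum sideband order, so the FFT
  resolves every retained coefficient without aliasing. The phase is
  evaluated from the closed form, not by numerical integration.
* **Order window**: `max_order = ceil(span_Hz/mas_hz) + 4`; CSA combs
  decay quickly beyond the static width. If a caller forces a smaller
  window that would truncate more than $10^{-4}$ of the total intensity
  the simulator raises an error instead of silently renormalizing.
* The test suite contains an independent oracle - explicit rotation
  matrices at every time slice, trapezoidal phase integration, direct
  DFT - and the two routes agree to better than $10^{-3}$ (in practice
  $10^{-7}$) on shared grids.

The 2D sideband-separation experiment itself (pulse timings, shearing)
is not simulated: the package works at the level the processed
experiment delivers, sideband order versus intensity.

### The inverse problem

`fit_tensor_from_sidebands()` recovers (span, skew) by least squares:
a coarse grid bracketing the observed comb width (span) and $[-1, 1]$
(skew) on a small powder grid, Nelder-Mead refinement on a medium grid,
final evaluation on the full grid. The isotropic shift comes from the
centerband position and is not fitted. Two failure modes are surfaced
rather than hidden: a pattern with fewer than three informative
sidebands is rejected as underdetermined, and when the mirrored-skew
solution fits within 10% of the best residual the result is flagged
`ambiguous` and both solutions are returned (near-axial and
near-symmetric patterns genuinely do not determine the sign of the
skew well). Noiseless round trips recover span within 2% and skew
within 0.1 across span-to-rotor-rate ratios of 3-30, the regime the
slow-MAS experiment operates in (600 and 2000 Hz at a 125.721 MHz
carrier, for spans of roughly 20-250 ppm).

## Relaxation model

The spin-lattice relaxation rate of a 13C site is modelled as the sum of
a CSA mechanism and heteronuclear dipole-dipole couplings:

$$\frac{1}{T_1} = \underbrace{\frac{2}{15}\,\omega_C^2 S^2
\frac{\tau_2}{1+\omega_C^2\tau_2^2}}_{\text{CSA}} +
\underbrace{\sum_X \frac{d_X^2}{10}\left[J(\omega_X{-}\omega_C) +
3J(\omega_C) + 6J(\omega_X{+}\omega_C)\right]}_{\text{dipolar}},$$

with $S^2 = (\Delta\delta)^2(1 + \eta^2/3)$ (ppm$^2$, converted to a
dimensionless shielding variance), $\tau_c = 3\tau_2$,
$J(\omega) = \tau_c/(1+\omega^2\tau_c^2)$, and
$d_X = (\mu_0/4\pi)\hbar\gamma_C\gamma_X/r_{CX}^3$. Each prefactor
(2/15, 1/10, $\mu_0/4\pi$) is a single named constant at the top of the
source file, so an alternative literature convention is a one-line
change; every validation property (round trips, limits, branch
selection) is independent of the prefactor values. A
`first_term_only` spectral-density mode retains only the
$J(\omega_X-\omega_C)$ term, the common truncation for slow motion.
Gyromagnetic ratios are accepted in MHz/T and converted explicitly
($\times 2\pi\times10^6$); mixing linear and angular frequency
conventions silently is the classic error in this arithmetic and the
conversion is tested.

Two slightly different carrier frequencies circulate with the packaged
data set (125.721 MHz for acquisition, 125.758 MHz quoted with the
relaxation constants); both are carried as named defaults in
`acquisition_context()` and `physical_constants()` respectively,
and neither is "corrected" to the other.

**Inversion.** $R_1(\tau_c)$ is single-peaked, so any feasible measured
rate has two roots: the fast-motion root below the peak and the
slow-motion root above it ($\omega\tau_c > 1$). The package reports the
slow root - rigid crystalline solids with T1 of tens to hundreds of
seconds live on that branch - and returns the fast root alongside. The
root search brackets the peak (found by golden-section on the log axis)
and runs `uniroot` on each side; the fast root can fall below
$10^{-12}$ s for strongly dipolar-coupled sites, so the lower bracket
extends adaptively. An infeasible T1 (rate above the model maximum)
raises an error reporting that maximum rather than returning a boundary
value.

**T1 fitting** is unweighted nonlinear least squares of
$M_0 e^{-t/T_1}$ (Levenberg-Marquardt via `minpack.lm`, log-linear
initialization): fitting the log-transform instead would bias the
low-SNR tail. Non-decaying input is an explicit fit failure.

**Geometry defaults.** The dipolar term needs C-X distances, which come
from crystallography and are user-supplied. When none are given,
`site_relaxation_model()` falls back to nominal directly bonded protons
by group type (methyl 3, methylene 2, methine 1, at 1.09 Å, flagged
`nominal`; nonprotonated carbons get a pure-CSA model). This is a
deliberately minimal motional model: one isotropic correlation time per
site, no NOE or cross-relaxation, no separate 19F channel beyond
treating F as a dipolar partner, no Lipari-Szabo order parameters.

**What the packaged correlation times can and cannot check.** The
reference table's T1 values and tensor parameters are reproducible
inputs, but its printed correlation times were computed with
crystallographic C-X distance sets that are not part of the table, and
the exact prefactor conventions behind them are not recoverable either.
Under this package's configured model the slow-branch inversion
reproduces the order of magnitude for protonated sites with nominal
geometry (methyl sites nearly exactly) but sits roughly two orders of
magnitude below the printed values for the nonprotonated, CSA-only
sites - uniformly so, which points at a prefactor-scale difference
rather than noise. The package therefore validates the relaxation stage
by forward-inverse consistency (exact to $10^{-6}$ relative across 100
random models by construction) and by branch/order-of-magnitude
agreement against its own model applied to the true T1, and reports
comparisons with the printed correlation times as diagnostics only.

## Synthetic data

The generators produce every input the pipeline consumes from known
ground truth, so the whole chain is testable offline:

* **Sideband spectra**: Lorentzian combs (default fwhm 30 Hz) with areas
  from the simulator plus iid Gaussian noise (fraction of the maximum
  amplitude), seeded and bit-reproducible. Pattern extraction from a
  spectrum solves a linear least-squares problem against the known comb
  of unit-area Lorentzians - naive window integration cannot beat the
  fat Lorentzian tails, deconvolution can, and is exact without noise.
* **Decay curves**: $M_0 e^{-t/T_1}$ plus Gaussian noise at 2% of
  $M_0$, 12 delays log-spaced over $[0.05, 3]\times T_1$. The 2% level
  is a stand-in chosen to reproduce the $\pm 5$-$10$ s uncertainties of
  the reference T1 table (200-replicate recovery at $T_1 = 190$ s shows
  bias below 2 s and spread at that scale); the underlying raw decay
  data are not published, so this is a plausible noise model, not a
  measured one.

What synthetic validation does **not** show: the generators share the
package's forward models, so passing round trips demonstrate
self-consistency and inverse-problem conditioning, not the adequacy of
mono-exponential decay or single-correlation-time motion for real
spectrometer data - systematic effects (CP dynamics, spin diffusion,
finite-pulse artefacts, baseline and phasing errors) are out of scope
by design.

## Problem sizes

Default study conditions used throughout the tests: 22 sites, MAS 600
and 2000 Hz at a 125.721 MHz carrier, 4181-point powder grids (1597/610
during fitting stages), 256 time slices per rotor period, 100-model
relaxation round trips, 200-replicate T1 recovery. On one CPU the full
suite runs in about 75 s.
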