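---
title: "Spectrally weighted modeling of metal-enhanced fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrally weighted modeling of metal-enhanced fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mefopt)
```

## The problem

A fluorophore next to a gold or silver nanoparticle can emit far more
light than it does in free solution. Two competing mechanisms set the
balance: the particle's localized surface plasmon resonance (LSPR)
concentrates the excitation field at the molecule (raising absorption),
and the same resonance opens new decay channels for the excited state —
radiative ones (the Purcell effect, more photons) and non-radiative ones
(energy dumped into the metal, Förster-type quenching, fewer photons).
Tuning a nanorod's aspect ratio (AR) slides the LSPR across the visible
spectrum, so the design question is: *which AR, excitation wavelength,
and molecule–particle gap maximize the fluorescence signal of a given
fluorophore?*

The traditional way to answer this (the monochromatic model, TM here)
reduces the fluorophore to two numbers — the wavelengths of its
excitation and emission peaks — and maximizes
$K_{flu} = \xi(\lambda_{ex}) \cdot Y(\lambda_{em})$, where
$\xi = |E|^2/|E_0|^2$ is the near-field intensity enhancement at the
molecule and $Y$ its modified quantum yield. But a real emission band is
broad: for a TagRFP-like emitter, only about a third of the emitted power
lies in the 26 nm band where the normalized emission exceeds 0.9. The
refined model (RM) implemented here therefore weights every quantity by
the fluorophore's normalized spectra $I_{ex}(\lambda)$, $I_{em}(\lambda)$:

$$\xi_{eff}(\lambda) = I_{ex}(\lambda)\,\xi(\lambda), \qquad
  \Gamma_{rad,eff} = I_{em}\,\Gamma_{rad}, \qquad
  \Gamma_{nr,eff} = I_{em}\,\Gamma_{nr},$$

$$Y_{eff} = \frac{\Gamma_{rad,eff}}
  {\Gamma_{rad,eff} + \Gamma_{nr,eff} + 1/Y_0 - 1}, \qquad
  K_{flu,eff} = \xi_{eff}(\lambda_{exc}) \cdot Y_{eff}(\lambda),$$

with all rates normalized to the radiative rate of the isolated molecule
in the same host medium, and $Y_0$ its intrinsic quantum yield. The
$\hbar\omega$ factors that appear in the dimensional definitions of the
effective rates cancel in these normalized ratios; the spectral
dependence of the photon energy re-enters only in the integral
total-power criterion below.

## Electromagnetic backends and their contract

Every backend answers two questions per wavelength, under one contract:

* **excitation**: for a plane wave polarized along the rod's long axis,
  the enhancement $\xi$ at the molecule position and the cross-sections
  $C_{abs}$, $C_{sca}$, $C_{ext}$ (with $C_{ext} = C_{abs} + C_{sca}$ —
  the scattered and absorbed powers per incident intensity);
* **emission**: for a point dipole at the molecule position, the
  normalized rates $\Gamma_{rad}$, $\Gamma_{nr}$.

The molecule sits on the long axis, a gap $\Delta$ beyond the cap apex,
with its transition dipole perpendicular to the surface (along the
axis) — the orientation that couples to the longitudinal plasmon. Both
orientations are implemented; the perpendicular one is the default.

**Spheres (`mie_sphere`).** Exact Mie series. $C_{ext}$ comes from the
optical theorem, $C_{sca}$ from the scattered-power series, and
$C_{abs}$ from the net-flux (absorbed-power) series, so the closure
$C_{ext} = C_{abs} + C_{sca}$ is an analytic identity the test suite
verifies to $10^{-9}$, not an assignment. $\xi$ is evaluated from the
full vector-harmonic near field on the polarization axis. The dipole
rates use the classical multipole expressions for an emitter outside a
sphere; the quenching series converges like $(a/r)^{2n}$ and its terms
pair exponentially small scattering coefficients with exponentially
large Hankel functions, so it is accumulated through ratio recurrences
of the products — the implementation is stable down to sub-nm gaps
(hundreds of multipole orders) without overflow. It is validated against
an independently coded quasistatic image-multipole series, against the
$\Gamma_{nr} \propto \Delta^{-3}$ small-gap law, and against exact
energy conservation for lossless spheres.

**Rods (`spheroid_mlwa`).** Nanorods (cylinders with hemispherical
caps) are replaced by prolate spheroids treated in the modified
long-wavelength approximation: the quasistatic polarizability along the
driven axis, corrected for dynamic depolarization ($k^2$ term scaled by
the driven semi-axis) and radiative reaction ($ik^3$ term, which keeps
$C_{abs} \ge 0$). The near field at the molecule is the incident field
plus the retarded dipole field of the induced moment; emission uses the
same coupling reciprocally — the emitter's near field polarizes the
particle, radiative enhancement comes from the interference of the two
dipole moments, $|1 + \alpha g(r)|^2$, and quenching from the absorptive
part of the particle response, $(6\pi/k^3)\,\mathrm{Im}(\alpha_{abs})\,|g(r)|^2$.

*Choosing the surrogate spheroid.* An equal-diameter, equal-length
spheroid systematically underestimates how fast the longitudinal LSPR
tunes with AR, because a spheroid of the same AR is effectively less
elongated than a capped cylinder (it lacks the cylindrical mid-section's
volume). The default mapping therefore preserves diameter and *volume*,
which for a capped cylinder of aspect ratio AR gives an effective
spheroid aspect ratio $1.5\,\mathrm{AR} - 0.5$. On the default gold
sweep this yields a $C_{abs}$ peak tuning rate of ~30 nm per +0.2 AR
(silver ~38 nm) — the right scale for fat ($d = 50$ nm) rods — where the
equal-length mapping gives only ~19 nm (silver ~21 nm). The equal-length
mapping remains available (`nanorod_geometry(..., mapping = "length")`).
Volume-equivalent spheroids are the standard effective model for
capped-cylinder rods and this choice is the dominant surrogate error
source for all rod-level numbers.

**Tabulated (`tabulated_backend`).** Any external solver's exported
per-wavelength response can be registered under the same contract and
drives the whole sweep machinery unchanged; rows are interpolated
linearly.

## Materials

Vendored experimental optical constants (evaporated-film measurements of
Johnson & Christy, 1972) for gold and silver ship as n,k tables and are
interpolated **linearly in the complex permittivity versus wavelength** —
linear interpolation of non-negative $\varepsilon''$ can never produce
gain, unlike spline interpolation of n,k, which can overshoot below
zero. The cost is kinked spectra between nodes; the silver table's
~25–30 nm node spacing in the visible is the main resolution limit on
silver peak positions (see Limitations). Analytic Drude–Lorentz fits
(Rakić et al., 1998) are included as an independent cross-check source;
the two gold datasets agree at 532 nm to a few tenths of a permittivity
unit. The host is non-absorbing water ($n = 1.33$) and all materials are
non-magnetic ($\mu = 1$).

## The fluorophore and the synthetic-spectra generator

Spectra are stored normalized to unit maxima with peaks refined by
parabolic interpolation. Real spectra load from the two-column CSV
dialect of public fluorescent-protein repositories. The generator
`synth_spectra()` produces split-Gaussian bands (independent blue/red
widths via an asymmetry ratio); `tagrfp_spectra()` is the TagRFP-like
default: excitation peaking at 555 nm with a blue shoulder, emission at
584 nm with a red tail. The emission band is calibrated so the region
with $I_{em} > 0.9$ is 26 nm wide; any Gaussian band then automatically
carries $\mathrm{erf}(\sqrt{-\ln 0.9}) \approx 35\%$ of the emitted
power in that band, matching the published TagRFP curve. The intrinsic
quantum yield is not part of public spectra files; the default
$Y_0 = 0.48$ is the published TagRFP value and is echoed into every
output so the assumption is always visible.

What the generator does **not** emulate: vibronic substructure,
solvent/conformational shifts, photobleaching, and any secondary
excitation band. Tests that pass on these clean single-band spectra
therefore validate the spectral-weighting machinery, not the
idiosyncrasies of any particular dye.

## Sweeps, peak tracking, and the recommendation

`build_map()` evaluates any quantity over (wavelength × AR);
`track_peaks()` locates per-AR maxima with parabolic refinement.
Boundary maxima are flagged and never refined, silently reported as
optima, or fed into spacing/redshift statistics; plateau ties report the
leftmost node and are flagged. Halving the 1 nm default wavelength step
moves refined peaks by well under 0.5 nm.

`recommend()` picks the AR maximizing $K_{flu,eff}$ (RM), the
excitation wavelength maximizing $\xi_{eff}$ at that AR, and reports the
TM recommendation alongside — the two can differ, which is the point of
the refined model. Two diagnostic observables are also reported:

* the **near-field redshift**, $\lambda_{peak}(\xi) - \lambda_{peak}(C_{abs})$:
  the field maximum lies to the red of the absorption resonance (larger
  for the broader gold resonance than for silver), which matters because
  only $C_{ext}$-type quantities are experimentally accessible;
* the **stabilization ratio** of $C_{abs}$ to $\xi_{eff}$ peak spacings:
  weighting by $I_{ex}$ pins the effective excitation peak near the
  fluorophore band, so it moves several-fold less per AR step than the
  bare resonance.

For gap studies, `gap_sweep()` scans $\Delta$; on the exact Mie sphere
backend the enhancement/quenching competition produces the expected
interior optimum (around 8 nm for a 20 nm gold sphere with the default
spectra).

An integral figure of merit complements the peak criterion:
`integral_criterion()` integrates $\Gamma_{rad,eff}$ over the emission
support weighted by the relative photon energy $\lambda_{em}/\lambda$
and multiplies by $\max \xi_{eff}$ — an estimate of the *total* emitted
power gain rather than the peak spectral gain.

## Numerical choices

* Mie series: Wiscombe truncation $x + 4x^{1/3} + 2$ for plane-wave
  quantities; dipole-rate series truncated at a $10^{-12}$ relative
  term, with depth pre-sized from the $(a/r)^{2n}$ decay.
* Degenerate inputs: an index-matched particle returns $\xi = 1$, zero
  cross-sections, rates $(1, 0)$ exactly; zero rates with $Y_0 = 1$
  give $Y_{eff} = 0$ by convention (no emission in band); spectral peaks
  outside a solver grid evaluate at the nearest grid edge.
* The effective-yield denominator applies $I_{em}$ to both rates, so at
  band edges the constant $1/Y_0 - 1$ dominates and $Y_{eff} \to 0$;
  this is the defining formula's behavior, documented rather than
  altered — numerically $Y_{eff} \le Y$ whenever $Y_0 < 1$.
* Gaps below 1 nm trigger a warning (the dipole surrogate and local
  response approximation both degrade).
* All sweeps are deterministic; randomized studies (the planted-optimum
  recovery test) take explicit seeds.

Default problem sizes — wavelengths 450–700 nm in 1 nm steps, six AR
values, one gap — evaluate in well under a second per metal, so the full
study (both metals, maps, recommendation, gap scans) is interactive.

## Known limitations

* **Rod-level absolute numbers are surrogate-limited.** The
  dipole-order spheroid misses the lightning-rod field concentration at
  the rod tips, so absolute $\xi$ and $K$ for rods (especially sharp
  silver resonances at small gaps) are underestimates, and multipolar
  quenching at few-nm gaps is missing — for rods, $K(\Delta)$ keeps
  rising toward small gaps instead of turning over as a full-wave
  solution does. Trends across AR and wavelength, peak locations, and
  all sphere-backend results are the reliable outputs; plug in a
  tabulated full-wave export when absolute rod numbers matter.
* **Silver peak positions carry a few-nm jitter** inherited from the
  sparse vendored silver table under linear interpolation; quantities
  built as small differences of two peak positions (per-AR redshifts)
  fluctuate accordingly. Averages across ARs are more stable than any
  single-AR value.
* Shells, spacer chemistry, chemical interface damping, substrate
  effects, and emitter saturation are all out of scope by design.
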