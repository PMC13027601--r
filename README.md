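# mefopt

Spectral optimization of metal-enhanced fluorescence (MEF)
nanocomplexes: a fluorophore molecule held a few nanometers from a gold
or silver nanorod, tuned through the rod's aspect ratio so the
localized surface plasmon resonance (LSPR) overlaps the molecule's
excitation and emission bands. The package is for researchers designing
such complexes (biosensing labels, single-molecule probes) who need to
pick the rod aspect ratio, excitation wavelength, and gap before
committing to synthesis or to expensive full-wave simulation.

## The model

Near a plasmonic particle, the fluorescence signal of a molecule with
intrinsic quantum yield Y₀ changes through two channels: the local
excitation intensity is enhanced by ξ = |E|²/|E₀|², and the excited
state decays with modified radiative and non-radiative rates Γ_rad,
Γ_nr (normalized to the isolated molecule's radiative rate). The
classical *monochromatic* figure of merit freezes the fluorophore at
its two spectral peaks:

    K_flu = ξ(λ_ex) · Y(λ_em),     Y = Γ_rad / (Γ_rad + Γ_nr + 1/Y₀ − 1)

The package's main subject is the *spectrally refined* description, in
which the normalized excitation and emission spectra I_ex(λ), I_em(λ)
weight every quantity:

    ξ_eff = I_ex · ξ
    Γ_rad,eff = I_em · Γ_rad ,  Γ_nr,eff = I_em · Γ_nr
    Y_eff = Γ_rad,eff / (Γ_rad,eff + Γ_nr,eff + 1/Y₀ − 1)
    K_flu,eff = ξ_eff(λ_exc) · Y_eff(λ)

so enhancement only counts where the molecule actually absorbs and
emits. Electromagnetics come from interchangeable backends: exact Mie
series for spheres (cross-sections, on-axis near field, and
dipole decay rates, stable to sub-nm gaps), a modified
long-wavelength-approximation (MLWA) prolate-spheroid surrogate for
nanorods, and a tabulated plug-in for responses exported from any
full-wave solver. Sweep tools map every quantity over
(wavelength × aspect ratio), track resonance peaks, scan the gap, and
recommend the optimal configuration under both models.

## Worked example

```r
library(mefopt)

cfg <- run_config(metal = "gold")   # d = 50 nm rods in water, AR 1.1-2.1,
print(cfg)                          # 6 nm gap, TagRFP-like spectra, Y0 = 0.48
#> <run_config> gold rod d = 50 nm, AR [1.1, 2.1], gap 6 nm (perpendicular), RM model
#>   medium n = 1.33; lambda 450-700 nm; Y0 = 0.48; hash bec78a3c...

recommend(cfg)
#> <optimization_report>
#>   RM: optimal AR = 1.10, K_flu_eff = 11.8, excite at 556.8 nm
#>   TM: optimal AR = 1.10, K_flu = 8.56
#>   NOTE: optimum on the AR grid edge - widen the AR grid
#>   C_abs peak shift per AR step: 30.2 nm; xi_eff spacing: -3.50 nm (ratio 5.4)
#>   xi redshift vs C_abs at optimal AR: 18.4 nm
```

Reading the report: the gold rod's absorption resonance tunes ~30 nm to
the red per +0.2 of aspect ratio, while the spectrally weighted field
enhancement peak moves only ~3.5 nm (the stabilization ratio ~5) —
weighting by the excitation band pins the effective optimum near the
fluorophore. The near-field maximum sits ~18 nm red of the absorption
peak, which matters when tuning against a measured extinction spectrum.
The best enhancement, K_flu,eff ≈ 12 versus the free-molecule baseline,
comes from the smallest rod in the grid (its resonance sits closest to
the 555 nm excitation peak), excited at ~557 nm rather than exactly at
the excitation peak. The flagged edge optimum advises widening the AR
grid below 1.1.

The TagRFP-like default spectra are synthetic but calibrated:

```r
sp <- tagrfp_spectra()
print(sp)
#> <fluorophore_spectra> 351 points, 400-750 nm; ex peak 554.8 nm, em peak 584.3 nm, Y0 = 0.48
emission_power_fraction(sp, 0.9)   # ~34% of emitted power in a ~25 nm band
```

Real spectra load with `read_spectra_csv()` (the two-column dialect of
public fluorescent-protein repositories); measured or full-wave solver
responses plug in through `tabulated_backend()` and
`register_backend()`. A thin command-line wrapper with `recommend`,
`sweep`, `gapsweep`, and `peaks` subcommands is installed under
`system.file("exec", "mefopt", package = "mefopt")`.

See the vignette (`vignettes/mef-spectral-model.Rmd`) for the model's
assumptions, the spheroid-surrogate design choices, and known
limitations.

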