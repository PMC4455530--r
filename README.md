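# gcrsim

Design ground-based reference fields that stand in for the shielded
galactic-cosmic-ray (GCR) environment, and size chronic-exposure
simulations so they do not create multiple-traversal artifacts.

## Who this is for

Space radiobiology and dosimetry groups planning mixed-field accelerator
campaigns: the package turns transport-code dose predictions behind two
spacecraft shielding configurations (*habitat*: 5 g/cm² aluminum + 5-cm
tissue; *transfer vehicle*: 20 g/cm² aluminum + 5-cm tissue) into a
concrete beam list — nine HZE beam-energy combinations (¹⁶O, ²⁸Si, ⁵⁶Fe
at 500/900/1500 MeV/u), each with a polyethylene absorber, plus 16
proton and 11 ⁴He energies — with per-beam fluence budgets, a randomized
fraction-by-fraction delivery schedule, and a kinetics model of how many
cells get hit how often.

## The model in brief

* **Dose–fluence**: `D = ρΦL`, implemented as
  `D[mGy] = 160.2 · L[keV/µm] · Φ[/µm²] / ρ`, with LET from the
  relativistic Bethe formula (Barkas effective charge, Bragg additivity,
  tissue = unit-density water, I = 75 eV).
* **Absorber design**: the primary dose surviving an absorber of depth
  `x` follows exponential extinction `e^(−σ_abs · x)`, so the depth that
  leaves the beam its GCR dose share `f` is `x_pe = −ln(f)/σ_abs`.
* **Fluence budgets**: the bare beam delivers the primary share `B` of
  its charge-group energy-bin dose, `Φ = (D/1000)·B·φ_G`; the
  behind-absorber component delivers the fragment share,
  `Φ = (D/1000)·(1−B)·φ_G / r`, with `φ_G` the per-Gy beam fluence and
  `r` the behind-to-bare dose ratio.
* **Multi-hit kinetics**: cells of area `A` accrue hits at rate
  `H_r = F·A`; populations `n_i` with `i` hits follow
  `dn_0/dt = −H_r n_0 + K_D Σ f_i n_i`,
  `dn_i/dt = H_r(1−q) n_{i−1} − (H_r + K_D + K_in,i) n_i`,
  with `K_D = ln2/τ_relax` resetting all hits and `q` (default 0.1) the
  per-hit inactivation branched into a dead pool.  A per-cell Monte
  Carlo simulator independently checks the ladder.

## Worked example

```r
library(gcrsim)
library(dplyr)

field <- design_reference_field("habitat")
glance(field)
#> # A tibble: 1 × 7
#>   scenario n_hze_beams n_light_beams total_dose_mGy hze_dose_mGy ...
#> 1 habitat            9            27           202.         38.6

# the 16O 500 MeV/u pair of rows: bare primary + behind-absorber fragments
tidy(field) |> filter(ion == "16O", energy_MeVu == 500)
#>   ion       Z     A energy_MeVu role      absorber_gcm2 dose_mGy fluence_per_um2
#> 1 16O       8    16         500 primary             0       2.25        0.000794
#> 2 16O       8    16         500 fragments          17.8    11.5         0.00471

# a 2-day compressed delivery of the transfer-vehicle HZE fluence:
# what fraction of 100-µm² nuclei is hit twice or more?
ft <- design_reference_field("transfer")
hze <- sum(ft$fluence_per_um2[ft$role != "beam"])   # ~7.7e-3 /µm²
kin <- solve_hit_kinetics(kinetics_params(area_um2 = 100, tau_relax_days = 7),
                          exposure_window(hze, 2))
kin
#> <hit_kinetics: 2-day window, H_r = 0.3856/day>
#>   end of window: >=1 hit 42.5%, >=2 hits 12.6%, dead 7.42%

# ~360-fraction randomized session, ~6 h at 1-min switching
sched <- schedule_exposures(field, schedule_policy(seed = 1))
nrow(sched); session_duration(sched) / 60
#> [1] 360
#> [1] 6
```

The total field dose (202 mGy/y) reproduces the scenario's annual
charge-group total; the 12.6 % two-or-more-hit fraction is the
fluence-rate artifact that motivates stretching "chronic" simulations to
several weeks — in a year-long space exposure of the same fluence the
multi-hit fraction stays negligible.

`validate_field_design()` recomputes every derivable cell of the shipped
design tables and reports `pass` / `close` (printed-rounding) / `tuned`
(transport-tuned absorber depths) / `fail` per cell.  A thin CLI over
the same functions ships in `inst/cli/gcrsim.R`
(`design`, `validate`, `kinetics`, `schedule`).

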