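# oligosizer

Sizing regular oligomeric protein complexes from polarization-resolved
cryo-SMLM localization data.

## The problem

Single molecule localization microscopy (SMLM) can in principle resolve
protein complexes only a few nanometers across, but two obstacles stand in
the way: every dye molecule blinks a random number of times, and the
per-blink localization error (1–10 nm) rivals the size of the structure.
At cryogenic temperatures the fluorophores' transition dipoles are frozen,
so alternating x/y-polarized excitation gives every dye a characteristic
pair of expected channel brightnesses

    N_x = N_max cos²θ cos²φ,   N_y = N_max cos²θ sin²φ

for dipole azimuth φ and elevation θ. This fingerprint is used to assign
blinks to individual protomers; the per-protomer mean positions are then
fitted with a geometric circle, and the fitted radius is corrected for its
second-order heteroscedastic bias:

    r̂_corr = r̂/2 + sqrt( (r̂/2)² − (1/(2n) + 1/n²) Σᵢ ẑᵢ ),
    l̂ = 2 r̂_corr sin(π/n),

where ẑᵢ = mᵢ⁻² Σⱼ sⱼ² is the variance of protomer i's mean position
(mᵢ blinks with precision estimates sⱼ). Populations of oligomers are
aggregated by the median with bootstrap confidence intervals. For
simulated 5 nm tetramers at N_max = 10⁴ photons the median side-length
estimate is accurate to well under 1% even though individual localizations
are only good to ~2.3 nm.

The package is aimed at microscopists and method developers who want to
simulate such experiments, benchmark the assignment/fit/correction
workflow, or run it on their own localization tables (CSV with per-blink
position, two channel intensities and a precision estimate).

## Worked example

```r
library(oligosizer)

acq  <- acquisition_model(N_max = 1e4)          # b = 0, 100 nm pixels, 160 nm PSF
spec <- oligomer_spec(n = 4, l = 5, n_oligomers = 20000)
tbl  <- simulate_dataset(spec, acq, seed = 1)
res  <- size_oligomers(tbl, acq, n = 4, nominal_l = 5, n_boot = 200,
                       n_simulated = 2e4)
```

which prints, via the accessors:

```
Acquisition model (polarization-resolved cryo-SMLM)
  N_max: 10000 photons   background b: 0
  pixel: 100 nm   sigma_PSF: 160 nm
  precision cutoff: 10 nm  ->  N_min: 264.33 photons
  intensity-group separation delta_p: 400 photons

Localization table: 505805 blinks, 20000 oligomers

L_hat (median): 5.0391 nm  CI [5.0266, 5.0586]
relative error: 0.781 %
counts:    simulated 20000  eligible 16674  converged 16646  corrected 16069
fractions: eligible 0.8337  correct 0.9979
```

Reading: of 20000 simulated tetramers, 83% produced exactly four
well-separated intensity groups (eligible); almost all eligible oligomers
had every blink assigned to the right molecule; and the median corrected
side length lands within 0.8% of the nominal 5 nm. `run_experiment()` +
`report_sweep()` drive parameter sweeps (brightness, background, labeling
efficiency, side length, oligomer order, tilt), and
`inst/cli/oligosizer.R` exposes `simulate` / `analyze` / `sweep`
subcommands for shell use.

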