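# metaflim

Analysis toolkit for label-free optical metabolic imaging of NAD(P)H and
FAD autofluorescence: calibrated optical redox ratio (ORR) imaging,
time-domain fluorescence lifetime (TCSPC FLIM) analysis by biexponential
fitting and by phasor analysis, and machine-checkable quality control
against the field's consensus reporting recommendations. A seeded
synthetic generator produces every input the pipeline consumes — photon
count decay stacks, intensity channel pairs, calibration-solution frames,
IRFs — so the whole chain can be validated against known ground truth
without instrument data.

Intended users: microscopists and image analysts working with two-photon
NAD(P)H/FAD autofluorescence who need reproducible, cross-system-comparable
redox and lifetime metrics, and methods developers who want a tested
reference implementation of the standard analysis chain.

## The quantities computed

**Optical redox ratio.** Both normalized conventions, which sum to 1:

    ORR_oxidized = FAD / (NAD(P)H + FAD)        (default)
    ORR_reduced  = NAD(P)H / (NAD(P)H + FAD)

Channels can be calibrated by dividing by the mean intensity of 1 mM NADH
and FAD solution standards imaged under the same settings, which cancels
per-channel instrument factors and makes ORR comparable across acquisition
conditions and systems. Per-region aggregation reports both the
ratio-of-means and the mean-of-ratios side by side.

**Biexponential FLIM.** Per-pixel decays are modeled as

    I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + C

with the short component tau1 conventionally free NAD(P)H and the long
component tau2 protein-bound. The measured curve is the period-wrapped
model circularly convolved with the instrument response function (IRF),
fitted by Levenberg–Marquardt with either Neyman-weighted least squares
(WLS) or Poisson maximum likelihood (MLE). Derived summaries: the
amplitude-weighted mean lifetime `tau_m = (a1 tau1 + a2 tau2)/(a1 + a2)`
and the bound intensity fraction `f2 = a2 tau2 / (a1 tau1 + a2 tau2)`
(distinct from the amplitude fraction `a2/(a1+a2)` — the two must not be
compared).

**Phasor analysis.** Each decay maps to normalized Fourier coordinates at
a harmonic of the repetition rate:

    g = sum I(t) cos(wt) / sum I(t),   s = sum I(t) sin(wt) / sum I(t)

Monoexponential decays fall on the universal circle `s^2 = g(1-g)`;
mixtures fall on the chord between component phasors, weighted by
intensity fractions. After calibration with a reference dye of known
lifetime (e.g. fluorescein in ethanol, 3.05 ns), the package computes
phase and modulation lifetimes (`tau_phi = s/(g w)`,
`tau_mod = sqrt(1/(g^2+s^2) - 1)/w`), the distance `d` from the free
NAD(P)H position (0.4 ns by convention), and the normalized bound
fraction from two endpoints — assigned from lifetimes or extracted by a
total-least-squares line fit of the phasor cloud.

**Quality control.** Photon statistics pre/post binning, the pile-up
bound (detected rate below 5–10% of the pulse rate), Poisson SNR
(sqrt(N)), and the four consensus reporting checklists (7 + 5 intensity
items, 5 + 4 FLIM items) evaluated from run metadata into a structured
pass/fail/missing report.

## Worked example

```r
library(metaflim)

grid <- time_grid(256, 12.5e-9 / 256, 80e6)   # 80 MHz, 12.5 ns window
irf  <- make_gaussian_irf(grid, fwhm = 150e-12)

# two cell populations with different bound-NAD(P)H fractions
params <- list("1" = biexp_params(0.5e-9, 3.0e-9, 700, 100),
               "2" = biexp_params(0.5e-9, 3.0e-9, 300, 250))
scene <- make_cell_scene(dim = c(48, 48), n_cells = 2, params = params,
                         photons = 1500, seed = 1)
stack <- simulate_tcspc_image(scene, grid, irf, seed = 2)

fit <- fit_stack(stack, irf, method = "mle", bin_size = 3,
                 min_photons = 200)
print(fit)
#> Biexponential fit map (mle): 300 fitted / 2304 pixels (bin 3x3, threshold 200 photons)
#>  parameter         mean       median           sd
#>       tau1 4.848903e-10 4.936576e-10 4.051043e-11
#>       tau2 3.010416e-09 3.012406e-09 7.289220e-11
#>       ...
#>       chi2 1.013985e+00 1.011079e+00 8.559944e-02
```

The fitted lifetimes recover the generating 0.5 ns / 3.0 ns components,
and the reduced chi-square distribution sits at 1, as it should for
Poisson data under the correct model. The fit-free phasor route gives the
same per-region bound fractions:

```r
reference <- simulate_decay(biexp_params(3.05e-9, 3.05e-9, 1, 1),
                            grid, irf, 1e6, poisson = FALSE)
field <- calibrate_phasor(phasor_transform(stack), reference, 3.05e-9)
field <- median_filter_phasor(field, 3)
f2 <- bound_fraction_normalized(
  field, endpoints_from_lifetimes(0.5e-9, 3.0e-9, grid_omega(grid)))
#> region 1: phasor f2 = 0.461 (truth 0.462)
#> region 2: phasor f2 = 0.836 (truth 0.833)
```

and the QC report records photon statistics, the pile-up margin and the
reporting checklist:

```r
qc <- build_checklist(run_metadata = list(power_mw = 20, ...),
                      analysis_config = list(fit_method = "mle", ...),
                      mode = "flim",
                      photon_stats = photon_stats(stack, bin_size = 3),
                      pileup = pileup_check(5e5, 80e6))
print(qc)
#> QC report (schema 1.0, mode flim)
#>   pile-up: 0.625% of pulse rate [pass]
#>   photons/decay (binned): min 6068, mean 11491, median 12063
#>   checklist: missing 2, not_applicable 12, pass 7
#>   ...
#>   [pass   ] fe5: free NAD(P)H endpoint 0.4 ns, assigned
#>   [missing] fb4: requires attestation field orthogonal_validation_performed
```

A command-line front end wraps the same functions
(`inst/cli/metaflim simulate|fit|phasor|redox|qc`); every run writes a
manifest with the full configuration, seed and output checksums.

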