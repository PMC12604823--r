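---
title: "Models and numerical choices in metaflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in metaflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models metaflim implements, the assumptions
behind them, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the numerical
decisions a maintainer or careful user should know about.

## The decay model and its timing conventions

Per-pixel TCSPC data are photon-arrival histograms on a `time_grid`
(`n_bins` bins of width `bin_width` seconds under repetition rate
`rep_rate` Hz; default fixtures use 256 bins spanning the full 12.5 ns
period of 80 MHz excitation). All curves are sampled at bin centers
`t_k = (k + 0.5) * bin_width`, everywhere: simulation, fitting, and the
phasor transform use the same convention, so discretization offsets
cancel between model and data.

The fluorescence model is the two-component decay

$$I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C,$$

with `tau1 <= tau2` enforced by canonical ordering at construction (the
short component is conventionally free NAD(P)H, the long one
protein-bound). Amplitudes are stored in photon-count units, matching
how fitting software reports them; fractional views — the amplitude
fraction `a2/(a1+a2)` and the intensity fraction
`f2 = a2*tau2/(a1*tau1 + a2*tau2)` — are derived quantities. The two
fractions are deliberately kept distinct in the API because they are
numerically different summaries of the same decay and must never be
compared across methods.

**Incomplete-decay wrap-around.** At 80 MHz a 3 ns component retains
about 1.6% of its amplitude at the end of the period, so the steady
state the instrument observes is the periodically wrapped decay
$\alpha e^{-t/\tau} / (1 - e^{-T/\tau})$. Simulation and fitting both
use this wrapped form, and IRF convolution is circular over the period
(FFT-based), so counts are conserved exactly and phasors of wrapped
decays match the continuous closed forms at harmonic frequencies. A
linear-convolution mode exists for long-period data where the decay
completes well inside the window. The wrapped component still
integrates to $\alpha\tau$ per period, which is why intensity fractions
are unaffected by the wrapping convention.

**A half-bin subtlety.** Discrete circular convolution composes bin
indices, so the centroid of a convolved curve is
`centroid(decay) + centroid(IRF) - bin_width/2`: two bin-center offsets
enter, one leaves. Moment-based estimators (used as an oracle in the
tests) must add the half bin back. None of the estimators in the
package itself are affected, because model and data share the offset.

## Fitting

The fitted model is the wrapped biexponential circularly convolved with
the unit-sum-normalized IRF. Optimization is Levenberg–Marquardt
(`minpack.lm`) with box constraints; lifetimes are passed to the
optimizer in nanoseconds so the parameter scales are comparable.

* **WLS** minimizes Neyman-weighted least squares, weights
  `1/max(counts, 1)`. This is the classical choice but it is known to
  bias lifetimes downward when many bins hold only a few counts (bins
  fluctuating low get overweighted). The suite measures this directly:
  at 500 photons per decay the WLS mean-lifetime bias is several
  percent while MLE's is an order of magnitude smaller.
* **MLE** minimizes the Poisson deviance via signed square-root
  deviance residuals, which lets the same Levenberg–Marquardt machinery
  find the maximum-likelihood estimate. It is the recommended method at
  the photon counts typical of NAD(P)H FLIM and is what the
  parameter-recovery tests use.

**Goodness of fit** is reported as the reduced Pearson chi-square
`sum((y - m)^2 / m) / (n_bins - n_free)`. The Neyman form
(`1/max(y, 1)` weights) is biased upward under a correct model at the
few-counts-per-bin level of FLIM tails, whereas the Pearson statistic
has unit expectation per bin for Poisson data at any count level; the
tests confirm the distribution centers on 1 at 5,000 photons per decay.

**Background.** `C` defaults to 0. Under full-period repetitive
excitation there is no signal-free "pre-rise" region: bins before the
IRF rise contain the wrapped tail of the decay itself, which the
periodic model accounts for, so estimating background from them is
wrong (it measurably biased every fit when tried during development).
A known background can be fixed, or fitted as a fifth parameter with
`fit_background = TRUE`.

**Initialization and bounds.** The long lifetime starts from the
log-linear slope of the tail (clamped to 0.8–6 ns), the short lifetime
at 0.4 ns (the conventional free-NAD(P)H value), and amplitudes from a
linear solve at those fixed lifetimes. Lifetime box constraints default
to 0.01–10 ns, wide enough for any physiological NAD(P)H/FAD component
while preventing divergence on degenerate decays. No component is ever
fixed by default — lifetimes in cells differ from solution values, so
fixing is available only by explicit initialization.

**Binning and thresholding.** `bin_and_threshold` sums each pixel's
decay over a `bin_size x bin_size` neighborhood (default 3) and masks
on the *original* per-pixel total (default 200 photons). Edge
neighborhoods are truncated, not mirrored, so photon counts stay
honest; consequently the "threshold x bin area" floor (1800 photons at
the defaults) is guaranteed only for pixels with full neighborhoods,
and the reported statistics distinguish the two.

## Phasor analysis

The transform is a plain Riemann sum at bin centers over the acquired
window, normalized by the per-pixel total; no apodization. With a
full-period window the discrete sums reproduce the continuous closed
forms to ~2e-4 at 256 bins, comfortably inside every tolerance used.
Zero-count pixels are masked (NA), never NaN-propagated. Background is
subtracted only if supplied explicitly (same reasoning as for fitting:
with wrapped decays there is no pre-rise region to estimate it from).

**Calibration** is a single global complex factor — a phase rotation
plus modulation scaling — that maps the measured phasor of a reference
standard onto the theoretical position of its known monoexponential
lifetime. This removes the instrument's phase and modulation response
in one step; per-pixel calibration is deliberately unsupported. The
reference must be measured under the same timing conditions. An
IRF-free ideal reference yields a correction factor of 1 up to the
discretization residual, so repeated calibration is idempotent to
~1e-4.

**Bound fractions.** The distance
`d = sqrt((g - g1)^2 + (s - s1)^2)` from the free-NAD(P)H position
(default 0.4 ns at the first harmonic) is reported *as a distance*. It
becomes the normalized fraction `f2 = d / |bound - free|` only when
both endpoints are supplied, because without the bound endpoint the
distance is not a fraction of anything — and because the amplitude
fraction from fitting and the intensity fraction from phasors are
different quantities. Values beyond the segment are clipped to [0, 1]
with the out-of-segment count reported. Endpoints can be assigned from
lifetimes or extracted by an intensity-weighted total-least-squares
line through the phasor cloud, intersected with the universal circle;
the fit refuses clouds with fewer than 10 pixels, no measurable spread
(leading eigenvalue < 1e-8), or near-isotropic spread
(minor/major eigenvalue ratio > 0.5), since those cannot determine a
line direction.

**Median filtering** of g and s (default 3x3, NA-aware inside the
mask) is the standard low-photon denoising step; the intensity image
is never filtered.

## Optical redox ratio

Both normalized conventions are implemented; `oxidized`
(FAD/(NAD(P)H+FAD)) is the default and the convention string is stamped
on every result object and output table, so no downstream consumer can
mistake one for the other. Defaults mirror common practice: 3x3 box-sum
prefilter on both channels, 5x5 median postfilter on the ratio image,
intensity threshold applied to the NAD(P)H channel. Division-by-zero
pixels are masked rather than clipped and the masked-pixel count is
reported, so heterogeneity statistics stay honest. Negative mask labels
(nuclei, lipid droplets) are excluded from aggregation by default.

Solution-standard calibration divides each channel by the spatial mean
of its matching 1 mM standard frame. The mean is taken on the raw
standard frame — for a uniform frame the box filter leaves the mean
unchanged, so filtering order is immaterial there. Calibration is
algebraically gain-invariant: scaling a channel and its standard by the
same factor leaves the calibrated ORR unchanged to floating precision,
which is the property the tests verify to 1e-12. Spectral crosstalk
between channels is *not* corrected; a leakage warning can only be
propagated through metadata.

When two acquisition settings are compared in the tests, "overlap after
calibration" is asserted three ways: means within 0.02 (vs a raw gap
above 0.15), and a Kolmogorov–Smirnov distance below 0.25 (vs above 0.5
uncalibrated). The KS bound is looser than the mean bound on purpose: a
detector-gain change also scales photon counts, so two correctly
calibrated acquisitions share a mean but differ in Poisson spread,
which alone produces a KS distance of 0.15–0.2 at these count levels.

## Quality control and the reporting checklists

The four consensus reporting lists (7 essential + 5 best-practice items
for intensity-based redox, 5 + 4 for FLIM) are shipped as a data table
(`inst/extdata/qc_checklist.csv`) with a small predicate vocabulary:
required-fields items, boolean-flag items, and attestation items that
only a human can certify (orthogonal validation experiments, same-day
controls) and that stay "missing" until attested in the configuration.
Every item is always emitted — items outside the analyzed modality are
marked not-applicable rather than dropped — and no status ever defaults
to pass. The pile-up check uses the conservative 5% bound on detected
rate / pulse rate and reports the 10% alternative alongside. SNR is
`sqrt(N)` under Poisson statistics; signal-to-background, where a
background region exists, is mean(signal)/mean(background over label-0
pixels).

## What the synthetic generator emulates — and what it does not

The generator draws independent Poisson counts per bin around the
IRF-convolved, period-wrapped model (equivalent to a multinomial over
bins conditioned on a Poisson total), with Gaussian IRFs of configurable
FWHM, elliptical cytoplasm regions with elliptical nuclear holes, and
uniform solution frames with Poisson noise. Every generator is a pure
function of configuration and seed, and restores the caller's RNG
state.

It does **not** emulate: optical blur, detector afterpulsing or dark
noise correlation, pile-up distortion (the consensus bound is far from
reached at NAD(P)H/FAD count rates; a QC flag covers it), spectral
crosstalk between channels, autofluorescence of other fluorophores, or
realistic cell morphology. Passing tests therefore demonstrate the
correctness of the estimators under the stated noise model — not
robustness to those instrument- and sample-specific effects, which is
exactly why the QC checklist keeps demanding controls and orthogonal
validation on real data.

## Problem sizes and statistical design of the validation suite

The simulation tests are sized to hold Monte-Carlo error well below the
tolerances they assert: 200 replicate decays per condition for
parameter-recovery medians (the hardest corner, the short lifetime at
bound fraction 0.7 and 1e4 photons, has a Cramér–Rao bound of 5.8%
relative standard deviation, so a median-error estimate from fewer
replicates would be dominated by sampling noise against the 5%
criterion), 200 replicates per photon level for precision-scaling
ratios, 40 per budget for monotonicity of RMSE, and scenes of 12x12 to
48x48 pixels for map-level checks. Noiseless round trips (simulate,
then fit or phasor-transform) recover generating parameters to machine
or discretization precision and anchor the tolerances everywhere else.

## Known limitations

Tri-exponential and stretched-exponential models, color-shift IRF
fitting, global multi-pixel fitting, wavelet phasor filtering,
automated phasor clustering, multi-harmonic unmixing of three or more
species, spectral unmixing, and vendor TCSPC formats (SDT, PTU) are out
of scope; pre-converted TIFF/CSV is the ingestion seam. Parameter maps
from the CLI are written as CSV tables rather than float TIFF so that
all outputs remain lossless, text-based formats.
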