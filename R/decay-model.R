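# Core decay model: time grids, biexponential parameters, IRF convolution,
# and the lifetime/fraction conversions shared by simulation, fitting and
# phasor analysis.

#' TCSPC time grid
#'
#' Describes the timing axis of a photon-arrival histogram: the number of
#' time bins, the bin width, and the excitation repetition rate. The laser
#' period is `T = 1/rep_rate`; the acquisition window `n_bins * bin_width`
#' must not exceed the period by more than one bin. Time samples throughout
#' the package are taken at bin centers `t_k = (k + 0.5) * bin_width`.
#'
#' @param n_bins Positive integer number of time bins.
#' @param bin_width Bin width in seconds.
#' @param rep_rate Excitation repetition rate in Hz (e.g. `80e6`).
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(256, 12.5e-9 / 256, 80e6)
#' grid_period(g)
#' @export
time_grid <- function(n_bins, bin_width, rep_rate) {
  stopifnot(length(n_bins) == 1L, length(bin_width) == 1L,
            length(rep_rate) == 1L)
  n_bins <- as.integer(n_bins)
  if (!is.finite(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (!is.finite(rep_rate) || rep_rate <= 0) stop("rep_rate must be > 0")
  period <- 1 / rep_rate
  if (n_bins * bin_width > period + bin_width * (1 + 1e-9)) {
    stop("acquisition window n_bins * bin_width exceeds the laser period ",
         "by more than one bin")
  }
  structure(list(n_bins = n_bins, bin_width = bin_width,
                 rep_rate = rep_rate),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_period <- function(grid) 1 / grid$rep_rate

#' @rdname time_grid
#' @param harmonic Positive integer harmonic of the repetition rate.
#' @export
grid_omega <- function(grid, harmonic = 1L) {
  stopifnot(harmonic >= 1)
  2 * pi * grid$rep_rate * harmonic
}

#' @rdname time_grid
#' @export
bin_centers <- function(grid) {
  (seq_len(grid$n_bins) - 0.5) * grid$bin_width
}

#' Biexponential decay parameters
#'
#' Parameters of the two-component fluorescence decay
#' `I(t) = alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2) + C`
#' used for free (short, `tau1`) and protein-bound (long, `tau2`) NAD(P)H.
#' Amplitudes are stored in photon-count units, not normalized fractions;
#' fractional views are derived (see [intensity_fraction_bound()]).
#' Components are canonically ordered `tau1 <= tau2` on construction:
#' supplying them swapped exchanges the component pairs, which leaves the
#' evaluated decay unchanged.
#'
#' @param tau1,tau2 Component lifetimes in seconds.
#' @param alpha1,alpha2 Nonnegative component amplitudes (counts).
#' @param background Constant offset C in counts/bin (nonnegative).
#' @return Object of class `biexp_params`.
#' @examples
#' p <- biexp_params(0.54e-9, 2.81e-9, 2640, 1180)
#' amplitude_weighted_mean_lifetime(p)  # 1.2412 ns
#' intensity_fraction_bound(p)          # 0.699
#' @export
biexp_params <- function(tau1, tau2, alpha1, alpha2, background = 0) {
  vals <- c(tau1, tau2, alpha1, alpha2, background)
  if (length(vals) != 5L || !all(is.finite(vals))) {
    stop("biexponential parameters must be finite scalars")
  }
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be > 0")
  if (alpha1 < 0 || alpha2 < 0 || background < 0) {
    stop("amplitudes and background must be >= 0")
  }
  if (alpha1 == 0 && alpha2 == 0) stop("at least one amplitude must be > 0")
  if (tau1 > tau2) {   # canonical ordering: short component first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- alpha1; alpha1 <- alpha2; alpha2 <- tmp
  }
  structure(list(tau1 = tau1, tau2 = tau2, alpha1 = alpha1,
                 alpha2 = alpha2, background = background),
            class = "biexp_params")
}

#' Instrument response function curve
#'
#' A nonnegative 1-D histogram of the system's temporal response on a given
#' [time_grid()]. The IRF is renormalized to unit sum before convolution so
#' that model amplitudes keep photon-count units.
#'
#' @param values Nonnegative numeric vector, one entry per time bin.
#' @param grid The associated [time_grid()].
#' @param fwhm Optional full width at half maximum in seconds (metadata).
#' @return Object of class `irf_curve`.
#' @export
irf_curve <- function(values, grid, fwhm = NA_real_) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_bins) {
    stop("IRF length (", length(values), ") does not match grid n_bins (",
         grid$n_bins, ")")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("IRF values must be finite and nonnegative")
  }
  if (sum(values) <= 0) stop("IRF must have positive total")
  structure(list(values = values, grid = grid, fwhm = fwhm),
            class = "irf_curve")
}

#' Evaluate the biexponential decay model
#'
#' Returns `I(t_k)` at bin centers. With `wrapped = TRUE` each component is
#' replaced by its periodic steady state under repetitive excitation,
#' `alpha * exp(-t/tau) / (1 - exp(-T/tau))`, which is what a TCSPC system
#' running at 80 MHz actually observes when the decay does not complete
#' within one laser period. The wrapped component still integrates to
#' `alpha * tau` over one period, so intensity fractions are unaffected.
#'
#' @param params A [biexp_params()].
#' @param grid A [time_grid()].
#' @param wrapped Include incomplete-decay wrap-around from previous pulses.
#' @return Numeric vector of model counts per bin.
#' @export
evaluate_biexp <- function(params, grid, wrapped = FALSE) {
  stopifnot(inherits(params, "biexp_params"), inherits(grid, "time_grid"))
  t <- bin_centers(grid)
  if (wrapped) {
    tp <- grid_period(grid)
    w1 <- 1 - exp(-tp / params$tau1)
    w2 <- 1 - exp(-tp / params$tau2)
  } else {
    w1 <- 1; w2 <- 1
  }
  params$alpha1 * exp(-t / params$tau1) / w1 +
    params$alpha2 * exp(-t / params$tau2) / w2 +
    params$background
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_m = (alpha1 * tau1 + alpha2 * tau2) / (alpha1 + alpha2)`, the
#' standard summary lifetime of a biexponential fit; always lies between
#' `tau1` and `tau2`.
#'
#' @param params A [biexp_params()].
#' @return Mean lifetime in seconds.
#' @export
amplitude_weighted_mean_lifetime <- function(params) {
  stopifnot(inherits(params, "biexp_params"))
  a <- params$alpha1 + params$alpha2
  if (a <= 0) stop("degenerate decay: both amplitudes are zero")
  (params$alpha1 * params$tau1 + params$alpha2 * params$tau2) / a
}

#' Intensity fraction of the long-lifetime (bound) component
#'
#' `f2 = alpha2 * tau2 / (alpha1 * tau1 + alpha2 * tau2)`: the relative
#' fluorescence intensity contribution of the bound component, the quantity
#' phasor analysis estimates. Distinct from the amplitude fraction
#' `alpha2 / (alpha1 + alpha2)`; the two must not be compared directly.
#'
#' @param params A [biexp_params()].
#' @return `f2` in `[0, 1]`; the free-component fraction is `1 - f2`.
#' @export
intensity_fraction_bound <- function(params) {
  stopifnot(inherits(params, "biexp_params"))
  denom <- params$alpha1 * params$tau1 + params$alpha2 * params$tau2
  if (denom <= 0) stop("degenerate decay: zero total intensity")
  params$alpha2 * params$tau2 / denom
}

#' Convolve a model decay with the instrument response
#'
#' Discrete convolution of a decay curve with the unit-sum-normalized IRF.
#' In periodic mode (default) the convolution is circular over the laser
#' period, matching repetitive excitation where both the IRF and the decay
#' wrap around; total counts are conserved exactly. Linear mode performs an
#' ordinary causal convolution truncated to the window, appropriate when the
#' decay fully completes well inside the acquisition window.
#'
#' @param decay Numeric vector of model counts per bin.
#' @param irf An [irf_curve()] on the same grid.
#' @param periodic Use circular convolution over the period (default TRUE).
#' @return Numeric vector of measured-model counts per bin.
#' @export
convolve_with_irf <- function(decay, irf, periodic = TRUE) {
  stopifnot(inherits(irf, "irf_curve"))
  decay <- as.numeric(decay)
  n <- length(decay)
  if (n != irf$grid$n_bins) {
    stop("grid mismatch: decay has ", n, " bins, IRF grid has ",
         irf$grid$n_bins)
  }
  kern <- irf$values / sum(irf$values)
  if (periodic) {
    out <- Re(stats::fft(stats::fft(decay) * stats::fft(kern),
                         inverse = TRUE)) / n
  } else {
    full <- stats::convolve(decay, rev(kern), type = "open")
    out <- full[seq_len(n)]
  }
  # counts can dip epsilon-negative from fft roundoff
  pmax(out, 0)
}
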