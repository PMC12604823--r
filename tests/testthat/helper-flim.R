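# Shared fixtures: a standard 80 MHz / 256-bin TCSPC grid, a 150 ps
# Gaussian IRF, and a noiseless fluorescein-like calibration reference
# (3.05 ns monoexponential).

flim_grid <- function(n_bins = 256L, rep_rate = 80e6) {
  time_grid(n_bins, (1 / rep_rate) / n_bins, rep_rate)
}

flim_irf <- function(grid = flim_grid(), fwhm = 150e-12) {
  make_gaussian_irf(grid, fwhm)
}

# Monoexponential helper (the two-component container with equal lifetimes)
mono_params <- function(tau, amplitude = 1000) {
  biexp_params(tau, tau, amplitude / 2, amplitude / 2)
}

# Biexponential with a prescribed bound intensity fraction f2:
# f2 = a2*tau2 / (a1*tau1 + a2*tau2)  =>  a1 ~ (1-f2)/tau1, a2 ~ f2/tau2.
biexp_from_f2 <- function(f2, tau1 = 0.5e-9, tau2 = 3e-9, scale = 1e-6) {
  biexp_params(tau1, tau2, (1 - f2) / tau1 * scale, f2 / tau2 * scale)
}

# Noiseless measured reference decay for phasor calibration.
fluorescein_reference <- function(grid = flim_grid(),
                                  irf = flim_irf(grid)) {
  simulate_decay(mono_params(3.05e-9), grid, irf, 1e6, poisson = FALSE)
}

# Uniform decay stack: every pixel holds the same histogram.
uniform_stack <- function(decay, grid, dims = c(8L, 8L)) {
  counts <- array(0, c(grid$n_bins, dims[1L], dims[2L]))
  counts[] <- rep(decay, prod(dims))
  decay_stack(counts, grid)
}
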