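# Phasor transform, calibration, lifetimes, bound fractions, cloud fits.

test_that("noiseless monoexponentials land on the closed-form phasor", {
  g <- flim_grid()
  om <- grid_omega(g)
  d <- simulate_decay(mono_params(0.4e-9), g, NULL, 1e6, poisson = FALSE)
  f <- phasor_transform(d, grid = g)
  th <- phasor_of_lifetime(0.4e-9, om)
  expect_equal(c(th$g, th$s), c(0.9611, 0.1933), tolerance = 1e-3)
  expect_lt(abs(f$g[1L] - th$g), 1e-3)
  expect_lt(abs(f$s[1L] - th$s), 1e-3)
})

test_that("limit cases: impulse at (1,0), flat signal at (0,0)", {
  g <- flim_grid()
  impulse <- numeric(g$n_bins); impulse[1L] <- 1000
  fi <- phasor_transform(impulse, grid = g)
  # the impulse sits at the first bin center t = bin_width/2, so its
  # phasor is (cos, sin)(omega * bin_width / 2), within half a bin of
  # the delta-function limit (1, 0)
  expect_equal(c(fi$g[1L], fi$s[1L]),
               c(cos(fi$omega * g$bin_width / 2),
                 sin(fi$omega * g$bin_width / 2)), tolerance = 1e-9)
  expect_lt(abs(fi$g[1L] - 1), 1e-3)
  expect_lt(abs(fi$s[1L]), sin(fi$omega * g$bin_width))
  flat <- rep(50, g$n_bins)
  ff <- phasor_transform(flat, grid = g)
  expect_equal(c(ff$g[1L], ff$s[1L]), c(0, 0), tolerance = 1e-12)
  # zero-count pixels are masked, not NaN
  g8 <- flim_grid(8L)
  st <- decay_stack(array(c(rep(1, 8), rep(0, 8)), c(8L, 2L, 1L)), g8)
  fz <- phasor_transform(st)
  expect_true(is.na(fz$g[2L, 1L]) && !is.nan(fz$g[2L, 1L]))
})

test_that("reference calibration is a round-trip identity and idempotent
          for an ideal reference", {
  g <- flim_grid()
  irf <- flim_irf(g)
  ref <- fluorescein_reference(g, irf)
  f <- calibrate_phasor(phasor_transform(ref, grid = g), ref, 3.05e-9)
  lt <- lifetimes_from_phasor(f$g[1L], f$s[1L], f$omega)
  expect_equal(lt$tau_phase, 3.05e-9, tolerance = 5e-3)
  expect_equal(lt$tau_mod, 3.05e-9, tolerance = 5e-3)
  # ideal (IRF-free) reference: the correction factor is unity up to the
  # time-discretization residual (~2e-5 at 256 bins), so applying the
  # calibration twice equals applying it once to that accuracy
  ideal <- simulate_decay(mono_params(3.05e-9), g, NULL, 1e6,
                          poisson = FALSE)
  f1 <- calibrate_phasor(phasor_transform(ideal, grid = g), ideal,
                         3.05e-9)
  f2 <- calibrate_phasor(f1, ideal, 3.05e-9)
  expect_equal(f2$g, f1$g, tolerance = 1e-4)
  expect_equal(f2$s, f1$s, tolerance = 1e-4)
  expect_error(
    calibrate_phasor(phasor_transform(ref, grid = g), rep(1, g$n_bins),
                     3.05e-9),
    "modulation")
})

test_that("calibrated monoexponentials satisfy the universal circle", {
  g <- flim_grid()
  irf <- flim_irf(g)
  ref <- fluorescein_reference(g, irf)
  for (tau in c(0.5e-9, 1e-9, 2e-9, 4e-9)) {
    d <- simulate_decay(mono_params(tau), g, irf, 1e6, poisson = FALSE)
    f <- calibrate_phasor(phasor_transform(d, grid = g), ref, 3.05e-9)
    expect_lt(abs(f$s[1L]^2 - f$g[1L] * (1 - f$g[1L])), 1e-3)
  }
})

test_that("phase/modulation lifetimes invert the closed forms and order
          correctly for mixtures", {
  g <- flim_grid()
  om <- grid_omega(g)
  th <- phasor_of_lifetime(0.4e-9, om)
  lt <- lifetimes_from_phasor(th$g, th$s, om)
  expect_equal(lt$tau_phase, 0.4e-9, tolerance = 1e-6)
  expect_equal(lt$tau_mod, 0.4e-9, tolerance = 1e-6)
  # 50/50 intensity mixture of 0.4 and 2.81 ns species
  p1 <- phasor_of_lifetime(0.4e-9, om)
  p2 <- phasor_of_lifetime(2.81e-9, om)
  gm <- (p1$g + p2$g) / 2; sm <- (p1$s + p2$s) / 2
  expect_equal(c(gm, sm), c(0.6475, 0.3324), tolerance = 1e-3)
  ltm <- lifetimes_from_phasor(gm, sm, om)
  expect_equal(ltm$tau_phase, 1.021e-9, tolerance = 1e-3)
  expect_equal(ltm$tau_mod, 1.874e-9, tolerance = 1e-3)
  expect_lt(ltm$tau_phase, ltm$tau_mod)
  # degenerate point and out-of-domain flagging
  lt0 <- lifetimes_from_phasor(1, 0, om)
  expect_equal(c(lt0$tau_phase, lt0$tau_mod), c(0, 0))
  expect_true(lifetimes_from_phasor(-0.1, 0.2, om)$out_of_domain)
})

test_that("tau_phase < tau_mod strictly for genuinely biexponential
          decays, equality for monoexponentials", {
  g <- flim_grid()
  om <- grid_omega(g)
  for (f2 in seq(0.1, 0.9, by = 0.2)) {
    d <- simulate_decay(biexp_from_f2(f2, 0.4e-9, 2.81e-9), g, NULL,
                        1e6, poisson = FALSE)
    f <- phasor_transform(d, grid = g)
    lt <- lifetimes_from_phasor(f$g[1L], f$s[1L], om)
    expect_lt(lt$tau_phase, lt$tau_mod)
  }
  d <- simulate_decay(mono_params(1.5e-9), g, NULL, 1e6, poisson = FALSE)
  f <- phasor_transform(d, grid = g)
  lt <- lifetimes_from_phasor(f$g[1L], f$s[1L], om)
  expect_equal(lt$tau_phase, lt$tau_mod, tolerance = 1e-3)
})

test_that("phasor mixing is linear in intensity fractions (K = 2 and 3)", {
  g <- flim_grid()
  om <- grid_omega(g)
  taus <- c(0.4e-9, 1.5e-9, 3.05e-9)
  pts <- phasor_of_lifetime(taus, om)
  mix <- function(fracs) {
    d <- 0
    for (k in seq_along(taus)) {
      # unit total intensity per component requires amplitude 1/tau
      d <- d + fracs[k] / taus[k] *
        evaluate_biexp(mono_params(taus[k]), g, wrapped = TRUE) / 1000
    }
    f <- phasor_transform(d, grid = g)
    c(f$g[1L], f$s[1L])
  }
  for (fr in list(c(0.3, 0.7, 0), c(0.2, 0.3, 0.5), c(0.6, 0, 0.4))) {
    expect_equal(mix(fr),
                 c(sum(fr * pts$g), sum(fr * pts$s)), tolerance = 1e-3)
  }
})

test_that("phasors are harmonic-consistent (n = 1, 2, 3)", {
  g <- flim_grid()
  tau <- 1.8e-9
  d <- simulate_decay(mono_params(tau), g, NULL, 1e6, poisson = FALSE)
  for (n in 1:3) {
    f <- phasor_transform(d, harmonic = n, grid = g)
    th <- phasor_of_lifetime(tau, grid_omega(g, n))
    expect_equal(c(f$g[1L], f$s[1L]), c(th$g, th$s), tolerance = 2e-3)
  }
})

test_that("distance from the free phasor position follows the closed
          forms", {
  g <- flim_grid()
  irf <- flim_irf(g)
  om <- grid_omega(g)
  ref <- fluorescein_reference(g, irf)
  field_of <- function(params) {
    d <- simulate_decay(params, g, irf, 1e6, poisson = FALSE)
    calibrate_phasor(phasor_transform(d, grid = g), ref, 3.05e-9)
  }
  # pure free species sits at distance ~0
  d_free <- bound_fraction_distance(field_of(mono_params(0.4e-9)))
  expect_lt(d_free[1L], 2e-3)
  # pure bound species at 2.81 ns: d = 0.686
  d_bound <- bound_fraction_distance(field_of(mono_params(2.81e-9)))
  expect_equal(d_bound[1L], 0.686, tolerance = 2e-3)
  # equal-intensity mixture lands halfway along the segment
  d_mix <- bound_fraction_distance(field_of(
    biexp_from_f2(0.5, 0.4e-9, 2.81e-9)))
  expect_equal(d_mix[1L], 0.686 / 2, tolerance = 2e-3)
  # distances are refused before calibration
  raw <- phasor_transform(simulate_decay(mono_params(1e-9), g, NULL,
                                         1e3, poisson = FALSE), grid = g)
  expect_error(bound_fraction_distance(raw), "calibrat")
})

test_that("normalized bound fraction interpolates the endpoint segment
          and matches the generating intensity fraction", {
  g <- flim_grid()
  irf <- flim_irf(g)
  om <- grid_omega(g)
  ref <- fluorescein_reference(g, irf)
  ep <- endpoints_from_lifetimes(0.4e-9, 2.81e-9, om)
  field_of <- function(params) {
    d <- simulate_decay(params, g, irf, 1e6, poisson = FALSE)
    calibrate_phasor(phasor_transform(d, grid = g), ref, 3.05e-9)
  }
  expect_equal(
    bound_fraction_normalized(field_of(mono_params(0.4e-9)), ep)[1L],
    0, tolerance = 3e-3)
  expect_equal(
    bound_fraction_normalized(field_of(mono_params(2.81e-9)), ep)[1L],
    1, tolerance = 3e-3)
  p <- biexp_from_f2(0.6, 0.4e-9, 2.81e-9)
  expect_equal(bound_fraction_normalized(field_of(p), ep)[1L],
               intensity_fraction_bound(p), tolerance = 1e-3)
  expect_error(phasor_endpoints(c(0.5, 0.3), c(0.5, 0.3)), "coincide")
  expect_error(phasor_endpoints(c(0.5, 0.9), c(0.3, 0.4)),
               "semicircle")
})

test_that("phasor-cloud line fitting recovers analytic endpoints and
          rejects degenerate clouds", {
  g <- flim_grid()
  om <- grid_omega(g)
  # noiseless collinear cloud from three mixtures
  curves <- lapply(c(0.2, 0.5, 0.8), function(f2) {
    simulate_decay(biexp_from_f2(f2, 0.4e-9, 2.81e-9), g, NULL, 1e6,
                   poisson = FALSE)
  })
  counts <- array(0, c(g$n_bins, 4L, 3L))
  for (j in 1:3) for (i in 1:4) counts[, i, j] <- round(curves[[j]])
  field <- phasor_transform(decay_stack(counts, g))
  field$calibrated <- TRUE   # ideal, IRF-free synthesis needs no reference
  ep <- fit_phasor_line(field)
  th1 <- phasor_of_lifetime(0.4e-9, om)
  th2 <- phasor_of_lifetime(2.81e-9, om)
  expect_equal(ep$free, c(th1$g, th1$s), tolerance = 5e-3)
  expect_equal(ep$bound, c(th2$g, th2$s), tolerance = 5e-3)
  expect_equal(ep$provenance, "cloud-fit")
  # single-lifetime cloud: no spread, degenerate
  mono <- round(simulate_decay(mono_params(1e-9), g, NULL, 1e6,
                               poisson = FALSE))
  counts1 <- array(rep(mono, 12L), c(g$n_bins, 4L, 3L))
  expect_error(fit_phasor_line(phasor_transform(decay_stack(counts1, g))),
               "degenerate")
})

test_that("noisy two-component clouds yield endpoint lifetimes within
          10%", {
  g <- flim_grid()
  irf <- flim_irf(g)
  om <- grid_omega(g)
  mk <- function(f2) biexp_from_f2(f2, 0.4e-9, 2.81e-9)
  labels <- matrix(rep(1:5, each = 60L), 15L, 20L)
  prm <- stats::setNames(lapply(seq(0.25, 0.75, length.out = 5), mk),
                         1:5)
  scene <- cell_scene(labels, prm, photons = 3e4)
  st <- simulate_tcspc_image(scene, g, irf, seed = 17)
  ref <- fluorescein_reference(g, irf)
  f <- calibrate_phasor(phasor_transform(st), ref, 3.05e-9)
  ep <- fit_phasor_line(f)
  lt_free <- lifetimes_from_phasor(ep$free[1L], ep$free[2L], om)
  lt_bound <- lifetimes_from_phasor(ep$bound[1L], ep$bound[2L], om)
  expect_equal(lt_free$tau_phase, 0.4e-9, tolerance = 0.10)
  expect_equal(lt_bound$tau_phase, 2.81e-9, tolerance = 0.10)
})

test_that("median filtering denoises g without shifting its mean", {
  g <- flim_grid()
  irf <- flim_irf(g)
  p <- biexp_from_f2(0.5, 0.4e-9, 2.81e-9)
  scene <- cell_scene(matrix(1L, 14L, 14L), list("1" = p),
                      photons = 2000)
  st <- simulate_tcspc_image(scene, g, irf, seed = 23)
  f <- phasor_transform(st)
  fm <- median_filter_phasor(f, 3L)
  expect_lt(stats::sd(fm$g), stats::sd(f$g))
  expect_lt(abs(mean(fm$g) - mean(f$g)) / abs(mean(f$g)), 0.005)
  expect_identical(fm$intensity, f$intensity)
  # constant field unchanged; single outlier removed
  fc <- f
  fc$g <- matrix(0.5, 5L, 5L); fc$s <- matrix(0.3, 5L, 5L)
  fc$g[3L, 3L] <- 0.9
  out <- median_filter_phasor(fc, 5L)
  expect_equal(out$g[3L, 3L], 0.5)
  expect_true(all(out$s == 0.3))
  expect_error(median_filter_phasor(f, 4L), "odd")
})
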