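# Synthetic data generation: Gaussian IRFs, Poisson TCSPC decays, cell-like
# scenes, intensity channel pairs and uniform solution-standard frames.
# Every generator is a pure function of (configuration, seed).

#' Gaussian instrument response function
#'
#' Builds a unit-sum Gaussian IRF histogram on a time grid, wrapped
#' periodically over the acquisition window so mass near the window edges is
#' not lost. `sigma = fwhm / (2 * sqrt(2 * log(2)))`. If `fwhm` is narrower
#' than half a bin the Gaussian cannot be resolved; a warning is issued and
#' an impulse at the nearest bin is returned.
#'
#' @param grid A [time_grid()].
#' @param fwhm Full width at half maximum in seconds.
#' @param center Peak position in seconds (default 1/25 of the window).
#' @return An [irf_curve()].
#' @export
make_gaussian_irf <- function(grid, fwhm, center = NULL) {
  stopifnot(inherits(grid, "time_grid"), fwhm > 0)
  window <- grid$n_bins * grid$bin_width
  center <- center %||% (window / 25)
  if (center < 0 || center > window) {
    stop("IRF center must lie within the acquisition window")
  }
  t <- bin_centers(grid)
  if (fwhm < grid$bin_width / 2) {
    warning("IRF FWHM below half a bin width; returning an impulse")
    values <- numeric(grid$n_bins)
    values[which.min(abs(t - center))] <- 1
    return(irf_curve(values, grid, fwhm = fwhm))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  values <- stats::dnorm(t, center, sigma) +
    stats::dnorm(t - window, center, sigma) +
    stats::dnorm(t + window, center, sigma)
  irf_curve(values / sum(values), grid, fwhm = fwhm)
}

#' Measure the FWHM of an IRF histogram
#'
#' Linear interpolation of the half-maximum crossings.
#' @param irf An [irf_curve()].
#' @return FWHM in seconds.
#' @export
irf_fwhm_measured <- function(irf) {
  stopifnot(inherits(irf, "irf_curve"))
  v <- irf$values
  t <- bin_centers(irf$grid)
  half <- max(v) / 2
  above <- which(v >= half)
  if (length(above) < 1L) return(NA_real_)
  lo <- min(above); hi <- max(above)
  left <- if (lo > 1L) {
    t[lo - 1L] + (half - v[lo - 1L]) / (v[lo] - v[lo - 1L]) *
      (t[lo] - t[lo - 1L])
  } else t[lo] - irf$grid$bin_width / 2
  right <- if (hi < length(v)) {
    t[hi] + (v[hi] - half) / (v[hi] - v[hi + 1L]) * (t[hi + 1L] - t[hi])
  } else t[hi] + irf$grid$bin_width / 2
  right - left
}

#' Expected (noise-free) measured decay curve
#'
#' The periodically wrapped biexponential model convolved with the IRF and
#' scaled to a total of `n_photons` expected counts. This is the mean of the
#' Poisson law that [simulate_decay()] samples from.
#'
#' @param params A [biexp_params()].
#' @param grid A [time_grid()].
#' @param irf Optional [irf_curve()]; omit for an ideal (delta) response.
#' @param n_photons Expected total photon count.
#' @return Numeric vector of expected counts per bin.
#' @export
expected_decay <- function(params, grid, irf = NULL, n_photons) {
  stopifnot(n_photons >= 0)
  shape <- evaluate_biexp(params, grid, wrapped = TRUE)
  if (!is.null(irf)) shape <- convolve_with_irf(shape, irf, periodic = TRUE)
  s <- sum(shape)
  if (s <= 0) stop("degenerate decay shape")
  shape * (n_photons / s)
}

#' Simulate a TCSPC photon-arrival histogram
#'
#' Draws independent Poisson counts per bin whose mean is the IRF-convolved,
#' period-wrapped biexponential shape scaled to `n_photons` expected total
#' counts (equivalent to a multinomial over bins conditioned on a Poisson
#' total). Reproducible for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @inheritParams expected_decay
#' @param seed Integer seed, or NULL to use (and advance) the current RNG.
#' @param poisson Set FALSE to return the noise-free expectation.
#' @return Integer-valued numeric vector of counts per bin.
#' @export
simulate_decay <- function(params, grid, irf = NULL, n_photons,
                           seed = NULL, poisson = TRUE) {
  lambda <- expected_decay(params, grid, irf, n_photons)
  if (!poisson) return(lambda)
  if (n_photons == 0) return(numeric(grid$n_bins))
  with_seed(seed, stats::rpois(grid$n_bins, lambda))
}

#' Cell-like scene with per-region ground truth
#'
#' A labelled 2-D scene: 0 is background, positive labels are cell
#' cytoplasm regions, and negative labels mark excluded organelle regions
#' (nuclei, lipid droplets) that carry no NAD(P)H ground truth. Each
#' positive region has biexponential decay parameters, a per-pixel photon
#' budget, and per-channel intensity levels (arbitrary concentration
#' proxies) used by [simulate_channel_pair()].
#'
#' @param label_mask Integer matrix of region labels.
#' @param params Named list mapping positive label -> [biexp_params()].
#' @param photons Per-pixel photon budget: scalar or named by label.
#' @param intensity_nadph,intensity_fad Per-region mean channel intensities
#'   (counts at unit gain): scalar or named by label.
#' @param background_rate Dark counts per pixel (total over the window).
#' @return Object of class `cell_scene`.
#' @export
cell_scene <- function(label_mask, params, photons,
                       intensity_nadph = photons,
                       intensity_fad = photons,
                       background_rate = 0) {
  stopifnot(is.matrix(label_mask))
  label_mask <- matrix(as.integer(label_mask), nrow(label_mask))
  if (any(!is.finite(label_mask))) stop("labels must be finite integers")
  pos <- sort(unique(label_mask[label_mask > 0L]))
  per_region <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      stats::setNames(rep(as.numeric(x), length(pos)), as.character(pos))
    } else {
      miss <- setdiff(as.character(pos), names(x))
      if (length(miss)) {
        stop("missing ", what, " for region(s): ",
             paste(miss, collapse = ", "))
      }
      x_num <- as.numeric(x[as.character(pos)])
      stats::setNames(x_num, as.character(pos))
    }
  }
  miss <- setdiff(as.character(pos), names(params))
  if (length(miss)) {
    stop("missing decay parameters for region(s): ",
         paste(miss, collapse = ", "))
  }
  for (p in params) stopifnot(inherits(p, "biexp_params"))
  photons <- per_region(photons, "photon budget")
  if (any(photons < 0)) stop("photon budgets must be >= 0")
  structure(list(label_mask = label_mask,
                 params = params[as.character(pos)],
                 photons = photons,
                 intensity_nadph = per_region(intensity_nadph,
                                              "NAD(P)H intensity"),
                 intensity_fad = per_region(intensity_fad, "FAD intensity"),
                 background_rate = background_rate),
            class = "cell_scene")
}

#' Randomly generated elliptical-cell scene
#'
#' Places `n_cells` elliptical cytoplasm regions (labels 1..n) with
#' elliptical nuclear holes (labels -1..-n) on a background of zeros.
#' Morphological realism is not the goal; the mask topology exercises
#' segmentation-aware statistics downstream.
#'
#' @param dim Scene size `c(height, width)`.
#' @param n_cells Number of cells.
#' @param params Named list of [biexp_params()] per cell label, or a single
#'   `biexp_params` recycled to all cells.
#' @param photons Per-pixel photon budget (scalar or named by label).
#' @param seed Integer seed for cell placement.
#' @inheritParams cell_scene
#' @return A [cell_scene()].
#' @export
make_cell_scene <- function(dim = c(48L, 48L), n_cells = 3L, params,
                            photons = 1000, intensity_nadph = photons,
                            intensity_fad = photons,
                            background_rate = 0, seed = NULL) {
  if (inherits(params, "biexp_params")) {
    params <- stats::setNames(rep(list(params), n_cells),
                              as.character(seq_len(n_cells)))
  }
  h <- dim[1L]; w <- dim[2L]
  label <- matrix(0L, h, w)
  yy <- row(label); xx <- col(label)
  with_seed(seed, {
    for (k in seq_len(n_cells)) {
      cy <- stats::runif(1, 0.2, 0.8) * h
      cx <- stats::runif(1, 0.2, 0.8) * w
      ry <- stats::runif(1, 0.10, 0.18) * h
      rx <- stats::runif(1, 0.10, 0.18) * w
      inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
      label[inside & label == 0L] <- k
      nucleus <- ((yy - cy) / (0.45 * ry))^2 +
        ((xx - cx) / (0.45 * rx))^2 <= 1
      label[nucleus & label == k] <- -k
    }
  })
  cell_scene(label, params, photons, intensity_nadph, intensity_fad,
             background_rate)
}

#' Simulate a TCSPC decay stack for a scene
#'
#' Per-pixel Poisson photon histograms following each region's ground-truth
#' decay; background and excluded (nonpositive-label) pixels receive only
#' uniform-in-time dark counts at the scene's background rate.
#'
#' @param scene A [cell_scene()].
#' @param grid A [time_grid()].
#' @param irf Optional [irf_curve()].
#' @param seed Integer seed.
#' @return A [decay_stack()] with dimensions (time, y, x).
#' @export
simulate_tcspc_image <- function(scene, grid, irf = NULL, seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"), inherits(grid, "time_grid"))
  h <- nrow(scene$label_mask); w <- ncol(scene$label_mask)
  counts <- array(0, dim = c(grid$n_bins, h, w))
  with_seed(seed, {
    for (lab in names(scene$params)) {
      idx <- which(scene$label_mask == as.integer(lab))
      if (!length(idx)) next
      lambda <- expected_decay(scene$params[[lab]], grid, irf,
                               scene$photons[[lab]])
      draws <- stats::rpois(length(idx) * grid$n_bins, rep(lambda,
                                                           length(idx)))
      m <- matrix(counts, grid$n_bins)
      m[, idx] <- matrix(draws, grid$n_bins)
      counts <- array(m, dim = c(grid$n_bins, h, w))
    }
    if (scene$background_rate > 0) {
      idx <- which(scene$label_mask <= 0L)
      if (length(idx)) {
        lam <- scene$background_rate / grid$n_bins
        m <- matrix(counts, grid$n_bins)
        m[, idx] <- m[, idx] +
          matrix(stats::rpois(length(idx) * grid$n_bins, lam), grid$n_bins)
        counts <- array(m, dim = c(grid$n_bins, h, w))
      }
    }
  })
  decay_stack(counts, grid)
}

#' Uniform solution-standard frame
#'
#' A spatially uniform intensity image of a calibration solution (e.g. 1 mM
#' NADH or FAD) with Poisson counting noise, plus acquisition metadata.
#'
#' @param channel `"nadph"` or `"fad"`.
#' @param mean_intensity Expected counts per pixel.
#' @param dim Frame size `c(height, width)`.
#' @param concentration Solution concentration in mol/L (metadata).
#' @param metadata Named list of acquisition metadata.
#' @param seed Integer seed; NULL for a noise-free frame.
#' @return Object of class `solution_frame`.
#' @export
solution_frame <- function(channel = c("nadph", "fad"), mean_intensity,
                           dim = c(32L, 32L), concentration = 1e-3,
                           metadata = list(), seed = NULL) {
  channel <- match.arg(channel)
  stopifnot(mean_intensity >= 0)
  img <- if (is.null(seed)) {
    matrix(mean_intensity, dim[1L], dim[2L])
  } else {
    with_seed(seed,
              matrix(stats::rpois(prod(dim), mean_intensity),
                     dim[1L], dim[2L]))
  }
  structure(list(channel = channel, concentration = concentration,
                 intensity_image = img, metadata = metadata),
            class = "solution_frame")
}

#' Simulate an NAD(P)H / FAD intensity channel pair with matched standards
#'
#' Region mean intensities are the scene's per-channel ground-truth levels
#' times the per-channel detection gain; Poisson noise is added per pixel.
#' Solution-standard frames for both channels are generated with the same
#' gains, so solution-standard calibration removes the gains exactly in
#' expectation.
#'
#' @param scene A [cell_scene()].
#' @param gains Named numeric `c(nadph = , fad = )` channel gain multipliers.
#' @param solution_mean Expected standard-frame counts per pixel at unit
#'   gain, named per channel.
#' @param metadata Acquisition metadata recorded on both channels.
#' @param seed Integer seed.
#' @return List with elements `pair` (a [channel_pair()]) and
#'   `nadh_standard`, `fad_standard` ([solution_frame()]s).
#' @export
simulate_channel_pair <- function(scene, gains = c(nadph = 1, fad = 1),
                                  solution_mean = c(nadph = 500, fad = 500),
                                  metadata = list(), seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"), all(gains > 0))
  h <- nrow(scene$label_mask); w <- ncol(scene$label_mask)
  mean_im <- function(levels, gain) {
    img <- matrix(scene$background_rate * gain, h, w)
    for (lab in names(levels)) {
      img[scene$label_mask == as.integer(lab)] <- levels[[lab]] * gain
    }
    img
  }
  mu_n <- mean_im(scene$intensity_nadph, gains[["nadph"]])
  mu_f <- mean_im(scene$intensity_fad, gains[["fad"]])
  out <- with_seed(seed, {
    nad <- matrix(stats::rpois(h * w, mu_n), h, w)
    fad <- matrix(stats::rpois(h * w, mu_f), h, w)
    s_n <- solution_frame("nadph",
                          solution_mean[["nadph"]] * gains[["nadph"]],
                          dim = c(h, w), metadata = metadata,
                          seed = stats::runif(1, 1, 2^30))
    s_f <- solution_frame("fad", solution_mean[["fad"]] * gains[["fad"]],
                          dim = c(h, w), metadata = metadata,
                          seed = stats::runif(1, 1, 2^30))
    list(nad = nad, fad = fad, s_n = s_n, s_f = s_f)
  })
  pair <- channel_pair(out$nad, out$fad,
                       metadata = list(nadph = metadata, fad = metadata),
                       mask = scene$label_mask)
  list(pair = pair, nadh_standard = out$s_n, fad_standard = out$s_f)
}
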