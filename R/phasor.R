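# Fit-free phasor analysis: transform, reference calibration, phase and
# modulation lifetimes, bound-fraction estimation, cloud line fitting and
# median filtering.

#' Closed-form phasor of a monoexponential decay
#'
#' `g = 1 / (1 + (w*tau)^2)`, `s = w*tau / (1 + (w*tau)^2)`: the point on
#' the universal circle `s^2 = g * (1 - g)` where a single-lifetime decay
#' lands.
#'
#' @param tau Lifetime in seconds (vectorized).
#' @param omega Angular frequency in rad/s (`2 * pi * rep_rate * harmonic`).
#' @return List with numeric `g` and `s`.
#' @export
phasor_of_lifetime <- function(tau, omega) {
  wt <- omega * tau
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phasor transform of a decay stack
#'
#' Per-pixel normalized cosine/sine Fourier coefficients at the chosen
#' harmonic of the repetition rate, computed as Riemann sums at bin centers
#' over the acquired window:
#' `g = sum(I * cos(w t)) / sum(I)`, `s = sum(I * sin(w t)) / sum(I)`.
#' A constant per-bin background can be subtracted before the transform
#' (background light otherwise drags phasors toward the origin). Zero-count
#' pixels are masked (NA), never NaN-propagated.
#'
#' @param stack A [decay_stack()], or a numeric decay vector with `grid`.
#' @param harmonic Positive integer harmonic (default 1).
#' @param grid Required when `stack` is a plain vector.
#' @param background Constant counts/bin (scalar or per-pixel matrix)
#'   subtracted before the transform.
#' @return Object of class `phasor_field` with matrices `g`, `s`,
#'   `intensity`, plus `harmonic`, `omega`, `grid` and a `calibrated` flag.
#' @export
phasor_transform <- function(stack, harmonic = 1L, grid = NULL,
                             background = 0) {
  if (is.numeric(stack) && is.null(dim(stack))) {
    stopifnot(inherits(grid, "time_grid"))
    if (length(stack) != grid$n_bins) {
      stop("decay length does not match grid n_bins")
    }
    m <- matrix(as.numeric(stack), ncol = 1L)
    d <- c(grid$n_bins, 1L, 1L)
  } else {
    stopifnot(inherits(stack, "decay_stack"))
    grid <- stack$grid
    d <- dim(stack$counts)
    m <- matrix(stack$counts, d[1L])
  }
  stopifnot(harmonic >= 1L)
  omega <- grid_omega(grid, harmonic)
  t <- bin_centers(grid)
  if (!identical(background, 0)) {
    m <- if (is.matrix(background)) {
      sweep(m, 2L, as.vector(background), `-`)
    } else m - background
    m <- pmax(m, 0)
  }
  tot <- colSums(m)
  gv <- as.vector(crossprod(m, cos(omega * t)))
  sv <- as.vector(crossprod(m, sin(omega * t)))
  ok <- tot > 0
  g <- s <- rep(NA_real_, length(tot))
  g[ok] <- gv[ok] / tot[ok]
  s[ok] <- sv[ok] / tot[ok]
  structure(list(g = matrix(g, d[2L], d[3L]),
                 s = matrix(s, d[2L], d[3L]),
                 intensity = matrix(tot, d[2L], d[3L]),
                 harmonic = as.integer(harmonic), omega = omega,
                 grid = grid, calibrated = FALSE),
            class = "phasor_field")
}

#' Calibrate a phasor field with a reference standard
#'
#' Computes the phasor of a measured reference decay (a dye of known
#' monoexponential lifetime, e.g. fluorescein at 3.05 ns, or the IRF with
#' lifetime 0) and applies to every pixel the single global complex factor
#' (phase rotation + modulation scaling) that maps the measured reference
#' phasor onto its theoretical position. This removes the instrument phase
#' and modulation response; after calibration monoexponential pixels lie on
#' the universal circle.
#'
#' @param field An uncalibrated [phasor_transform()] output.
#' @param reference A numeric reference decay, or a [decay_stack()] whose
#'   pixels are summed.
#' @param reference_lifetime Known reference lifetime in seconds.
#' @return The field with rotated/scaled `g`, `s` and `calibrated = TRUE`.
#' @export
calibrate_phasor <- function(field, reference, reference_lifetime) {
  stopifnot(inherits(field, "phasor_field"), reference_lifetime >= 0)
  if (inherits(reference, "decay_stack")) {
    d <- dim(reference$counts)
    reference <- rowSums(matrix(reference$counts, d[1L]))
  }
  ref_field <- phasor_transform(as.numeric(reference),
                                harmonic = field$harmonic,
                                grid = field$grid)
  meas <- complex(real = ref_field$g[1L], imaginary = ref_field$s[1L])
  if (!is.finite(Mod(meas)) || Mod(meas) < 1e-9) {
    stop("calibration failure: reference has near-zero modulation")
  }
  th <- phasor_of_lifetime(reference_lifetime, field$omega)
  fac <- complex(real = th$g, imaginary = th$s) / meas
  z <- complex(real = field$g, imaginary = field$s) * fac
  field$g <- matrix(Re(z), nrow(field$g))
  field$s <- matrix(Im(z), nrow(field$s))
  field$calibrated <- TRUE
  field$calibration <- list(reference_lifetime = reference_lifetime,
                            factor = fac)
  field
}

#' Phase and modulation lifetimes from phasor coordinates
#'
#' `tau_phase = (1/w) * s/g` and
#' `tau_mod = (1/w) * sqrt(1/(g^2 + s^2) - 1)`. The two agree exactly on
#' the universal circle (monoexponential decays) and diverge
#' (`tau_phase < tau_mod`) for multiexponential mixtures. Points with
#' `g <= 0` or modulation beyond 1 are flagged out-of-domain and yield NA.
#'
#' @param g,s Numeric (vectorized) phasor coordinates.
#' @param omega Angular frequency in rad/s.
#' @param tol Tolerance on the modulation bound.
#' @return List with `tau_phase`, `tau_mod` (seconds) and logical
#'   `out_of_domain`.
#' @export
lifetimes_from_phasor <- function(g, s, omega, tol = 1e-9) {
  mod2 <- g^2 + s^2
  bad <- !is.finite(g) | !is.finite(s) | g <= 0 | mod2 > 1 + tol |
    mod2 <= 0
  tau_phase <- ifelse(bad, NA_real_, s / g / omega)
  tau_mod <- ifelse(bad, NA_real_,
                    sqrt(pmax(1 / pmin(mod2, 1) - 1, 0)) / omega)
  list(tau_phase = tau_phase, tau_mod = tau_mod, out_of_domain = bad)
}

#' Free/bound endpoint pair on the phasor plot
#'
#' The phasor positions of the pure free and bound species. Both points
#' must lie on or inside the universal semicircle and must differ.
#'
#' @param free_point,bound_point Numeric `c(g, s)` pairs.
#' @param provenance `"assigned-lifetime"` or `"cloud-fit"`.
#' @return Object of class `phasor_endpoints`.
#' @export
phasor_endpoints <- function(free_point, bound_point,
                             provenance = c("assigned-lifetime",
                                            "cloud-fit")) {
  provenance <- match.arg(provenance)
  check_pt <- function(p, nm) {
    if (length(p) != 2L || !all(is.finite(p))) {
      stop(nm, " must be a finite (g, s) pair")
    }
    if (p[1L] < -1e-6 || p[1L] > 1 + 1e-6 || p[2L] < -1e-6 ||
        p[2L]^2 > p[1L] * (1 - p[1L]) + 1e-3) {
      stop(nm, " lies outside the universal semicircle region")
    }
  }
  check_pt(free_point, "free_point")
  check_pt(bound_point, "bound_point")
  if (sqrt(sum((free_point - bound_point)^2)) < 1e-9) {
    stop("free and bound endpoints coincide")
  }
  structure(list(free = as.numeric(free_point),
                 bound = as.numeric(bound_point),
                 provenance = provenance),
            class = "phasor_endpoints")
}

#' Endpoints from assigned pure-species lifetimes
#' @param tau_free,tau_bound Lifetimes in seconds (free NAD(P)H is
#'   conventionally assigned 0.4 ns).
#' @param omega Angular frequency in rad/s.
#' @return A [phasor_endpoints()] with provenance `"assigned-lifetime"`.
#' @export
endpoints_from_lifetimes <- function(tau_free, tau_bound, omega) {
  pf <- phasor_of_lifetime(tau_free, omega)
  pb <- phasor_of_lifetime(tau_bound, omega)
  phasor_endpoints(c(pf$g, pf$s), c(pb$g, pb$s), "assigned-lifetime")
}

#' Distance from the free-NAD(P)H phasor position
#'
#' `d = sqrt((g - g1)^2 + (s - s1)^2)` per pixel, with the free point
#' defaulting to the 0.4 ns monoexponential phasor at the field's
#' frequency. Reported as a distance, not a fraction: converting to a
#' normalized bound fraction requires both endpoints
#' (see [bound_fraction_normalized()]). Refuses uncalibrated fields, where
#' distances are meaningless.
#'
#' @param field A calibrated `phasor_field`.
#' @param free_point Optional `c(g, s)`; overrides `free_tau`.
#' @param free_tau Assigned free-species lifetime in seconds.
#' @return Matrix of distances (NA outside the intensity mask), with the
#'   free point used stored in attribute `free_point`.
#' @export
bound_fraction_distance <- function(field, free_point = NULL,
                                    free_tau = 0.4e-9) {
  stopifnot(inherits(field, "phasor_field"))
  if (!isTRUE(field$calibrated)) {
    stop("field is not calibrated; distances on the phasor plot are ",
         "meaningless before reference calibration")
  }
  if (is.null(free_point)) {
    pf <- phasor_of_lifetime(free_tau, field$omega)
    free_point <- c(pf$g, pf$s)
  }
  d <- sqrt((field$g - free_point[1L])^2 + (field$s - free_point[2L])^2)
  attr(d, "free_point") <- free_point
  d
}

#' Normalized bound fraction from two-endpoint phasor analysis
#'
#' `f2 = dist(p, free) / dist(bound, free)`: the position of each pixel
#' along the segment joining the free and bound endpoints, equal to the
#' relative fluorescence intensity contribution of the bound species
#' (`f2 = alpha2*tau2 / (alpha1*tau1 + alpha2*tau2)`) by phasor linearity.
#' Values are clipped to `[0, 1]`; the count of out-of-segment pixels
#' before clipping is reported in attribute `n_out_of_segment`.
#'
#' @param field A calibrated `phasor_field`.
#' @param endpoints A [phasor_endpoints()].
#' @return Matrix of `f2` in `[0, 1]`.
#' @export
bound_fraction_normalized <- function(field, endpoints) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(endpoints, "phasor_endpoints"))
  if (!isTRUE(field$calibrated)) {
    stop("field is not calibrated; calibrate before estimating fractions")
  }
  span <- sqrt(sum((endpoints$bound - endpoints$free)^2))
  d <- sqrt((field$g - endpoints$free[1L])^2 +
              (field$s - endpoints$free[2L])^2)
  f2 <- d / span
  n_out <- sum(f2 > 1, na.rm = TRUE)
  f2 <- pmin(pmax(f2, 0), 1)
  attr(f2, "n_out_of_segment") <- n_out
  attr(f2, "endpoints") <- endpoints
  f2
}

#' Extract endpoints from a linear fit of the phasor cloud
#'
#' Total-least-squares line through the (g, s) cloud (optionally
#' intensity-weighted), intersected with the universal circle
#' `s^2 = g * (1 - g)`. The intersection at larger `g` (shorter lifetime)
#' is the free endpoint. Errors: fewer than `min_pixels` usable pixels, a
#' degenerate (near-isotropic or collapsed) cloud, or a line missing the
#' circle.
#'
#' @param field A `phasor_field`.
#' @param mask Optional logical matrix restricting the cloud.
#' @param weighted Intensity-weight the fit (default TRUE).
#' @param min_pixels Minimum usable pixels.
#' @param min_var Floor on the leading eigenvalue of the cloud covariance.
#' @param max_isotropy Maximum minor/major eigenvalue ratio before the
#'   cloud direction is declared unresolved.
#' @return A [phasor_endpoints()] with provenance `"cloud-fit"`.
#' @export
fit_phasor_line <- function(field, mask = NULL, weighted = TRUE,
                            min_pixels = 10L, min_var = 1e-8,
                            max_isotropy = 0.5) {
  stopifnot(inherits(field, "phasor_field"))
  ok <- is.finite(field$g) & is.finite(field$s)
  if (!is.null(mask)) ok <- ok & mask
  g <- field$g[ok]; s <- field$s[ok]
  w <- if (weighted) field$intensity[ok] else rep(1, length(g))
  if (length(g) < min_pixels) {
    stop("phasor cloud has fewer than ", min_pixels, " usable pixels")
  }
  w <- w / sum(w)
  cg <- sum(w * g); cs <- sum(w * s)
  cov <- matrix(c(sum(w * (g - cg)^2), sum(w * (g - cg) * (s - cs)),
                  sum(w * (g - cg) * (s - cs)), sum(w * (s - cs)^2)), 2L)
  eig <- eigen(cov, symmetric = TRUE)
  if (eig$values[1L] < min_var) {
    stop("degenerate phasor cloud: no measurable spread to fit a line")
  }
  if (eig$values[2L] / eig$values[1L] > max_isotropy) {
    stop("degenerate phasor cloud: spread is near-isotropic, line ",
         "direction unresolved (eigenvalue ratio ",
         signif(eig$values[2L] / eig$values[1L], 3), ")")
  }
  v <- eig$vectors[, 1L]
  # line p(t) = c + t v meets g^2 - g + s^2 = 0
  b <- 2 * (cg * v[1L] + cs * v[2L]) - v[1L]
  e <- cg^2 + cs^2 - cg
  disc <- b^2 - 4 * e
  if (disc < 0) {
    stop("phasor-cloud line does not intersect the universal circle ",
         "(discriminant ", signif(disc, 3), ")")
  }
  t1 <- (-b - sqrt(disc)) / 2
  t2 <- (-b + sqrt(disc)) / 2
  p1 <- c(cg, cs) + t1 * v
  p2 <- c(cg, cs) + t2 * v
  if (p1[1L] < p2[1L]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  phasor_endpoints(p1, p2, "cloud-fit")
}

#' Median-filter the phasor coordinates
#'
#' Applies an NA-aware median filter independently to the g and s images
#' inside the intensity mask; the intensity image is untouched. Standard
#' low-photon-budget denoising that raises phasor SNR without resampling
#' the decays.
#'
#' @param field A `phasor_field`.
#' @param kernel Odd integer window side (default 3).
#' @return The filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, kernel = 3L) {
  stopifnot(inherits(field, "phasor_field"))
  if (kernel < 1L || kernel %% 2L != 1L) {
    stop("kernel must be a positive odd integer")
  }
  field$g <- median_filter2(field$g, kernel)
  field$s <- median_filter2(field$s, kernel)
  field
}
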