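# Containers and readers/writers: decay stacks as multi-page TIFF with a
# JSON timing sidecar, intensity images and label masks as 16-bit TIFF,
# IRFs as 2-column CSV, run configs and manifests as JSON.

#' Photon-count decay stack
#'
#' The raw FLIM measurement: a 3-D nonnegative integer photon-count
#' histogram cube with dimensions (time, y, x) plus its [time_grid()].
#'
#' @param counts 3-D array of nonnegative integer counts, time first.
#' @param grid A [time_grid()] whose `n_bins` matches `dim(counts)[1]`.
#' @return Object of class `decay_stack`.
#' @export
decay_stack <- function(counts, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(dim(counts)) != 3L) {
    stop("counts must be a 3-D (time, y, x) array")
  }
  if (dim(counts)[1L] != grid$n_bins) {
    stop("first dimension of counts (", dim(counts)[1L],
         ") does not match grid n_bins (", grid$n_bins, ")")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (max(abs(counts - round(counts))) > 1e-6) {
    stop("counts must be integers (photon counts)")
  }
  structure(list(counts = counts, grid = grid), class = "decay_stack")
}

#' Per-pixel total photon counts of a stack
#' @param stack A [decay_stack()].
#' @return Matrix of per-pixel totals.
#' @export
stack_totals <- function(stack) {
  stopifnot(inherits(stack, "decay_stack"))
  d <- dim(stack$counts)
  matrix(colSums(matrix(stack$counts, d[1L])), d[2L], d[3L])
}

# 16-bit TIFF payload limit; photon counts above this must be rebinned.
MAX_TIFF16 <- 65535L

write_tiff16 <- function(x, path) {
  rng <- if (is.list(x)) range(vapply(x, range, numeric(2L))) else range(x)
  if (rng[2L] > MAX_TIFF16) {
    stop("values exceed the 16-bit TIFF limit (", MAX_TIFF16, ")")
  }
  if (rng[1L] < 0) stop("negative values cannot be stored")
  write_atomic(path, function(tmp) {
    if (is.list(x)) {
      tiff::writeTIFF(lapply(x, function(m) m / MAX_TIFF16), tmp,
                      bits.per.sample = 16L)
    } else {
      tiff::writeTIFF(x / MAX_TIFF16, tmp, bits.per.sample = 16L)
    }
  })
}

sidecar_path <- function(path) {
  sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
}

#' Read and write decay stacks
#'
#' A decay stack is stored as a multi-page 16-bit TIFF (one page per time
#' bin, page order = increasing time) together with a JSON metadata sidecar
#' holding the timing keys `n_bins`, `bin_width_s` and `rep_rate_hz`. The
#' round trip is bit-exact for integer counts up to 65535 per bin.
#'
#' @param stack A [decay_stack()].
#' @param path Path to the `.tif` file; the sidecar uses the same basename
#'   with a `.json` extension.
#' @return `read_decay_stack` returns a [decay_stack()];
#'   `write_decay_stack` invisibly returns `path`.
#' @export
write_decay_stack <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  pages <- lapply(seq_len(stack$grid$n_bins),
                  function(k) stack$counts[k, , , drop = TRUE])
  write_tiff16(pages, path)
  meta <- list(n_bins = stack$grid$n_bins,
               bin_width_s = stack$grid$bin_width,
               rep_rate_hz = stack$grid$rep_rate)
  write_atomic(sidecar_path(path), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_decay_stack
#' @export
read_decay_stack <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing JSON sidecar '", side, "'; required keys: n_bins, ",
         "bin_width_s, rep_rate_hz")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("n_bins", "bin_width_s", "rep_rate_hz")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("sidecar '", side, "' is missing required key(s): ",
         paste(miss, collapse = ", "))
  }
  grid <- time_grid(meta$n_bins, meta$bin_width_s, meta$rep_rate_hz)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != grid$n_bins) {
    stop("TIFF page count (", length(pages),
         ") does not match sidecar n_bins (", grid$n_bins, ")")
  }
  counts <- array(0, dim = c(grid$n_bins, nrow(pages[[1L]]),
                             ncol(pages[[1L]])))
  for (k in seq_along(pages)) counts[k, , ] <- pages[[k]]
  decay_stack(counts, grid)
}

#' Read and write 2-D intensity images
#'
#' Single-page 16-bit TIFF holding nonnegative integer counts.
#'
#' @param image Nonnegative integer matrix.
#' @param path TIFF path.
#' @return `read_intensity_image` returns an integer matrix.
#' @export
write_intensity_image <- function(image, path) {
  stopifnot(is.matrix(image))
  write_tiff16(round(image), path)
  invisible(path)
}

#' @rdname write_intensity_image
#' @export
read_intensity_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.numeric(img), nrow(img))
}

#' Read and write integer label masks
#'
#' Label masks are 16-bit TIFFs. TIFF stores unsigned integers, so negative
#' exclusion codes (nuclei, lipid droplets) are mapped into a reserved high
#' range on write: code `c < 0` is stored as `c + 65536` and any stored
#' value above 32767 is mapped back on read.
#'
#' @param mask Integer matrix of labels in `[-32768, 32767]`.
#' @param path TIFF path.
#' @return `read_label_mask` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- round(mask)
  if (any(m < -32768L) || any(m > 32767L)) {
    stop("labels must lie in [-32768, 32767]")
  }
  m[m < 0] <- m[m < 0] + 65536L
  write_tiff16(m, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  m <- matrix(as.integer(m), nrow(m))
  m[m > 32767L] <- m[m > 32767L] - 65536L
  m
}

#' Read and write IRF histograms as CSV
#'
#' Two columns: `time_s` (bin centers) and `counts`.
#'
#' @param irf An [irf_curve()].
#' @param path CSV path.
#' @param grid Optional [time_grid()] the IRF must match; if omitted, a grid
#'   is reconstructed from the time column assuming a full-period window.
#' @return `read_irf_csv` returns an [irf_curve()].
#' @export
write_irf_csv <- function(irf, path) {
  stopifnot(inherits(irf, "irf_curve"))
  df <- data.frame(time_s = bin_centers(irf$grid), counts = irf$values)
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
  invisible(path)
}

#' @rdname write_irf_csv
#' @export
read_irf_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "counts")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("IRF CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(grid)) {
    n <- nrow(df)
    bw <- if (n > 1L) df$time_s[2L] - df$time_s[1L] else df$time_s[1L] * 2
    grid <- time_grid(n, bw, 1 / (n * bw))
  } else if (nrow(df) != grid$n_bins) {
    stop("IRF CSV has ", nrow(df), " rows but grid expects ", grid$n_bins)
  }
  irf_curve(df$counts, grid)
}

# Keys accepted in a run configuration file. Unknown keys are rejected so a
# typo cannot silently fall back to a default.
RUN_CONFIG_KEYS <- c(
  "seed", "n_bins", "bin_width_s", "rep_rate_hz",
  "bin_size", "min_photons", "fit_method", "fit_background",
  "harmonic", "free_tau_s", "calibration_lifetime_s",
  "calibration_standard", "median_kernel",
  "convention", "prefilter", "postfilter", "min_intensity",
  "threshold_channel", "normalized_by_power",
  "count_rate_hz", "max_pileup_fraction",
  "metadata", "attestations", "paths"
)

#' Read and validate a run configuration
#'
#' JSON configuration for pipeline runs. Unknown top-level keys are
#' rejected; every analysis default the pipeline fills in is echoed back
#' into output manifests so no default stays silent.
#'
#' @param path JSON path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Write a run manifest
#'
#' Records beside the outputs everything needed to reproduce them: the full
#' configuration (defaults included), package version, seed, and MD5
#' checksums of the files written.
#'
#' @param dir Output directory.
#' @param config Named list of all analysis parameters used.
#' @param seed The seed used (or NULL).
#' @param files Character vector of output file paths to checksum.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config, seed = NULL, files = character()) {
  manifest <- list(
    package = "metaflim",
    version = as.character(utils::packageVersion("metaflim")),
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(files))
  )
  path <- file.path(dir, "manifest.json")
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })
  invisible(path)
}
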