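# Intensity-based optical redox ratio: both ORR conventions,
# solution-standard calibration, segmentation-aware aggregation, spatial
# filtering, and the pathway interpretation table.

#' Registered NAD(P)H / FAD intensity image pair
#'
#' Two same-shape nonnegative intensity images with per-channel acquisition
#' metadata and an optional integer label mask (0 background, positive
#' labels = cells, negative labels = excluded organelle regions).
#'
#' @param nadph_image,fad_image Nonnegative numeric matrices, same shape.
#' @param metadata List with elements `nadph` and `fad`, each a named list
#'   (excitation_nm, emission_nm, power_mw, dwell_time_us, detector_gain,
#'   ...). Missing fields are tracked by QC, not fatal here.
#' @param mask Optional integer label matrix.
#' @return Object of class `channel_pair` with `calibrated = FALSE`.
#' @export
channel_pair <- function(nadph_image, fad_image,
                         metadata = list(nadph = list(), fad = list()),
                         mask = NULL) {
  stopifnot(is.matrix(nadph_image), is.matrix(fad_image))
  if (!identical(dim(nadph_image), dim(fad_image))) {
    stop("NAD(P)H and FAD images must have identical shape")
  }
  if (any(nadph_image < 0) || any(fad_image < 0)) {
    stop("intensities must be nonnegative")
  }
  if (!is.null(mask) && !identical(dim(mask), dim(nadph_image))) {
    stop("mask shape does not match the images")
  }
  structure(list(nadph = nadph_image, fad = fad_image,
                 metadata = metadata, mask = mask, calibrated = FALSE,
                 calibration = NULL),
            class = "channel_pair")
}

#' Calibrate channel intensities with solution standards
#'
#' Divides each channel by the spatial mean intensity of its matching
#' uniform solution standard (e.g. 1 mM NADH and FAD imaged under the same
#' acquisition settings). This cancels per-channel instrument factors
#' (power, detector gain, dwell time), making ORR values comparable across
#' acquisition conditions and systems. Standard means are taken on the raw
#' standard frames (means are filter-invariant for uniform frames).
#' Metadata fields that differ between sample and standard are flagged in
#' the calibration provenance, not fatal.
#'
#' @param pair A [channel_pair()].
#' @param nadh_standard,fad_standard [solution_frame()]s for the matching
#'   channels.
#' @return The calibrated `channel_pair`, with provenance in
#'   `$calibration`.
#' @export
calibrate_channels <- function(pair, nadh_standard, fad_standard) {
  stopifnot(inherits(pair, "channel_pair"),
            inherits(nadh_standard, "solution_frame"),
            inherits(fad_standard, "solution_frame"))
  if (nadh_standard$channel != "nadph" || fad_standard$channel != "fad") {
    stop("standards supplied for the wrong channels")
  }
  mean_n <- mean(nadh_standard$intensity_image)
  mean_f <- mean(fad_standard$intensity_image)
  if (mean_n <= 0 || mean_f <= 0) {
    stop("calibration error: solution standard has zero mean intensity")
  }
  flag_mismatch <- function(sample_meta, std_meta) {
    shared <- intersect(names(sample_meta), names(std_meta))
    shared[vapply(shared, function(k) {
      !isTRUE(all.equal(sample_meta[[k]], std_meta[[k]]))
    }, logical(1L))]
  }
  flags <- list(
    nadph = flag_mismatch(pair$metadata$nadph %||% list(),
                          nadh_standard$metadata),
    fad = flag_mismatch(pair$metadata$fad %||% list(),
                        fad_standard$metadata))
  pair$nadph <- pair$nadph / mean_n
  pair$fad <- pair$fad / mean_f
  pair$calibrated <- TRUE
  pair$calibration <- list(nadh_standard_mean = mean_n,
                           fad_standard_mean = mean_f,
                           metadata_mismatches = flags)
  pair
}

#' Compute the optical redox ratio image
#'
#' Pixelwise normalized redox ratio in the chosen convention:
#' oxidized `ORR = FAD / (NAD(P)H + FAD)` or reduced
#' `ORR = NAD(P)H / (NAD(P)H + FAD)`; the two sum to 1 at every pixel.
#' Both channels are pre-filtered with a truncated box sum (default 3x3)
#' before the ratio, the ratio image is median-filtered (default 5x5) to
#' remove outliers, and pixels below `min_intensity` in the thresholding
#' channel (default NAD(P)H, on the pre-filtered image) or with zero total
#' signal are masked, never NaN. All filter and threshold choices are
#' recorded in the result.
#'
#' @param pair A [channel_pair()] (calibrated or not).
#' @param convention `"oxidized"` (default) or `"reduced"`.
#' @param prefilter Odd box-sum size applied to both channels (1 = none).
#' @param postfilter Odd median-filter size applied to the ORR image.
#' @param min_intensity Threshold on the pre-filtered thresholding channel.
#' @param threshold_channel `"nadph"` (default) or `"fad"`.
#' @return Object of class `orr_result`: `orr_image` (NA outside the
#'   mask), `mask`, the filtered channel images, the convention string and
#'   every parameter used.
#' @export
compute_orr <- function(pair, convention = c("oxidized", "reduced"),
                        prefilter = 3L, postfilter = 5L,
                        min_intensity = 0,
                        threshold_channel = c("nadph", "fad")) {
  convention <- match.arg(convention)
  threshold_channel <- match.arg(threshold_channel)
  stopifnot(inherits(pair, "channel_pair"), min_intensity >= 0)
  nad <- neighborhood_sum(pair$nadph, prefilter)
  fad <- neighborhood_sum(pair$fad, prefilter)
  total <- nad + fad
  thr_im <- if (threshold_channel == "nadph") nad else fad
  mask <- thr_im >= min_intensity & total > 0
  num <- if (convention == "oxidized") fad else nad
  orr <- matrix(NA_real_, nrow(nad), ncol(nad))
  orr[mask] <- num[mask] / total[mask]
  orr <- median_filter2(orr, postfilter)
  structure(list(orr_image = orr, mask = mask,
                 nadph_filtered = nad, fad_filtered = fad,
                 convention = convention,
                 params = list(prefilter = prefilter,
                               postfilter = postfilter,
                               min_intensity = min_intensity,
                               threshold_channel = threshold_channel),
                 calibrated = isTRUE(pair$calibrated),
                 calibration = pair$calibration,
                 n_masked_out = sum(!mask), label_mask = pair$mask),
            class = "orr_result")
}

#' Aggregate ORR per labelled region, both conventions of averaging
#'
#' For each positive region label, reports side by side:
#' `ratio_of_means` — the ORR formula applied to the region-mean channel
#' intensities (better SNR, robust to dim pixels) — and `mean_of_ratios` —
#' the mean of the pixelwise ORR over the region (preserves heterogeneity
#' weighting). Negative labels (nuclei, lipid droplets) are excluded by
#' default; regions with no pixel passing the intensity mask are absent
#' from the table with a warning.
#'
#' @param result An [compute_orr()] result.
#' @param mask Optional label matrix (defaults to the pair's mask).
#' @param include_negative Include negative-label regions (default FALSE).
#' @return Data frame with columns region_id, n_pixels,
#'   orr_ratio_of_means, orr_mean_of_ratios, convention, calibrated.
#' @export
aggregate_orr <- function(result, mask = NULL, include_negative = FALSE) {
  stopifnot(inherits(result, "orr_result"))
  mask <- mask %||% result$label_mask
  if (is.null(mask)) stop("no label mask available for aggregation")
  labs <- sort(unique(mask[mask != 0L]))
  if (!include_negative) labs <- labs[labs > 0L]
  rows <- list()
  for (lab in labs) {
    sel <- mask == lab & result$mask
    n <- sum(sel)
    if (n == 0L) {
      warning("region ", lab, " has no pixel passing the intensity mask; ",
              "omitted from the table")
      next
    }
    mn <- mean(result$nadph_filtered[sel])
    mf <- mean(result$fad_filtered[sel])
    rom <- if (result$convention == "oxidized") {
      mf / (mn + mf)
    } else {
      mn / (mn + mf)
    }
    mor <- mean(result$orr_image[sel], na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = lab, n_pixels = n, orr_ratio_of_means = rom,
      orr_mean_of_ratios = mor, convention = result$convention,
      calibrated = result$calibrated)
  }
  if (!length(rows)) {
    return(data.frame(region_id = integer(), n_pixels = integer(),
                      orr_ratio_of_means = numeric(),
                      orr_mean_of_ratios = numeric(),
                      convention = character(), calibrated = logical()))
  }
  do.call(rbind, rows)
}

# Pathway-direction table: typical co-movement of metabolic pathway
# activity with the oxidized ORR and the NAD(P)H bound fraction / mean
# lifetime. Directions can be transient and cell/tissue/environment
# dependent; annotations are descriptive, never mechanistic claims.
pathway_table <- function() {
  data.frame(
    pathway = c("ETC activity", "glutaminolysis", "ETC uncoupling",
                "glycolysis", "fatty acid oxidation",
                "fatty acid synthesis", "TCA relative to ETC activity"),
    orr_oxidized = c("up", "up", "up", "down", "down", "down", "down"),
    bound_fraction_or_tau_m = c("up", "up", "up_or_down", "down", "down",
                                "up", "down"),
    stringsAsFactors = FALSE)
}

#' Pathways consistent with an observed metric change
#'
#' Maps an observed direction of change in an optical metabolic metric to
#' the set of pathway activity increases typically associated with it.
#' Purely annotational: the associations can be transient and
#' cell/tissue/environment dependent, and several pathways move each
#' metric, so this is a candidate list, never a mechanism claim (the
#' caveat is attached to every row).
#'
#' @param metric One of `"orr_oxidized"`, `"orr_reduced"`,
#'   `"bound_fraction_or_tau_m"`.
#' @param direction `"up"` or `"down"` (the observed change).
#' @return Data frame of pathway annotations (each row: an increase in
#'   that pathway's activity is consistent with the observed change), with
#'   a `caveat` column.
#' @export
interpret_metric_change <- function(metric = c("orr_oxidized",
                                               "orr_reduced",
                                               "bound_fraction_or_tau_m"),
                                    direction = c("up", "down")) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  tbl <- pathway_table()
  col <- if (metric == "orr_reduced") {
    # reduced convention moves opposite to oxidized
    ifelse(tbl$orr_oxidized == "up", "down", "up")
  } else {
    tbl[[metric]]
  }
  hit <- col == direction | col == "up_or_down"
  out <- data.frame(
    pathway = tbl$pathway[hit],
    pathway_change = "up",
    metric = metric, metric_direction = direction,
    caveat = paste("changes can be transient and",
                   "cell/tissue/environment dependent"),
    stringsAsFactors = FALSE)
  out
}
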