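# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators never
#' perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Truncated box sum over a square neighborhood
#'
#' Each output pixel is the sum of the size x size window centred on it;
#' windows are truncated at the image edge (no padding or mirroring), so
#' edge sums honestly reflect fewer contributing pixels.
#' @noRd
neighborhood_sum <- function(x, size) {
  stopifnot(is.matrix(x), size >= 1L, size %% 2L == 1L)
  if (size == 1L) return(x)
  r <- (size - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (dy in -r:r) {
    ti <- max(1L, 1L - dy):min(h, h - dy)
    for (dx in -r:r) {
      tj <- max(1L, 1L - dx):min(w, w - dx)
      out[ti, tj] <- out[ti, tj] + x[ti + dy, tj + dx, drop = FALSE]
    }
  }
  out
}

# Same truncated box sum applied along dims 2:3 of a (time, y, x) array.
#' @noRd
neighborhood_sum_stack <- function(a, size) {
  stopifnot(length(dim(a)) == 3L, size >= 1L, size %% 2L == 1L)
  if (size == 1L) return(a)
  r <- (size - 1L) %/% 2L
  h <- dim(a)[2L]; w <- dim(a)[3L]
  out <- array(0, dim(a))
  for (dy in -r:r) {
    ti <- max(1L, 1L - dy):min(h, h - dy)
    for (dx in -r:r) {
      tj <- max(1L, 1L - dx):min(w, w - dx)
      out[, ti, tj] <- out[, ti, tj, drop = FALSE] +
        a[, ti + dy, tj + dx, drop = FALSE]
    }
  }
  out
}

#' 2-D median filter with NA-aware windows
#'
#' Values outside the mask (or off the image) are ignored; a pixel whose
#' window holds no finite value keeps NA.
#' @noRd
median_filter2 <- function(x, size) {
  stopifnot(is.matrix(x), size >= 1L, size %% 2L == 1L)
  if (size == 1L) return(x)
  r <- (size - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  k <- (2L * r + 1L)^2
  stackm <- matrix(NA_real_, h * w, k)
  col <- 0L
  for (dy in -r:r) {
    for (dx in -r:r) {
      col <- col + 1L
      shifted <- matrix(NA_real_, h, w)
      ti <- max(1L, 1L - dy):min(h, h - dy)
      tj <- max(1L, 1L - dx):min(w, w - dx)
      shifted[ti, tj] <- x[ti + dy, tj + dx]
      stackm[, col] <- as.vector(shifted)
    }
  }
  out <- apply(stackm, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  keep_na <- !is.finite(as.vector(x))
  out[keep_na] <- NA_real_
  matrix(out, h, w)
}

# Write through a temporary file in the target directory, then rename, so a
# crash never leaves a half-written output.
#' @noRd
write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."),
                  tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic write failed for '", path, "'")
  }
  ok <- TRUE
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
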