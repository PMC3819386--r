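# Preprocessing: nuisance regression, band-pass filtering, per-run
# normalization and concatenation, gray-matter masking, PSD QC.
# The fixed stage order is regression -> band-pass -> normalize/concatenate
# and is recorded in the provenance attribute of the clean series.

#' Regress nuisance signals out of a node-by-time matrix
#'
#' Ordinary least squares per node: the returned residuals are the input
#' series minus its projection onto the column space of the design, and are
#' orthogonal to every design column.  Collinear columns are dropped with a
#' warning; a design still rank-deficient afterwards is an error.
#'
#' @param series Numeric node-by-time matrix.
#' @param design Numeric time-by-p matrix with named columns, including an
#'   intercept column.
#' @return Residual node-by-time matrix.
#' @export
regress_nuisance <- function(series, design) {
  stopifnot(is.matrix(series), is.matrix(design))
  if (ncol(series) != nrow(design)) {
    abort("Design rows must match the series' time points.")
  }
  cn <- colnames(design) %||% paste0("V", seq_len(ncol(design)))
  if (!any(apply(design, 2, function(col) sd(col) == 0 & all(col != 0)))) {
    abort("The nuisance design must contain an intercept column.")
  }
  zero_cols <- apply(design, 2, function(col) all(col == 0))
  if (any(zero_cols)) {
    abort(paste0("All-zero nuisance column(s): ",
                 paste(cn[zero_cols], collapse = ", ")))
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    drop_idx <- qr_d$pivot[(qr_d$rank + 1):ncol(design)]
    warn(paste0("Dropping collinear nuisance column(s): ",
                paste(cn[drop_idx], collapse = ", ")))
    design <- design[, -drop_idx, drop = FALSE]
    cn <- cn[-drop_idx]
    if (qr(design)$rank < ncol(design)) {
      abort(paste0("Design remains rank deficient after dropping: ",
                   paste(cn, collapse = ", ")))
    }
  }
  fit <- lm.fit(design, t(series))
  res <- t(t(series) - design %*% fit$coefficients)
  dimnames(res) <- dimnames(series)
  res
}

#' Ideal frequency-domain band-pass filter
#'
#' FFT bins with frequency strictly inside `(lo_hz, hi_hz)` are retained,
#' all others (including DC) are zeroed, and the series is inverse
#' transformed.  The output is real.
#'
#' @param series Numeric node-by-time matrix.
#' @param lo_hz,hi_hz Pass band in Hz; requires
#'   `0 <= lo_hz < hi_hz < 1/(2 tr)`.
#' @param tr Sampling interval in seconds.
#' @return Filtered node-by-time matrix.
#' @export
bandpass <- function(series, lo_hz = 0.008, hi_hz = 0.08, tr = 1.5) {
  stopifnot(is.matrix(series))
  nyquist <- 1 / (2 * tr)
  if (lo_hz < 0 || lo_hz >= hi_hz) abort("Need 0 <= lo_hz < hi_hz.")
  if (hi_hz >= nyquist) {
    abort(sprintf("hi_hz must be below the Nyquist frequency %.4f Hz.",
                  nyquist))
  }
  t_len <- ncol(series)
  k <- 0:(t_len - 1)
  freq <- pmin(k, t_len - k) / (t_len * tr)
  keep <- freq > lo_hz & freq < hi_hz
  f <- mvfft(t(series))
  f[!keep, ] <- 0
  out <- t(Re(mvfft(f, inverse = TRUE)) / t_len)
  dimnames(out) <- dimnames(series)
  out
}

#' Normalize runs per node and concatenate along time
#'
#' Each run is demeaned and scaled to unit variance per node, then the runs
#' are concatenated.  Zero-variance nodes within a run are left at zero.
#'
#' @param runs List of node-by-time matrices sharing a node count.
#' @return A `clean_series` matrix (node x total time) with attributes
#'   `run_boundaries` (end column of each run) and `provenance`.
#' @export
normalize_and_concatenate <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1)
  n_nodes <- vapply(runs, nrow, integer(1))
  if (length(unique(n_nodes)) != 1) {
    abort("All runs must share the same node count.")
  }
  normed <- lapply(runs, function(x) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    z <- (x - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    z
  })
  out <- do.call(cbind, normed)
  structure(out,
            run_boundaries = cumsum(vapply(runs, ncol, integer(1))),
            provenance = "regress -> bandpass -> normalize/concatenate",
            class = c("clean_series", class(out)))
}

#' @export
print.clean_series <- function(x, ...) {
  cat("<clean_series> ", nrow(x), " nodes x ", ncol(x), " time points, ",
      length(attr(x, "run_boundaries")), " run(s)\n", sep = "")
  invisible(x)
}

#' Full per-subject preprocessing
#'
#' Applies the fixed stage order to every run - nuisance regression, ideal
#' band-pass, per-run z-scoring - and concatenates the runs.
#'
#' @param runs List of node-by-time matrices.
#' @param designs List of matching time-by-p nuisance design matrices
#'   (`NULL` to skip regression).
#' @param lo_hz,hi_hz,tr Band-pass parameters, see [bandpass()].
#' @return A `clean_series` matrix.
#' @export
preprocess_subject <- function(runs, designs = NULL,
                               lo_hz = 0.008, hi_hz = 0.08, tr = 1.5) {
  stopifnot(is.list(runs))
  if (!is.null(designs) && length(designs) != length(runs)) {
    abort("`designs` must match `runs` in length.")
  }
  cleaned <- lapply(seq_along(runs), function(r) {
    x <- runs[[r]]
    if (!is.null(designs)) x <- regress_nuisance(x, designs[[r]])
    bandpass(x, lo_hz, hi_hz, tr)
  })
  out <- normalize_and_concatenate(cleaned)
  attr(out, "tr") <- tr
  out
}

#' Gray-matter mask from a tissue-prior volume
#'
#' Thresholds a 3D tissue-prior volume at the quantile keeping the top
#' `keep_top` fraction of intensities (linear-interpolation percentile
#' definition; ties at the threshold are included) and records the linear
#' node index map (x-fastest raster order over in-mask voxels).
#'
#' @param prior Numeric 3D array.
#' @param keep_top Fraction of voxels to keep (default 0.8).
#' @return Object of class `gm_mask`: list with logical array `mask`, voxel
#'   count `n`, and `node_map` (tibble node, x, y, z).
#' @export
gray_matter_mask <- function(prior, keep_top = 0.8) {
  stopifnot(is.array(prior), length(dim(prior)) == 3)
  if (keep_top <= 0 || keep_top > 1) abort("`keep_top` must be in (0, 1].")
  thr <- quantile(prior, probs = 1 - keep_top, type = 7, names = FALSE)
  mask_from_logical(prior >= thr)
}

#' Build a mask object from a logical 3D array
#'
#' @param mask Logical 3D array of in-mask voxels.
#' @return Object of class `gm_mask`.
#' @export
mask_from_logical <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  idx <- which(mask)  # linear indices, x fastest
  if (length(idx) < 2) abort("A mask must contain at least 2 voxels.")
  co <- arrayInd(idx, dim(mask))
  structure(
    list(mask = mask, n = length(idx),
         node_map = tibble(node = seq_along(idx),
                           x = co[, 1], y = co[, 2], z = co[, 3])),
    class = "gm_mask"
  )
}

#' @export
print.gm_mask <- function(x, ...) {
  cat("<gm_mask> ", x$n, " voxels in a ",
      paste(dim(x$mask), collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Extract in-mask voxel time series from a 4D volume
#'
#' Rows follow the mask's linear node index (x-fastest raster order), so
#' [unmask()] restores voxel placement exactly.
#'
#' @param volume Numeric 4D array (x, y, z, t).
#' @param mask A `gm_mask`.
#' @return Node-by-time matrix.
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(mask, "gm_mask"), is.array(volume),
            length(dim(volume)) == 4)
  if (!all(dim(volume)[1:3] == dim(mask$mask))) {
    abort("Volume spatial dimensions do not match the mask.")
  }
  t_len <- dim(volume)[4]
  flat <- matrix(volume, ncol = t_len)
  flat[which(mask$mask), , drop = FALSE]
}

#' Restore masked node values to volume space
#'
#' @param values Node-by-time matrix or per-node vector aligned to the
#'   mask's node index.
#' @param mask A `gm_mask`.
#' @param fill Value for out-of-mask voxels.
#' @return 4D array (or 3D array for a vector input).
#' @export
unmask <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "gm_mask"))
  dims <- dim(mask$mask)
  if (is.matrix(values)) {
    stopifnot(nrow(values) == mask$n)
    t_len <- ncol(values)
    out <- matrix(fill, prod(dims), t_len)
    out[which(mask$mask), ] <- values
    array(out, c(dims, t_len))
  } else {
    stopifnot(length(values) == mask$n)
    out <- array(fill, dims)
    out[which(mask$mask)] <- values
    out
  }
}

#' Voxel-wise power spectral density summarized over frequency bands
#'
#' Computes the periodogram of each node series and averages power within
#' each requested band.  Default bands bracket the low-frequency range and
#' the residual task-signal range used for QC.
#'
#' @param series Node-by-time matrix with at least 8 time points.
#' @param tr Sampling interval in seconds.
#' @param bands List of `(lo, hi)` frequency pairs in Hz; each band must lie
#'   inside `(0, Nyquist]`.
#' @return Tibble with columns `node`, `band`, `lo_hz`, `hi_hz`, `power`.
#' @export
voxelwise_psd <- function(series, tr = 1.5,
                          bands = list(c(0, 0.016), c(0.019, 0.03))) {
  stopifnot(is.matrix(series))
  t_len <- ncol(series)
  if (t_len < 8) abort("At least 8 time points are required.")
  nyquist <- 1 / (2 * tr)
  for (b in bands) {
    if (b[1] < 0 || b[2] <= b[1] || b[2] > nyquist) {
      abort("Each band must lie inside (0, Nyquist].")
    }
  }
  f <- mvfft(t(series))
  pow <- Mod(f)^2 / t_len           # periodogram, frequency x node
  k <- 0:(t_len - 1)
  freq <- k / (t_len * tr)
  keep <- freq > 0 & freq <= nyquist
  purrr::imap_dfr(bands, function(b, i) {
    sel <- keep & freq > b[1] & freq <= b[2]
    p <- if (any(sel)) colMeans(pow[sel, , drop = FALSE]) else
      rep(NA_real_, nrow(series))
    tibble(node = seq_len(nrow(series)), band = i,
           lo_hz = b[1], hi_hz = b[2], power = p)
  })
}
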