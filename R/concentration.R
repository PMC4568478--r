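# Signal-to-concentration conversion: from the raw 4D bolus-tracking series
# to the voxelwise contrast concentration that feeds the deconvolution.

#' 4D perfusion-weighted series
#'
#' @param data 4D numeric array (x, y, z, t) of signal intensities
#' @param dt frame interval, seconds
#' @param te echo time, seconds
#' @param affine 4x4 voxel-to-world matrix (identity when not given)
#' @return a \code{perfusion_series}
#' @export
perfusion_series <- function(data, dt, te, affine = diag(4)) {
  if (length(dim(data)) != 4L) stopf("'data' must be a 4D array")
  if (dim(data)[4] < 20L) stopf("a perfusion series needs >= 20 frames")
  if (!all(is.finite(data))) stopf("'data' contains non-finite values")
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(te, "te", 0, strict = TRUE)
  structure(list(data = data, dt = dt, te = te, affine = affine),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perfusion_series> %dx%dx%d voxels, %d frames, dt=%.3gs, te=%.3gs\n",
              d[1], d[2], d[3], d[4], x$dt, x$te))
  invisible(x)
}

#' Baseline map and brain mask from pre-bolus frames
#'
#' The baseline \eqn{S_0} is the per-voxel mean of the first
#' \code{n_baseline} frames (which must precede bolus arrival). The brain
#' mask keeps voxels whose baseline exceeds \code{mask_frac} of the robust
#' (99th-percentile) image maximum.
#'
#' @param series a \code{\link{perfusion_series}}
#' @param n_baseline number of pre-bolus frames averaged (default 8,
#'   i.e. 12 s at dt = 1.5 s)
#' @param mask_frac brain-mask threshold as a fraction of the
#'   99th-percentile baseline
#' @return list with \code{s0} (3D array) and \code{brain_mask} (3D logical)
#' @export
estimate_baseline <- function(series, n_baseline = 8L, mask_frac = 0.1) {
  stopifnot(inherits(series, "perfusion_series"))
  nt <- dim(series$data)[4]
  if (n_baseline < 1L || n_baseline >= nt)
    stopf("'n_baseline' must be in [1, %d)", nt)
  dims <- dim(series$data)[1:3]
  m <- matrix(series$data, nrow = prod(dims))
  s0 <- array(rowMeans(m[, seq_len(n_baseline), drop = FALSE]), dim = dims)
  thr <- mask_frac * stats::quantile(s0, 0.99, names = FALSE)
  list(s0 = s0, brain_mask = s0 > thr)
}

#' Convert signal to contrast concentration
#'
#' Standard DSC relation \eqn{C(t) = -\log(S(t)/S_0) / (k \cdot TE)}.
#' Negative concentrations (noise pushing S above S0) are retained so the
#' deconvolution input stays unbiased. Non-positive or near-zero signal is
#' floored at \code{floor_frac * S0} before the log and counted in the QC
#' summary. Voxels outside the brain mask are identically zero.
#'
#' @param series a \code{\link{perfusion_series}}
#' @param baseline result of \code{\link{estimate_baseline}}
#' @param k relaxivity constant (arbitrary units; must match the forward
#'   model when applied to simulated data)
#' @param floor_frac signal floor as a fraction of S0
#' @return a \code{concentration_series}: list with 4D \code{data}, the
#'   \code{s0} map, \code{brain_mask}, timing and a \code{qc} record
#' @export
signal_to_concentration <- function(series, baseline, k = 1,
                                    floor_frac = 0.01) {
  stopifnot(inherits(series, "perfusion_series"))
  s0 <- baseline$s0
  mask <- baseline$brain_mask
  if (any(s0[mask] <= 0))
    stopf("baseline S0 must be positive inside the brain mask")
  dims <- dim(series$data)
  m <- matrix(series$data, nrow = prod(dims[1:3]))
  midx <- which(mask)
  conc <- matrix(0, nrow = nrow(m), ncol = dims[4])
  sm <- m[midx, , drop = FALSE]
  floorv <- floor_frac * s0[midx]
  n_floored <- sum(sm < floorv)
  sm <- pmax(sm, floorv)
  conc[midx, ] <- -log(sm / s0[midx]) / (k * series$te)
  structure(list(data = array(conc, dim = dims), s0 = s0,
                 brain_mask = mask, dt = series$dt, te = series$te,
                 qc = list(n_floored = n_floored,
                           n_mask = length(midx))),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<concentration_series> %dx%dx%d voxels, %d frames, %d in mask (%d floored samples)\n",
              d[1], d[2], d[3], d[4], x$qc$n_mask, x$qc$n_floored))
  invisible(x)
}

# masked voxel curves as a frames x voxels matrix, plus voxel indices
masked_curves <- function(conc) {
  dims <- dim(conc$data)
  idx <- which(conc$brain_mask)
  m <- matrix(conc$data, nrow = prod(dims[1:3]))
  list(curves = t(m[idx, , drop = FALSE]), idx = idx, dims = dims[1:3])
}
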