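# SVD deconvolution of the tissue-concentration convolution model.
#
# The sampled model is C_v = A (F R), with A the discretized AIF operator
# scaled by dt. Simple mode uses the lower-triangular Toeplitz operator;
# circulant mode embeds the zero-padded AIF in a circulant matrix, which is
# linear convolution with time aliasing and makes the inversion insensitive
# to bolus delay. The pseudoinverse is truncated: singular values below
# truncation x (largest singular value) are dropped.

default_truncation <- function(mode) {
  switch(mode, simple = 0.2, circulant = 0.03)
}

#' Discretized AIF convolution operator
#'
#' Simple mode: \code{A[i, j] = dt * aif[i - j + 1]} for \code{j <= i},
#' zero above the diagonal. Circulant mode: first column is the AIF
#' zero-padded to \code{n + pad_length} (default pad of one full series
#' length, i.e. dimension 2n) and scaled by dt; every further column is a
#' cyclic shift.
#'
#' @param aif an \code{arterial_input_function} or a numeric curve
#' @param dt sampling interval, seconds (taken from the AIF object when
#'   available)
#' @param mode "circulant" (delay-insensitive, default) or "simple"
#' @param pad_length zero-padding length for circulant mode; must be at
#'   least the AIF length to avoid wrap-around
#' @param truncation singular-value cutoff as a fraction of the largest
#'   singular value; defaults to 0.2 (simple) or 0.03 (circulant)
#' @return a \code{convolution_system} carrying the matrix and its SVD
#' @export
build_convolution_matrix <- function(aif, dt = NULL,
                                     mode = c("circulant", "simple"),
                                     pad_length = NULL, truncation = NULL) {
  mode <- match.arg(mode)
  if (inherits(aif, "arterial_input_function")) {
    dt <- dt %||% aif$dt
    aif <- aif$curve
  }
  if (is.null(dt)) stopf("'dt' is required when 'aif' is a plain vector")
  n <- length(aif)
  if (n < 2L) stopf("aif must have length >= 2")
  truncation <- truncation %||% default_truncation(mode)
  if (truncation <= 0 || truncation >= 1)
    stopf("'truncation' must be in (0, 1)")
  if (mode == "simple") {
    pad_length <- 0L
    A <- matrix(0, n, n)
    for (j in seq_len(n)) A[j:n, j] <- dt * aif[seq_len(n - j + 1L)]
  } else {
    pad_length <- as.integer(pad_length %||% n)
    if (pad_length < n)
      stopf("circulant 'pad_length' (%d) must be >= aif length (%d)",
            pad_length, n)
    N <- n + pad_length
    col1 <- c(aif, numeric(pad_length)) * dt
    A <- matrix(0, N, N)
    for (j in seq_len(N))
      A[, j] <- col1[((seq_len(N) - j) %% N) + 1L]
  }
  structure(list(matrix = A, mode = mode, dt = dt, n_frames = n,
                 pad_length = pad_length, truncation = truncation,
                 svd = svd(A)),
            class = "convolution_system")
}

# truncated pseudoinverse of the system operator
system_pinv <- function(system, truncation = NULL) {
  truncation <- truncation %||% system$truncation
  s <- system$svd
  keep <- s$d >= truncation * max(s$d)
  if (!any(keep))
    stopf("all singular values fall below the truncation threshold (degenerate AIF)")
  s$v %*% ((ifelse(keep, 1 / s$d, 0)) * t(s$u))
}

#' Deconvolve one tissue curve
#'
#' Solves the truncated-SVD least-squares problem for \eqn{F R(t)}. In
#' circulant mode the input curve is zero-padded to the system dimension;
#' the returned \code{values} are the first \code{n_frames} samples while
#' \code{values_full} keeps the whole padded solution (whose maximum is the
#' delay-insensitive flow estimate).
#'
#' @param system a \code{convolution_system}
#' @param conc_curve tissue concentration samples (length \code{n_frames})
#' @param truncation optional override of the system truncation
#' @return a \code{residue_curve}: \code{values}, \code{values_full},
#'   \code{dt}, \code{mode}
#' @export
svd_deconvolve <- function(system, conc_curve, truncation = NULL) {
  stopifnot(inherits(system, "convolution_system"))
  n <- system$n_frames
  if (length(conc_curve) != n)
    stopf("curve length %d does not match the system (%d frames)",
          length(conc_curve), n)
  b <- if (system$mode == "circulant")
    c(conc_curve, numeric(system$pad_length)) else conc_curve
  x <- as.vector(system_pinv(system, truncation) %*% b)
  structure(list(values = x[seq_len(n)], values_full = x,
                 dt = system$dt, mode = system$mode),
            class = "residue_curve")
}

#' Perfusion parameters from a flow-scaled residue curve
#'
#' CBF is the peak of \eqn{F R(t)} over all time points; CBV the area under
#' its positive part within the acquisition window (negative SVD
#' oscillations are zeroed before the area integral but not before the
#' peak); MTT = CBV/CBF by the central volume principle. A voxel whose peak
#' is not positive is flagged and gets all-zero parameters.
#'
#' @param residue a \code{residue_curve} (or numeric vector, with \code{dt})
#' @param dt sampling interval when \code{residue} is a plain vector
#' @param quadrature "trapezoid" (default; area under the sampled curve) or
#'   "rectangle" (plain \code{dt * sum})
#' @param flow_scale divisor returning CBF/CBV to nominal flow units; see
#'   \code{\link{dsc_flow_scale}}
#' @return list with \code{cbf}, \code{cbv}, \code{mtt}, \code{flagged}
#' @export
perfusion_parameters <- function(residue, dt = NULL,
                                 quadrature = c("trapezoid", "rectangle"),
                                 flow_scale = 1) {
  quadrature <- match.arg(quadrature)
  if (inherits(residue, "residue_curve")) {
    dt <- residue$dt
    full <- residue$values_full
    win <- residue$values
  } else {
    if (is.null(dt)) stopf("'dt' is required for a plain residue vector")
    full <- win <- as.numeric(residue)
  }
  if (!all(is.finite(full))) stopf("residue curve must be finite")
  peak <- max(full)
  if (peak <= 0)
    return(list(cbf = 0, cbv = 0, mtt = 0, flagged = TRUE))
  pos <- pmax(win, 0)
  area <- if (quadrature == "trapezoid") trapz(pos, dt) else dt * sum(pos)
  cbf <- peak / flow_scale
  cbv <- area / flow_scale
  list(cbf = cbf, cbv = cbv, mtt = cbv / cbf, flagged = FALSE)
}

#' Voxelwise perfusion maps by SVD deconvolution
#'
#' Applies build-system / deconvolve / parameter extraction to every voxel
#' in the brain mask in one pass (the truncated pseudoinverse is formed
#' once and applied to the voxel-curve matrix). Voxels outside the mask are
#' zero; degenerate voxels are flagged and excluded from downstream
#' regional means.
#'
#' @param conc a \code{concentration_series}
#' @param aif an \code{arterial_input_function}
#' @param mode,truncation,pad_length see
#'   \code{\link{build_convolution_matrix}}
#' @param quadrature,flow_scale see \code{\link{perfusion_parameters}}
#' @return \code{perfusion_maps}: 3D \code{cbf}, \code{cbv}, \code{mtt},
#'   logical \code{flagged}, and a \code{qc} list (flagged count,
#'   negative-residue fraction, truncation used)
#' @export
compute_maps <- function(conc, aif, mode = c("circulant", "simple"),
                         truncation = NULL, pad_length = NULL,
                         quadrature = c("trapezoid", "rectangle"),
                         flow_scale = dsc_flow_scale()) {
  mode <- match.arg(mode)
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(conc, "concentration_series"))
  system <- build_convolution_matrix(aif, dt = conc$dt, mode = mode,
                                     pad_length = pad_length,
                                     truncation = truncation)
  if (system$n_frames != dim(conc$data)[4])
    stopf("AIF length and series frame count differ")
  P <- system_pinv(system)
  mc <- masked_curves(conc)
  b <- mc$curves
  if (system$mode == "circulant")
    b <- rbind(b, matrix(0, system$pad_length, ncol(b)))
  fr <- P %*% b                          # (N) x voxels flow-scaled residues
  n <- system$n_frames
  peak <- apply(fr, 2L, max)
  win <- fr[seq_len(n), , drop = FALSE]
  pos <- pmax(win, 0)
  area <- if (quadrature == "trapezoid")
    system$dt * (colSums(pos) - (pos[1L, ] + pos[n, ]) / 2)
  else system$dt * colSums(pos)
  flagged <- !(peak > 0)
  cbf <- ifelse(flagged, 0, peak / flow_scale)
  cbv <- ifelse(flagged, 0, area / flow_scale)
  mtt <- ifelse(flagged, 0, cbv / cbf)

  shape <- function(v, init = 0) {
    a <- array(init, dim = mc$dims); a[mc$idx] <- v; a
  }
  structure(list(cbf = shape(cbf), cbv = shape(cbv), mtt = shape(mtt),
                 flagged = shape(flagged, FALSE),
                 brain_mask = conc$brain_mask,
                 qc = list(n_flagged = sum(flagged),
                           negative_residue_fraction = mean(win < 0),
                           truncation = system$truncation, mode = mode)),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("<perfusion_maps> %s, %d masked voxels, %d flagged (trunc %.3g, %s mode)\n",
              paste(dim(x$cbf), collapse = "x"), sum(x$brain_mask),
              x$qc$n_flagged, x$qc$truncation, x$qc$mode))
  invisible(x)
}

#' Brute-force discrete convolution (reference implementation)
#'
#' Direct evaluation of the sampled convolution sum
#' \eqn{(A x)_i = dt \sum_{j \le i} aif_{i-j+1} x_j}; the independent
#' oracle against which the matrix operator is checked.
#'
#' @param aif sampled arterial curve
#' @param x sampled residue (same length)
#' @param dt sampling interval
#' @return the convolved curve
#' @export
direct_convolution <- function(aif, x, dt) {
  n <- length(aif)
  stopifnot(length(x) == n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) acc <- acc + aif[i - j + 1L] * x[j]
    out[i] <- dt * acc
  }
  out
}
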