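# Automatic arterial-input-function search: screen voxels by curve features
# (peak concentration, time-to-peak, first-moment transit time), then take
# the highest-peak candidates.

#' Per-voxel bolus curve features
#'
#' For every voxel in the brain mask: \code{peak} is the maximum
#' concentration; \code{ttp} the time of that maximum (seconds from scan
#' start); \code{fm_mtt} a transit-time proxy, the first moment of the
#' positive part of the curve minus the bolus arrival time. Arrival is the
#' time the curve first reaches \code{arrival_frac} of its peak.
#'
#' @param conc a \code{concentration_series}
#' @param arrival_frac fraction of peak defining bolus arrival
#' @return \code{curve_features}: 3D arrays \code{peak}, \code{ttp},
#'   \code{fm_mtt} (NA outside the mask or where the peak is not positive)
#' @export
compute_curve_features <- function(conc, arrival_frac = 0.2) {
  stopifnot(inherits(conc, "concentration_series"))
  mc <- masked_curves(conc)
  if (!length(mc$idx)) stopf("brain mask is empty")
  nt <- nrow(mc$curves)
  t <- time_axis(nt, conc$dt)
  cur <- mc$curves                      # frames x voxels
  pk <- apply(cur, 2L, max)
  imax <- max.col(t(cur), ties.method = "first")
  ttp <- t[imax]
  pos <- pmax(cur, 0)
  fm <- colSums(t * pos) / colSums(pos)
  arrival <- t[max.col(t(cur >= rep(arrival_frac * pk, each = nt)),
                       ties.method = "first")]
  fm_mtt <- pmax(fm - arrival, conc$dt / 100)   # keep strictly positive
  bad <- !(pk > 0) | !is.finite(fm_mtt)
  pk[bad] <- NA; ttp[bad] <- NA; fm_mtt[bad] <- NA
  shape <- function(v) {
    a <- array(NA_real_, dim = mc$dims); a[mc$idx] <- v; a
  }
  structure(list(peak = shape(pk), ttp = shape(ttp), fm_mtt = shape(fm_mtt),
                 brain_mask = conc$brain_mask, dt = conc$dt),
            class = "curve_features")
}

#' Select arterial voxels and average their curves
#'
#' Deterministic realisation of the histogram-threshold AIF search:
#' candidates are masked voxels in the lowest \code{ttp_quantile} of
#' time-to-peak and the lowest \code{mtt_quantile} of the first-moment
#' transit time (early, narrow curves); of those, the \code{n_aif} voxels
#' with the highest peak are kept and their curves averaged. Ties in peak
#' are broken by lower ttp, then by voxel index. An optional \code{roi_mask}
#' restricts the candidate pool (standing in for a manual location check);
#' the selection is rejected if the chosen voxels are not clearly
#' artery-like in peak height.
#'
#' @param conc a \code{concentration_series}
#' @param features result of \code{\link{compute_curve_features}}
#' @param n_aif number of voxels to average
#' @param ttp_quantile,mtt_quantile screening quantiles in (0, 1)
#' @param roi_mask optional 3D logical array restricting candidates
#' @param require_peak_ratio minimum ratio of the mean selected peak to the
#'   median masked-voxel peak (arterial peaks roughly double the tissue peaks in this contrast regime); guards against a silent tissue AIF
#' @return an \code{arterial_input_function}: the averaged \code{curve},
#'   selected \code{voxel_ids} (n x 3 index matrix), and
#'   \code{thresholds_used}
#' @export
select_aif_voxels <- function(conc, features, n_aif = 10L,
                              ttp_quantile = 0.1, mtt_quantile = 0.2,
                              roi_mask = NULL, require_peak_ratio = 1.5) {
  stopifnot(inherits(features, "curve_features"))
  if (n_aif < 1L) stopf("'n_aif' must be >= 1")
  if (ttp_quantile <= 0 || ttp_quantile >= 1 ||
      mtt_quantile <= 0 || mtt_quantile >= 1)
    stopf("screening quantiles must lie in (0, 1)")
  pool <- features$brain_mask & !is.na(features$peak)
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(pool)))
      stopf("'roi_mask' grid does not match the series grid")
    pool <- pool & roi_mask
  }
  idx <- which(pool)
  if (!length(idx)) stopf("no voxels in the AIF candidate pool")
  ttp <- features$ttp[idx]; fm <- features$fm_mtt[idx]
  pk <- features$peak[idx]
  ttp_cut <- stats::quantile(ttp, ttp_quantile, names = FALSE)
  mtt_cut <- stats::quantile(fm, mtt_quantile, names = FALSE)
  cand <- which(ttp <= ttp_cut & fm <= mtt_cut)
  if (!length(cand))
    stopf("no AIF candidates below ttp <= %.3g s and fm_mtt <= %.3g s",
          ttp_cut, mtt_cut)
  saturated <- length(cand) < n_aif
  if (saturated)
    warnf("only %d AIF candidates for n_aif = %d; using all of them",
          length(cand), n_aif)
  ord <- cand[order(-pk[cand], ttp[cand], idx[cand])]
  sel <- ord[seq_len(min(n_aif, length(ord)))]
  sel_idx <- idx[sel]

  med_peak <- stats::median(features$peak[features$brain_mask], na.rm = TRUE)
  if (mean(pk[sel]) < require_peak_ratio * med_peak)
    stopf(paste("selected AIF voxels are not artery-like:",
                "mean peak %.3g < %g x median masked peak %.3g",
                "(is the ROI excluding the artery?)"),
          mean(pk[sel]), require_peak_ratio, med_peak)

  dims <- dim(features$peak)
  mc <- masked_curves(conc)
  pos_in_mask <- match(sel_idx, mc$idx)
  curves <- mc$curves[, pos_in_mask, drop = FALSE]
  structure(list(curve = rowMeans(curves),
                 voxel_ids = which_coords(sel_idx, dims),
                 thresholds_used = list(ttp = ttp_cut, fm_mtt = mtt_cut,
                                        n_aif = n_aif,
                                        saturated = saturated),
                 dt = conc$dt),
            class = "arterial_input_function")
}

# linear indices to (x, y, z) coordinates
which_coords <- function(idx, dims) {
  arr <- arrayInd(idx, dims)
  colnames(arr) <- c("x", "y", "z")
  arr
}

#' @export
print.arterial_input_function <- function(x, ...) {
  cat(sprintf("<arterial_input_function> %d voxels, peak %.3g at frame %d\n",
              nrow(x$voxel_ids), max(x$curve), which.max(x$curve)))
  invisible(x)
}
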