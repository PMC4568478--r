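# Vascular-territory aggregation: regional means over the labelled atlas,
# surgical-to-contralateral relative values, percentage increases.

#' Labelled vascular-territory atlas
#'
#' @param labels 3D integer array of territory labels (0 = background)
#' @param dictionary data.frame with columns \code{label},
#'   \code{territory}, \code{side} ("left", "right" or "other")
#' @return a \code{territory_atlas}
#' @export
territory_atlas <- function(labels, dictionary) {
  if (length(dim(labels)) != 3L) stopf("'labels' must be a 3D array")
  need <- c("label", "territory", "side")
  if (!all(need %in% names(dictionary)))
    stopf("dictionary needs columns: %s", paste(need, collapse = ", "))
  present <- sort(unique(labels[labels > 0]))
  missing <- setdiff(present, dictionary$label)
  if (length(missing))
    stopf("atlas labels without dictionary entry: %s",
          paste(missing, collapse = ", "))
  sided <- dictionary[dictionary$side %in% c("left", "right"), ]
  both <- table(sided$territory)
  if (any(both < 2L))
    stopf("territory not present on both sides: %s",
          paste(names(both)[both < 2L], collapse = ", "))
  structure(list(labels = labels, dictionary = dictionary),
            class = "territory_atlas")
}

#' @export
print.territory_atlas <- function(x, ...) {
  cat(sprintf("<territory_atlas> %s, %d labels\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$dictionary)))
  invisible(x)
}

#' Regional means of the perfusion maps
#'
#' Arithmetic mean of CBF, CBV and MTT over every labelled region; voxels
#' flagged by the deconvolution are excluded so they do not dilute the
#' means.
#'
#' @param maps a \code{perfusion_maps}
#' @param atlas a \code{\link{territory_atlas}} on the same grid
#' @return data.frame: label, territory, side, n_voxels (unflagged), mean
#'   cbf/cbv/mtt
#' @export
regional_means <- function(maps, atlas) {
  stopifnot(inherits(maps, "perfusion_maps"),
            inherits(atlas, "territory_atlas"))
  if (!identical(dim(maps$cbf), dim(atlas$labels)))
    stopf("maps grid %s does not match atlas grid %s",
          paste(dim(maps$cbf), collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  dict <- atlas$dictionary
  out <- dict
  out$n_voxels <- NA_integer_
  out$cbf <- out$cbv <- out$mtt <- NA_real_
  for (i in seq_len(nrow(dict))) {
    sel <- atlas$labels == dict$label[i]
    if (!any(sel)) stopf("empty atlas region: label %d", dict$label[i])
    ok <- sel & !maps$flagged & maps$brain_mask
    out$n_voxels[i] <- sum(ok)
    if (!any(ok)) {
      warnf("all voxels flagged in region '%s %s'; means set to NA",
            dict$side[i], dict$territory[i])
      next
    }
    out$cbf[i] <- mean(maps$cbf[ok])
    out$cbv[i] <- mean(maps$cbv[ok])
    out$mtt[i] <- mean(maps$mtt[ok])
  }
  out
}

#' Surgical-to-contralateral relative parameters
#'
#' For every territory present on both sides, the ratio of the
#' surgical-side regional mean to the contralateral mean, for CBF, CBV and
#' MTT. This removes scanner and calibration scale (hence
#' "semiquantitative" analysis).
#'
#' @param means output of \code{\link{regional_means}}
#' @param surgical_side "left" or "right"
#' @return data.frame: territory, relative_cbf, relative_cbv, relative_mtt
#' @export
relative_parameters <- function(means, surgical_side = c("left", "right")) {
  surgical_side <- match.arg(surgical_side)
  contra <- if (surgical_side == "left") "right" else "left"
  sided <- means[means$side %in% c("left", "right"), ]
  terrs <- unique(sided$territory)
  out <- data.frame(territory = terrs, relative_cbf = NA_real_,
                    relative_cbv = NA_real_, relative_mtt = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(terrs)) {
    s <- sided[sided$territory == terrs[i] & sided$side == surgical_side, ]
    c_ <- sided[sided$territory == terrs[i] & sided$side == contra, ]
    if (nrow(s) != 1L || nrow(c_) != 1L)
      stopf("territory '%s' is not present exactly once per side", terrs[i])
    for (p in c("cbf", "cbv", "mtt")) {
      if (!is.finite(c_[[p]]) || c_[[p]] == 0)
        stopf("zero or missing contralateral %s mean in territory '%s'",
              toupper(p), terrs[i])
      out[[paste0("relative_", p)]][i] <- s[[p]] / c_[[p]]
    }
  }
  out
}

#' Percentage increase between paired measurements
#'
#' Signed definition \code{100 * (intra - pre) / pre}, applied per subject;
#' group-level percentage increases are means of these per-subject values.
#'
#' @param pre,intra paired values; \code{pre} must be positive
#' @return percentage change(s)
#' @export
percent_increase <- function(pre, intra) {
  if (length(pre) != length(intra))
    stopf("'pre' and 'intra' must have equal length")
  if (any(!is.finite(pre)) || any(pre <= 0))
    stopf("'pre' values must be positive and finite")
  100 * (intra - pre) / pre
}
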