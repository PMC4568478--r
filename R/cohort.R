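# Paired pre/intra-operative cohort simulation: a CHS group carrying a
# territory-specific intra-operative CBF increase on the surgical side
# against a non-CHS null, with between-subject variability.

#' Group effect map for the hyperperfusion cohort
#'
#' Fractional intra/pre CBF change applied to the surgical-side territory,
#' per group. The default encodes the designed effect: +14.3 percent at
#' the terminal MCA territory for CHS subjects, no change for non-CHS.
#'
#' @param chs,non_chs named numeric vectors (territory -> fractional
#'   change); unnamed territories default to 0
#' @return list with elements \code{CHS} and \code{non-CHS}
#' @export
chs_effect_map <- function(chs = c("MCA-terminal" = 0.143),
                           non_chs = c("MCA-terminal" = 0)) {
  list(CHS = chs, `non-CHS` = non_chs)
}

#' Cohort design specification
#'
#' @param n_chs,n_nonchs group sizes (default 5 and 9)
#' @param effect_map see \code{\link{chs_effect_map}}
#' @param between_subject_sd SD of the subject-level Gaussian perturbation
#'   added to the fractional effect (default 0.07)
#' @param seed integer seed driving group effects, surgical sides and
#'   per-session phantom seeds
#' @return a \code{cohort_spec}
#' @export
cohort_spec <- function(n_chs = 5L, n_nonchs = 9L,
                        effect_map = chs_effect_map(),
                        between_subject_sd = 0.07, seed = 1L) {
  check_scalar(n_chs, "n_chs", 1)
  check_scalar(n_nonchs, "n_nonchs", 1)
  check_scalar(between_subject_sd, "between_subject_sd", 0)
  check_scalar(seed, "seed")
  stopifnot(is.list(effect_map), all(c("CHS", "non-CHS") %in% names(effect_map)))
  structure(list(n_chs = as.integer(n_chs), n_nonchs = as.integer(n_nonchs),
                 effect_map = effect_map,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw the per-subject design: group, surgical side, per-territory
# fractional intra/pre change (effect + subject perturbation)
draw_cohort_design <- function(cohort, territories) {
  n <- cohort$n_chs + cohort$n_nonchs
  if (n < 1L) stopf("empty cohort")
  with_seed(cohort$seed, {
    design <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = c(rep("CHS", cohort$n_chs), rep("non-CHS", cohort$n_nonchs)),
      surgical_side = sample(c("left", "right"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    eff <- matrix(0, nrow = n, ncol = length(territories),
                  dimnames = list(design$subject_id, territories))
    for (i in seq_len(n)) {
      base <- cohort$effect_map[[design$group[i]]]
      for (terr in territories) {
        mu <- if (terr %in% names(base)) base[[terr]] else 0
        eff[i, terr] <- mu + stats::rnorm(1, 0, cohort$between_subject_sd)
      }
    }
    design$session_seed_pre <- sample.int(.Machine$integer.max, n)
    design$session_seed_intra <- sample.int(.Machine$integer.max, n)
    list(design = design, effects = eff)
  })
}

#' Simulate a paired pre/intra cohort of phantom sessions
#'
#' Every subject gets a pre-operative session built from the base truth
#' table and an intra-operative session in which the surgical-side
#' territory CBF is multiplied by (1 + group effect + subject
#' perturbation); CBV follows through the central volume principle, MTT is
#' unchanged, and the contralateral side is untouched. Image sessions are
#' generated lazily by \code{\link{cohort_session}} to keep memory small.
#'
#' @param cohort a \code{\link{cohort_spec}}
#' @param phantom a \code{\link{phantom_spec}} shared by all sessions
#'   (per-session noise seeds are derived from the cohort seed)
#' @param base_truths truth table common to all pre-operative sessions
#' @return a \code{dsc_cohort}: \code{manifest} (subject_id, group,
#'   surgical_side, session rows), per-subject truth tables, the effect
#'   draws, and the atlas
#' @export
simulate_cohort <- function(cohort, phantom = phantom_spec(),
                            base_truths = default_territory_truths()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(phantom, "phantom_spec"))
  base_truths <- territory_truth_table(base_truths)
  bad <- setdiff(unlist(lapply(cohort$effect_map, names)),
                 unique(base_truths$territory))
  if (length(bad))
    stopf("effect_map names not in the truth table: %s",
          paste(bad, collapse = ", "))
  dd <- draw_cohort_design(cohort, unique(base_truths$territory))
  design <- dd$design

  subject_truths <- lapply(seq_len(nrow(design)), function(i) {
    intra <- base_truths
    side <- design$surgical_side[i]
    for (terr in colnames(dd$effects)) {
      row <- intra$territory == terr & intra$side == side
      intra$cbf[row] <- intra$cbf[row] * (1 + dd$effects[i, terr])
    }
    intra$cbv <- intra$cbf * intra$mtt
    list(pre = base_truths, intra = intra)
  })
  names(subject_truths) <- design$subject_id

  manifest <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    data.frame(subject_id = design$subject_id[i],
               group = design$group[i],
               surgical_side = design$surgical_side[i],
               session = c("pre", "intra"),
               seed = c(design$session_seed_pre[i],
                        design$session_seed_intra[i]),
               stringsAsFactors = FALSE)
  }))
  structure(list(manifest = manifest, subject_truths = subject_truths,
                 effects = dd$effects, phantom = phantom,
                 atlas = build_phantom_atlas(phantom$grid_shape),
                 cohort = cohort),
            class = "dsc_cohort")
}

#' @export
print.dsc_cohort <- function(x, ...) {
  cat(sprintf("<dsc_cohort> %d subjects (%d CHS, %d non-CHS), %d sessions\n",
              length(x$subject_truths), x$cohort$n_chs, x$cohort$n_nonchs,
              nrow(x$manifest)))
  invisible(x)
}

#' Materialise one cohort session as a phantom acquisition
#'
#' @param cohort_obj a \code{dsc_cohort}
#' @param subject_id subject identifier from the manifest
#' @param session "pre" or "intra"
#' @return a phantom session (see \code{\link{simulate_phantom_session}})
#' @export
cohort_session <- function(cohort_obj, subject_id,
                           session = c("pre", "intra")) {
  session <- match.arg(session)
  stopifnot(inherits(cohort_obj, "dsc_cohort"))
  row <- cohort_obj$manifest[cohort_obj$manifest$subject_id == subject_id &
                               cohort_obj$manifest$session == session, ]
  if (nrow(row) != 1L) stopf("unknown session: %s/%s", subject_id, session)
  spec <- cohort_obj$phantom
  spec$seed <- row$seed
  simulate_phantom_session(spec, atlas = cohort_obj$atlas,
                           truths = cohort_obj$subject_truths[[subject_id]][[session]])
}

#' Exact relative-value summaries implied by the cohort ground truth
#'
#' Skips image formation entirely: per subject, session and territory, the
#' relative CBF/CBV/MTT values that a perfect measurement of the sidecar
#' ground truth would produce (pre-operative relative values are 1 under
#' the symmetric base truths; intra-operative surgical-side values carry
#' the drawn effect). Optional Gaussian measurement noise emulates
#' map-level estimation error.
#'
#' @param cohort a \code{\link{cohort_spec}}
#' @param base_truths base truth table
#' @param measurement_sd SD of multiplicative measurement noise added to
#'   every observed relative value (0 = exact)
#' @return long data.frame ready for
#'   \code{\link{build_comparison_tables}}, plus manifest columns
#' @export
simulate_cohort_summaries <- function(cohort,
                                      base_truths = default_territory_truths(),
                                      measurement_sd = 0) {
  base_truths <- territory_truth_table(base_truths)
  terrs <- unique(base_truths$territory)
  dd <- draw_cohort_design(cohort, terrs)
  design <- dd$design
  n <- nrow(design)
  # base surgical/contralateral ratios per territory, for either side
  key <- paste(base_truths$territory, base_truths$side)
  base_rel <- function(param, side) {
    s <- base_truths[[param]][match(paste(terrs, side), key)]
    c_ <- base_truths[[param]][match(paste(terrs,
                                           ifelse(side == "left", "right", "left")), key)]
    s / c_
  }
  grid_t <- rep(seq_along(terrs), times = n)   # territory fastest
  grid_s <- rep(seq_len(n), each = length(terrs))
  side <- design$surgical_side[grid_s]
  left <- side == "left"
  pick <- function(param) {
    ifelse(left, base_rel(param, "left")[grid_t],
           base_rel(param, "right")[grid_t])
  }
  eff <- dd$effects[cbind(grid_s, grid_t)]
  pre <- data.frame(subject_id = design$subject_id[grid_s],
                    group = design$group[grid_s], surgical_side = side,
                    session = "pre", territory = terrs[grid_t],
                    relative_cbf = pick("cbf"), relative_cbv = pick("cbv"),
                    relative_mtt = pick("mtt"), stringsAsFactors = FALSE)
  intra <- pre
  intra$session <- "intra"
  # the surgical-side CBF effect carries to CBV (MTT unchanged)
  intra$relative_cbf <- pre$relative_cbf * (1 + eff)
  intra$relative_cbv <- pre$relative_cbv * (1 + eff)
  out <- rbind(pre, intra)
  if (measurement_sd > 0) {
    m <- nrow(out)
    nz <- with_seed(cohort$seed + 1L, stats::rnorm(3L * m, 0, measurement_sd))
    out$relative_cbf <- out$relative_cbf * (1 + nz[seq_len(m)])
    out$relative_cbv <- out$relative_cbv * (1 + nz[m + seq_len(m)])
    out$relative_mtt <- out$relative_mtt * (1 + nz[2L * m + seq_len(m)])
  }
  rownames(out) <- NULL
  out
}
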