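# Group statistics: paired and independent two-sided t-tests,
# Benjamini-Hochberg FDR control, and the three-parameter comparison
# tables (one per perfusion parameter).

#' Two-tailed paired Student's t-test
#'
#' Thin wrapper around \code{stats::t.test} on the per-subject differences
#' \code{intra - pre}, with explicit handling of the degenerate
#' zero-variance cases: identical pairs give t = 0, p = 1 (exact tie); a
#' constant non-zero difference has no finite t statistic and is reported
#' as not computable.
#'
#' @param pre,intra paired per-subject values (equal length, n >= 2)
#' @return list: \code{t}, \code{p}, \code{df}, \code{n}, \code{note}
#' @export
paired_ttest <- function(pre, intra) {
  n <- length(pre)
  if (length(intra) != n) stopf("'pre' and 'intra' must be paired")
  if (n < 2L) stopf("paired test needs n >= 2")
  d <- intra - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = n - 1L, n = n, note = "exact tie"))
    return(list(t = NA_real_, p = NA_real_, df = n - 1L, n = n,
                note = "zero-variance differences"))
  }
  ht <- stats::t.test(intra, pre, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = n, note = NULL)
}

#' Two-tailed independent-sample t-test
#'
#' Pooled-variance Student's test by default (\code{equal_var = TRUE});
#' Welch's correction is available as a flag. Groups that are both
#' constant are degenerate: equal constants give t = 0, p = 1, otherwise
#' the test is reported as not computable.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2
#' @param equal_var pool the variances (Student) or not (Welch)
#' @return list: \code{t}, \code{p}, \code{df}, \code{n}, \code{note}
#' @export
independent_ttest <- function(group_a, group_b, equal_var = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs n >= 2")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1, df = NA_real_,
                  n = c(length(group_a), length(group_b)),
                  note = "exact tie"))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n = c(length(group_a), length(group_b)),
                note = "zero variance in both groups"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = equal_var)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       n = c(length(group_a), length(group_b)), note = NULL)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Adjusted p-values via \code{stats::p.adjust(method = "BH")}; the
#' rejection set (adjusted p <= q) is identical to the classical step-up
#' rule: sort ascending, find the largest k with p(k) <= k q / m, reject
#' ranks 1..k. NA entries are excluded from the family (m counts only
#' non-missing tests) and stay NA.
#'
#' @param p_values raw p-values in [0, 1] (NA allowed)
#' @param q false discovery rate in (0, 1)
#' @return list: logical \code{reject}, numeric \code{adjusted}, \code{q},
#'   family size \code{m}
#' @export
benjamini_hochberg <- function(p_values, q = 0.2) {
  if (q <= 0 || q >= 1) stopf("'q' must be in (0, 1)")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  adjusted <- rep(NA_real_, length(p_values))
  adjusted[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(reject = !is.na(adjusted) & adjusted <= q, adjusted = adjusted,
       q = q, m = sum(ok))
}

# territories in the row order of the published tables
table_territories <- function() {
  c("ACA-terminal", "ACA-central", "MCA-terminal", "MCA-central",
    "PCA-terminal")
}

#' Cohort comparison tables (one per perfusion parameter)
#'
#' From per-subject, per-session relative values, builds the three
#' parameter tables of the analysis: for each territory, group means of
#' the pre and intra relative values, the mean per-subject percentage
#' increase, the paired pre-vs-intra p-value (all patients and per group),
#' and across-group (CHS vs non-CHS) independent tests on the intra values
#' and on the percentage increases. BH correction is applied per parameter
#' over the family of 15 p-values (5 territories x paired-all /
#' intra-across / increase-across).
#'
#' @param summaries long data.frame with columns subject_id, group ("CHS"
#'   or "non-CHS"), session ("pre" or "intra"), territory, relative_cbf,
#'   relative_cbv, relative_mtt
#' @param q FDR level for the BH correction
#' @param equal_var pooled-variance across-group tests (see
#'   \code{\link{independent_ttest}})
#' @return a \code{cohort_result}: \code{tables} (list of three
#'   table-shaped data.frames), \code{stats} (long machine-readable
#'   data.frame with raw and adjusted p-values and rejection flags),
#'   \code{q}
#' @export
build_comparison_tables <- function(summaries, q = 0.2, equal_var = TRUE) {
  need <- c("subject_id", "group", "session", "territory",
            "relative_cbf", "relative_cbv", "relative_mtt")
  if (!all(need %in% names(summaries)))
    stopf("summaries must have columns: %s", paste(need, collapse = ", "))
  subjects <- unique(summaries$subject_id)
  for (s in subjects) {
    ses <- summaries$session[summaries$subject_id == s]
    if (!all(c("pre", "intra") %in% ses))
      stopf("subject '%s' is missing a pre or intra session", s)
  }
  terrs <- intersect(table_territories(), unique(summaries$territory))
  params <- c("cbf", "cbv", "mtt")
  groups <- list(All = subjects,
                 CHS = unique(summaries$subject_id[summaries$group == "CHS"]),
                 `non-CHS` = unique(summaries$subject_id[summaries$group == "non-CHS"]))

  grab <- function(param, terr, session, subj) {
    col <- paste0("relative_", param)
    rows <- summaries[summaries$territory == terr &
                        summaries$session == session &
                        summaries$subject_id %in% subj, ]
    rows <- rows[match(intersect(subj, rows$subject_id), rows$subject_id), ]
    stats::setNames(rows[[col]], rows$subject_id)
  }
  safe_paired <- function(pre, intra) {
    if (length(pre) < 2L)
      return(list(t = NA_real_, p = NA_real_, note = "single subject"))
    paired_ttest(pre, intra)
  }
  safe_indep <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
      return(list(t = NA_real_, p = NA_real_, note = "single-subject group"))
    independent_ttest(a, b, equal_var = equal_var)
  }

  tables <- list()
  stats_rows <- list()
  for (param in params) {
    tab <- data.frame()
    fam <- list()   # BH family for this parameter
    for (terr in terrs) {
      cells <- list()
      for (g in names(groups)) {
        pre <- grab(param, terr, "pre", groups[[g]])
        intra <- grab(param, terr, "intra", groups[[g]])
        pct <- percent_increase(pre, intra)
        pp <- safe_paired(pre, intra)
        cells[[g]] <- list(pre = mean(pre), intra = mean(intra),
                           pct = mean(pct), p_paired = pp$p)
      }
      chs_intra <- grab(param, terr, "intra", groups$CHS)
      non_intra <- grab(param, terr, "intra", groups$`non-CHS`)
      chs_pct <- percent_increase(grab(param, terr, "pre", groups$CHS),
                                  chs_intra)
      non_pct <- percent_increase(grab(param, terr, "pre", groups$`non-CHS`),
                                  non_intra)
      p_intra_across <- safe_indep(chs_intra, non_intra)$p
      p_pct_across <- safe_indep(chs_pct, non_pct)$p
      fam[[terr]] <- c(paired_all = cells$All$p_paired,
                       intra_across = p_intra_across,
                       pct_across = p_pct_across)
      tab <- rbind(tab, data.frame(
        territory = terr,
        quantity = c("Pre", "Intra", "%increase", "P-value (Pre vs Intra)"),
        all = c(cells$All$pre, cells$All$intra, cells$All$pct,
                cells$All$p_paired),
        chs = c(cells$CHS$pre, cells$CHS$intra, cells$CHS$pct,
                cells$CHS$p_paired),
        non_chs = c(cells$`non-CHS`$pre, cells$`non-CHS`$intra,
                    cells$`non-CHS`$pct, cells$`non-CHS`$p_paired),
        p_across = c(NA, p_intra_across, p_pct_across, NA),
        stringsAsFactors = FALSE))
    }
    pvec <- unlist(fam)
    bh <- benjamini_hochberg(pvec, q)
    stats_rows[[param]] <- data.frame(
      parameter = param,
      territory = rep(names(fam), each = 3L),
      test = rep(c("paired_all", "intra_across", "pct_across"),
                 times = length(fam)),
      p = unname(pvec), p_adjusted = unname(bh$adjusted),
      significant = unname(bh$reject),
      stringsAsFactors = FALSE)
    tables[[param]] <- tab
  }
  structure(list(tables = tables,
                 stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
                 q = q,
                 n_chs = length(groups$CHS), n_nonchs = length(groups$`non-CHS`)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d CHS vs %d non-CHS; %d tests/parameter, FDR q = %g\n",
              x$n_chs, x$n_nonchs, nrow(x$stats) / length(x$tables), x$q))
  sig <- x$stats[x$stats$significant %in% TRUE, ]
  if (nrow(sig)) {
    cat("significant after BH:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s %s %s (p = %.4f, adj %.4f)\n", sig$parameter[i],
                  sig$territory[i], sig$test[i], sig$p[i], sig$p_adjusted[i]))
  } else cat("no test significant after BH\n")
  invisible(x)
}
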