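# Validation experiments: parameter-recovery and delay-sensitivity studies
# on synthetic curves, power and type-I calibration on simulated cohorts.
# These are the quantitative checks behind the package's accuracy claims;
# the analysis scripts, test suite and acceptance script all call them.

#' Curve-level parameter recovery experiment
#'
#' For every (CBF, MTT) pair: simulate the tissue curve from the default
#' gamma-variate bolus, optionally pass it through the signal equation with
#' Gaussian noise at the given baseline SNR, convert back to
#' concentration, deconvolve, and extract parameters. Noise-free runs are
#' exact up to the singular-value truncation, so they default to an
#' effectively unregularised pseudoinverse; noisy runs should use the
#' clinical default truncation.
#'
#' @param cbf,mtt grids of ground-truth values (nominal flow units, s)
#' @param mode,truncation deconvolution settings
#' @param snr baseline signal-to-noise ratio s0/noise_sd; \code{Inf} for
#'   noise-free
#' @param n_rep noisy replicates per grid cell
#' @param seed RNG seed for the noise draws
#' @param n_frames,dt,te,s0,k,flow_scale,aif_params forward-model settings
#' @return data.frame with truth, estimates and relative errors per
#'   replicate
#' @export
recovery_experiment <- function(cbf = c(20, 40, 60, 80),
                                mtt = c(3, 4.5, 6, 12),
                                mode = "circulant",
                                truncation = if (is.infinite(snr)) 1e-6 else NULL,
                                snr = Inf, n_rep = 1L, seed = 1L,
                                n_frames = 60L, dt = 1.5, te = 0.03,
                                s0 = 100, k = 1,
                                flow_scale = dsc_flow_scale(),
                                aif_params = default_aif_params()) {
  t <- time_axis(n_frames, dt)
  aif <- do.call(gamma_variate_aif, c(list(t = t), aif_params))
  system <- build_convolution_matrix(aif, dt = dt, mode = mode,
                                     truncation = truncation)
  grid <- expand.grid(cbf = cbf, mtt = mtt)
  noise_sd <- if (is.infinite(snr)) 0 else s0 / snr
  if (noise_sd == 0) n_rep <- 1L
  with_seed(seed, {
    out <- lapply(seq_len(nrow(grid)), function(i) {
      curve <- simulate_tissue_curve(aif, grid$cbf[i], grid$mtt[i], dt,
                                     flow_scale = flow_scale)
      reps <- lapply(seq_len(n_rep), function(r) {
        cc <- curve
        if (noise_sd > 0) {
          sig <- s0 * exp(-k * te * curve) + stats::rnorm(n_frames, 0, noise_sd)
          sig <- pmax(sig, 0.01 * s0)
          cc <- -log(sig / s0) / (k * te)
        }
        res <- svd_deconvolve(system, cc)
        pp <- perfusion_parameters(res, flow_scale = flow_scale)
        data.frame(cbf_true = grid$cbf[i], mtt_true = grid$mtt[i], rep = r,
                   cbf_hat = pp$cbf, mtt_hat = pp$mtt,
                   cbf_rel_err = pp$cbf / grid$cbf[i] - 1,
                   mtt_rel_err = pp$mtt / grid$mtt[i] - 1)
      })
      do.call(rbind, reps)
    })
    do.call(rbind, out)
  })
}

#' Bolus-delay sensitivity of the two deconvolution modes
#'
#' The tissue curve is shifted later by whole frames relative to the AIF
#' and deconvolved in simple (truncated lower-triangular) and circulant
#' mode at their clinical truncations. Reports the flow estimate per delay
#' and mode; the circulant estimate should be delay-invariant while the
#' simple-mode estimate degrades.
#'
#' @param delays_frames integer frame shifts applied to the tissue curve
#' @param cbf,mtt ground truth of the test curve
#' @param truncation_simple,truncation_circulant singular-value cutoffs
#' @param n_frames,dt,flow_scale,aif_params forward-model settings
#' @return data.frame: delay_frames, cbf_simple, cbf_circulant
#' @export
delay_experiment <- function(delays_frames = 0:3, cbf = 60, mtt = 4.5,
                             truncation_simple = 0.2,
                             truncation_circulant = NULL,
                             n_frames = 60L, dt = 1.5,
                             flow_scale = dsc_flow_scale(),
                             aif_params = default_aif_params()) {
  t <- time_axis(n_frames, dt)
  aif <- do.call(gamma_variate_aif, c(list(t = t), aif_params))
  sys_s <- build_convolution_matrix(aif, dt = dt, mode = "simple",
                                    truncation = truncation_simple)
  sys_c <- build_convolution_matrix(aif, dt = dt, mode = "circulant",
                                    truncation = truncation_circulant)
  base <- simulate_tissue_curve(aif, cbf, mtt, dt, flow_scale = flow_scale)
  est <- function(system, curve)
    perfusion_parameters(svd_deconvolve(system, curve),
                         flow_scale = flow_scale)$cbf
  out <- lapply(delays_frames, function(kk) {
    curve <- if (kk > 0) c(numeric(kk), base)[seq_len(n_frames)] else base
    data.frame(delay_frames = kk, delay_s = kk * dt,
               cbf_simple = est(sys_s, curve),
               cbf_circulant = est(sys_c, curve))
  })
  do.call(rbind, out)
}

#' Power of the across-group percentage-increase test
#'
#' Repeatedly simulates cohort summaries under the designed effect,
#' builds the comparison tables, and records whether the across-group
#' percentage-increase test at the target territory rejects at
#' \code{alpha}, and which territory is most significant on that test.
#'
#' @param n_rep number of simulated cohorts
#' @param cohort a \code{\link{cohort_spec}} (the designed-effect default)
#' @param target territory carrying the designed effect
#' @param alpha rejection level for the raw p-value
#' @param seed base RNG seed; replicate r uses \code{seed + r}
#' @return list: \code{power}, \code{modal_territory},
#'   \code{modal_share}, per-replicate data.frame \code{detail}
#' @export
power_experiment <- function(n_rep = 200L, cohort = cohort_spec(),
                             target = "MCA-terminal", alpha = 0.05,
                             seed = 1L) {
  detail <- lapply(seq_len(n_rep), function(r) {
    cs <- cohort
    cs$seed <- seed + r
    summ <- simulate_cohort_summaries(cs)
    res <- build_comparison_tables(summ)
    st <- res$stats[res$stats$parameter == "cbf" &
                      res$stats$test == "pct_across", ]
    data.frame(rep = r, p_target = st$p[st$territory == target],
               most_significant = st$territory[which.min(st$p)])
  })
  detail <- do.call(rbind, detail)
  tab <- table(detail$most_significant)
  list(power = mean(detail$p_target < alpha),
       modal_territory = names(tab)[which.max(tab)],
       modal_share = max(tab) / n_rep,
       detail = detail)
}

#' Type-I error calibration under a null cohort
#'
#' Simulates cohorts with zero group effect (between-subject variability
#' only), applies the three raw test types per territory, and reports the
#' rejection rate of each test type at \code{alpha}, pooled over
#' territories (the per-territory draws are independent).
#'
#' @param n_rep number of simulated null cohorts
#' @param cohort a null \code{\link{cohort_spec}} (all effects 0)
#' @param alpha nominal level
#' @param seed base RNG seed
#' @return list with per-test-type rejection rates and the trial count
#' @export
null_calibration <- function(n_rep = 1000L,
                             cohort = cohort_spec(effect_map =
                               chs_effect_map(chs = c("MCA-terminal" = 0))),
                             alpha = 0.05, seed = 1L) {
  rates <- matrix(0, nrow = 0, ncol = 3,
                  dimnames = list(NULL, c("paired_all", "intra_across",
                                          "pct_across")))
  for (r in seq_len(n_rep)) {
    cs <- cohort
    cs$seed <- seed + r
    summ <- simulate_cohort_summaries(cs)
    for (terr in unique(summ$territory)) {
      s <- summ[summ$territory == terr, ]
      pre <- s$relative_cbf[s$session == "pre"]
      intra <- s$relative_cbf[s$session == "intra"]
      names(pre) <- s$subject_id[s$session == "pre"]
      intra <- intra[match(names(pre), s$subject_id[s$session == "intra"])]
      grp <- s$group[match(names(pre), s$subject_id)]
      pct <- percent_increase(pre, intra)
      p1 <- paired_ttest(pre, intra)$p
      p2 <- independent_ttest(intra[grp == "CHS"], intra[grp == "non-CHS"])$p
      p3 <- independent_ttest(pct[grp == "CHS"], pct[grp == "non-CHS"])$p
      rates <- rbind(rates, c(p1, p2, p3) < alpha)
    }
  }
  list(rates = colMeans(rates), n_trials = nrow(rates), alpha = alpha)
}
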