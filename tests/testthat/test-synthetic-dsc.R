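# Forward model: gamma-variate bolus, tissue convolution, phantom sessions.

test_that("gamma-variate bolus has the analytic shape", {
  t <- seq(0, 60, by = 0.01)
  # zero bolus
  expect_equal(gamma_variate_aif(t, amplitude = 0), numeric(length(t)))
  # zero before arrival, nonnegative, single-peaked at t0 + alpha*beta
  curve <- gamma_variate_aif(t, t0 = 10, alpha = 3, beta = 1.5, amplitude = 5)
  expect_true(all(curve[t <= 10] == 0))
  expect_true(all(curve >= 0))
  expect_equal(t[which.max(curve)], 14.5, tolerance = 0.011)
  d <- diff(curve[t > 10])
  turn <- which(d < 0)[1]
  expect_true(all(d[seq_len(turn - 1L)] >= 0))   # rises once...
  expect_true(all(d[turn:length(d)] <= 0))       # ...then falls
  # exact linearity in amplitude
  expect_identical(gamma_variate_aif(t, amplitude = 2),
                   2 * gamma_variate_aif(t, amplitude = 1))
  expect_error(gamma_variate_aif(t, alpha = 0), "alpha")
  expect_error(gamma_variate_aif(t, beta = -1), "beta")
})

test_that("tissue curve follows the convolution model", {
  n <- 60L; dt <- 1.5
  aif <- default_aif_curve(n, dt)
  # no flow, no signal
  expect_equal(simulate_tissue_curve(aif, 0, 4, dt), numeric(n))
  # impulse-residue limit: with MTT far below the bolus time scale (but
  # still resolved by the sampling), C approaches F * MTT * AIF pointwise;
  # the comparison needs fine dt because the limit is a continuous-time one
  dt_f <- 5e-5
  tf <- (seq_len(600000L) - 1L) * dt_f
  aif_f <- gamma_variate_aif(tf, amplitude = 1)
  cf <- simulate_tissue_curve(aif_f, 10, 0.005, dt_f)
  sel <- aif_f > 0.3
  expect_lt(max(abs(cf[sel] / (10 * 0.005 * aif_f[sel]) - 1)), 0.012)
  # integral identity: area(Cv)/area(AIF) = F * MTT (central volume),
  # oracle = trapezoidal quadrature of both sides on a long, finely
  # sampled window (the residue sampling bias vanishes as dt -> 0)
  for (mtt in c(3, 6, 12)) {
    dt_q <- 0.05
    aif_l <- gamma_variate_aif((seq_len(4000L) - 1L) * dt_q)
    cv <- simulate_tissue_curve(aif_l, 42, mtt, dt_q)
    ratio <- trapz_area(cv, dt_q) / trapz_area(aif_l, dt_q)
    expect_equal(ratio, 42 * mtt, tolerance = 0.02)
  }
  expect_error(simulate_tissue_curve(aif, -1, 4, dt))
  expect_error(simulate_tissue_curve(aif, 10, 0, dt))
})

test_that("noise-free phantom signal is exactly invertible", {
  spec <- small_spec(seed = 3, noise_sd = 0)
  ses <- simulate_phantom_session(spec)
  # pre-bolus frames are pure baseline
  expect_equal(ses$series$data[, , , 1:8],
               array(ifelse(ses$atlas$labels > 0, spec$s0, 0),
                     dim = c(spec$grid_shape, 8L)))
  # zero tissue concentration, zero noise: constant s0 in all tissue
  # (the artery label still carries its bolus)
  flat <- simulate_phantom_session(
    spec, truths = within(ses$truths, cbf <- cbf * 0 + 1e-12))
  tissue <- flat$atlas$labels %in% 1:10
  expect_lt(max(abs(flat$series$data[rep(tissue, spec$n_frames)] - spec$s0)),
            1e-6)
  # round-trip signal -> concentration recovers C(t) to 1e-10
  bl <- estimate_baseline(ses$series)
  conc <- signal_to_concentration(ses$series, bl)
  idx <- which(ses$atlas$labels == 4L)[1]        # an MCA-terminal voxel
  coords <- arrayInd(idx, spec$grid_shape)
  truth_row <- ses$truths[ses$truths$label == 4L, ]
  expected <- simulate_tissue_curve(ses$aif, truth_row$cbf, truth_row$mtt,
                                    spec$dt, flow_scale = ses$flow_scale)
  got <- conc$data[coords[1], coords[2], coords[3], ]
  expect_lt(max(abs(got - expected)) / max(expected), 1e-10)
})

test_that("phantom generation is seed-deterministic", {
  a <- simulate_phantom_session(small_spec(seed = 17, noise_sd = 2))
  b <- simulate_phantom_session(small_spec(seed = 17, noise_sd = 2))
  expect_identical(a$series$data, b$series$data)
  c <- simulate_phantom_session(small_spec(seed = 18, noise_sd = 2))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("sidecar obeys the central volume principle and linearity", {
  truths <- default_territory_truths()
  expect_identical(truths$cbv, truths$cbf * truths$mtt)
  # scaling all flows scales every noise-free tissue curve pointwise
  aif <- default_aif_curve()
  for (i in c(1L, 4L)) {
    base <- simulate_tissue_curve(aif, truths$cbf[i], truths$mtt[i], 1.5)
    scaled <- simulate_tissue_curve(aif, 3 * truths$cbf[i], truths$mtt[i], 1.5)
    expect_equal(scaled, 3 * base)
  }
  expect_error(territory_truth_table(within(truths, cbf[2] <- -1)), "cbf")
  expect_error(territory_truth_table(within(truths, mtt[2] <- 0)), "mtt")
})

test_that("phantom session validates atlas and truth coverage", {
  spec <- small_spec()
  atlas <- build_phantom_atlas(spec$grid_shape)
  truths <- default_territory_truths()
  expect_error(
    simulate_phantom_session(spec, atlas = build_phantom_atlas(c(8L, 8L, 4L))),
    "grid")
  expect_error(
    simulate_phantom_session(spec, truths = truths[truths$label != 4L, ]),
    "label")
})

test_that("cohort construction matches its design arithmetic", {
  # null cohort with no variability: pre and intra truths identical
  null_c <- cohort_spec(n_chs = 2, n_nonchs = 2,
                        effect_map = chs_effect_map(chs = c("MCA-terminal" = 0)),
                        between_subject_sd = 0, seed = 5)
  co <- simulate_cohort(null_c, small_spec())
  for (s in names(co$subject_truths))
    expect_identical(co$subject_truths[[s]]$pre, co$subject_truths[[s]]$intra)
  # designed effect, sd = 0: surgical-side sidecar ratio exactly 1.143
  eff <- cohort_spec(n_chs = 2, n_nonchs = 2, between_subject_sd = 0, seed = 5)
  co2 <- simulate_cohort(eff, small_spec())
  man <- co2$manifest
  for (s in unique(man$subject_id)) {
    side <- man$surgical_side[man$subject_id == s][1]
    grp <- man$group[man$subject_id == s][1]
    tr <- co2$subject_truths[[s]]
    i_mca <- tr$pre$territory == "MCA-terminal" & tr$pre$side == side
    expected <- if (grp == "CHS") 1.143 else 1
    expect_equal(tr$intra$cbf[i_mca] / tr$pre$cbf[i_mca], expected)
    contra <- tr$pre$territory == "MCA-terminal" & tr$pre$side != side &
      tr$pre$side != "other"
    expect_equal(tr$intra$cbf[contra], tr$pre$cbf[contra])
  }
  # default design: 14 subjects, 28 sessions
  co3 <- simulate_cohort(cohort_spec(seed = 1), small_spec())
  expect_length(co3$subject_truths, 14L)
  expect_identical(nrow(co3$manifest), 28L)
  expect_error(cohort_spec(n_chs = 0), "n_chs")
})

test_that("cohort summaries mirror the sidecar exactly", {
  cs <- cohort_spec(n_chs = 3, n_nonchs = 3, between_subject_sd = 0, seed = 9)
  summ <- simulate_cohort_summaries(cs)
  mca <- summ[summ$territory == "MCA-terminal", ]
  expect_true(all(mca$relative_cbf[mca$session == "pre"] == 1))
  expect_equal(mca$relative_cbf[mca$session == "intra" & mca$group == "CHS"],
               rep(1.143, 3))
  expect_equal(mca$relative_cbf[mca$session == "intra" & mca$group == "non-CHS"],
               rep(1, 3))
  expect_true(all(summ$relative_mtt == 1))
  expect_equal(summ$relative_cbv, summ$relative_cbf)
})
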