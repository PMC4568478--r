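# Convolution operators, truncated-SVD inversion, parameter extraction.

test_that("simple operator is the discrete convolution sum", {
  # delta AIF at frame 0, dt = 1: the operator is the identity
  delta <- c(1, numeric(9))
  sys <- build_convolution_matrix(delta, dt = 1, mode = "simple")
  expect_equal(sys$matrix, diag(10))
  # random instances against the brute-force summation oracle
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    aif <- abs(rnorm(n)); x <- rnorm(n); dt <- runif(1, 0.5, 2)
    sys <- build_convolution_matrix(aif, dt = dt, mode = "simple")
    expect_equal(as.vector(sys$matrix %*% x), direct_convolution(aif, x, dt),
                 tolerance = 1e-12)
  }
})

test_that("circulant operator is a cyclic embedding of the padded AIF", {
  aif <- abs(rnorm(12)) + 0.1
  sys <- build_convolution_matrix(aif, dt = 1.5, mode = "circulant")
  expect_identical(dim(sys$matrix), c(24L, 24L))
  # every column sums to dt * sum(AIF)
  expect_equal(unname(colSums(sys$matrix)), rep(1.5 * sum(aif), 24))
  # first column is the zero-padded AIF
  expect_equal(sys$matrix[, 1], c(aif, numeric(12)) * 1.5)
  expect_error(build_convolution_matrix(aif, dt = 1.5, mode = "circulant",
                                        pad_length = 4), "pad_length")
  expect_error(build_convolution_matrix(aif, dt = 1.5, truncation = 0), "truncation")
})

test_that("identity system inverts exactly and degenerate AIFs fail loudly", {
  delta <- c(1, numeric(19))
  sys <- build_convolution_matrix(delta, dt = 1, mode = "simple")
  x <- rnorm(20)
  expect_equal(svd_deconvolve(sys, x)$values, x)
  expect_error(svd_deconvolve(sys, x[1:5]), "length")
  expect_error(
    svd_deconvolve(sys, x, truncation = 1 - 1e-12) -> res,
    NA)  # threshold just below the top singular value still keeps one mode
  sys2 <- build_convolution_matrix(c(1, 1e-9, numeric(18)), dt = 1)
  expect_silent(svd_deconvolve(sys2, x))
})

test_that("noise-free deconvolution recovers flow in both modes", {
  n <- 60L; dt <- 1.5
  aif <- default_aif_curve(n, dt)
  curve <- simulate_tissue_curve(aif, 60, 4.5, dt, flow_scale = 1 / 300)
  for (mode in c("simple", "circulant")) {
    sys <- build_convolution_matrix(aif, dt = dt, mode = mode,
                                    truncation = 1e-6)
    pp <- perfusion_parameters(svd_deconvolve(sys, curve),
                               flow_scale = 1 / 300)
    expect_equal(pp$cbf, 60, tolerance = 0.02)
    expect_equal(pp$mtt, 4.5, tolerance = 0.05)
  }
})

test_that("delayed boluses separate the two modes", {
  d <- delay_experiment(delays_frames = 0:3)
  # circulant flow estimate is delay-insensitive
  expect_lt(max(abs(d$cbf_circulant / d$cbf_circulant[1] - 1)), 0.05)
  # at a 3-frame delay the simple-mode estimate sits strictly below the
  # circulant one (the classic truncated-sSVD delay penalty)
  expect_lt(d$cbf_simple[4], d$cbf_circulant[4])
  # and below its own zero-delay value for every tested delay
  expect_true(all(d$cbf_simple[-1] < d$cbf_simple[1]))
})

test_that("perfusion parameters follow the stated conventions", {
  # geometric residue, rectangle quadrature: plain discrete-sum arithmetic
  fr <- 2 * 0.5^(0:59)
  pp <- perfusion_parameters(fr, dt = 1, quadrature = "rectangle")
  expect_equal(pp$cbf, 2)
  expect_equal(pp$cbv, 4)
  expect_equal(pp$mtt, 2)
  # trapezoid quadrature subtracts the half-weights at the ends
  pt <- perfusion_parameters(fr, dt = 1, quadrature = "trapezoid")
  expect_equal(pt$cbv, 4 - (2 + fr[60]) / 2)
  # all-zero residue: flagged, all parameters zero
  p0 <- perfusion_parameters(numeric(30), dt = 1)
  expect_true(p0$flagged)
  expect_identical(c(p0$cbf, p0$cbv, p0$mtt), c(0, 0, 0))
  expect_error(perfusion_parameters(c(1, NA), dt = 1), "finite")
  # negative excursions are zeroed for the area but not for the peak
  fr2 <- c(1, -0.4, 0.5, numeric(27))
  pn <- perfusion_parameters(fr2, dt = 1, quadrature = "rectangle")
  expect_equal(pn$cbf, 1)
  expect_equal(pn$cbv, 1.5)
})

test_that("map computation is uniform on uniform tissue and respects the mask", {
  spec <- small_spec(seed = 12, noise_sd = 0)
  truths <- default_territory_truths()
  truths$cbf[] <- 50; truths$mtt[] <- 5
  ses <- simulate_phantom_session(spec, truths = territory_truth_table(truths))
  conc <- signal_to_concentration(ses$series, estimate_baseline(ses$series))
  f <- compute_curve_features(conc)
  aif <- select_aif_voxels(conc, f)
  maps <- compute_maps(conc, aif, truncation = 1e-6)
  tissue <- ses$atlas$labels %in% 1:10
  expect_lt(diff(range(maps$cbf[tissue])) / mean(maps$cbf[tissue]), 0.01)
  expect_true(all(maps$cbf[!conc$brain_mask] == 0))
  expect_true(all(maps$cbv[!conc$brain_mask] == 0))
})

test_that("two-territory flow ratio survives the full map pipeline", {
  spec <- small_spec(seed = 13, noise_sd = 0)
  truths <- default_territory_truths()
  truths$mtt[] <- 5
  truths$cbf[] <- 30
  truths$cbf[truths$territory == "MCA-terminal"] <- 60  # 2:1 vs the rest
  ses <- simulate_phantom_session(spec, truths = territory_truth_table(truths))
  conc <- signal_to_concentration(ses$series, estimate_baseline(ses$series))
  aif <- select_aif_voxels(conc, compute_curve_features(conc))
  maps <- compute_maps(conc, aif, truncation = 1e-6)
  m <- regional_means(maps, ses$atlas)
  hi <- m$cbf[m$territory == "MCA-terminal" & m$side == "left"]
  lo <- m$cbf[m$territory == "PCA-terminal" & m$side == "left"]
  expect_equal(hi / lo, 2, tolerance = 0.03)
})

test_that("parameter recovery holds over the physiological grid", {
  r <- recovery_experiment()   # noise-free, unregularised
  expect_lt(max(abs(r$cbf_rel_err)), 0.05)
  expect_lt(max(abs(r$mtt_rel_err)), 0.05)
})

test_that("central volume identity is exact on every unflagged voxel", {
  ses <- simulate_phantom_session(small_spec(seed = 14, noise_sd = 2))
  conc <- signal_to_concentration(ses$series, estimate_baseline(ses$series))
  aif <- select_aif_voxels(conc, compute_curve_features(conc))
  maps <- compute_maps(conc, aif)
  ok <- maps$cbf > 0
  expect_lt(max(abs(maps$cbv[ok] - maps$cbf[ok] * maps$mtt[ok])) /
              max(maps$cbv[ok]), 1e-12)
})
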