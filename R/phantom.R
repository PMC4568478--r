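# Digital DSC-MRI phantom: territory-labelled brain, gamma-variate bolus,
# exponential residue tissue model, multiplicative T2* signal formation.

#' Flow-to-concentration unit scale
#'
#' Nominal tissue flow values are carried in conventional mL/100g/min
#' magnitudes (tens of units). The forward model multiplies them by this
#' fixed constant so that the simulated tissue signal drop matches what a
#' clinical double-dose (0.2 mmol/kg) DSC acquisition shows (peak tissue
#' attenuation around 20--70 percent, arterial attenuation deeper). Map
#' reconstruction divides by the same constant, so reported CBF is on the
#' nominal input scale; relative (side-to-side) values are unaffected by it.
#'
#' @return the scalar conversion constant
#' @export
dsc_flow_scale <- function() 1 / 300

#' Phantom acquisition specification
#'
#' @param grid_shape integer vector of 3 voxel dimensions
#' @param n_frames number of time frames (at least 20)
#' @param dt frame interval in seconds (sampling interval of the
#'   discretized convolution)
#' @param te echo time in seconds
#' @param s0 baseline signal, arbitrary units
#' @param noise_sd Gaussian noise standard deviation on the signal, same
#'   units as \code{s0}
#' @param seed integer seed; identical seeds give bit-identical phantoms
#' @return a \code{phantom_spec} object
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 10L), n_frames = 60L,
                         dt = 1.5, te = 0.03, s0 = 100, noise_sd = 2,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stopf("'grid_shape' must be 3 dimensions, each >= 4")
  check_scalar(n_frames, "n_frames", 20)
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(te, "te", 0, strict = TRUE)
  check_scalar(s0, "s0", 0, strict = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(seed, "seed")
  structure(list(grid_shape = as.integer(grid_shape),
                 n_frames = as.integer(n_frames), dt = dt, te = te,
                 s0 = s0, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gamma-variate arterial bolus curve
#'
#' \eqn{AIF(t) = A \, ((t-t_0)/(\alpha\beta))^\alpha \exp(\alpha - (t-t_0)/\beta)}
#' for \eqn{t > t_0}, zero before. Normalised so the peak value is
#' \code{amplitude}, attained at \eqn{t_0 + \alpha\beta}.
#'
#' @param t time points, seconds
#' @param t0 bolus arrival time, seconds
#' @param alpha shape parameter (> 0)
#' @param beta time-scale parameter, seconds (> 0)
#' @param amplitude peak concentration, arbitrary units
#' @return concentration at each \code{t}
#' @export
gamma_variate_aif <- function(t, t0 = 15, alpha = 3, beta = 1.5,
                              amplitude = 90) {
  check_scalar(alpha, "alpha", 0, strict = TRUE)
  check_scalar(beta, "beta", 0, strict = TRUE)
  check_scalar(t0, "t0", 0)
  out <- numeric(length(t))
  u <- t - t0
  pos <- u > 0
  out[pos] <- amplitude * (u[pos] / (alpha * beta))^alpha *
    exp(alpha - u[pos] / beta)
  out
}

default_aif_params <- function() list(t0 = 15, alpha = 3, beta = 1.5,
                                      amplitude = 90)

#' Ground-truth perfusion parameters per vascular territory
#'
#' One row per atlas label: flow (nominal mL/100g/min scale), mean transit
#' time in seconds, bolus delay in seconds; blood volume follows from the
#' central volume principle, cbv = cbf * mtt (units: flow x seconds).
#' Defaults are hemispherically symmetric with gray-matter-like values.
#'
#' @return data.frame with columns label, territory, side, cbf, mtt, delay, cbv
#' @export
default_territory_truths <- function() {
  base <- data.frame(
    territory = c("ACA-terminal", "ACA-central", "MCA-central",
                  "MCA-terminal", "PCA-terminal"),
    cbf = c(40, 45, 55, 50, 45),
    mtt = c(6, 5, 4.5, 5.5, 5),
    delay = 0,
    stringsAsFactors = FALSE)
  truths <- rbind(cbind(base, side = "left"), cbind(base, side = "right"))
  truths$label <- seq_len(nrow(truths))
  territory_truth_table(truths)
}

#' Validate and complete a territory truth table
#'
#' Enforces cbf > 0, mtt > 0, delay >= 0 and recomputes cbv = cbf * mtt.
#' @param truths data.frame with label, territory, side, cbf, mtt, delay
#' @return the completed data.frame
#' @export
territory_truth_table <- function(truths) {
  need <- c("label", "territory", "side", "cbf", "mtt", "delay")
  if (!all(need %in% names(truths)))
    stopf("truth table must have columns: %s", paste(need, collapse = ", "))
  if (any(truths$cbf <= 0)) stopf("all territory cbf must be > 0")
  if (any(truths$mtt <= 0)) stopf("all territory mtt must be > 0")
  if (any(truths$delay < 0)) stopf("territory delay must be >= 0")
  truths$cbv <- truths$cbf * truths$mtt
  truths[c("label", "territory", "side", "cbf", "mtt", "delay", "cbv")]
}

# label used for the pure-AIF artery region in phantom atlases
artery_label <- function() 11L

#' Build the phantom vascular-territory atlas
#'
#' A rectangular brain with a 2-voxel background rim, split into left/right
#' hemispheres along x, each partitioned into five anterior-to-posterior
#' bands (ACA terminal/central, MCA central/terminal, PCA terminal). A small
#' block near the left MCA band carries the artery label and holds the pure
#' arterial input curve.
#'
#' @param grid_shape integer vector of 3 voxel dimensions
#' @return a \code{territory_atlas} (see \code{\link{territory_atlas}})
#' @export
build_phantom_atlas <- function(grid_shape = c(32L, 32L, 10L)) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  lab <- array(0L, dim = grid_shape)
  x0 <- 3L; x1 <- nx - 2L; y0 <- 3L; y1 <- ny - 2L
  z0 <- min(2L, nz); z1 <- max(nz - 1L, z0)
  xmid <- (x0 + x1) %/% 2L
  bands <- floor(seq(y0, y1 + 1L, length.out = 6L))
  for (b in 1:5) {
    ys <- bands[b]:(bands[b + 1] - 1L)
    lab[x0:xmid, ys, z0:z1] <- b          # left hemisphere labels 1..5
    lab[(xmid + 1L):x1, ys, z0:z1] <- b + 5L  # right hemisphere 6..10
  }
  # artery block (>= 12 voxels so the default 10-voxel AIF search stays
  # inside it): in the left MCA-central band, near the midline
  ya <- (bands[3] + bands[4]) %/% 2L
  za <- max(z0, nz %/% 2L)
  lab[max(x0, xmid - 1L):xmid, ya:min(ya + 2L, y1),
      za:min(za + 1L, z1)] <- artery_label()
  dict <- data.frame(
    label = c(1:10, artery_label()),
    territory = c(rep(c("ACA-terminal", "ACA-central", "MCA-central",
                        "MCA-terminal", "PCA-terminal"), 2L), "artery"),
    side = c(rep("left", 5L), rep("right", 5L), "other"),
    stringsAsFactors = FALSE)
  territory_atlas(lab, dict)
}

#' Simulate a tissue concentration curve
#'
#' Discretized single-compartment bolus passage: the tissue concentration is
#' the causal convolution \eqn{C_v(t) = F \Delta t \sum_\tau AIF(t - \tau -
#' delay) R(\tau)} with exponential residue \eqn{R(\tau) =
#' \exp(-\tau/MTT)}. Delay is applied by shifting the AIF a whole number of
#' frames (\code{round(delay/dt)}).
#'
#' @param aif sampled arterial input curve (uniform grid, spacing \code{dt})
#' @param cbf tissue flow F (any linear unit; see \code{\link{dsc_flow_scale}})
#' @param mtt mean transit time, seconds
#' @param dt sampling interval, seconds
#' @param delay tissue bolus delay, seconds (>= 0)
#' @param flow_scale multiplier applied to \code{cbf} before the convolution
#' @return tissue concentration sampled on the same grid as \code{aif}
#' @export
simulate_tissue_curve <- function(aif, cbf, mtt, dt, delay = 0,
                                  flow_scale = 1) {
  check_scalar(cbf, "cbf", 0)
  check_scalar(mtt, "mtt", 0, strict = TRUE)
  check_scalar(delay, "delay", 0)
  n <- length(aif)
  if (n < 2L) stopf("aif must have at least 2 samples")
  if (cbf == 0) return(numeric(n))
  k <- round(delay / dt)
  a <- if (k > 0) c(numeric(k), aif)[seq_len(n)] else aif
  fr <- cbf * flow_scale * exp(-time_axis(n, dt) / mtt)
  # causal discrete convolution, truncated to the acquisition window
  dt * fft_causal_convolve(a, fr)
}

# first n terms of the linear convolution of two length-n vectors, via FFT
# on a highly composite padded length (plain 2n-1 can be near-prime and
# push R's mixed-radix FFT into quadratic time for long curves)
fft_causal_convolve <- function(a, b) {
  n <- length(a)
  N <- stats::nextn(2L * n - 1L, c(2L, 3L, 5L))
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - n)))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / N
}

# exact per-voxel parameter volumes implied by atlas + truths
truth_volumes <- function(atlas, truths) {
  lab <- atlas$labels
  mk <- function(values) {
    v <- array(NA_real_, dim = dim(lab))
    for (i in seq_len(nrow(truths)))
      v[lab == truths$label[i]] <- values[i]
    v
  }
  list(cbf = mk(truths$cbf), cbv = mk(truths$cbv), mtt = mk(truths$mtt))
}

#' Simulate one phantom DSC acquisition
#'
#' Builds per-territory tissue curves from the truth table, places the pure
#' gamma-variate bolus in the artery label, forms the signal as
#' \eqn{S(t) = S_0 \exp(-k \cdot TE \cdot C(t))} and adds Gaussian noise.
#' Background voxels have zero baseline signal. The returned sidecar holds
#' the exact per-voxel CBF/CBV/MTT ground truth.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param atlas a \code{\link{territory_atlas}} on \code{spec$grid_shape};
#'   defaults to \code{\link{build_phantom_atlas}}
#' @param truths territory truth table (one row per tissue label)
#' @param aif_params list with t0, alpha, beta, amplitude for the bolus
#' @param k relaxivity constant of the signal equation (arbitrary units)
#' @param flow_scale see \code{\link{dsc_flow_scale}}
#' @return list with \code{series} (a \code{\link{perfusion_series}}),
#'   \code{atlas}, \code{truths}, \code{truth_maps} (exact per-voxel
#'   volumes), \code{aif} (the noise-free arterial curve) and \code{spec}
#' @export
simulate_phantom_session <- function(spec, atlas = NULL,
                                     truths = default_territory_truths(),
                                     aif_params = default_aif_params(),
                                     k = 1, flow_scale = dsc_flow_scale()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(atlas)) atlas <- build_phantom_atlas(spec$grid_shape)
  lab <- atlas$labels
  if (!identical(dim(lab), as.integer(spec$grid_shape)))
    stopf("atlas grid %s does not match phantom grid %s",
          paste(dim(lab), collapse = "x"),
          paste(spec$grid_shape, collapse = "x"))
  truths <- territory_truth_table(truths)
  tissue_labels <- setdiff(sort(unique(lab[lab > 0])), artery_label())
  missing <- setdiff(tissue_labels, truths$label)
  if (length(missing))
    stopf("no territory truth for atlas label(s): %s",
          paste(missing, collapse = ", "))

  t <- time_axis(spec$n_frames, spec$dt)
  aif <- do.call(gamma_variate_aif, c(list(t = t), aif_params))

  conc <- array(0, dim = c(spec$grid_shape, spec$n_frames))
  nvox <- prod(spec$grid_shape)
  cmat <- matrix(0, nrow = nvox, ncol = spec$n_frames)
  for (i in seq_len(nrow(truths))) {
    idx <- which(lab == truths$label[i])
    if (!length(idx)) next
    curve <- simulate_tissue_curve(aif, truths$cbf[i], truths$mtt[i],
                                   spec$dt, truths$delay[i], flow_scale)
    cmat[idx, ] <- rep(curve, each = length(idx))
  }
  cmat[which(lab == artery_label()), ] <-
    rep(aif, each = sum(lab == artery_label()))
  conc[] <- cmat

  s0vol <- ifelse(lab > 0, spec$s0, 0)
  signal <- array(rep(s0vol, spec$n_frames), dim = dim(conc)) *
    exp(-k * spec$te * conc)
  if (spec$noise_sd > 0)
    signal <- signal + with_seed(spec$seed,
      array(stats::rnorm(length(signal), 0, spec$noise_sd), dim = dim(signal)))

  list(series = perfusion_series(signal, dt = spec$dt, te = spec$te),
       atlas = atlas, truths = truths,
       truth_maps = truth_volumes(atlas, truths),
       aif = aif, aif_params = aif_params, k = k,
       flow_scale = flow_scale, spec = spec)
}

# evaluate code with a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
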