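# Shared fixtures: everything is generated in code, no files.

# small phantom for full-pipeline tests (fast: ~2k brain voxels)
small_spec <- function(seed = 1L, noise_sd = 0, n_frames = 60L) {
  phantom_spec(grid_shape = c(20L, 20L, 6L), n_frames = n_frames,
               noise_sd = noise_sd, seed = seed)
}

default_time <- function(n = 60L, dt = 1.5) (seq_len(n) - 1L) * dt

default_aif_curve <- function(n = 60L, dt = 1.5) {
  gamma_variate_aif(default_time(n, dt))
}

# constant-signal series (optionally noisy) for baseline/concentration tests
constant_series <- function(value = 100, dims = c(4L, 4L, 2L), n = 24L,
                            noise_sd = 0, seed = 1L) {
  data <- array(value, dim = c(dims, n))
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + array(rnorm(length(data), 0, noise_sd), dim = dim(data))
  }
  perfusion_series(data, dt = 1.5, te = 0.03)
}

# quadrature helper used by integral oracles
trapz_area <- function(y, dt) dt * (sum(y) - (y[1] + y[length(y)]) / 2)

# independent step-up implementation used as the BH oracle: literally walk
# the definition (largest k with p_(k) <= k q / m, reject ranks 1..k)
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- logical(m)
  if (k > 0L) reject[ord[seq_len(k)]] <- TRUE
  reject
}
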