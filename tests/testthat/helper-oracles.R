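# Shared fixtures and independent oracles used across the suite.

# Independent forward-Euler reference for the AdEx equations (plain R),
# used at a finer time step than the package integrator.
adex_euler_reference <- function(I_fun, dur_ms, dt_ms, p, Vh, t_ref = 2) {
  n <- round(dur_ms / dt_ms)
  v <- Vh
  w <- p$a_nS * (Vh - p$EL_mV)
  vpeak <- p$VT_mV + 3 * p$DeltaT_mV
  spikes <- 0
  ref_until <- -Inf
  for (i in seq_len(n)) {
    t <- (i - 1) * dt_ms
    if (t < ref_until) next
    ex <- min((v - p$VT_mV) / p$DeltaT_mV, 20)
    dv <- (-p$gL_nS * (v - p$EL_mV) + p$gL_nS * p$DeltaT_mV * exp(ex) -
             w + I_fun(t)) / p$C_pF
    dw <- (p$a_nS * (v - p$EL_mV) - w) / p$tau_w_ms
    v <- v + dt_ms * dv
    w <- w + dt_ms * dw
    if (v >= vpeak) {
      spikes <- spikes + 1
      v <- p$Vreset_mV
      w <- w + p$b_pA
      ref_until <- t + t_ref
    }
  }
  spikes
}

# step-by-step normalisation oracle: the four transforms applied separately
normalize_oracle <- function(m) {
  m <- as.matrix(m)
  s1 <- apply(m, 2, function(x) x - min(x))
  s2 <- apply(s1, 2, function(x) if (sum(x) > 0) x / sum(x) * 10000 else x)
  s3 <- log1p(s2)
  apply(s3, 2, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
}

# explicit O(n * k) convolution with a normalised Gaussian kernel
gauss_conv_oracle <- function(x, sigma, radius = 4) {
  h <- max(1L, ceiling(radius * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq(-h, h)) {
      idx <- i + j
      if (idx >= 1 && idx <= n) acc <- acc + x[idx] * k[j + h + 1]
    }
    out[i] <- acc
  }
  out
}

# closed-form least squares (normal equations)
lstsq_oracle <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - slope * xm, slope = slope)
}

# small archetype batch reused by several tests (cached per session)
small_batch <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_archetype_batch(
        n_per_type = 6, protocol = protocol_spec(spont_s = 5), seed = 42)
    cache
  }
})

# flat two-block dataset for tuning tests
flat_dataset <- function(n_units = 4, baseline_hz = 5, seed = 1,
                         block_trials = c(50, 100, 50, 50), ...) {
  simulate_population(population_design(
    n_units = n_units, baseline_hz = baseline_hz,
    block_trials = block_trials, seed = seed, ...))
}

# well-separated isotropic Gaussian blobs
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}
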