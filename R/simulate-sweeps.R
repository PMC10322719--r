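# Current-clamp sweep simulator: AdEx subthreshold/firing dynamics with a
# stereotyped AP waveform spliced (additively) at every spike, so that
# waveform-shape features are defined on the output traces.

# deviation kernel of one action potential, sampled at dt_ms; baseline 0
ap_kernel <- function(ap, dt_ms) {
  rise <- ap$rise_ms; fall <- ap$fall_ms
  amp <- ap$amp_mV; ahp <- ap$ahp_amp_mV
  tail_ms <- rise + fall + 4 * ap$ahp_tau_ms
  t <- seq(0, tail_ms, by = dt_ms)
  d <- numeric(length(t))
  i1 <- t < rise
  d[i1] <- amp * sin(pi / 2 * t[i1] / rise)^2
  i2 <- t >= rise & t < rise + fall
  d[i2] <- -ahp + (amp + ahp) * cos(pi / 2 * (t[i2] - rise) / fall)^2
  i3 <- t >= rise + fall
  u <- t[i3] - rise - fall
  d[i3] <- -ahp * exp(-u / ap$ahp_tau_ms)
  if (ap$adp_amp_mV > 0) {
    d[i3] <- d[i3] + ap$adp_amp_mV * (u / ap$adp_rise_ms) *
      exp(1 - u / ap$adp_rise_ms)
  }
  d
}

# draw one neuron's jittered parameter set from an archetype spec
draw_params <- function(spec) {
  cv <- spec$jitter_cv
  mlog <- function(x) if (cv > 0) x * rlnorm(1, -cv^2 / 2, cv) else x
  madd <- function(x) x + rnorm(1, 0, 10 * cv)
  ap <- spec$ap
  ap$amp_mV <- mlog(ap$amp_mV); ap$rise_ms <- mlog(ap$rise_ms)
  ap$fall_ms <- mlog(ap$fall_ms); ap$ahp_tau_ms <- mlog(ap$ahp_tau_ms)
  if (ap$ahp_amp_mV > 0) ap$ahp_amp_mV <- mlog(ap$ahp_amp_mV)
  if (ap$adp_amp_mV > 0) ap$adp_amp_mV <- mlog(ap$adp_amp_mV)
  tonic <- max(0.2, rnorm(1, spec$tonic_rate_hz, spec$tonic_rate_sd_hz))
  list(C_pF = mlog(spec$C_pF), gL_nS = mlog(spec$gL_nS),
       EL_mV = madd(spec$EL_mV), VT_mV = madd(spec$VT_mV),
       DeltaT_mV = spec$DeltaT_mV,
       a_nS = sign(spec$a_nS) * mlog(abs(spec$a_nS)),
       tau_w_ms = mlog(spec$tau_w_ms),
       b_pA = if (spec$b_pA > 0) mlog(spec$b_pA) else 0,
       Vreset_mV = madd(spec$Vreset_mV),
       tonic_rate_hz = tonic, tonic_shape = spec$tonic_shape, ap = ap)
}

# holding current (pA) pinning the AdEx neuron at Vh in steady state
holding_current <- function(p, Vh) {
  p$gL_nS * (Vh - p$EL_mV) -
    p$gL_nS * p$DeltaT_mV * exp((Vh - p$VT_mV) / p$DeltaT_mV) +
    p$a_nS * (Vh - p$EL_mV)
}

integrate_sweep <- function(p, protocol, amp_pA, kernel) {
  fs <- protocol$fs_hz
  dt <- 1000 / fs                             # ms
  n_pre <- round(protocol$pre_s * fs)
  n_step <- round(protocol$step_s * fs)
  n_post <- round(protocol$post_s * fs)
  n <- n_pre + n_step + n_post
  Ih <- holding_current(p, protocol$holding_mV)
  I <- rep(Ih, n)
  I[(n_pre + 1):(n_pre + n_step)] <- Ih + amp_pA
  noise <- if (protocol$noise_sd_pA > 0)
    rnorm(n, 0, protocol$noise_sd_pA * sqrt(fs / 1000)) else numeric(0)
  vpeak <- p$VT_mV + 3 * p$DeltaT_mV
  w0 <- p$a_nS * (protocol$holding_mV - p$EL_mV)
  out <- adex_integrate_cpp(I, noise, dt, p$C_pF, p$gL_nS, p$EL_mV,
                            p$VT_mV, p$DeltaT_mV, p$a_nS, p$tau_w_ms,
                            p$b_pA, p$Vreset_mV, vpeak,
                            protocol$holding_mV, w0, t_ref = 2)
  v <- out$V
  for (s in out$spikes) {
    idx <- s:min(s + length(kernel) - 1L, n)
    v[idx] <- v[idx] + kernel[seq_along(idx)]
  }
  list(v = v, spike_idx = out$spikes)
}

# spontaneous cell-attached trace: gamma-renewal spike train rendered as a
# biphasic extracellular waveform on a noisy baseline (arbitrary units)
simulate_spontaneous <- function(rate_hz, shape, duration_s, fs_hz = 10000) {
  n_max <- max(20, ceiling(rate_hz * duration_s * 3 + 20))
  isis <- rgamma(n_max, shape = shape, rate = shape * rate_hz)
  st <- cumsum(isis)
  st <- st[st < duration_s]
  n <- round(duration_s * fs_hz)
  trace <- rnorm(n, 0, 1)
  k <- c(seq(0, 30, length.out = round(fs_hz * 4e-4)),
         seq(30, -10, length.out = round(fs_hz * 6e-4)),
         seq(-10, 0, length.out = round(fs_hz * 8e-4)))
  for (s in st) {
    i0 <- floor(s * fs_hz) + 1L
    idx <- i0:min(i0 + length(k) - 1L, n)
    trace[idx] <- trace[idx] + k[seq_along(idx)]
  }
  list(trace = trace, fs_hz = fs_hz, duration_s = duration_s,
       spike_times_s = st)
}

#' Simulate one neuron's current-clamp sweep set
#'
#' Integrates an AdEx neuron (with per-neuron jittered parameters drawn from
#' the archetype) through the full step protocol and splices the archetype's
#' stereotyped AP waveform at every spike. Also produces a spontaneous
#' cell-attached trace whose rate is drawn from the archetype's tonic-rate
#' distribution. Identical `spec` + `protocol` + `seed` give bit-identical
#' output.
#'
#' @param spec an [archetype_spec()].
#' @param protocol a [protocol_spec()].
#' @param seed integer seed.
#' @return an object of class `sweep_set`: list with `voltage` (samples x
#'   sweeps matrix, mV), `amp_pA` (per-sweep step amplitude; the repeated
#'   -40 pA time-constant sweeps share an amplitude), `fs_hz`, `pre_s`,
#'   `step_s`, `post_s`, `spont` (spontaneous trace) and `meta` (drawn
#'   parameters, archetype name, seed).
#' @export
simulate_sweep_set <- function(spec, protocol = protocol_spec(), seed = 1) {
  stopifnot(inherits(spec, "archetype_spec"), inherits(protocol, "protocol_spec"))
  with_seed(seed, {
    p <- draw_params(spec)
    kernel <- ap_kernel(p$ap, 1000 / protocol$fs_hz)
    amps <- c(protocol$amps_pA,
              rep(-40, max(0, protocol$n_tau_sweeps - sum(protocol$amps_pA == -40))))
    sweeps <- lapply(amps, function(a) integrate_sweep(p, protocol, a, kernel))
    v <- vapply(sweeps, `[[`, numeric(length(sweeps[[1]]$v)), "v")
    spont <- if (protocol$spont_s > 0)
      simulate_spontaneous(p$tonic_rate_hz, p$tonic_shape, protocol$spont_s)
    else NULL
    structure(list(voltage = v, amp_pA = amps, fs_hz = protocol$fs_hz,
                   pre_s = protocol$pre_s, step_s = protocol$step_s,
                   post_s = protocol$post_s, spont = spont,
                   spike_idx = lapply(sweeps, `[[`, "spike_idx"),
                   meta = list(archetype = spec$name, seed = seed,
                               params = p)),
              class = "sweep_set")
  })
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set>", x$meta$archetype, "-", ncol(x$voltage), "sweeps @",
      x$fs_hz, "Hz; steps", paste0(range(x$amp_pA), collapse = ".."),
      "pA\n")
  invisible(x)
}

#' Simulate a batch of archetype neurons
#'
#' `simulate_archetype_batch()` returns the full sweep sets (voltage
#' traces), which for hundreds of neurons occupies gigabytes;
#' `simulate_archetype_features()` simulates one neuron at a time, extracts
#' its intrinsic features and discards the traces, so large typing studies
#' run in constant memory.
#'
#' @param n_per_type neurons per archetype.
#' @param archetypes list of specs, default [lhb_archetypes()].
#' @param protocol a [protocol_spec()].
#' @param seed integer; neuron i receives seed `seed * 10000 + i`.
#' @return list with `sweep_sets` (list) and `labels` (generative archetype
#'   of each neuron).
#' @export
simulate_archetype_batch <- function(n_per_type = 40,
                                     archetypes = lhb_archetypes(),
                                     protocol = protocol_spec(),
                                     seed = 1) {
  labels <- rep(names(archetypes), each = n_per_type)
  sets <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sets[[i]] <- simulate_sweep_set(archetypes[[labels[i]]], protocol,
                                    seed = (seed * 10000 + i) %% .Machine$integer.max)
  }
  list(sweep_sets = sets, labels = labels)
}

#' @rdname simulate_archetype_batch
#' @return `simulate_archetype_features()`: a feature data.frame as from
#'   [extract_feature_table()], with a `label` column.
#' @export
simulate_archetype_features <- function(n_per_type = 40,
                                        archetypes = lhb_archetypes(),
                                        protocol = protocol_spec(),
                                        seed = 1) {
  labels <- rep(names(archetypes), each = n_per_type)
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    ss <- simulate_sweep_set(archetypes[[labels[i]]], protocol,
                             seed = (seed * 10000 + i) %% .Machine$integer.max)
    rows[[i]] <- extract_features(ss)
  }
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- labels
  attr(df, "units") <- feature_units()
  df
}
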