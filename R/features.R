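# Intrinsic electrophysiological parameters from current-clamp sweep sets.
# All voltages mV, times ms (except durations in s where named _s), rates Hz.

# central-difference derivative in mV/ms
voltage_derivative <- function(v, fs_hz) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  d * fs_hz / 1000
}

#' Detect action potentials in a voltage trace
#'
#' A spike is a local voltage maximum above `peak_min_mV` preceded (within
#' `search_ms`) by a rising slope of at least `slope_mV_ms`; peaks closer
#' than `refractory_ms` are merged, keeping the larger.
#'
#' @param v voltage trace (mV).
#' @param fs_hz sampling rate.
#' @param peak_min_mV minimum peak voltage.
#' @param slope_mV_ms required upstroke slope (mV/ms).
#' @param refractory_ms merge window for duplicate peaks.
#' @param search_ms how far before the peak the slope criterion is checked.
#' @return integer vector of peak sample indices.
#' @export
detect_spikes <- function(v, fs_hz, peak_min_mV = -10, slope_mV_ms = 10,
                          refractory_ms = 1, search_ms = 5) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- voltage_derivative(v, fs_hz)
  i <- 2:(n - 1)
  cand <- i[v[i] >= v[i - 1] & v[i] > v[i + 1] & v[i] > peak_min_mV]
  if (!length(cand)) return(integer(0))
  back <- max(1L, round(search_ms * fs_hz / 1000))
  ok <- vapply(cand, function(p) {
    j <- max(1L, p - back)
    any(d[j:p] >= slope_mV_ms)
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) return(integer(0))
  # merge peaks within the refractory window
  ref <- refractory_ms * fs_hz / 1000
  keep <- integer(0)
  cur <- cand[1]
  for (p in cand[-1]) {
    if (p - cur <= ref) {
      if (v[p] > v[cur]) cur <- p
    } else {
      keep <- c(keep, cur); cur <- p
    }
  }
  c(keep, cur)
}

#' Tonic firing rate from a cell-attached trace
#'
#' Spike count divided by trace duration. Spikes in the (arbitrary-unit)
#' extracellular trace are detected as peaks exceeding `threshold_sd` robust
#' standard deviations (MAD) of the trace.
#'
#' @param x either a numeric trace or the `spont` element of a
#'   [simulate_sweep_set()] result (a list with `trace` and `fs_hz`).
#' @param fs_hz sampling rate; taken from `x` when it is a list.
#' @param threshold_sd detection threshold in robust s.d. units.
#' @return firing rate (Hz).
#' @export
tonic_rate <- function(x, fs_hz = NULL, threshold_sd = 5) {
  if (is.list(x)) { fs_hz <- x$fs_hz; x <- x$trace }
  stopifnot(is.numeric(x), !is.null(fs_hz))
  dur_s <- length(x) / fs_hz
  if (dur_s < 1) stop("insufficient data: trace shorter than 1 s")
  if (dur_s < 5) warning("trace shorter than the recommended 5 s")
  thr <- threshold_sd * stats::mad(x)
  i <- 2:(length(x) - 1)
  peaks <- i[x[i] >= x[i - 1] & x[i] > x[i + 1] & x[i] > thr]
  # merge within 2 ms
  if (length(peaks) > 1) {
    gap <- diff(peaks) > 0.002 * fs_hz
    peaks <- peaks[c(TRUE, gap)]
  }
  length(peaks) / dur_s
}

# steady-state voltage deflections of selected sweeps (mV), and amplitudes
sweep_deflections <- function(ss, amps, ss_window_s = 0.1) {
  fs <- ss$fs_hz
  n_pre <- round(ss$pre_s * fs); n_step <- round(ss$step_s * fs)
  idx <- which(ss$amp_pA %in% amps)
  dv <- vapply(idx, function(j) {
    v <- ss$voltage[, j]
    base <- mean(v[seq_len(n_pre)])
    w <- (n_pre + n_step - round(ss_window_s * fs) + 1):(n_pre + n_step)
    mean(v[w]) - base
  }, numeric(1))
  list(dv_mV = dv, di_pA = ss$amp_pA[idx])
}

#' Membrane input resistance
#'
#' Slope of the least-squares fit of steady-state voltage deflection (mean
#' over the last `ss_window_s` of the step, relative to the pre-step
#' baseline) against injected current, over the +/-20 pA subthreshold
#' sweeps. Reported in megaohms.
#'
#' @param x a `sweep_set`, or a numeric vector of voltage deflections (mV).
#' @param di_pA current amplitudes (pA) when `x` is numeric.
#' @param amps amplitudes (pA) of the sweeps used from a sweep set.
#' @param ss_window_s steady-state averaging window (s).
#' @return resistance (MOhm).
#' @export
input_resistance <- function(x, di_pA = NULL, amps = c(-20, 20),
                             ss_window_s = 0.1) {
  if (inherits(x, "sweep_set")) {
    d <- sweep_deflections(x, amps, ss_window_s)
    dv <- d$dv_mV; di <- d$di_pA
  } else { dv <- x; di <- di_pA }
  if (length(dv) < 2 || length(unique(di)) < 2)
    stop("singular fit: need >= 2 distinct current amplitudes")
  slope <- coef(lm(dv ~ di))[["di"]]
  slope * 1000  # mV/pA -> MOhm
}

#' Membrane time constant
#'
#' Averages up to `n_max` hyperpolarising responses (default the -40 pA
#' sweeps) and fits a single exponential to the onset transient.
#'
#' @param x a `sweep_set`, or a samples-x-responses matrix of voltage
#'   containing the step onset at sample `onset_idx`.
#' @param fs_hz,onset_idx sampling rate and onset sample for matrix input.
#' @param amp_pA amplitude of the hyperpolarising sweeps used from a sweep
#'   set.
#' @param fit_window_s portion of the transient fitted (s).
#' @param n_max maximum number of responses averaged.
#' @return time constant (ms), or `NA` with a warning when the fit fails.
#' @export
membrane_time_constant <- function(x, fs_hz = NULL, onset_idx = NULL,
                                   amp_pA = -40, fit_window_s = 0.15,
                                   n_max = 20) {
  if (inherits(x, "sweep_set")) {
    idx <- which(x$amp_pA == amp_pA)
    if (!length(idx)) stop("no hyperpolarising sweeps at ", amp_pA, " pA")
    idx <- head(idx, n_max)
    fs_hz <- x$fs_hz
    onset_idx <- round(x$pre_s * fs_hz) + 1L
    m <- x$voltage[, idx, drop = FALSE]
  } else { m <- as.matrix(x) }
  stopifnot(!is.null(fs_hz), !is.null(onset_idx))
  v <- rowMeans(m)
  n_fit <- min(length(v) - onset_idx, round(fit_window_s * fs_hz))
  seg <- v[onset_idx:(onset_idx + n_fit)]
  t_ms <- (seq_along(seg) - 1) / fs_hz * 1000
  v_inf <- mean(tail(seg, max(5, round(length(seg) / 10))))
  a0 <- seg[1] - v_inf
  # initial tau from the 63% crossing
  cross <- which(abs(seg - v_inf) <= abs(a0) * exp(-1))[1]
  tau0 <- if (is.na(cross) || cross < 2) n_fit / fs_hz * 250 else t_ms[cross]
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ vinf + A * exp(-t_ms / tau),
                      start = list(vinf = v_inf, A = a0, tau = max(tau0, 1e-3)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) { warning("time-constant fit failed"); return(NA_real_) }
  tau <- coef(fit)[["tau"]]
  if (tau <= 0) { warning("time-constant fit failed"); return(NA_real_) }
  tau
}

#' Action-potential threshold
#'
#' Voltage where the upstroke slope first reaches `slope_mV_ms`, located by
#' searching backward from the AP peak.
#'
#' @param v voltage trace (mV).
#' @param fs_hz sampling rate.
#' @param peak_idx sample index of the AP peak.
#' @param slope_mV_ms slope criterion (mV/ms).
#' @param search_ms maximum backward search (ms).
#' @return threshold voltage (mV) with attribute `idx` (sample index).
#' @export
ap_threshold <- function(v, fs_hz, peak_idx, slope_mV_ms = 10,
                         search_ms = 5) {
  d <- voltage_derivative(v, fs_hz)
  lo <- max(1L, peak_idx - round(search_ms * fs_hz / 1000))
  j <- peak_idx
  while (j > lo && d[j] < slope_mV_ms) j <- j - 1L
  if (d[j] < slope_mV_ms)
    stop("no AP: slope never reaches ", slope_mV_ms, " mV/ms before peak")
  while (j > lo && d[j - 1L] >= slope_mV_ms) j <- j - 1L
  structure(v[j], idx = j)
}

#' Action-potential waveform features
#'
#' Rise time (threshold to peak), half-width at half amplitude (linear
#' interpolation at the crossings), and the extrema of the numerical
#' derivative (maximal upstroke / downstroke).
#'
#' @param v,fs_hz voltage trace (mV) and sampling rate.
#' @param thr_idx,peak_idx threshold and peak sample indices.
#' @param down_search_ms how far past the peak the repolarisation is
#'   examined.
#' @return list with `rise_ms`, `half_width_ms`, `upstroke_mV_ms`,
#'   `downstroke_mV_ms`, `amp_mV`; `half_width_ms` is `NA` (partial AP) when
#'   the trace ends before repolarisation.
#' @export
ap_waveform <- function(v, fs_hz, thr_idx, peak_idx, down_search_ms = 10) {
  d <- voltage_derivative(v, fs_hz)
  amp <- v[peak_idx] - v[thr_idx]
  half <- v[thr_idx] + amp / 2
  rise_ms <- (peak_idx - thr_idx) / fs_hz * 1000
  # upward half crossing with linear interpolation
  seg <- thr_idx:peak_idx
  iu <- seg[v[seg] <= half]
  iu <- if (length(iu)) max(iu) else thr_idx
  t_up <- if (v[iu + 1] != v[iu])
    iu + (half - v[iu]) / (v[iu + 1] - v[iu]) else iu
  # downward crossing
  lim <- min(length(v), peak_idx + round(down_search_ms * fs_hz / 1000))
  down <- peak_idx:lim
  idn <- down[v[down] < half][1]
  half_width_ms <- NA_real_
  if (!is.na(idn)) {
    j <- idn - 1L
    t_dn <- j + (half - v[j]) / (v[j + 1] - v[j])
    half_width_ms <- (t_dn - t_up) / fs_hz * 1000
  }
  up <- max(d[thr_idx:peak_idx])
  # downstroke until voltage falls back to threshold (or the search limit)
  below <- down[v[down] <= v[thr_idx]][1]
  dn_end <- if (is.na(below)) lim else below
  dn <- min(d[peak_idx:dn_end])
  list(rise_ms = rise_ms, half_width_ms = half_width_ms,
       upstroke_mV_ms = up, downstroke_mV_ms = dn, amp_mV = amp)
}

#' Afterpotential measurements
#'
#' Classifies the post-spike voltage as a convex AHP (single trough, no
#' rebound), an ADP followed by a concave AHP (trough, rebound hump,
#' second trough), or none. The ADP amplitude is measured from the fast
#' repolarisation trough to the ADP peak; the convex AHP amplitude from the
#' AP threshold to the trough; the concave AHP from the ADP peak to the
#' following trough.
#'
#' @param v,fs_hz voltage trace (mV) and sampling rate.
#' @param peak_idx AP peak sample.
#' @param end_idx last sample of the inter-spike segment (next AP threshold
#'   or step end).
#' @param thr_mV AP threshold voltage reference.
#' @param min_prominence_mV minimum rebound counted as an ADP.
#' @param smooth_ms boxcar width applied before extremum detection.
#' @param max_window_ms afterpotentials are searched within this window
#'   after the AP peak. They are fast events: beyond a few tens of
#'   milliseconds the voltage is dominated by the subthreshold trajectory
#'   and by slow adaptation, whose partial-recovery rebound would
#'   otherwise be misread as an ADP.
#' @return list with `adp_mV`, `adp_rise_ms`, `ahp_convex_mV`,
#'   `ahp_concave_mV`, `ahp_rise_ms`, `shape` (one of `"convex-AHP"`,
#'   `"ADP-concave-AHP"`, `"none"`).
#' @export
afterpotentials <- function(v, fs_hz, peak_idx, end_idx, thr_mV,
                            min_prominence_mV = 0.5, smooth_ms = 0.2,
                            max_window_ms = 20) {
  na <- list(adp_mV = NA_real_, adp_rise_ms = NA_real_,
             ahp_convex_mV = NA_real_, ahp_concave_mV = NA_real_,
             ahp_rise_ms = NA_real_, shape = "none")
  end_idx <- min(end_idx, peak_idx + round(max_window_ms * fs_hz / 1000))
  if (end_idx - peak_idx < 4) return(na)
  s <- v[peak_idx:end_idx]
  w <- max(1L, round(smooth_ms * fs_hz / 1000))
  if (w > 1) s <- stats::filter(s, rep(1 / w, w), sides = 2) |> as.numeric()
  ok <- !is.na(s)
  s <- s[ok]
  n <- length(s)
  if (n < 4) return(na)
  # first trough after the repolarisation drops below threshold
  started <- which(s < thr_mV)[1]
  if (is.na(started)) return(na)
  i <- started:(n - 1)
  mins <- i[s[i] <= s[i - 1] & s[i] < s[i + 1]]
  if (!length(mins)) {
    # monotone decay to segment end: trough at the end
    trough1 <- which.min(s)
    if (trough1 <= started) return(na)
    return(list(adp_mV = NA_real_, adp_rise_ms = NA_real_,
                ahp_convex_mV = thr_mV - s[trough1],
                ahp_concave_mV = NA_real_,
                ahp_rise_ms = (trough1 - 1) / fs_hz * 1000,
                shape = "convex-AHP"))
  }
  trough1 <- mins[1]
  after <- if (trough1 < n - 1) (trough1 + 1):(n - 1) else integer(0)
  maxs <- after[s[after] >= s[after - 1] & s[after] > s[after + 1]]
  maxs <- maxs[s[maxs] - s[trough1] >= min_prominence_mV]
  if (!length(maxs)) {
    tr <- trough1 + which.min(s[trough1:n]) - 1L  # deepest point
    return(list(adp_mV = NA_real_, adp_rise_ms = NA_real_,
                ahp_convex_mV = thr_mV - s[tr], ahp_concave_mV = NA_real_,
                ahp_rise_ms = (tr - 1) / fs_hz * 1000, shape = "convex-AHP"))
  }
  adp <- maxs[1]
  rest <- if (adp < n) adp:n else integer(0)
  tr2 <- rest[which.min(s[rest])]
  list(adp_mV = s[adp] - s[trough1],
       adp_rise_ms = (adp - trough1) / fs_hz * 1000,
       ahp_convex_mV = NA_real_,
       ahp_concave_mV = s[adp] - s[tr2],
       ahp_rise_ms = (tr2 - 1) / fs_hz * 1000,
       shape = "ADP-concave-AHP")
}

# spikes within the step window of sweep j
step_spikes <- function(ss, j) {
  fs <- ss$fs_hz
  n_pre <- round(ss$pre_s * fs); n_step <- round(ss$step_s * fs)
  p <- detect_spikes(ss$voltage[, j], fs)
  p[p > n_pre & p <= n_pre + n_step]
}

isi_hz <- function(peaks, fs) {
  if (length(peaks) < 2) return(numeric(0))
  fs / diff(peaks)
}

#' Firing-pattern features from the depolarising sweep ladder
#'
#' Locates the rheobase (smallest depolarising amplitude evoking at least
#' one AP during the step), the sweep closest to twice rheobase and the
#' maximal-frequency sweep, then derives spike counts split at the step
#' midpoint, first/second interspike intervals as instantaneous frequencies,
#' adaptation ratios (last ISI over first, last over second, measured on the
#' 2x-rheobase sweep), the firing frequency at 2x rheobase, and the mean
#' post-step voltage deviation over the 150 ms after the step (on the
#' maximal-frequency sweep).
#'
#' @param ss a `sweep_set`.
#' @param poststep_window_s window after step offset for the post-step
#'   voltage (s).
#' @return named list; spiking features are `NA` when no sweep evokes APs
#'   (`rheobase_pA` is then `NA` too).
#' @export
firing_features <- function(ss, poststep_window_s = 0.15) {
  fs <- ss$fs_hz
  n_pre <- round(ss$pre_s * fs); n_step <- round(ss$step_s * fs)
  out <- list(rheobase_pA = NA_real_, rheo_first_half = NA_real_,
              rheo_second_half = NA_real_,
              isi1_2x_hz = NA_real_, isi2_2x_hz = NA_real_,
              isi1_max_hz = NA_real_, isi2_max_hz = NA_real_,
              adapt_1_last = NA_real_, adapt_2_last = NA_real_,
              firing_freq_hz = NA_real_, firing_poststep_mV = NA_real_,
              rheo_sweep = NA_integer_, sweep_2x = NA_integer_,
              sweep_max = NA_integer_)
  dep <- which(ss$amp_pA > 0)
  if (!length(dep)) return(out)
  sp <- lapply(dep, function(j) step_spikes(ss, j))
  ns <- lengths(sp)
  if (!any(ns > 0)) return(out)
  firing <- dep[ns > 0]
  rheo_j <- firing[which.min(ss$amp_pA[firing])]
  rheo_amp <- ss$amp_pA[rheo_j]
  out$rheobase_pA <- rheo_amp
  out$rheo_sweep <- rheo_j
  rs <- sp[[match(rheo_j, dep)]]
  half <- n_pre + n_step / 2
  out$rheo_first_half <- sum(rs <= half)
  out$rheo_second_half <- sum(rs > half)
  # sweep closest to twice rheobase (ties -> larger amplitude)
  d2 <- abs(ss$amp_pA[dep] - 2 * rheo_amp)
  j2 <- dep[order(d2, -ss$amp_pA[dep])][1]
  out$sweep_2x <- j2
  f2 <- isi_hz(sp[[match(j2, dep)]], fs)
  if (length(f2) >= 1) out$isi1_2x_hz <- f2[1]
  if (length(f2) >= 2) out$isi2_2x_hz <- f2[2]
  if (length(f2) >= 2) {
    out$adapt_1_last <- f2[1] / f2[length(f2)]        # last ISI / first ISI
    out$adapt_2_last <- f2[2] / f2[length(f2)]        # last ISI / second ISI
  }
  out$firing_freq_hz <- ns[match(j2, dep)] / ss$step_s
  jm <- dep[order(-ns, ss$amp_pA[dep])][1]
  out$sweep_max <- jm
  fm <- isi_hz(sp[[match(jm, dep)]], fs)
  if (length(fm) >= 1) out$isi1_max_hz <- fm[1]
  if (length(fm) >= 2) out$isi2_max_hz <- fm[2]
  vmax <- ss$voltage[, jm]
  base <- mean(vmax[seq_len(n_pre)])
  post <- (n_pre + n_step + 1):min(length(vmax),
                                   n_pre + n_step + round(poststep_window_s * fs))
  out$firing_poststep_mV <- mean(vmax[post]) - base
  out
}

#' Names and units of the intrinsic feature vector
#' @return data.frame with `feature` and `unit` columns.
#' @export
feature_units <- function() {
  data.frame(
    feature = c("tonic_rate_hz", "mem_resistance_mohm", "tau_ms",
                "ap_threshold_mv", "ap_rise_ms", "ap_half_width_ms",
                "ap_upstroke_mv_ms", "ap_downstroke_mv_ms",
                "adp_mv", "adp_rise_ms", "ahp_convex_mv", "ahp_concave_mv",
                "ahp_rise_ms", "rheo_first_half_aps", "rheo_second_half_aps",
                "isi1_2x_hz", "isi2_2x_hz", "isi1_max_hz", "isi2_max_hz",
                "adapt_1_last", "adapt_2_last", "firing_freq_hz",
                "firing_poststep_mv", "rheobase_pa"),
    unit = c("Hz", "MOhm", "ms", "mV", "ms", "ms", "mV/ms", "mV/ms",
             "mV", "ms", "mV", "mV", "ms", "count", "count",
             "Hz", "Hz", "Hz", "Hz", "ratio", "ratio", "Hz", "mV", "pA"))
}

#' Extract the full intrinsic feature vector of one neuron
#'
#' Orchestrates the passive, waveform, afterpotential and firing-pattern
#' measurements. AP-shape features are measured on the first rheobasic AP.
#' Missing features (absent sweeps, no spikes, failed fits) are `NA`.
#'
#' @param ss a `sweep_set`.
#' @return named numeric vector over [feature_units()]`$feature`, with a
#'   `provenance` attribute naming the sweep used per feature group.
#' @export
extract_features <- function(ss) {
  stopifnot(inherits(ss, "sweep_set"))
  fs <- ss$fs_hz
  n_pre <- round(ss$pre_s * fs); n_step <- round(ss$step_s * fs)
  f <- setNames(rep(NA_real_, nrow(feature_units())),
                feature_units()$feature)
  prov <- list()
  if (!is.null(ss$spont))
    f["tonic_rate_hz"] <- tonic_rate(ss$spont)
  if (all(c(-20, 20) %in% ss$amp_pA)) {
    f["mem_resistance_mohm"] <- input_resistance(ss)
    prov$resistance <- which(ss$amp_pA %in% c(-20, 20))
  }
  if (any(ss$amp_pA == -40)) {
    f["tau_ms"] <- suppressWarnings(membrane_time_constant(ss))
    prov$tau <- which(ss$amp_pA == -40)
  }
  ff <- firing_features(ss)
  f["rheobase_pa"] <- ff$rheobase_pA
  f["rheo_first_half_aps"] <- ff$rheo_first_half
  f["rheo_second_half_aps"] <- ff$rheo_second_half
  f["isi1_2x_hz"] <- ff$isi1_2x_hz; f["isi2_2x_hz"] <- ff$isi2_2x_hz
  f["isi1_max_hz"] <- ff$isi1_max_hz; f["isi2_max_hz"] <- ff$isi2_max_hz
  f["adapt_1_last"] <- ff$adapt_1_last; f["adapt_2_last"] <- ff$adapt_2_last
  f["firing_freq_hz"] <- ff$firing_freq_hz
  f["firing_poststep_mv"] <- ff$firing_poststep_mV
  if (!is.na(ff$rheo_sweep)) {
    j <- ff$rheo_sweep
    v <- ss$voltage[, j]
    peaks <- step_spikes(ss, j)
    p1 <- peaks[1]
    thr <- tryCatch(ap_threshold(v, fs, p1), error = function(e) NULL)
    if (!is.null(thr)) {
      ti <- attr(thr, "idx")
      f["ap_threshold_mv"] <- as.numeric(thr)
      wf <- ap_waveform(v, fs, ti, p1)
      f["ap_rise_ms"] <- wf$rise_ms
      f["ap_half_width_ms"] <- wf$half_width_ms
      f["ap_upstroke_mv_ms"] <- wf$upstroke_mV_ms
      f["ap_downstroke_mv_ms"] <- wf$downstroke_mV_ms
      end_idx <- if (length(peaks) >= 2) {
        t2 <- tryCatch(attr(ap_threshold(v, fs, peaks[2]), "idx"),
                       error = function(e) peaks[2] - 1L)
        t2
      } else n_pre + n_step
      ap <- afterpotentials(v, fs, p1, end_idx, as.numeric(thr))
      f["adp_mv"] <- ap$adp_mV; f["adp_rise_ms"] <- ap$adp_rise_ms
      f["ahp_convex_mv"] <- ap$ahp_convex_mV
      f["ahp_concave_mv"] <- ap$ahp_concave_mV
      f["ahp_rise_ms"] <- ap$ahp_rise_ms
    }
    prov$ap <- j
  }
  attr(f, "provenance") <- prov
  f
}

#' Feature table of a batch of neurons
#'
#' @param batch result of [simulate_archetype_batch()], or a list of
#'   `sweep_set` objects.
#' @return data.frame neurons x features with an optional `label` column
#'   and a `units` attribute.
#' @export
extract_feature_table <- function(batch) {
  sets <- if (!is.null(batch$sweep_sets)) batch$sweep_sets else batch
  m <- t(vapply(sets, extract_features, numeric(nrow(feature_units()))))
  df <- as.data.frame(m)
  if (!is.null(batch$labels)) df$label <- batch$labels
  attr(df, "units") <- feature_units()
  df
}
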