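test_that("tonic rate is spike count over duration", {
  fs <- 10000
  tr <- rnorm(10 * fs, 0, 1)
  at <- round(seq(0.2, 9.8, length.out = 30) * fs)
  tr[at] <- 40
  expect_equal(tonic_rate(tr, fs), 3)
  expect_equal(tonic_rate(rnorm(10 * fs), fs), 0)
  expect_error(tonic_rate(rnorm(fs / 2), fs), "insufficient")
  expect_warning(tonic_rate(rnorm(2 * fs), fs), "5 s")
})

test_that("tonic rate of simulated spontaneous traces recovers the set rate", {
  spec <- archetype_spec("t", C_pF = 200, gL_nS = 10, EL_mV = -70,
                         VT_mV = -50, DeltaT_mV = 2, a_nS = 0, tau_w_ms = 50,
                         b_pA = 0, Vreset_mV = -58, tonic_rate_hz = 8,
                         tonic_rate_sd_hz = 1e-9, jitter_cv = 0)
  rates <- vapply(1:20, function(i) {
    sp <- with(list(), {
      set.seed(i)
      lhbaxis:::simulate_spontaneous(8, 4, 10)
    })
    tonic_rate(sp)
  }, numeric(1))
  se <- sd(rates) / sqrt(20)
  expect_lt(abs(mean(rates) - 8), 3 * max(se, 0.1))
})

test_that("input resistance follows Ohm's law and the least-squares slope", {
  expect_equal(input_resistance(c(2, -2), c(20, -20)), 100)
  expect_equal(input_resistance(c(0, 0), c(20, -20)), 0)
  set.seed(1)
  di <- c(-20, -10, 10, 20)
  dv <- 0.08 * di + rnorm(4, 0, 0.1)
  o <- lstsq_oracle(di, dv)
  expect_equal(input_resistance(dv, di), o[["slope"]] * 1000,
               tolerance = 1e-9)
  expect_error(input_resistance(c(1, 2), c(20, 20)), "singular")
})

test_that("membrane time constant fits a single exponential", {
  fs <- 20000
  t_ms <- (0:4999) / fs * 1000
  v <- -70 - 8 * (1 - exp(-t_ms / 15))
  m <- matrix(v, ncol = 1)
  expect_equal(membrane_time_constant(m, fs_hz = fs, onset_idx = 1), 15,
               tolerance = 1e-6)
  # averaging identical responses changes nothing
  m20 <- matrix(rep(v, 20), ncol = 20)
  expect_equal(membrane_time_constant(m20, fs_hz = fs, onset_idx = 1),
               membrane_time_constant(m, fs_hz = fs, onset_idx = 1))
})

test_that("noisy time-constant recovery stays within 5%", {
  fs <- 20000
  t_ms <- (0:4999) / fs * 1000
  clean <- -70 - 8 * (1 - exp(-t_ms / 12))
  taus <- vapply(1:30, function(i) {
    set.seed(i)
    m <- matrix(clean + rnorm(20 * length(clean), 0, 0.2), ncol = 20)
    membrane_time_constant(m, fs_hz = fs, onset_idx = 1)
  }, numeric(1))
  expect_true(all(abs(taus - 12) / 12 < 0.05))
})

test_that("AP threshold sits where the slope first reaches 10 mV/ms", {
  fs <- 20000
  # constructed ramp: slope 2 mV/ms until -42 mV, then 50 mV/ms to peak
  dt_ms <- 1000 / fs
  seg1 <- seq(-60, -42, by = 2 * dt_ms)
  seg2 <- seq(-42 + 50 * dt_ms, 10, by = 50 * dt_ms)
  v <- c(rep(-60, 100), seg1, seg2, rev(seg2), rep(-60, 100))
  peak <- which.max(v)
  thr <- ap_threshold(v, fs, peak)
  expect_equal(as.numeric(thr), -42, tolerance = 2 * 50 * dt_ms)
  # subthreshold trace -> no-AP signal
  flat <- rep(-60, 1000) + sin(seq(0, 2 * pi, length.out = 1000))
  expect_error(ap_threshold(flat, fs, which.max(flat)), "no AP")
})

test_that("threshold matches an exhaustive derivative scan on real sweeps", {
  batch <- small_batch()
  ss <- batch$sweep_sets[[1]]
  ff <- firing_features(ss)
  v <- ss$voltage[, ff$rheo_sweep]
  peaks <- lhbaxis:::step_spikes(ss, ff$rheo_sweep)
  thr <- ap_threshold(v, ss$fs_hz, peaks[1])
  # brute force: scan every sample before the peak for the first of the
  # contiguous run of slope >= 10 ending at the peak upstroke
  d <- lhbaxis:::voltage_derivative(v, ss$fs_hz)
  run <- which(d[1:peaks[1]] >= 10)
  run <- run[run > peaks[1] - 0.005 * ss$fs_hz]
  expect_equal(attr(thr, "idx"), min(run))
})

test_that("waveform features match closed-form shapes", {
  fs <- 100000
  dt_ms <- 1000 / fs
  # symmetric triangular AP: amplitude 80 mV over a 2 ms base
  n_half <- round(1 / dt_ms)
  tri <- c(rep(-60, 50), seq(-60, 20, length.out = n_half + 1),
           seq(20, -60, length.out = n_half + 1)[-1], rep(-60, 50))
  peak <- which.max(tri)
  thr_idx <- 51
  wf <- ap_waveform(tri, fs, thr_idx, peak)
  expect_equal(wf$half_width_ms, 1, tolerance = 2 * dt_ms)
  expect_equal(wf$rise_ms, 1, tolerance = 2 * dt_ms)
  # Gaussian AP: FWHM = 2.3548 sigma
  sigma_ms <- 0.3
  t_ms <- seq(-3, 3, by = dt_ms)
  g <- -60 + 80 * exp(-t_ms^2 / (2 * sigma_ms^2))
  peak <- which.max(g)
  thr_idx <- which(g > -59.99)[1]  # near-baseline reference
  wf <- ap_waveform(g, fs, thr_idx, peak)
  expect_equal(wf$half_width_ms, 2.3548 * sigma_ms, tolerance = dt_ms * 5)
  # piecewise-linear upstroke of 250 mV/ms
  ramp <- c(rep(-60, 20), seq(-60, 20, by = 250 * dt_ms), rep(20, 5),
            seq(20, -60, length.out = 200))
  peak <- which.max(ramp)
  thr <- ap_threshold(ramp, fs, peak)
  wf <- ap_waveform(ramp, fs, attr(thr, "idx"), peak)
  expect_equal(wf$upstroke_mV_ms, 250, tolerance = 1)
})

test_that("afterpotential classification follows the constructed shape", {
  fs <- 20000
  dt_ms <- 1000 / fs
  ms <- function(x) round(x / dt_ms)
  # spike peak then monotone repolarisation to a single trough 6 mV below
  # threshold (-50), slow recovery
  thr <- -50
  v <- c(seq(20, thr - 6, length.out = ms(1)),
         thr - 6 + 5 * (1 - exp(-(1:ms(40)) / ms(15))))
  ap <- afterpotentials(c(rep(20, 2), v), fs, peak_idx = 1,
                        end_idx = length(v), thr_mV = thr)
  expect_equal(ap$shape, "convex-AHP")
  expect_equal(ap$ahp_convex_mV, 6, tolerance = 0.3)
  expect_true(is.na(ap$adp_mV))
  # trough, 3 mV rebound hump, deeper trough
  v2 <- c(seq(20, -58, length.out = ms(1)),
          -58 + 3 * sin(seq(0, pi, length.out = ms(6))),
          seq(-58, -60, length.out = ms(5)),
          seq(-60, -55, length.out = ms(20)))
  ap2 <- afterpotentials(v2, fs, peak_idx = 1, end_idx = length(v2),
                         thr_mV = thr)
  expect_equal(ap2$shape, "ADP-concave-AHP")
  expect_equal(ap2$adp_mV, 3, tolerance = 0.3)
  expect_gt(ap2$ahp_concave_mV, 2)
})

test_that("afterpotential amplitudes match a brute-force extremum scan", {
  batch <- small_batch()
  burst <- which(batch$labels == "Burst")[1]
  ss <- batch$sweep_sets[[burst]]
  ff <- firing_features(ss)
  v <- ss$voltage[, ff$rheo_sweep]
  fs <- ss$fs_hz
  peaks <- lhbaxis:::step_spikes(ss, ff$rheo_sweep)
  thr <- ap_threshold(v, fs, peaks[1])
  end_idx <- if (length(peaks) > 1) peaks[2] - round(0.001 * fs) else
    round((ss$pre_s + ss$step_s) * fs)
  ap <- afterpotentials(v, fs, peaks[1], end_idx, as.numeric(thr))
  # oracle: exhaustive extrema of the smoothed capped segment
  lim <- min(end_idx, peaks[1] + round(0.05 * fs))
  seg <- v[peaks[1]:lim]
  w <- round(0.0002 * fs)
  seg <- as.numeric(stats::filter(seg, rep(1 / w, w), sides = 2))
  seg <- seg[!is.na(seg)]
  started <- which(seg < as.numeric(thr))[1]
  i <- started:(length(seg) - 1)
  tr1 <- i[seg[i] <= seg[i - 1] & seg[i] < seg[i + 1]][1]
  j <- (tr1 + 1):(length(seg) - 1)
  hump <- j[seg[j] >= seg[j - 1] & seg[j] > seg[j + 1] &
              seg[j] - seg[tr1] >= 0.5][1]
  expect_false(is.na(hump))  # the burst archetype has an ADP
  expect_equal(ap$adp_mV, seg[hump] - seg[tr1], tolerance = 1e-6)
})

test_that("firing features follow directly from the spike times", {
  fs <- 20000
  pre <- 0.1; step <- 1
  make_sweep <- function(spike_ms, amp) {
    n <- round((pre + step + 0.15) * fs)
    v <- rep(-70, n)
    for (s in spike_ms) {
      i0 <- round((pre + s / 1000) * fs)
      up <- seq(-70, 10, length.out = round(0.0004 * fs))
      dn <- seq(10, -70, length.out = round(0.0006 * fs))
      k <- c(up, dn[-1])
      v[i0:(i0 + length(k) - 1)] <- k
    }
    v
  }
  # ladder: subthreshold sweeps, regular 10 Hz at rheobase, faster at 2x
  ss <- structure(list(
    voltage = cbind(make_sweep(numeric(0), 50),
                    make_sweep(seq(50, 950, by = 100), 100),
                    make_sweep(seq(40, 940, by = 60), 200)),
    amp_pA = c(50, 100, 200), fs_hz = fs, pre_s = pre, step_s = step,
    post_s = 0.15, spont = NULL, meta = list()), class = "sweep_set")
  ff <- firing_features(ss)
  expect_equal(ff$rheobase_pA, 100)
  expect_equal(ff$rheo_first_half, 5)
  expect_equal(ff$rheo_second_half, 5)
  expect_equal(ff$isi1_2x_hz, 1000 / 60, tolerance = 0.01)
  expect_equal(ff$isi2_2x_hz, 1000 / 60, tolerance = 0.01)
  expect_equal(ff$adapt_1_last, 1, tolerance = 0.01)
  # only two early spikes: second half count 0
  ss2 <- ss
  ss2$voltage[, 2] <- make_sweep(c(100, 300), 100)
  ff2 <- firing_features(ss2)
  expect_equal(ff2$rheo_second_half, 0)
  # geometric ISI train: ratios match direct list arithmetic
  isis <- 100 * 1.2^(0:5)
  at <- cumsum(c(50, isis))
  at <- at[at < 950]
  ss3 <- ss
  ss3$voltage[, 3] <- make_sweep(at, 200)
  ff3 <- firing_features(ss3)
  isis_obs <- diff(at)
  expect_equal(ff3$adapt_1_last, isis_obs[length(isis_obs)] / isis_obs[1],
               tolerance = 0.01)
  expect_equal(ff3$adapt_2_last, isis_obs[length(isis_obs)] / isis_obs[2],
               tolerance = 0.01)
  # no spiking sweep at all -> everything missing
  ss4 <- ss
  ss4$voltage[, 2] <- make_sweep(numeric(0), 100)
  ss4$voltage[, 3] <- make_sweep(numeric(0), 200)
  expect_true(is.na(firing_features(ss4)$rheobase_pA))
})

test_that("extract_features populates the vector and flags missing parts", {
  batch <- small_batch()
  f <- extract_features(batch$sweep_sets[[1]])
  expect_named(f, feature_units()$feature)
  core <- c("tonic_rate_hz", "mem_resistance_mohm", "tau_ms",
            "ap_threshold_mv", "ap_half_width_ms", "rheobase_pa")
  expect_false(any(is.na(f[core])))
  # drop hyperpolarising sweeps: passive features flagged missing
  ss <- batch$sweep_sets[[1]]
  keep <- ss$amp_pA > 0
  ss$voltage <- ss$voltage[, keep]
  ss$amp_pA <- ss$amp_pA[keep]
  f2 <- extract_features(ss)
  expect_true(is.na(f2["mem_resistance_mohm"]))
  expect_true(is.na(f2["tau_ms"]))
  expect_false(is.na(f2["rheobase_pa"]))
  # batch table has one row per neuron and all feature columns
  ft <- extract_feature_table(batch)
  expect_equal(nrow(ft), length(batch$labels))
  expect_true(all(feature_units()$feature %in% names(ft)))
})

test_that("derivative features ignore constant voltage offsets and sampling", {
  batch <- small_batch()
  ss <- batch$sweep_sets[[2]]
  ff <- firing_features(ss)
  v <- ss$voltage[, ff$rheo_sweep]
  fs <- ss$fs_hz
  p <- lhbaxis:::step_spikes(ss, ff$rheo_sweep)[1]
  thr <- ap_threshold(v, fs, p)
  wf <- ap_waveform(v, fs, attr(thr, "idx"), p)
  thr_off <- ap_threshold(v + 13, fs, p)
  wf_off <- ap_waveform(v + 13, fs, attr(thr_off, "idx"), p)
  expect_equal(as.numeric(thr_off), as.numeric(thr) + 13)
  expect_equal(wf_off$half_width_ms, wf$half_width_ms)
  expect_equal(wf_off$upstroke_mV_ms, wf$upstroke_mV_ms)
  # halving the sampling interval moves interpolated widths < one coarse
  # sample
  v2 <- approx(seq_along(v), v, n = 2 * length(v) - 1)$y
  p2 <- 2 * p - 1
  thr2 <- ap_threshold(v2, 2 * fs, p2)
  wf2 <- ap_waveform(v2, 2 * fs, attr(thr2, "idx"), p2)
  expect_lt(abs(wf2$half_width_ms - wf$half_width_ms), 1000 / fs)
  expect_lt(abs(wf2$rise_ms - wf$rise_ms), 1000 / fs)
  # ordering invariants
  expect_lt(as.numeric(thr), v[p])
})
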