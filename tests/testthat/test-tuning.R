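test_that("QC removes slow and refractory-violating units", {
  dur <- 1000
  set.seed(1)
  mk <- function(rate, viol = 0) {
    st <- sort(runif(round(rate * dur), 0, dur))
    st <- st[c(TRUE, diff(st) >= 0.002)]          # enforce refractory
    if (viol > 0) {
      n_v <- round(viol * length(st))
      st <- sort(c(st, st[sample(length(st), n_v)] + 0.0005))
    }
    st
  }
  sp <- rbind(data.frame(unit_id = 1, time_s = mk(0.05)),
              data.frame(unit_id = 2, time_s = mk(5, viol = 0.03)),
              data.frame(unit_id = 3, time_s = mk(5)))
  ds <- structure(list(spikes = sp,
                       units = data.frame(unit_id = 1:3, region = "PL",
                                          genotype = "Esr1"),
                       trials = data.frame(), events = data.frame(),
                       duration_s = dur), class = "spike_dataset")
  out <- qc_filter(ds)
  expect_equal(out$units$unit_id, 3)
  qc <- attr(out, "qc")
  expect_false(qc$pass[1])   # below 0.1 Hz
  expect_false(qc$pass[2])   # > 1% ISI violations
})

test_that("clock-drift correction recovers the linear map", {
  st <- sort(runif(100, 0, 3600))
  sync <- seq(0, 3600, by = 60)
  # identity
  same <- correct_clock_drift(st, sync, sync)
  expect_equal(as.numeric(same), st)
  # 10 ms per hour drift
  drift <- sync * (1 + 10e-3 / 3600)
  corr <- correct_clock_drift(st, sync, drift)
  expect_lt(max(abs(corr - st * (1 + 10e-3 / 3600))), 1e-7)
  # noisy pairs match the closed-form least squares
  set.seed(2)
  noisy <- drift + rnorm(length(sync), 0, 1e-4)
  corr2 <- correct_clock_drift(st, sync, noisy)
  o <- lstsq_oracle(sync, noisy)
  expect_equal(attr(corr2, "slope"), o[["slope"]], tolerance = 1e-10)
  # intercept compared on the scale of the data (QR vs normal equations)
  expect_lt(abs(attr(corr2, "intercept") - o[["intercept"]]) / sd(noisy),
            1e-10)
  expect_error(correct_clock_drift(st, 1, 1), "at least 2")
})

test_that("the closed-form Poisson fit equals stats::glm on real designs", {
  ds <- flat_dataset(n_units = 2, seed = 31, block_trials = c(10, 20, 10, 10),
                     event_gain = cbind(sound1 = 2, opto = c(1, 3),
                                        sound2 = 1, airpuff = 1))
  X <- build_event_design(ds)
  st <- ds$spikes$time_s[ds$spikes$unit_id == 2]
  cnt <- lhbaxis:::bin_counts(st, ds$duration_s, 0.1)
  fit <- fit_event_glm(cnt, X)
  expect_equal(fit$method, "closed_form")
  ref <- glm(cnt ~ X, family = poisson())
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
})

test_that("a regressor never active in the session is flagged undefined", {
  ds <- flat_dataset(n_units = 1, seed = 32, block_trials = c(5, 5, 5, 5))
  X <- build_event_design(ds)
  X[, "airpuff"] <- 0L
  cnt <- lhbaxis:::bin_counts(ds$spikes$time_s, ds$duration_s, 0.1)
  fit <- fit_event_glm(cnt, X)
  expect_true(fit$undefined[["airpuff"]])
  expect_true(is.na(fit$beta[["airpuff"]]))
})

test_that("circular shift preserves counts and offset zero is the identity", {
  ds <- flat_dataset(n_units = 1, seed = 33, block_trials = c(10, 20, 10, 10))
  X <- build_event_design(ds)
  cnt <- lhbaxis:::bin_counts(ds$spikes$time_s, ds$duration_s, 0.1)
  fit <- fit_event_glm(cnt, X)
  # multiset of counts preserved by rotation, exactly
  for (off in c(0, 17, 1000)) {
    expect_identical(sort(lhbaxis:::rotate_counts(cnt, off)), sort(cnt))
    expect_identical(sum(lhbaxis:::rotate_counts(cnt, off)), sum(cnt))
  }
  nl0 <- circular_shift_null(cnt, X, offsets = c(0L, 5L, 123L))
  expect_equal(unname(nl0$beta[1, ]), unname(fit$beta), tolerance = 1e-10)
  # FFT fast path equals the explicit refit for arbitrary offsets
  for (k in 2:3) {
    direct <- fit_event_glm(lhbaxis:::rotate_counts(cnt, nl0$offsets[k]), X)
    expect_equal(unname(nl0$beta[k, ]), unname(direct$beta),
                 tolerance = 1e-10)
  }
})

test_that("tuning scores are affine-equivariant and flags use percentiles", {
  set.seed(4)
  null <- matrix(rnorm(4000), 1000, 4,
                 dimnames = list(NULL, c("sound1", "opto", "sound2",
                                         "airpuff")))
  beta <- colMeans(null)
  sc <- score_and_classify(beta, null)
  expect_equal(unname(sc$score), rep(0, 4), tolerance = 1e-12)
  expect_true(all(sc$flag == "none"))
  # affine equivariance: rescaling null and beta leaves scores unchanged
  sc2 <- score_and_classify(beta * 3 + 1, null * 3 + 1)
  expect_equal(sc2$score, sc$score, tolerance = 1e-9)
  # heavy-tailed null: z = 2 but below the 99.9th percentile -> unflagged
  set.seed(5)
  heavy <- matrix(rt(4000, df = 2), 1000, 4,
                  dimnames = dimnames(null))
  b2 <- colMeans(heavy) + 2 * apply(heavy, 2, sd)
  sc3 <- score_and_classify(b2, heavy)
  expect_equal(unname(sc3$score), rep(2, 4), tolerance = 1e-9)
  expect_true(all(sc3$flag == "none"))
  # zero-sd null -> undefined score
  degen <- heavy; degen[, 2] <- 1
  sc4 <- score_and_classify(colMeans(degen), degen)
  expect_true(is.na(sc4$score[["opto"]]))
})

test_that("an unmodulated unit's coefficient sits inside its own null", {
  ds <- flat_dataset(n_units = 6, seed = 34)
  X <- build_event_design(ds)
  inside <- vapply(1:6, function(u) {
    cnt <- lhbaxis:::bin_counts(
      ds$spikes$time_s[ds$spikes$unit_id == u], ds$duration_s, 0.1)
    fit <- fit_event_glm(cnt, X)
    nl <- circular_shift_null(cnt, X, n = 400, seed = u)
    q <- apply(nl$beta, 2, quantile, c(0.025, 0.975))
    mean(fit$beta >= q[1, ] & fit$beta <= q[2, ])
  }, numeric(1))
  expect_gt(mean(inside), 0.8)
})

test_that("comodulated units have opto and air puff as their top tunings", {
  ds <- flat_dataset(n_units = 1, seed = 35, baseline_hz = 8,
                     event_gain = cbind(sound1 = 1, opto = 3, sound2 = 1,
                                        airpuff = 3))
  tt <- compute_tuning(ds, n_surrogates = 1000, seed = 9, conditioned = FALSE)
  expect_setequal(c(tt$primary, tt$secondary), c("opto", "airpuff"))
  expect_true(tt$comodulated)
})

test_that("opto tuning power grows with the true gain", {
  gains <- exp(c(0, 0.3, 0.6, 0.9))
  rate_flag <- vapply(seq_along(gains), function(gi) {
    ds <- simulate_population(population_design(
      n_units = 40, baseline_hz = 5, seed = 400 + gi,
      event_gain = cbind(sound1 = 1, opto = gains[gi], sound2 = 1,
                         airpuff = 1)))
    X <- build_event_design(ds)
    mean(vapply(1:40, function(u) {
      cnt <- lhbaxis:::bin_counts(
        ds$spikes$time_s[ds$spikes$unit_id == u], ds$duration_s, 0.1)
      fit <- fit_event_glm(cnt, X)
      nl <- circular_shift_null(cnt, X, n = 500, seed = u)
      score_and_classify(fit$beta, nl$beta)$flag[["opto"]] == "positive"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate_flag) >= 0))
  expect_lt(rate_flag[1], 0.05)
  expect_gte(rate_flag[4], 0.8)
})

test_that("conditioned flags require both tests of a block", {
  # no modulation at all -> not conditioned
  ds0 <- flat_dataset(n_units = 1, seed = 36)
  c0 <- conditioned_units(ds0, 1)
  expect_false(c0$conditioned_b2)
  expect_false(c0$conditioned_b4)
  # sound and air puff responses in block 4 -> conditioned there
  # gains chosen so the full 500 ms post-event rate is clearly elevated
  ds1 <- simulate_population(population_design(
    n_units = 1, baseline_hz = 5, seed = 37,
    event_gain = cbind(sound1 = 3.5, opto = 2.5, sound2 = 3.5,
                       airpuff = 2.5)))
  c1 <- conditioned_units(ds1, 1)
  expect_true(c1$conditioned_b2)
  expect_true(c1$conditioned_b4)
  expect_equal(c1$direction_b4, 1)
  # opto response without a tone response -> conjunction fails in block 2
  ds2 <- simulate_population(population_design(
    n_units = 1, baseline_hz = 5, seed = 38,
    event_gain = cbind(sound1 = 1, opto = 3, sound2 = 1, airpuff = 1)))
  c2 <- conditioned_units(ds2, 1)
  expect_false(c2$conditioned_b2)
  # too few trials -> not evaluable
  ds3 <- flat_dataset(n_units = 1, seed = 39, block_trials = c(5, 10, 5, 5))
  c3 <- conditioned_units(ds3, 1)
  expect_true(is.na(c3$conditioned_b2))
})

test_that("detecting a doubled post-event rate is well powered", {
  # sound gain 3.5 over its 200 ms window and opto gain 2 over its 500 ms
  # window both double the mean rate of the 500 ms post-event test window
  flags <- vapply(1:30, function(i) {
    ds <- simulate_population(population_design(
      n_units = 1, baseline_hz = 5, seed = 500 + i,
      event_gain = cbind(sound1 = 3.5, opto = 2, sound2 = 1, airpuff = 1)))
    isTRUE(conditioned_units(ds, 1)$conditioned_b2)
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("optotagging requires response probability, latency and waveform", {
  dur <- 600
  set.seed(6)
  pulses <- sort(runif(100, 1, dur - 1))
  spont <- sort(runif(2000, 0, dur))
  # reliable 3 ms latency, identical waveforms -> tagged
  driven <- sort(c(spont, pulses + 0.003))
  wf <- list(evoked = sin(seq(0, 3, 0.1)), spont = sin(seq(0, 3, 0.1)))
  r <- optotag(driven, pulses, dur, waveforms = wf, seed = 2)
  expect_true(r$tagged)
  expect_equal(r$response_prob, 1)
  # responds to only 5% of pulses -> rejected on response probability
  weak <- sort(c(spont, pulses[1:5] + 0.003))
  r2 <- optotag(weak, pulses, dur, waveforms = wf, seed = 2)
  expect_false(r2$response_pass)
  expect_false(r2$tagged)
  # waveform mismatch vetoes an otherwise responsive unit
  wf_bad <- list(evoked = sin(seq(0, 3, 0.1)), spont = cos(seq(0, 3, 0.1)))
  r3 <- optotag(driven, pulses, dur, waveforms = wf_bad, seed = 2)
  expect_false(r3$tagged)
  expect_false(r3$waveform_pass)
})
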