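# Single-unit in vivo pipeline: quality control, clock alignment, Poisson
# event GLM, circular-shift surrogate nulls, tuning scores and
# classification, conditioned-unit tests, optotag identification.

#' Unit quality control
#'
#' Retains units with mean firing rate above `min_rate_hz` and a fraction
#' of interspike intervals below the refractory bound smaller than
#' `max_isi_violation`.
#'
#' @param dataset a `spike_dataset`.
#' @param min_rate_hz minimum mean rate (Hz).
#' @param max_isi_violation maximum tolerated ISI-violation fraction.
#' @param refractory_ms refractory bound defining a violation (ms).
#' @return the dataset restricted to retained units; the per-unit QC table
#'   is attached as attribute `qc`.
#' @export
qc_filter <- function(dataset, min_rate_hz = 0.1, max_isi_violation = 0.01,
                      refractory_ms = 2) {
  stopifnot(inherits(dataset, "spike_dataset"))
  sp <- split(dataset$spikes$time_s, dataset$spikes$unit_id)
  ids <- dataset$units$unit_id
  qc <- data.frame(unit_id = ids, rate_hz = 0, isi_violation = 0,
                   pass = FALSE)
  for (i in seq_along(ids)) {
    st <- sp[[as.character(ids[i])]]
    if (is.null(st)) st <- numeric(0)
    qc$rate_hz[i] <- length(st) / dataset$duration_s
    isi <- diff(st)
    qc$isi_violation[i] <- if (length(isi)) mean(isi < refractory_ms / 1000) else 0
  }
  qc$pass <- qc$rate_hz > min_rate_hz & qc$isi_violation < max_isi_violation
  keep <- qc$unit_id[qc$pass]
  out <- dataset
  out$units <- dataset$units[dataset$units$unit_id %in% keep, ]
  out$spikes <- dataset$spikes[dataset$spikes$unit_id %in% keep, ]
  attr(out, "qc") <- qc
  out
}

#' Correct linear clock drift between two acquisition devices
#'
#' Fits timestamps of synchronisation events registered on device B against
#' the same events on device A by least squares and maps spike times
#' recorded on the A clock onto the B clock.
#'
#' @param spike_times spike times on the A clock (s).
#' @param sync_a,sync_b paired sync-event times on the two clocks (s).
#' @return corrected spike times; the fitted `intercept` and `slope` are
#'   attached as attributes.
#' @export
correct_clock_drift <- function(spike_times, sync_a, sync_b) {
  if (length(sync_a) < 2 || length(sync_a) != length(sync_b))
    stop("need at least 2 sync event pairs")
  fit <- lm(sync_b ~ sync_a)
  co <- coef(fit)
  structure(co[[1]] + co[[2]] * spike_times,
            intercept = co[[1]], slope = co[[2]])
}

# session-long bin counts for one unit
bin_counts <- function(spike_times, duration_s, bin_s) {
  n_bins <- floor(duration_s / bin_s + 1e-9)
  idx <- floor(spike_times / bin_s) + 1L
  idx <- idx[idx >= 1 & idx <= n_bins]
  tabulate(idx, n_bins)
}

#' Event regressor design matrix
#'
#' Binary indicator regressors binned at `bin_s`: sounds are active for
#' 200 ms after each onset, the optogenetic stimulation and the air puff
#' for 500 ms. A bin is active when its centre falls inside the window.
#'
#' @param dataset a `spike_dataset` (its `events` table is used).
#' @param bin_s bin width (s).
#' @return `n_bins x 4` 0/1 matrix with columns `sound1`, `opto`, `sound2`,
#'   `airpuff`.
#' @export
build_event_design <- function(dataset, bin_s = 0.1) {
  n_bins <- floor(dataset$duration_s / bin_s + 1e-9)
  win <- event_windows()
  X <- matrix(0L, n_bins, 4, dimnames = list(NULL, names(win)))
  centers <- (seq_len(n_bins) - 0.5) * bin_s
  for (r in seq_len(nrow(dataset$events))) {
    ev <- dataset$events$event[r]
    on <- dataset$events$onset_s[r]
    idx <- which(centers >= on & centers < on + win[[ev]])
    X[idx, ev] <- 1L
  }
  X
}

#' Poisson GLM of binned firing against the event regressors
#'
#' Log-link Poisson regression of 100-ms spike counts on the four binary
#' event regressors, with intercept. When the regressors form a partition
#' (binary, mutually non-overlapping, as the standard design does) the
#' maximum-likelihood coefficients have the closed form
#' `beta_j = log(mean count in regressor-j bins) - log(mean baseline
#' count)`, which is used directly; otherwise `stats::glm` is called. A
#' regressor never active in the session yields an `NA` coefficient.
#'
#' @param counts integer vector of per-bin spike counts.
#' @param design regressor matrix from [build_event_design()].
#' @return list: `beta` (named, length `ncol(design)`), `intercept`,
#'   `converged`, `undefined` (logical per regressor), `method`.
#' @export
fit_event_glm <- function(counts, design) {
  stopifnot(length(counts) == nrow(design))
  active <- colSums(design != 0) > 0
  if (is_partition_design(design)) {
    base <- rowSums(design) == 0
    mu0 <- mean(counts[base])
    beta <- rep(NA_real_, ncol(design))
    names(beta) <- colnames(design)
    for (j in seq_len(ncol(design))) {
      if (!active[j]) next
      beta[j] <- log(mean(counts[design[, j] == 1])) - log(mu0)
    }
    conv <- mu0 > 0 && all(is.finite(beta[active]))
    return(list(beta = beta, intercept = log(mu0), converged = conv,
                undefined = !active, method = "closed_form"))
  }
  X <- design[, active, drop = FALSE]
  fit <- suppressWarnings(glm(counts ~ X, family = poisson()))
  beta <- rep(NA_real_, ncol(design))
  names(beta) <- colnames(design)
  beta[active] <- coef(fit)[-1]
  list(beta = beta, intercept = coef(fit)[[1]], converged = fit$converged,
       undefined = !active, method = "glm")
}

is_partition_design <- function(design) {
  all(design %in% c(0, 1)) && max(rowSums(design)) <= 1
}

#' Circular-shift surrogate null distribution of the GLM coefficients
#'
#' For each surrogate the binned count vector is rotated by a random
#' offset (uniform over bins; rotation preserves the multiset of counts
#' exactly) and the GLM is refitted against the unchanged design. For the
#' standard partition design the refit reduces to group means of the
#' rotated vector, evaluated by direct indexing (the baseline group sum is
#' the total minus the event-group sums); the result is identical to
#' refitting explicitly.
#'
#' @param counts,design as in [fit_event_glm()].
#' @param n number of surrogates.
#' @param seed integer seed for the offsets.
#' @param offsets optional explicit offsets (0-based), overriding `n`/seed.
#' @return list: `beta` (`n x 4` matrix of surrogate coefficients),
#'   `offsets`.
#' @export
circular_shift_null <- function(counts, design, n = 1000, seed = 1,
                                offsets = NULL) {
  n_bins <- length(counts)
  if (n_bins < 10) stop("session too short for circular-shift surrogates")
  if (is.null(offsets))
    offsets <- with_seed(seed, sample.int(n_bins, n, replace = TRUE) - 1L)
  if (is_partition_design(design)) {
    total <- sum(counts)
    n_base <- sum(rowSums(design) == 0)
    # rotated group sum: S_j(off) = sum over i in group j of
    # counts[((i - 1 + off) mod n) + 1]; baseline = total - event groups
    S <- vapply(seq_len(ncol(design)), function(j) {
      idx <- which(design[, j] == 1)
      if (!length(idx)) return(rep(NA_real_, length(offsets)))
      pos <- outer(idx - 1L, offsets, `+`) %% n_bins + 1L
      colSums(matrix(counts[pos], nrow = length(idx)))
    }, numeric(length(offsets)))
    S <- matrix(S, ncol = ncol(design),
                dimnames = list(NULL, colnames(design)))
    ng <- colSums(design)
    S0 <- total - rowSums(S, na.rm = TRUE)
    mu <- sweep(S, 2, ng, `/`)
    beta <- log(mu) - log(S0 / n_base)
  } else {
    beta <- t(vapply(offsets, function(off) {
      rot <- rotate_counts(counts, off)
      fit_event_glm(rot, design)$beta
    }, numeric(ncol(design))))
  }
  list(beta = beta, offsets = offsets)
}

# rotate so that rotated[i] = counts[((i - 1 + off) mod n) + 1]
rotate_counts <- function(counts, off) {
  n <- length(counts)
  off <- off %% n
  if (off == 0) return(counts)
  c(counts[(off + 1):n], counts[1:off])
}

#' Tuning scores and significance classification
#'
#' The tuning score per regressor is the z-statistic of the fitted
#' coefficient against its surrogate null: (beta - null mean) / null s.d.
#' A unit is positively tuned to a regressor when beta exceeds the 99.9th
#' percentile of the null, negatively tuned when it falls below the 0.01th
#' percentile. Primary/secondary tunings rank the absolute scores;
#' a unit is comodulated when its primary and secondary tunings are the
#' optogenetic and air-puff regressors (in either order) and both are
#' significant.
#'
#' @param beta named coefficient vector from [fit_event_glm()].
#' @param null surrogate coefficient matrix from [circular_shift_null()].
#' @param pos_pct,neg_pct percentile thresholds (on a 0-100 scale).
#' @return list: `score`, `flag` (`"positive"`/`"negative"`/`"none"`, `NA`
#'   when the null s.d. is zero), `primary`, `secondary`, `comodulated`.
#' @export
score_and_classify <- function(beta, null, pos_pct = 99.9, neg_pct = 0.01) {
  mu <- colMeans(null)
  sdv <- apply(null, 2, sd)
  score <- ifelse(sdv > 0, (beta - mu) / sdv, NA_real_)
  names(score) <- names(beta)
  # (n+1)p order-statistic convention (quantile type 6): with 1,000
  # surrogates the 99.9th percentile is the sample maximum, so the flag
  # has its nominal 0.1% tail mass
  qhi <- apply(null, 2, quantile, probs = pos_pct / 100, names = FALSE,
               type = 6)
  qlo <- apply(null, 2, quantile, probs = neg_pct / 100, names = FALSE,
               type = 6)
  flag <- ifelse(is.na(score), NA_character_,
          ifelse(beta > qhi, "positive",
          ifelse(beta < qlo, "negative", "none")))
  names(flag) <- names(beta)
  ord <- order(-abs(score))
  primary <- names(beta)[ord[1]]
  secondary <- names(beta)[ord[2]]
  sig <- !is.na(flag) & flag != "none"
  comod <- setequal(c(primary, secondary), c("opto", "airpuff")) &&
    sig[primary] && sig[secondary]
  list(score = score, flag = flag, primary = primary,
       secondary = secondary, comodulated = comod)
}

#' Conditioned-unit tests
#'
#' Four paired Wilcoxon signed-rank tests per unit: tone and optogenetic
#' stimulation in block 2, the novel sound and the air puff in block 4.
#' Each compares the mean rate in the 500 ms before the sound onset with
#' the 500 ms after the tested event onset, over 50 trials (block 2 keeps
#' the even-indexed trials for 50-trial parity). A unit is conditioned in a
#' block when both of that block's tests are significant at the
#' Bonferroni-corrected alpha.
#'
#' @param dataset a `spike_dataset`.
#' @param unit_id unit to test.
#' @param alpha per-test significance level (default 0.001/4).
#' @param n_trials trials required per comparison.
#' @return list: `conditioned_b2`, `conditioned_b4` (logical, `NA` when not
#'   evaluable), `direction_b2`, `direction_b4` (+1/-1), `p` (named vector).
#' @export
conditioned_units <- function(dataset, unit_id, alpha = 0.001 / 4,
                              n_trials = 50) {
  st <- dataset$spikes$time_s[dataset$spikes$unit_id == unit_id]
  tr <- dataset$trials
  ev <- dataset$events
  rate_in <- function(t0) {
    vapply(t0, function(a) sum(st >= a & st < a + 0.5) / 0.5, numeric(1))
  }
  test_pair <- function(sound_on, event_on) {
    base <- rate_in(sound_on - 0.5)
    post <- rate_in(event_on)
    if (all(base == post)) return(list(p = 1, dir = 0))
    wt <- suppressWarnings(wilcox.test(post, base, paired = TRUE,
                                       exact = FALSE))
    list(p = wt$p.value, dir = sign(median(post - base)))
  }
  res <- list(conditioned_b2 = NA, conditioned_b4 = NA,
              direction_b2 = NA_real_, direction_b4 = NA_real_,
              p = c(tone_b2 = NA_real_, opto_b2 = NA_real_,
                    sound_b4 = NA_real_, airpuff_b4 = NA_real_))
  b2 <- tr[tr$block == 2, ]
  if (nrow(b2) >= 2 * n_trials - 1) {
    b2 <- b2[seq_len(nrow(b2)) %% 2 == 0, ]  # even-indexed trials kept
    b2 <- head(b2, n_trials)
    op <- ev[ev$event == "opto" & ev$trial_id %in% b2$trial_id, ]
    t1 <- test_pair(b2$onset_s, b2$onset_s)
    t2 <- test_pair(b2$onset_s, op$onset_s[match(b2$trial_id, op$trial_id)])
    res$p["tone_b2"] <- t1$p; res$p["opto_b2"] <- t2$p
    res$conditioned_b2 <- t1$p < alpha && t2$p < alpha
    res$direction_b2 <- t2$dir
  }
  b4 <- tr[tr$block == 4, ]
  if (nrow(b4) >= n_trials) {
    b4 <- head(b4, n_trials)
    ap <- ev[ev$event == "airpuff" & ev$trial_id %in% b4$trial_id, ]
    t3 <- test_pair(b4$onset_s, b4$onset_s)
    t4 <- test_pair(b4$onset_s, ap$onset_s[match(b4$trial_id, ap$trial_id)])
    res$p["sound_b4"] <- t3$p; res$p["airpuff_b4"] <- t4$p
    res$conditioned_b4 <- t3$p < alpha && t4$p < alpha
    res$direction_b4 <- t4$dir
  }
  res
}

#' Optotag identification
#'
#' A unit is optotagged when (i) it responds within the 10 ms bin after
#' more than `min_response` of the laser pulses, (ii) its post-pulse
#' first-spike latencies are significantly shorter than expected by chance
#' (permutation test against circularly shifted pulse trains at
#' `alpha`), and (iii) when waveforms are supplied, the mean light-evoked
#' and spontaneous waveforms correlate with Pearson r > `min_waveform_r`
#' (skipped with a warning otherwise).
#'
#' The latency statistic is the mean first-spike latency after the pulses,
#' censored at `cap_s`; its null distribution comes from `n_surrogates`
#' circular shifts of the pulse train; the permutation p-value uses the
#' add-one rule and the significance comparison is strict (p < alpha),
#' keeping the false-positive rate below `alpha`.
#'
#' @param spike_times sorted spike times (s).
#' @param pulse_times laser pulse onsets (s); at least 100 expected.
#' @param duration_s session duration (s).
#' @param response_win_s post-pulse response bin (s).
#' @param min_response minimum response probability.
#' @param alpha latency-test significance level.
#' @param n_surrogates surrogate pulse trains.
#' @param cap_s censoring bound of the latency statistic (s).
#' @param waveforms optional list with `evoked` and `spont` mean waveforms.
#' @param min_waveform_r waveform-correlation criterion.
#' @param seed integer seed for the surrogates.
#' @return list: `tagged`, `response_prob`, `latency_p`, `waveform_r`
#'   (`NA` when skipped), and per-criterion logicals.
#' @export
optotag <- function(spike_times, pulse_times, duration_s,
                    response_win_s = 0.01, min_response = 0.1,
                    alpha = 0.01, n_surrogates = 199, cap_s = 0.1,
                    waveforms = NULL, min_waveform_r = 0.9, seed = 1) {
  spike_times <- sort(spike_times)
  n_p <- length(pulse_times)
  if (n_p < 2) stop("need laser pulses")
  lat_stat <- function(p) {
    idx <- findInterval(p, spike_times)
    nxt <- spike_times[pmin(idx + 1L, length(spike_times))]
    lat <- nxt - p
    lat[idx >= length(spike_times) | lat < 0] <- Inf
    mean(pmin(lat, cap_s))
  }
  idx <- findInterval(pulse_times, spike_times)
  nxt_ok <- idx < length(spike_times)
  lat <- rep(Inf, n_p)
  lat[nxt_ok] <- spike_times[idx[nxt_ok] + 1L] - pulse_times[nxt_ok]
  response_prob <- mean(lat <= response_win_s)
  obs <- mean(pmin(lat, cap_s))
  null <- with_seed(seed, {
    offs <- runif(n_surrogates, 0, duration_s)
    vapply(offs, function(o) lat_stat((pulse_times + o) %% duration_s),
           numeric(1))
  })
  latency_p <- (1 + sum(null <= obs)) / (n_surrogates + 1)
  waveform_r <- NA_real_
  waveform_pass <- TRUE
  if (!is.null(waveforms)) {
    waveform_r <- cor(waveforms$evoked, waveforms$spont)
    waveform_pass <- waveform_r > min_waveform_r
  } else {
    warning("no waveforms supplied; waveform criterion skipped")
  }
  resp_pass <- response_prob > min_response
  lat_pass <- latency_p < alpha
  list(tagged = resp_pass && lat_pass && waveform_pass,
       response_prob = response_prob, latency_p = latency_p,
       waveform_r = waveform_r, response_pass = resp_pass,
       latency_pass = lat_pass, waveform_pass = waveform_pass)
}

#' Full tuning table of a dataset
#'
#' Runs QC, the event GLM, the circular-shift null, scoring and the
#' conditioned-unit tests for every retained unit.
#'
#' @param dataset a `spike_dataset`.
#' @param bin_s GLM bin width (s).
#' @param n_surrogates surrogates per unit.
#' @param seed integer seed.
#' @param conditioned whether to run the conditioned-unit tests.
#' @return data.frame (one row per retained unit) with coefficients,
#'   scores, flags, primary/secondary tuning, comodulation and conditioned
#'   flags; class `tuning_table`.
#' @export
compute_tuning <- function(dataset, bin_s = 0.1, n_surrogates = 1000,
                           seed = 1, conditioned = TRUE) {
  ds <- qc_filter(dataset)
  design <- build_event_design(ds, bin_s)
  ids <- ds$units$unit_id
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    st <- ds$spikes$time_s[ds$spikes$unit_id == ids[i]]
    counts <- bin_counts(st, ds$duration_s, bin_s)
    fit <- fit_event_glm(counts, design)
    null <- circular_shift_null(counts, design, n = n_surrogates,
                                seed = seed + i)
    sc <- score_and_classify(fit$beta, null$beta)
    row <- data.frame(unit_id = ids[i], converged = fit$converged,
                      t(fit$beta), t(sc$score), t(sc$flag),
                      primary = sc$primary, secondary = sc$secondary,
                      comodulated = sc$comodulated)
    names(row)[3:6] <- paste0("beta_", names(fit$beta))
    names(row)[7:10] <- paste0("score_", names(fit$beta))
    names(row)[11:14] <- paste0("flag_", names(fit$beta))
    if (conditioned) {
      cu <- conditioned_units(ds, ids[i])
      row$conditioned_b2 <- cu$conditioned_b2
      row$conditioned_b4 <- cu$conditioned_b4
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tuning_table", class(out))
  out
}
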