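# Block-structured spike-train generator: inhomogeneous Poisson units whose
# rate is baseline x block multiplier x event gain inside event-response
# windows, matching the linear-event assumption of the tuning GLM.

#' Population recording design
#'
#' Describes a four-block head-fixed session: block 1 tone only, block 2
#' tone followed by optogenetic stimulation (500 ms, starting 500 ms after
#' tone end), block 3 tone only, block 4 a new sound followed by an air puff
#' (50 ms, starting 500 ms after sound end). Event-response windows (during
#' which the event gain multiplies the rate) are 200 ms for sounds and
#' 500 ms for the optogenetic stimulation and the air puff.
#'
#' @param n_units number of units.
#' @param block_trials trials per block; default `c(50, 100, 50, 50)`.
#' @param trial_s nominal trial duration (s); the sound onset sits
#'   `sound_onset_s` into the trial so that a (-2.1, -0.1) s pre-sound
#'   baseline exists.
#' @param iti_jitter_s maximum inter-trial jitter (s): each trial is
#'   extended by a uniform multiple of 100 ms up to this value, as in a
#'   real session. The jitter keeps event onsets on the 100 ms analysis
#'   grid while making the event schedule aperiodic (without it, circular
#'   shifts by whole trials would map event windows onto themselves and
#'   degenerate the surrogate null).
#' @param sound_onset_s sound onset relative to trial start (s).
#' @param baseline_hz per-unit baseline rate (recycled); default draws
#'   log-normal rates with median 5 Hz, s.d. of log 0.4.
#' @param event_gain `n_units x 4` matrix of multiplicative gains for the
#'   regressors (columns `sound1`, `opto`, `sound2`, `airpuff`); default 1.
#' @param block_gain `n_units x 4` matrix of per-block baseline
#'   multipliers; default 1.
#' @param region,genotype unit metadata labels (recycled).
#' @param refractory_s absolute refractory period enforced on the spike
#'   trains (s); spikes closer than this to their predecessor are dropped,
#'   as in a real unit (and as assumed by the ISI-violation QC rule).
#' @param seed integer seed used by [simulate_population()].
#' @return object of class `population_design`.
#' @export
population_design <- function(n_units = 40,
                              block_trials = c(50, 100, 50, 50),
                              trial_s = 6, sound_onset_s = 2.2,
                              iti_jitter_s = 1, baseline_hz = NULL,
                              event_gain = NULL, block_gain = NULL,
                              region = "PL", genotype = "Esr1",
                              refractory_s = 0.002, seed = 1) {
  stopifnot(n_units >= 1, length(block_trials) == 4, all(block_trials > 0),
            trial_s > sound_onset_s + 1.2, sound_onset_s >= 2.1,
            iti_jitter_s >= 0)
  n_tr <- sum(block_trials)
  trial_len <- trial_s + with_seed(seed + 555L,
    sample(seq(0, iti_jitter_s, by = 0.1), n_tr, replace = TRUE))
  if (is.null(baseline_hz)) {
    baseline_hz <- with_seed(seed + 777L, rlnorm(n_units, log(5), 0.4))
  } else baseline_hz <- rep_len(baseline_hz, n_units)
  if (any(baseline_hz < 0)) stop("invalid design: negative baseline rates")
  ev <- c("sound1", "opto", "sound2", "airpuff")
  if (is.null(event_gain))
    event_gain <- matrix(1, n_units, 4, dimnames = list(NULL, ev))
  if (is.null(block_gain)) block_gain <- matrix(1, n_units, 4)
  if (nrow(event_gain) == 1 && n_units > 1)
    event_gain <- event_gain[rep(1, n_units), , drop = FALSE]
  if (nrow(block_gain) == 1 && n_units > 1)
    block_gain <- block_gain[rep(1, n_units), , drop = FALSE]
  stopifnot(nrow(event_gain) == n_units, nrow(block_gain) == n_units)
  colnames(event_gain) <- ev
  if (any(event_gain < 0) || any(block_gain < 0))
    stop("invalid design: negative gains")
  structure(list(n_units = n_units, block_trials = block_trials,
                 trial_s = trial_s, trial_len_s = trial_len,
                 sound_onset_s = sound_onset_s,
                 baseline_hz = baseline_hz, event_gain = event_gain,
                 block_gain = block_gain,
                 region = rep_len(region, n_units),
                 genotype = rep_len(genotype, n_units),
                 refractory_s = refractory_s, seed = seed),
            class = "population_design")
}

# event-response windows (s), shared with the GLM design builder
event_windows <- function() {
  c(sound1 = 0.2, opto = 0.5, sound2 = 0.2, airpuff = 0.5)
}

# trials and events tables for a design; onset_s is the sound onset
design_trials <- function(design) {
  n_tr <- sum(design$block_trials)
  block <- rep(1:4, design$block_trials)
  trial_id <- seq_len(n_tr)
  start_s <- cumsum(c(0, design$trial_len_s[-n_tr]))
  onset_s <- start_s + design$sound_onset_s
  trials <- data.frame(trial_id, block, start_s, onset_s)
  ev <- list()
  snd <- ifelse(block == 4, "sound2", "sound1")
  ev[[1]] <- data.frame(trial_id, event = snd, onset_s, duration_s = 0.2)
  b2 <- trials$block == 2
  ev[[2]] <- data.frame(trial_id = trial_id[b2], event = "opto",
                        onset_s = onset_s[b2] + 0.7, duration_s = 0.5)
  b4 <- trials$block == 4
  ev[[3]] <- data.frame(trial_id = trial_id[b4], event = "airpuff",
                        onset_s = onset_s[b4] + 0.7, duration_s = 0.05)
  events <- do.call(rbind, ev)
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL
  list(trials = trials, events = events)
}

#' Simulate a block-structured spike dataset
#'
#' Inhomogeneous Poisson spike trains with piecewise-constant rates:
#' baseline x per-block multiplier, further multiplied by the event gain
#' inside each event-response window; an absolute refractory period is then
#' enforced by dead-time thinning (at the default 2 ms this removes about
#' 1\% of spikes at 5 Hz). Ground-truth gains are kept in the output for
#' recovery tests.
#'
#' @param design a [population_design()].
#' @return object of class `spike_dataset`: `spikes` (data.frame `unit_id`,
#'   `time_s`; strictly increasing within unit), `units` metadata, `trials`,
#'   `events`, `duration_s` and `truth` (generative gains).
#' @export
simulate_population <- function(design) {
  stopifnot(inherits(design, "population_design"))
  dt_tab <- design_trials(design)
  trials <- dt_tab$trials; events <- dt_tab$events
  duration_s <- sum(design$trial_len_s)
  win <- event_windows()
  # segment grid per trial: baseline / sound / gap / aversive / rest
  seg <- list()
  for (k in seq_len(nrow(trials))) {
    on <- trials$onset_s[k]; bl <- trials$block[k]
    t0 <- trials$start_s[k]; t1 <- t0 + design$trial_len_s[k]
    snd_ev <- if (bl == 4) "sound2" else "sound1"
    cuts <- c(t0, on, on + win[[snd_ev]], on + 0.7, t1)
    avers <- if (bl == 2) "opto" else if (bl == 4) "airpuff" else NA
    if (!is.na(avers)) {
      cuts <- c(cuts[1:4], on + 0.7 + win[[avers]], t1)
      ev_of <- c(NA, snd_ev, NA, avers, NA)
    } else {
      ev_of <- c(NA, snd_ev, NA, NA)
    }
    seg[[k]] <- data.frame(t0 = cuts[-length(cuts)], t1 = cuts[-1],
                           block = bl, event = ev_of)
  }
  seg <- do.call(rbind, seg)
  seg_len <- seg$t1 - seg$t0
  spikes <- with_seed(design$seed, {
    out <- vector("list", design$n_units)
    for (u in seq_len(design$n_units)) {
      r <- design$baseline_hz[u] * design$block_gain[u, seg$block]
      has_ev <- !is.na(seg$event)
      r[has_ev] <- r[has_ev] * design$event_gain[u, seg$event[has_ev]]
      n <- rpois(nrow(seg), r * seg_len)
      tot <- sum(n)
      if (tot == 0) { out[[u]] <- numeric(0); next }
      st <- rep(seg$t0, n) + runif(tot) * rep(seg_len, n)
      st <- sort(st)
      if (design$refractory_s > 0 && length(st) > 1) {
        keep <- logical(length(st))
        keep[1] <- TRUE
        last <- st[1]
        for (k in 2:length(st)) {
          if (st[k] - last >= design$refractory_s) { keep[k] <- TRUE; last <- st[k] }
        }
        st <- st[keep]
      } else {
        dup <- c(FALSE, diff(st) <= 0)
        if (any(dup)) st <- st[!dup]
      }
      out[[u]] <- st
    }
    data.frame(unit_id = rep(seq_len(design$n_units), lengths(out)),
               time_s = unlist(out))
  })
  structure(list(spikes = spikes,
                 units = data.frame(unit_id = seq_len(design$n_units),
                                    region = design$region,
                                    genotype = design$genotype,
                                    baseline_hz = design$baseline_hz),
                 trials = trials, events = events, duration_s = duration_s,
                 truth = list(event_gain = design$event_gain,
                              block_gain = design$block_gain),
                 design = design),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset>", nrow(x$units), "units,", nrow(x$spikes), "spikes,",
      nrow(x$trials), "trials over", x$duration_s, "s\n")
  invisible(x)
}

#' Simulate soma axis measurements
#'
#' Generates the two perpendicular major axes (X, Y) and the 25\%/75\%
#' chords (Ymajor, Yminor) of soma profiles of a requested shape class, with
#' multiplicative jitter. Round somata have X = Y and equal chords;
#' elongated somata have X/Y about 2.1; triangular somata have
#' Ymajor/Yminor about 1.5.
#'
#' @param shape one of `"round"`, `"elongated"`, `"triangular"`.
#' @param size_um characteristic diameter (micrometres).
#' @param n number of somata.
#' @param jitter_cv multiplicative jitter CV per axis (0 for exact shapes).
#' @param seed integer seed.
#' @return data.frame with columns `X`, `Y`, `Ymajor`, `Yminor`,
#'   `area_um2`, `shape`.
#' @export
simulate_soma <- function(shape = c("round", "elongated", "triangular"),
                          size_um = 15, n = 1, jitter_cv = 0.05, seed = 1) {
  shape <- match.arg(shape)
  if (size_um <= 0) stop("size_um must be positive")
  base <- switch(shape,
    round      = c(X = 1,   Y = 1,    Ymajor = 0.866, Yminor = 0.866),
    elongated  = c(X = 2.1, Y = 1,    Ymajor = 0.866, Yminor = 0.866),
    triangular = c(X = 1,   Y = 0.95, Ymajor = 1.05,  Yminor = 0.70))
  with_seed(seed, {
    m <- matrix(rep(base * size_um, each = n), n, 4)
    if (jitter_cv > 0)
      m <- m * matrix(rlnorm(4 * n, -jitter_cv^2 / 2, jitter_cv), n, 4)
    colnames(m) <- names(base)
    df <- as.data.frame(m)
    df$area_um2 <- pi * df$X * df$Y / 4
    df$shape <- shape
    df
  })
}
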