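#' Archetype specification for the sweep simulator
#'
#' Bundles the membrane parameters of an adaptive exponential
#' integrate-and-fire (AdEx) neuron with a stereotyped action-potential
#' waveform template and a tonic-firing description. Six named archetypes
#' covering the firing phenotypes of hypothalamus-to-habenula projection
#' neurons (fast-adapting, bursting, regular-spiking and late-spiking with
#' narrow or wide spikes) are provided by [lhb_archetypes()].
#'
#' @param name archetype label.
#' @param C_pF membrane capacitance (pF).
#' @param gL_nS leak conductance (nS).
#' @param EL_mV leak reversal / resting potential (mV).
#' @param VT_mV spike-initiation threshold of the exponential term (mV).
#' @param DeltaT_mV spike-initiation sharpness (mV).
#' @param a_nS subthreshold adaptation coupling (nS); negative values give
#'   delayed ("late-spiking") onsets.
#' @param tau_w_ms adaptation time constant (ms).
#' @param b_pA spike-triggered adaptation increment (pA).
#' @param Vreset_mV post-spike reset potential (mV).
#' @param tonic_rate_hz,tonic_rate_sd_hz mean and s.d. (across neurons) of the
#'   spontaneous tonic firing rate (Hz); all archetypes fire spontaneously.
#' @param tonic_shape shape of the gamma renewal process used for spontaneous
#'   interspike intervals (larger = more regular).
#' @param ap named list of waveform-template parameters, see
#'   [ap_template_params()].
#' @param jitter_cv coefficient of variation of the per-neuron multiplicative
#'   parameter jitter (applied to C, gL, tau_w, b and waveform widths);
#'   voltage-valued parameters receive additive jitter of `10 * jitter_cv` mV.
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, C_pF, gL_nS, EL_mV, VT_mV, DeltaT_mV,
                           a_nS, tau_w_ms, b_pA, Vreset_mV,
                           tonic_rate_hz, tonic_rate_sd_hz = tonic_rate_hz / 4,
                           tonic_shape = 4,
                           ap = ap_template_params(),
                           jitter_cv = 0.1) {
  stopifnot(C_pF > 0, gL_nS > 0, DeltaT_mV > 0, tau_w_ms > 0,
            tonic_rate_hz > 0, jitter_cv >= 0)
  structure(list(name = name, C_pF = C_pF, gL_nS = gL_nS, EL_mV = EL_mV,
                 VT_mV = VT_mV, DeltaT_mV = DeltaT_mV, a_nS = a_nS,
                 tau_w_ms = tau_w_ms, b_pA = b_pA, Vreset_mV = Vreset_mV,
                 tonic_rate_hz = tonic_rate_hz,
                 tonic_rate_sd_hz = tonic_rate_sd_hz,
                 tonic_shape = tonic_shape, ap = ap, jitter_cv = jitter_cv),
            class = "archetype_spec")
}

#' Action-potential waveform template parameters
#'
#' The simulator splices a stereotyped spike waveform onto the AdEx
#' trajectory at every threshold crossing, so that waveform-shape features
#' (half-width, up/downstroke, afterpotentials) are defined. The template is
#' an additive deviation that decays back to the subthreshold trajectory.
#'
#' @param amp_mV spike amplitude above threshold (mV).
#' @param rise_ms threshold-to-peak time (ms).
#' @param fall_ms peak-to-trough repolarisation time (ms).
#' @param ahp_amp_mV depth of the afterhyperpolarisation below the local
#'   trajectory (mV); recovered with time constant `ahp_tau_ms`.
#' @param ahp_tau_ms AHP recovery time constant (ms).
#' @param adp_amp_mV afterdepolarisation hump amplitude (mV); 0 disables it.
#' @param adp_rise_ms time from the fast-repolarisation trough to the ADP
#'   peak (ms).
#' @param adp_tau_ms decay time constant of the ADP hump (ms).
#' @return named list of template parameters.
#' @export
ap_template_params <- function(amp_mV = 85, rise_ms = 0.4, fall_ms = 0.6,
                               ahp_amp_mV = 6, ahp_tau_ms = 30,
                               adp_amp_mV = 0, adp_rise_ms = 5,
                               adp_tau_ms = 15) {
  stopifnot(amp_mV > 0, rise_ms > 0, fall_ms > 0, ahp_tau_ms > 0)
  list(amp_mV = amp_mV, rise_ms = rise_ms, fall_ms = fall_ms,
       ahp_amp_mV = ahp_amp_mV, ahp_tau_ms = ahp_tau_ms,
       adp_amp_mV = adp_amp_mV, adp_rise_ms = adp_rise_ms,
       adp_tau_ms = adp_tau_ms)
}

#' The six built-in electrophysiological archetypes
#'
#' Returns specifications for the six firing phenotypes used throughout the
#' package: FA-Bk (fast adapting with a pronounced fast AHP), Burst
#' (doublet/burst onset via a high reset and strong spike-triggered
#' adaptation), RS-N (regular spiking, narrow spikes), LS-N (late spiking,
#' narrow spikes; negative subthreshold adaptation delays the first spike),
#' LS-W (late spiking, wide spikes) and RS-W (regular spiking, wide spikes).
#' The AdEx parameter regimes follow the classical tonic / adapting /
#' bursting / delayed families; waveform templates and tonic rates are set so
#' that the archetypes are separable in the extracted feature space.
#'
#' @param jitter_cv per-neuron parameter jitter applied when simulating; the
#'   default 0.1 (10\% coefficient of variation) is a typical within-type
#'   biological variability for intrinsic parameters.
#' @return named list of six [archetype_spec()] objects.
#' @export
lhb_archetypes <- function(jitter_cv = 0.1) {
  list(
    `FA-Bk` = archetype_spec("FA-Bk", C_pF = 200, gL_nS = 12, EL_mV = -70,
      VT_mV = -50, DeltaT_mV = 2, a_nS = 2, tau_w_ms = 300, b_pA = 60,
      Vreset_mV = -58, tonic_rate_hz = 10, tonic_rate_sd_hz = 2,
      ap = ap_template_params(amp_mV = 88, rise_ms = 0.35, fall_ms = 0.5,
                              ahp_amp_mV = 9, ahp_tau_ms = 25),
      jitter_cv = jitter_cv),
    Burst = archetype_spec("Burst", C_pF = 200, gL_nS = 10, EL_mV = -58,
      VT_mV = -50, DeltaT_mV = 2, a_nS = 2, tau_w_ms = 120, b_pA = 100,
      Vreset_mV = -46, tonic_rate_hz = 6, tonic_rate_sd_hz = 1.5,
      ap = ap_template_params(amp_mV = 80, rise_ms = 0.5, fall_ms = 0.9,
                              ahp_amp_mV = 5, ahp_tau_ms = 40,
                              adp_amp_mV = 4, adp_rise_ms = 5),
      jitter_cv = jitter_cv),
    `RS-N` = archetype_spec("RS-N", C_pF = 200, gL_nS = 10, EL_mV = -70,
      VT_mV = -50, DeltaT_mV = 2, a_nS = 2, tau_w_ms = 30, b_pA = 0,
      Vreset_mV = -58, tonic_rate_hz = 8, tonic_rate_sd_hz = 2,
      ap = ap_template_params(amp_mV = 85, rise_ms = 0.4, fall_ms = 0.55,
                              ahp_amp_mV = 6, ahp_tau_ms = 30),
      jitter_cv = jitter_cv),
    `LS-N` = archetype_spec("LS-N", C_pF = 200, gL_nS = 12, EL_mV = -70,
      VT_mV = -50, DeltaT_mV = 2, a_nS = -8, tau_w_ms = 300, b_pA = 0,
      Vreset_mV = -58, tonic_rate_hz = 3, tonic_rate_sd_hz = 1,
      ap = ap_template_params(amp_mV = 84, rise_ms = 0.45, fall_ms = 0.6,
                              ahp_amp_mV = 7, ahp_tau_ms = 35),
      jitter_cv = jitter_cv),
    `LS-W` = archetype_spec("LS-W", C_pF = 100, gL_nS = 10, EL_mV = -65,
      VT_mV = -50, DeltaT_mV = 2, a_nS = -6, tau_w_ms = 90, b_pA = 30,
      Vreset_mV = -47, tonic_rate_hz = 2, tonic_rate_sd_hz = 0.6,
      ap = ap_template_params(amp_mV = 78, rise_ms = 0.9, fall_ms = 1.6,
                              ahp_amp_mV = 4, ahp_tau_ms = 50),
      jitter_cv = jitter_cv),
    `RS-W` = archetype_spec("RS-W", C_pF = 250, gL_nS = 8, EL_mV = -68,
      VT_mV = -48, DeltaT_mV = 2.5, a_nS = 4, tau_w_ms = 150, b_pA = 20,
      Vreset_mV = -60, tonic_rate_hz = 4.5, tonic_rate_sd_hz = 1.2,
      ap = ap_template_params(amp_mV = 82, rise_ms = 0.8, fall_ms = 1.4,
                              ahp_amp_mV = 4, ahp_tau_ms = 45),
      jitter_cv = jitter_cv)
  )
}

#' Current-clamp protocol specification
#'
#' @param fs_hz sampling rate (Hz).
#' @param step_s duration of the current step (s); the analysis conventions
#'   assume the standard 1-s step.
#' @param pre_s baseline recorded before step onset (s).
#' @param post_s window recorded after step offset (s); defaults to the
#'   150 ms used by the post-step voltage feature.
#' @param amps_pA injected step amplitudes (pA); must include the
#'   hyperpolarising -40 and +/-20 pA steps used for the passive features and
#'   a depolarising ladder bracketing rheobase.
#' @param holding_mV holding potential before the step (mV).
#' @param n_tau_sweeps number of repeated -40 pA responses simulated for the
#'   membrane time-constant average (up to 20 are used by the extractor).
#' @param spont_s duration of the spontaneous cell-attached trace (s).
#' @param noise_sd_pA s.d. of the white current noise added during
#'   integration (pA); 0 gives a fully deterministic trajectory.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(fs_hz = 20000, step_s = 1, pre_s = 0.1,
                          post_s = 0.15,
                          amps_pA = c(-40, -20, 20, seq(40, 560, by = 20)),
                          holding_mV = -70, n_tau_sweeps = 5,
                          spont_s = 10, noise_sd_pA = 2) {
  if (fs_hz <= 0 || step_s <= 0)
    stop("invalid protocol: sampling rate and step duration must be positive")
  stopifnot(pre_s >= 0, post_s >= 0, length(amps_pA) >= 1, spont_s >= 0,
            noise_sd_pA >= 0, n_tau_sweeps >= 0)
  structure(list(fs_hz = fs_hz, step_s = step_s, pre_s = pre_s,
                 post_s = post_s, amps_pA = amps_pA,
                 holding_mV = holding_mV, n_tau_sweeps = n_tau_sweeps,
                 spont_s = spont_s, noise_sd_pA = noise_sd_pA),
            class = "protocol_spec")
}
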