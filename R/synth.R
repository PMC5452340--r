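#' Configuration of the synthetic epileptiform-recording generator
#'
#' Describes the statistical structure of a synthetic dual voltage-clamp
#' recording of epileptiform activity: a train of bursts, each a
#' shot-noise sum of unitary synaptic events under a rise/decay envelope,
#' with burst-to-burst variability in amplitude and in the
#' inhibitory/excitatory charge ratio, and seconds-scale interburst
#' intervals drawn from a gamma distribution parameterised by mean and CV.
#'
#' Defaults emulate the recorded templates this pipeline replaces: 24
#' consecutive bursts, interburst intervals of a few seconds, charge ratios
#' scattered around ~1.2, inhibition lagging excitation within each burst
#' (feed-forward interneuron recruitment follows the pyramidal discharge in
#' interictal events), and burst amplitudes spread so that playback of the
#' threshold-calibrated template drives roughly 1-5 APs per burst.
#'
#' @param n_bursts number of bursts (>= 1).
#' @param rise_ms,decay_ms envelope rise and decay constants (ms) of the
#'   excitatory barrage; the inhibitory envelope decays `i_decay_scale`
#'   times slower.
#' @param peak_gE_nS target peak excitatory conductance of the strongest
#'   burst (nS) before any threshold scaling.
#' @param burst_amp_cv lognormal CV of the per-burst amplitude factor.
#' @param ibi_mean_s,ibi_cv mean (s) and CV of the gamma-distributed
#'   interburst intervals.
#' @param ratio_mean,ratio_sd mean and SD of the per-burst inhibitory to
#'   excitatory charge ratio (lognormal).
#' @param event_rate_hz peak within-burst unitary event rate (Hz).
#' @param noise_sd_pA additive Gaussian recording noise (pA).
#' @param i_decay_scale inhibitory envelope decay relative to excitatory.
#' @param i_delay_ms onset lag of the inhibitory envelope within each burst
#'   (ms).
#' @param dt_ms sampling interval (ms).
#' @return Object of class `template_gen_config`.
#' @export
template_gen_config <- function(n_bursts = 24, rise_ms = 8, decay_ms = 60,
                                peak_gE_nS = 30, burst_amp_cv = 0.15,
                                ibi_mean_s = 3, ibi_cv = 0.4,
                                ratio_mean = 1.2, ratio_sd = 0.4,
                                event_rate_hz = 400, noise_sd_pA = 2,
                                i_decay_scale = 1.5, i_delay_ms = 15,
                                dt_ms = 0.1) {
  stopifnot(n_bursts >= 1, rise_ms > 0, decay_ms > rise_ms, peak_gE_nS > 0,
            ibi_mean_s > 0, ibi_cv > 0, ratio_mean > 0, ratio_sd > 0,
            event_rate_hz >= 0, noise_sd_pA >= 0, i_delay_ms >= 0,
            dt_ms > 0)
  structure(as.list(environment()), class = "template_gen_config")
}

# Normalised difference-of-exponentials envelope starting at 0, peak 1.
burst_envelope <- function(t, rise, decay) {
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  norm <- exp(-t_peak / decay) - exp(-t_peak / rise)
  pmax(0, (exp(-t / decay) - exp(-t / rise)) / norm)
}

# lognormal draws with a given arithmetic mean and sd
rlnorm_msd <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic dual epileptiform current recording
#'
#' Emits paired current traces as they would be recorded in voltage clamp:
#' the excitatory (AMPA) barrage as inward current at a -80 mV holding
#' potential and the inhibitory (GABA-A) barrage as outward current at
#' 0 mV, each burst a shot-noise sum of unitary synaptic events under the
#' configured envelope.  Per burst, the inhibitory component is scaled so
#' the charge ratio `Q_I/Q_E` equals a draw from the configured ratio
#' distribution.  Currents follow `I = -g * (V_rev - V_m)` so that
#' [current_to_conductance()] recovers the underlying conductances.
#' Ground-truth burst windows and ratios are returned.
#'
#' @param cfg a [template_gen_config()].
#' @param seed integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return List: `I_E`, `I_I` (pA), `meta_E`, `meta_I`
#'   ([recording_meta()]), `windows` (data.frame `start`, `end`, `onset`,
#'   `ordinal`), `true_ratios`, `dt_ms`, `config`.
#' @export
gen_epileptiform_recording <- function(cfg = template_gen_config(),
                                       seed = NULL) {
  stopifnot(inherits(cfg, "template_gen_config"))
  if (!is.null(seed)) set.seed(seed)
  dt <- cfg$dt_ms
  meta_E <- recording_meta(holding_mV = -80, ljp_mV = 13.6, v_rev_mV = 0,
                           dt_ms = dt)
  meta_I <- recording_meta(holding_mV = 0, ljp_mV = 13.6, v_rev_mV = -55,
                           dt_ms = dt)
  df_E <- meta_E$v_rev_mV - (meta_E$holding_mV - meta_E$ljp_mV)   #  93.6
  df_I <- meta_I$v_rev_mV - (meta_I$holding_mV - meta_I$ljp_mV)   # -41.4

  burst_dur <- cfg$rise_ms + 6 * cfg$decay_ms * cfg$i_decay_scale
  shape <- 1 / cfg$ibi_cv^2
  ibi <- stats::rgamma(cfg$n_bursts, shape = shape,
                       scale = cfg$ibi_mean_s * 1000 / shape)
  starts <- 500 + cumsum(c(0, ibi[-cfg$n_bursts] + burst_dur))
  total_ms <- starts[cfg$n_bursts] + burst_dur + 500
  n_samp <- round(total_ms / dt)

  amp <- rlnorm_msd(cfg$n_bursts, 1, cfg$burst_amp_cv)
  ratios <- rlnorm_msd(cfg$n_bursts, cfg$ratio_mean, cfg$ratio_sd)

  u_E <- unitary_epsc(peak_nS = 1, rise_ms = 0.5, decay_ms = 5)
  u_I <- unitary_epsc(peak_nS = 1, rise_ms = 1, decay_ms = 10)
  w_E <- unitary_epsc_waveform(u_E, dt = dt)
  w_I <- unitary_epsc_waveform(u_I, dt = dt)

  shot_burst <- function(n_burst_samp, env, wave, rate_hz) {
    g <- numeric(n_burst_samp + length(wave))
    # inhomogeneous Poisson events by per-sample thinning
    lam <- rate_hz / 1000 * dt * env
    ev <- which(stats::runif(n_burst_samp) < lam)
    for (i in ev) {
      idx <- i:(i + length(wave) - 1)
      g[idx] <- g[idx] + wave
    }
    g[seq_len(n_burst_samp)]
  }

  g_E <- numeric(n_samp); g_I <- numeric(n_samp)
  tb <- seq(0, burst_dur, by = dt); tb <- tb[-length(tb)]
  env_E <- burst_envelope(tb, cfg$rise_ms, cfg$decay_ms)
  env_I <- burst_envelope(tb - cfg$i_delay_ms, cfg$rise_ms,
                          cfg$decay_ms * cfg$i_decay_scale)
  env_I[tb < cfg$i_delay_ms] <- 0
  nb <- length(tb)
  for (k in seq_len(cfg$n_bursts)) {
    i0 <- round(starts[k] / dt) + 1
    bE <- shot_burst(nb, env_E, w_E, cfg$event_rate_hz)
    bI <- shot_burst(nb, env_I, w_I, cfg$event_rate_hz)
    if (max(bE) > 0) bE <- bE * amp[k] * cfg$peak_gE_nS / max(bE)
    # match the drawn charge ratio: Q = |sum(I)| dt = g-sum * |df|
    QE <- sum(bE) * abs(df_E)
    QI0 <- sum(bI) * abs(df_I)
    if (QI0 > 0) bI <- bI * ratios[k] * QE / QI0
    idx <- i0:(i0 + nb - 1)
    g_E[idx] <- g_E[idx] + bE
    g_I[idx] <- g_I[idx] + bI
  }

  I_E <- -g_E * df_E
  I_I <- -g_I * df_I
  if (cfg$noise_sd_pA > 0) {
    I_E <- I_E + stats::rnorm(n_samp, sd = cfg$noise_sd_pA)
    I_I <- I_I + stats::rnorm(n_samp, sd = cfg$noise_sd_pA)
  }
  windows <- data.frame(start = starts, end = starts + burst_dur,
                        onset = starts, ordinal = seq_len(cfg$n_bursts))
  list(I_E = I_E, I_I = I_I, meta_E = meta_E, meta_I = meta_I,
       windows = windows, true_ratios = ratios, dt_ms = dt,
       config = cfg, seed = seed)
}

#' Build a playback conductance template from a (synthetic) recording
#'
#' Converts the excitatory and inhibitory current traces through the
#' driving-force law and assembles a [conductance_template()] with the
#' dynamic-clamp playback reversals (0 / -75 mV) and the recording's burst
#' windows.  Recording noise makes tiny negative conductance excursions;
#' the non-negativity the template requires comes from the magnitude
#' convention of [current_to_conductance()].
#'
#' @param rec output of [gen_epileptiform_recording()] (or the same shape
#'   built from real data).
#' @param E_E,E_I playback reversal potentials (mV).
#' @param ljp_mV,apply_ljp playback LJP handling, see
#'   [conductance_template()].
#' @return An unscaled [conductance_template()].
#' @export
template_from_recording <- function(rec, E_E = 0, E_I = -75, ljp_mV = 14.9,
                                    apply_ljp = FALSE) {
  cE <- current_to_conductance(rec$I_E, rec$meta_E)
  cI <- current_to_conductance(rec$I_I, rec$meta_I)
  conductance_template(cE$g, cI$g, dt = rec$dt_ms, E_E = E_E, E_I = E_I,
                       windows = rec$windows, ljp_mV = ljp_mV,
                       apply_ljp = apply_ljp,
                       meta = list(driving_force_E = cE$driving_force_mV,
                                   driving_force_I = cI$driving_force_mV,
                                   generator_seed = rec$seed))
}

#' Generate a synthetic miniature-EPSC current trace
#'
#' Poisson-timed unitary AMPA events converted to current at the
#' recording's driving force (`I = -g * (V_rev - V_m)`), plus additive
#' Gaussian noise, mimicking a TTX mEPSC recording used to calibrate the
#' unitary conductance.  True event times are returned.
#'
#' @param rate_hz mean event rate (>= 0).
#' @param u a [unitary_epsc()] (the true underlying unitary conductance).
#' @param meta a [recording_meta()] (default: the -80 mV excitatory
#'   configuration).
#' @param noise_sd_pA additive noise SD.
#' @param duration_ms trace length.
#' @param seed integer seed.
#' @return List: `I` (pA), `event_times` (ms), `meta`, `dt_ms`.
#' @export
gen_mepsc_trace <- function(rate_hz, u = unitary_epsc(),
                            meta = recording_meta(-80, 13.6, 0),
                            noise_sd_pA = 1, duration_ms = 10000,
                            seed = NULL) {
  stopifnot(rate_hz >= 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- meta$dt_ms
  n <- round(duration_ms / dt)
  df <- meta$v_rev_mV - (meta$holding_mV - meta$ljp_mV)
  wave <- unitary_epsc_waveform(u, dt = dt)
  I <- numeric(n + length(wave))
  n_ev <- stats::rpois(1, rate_hz * duration_ms / 1000)
  ev <- sort(stats::runif(n_ev, 0, duration_ms - length(wave) * dt))
  ev_idx <- round(ev / dt) + 1
  for (i in ev_idx) I[i:(i + length(wave) - 1)] <-
    I[i:(i + length(wave) - 1)] + (-wave * df)
  I <- I[seq_len(n)]
  if (noise_sd_pA > 0) I <- I + stats::rnorm(n, sd = noise_sd_pA)
  list(I = I, event_times = (ev_idx - 1) * dt, meta = meta, dt_ms = dt)
}

#' Generate a voltage trace with planted action potentials
#'
#' Fixture generator for the AP detector: a flat baseline with stylised
#' spikes planted at given times.  Each spike rises linearly at
#' `rise_slope` (well above the 10 mV/ms criterion) from the baseline to
#' `peak_mV`, then falls linearly back, so the first sample of the rise is
#' exactly the detector's threshold point.  A sub-threshold variant
#' (`peak_mV < 0`) never crosses 0 mV and must be rejected by the detector.
#'
#' @param times planted spike times (ms); snapped to the sample grid,
#'   sorted, separated by more than one waveform width.
#' @param dt sample interval (ms).
#' @param duration trace length (ms).
#' @param baseline_mV resting level.
#' @param peak_mV spike peak.
#' @param rise_slope rise slope (mV/ms).
#' @param fall_slope repolarisation slope (mV/ms, negative).
#' @return List: `trace` ([voltage_trace()]), `threshold_times` (ms, the
#'   planted dV/dt-criterion times on the grid).
#' @export
gen_spiky_voltage <- function(times, dt = 0.1, duration = NULL,
                              baseline_mV = -70, peak_mV = 30,
                              rise_slope = 100, fall_slope = -20) {
  stopifnot(rise_slope > 10, fall_slope < 0)
  times <- sort(round(times / dt) * dt)
  n_rise <- ceiling((peak_mV - baseline_mV) / (rise_slope * dt))
  n_fall <- ceiling((peak_mV - baseline_mV) / (-fall_slope * dt))
  width_ms <- (n_rise + n_fall) * dt
  if (length(times) > 1 && any(diff(times) <= width_ms))
    stop("planted spikes overlap: separate times by more than the waveform width")
  if (is.null(duration)) duration <- (if (length(times)) max(times) else 0) +
    width_ms + 50
  n <- round(duration / dt) + 1
  V <- rep(baseline_mV, n)
  for (tt in times) {
    i0 <- round(tt / dt) + 1
    up <- baseline_mV + rise_slope * dt * seq_len(n_rise)
    up[up > peak_mV] <- peak_mV
    down <- peak_mV + fall_slope * dt * seq_len(n_fall)
    down[down < baseline_mV] <- baseline_mV
    w <- c(up, down)
    idx <- i0 + seq_along(w)
    keep <- idx <= n
    V[idx[keep]] <- w[keep]
  }
  list(trace = voltage_trace(V, dt, meta = list(planted = times)),
       threshold_times = times)
}
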