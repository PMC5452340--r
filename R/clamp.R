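#' Voltage-clamp recording metadata
#'
#' Metadata needed to convert an isolated synaptic current recording into a
#' conductance series: the commanded holding potential, the liquid junction
#' potential (LJP, subtracted from the command to obtain the true membrane
#' potential), the assumed reversal potential of the isolated current, and
#' the sampling interval.
#'
#' @param holding_mV commanded holding potential (mV).
#' @param ljp_mV liquid junction potential (mV).
#' @param v_rev_mV assumed reversal potential of the isolated current (mV).
#' @param dt_ms sampling interval (ms).
#' @return Object of class `recording_meta`.
#' @export
recording_meta <- function(holding_mV, ljp_mV = 13.6, v_rev_mV, dt_ms = 0.1) {
  stopifnot(dt_ms > 0)
  structure(list(holding_mV = holding_mV, ljp_mV = ljp_mV,
                 v_rev_mV = v_rev_mV, dt_ms = dt_ms),
            class = "recording_meta")
}

#' Convert a recorded current into a conductance series
#'
#' Applies the driving-force law `g = I / (V_rev - V_m)` with the effective
#' membrane potential `V_m = holding - LJP`.  With the standard recording
#' configuration the excitatory driving force (holding -80 mV, LJP 13.6 mV,
#' reversal 0 mV) is 93.6 mV and the inhibitory one (holding 0 mV, reversal
#' -55 mV, shifted by the elevated extracellular potassium) is -41.4 mV.
#' The returned conductance is non-negative, `|I| / |driving force|`: an
#' inward (negative) current over a positive driving force, or an outward
#' current over a negative one, are both genuine conductance increases, and
#' playback requires `g >= 0`.  The driving force itself is reported signed.
#'
#' @param I recorded current series (pA).
#' @param meta a [recording_meta()].
#' @return List with `g` (nS), `driving_force_mV` (signed) and `V_m_mV`.
#' @examples
#' m <- recording_meta(holding_mV = -80, ljp_mV = 13.6, v_rev_mV = 0)
#' current_to_conductance(c(-93.6, 0), m)$driving_force_mV  # 93.6
#' @export
current_to_conductance <- function(I, meta) {
  stopifnot(inherits(meta, "recording_meta"))
  V_m <- meta$holding_mV - meta$ljp_mV
  df <- meta$v_rev_mV - V_m
  if (df == 0) stop("zero driving force: V_rev equals the effective V_m")
  list(g = abs(I) / abs(df), driving_force_mV = df, V_m_mV = V_m)
}

#' Per-burst charge and inhibitory/excitatory charge ratio
#'
#' Integrates the excitatory and inhibitory currents over each annotated
#' burst window; `Q = |integral of I dt|` in pC, ratio `Q_I / Q_E`.
#' Windows with zero excitatory charge get `NA` ratio and a flag.
#'
#' @param I_E,I_I current series (pA) on a shared time base.
#' @param windows data.frame with `start`, `end` (ms).
#' @param dt_ms sampling interval (ms).
#' @return data.frame with one row per window: `Q_E_pC`, `Q_I_pC`, `ratio`,
#'   `flagged`.
#' @export
compute_charge_ratio <- function(I_E, I_I, windows, dt_ms) {
  stopifnot(length(I_E) == length(I_I), dt_ms > 0)
  t <- (seq_along(I_E) - 1) * dt_ms
  out <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- t >= windows$start[i] & t <= windows$end[i]
    # pA * ms = fC; /1000 -> pC
    Q_E <- abs(sum(I_E[sel]) * dt_ms) / 1000
    Q_I <- abs(sum(I_I[sel]) * dt_ms) / 1000
    data.frame(Q_E_pC = Q_E, Q_I_pC = Q_I,
               ratio = if (Q_E > 0) Q_I / Q_E else NA_real_,
               flagged = Q_E == 0)
  })
  cbind(windows[, c("start", "end")], do.call(rbind, out))
}

#' Unitary AMPA conductance description
#'
#' Amplitude and kinetics of the average miniature EPSC-derived unitary
#' synaptic conductance, used both to calibrate the conductance threshold
#' and as the event kernel of the synthetic template generator.  Defaults
#' correspond to a typical CA1 AMPA mEPSC: ~15 pA at a 93.6 mV driving
#' force (~0.16 nS), sub-millisecond rise, ~5 ms decay.
#'
#' @param peak_nS peak conductance (nS).
#' @param rise_ms,decay_ms rise and decay time constants (ms);
#'   `decay > rise > 0`.
#' @return Object of class `unitary_epsc`.
#' @export
unitary_epsc <- function(peak_nS = 0.16, rise_ms = 0.5, decay_ms = 5) {
  stopifnot("peak must be > 0" = peak_nS > 0,
            "need decay > rise > 0" = decay_ms > rise_ms && rise_ms > 0)
  structure(list(peak_nS = peak_nS, rise_ms = rise_ms, decay_ms = decay_ms),
            class = "unitary_epsc")
}

#' Difference-of-exponentials unitary conductance waveform
#'
#' `g(t) = A * (exp(-t/decay) - exp(-t/rise))`, starting at 0 and normalised
#' so its maximum equals the configured peak conductance (the closed-form
#' peak time is `log(decay/rise) * rise*decay/(decay - rise)`).
#'
#' @param u a [unitary_epsc()].
#' @param dt sample interval (ms).
#' @param duration waveform length (ms); default covers 8 decay constants.
#' @return Numeric conductance series (nS).
#' @export
unitary_epsc_waveform <- function(u, dt = 0.1, duration = 8 * u$decay_ms) {
  stopifnot(inherits(u, "unitary_epsc"))
  t <- seq(0, duration, by = dt)
  tr <- u$rise_ms; td <- u$decay_ms
  t_peak <- log(td / tr) * tr * td / (td - tr)
  norm <- exp(-t_peak / td) - exp(-t_peak / tr)
  u$peak_nS * (exp(-t / td) - exp(-t / tr)) / norm
}

#' Minimal number of simultaneous unitary conductances to trigger a spike
#'
#' Scans the number `k` of simultaneous unitary AMPA conductance waveforms
#' injected into the (deterministic, `sigma = 0`) model neuron at rest and
#' returns the smallest `k` that elicits at least one spike, together with
#' the corresponding conductance threshold `k * peak`.  Because spiking is
#' monotone in `k`, a bisection search gives the same answer as a linear
#' scan; both are available and cross-checked in the test-suite.
#'
#' @param p a [reif_params()] object (noise is forced off).
#' @param u a [unitary_epsc()].
#' @param dt integration step (ms).
#' @param E_E excitatory reversal used for injection (mV).
#' @param cap largest `k` tried before giving up with an error.
#' @param method `"scan"` (linear) or `"bisect"`.
#' @return List with `k` and `threshold_nS = k * peak_nS`.
#' @export
find_conductance_threshold <- function(p, u, dt = 0.1, E_E = 0,
                                       cap = 1000,
                                       method = c("scan", "bisect")) {
  method <- match.arg(method)
  wave <- unitary_epsc_waveform(u, dt = dt)
  pad <- rep(0, round(50 / dt))
  g1 <- c(wave, pad)
  spikes_at <- function(k) {
    dr <- conductance_drive(k * g1, rep(0, length(g1)), E_E = E_E)
    length(simulate_neuron(p, dr, dt = dt, sigma = 0,
                           record_v = FALSE)$spikes) >= 1
  }
  if (!spikes_at(cap))
    stop(sprintf("no spike up to cap of %d unitary conductances", cap))
  if (method == "scan") {
    k <- 1
    while (!spikes_at(k)) k <- k + 1
  } else {
    lo <- 0; hi <- cap   # invariant: lo never spikes, hi spikes
    if (spikes_at(1)) { lo <- 0; hi <- 1 }
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (mid == 0) break
      if (spikes_at(mid)) hi <- mid else lo <- mid
    }
    k <- hi
  }
  list(k = k, threshold_nS = k * u$peak_nS)
}

#' Conductance template for activity-clamp playback
#'
#' Paired excitatory and inhibitory conductance series with their playback
#' reversal potentials and per-burst window annotations.  Playback
#' reversals default to the dynamic-clamp settings (0 / -75 mV); when a
#' liquid junction potential is given with `apply_ljp = TRUE` the effective
#' reversals on the amplifier scale are `E - ljp` — for playback into model
#' neurons (whose voltage is the true membrane potential) no correction
#' applies and the default is off.  The choice is recorded on the object.
#'
#' @param g_E,g_I conductance series (nS), equal length, non-negative.
#' @param dt sample interval (ms).
#' @param E_E,E_I intended physiological reversal potentials (mV).
#' @param windows data.frame of burst annotations: `start`, `end`, and
#'   `onset` (excitatory-conductance onset used as the latency reference;
#'   defaults to `start`), sorted and non-overlapping.
#' @param ljp_mV playback liquid junction potential (mV).
#' @param apply_ljp correct the reversals by `-ljp_mV` (amplifier scale)?
#' @param scale_factor multiplicative factor already applied (bookkeeping).
#' @param meta free-form provenance list.
#' @return Object of class `conductance_template`.
#' @export
conductance_template <- function(g_E, g_I, dt, E_E = 0, E_I = -75,
                                 windows = NULL, ljp_mV = 14.9,
                                 apply_ljp = FALSE, scale_factor = NA_real_,
                                 meta = list()) {
  stopifnot(length(g_E) == length(g_I), dt > 0,
            "conductances must be non-negative" = all(g_E >= 0) && all(g_I >= 0))
  if (!is.null(windows)) {
    stopifnot(all(diff(windows$start) > 0),
              "windows must not overlap" =
                all(windows$start[-1] >= windows$end[-nrow(windows)]))
    if (is.null(windows$onset)) windows$onset <- windows$start
    if (is.null(windows$ordinal)) windows$ordinal <- seq_len(nrow(windows))
  }
  structure(list(g_E = as.numeric(g_E), g_I = as.numeric(g_I), dt = dt,
                 E_E = E_E, E_I = E_I, windows = windows,
                 ljp_mV = ljp_mV, apply_ljp = apply_ljp,
                 scale_factor = scale_factor, meta = meta),
            class = "conductance_template")
}

#' @export
print.conductance_template <- function(x, ...) {
  cat(sprintf("conductance_template: %d samples at dt = %g ms (%.1f s)\n",
              length(x$g_E), x$dt, length(x$g_E) * x$dt / 1000))
  cat(sprintf("  max g_E = %.2f nS, max g_I = %.2f nS, reversals %g / %g mV\n",
              max(x$g_E), max(x$g_I), x$E_E, x$E_I))
  if (!is.null(x$windows)) cat(sprintf("  %d burst windows\n", nrow(x$windows)))
  if (!is.na(x$scale_factor))
    cat(sprintf("  scaled by %.4g\n", x$scale_factor))
  invisible(x)
}

#' Scale a template so its excitatory peak matches a conductance threshold
#'
#' Both series are multiplied by the single factor
#' `threshold_g / max(g_E)`, so the maximal excitatory conductance of the
#' template matches the neuron's calibrated conductance threshold while the
#' inhibitory/excitatory ratio at every sample is preserved.
#'
#' @param template a [conductance_template()].
#' @param threshold_g target peak excitatory conductance (nS), e.g. from
#'   [find_conductance_threshold()].
#' @return The scaled template with `scale_factor` recorded.
#' @export
scale_template <- function(template, threshold_g) {
  stopifnot(inherits(template, "conductance_template"), threshold_g > 0)
  m <- max(template$g_E)
  if (m <= 0) stop("flat excitatory template cannot be scaled")
  f <- threshold_g / m
  template$g_E <- template$g_E * f
  template$g_I <- template$g_I * f
  template$scale_factor <- if (is.na(template$scale_factor)) f
                           else template$scale_factor * f
  template
}

# Effective playback reversals (LJP-corrected if requested).
playback_reversals <- function(template) {
  off <- if (isTRUE(template$apply_ljp)) template$ljp_mV else 0
  c(E_E = template$E_E - off, E_I = template$E_I - off)
}

#' Play a conductance template into a model neuron
#'
#' Repeated dynamic-clamp playback: each step injects
#' `I = g_E(t)*(E_E - V) + g_I(t)*(E_I - V)` with the template's (optionally
#' LJP-corrected) reversals.  Repeats differ only in the voltage-noise
#' stream; with `sigma = 0` all repeats are identical.  Playing an unscaled
#' template is allowed but flagged in the output metadata.
#'
#' @param p a [reif_params()] object.
#' @param template a [conductance_template()].
#' @param repeats number of playback repetitions.
#' @param seed integer seed for the noise streams.
#' @param sigma optional override of the noise intensity (mV/sqrt(s)).
#' @param record_v keep voltage traces (memory: repeats x samples).
#' @return List with `spikes` (list of spike-time vectors, one per repeat),
#'   `traces` (list of [voltage_trace()] or NULL), `reversals` and
#'   `unscaled` flag.
#' @export
play_template <- function(p, template, repeats = 1, seed = NULL,
                          sigma = NULL, record_v = FALSE) {
  stopifnot(inherits(p, "reif_params"),
            inherits(template, "conductance_template"), repeats >= 1)
  rev <- playback_reversals(template)
  dr <- conductance_drive(template$g_E, template$g_I,
                          E_E = rev[["E_E"]], E_I = rev[["E_I"]])
  if (!is.null(seed)) set.seed(seed)
  spikes <- vector("list", repeats)
  traces <- if (record_v) vector("list", repeats) else NULL
  for (k in seq_len(repeats)) {
    r <- simulate_neuron(p, dr, dt = template$dt, sigma = sigma,
                         record_v = record_v)
    spikes[[k]] <- r$spikes
    if (record_v) traces[[k]] <- r$trace
  }
  list(spikes = spikes, traces = traces, reversals = rev,
       unscaled = is.na(template$scale_factor))
}

#' Ramp and square-step current protocols
#'
#' `ramp` rises linearly from 0 to `amplitude` over `duration`; `step` is a
#' constant `amplitude` for `duration`.  Both are padded with a zero
#' baseline before and after.
#'
#' @param kind `"ramp"` or `"step"`.
#' @param amplitude peak current (pA, >= 0).
#' @param duration stimulus duration (ms, > 0).
#' @param dt sample interval (ms).
#' @param baseline_ms zero padding before the stimulus (ms).
#' @param tail_ms zero padding after the stimulus (ms).
#' @return List with `I` (pA series), `onset_ms` (stimulus start) and `dt`.
#' @export
make_current_protocol <- function(kind = c("ramp", "step"), amplitude,
                                  duration, dt = 0.1, baseline_ms = 100,
                                  tail_ms = 100) {
  kind <- match.arg(kind)
  stopifnot("amplitude must be >= 0" = amplitude >= 0,
            "duration must be > 0" = duration > 0)
  n_stim <- round(duration / dt)
  stim <- if (kind == "ramp") amplitude * seq_len(n_stim) / n_stim
          else rep(amplitude, n_stim)
  I <- c(rep(0, round(baseline_ms / dt)), stim, rep(0, round(tail_ms / dt)))
  list(I = I, onset_ms = round(baseline_ms / dt) * dt, dt = dt, kind = kind,
       amplitude = amplitude, duration = duration)
}

#' Read / write conductance templates as columnar text plus a JSON sidecar
#'
#' The main file holds `time_ms`, `gE_nS`, `gI_nS`; `<path>.json` holds the
#' reversals, LJP settings, burst windows and scale factor.
#'
#' @param template a [conductance_template()].
#' @param path path of the columnar text file.
#' @return `write_template()` returns `path` invisibly; `read_template()`
#'   the restored template.
#' @export
write_template <- function(template, path) {
  t_ms <- (seq_along(template$g_E) - 1) * template$dt
  utils::write.table(
    data.frame(time_ms = t_ms, gE_nS = template$g_E, gI_nS = template$g_I),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(dt = template$dt, E_E = template$E_E, E_I = template$E_I,
               ljp_mV = template$ljp_mV, apply_ljp = template$apply_ljp,
               scale_factor = template$scale_factor,
               windows = template$windows, meta = template$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  windows <- side$windows
  if (!is.null(windows) && !is.data.frame(windows))
    windows <- as.data.frame(windows)
  conductance_template(d$gE_nS, d$gI_nS, dt = side$dt,
                       E_E = side$E_E, E_I = side$E_I, windows = windows,
                       ljp_mV = side$ljp_mV, apply_ljp = side$apply_ljp,
                       scale_factor = if (is.null(side$scale_factor))
                         NA_real_ else side$scale_factor,
                       meta = as.list(side$meta))
}
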