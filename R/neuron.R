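#' Instantaneous rEIF parameters at a given time since the last spike
#'
#' Evaluates the post-spike exponential relaxation of the four time-varying
#' neuron parameters.  Each is its basal value plus amplitude terms decaying
#' with the time `T` since the last spike; the leak reversal carries two
#' exponential terms (a fast depolarising and a slower hyperpolarising one),
#' both acting additively from the moment of the spike.
#'
#' @param T time since the last spike (ms).  `Inf` (the "never spiked"
#'   sentinel) yields exactly the basal values.
#' @param p a [reif_params()] object.
#' @return Named numeric vector `G_L` (nS), `V_L` (mV), `V_T` (mV),
#'   `Delta_T` (mV).
#' @examples
#' relax_params(0, reif_params())   # just after a spike: V_T at V_Tabs
#' @export
relax_params <- function(T, p) {
  stopifnot(inherits(p, "reif_params"))
  if (!is.numeric(T) || length(T) != 1 || is.na(T))
    stop("T must be a single numeric value")
  if (is.finite(T) && T < 0) stop("negative time-since-spike")
  relax_params_cpp(pack_params(p), T)
}

#' One Euler-Maruyama step of the rEIF neuron
#'
#' Advances the neuron state by one fixed step.  The deterministic drift is
#' `dt/C * (-G_L*(V - V_L) + G_L*Delta_T*exp((V - V_T)/Delta_T) + I_in)`
#' with the instantaneous parameters from [relax_params()]; noise enters as
#' the additive voltage increment `sigma*sqrt(dt)*noise_draw`.  If the
#' updated voltage reaches the absolute threshold `V_Tabs` the neuron
#' spikes: the voltage resets to `V_r` and the time-since-spike clock to 0.
#'
#' This scalar-step function exists for inspection and testing; bulk
#' simulation goes through the compiled loop in [simulate_neuron()].
#'
#' @param state list with `V` (mV) and `T` (ms since last spike; `Inf` if
#'   never spiked).
#' @param p a [reif_params()] object.
#' @param I_in input current (pA).
#' @param dt step size (ms).
#' @param noise_draw a standard-normal draw (ignored when `sigma = 0`).
#' @return List with the new `state` and logical `spike`.
#' @export
step_neuron <- function(state, p, I_in, dt, noise_draw = 0) {
  stopifnot(dt > 0, is.finite(state$V))
  rp <- relax_params(state$T, p)
  arg <- min((state$V - rp[["V_T"]]) / rp[["Delta_T"]], 20)
  drift <- (-rp[["G_L"]] * (state$V - rp[["V_L"]]) +
              rp[["G_L"]] * rp[["Delta_T"]] * exp(arg) + I_in) / p$C
  V <- state$V + dt * drift + (p$sigma / sqrt(1000)) * sqrt(dt) * noise_draw
  if (!is.finite(V))
    stop(sprintf("non-finite voltage after step (V = %g, I_in = %g, dt = %g)",
                 state$V, I_in, dt))
  if (V >= p$V_Tabs) {
    list(state = list(V = p$V_r, T = 0), spike = TRUE)
  } else {
    list(state = list(V = V, T = state$T + dt), spike = FALSE)
  }
}

#' Voltage trace container
#'
#' @param V voltage samples (mV), including the initial value.
#' @param dt sample interval (ms).
#' @param meta named list of provenance metadata (seed, condition label, ...).
#' @return Object of class `voltage_trace`.
#' @export
voltage_trace <- function(V, dt, meta = list()) {
  stopifnot(dt > 0, length(V) >= 1)
  structure(list(V = as.numeric(V), dt = dt, meta = meta),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %d samples at dt = %g ms (%.1f ms), range [%.1f, %.1f] mV\n",
              length(x$V), x$dt, (length(x$V) - 1) * x$dt,
              min(x$V), max(x$V)))
  invisible(x)
}

#' Time axis of a voltage trace (ms, starting at 0)
#' @param x a `voltage_trace`.
#' @export
trace_times <- function(x) seq(0, by = x$dt, length.out = length(x$V))

#' Current-drive and conductance-drive constructors for simulation
#'
#' `current_drive()` wraps an external current series (pA).
#' `conductance_drive()` wraps paired excitatory/inhibitory conductance
#' series (nS) with their reversal potentials; during simulation the
#' injected current is recomputed every step from the instantaneous
#' voltage, `I = g_E(t)*(E_E - V) + g_I(t)*(E_I - V)`, exactly as a dynamic
#' clamp does.
#'
#' @param I current series (pA).
#' @return A drive object consumed by [simulate_neuron()].
#' @export
current_drive <- function(I) {
  structure(list(type = "current", I = as.numeric(I)), class = "reif_drive")
}

#' @rdname current_drive
#' @param g_E,g_I conductance series (nS), equal length.
#' @param E_E,E_I reversal potentials (mV).
#' @export
conductance_drive <- function(g_E, g_I, E_E = 0, E_I = -75) {
  stopifnot(length(g_E) == length(g_I), all(g_E >= 0), all(g_I >= 0))
  structure(list(type = "conductance", g_E = as.numeric(g_E),
                 g_I = as.numeric(g_I), E_E = E_E, E_I = E_I),
            class = "reif_drive")
}

#' Simulate a single rEIF neuron
#'
#' Fixed-step Euler-Maruyama integration (default step 0.1 ms) of the rEIF
#' neuron under a current or conductance drive.  With `sigma > 0` one
#' standard normal is consumed per step from R's RNG, so runs are
#' reproducible given a seed and can be split into consecutive calls that
#' carry over `state` and share the RNG stream.  Spike times are the step
#' end times at which the reset fired.
#'
#' @param p a [reif_params()] object.
#' @param drive a [current_drive()] or [conductance_drive()]; it must cover
#'   `duration/dt` steps.  `NULL` means zero current.
#' @param duration simulated time (ms); defaults to the drive length.
#' @param dt step size (ms).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param state initial state list `(V, T)`; default `V = V_L0`, never
#'   spiked.
#' @param sigma optional override of the noise intensity (mV/sqrt(s)).
#' @param record_v keep the full voltage trace (TRUE) or only spikes.
#' @return List with `trace` (a [voltage_trace()], `NULL` if not recorded),
#'   `spikes` (ms) and the final `state`.
#' @examples
#' p <- reif_params(sigma = 0)
#' r <- simulate_neuron(p, current_drive(rep(400, 5000)), dt = 0.1)
#' length(r$spikes)
#' @export
simulate_neuron <- function(p, drive = NULL, duration = NULL, dt = 0.1,
                            seed = NULL, state = NULL, sigma = NULL,
                            record_v = TRUE) {
  stopifnot(inherits(p, "reif_params"), dt > 0)
  if (is.null(drive)) {
    if (is.null(duration)) stop("need a drive or a duration")
    drive <- current_drive(rep(0, round(duration / dt)))
  }
  n_steps <- if (drive$type == "current") length(drive$I) else length(drive$g_E)
  if (!is.null(duration)) {
    need <- round(duration / dt)
    if (n_steps < need)
      stop(sprintf("drive covers %d steps but duration needs %d", n_steps, need))
    n_steps <- need
  }
  if (is.null(state)) state <- list(V = p$V_L0, T = Inf)
  if (!is.null(seed)) set.seed(seed)

  if (drive$type == "current") {
    I_ext <- drive$I[seq_len(n_steps)]
    gE <- numeric(0); gI <- numeric(0); VE <- 0; VI <- 0
  } else {
    I_ext <- rep(0, n_steps)
    gE <- drive$g_E[seq_len(n_steps)]
    gI <- drive$g_I[seq_len(n_steps)]
    VE <- drive$E_E; VI <- drive$E_I
  }

  out <- sim_neuron_cpp(pack_params(p, sigma_override = sigma),
                        I_ext, gE, gI, VE, VI, dt, state$V, state$T, record_v)
  trace <- if (record_v)
    voltage_trace(out$V, dt, meta = list(seed = seed)) else NULL
  list(trace = trace, spikes = out$spikes,
       state = list(V = out$V_end, T = out$T_end))
}
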