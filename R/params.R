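#' Single-neuron rEIF parameter set
#'
#' Constructs the parameter set of the refractory exponential
#' integrate-and-fire (rEIF) neuron.  Four parameters — the leak conductance
#' `G_L`, the leak reversal `V_L`, the soft spike threshold `V_T` and the
#' spike-width parameter `Delta_T` — relax exponentially back to their basal
#' values as functions of the time since the last spike, which captures the
#' refractory behaviour of pyramidal neurons.  Defaults are the published
#' values for a CA1 pyramidal neuron under control conditions; the single
#' carbamazepine (CBZ) manipulation is a slower soft-threshold recovery
#' (`tau_VT` 13 to 15 ms), applied with [apply_condition()].
#'
#' Units are mV / ms / pA / nS / pF throughout, except `sigma`
#' (mV per sqrt(s), as conventionally quoted) which is converted internally.
#'
#' @param C membrane capacitance (pF).
#' @param V_Tabs absolute spike threshold triggering reset (mV).
#' @param V_r post-spike reset voltage (mV).
#' @param G_L0,a_GL,tau_GL basal leak conductance (nS), its post-spike
#'   increment (nS) and decay time constant (ms).
#' @param V_L0 basal leak reversal potential (mV).
#' @param a_VL,tau_VLa first post-spike leak-reversal deviation (mV) and its
#'   time constant (ms).
#' @param b_VL,tau_VLb second (signed) leak-reversal deviation (mV) and its
#'   time constant (ms); both exponentials act additively from the spike.
#' @param V_T0,a_VT,tau_VT basal soft threshold (mV), post-spike elevation
#'   (mV) and recovery time constant (ms).  `V_T0 + a_VT` equals `V_Tabs` for
#'   the defaults, so the threshold sits at the absolute ceiling right after
#'   a spike.
#' @param DeltaT0,a_DeltaT,tau_DeltaT basal spike-width parameter (mV), its
#'   post-spike deviation (mV) and time constant (ms).
#' @param sigma voltage noise intensity (mV/sqrt(s)); 0 gives a
#'   deterministic neuron.
#' @return An object of class `reif_params` (a validated named list).
#' @examples
#' p <- reif_params()
#' relax_params(Inf, p)   # basal values
#' @export
reif_params <- function(C = 170, V_Tabs = -37, V_r = -43,
                        G_L0 = 6.8, a_GL = 9, tau_GL = 30,
                        V_L0 = -75, a_VL = 16, tau_VLa = 25,
                        b_VL = -10, tau_VLb = 100,
                        V_T0 = -52, a_VT = 15, tau_VT = 13,
                        DeltaT0 = 2, a_DeltaT = 0, tau_DeltaT = 0.005,
                        sigma = 170) {
  p <- list(C = C, V_Tabs = V_Tabs, V_r = V_r,
            G_L0 = G_L0, a_GL = a_GL, tau_GL = tau_GL,
            V_L0 = V_L0, a_VL = a_VL, tau_VLa = tau_VLa,
            b_VL = b_VL, tau_VLb = tau_VLb,
            V_T0 = V_T0, a_VT = a_VT, tau_VT = tau_VT,
            DeltaT0 = DeltaT0, a_DeltaT = a_DeltaT, tau_DeltaT = tau_DeltaT,
            sigma = sigma)
  validate_reif_params(p)
  structure(p, class = "reif_params")
}

validate_reif_params <- function(p) {
  stopifnot(
    "C must be > 0" = p$C > 0,
    "G_L0 must be >= 0" = p$G_L0 >= 0,
    "G_L0 + a_GL must be >= 0" = p$G_L0 + p$a_GL >= 0,
    "time constants must be > 0" =
      all(c(p$tau_GL, p$tau_VLa, p$tau_VLb, p$tau_VT, p$tau_DeltaT) > 0),
    "DeltaT0 must be > 0" = p$DeltaT0 > 0,
    "V_r must be below V_Tabs" = p$V_r < p$V_Tabs,
    "sigma must be >= 0" = p$sigma >= 0
  )
  invisible(p)
}

#' @export
print.reif_params <- function(x, ...) {
  cat("rEIF neuron parameters\n")
  cat(sprintf("  C = %g pF, V_Tabs = %g mV, V_r = %g mV\n", x$C, x$V_Tabs, x$V_r))
  cat(sprintf("  G_L: %g + %g exp(-T/%g) nS\n", x$G_L0, x$a_GL, x$tau_GL))
  cat(sprintf("  V_L: %g + %g exp(-T/%g) + %g exp(-T/%g) mV\n",
              x$V_L0, x$a_VL, x$tau_VLa, x$b_VL, x$tau_VLb))
  cat(sprintf("  V_T: %g + %g exp(-T/%g) mV\n", x$V_T0, x$a_VT, x$tau_VT))
  cat(sprintf("  Delta_T: %g + %g exp(-T/%g) mV\n",
              x$DeltaT0, x$a_DeltaT, x$tau_DeltaT))
  cat(sprintf("  sigma = %g mV/sqrt(s)\n", x$sigma))
  invisible(x)
}

# Pack a reif_params into the fixed-order numeric vector the C++ kernel
# expects; converts sigma from mV/sqrt(s) to mV/sqrt(ms).
pack_params <- function(p, sigma_override = NULL) {
  sigma <- if (is.null(sigma_override)) p$sigma else sigma_override
  c(p$C, p$V_Tabs, p$V_r,
    p$G_L0, p$a_GL, p$tau_GL,
    p$V_L0, p$a_VL, p$tau_VLa, p$b_VL, p$tau_VLb,
    p$V_T0, p$a_VT, p$tau_VT,
    p$DeltaT0, p$a_DeltaT, p$tau_DeltaT,
    sigma / sqrt(1000))
}

#' Switch a parameter set between experimental conditions
#'
#' The only parameter that differs between conditions is the soft-threshold
#' recovery constant: 13 ms under control, 15 ms in the presence of CBZ.
#' The slower recovery phenomenologically represents the drug's
#' use-dependent block, i.e. the slower recovery of sodium channels from
#' inactivation after a spike.  The call is idempotent.
#'
#' @param p a [reif_params()] object.
#' @param condition `"control"` or `"cbz"`.
#' @return The parameter set with `tau_VT` set for the condition.
#' @examples
#' apply_condition(reif_params(), "cbz")$tau_VT  # 15
#' @export
apply_condition <- function(p, condition = c("control", "cbz")) {
  stopifnot(inherits(p, "reif_params"))
  condition <- match.arg(condition)
  p$tau_VT <- if (condition == "control") 13 else 15
  validate_reif_params(p)
  p
}

#' Network synapse parameters
#'
#' Constants of the presynaptic vesicle-depletion synapse and of the network
#' input.  Every spike releases the fraction `r` of the neuron's available
#' glutamate vesicle pool `N` (normalised to \[0, 1\]); the pool recovers
#' towards 1 with time constant `tau_N`.  The efferent excitatory
#' conductance jumps by the released fraction and decays with `tau_GE`.
#' Defaults are the published network values.
#'
#' @param tau_N vesicle recovery time constant (s; converted to ms
#'   internally).
#' @param r fraction of available vesicles released per spike.
#' @param tau_GE efferent conductance decay constant (ms).
#' @param gamma_max scaling of the connectivity matrix (nS).
#' @param I_0 tonic current input to all neurons (pA).
#' @param V_E,V_I excitatory and inhibitory reversal potentials (mV); the
#'   network is excitatory-only, `V_I` is carried for playback use.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau_N = 8, r = 0.3, tau_GE = 10,
                           gamma_max = 267, I_0 = 128,
                           V_E = 0, V_I = -56) {
  stopifnot("r must be in (0,1)" = r > 0 && r < 1,
            "tau_N must be > 0" = tau_N > 0,
            "tau_GE must be > 0" = tau_GE > 0,
            "gamma_max must be >= 0" = gamma_max >= 0)
  structure(list(tau_N = tau_N, r = r, tau_GE = tau_GE,
                 gamma_max = gamma_max, I_0 = I_0, V_E = V_E, V_I = V_I),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Vesicle-depletion synapse parameters\n")
  cat(sprintf("  tau_N = %g s, r = %g, tau_GE = %g ms\n", x$tau_N, x$r, x$tau_GE))
  cat(sprintf("  gamma_max = %g nS, I_0 = %g pA, V_E = %g mV, V_I = %g mV\n",
              x$gamma_max, x$I_0, x$V_E, x$V_I))
  invisible(x)
}

#' Read / write parameter sets as JSON
#'
#' Field names in the JSON file mirror the argument names of
#' [reif_params()] and [synapse_params()].
#'
#' @param path file path.
#' @param what `"neuron"` or `"synapse"`.
#' @return `load_params()` returns the parameter object; `save_params()`
#'   returns `path` invisibly.
#' @export
load_params <- function(path, what = c("neuron", "synapse")) {
  what <- match.arg(what)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (what == "neuron") do.call(reif_params, x) else do.call(synapse_params, x)
}

#' @rdname load_params
#' @param p parameter object to write.
#' @export
save_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
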