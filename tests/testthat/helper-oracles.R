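# Independent oracles used across the test files.

# Adaptive high-accuracy ODE integration of the deterministic rEIF neuron
# (deSolve::lsoda with root-triggered reset), independent of the package's
# fixed-step integrator.  `drive_fun(t)` returns the external current (pA);
# conductance drives are folded into it via g(t)*(E - V) inside the RHS.
ode_oracle <- function(p, duration, drive_fun = function(t) 0,
                       gE_fun = NULL, gI_fun = NULL, E_E = 0, E_I = -75,
                       V0 = p$V_L0, out_dt = 0.1) {
  rhs <- function(t, y, parms) {
    V <- y[1]; T <- y[2]
    rp <- relax_params(T, p)
    I <- drive_fun(t)
    if (!is.null(gE_fun)) I <- I + gE_fun(t) * (E_E - V)
    if (!is.null(gI_fun)) I <- I + gI_fun(t) * (E_I - V)
    arg <- min((V - rp[["V_T"]]) / rp[["Delta_T"]], 20)
    dV <- (-rp[["G_L"]] * (V - rp[["V_L"]]) +
             rp[["G_L"]] * rp[["Delta_T"]] * exp(arg) + I) / p$C
    list(c(dV, 1))
  }
  root <- function(t, y, parms) y[1] - p$V_Tabs
  event <- function(t, y, parms) c(p$V_r, 0)
  times <- seq(0, duration, by = out_dt)
  # start "never spiked" via a huge T (relax_params handles Inf; lsoda needs
  # finite state, 1e7 ms is indistinguishable from the basal values)
  out <- deSolve::lsoda(c(V = V0, T = 1e7), times, rhs, NULL,
                        rootfunc = root,
                        events = list(func = event, root = TRUE),
                        rtol = 1e-8, atol = 1e-8, maxsteps = 50000)
  spikes <- attributes(out)$troot
  list(t = out[, 1], V = out[, 2],
       spikes = if (is.null(spikes)) numeric(0) else spikes)
}

# Plain-R, loop-based network integrator mirroring the compiled kernel's
# update order and RNG consumption (one rnorm(n) block per step), with an
# explicit W %*% G product every step instead of the incremental carry.
r_reference_network <- function(p, sp, W, duration_ms, dt = 0.1,
                                noise_seed = NULL, gamma_eff = NULL) {
  n <- nrow(W)
  if (!is.null(noise_seed)) set.seed(noise_seed)
  tauN <- sp$tau_N * 1000
  gmax <- if (is.null(gamma_eff)) sp$gamma_max else gamma_eff
  decay <- exp(-dt / sp$tau_GE)
  sig_ms <- p$sigma / sqrt(1000)
  V <- rep(p$V_L0, n); T <- rep(Inf, n); N <- rep(1, n); G <- rep(0, n)
  n_steps <- round(duration_ms / dt)
  sp_id <- integer(0); sp_t <- numeric(0)
  for (k in seq_len(n_steps)) {
    N <- N + dt * (1 - N) / tauN
    G <- G * decay
    s <- as.numeric(W %*% G)
    Iin <- gmax * s * (sp$V_E - V) + sp$I_0
    GL <- p$G_L0 + p$a_GL * exp(-T / p$tau_GL)
    VL <- p$V_L0 + p$a_VL * exp(-T / p$tau_VLa) + p$b_VL * exp(-T / p$tau_VLb)
    VT <- p$V_T0 + p$a_VT * exp(-T / p$tau_VT)
    DT <- p$DeltaT0 + p$a_DeltaT * exp(-T / p$tau_DeltaT)
    GL[!is.finite(T)] <- p$G_L0; VL[!is.finite(T)] <- p$V_L0
    VT[!is.finite(T)] <- p$V_T0; DT[!is.finite(T)] <- p$DeltaT0
    arg <- pmin((V - VT) / DT, 20)
    dV <- dt * (-GL * (V - VL) + GL * DT * exp(arg) + Iin) / p$C
    if (p$sigma > 0) dV <- dV + sig_ms * sqrt(dt) * stats::rnorm(n)
    V <- V + dV
    spiked <- which(V >= p$V_Tabs)
    T <- T + dt
    if (length(spiked)) {
      V[spiked] <- p$V_r; T[spiked] <- 0
      dG <- sp$r * N[spiked]
      N[spiked] <- N[spiked] - dG
      G[spiked] <- G[spiked] + dG
      sp_id <- c(sp_id, spiked); sp_t <- c(sp_t, rep(k * dt, length(spiked)))
    }
  }
  list(raster = data.frame(neuron = sp_id, time = sp_t), V = V, N = N, G = G)
}
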