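test_that("driving forces match the standard recording configurations", {
  exc <- current_to_conductance(0, recording_meta(-80, 13.6, 0))
  inh <- current_to_conductance(0, recording_meta(0, 13.6, -55))
  expect_equal(exc$driving_force_mV, 93.6)
  expect_equal(inh$driving_force_mV, -41.4)
})

test_that("conversion yields non-negative conductance and errors on zero DF", {
  m <- recording_meta(-80, 13.6, 0)
  out <- current_to_conductance(c(-93.6, 0, -9.36), m)
  expect_equal(out$g, c(1, 0, 0.1))
  expect_error(current_to_conductance(1, recording_meta(-80, 13.6, -93.6)),
               "zero driving force")
})

test_that("conductance -> current -> conductance round trip is exact", {
  set.seed(3)
  g <- abs(stats::rnorm(2000, 2, 1))
  for (m in list(recording_meta(-80, 13.6, 0), recording_meta(0, 13.6, -55))) {
    df <- m$v_rev_mV - (m$holding_mV - m$ljp_mV)
    I <- -g * df
    expect_lt(max(abs(current_to_conductance(I, m)$g - g) / pmax(g, 1e-12)),
              1e-6)
  }
})

test_that("charge integration: rectangular pulse and zero current", {
  dt <- 0.1
  I <- rep(0, 2000)
  I[501:1000] <- 100  # 100 pA for 50 ms
  w <- data.frame(start = 0, end = 200)
  out <- compute_charge_ratio(I, I * 0, w, dt)
  expect_equal(out$Q_E_pC, 5, tolerance = 0.01)
  expect_equal(out$Q_I_pC, 0)
  expect_true(out$flagged[1] == FALSE)
  zero <- compute_charge_ratio(I * 0, I * 0, w, dt)
  expect_equal(zero$Q_E_pC, 0)
  expect_true(is.na(zero$ratio))
  expect_true(zero$flagged)
})

test_that("unitary waveform starts at 0 and peaks at the configured value", {
  u <- unitary_epsc(peak_nS = 0.7, rise_ms = 0.4, decay_ms = 6)
  w <- unitary_epsc_waveform(u, dt = 0.001)
  expect_equal(w[1], 0)
  expect_lt(abs(max(w) - 0.7) / 0.7, 1e-3)
  expect_error(unitary_epsc(rise_ms = 5, decay_ms = 2))
})

test_that("threshold search: scan equals bisection, monotone in unit size", {
  p <- reif_params(sigma = 0)
  u <- unitary_epsc()
  scan <- find_conductance_threshold(p, u, method = "scan")
  bis <- find_conductance_threshold(p, u, method = "bisect")
  expect_equal(scan$k, bis$k)
  expect_equal(scan$threshold_nS, scan$k * u$peak_nS)
  expect_gt(scan$k, 1)
  # doubling the unitary peak cannot increase the count
  k2 <- find_conductance_threshold(p, unitary_epsc(peak_nS = 2 * u$peak_nS),
                                   method = "bisect")$k
  k4 <- find_conductance_threshold(p, unitary_epsc(peak_nS = 4 * u$peak_nS),
                                   method = "bisect")$k
  expect_lte(k2, scan$k)
  expect_lte(k4, k2)
  # a unit that already spikes alone gives k = 1
  big <- unitary_epsc(peak_nS = 100)
  expect_equal(find_conductance_threshold(p, big, method = "scan")$k, 1)
  expect_error(find_conductance_threshold(p, unitary_epsc(peak_nS = 1e-4),
                                          cap = 8), "cap")
})

test_that("template scaling matches the peak and preserves the I/E ratio", {
  set.seed(11)
  gE <- abs(rnorm(500, 3)); gI <- abs(rnorm(500, 2))
  tm <- conductance_template(gE, gI, dt = 0.1)
  sc <- scale_template(tm, 20.17)
  expect_equal(max(sc$g_E), 20.17)
  expect_equal(sc$g_I / sc$g_E, gI / gE)
  expect_equal(sc$scale_factor, 20.17 / max(gE))
  same <- scale_template(tm, max(gE))
  expect_equal(same$g_E, gE)
  expect_error(scale_template(conductance_template(gE * 0, gI, dt = 0.1), 5))
})

test_that("zero template playback produces no spikes and is flagged unscaled", {
  tm <- conductance_template(rep(0, 5000), rep(0, 5000), dt = 0.1)
  out <- play_template(reif_params(sigma = 0), tm)
  expect_length(out$spikes[[1]], 0)
  expect_true(out$unscaled)
})

test_that("playback injects the dynamic-clamp current law", {
  # a pure excitatory conductance step must match a current-drive simulation
  # through the ODE oracle current I = g*(E - V)
  p <- reif_params(sigma = 0)
  g <- c(rep(0, 500), rep(15, 1000), rep(0, 1500))
  tm <- conductance_template(g, g * 0, dt = 0.1, scale_factor = 1)
  out <- play_template(p, tm, record_v = TRUE)
  o <- ode_oracle(p, duration = 299,
                  gE_fun = stats::approxfun((seq_along(g) - 1) * 0.1, g,
                                            method = "constant", rule = 2))
  expect_equal(length(out$spikes[[1]]), length(o$spikes))
  # fixed-step event times drift slightly across successive resets
  expect_lt(max(abs(out$spikes[[1]] - o$spikes)), 2.5)
})

test_that("LJP handling shifts playback reversals as configured", {
  g <- rep(1, 10)
  tm0 <- conductance_template(g, g, dt = 0.1, apply_ljp = FALSE)
  tm1 <- conductance_template(g, g, dt = 0.1, apply_ljp = TRUE, ljp_mV = 14.9)
  expect_equal(unname(reifburst:::playback_reversals(tm0)), c(0, -75))
  expect_equal(unname(reifburst:::playback_reversals(tm1)),
               c(-14.9, -89.9))
})

test_that("scaling commutes with LJP correction in playback", {
  set.seed(5)
  g <- abs(rnorm(3000, 2))
  gi <- abs(rnorm(3000, 1))
  a <- conductance_template(g, gi, dt = 0.1, apply_ljp = TRUE)
  a <- scale_template(a, 12)
  b <- scale_template(conductance_template(g, gi, dt = 0.1), 12)
  b$apply_ljp <- TRUE
  pa <- play_template(reif_params(sigma = 0), a)
  pb <- play_template(reif_params(sigma = 0), b)
  expect_equal(pa$spikes, pb$spikes)
})

test_that("current protocols have the documented shapes", {
  ramp <- make_current_protocol("ramp", 200, 100, dt = 0.1)
  expect_equal(max(ramp$I), 200)
  expect_equal(tail(ramp$I[ramp$I > 0], 1), 200)
  expect_equal(sum(ramp$I > 0), 1000)
  step <- make_current_protocol("step", 150, 250, dt = 0.1)
  expect_equal(unique(step$I[step$I > 0]), 150)
  zero <- make_current_protocol("ramp", 0, 100)
  expect_true(all(zero$I == 0))
  expect_error(make_current_protocol("step", 100, -5))
})

test_that("a 250 pA / 100 ms ramp drives spiking that matches the oracle", {
  # 250 pA is the top of the published ramp range and is just above this
  # model neuron's 100 ms ramp threshold
  p <- reif_params(sigma = 0)
  pr <- make_current_protocol("ramp", 250, 100, dt = 0.1)
  r <- simulate_neuron(p, current_drive(pr$I), dt = 0.1)
  tt <- (seq_along(pr$I) - 1) * 0.1
  o <- ode_oracle(p, duration = max(tt) - 0.1,
                  drive_fun = stats::approxfun(tt, pr$I, rule = 2))
  expect_gte(length(r$spikes), 1)
  expect_equal(length(r$spikes), length(o$spikes))
})

test_that("templates survive the text + sidecar round trip", {
  rec <- gen_epileptiform_recording(template_gen_config(n_bursts = 2,
                                                        ibi_mean_s = 0.8),
                                    seed = 9)
  tm <- template_from_recording(rec)
  tm <- scale_template(tm, 11)
  f <- tempfile(fileext = ".tsv")
  write_template(tm, f)
  back <- read_template(f)
  expect_equal(back$g_E, tm$g_E, tolerance = 1e-12)
  expect_equal(back$scale_factor, tm$scale_factor)
  expect_equal(back$windows$start, tm$windows$start)
  expect_equal(back$E_I, tm$E_I)
})
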