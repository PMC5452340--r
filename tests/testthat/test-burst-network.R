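test_that("connectivity sampling: shape, range, reproducibility, moments", {
  W <- sample_connectivity(100, seed = 4)
  expect_equal(dim(W), c(100, 100))
  expect_true(all(diag(W) == 0))
  off <- W[row(W) != col(W)]
  expect_true(all(off >= 0 & off <= 1))
  expect_identical(W, sample_connectivity(100, seed = 4))
  expect_error(sample_connectivity(1), "at least 2")
  W2 <- sample_connectivity(200, seed = 9)
  off2 <- W2[row(W2) != col(W2)]
  se <- sqrt(1 / 12) / sqrt(length(off2))
  expect_lt(abs(mean(off2) - 0.5), 3 * se)
})

test_that("vesicle release and recovery follow the closed form", {
  # uncoupled neurons driven above rheobase fire tonically; each spike must
  # release r*N and the pool must recover exponentially between spikes
  p <- reif_params(sigma = 0)
  sp <- synapse_params(gamma_max = 0, I_0 = 200)
  run <- simulate_network(n = 2, duration_s = 30, condition = "control",
                          p = p, sp = sp, conn_seed = 1, sigma = 0)
  r1 <- run$raster[run$raster$neuron == 1, ]
  expect_gt(nrow(r1), 3)
  # first spike releases exactly r * 1
  expect_equal(r1$release[1], 0.3)
  # subsequent releases match the recursive closed form within Euler error
  tau <- run$syn$tau_N * 1000
  N_post <- 1 - r1$release[1] / 0.3 + 0  # bookkeeping below
  N_avail <- 1
  for (k in 2:nrow(r1)) {
    N_after <- N_avail * 0.7
    isi <- r1$time[k] - r1$time[k - 1]
    N_avail <- 1 - (1 - N_after) * exp(-isi / tau)
    expect_equal(r1$release[k], 0.3 * N_avail, tolerance = 1e-3)
  }
})

test_that("vesicle recovery after one release matches 1 - 0.3*exp(-t/tau)", {
  # a quiet network: place one release by hand through a short suprathreshold
  # epoch, then verify the decimated N trace against the analytic recovery
  p <- reif_params(sigma = 0)
  sp <- synapse_params(gamma_max = 0, I_0 = 200)
  run <- simulate_network(n = 2, duration_s = 16, condition = "control",
                          p = p, sp = sp, conn_seed = 2, sigma = 0)
  t1 <- run$raster$time[run$raster$neuron == 1][1]
  tau <- sp$tau_N * 1000
  idx <- which(run$t_dec > t1 & run$t_dec < t1 + 7000)
  # only test samples before the second spike of that neuron
  t2 <- run$raster$time[run$raster$neuron == 1][2]
  if (!is.na(t2)) idx <- idx[run$t_dec[idx] < t2]
  expect_gt(length(idx), 5)
  pred <- 1 - 0.3 * exp(-(run$t_dec[idx] - t1) / tau)
  expect_equal(run$N_dec[1, idx], pred, tolerance = 1e-3)
})

test_that("no spikes means vesicles recover and conductances stay zero", {
  p <- reif_params(sigma = 0)
  sp <- synapse_params(I_0 = 0)
  run <- simulate_network(n = 5, duration_s = 2, condition = "control",
                          p = p, sp = sp, conn_seed = 3, sigma = 0)
  expect_equal(nrow(run$raster), 0)
  expect_true(all(run$N_dec == 1))
  expect_true(all(run$meanG_dec == 0))
})

test_that("vesicle pool stays in [0,1] and release bookkeeping is exact", {
  run <- simulate_network(n = 50, duration_s = 10, condition = "control",
                          conn_seed = 5, noise_seed = 55)
  expect_true(all(run$N_dec >= 0 & run$N_dec <= 1))
  expect_true(all(run$meanG_dec >= 0))
  expect_true(all(run$raster$release > 0 & run$raster$release <= 0.3))
  # bookkeeping identity on an arbitrary window
  w <- c(2000, 8000)
  sel <- run$raster$time >= w[1] & run$raster$time <= w[2]
  total <- sum(run$raster$release[sel])
  per_neuron <- tapply(run$raster$release[sel], run$raster$neuron[sel], sum)
  expect_equal(sum(per_neuron), total)
})

test_that("compiled kernel matches the plain-R reference integrator", {
  p <- reif_params(sigma = 12.5)
  sp <- synapse_params()
  n <- 30
  W <- sample_connectivity(n, seed = 7)
  dur <- 4000
  run <- simulate_network(n = n, duration_s = dur / 1000, p = p, sp = sp,
                          W = W, noise_seed = 77)
  gamma_eff <- attr(run, "gamma_eff")
  ref <- r_reference_network(p, sp, W, dur, noise_seed = 77,
                             gamma_eff = gamma_eff)
  # identical RNG stream and update order: early rasters agree exactly;
  # floating-point drift may reorder late events
  k <- min(nrow(run$raster), nrow(ref$raster), 100)
  expect_gt(k, 10)
  expect_equal(run$raster$time[1:k], ref$raster$time[1:k])
  expect_equal(run$raster$neuron[1:k], ref$raster$neuron[1:k])
  # totals stay close even after drift
  expect_lt(abs(nrow(run$raster) - nrow(ref$raster)) /
              max(nrow(ref$raster), 1), 0.1)
})

test_that("control and cbz runs share every code path except tau_VT", {
  run_c <- simulate_network(n = 10, duration_s = 1, condition = "control",
                            conn_seed = 11, noise_seed = 12)
  run_z <- simulate_network(n = 10, duration_s = 1, condition = "cbz",
                            conn_seed = 11, noise_seed = 12)
  pc <- unclass(run_c$params); pz <- unclass(run_z$params)
  expect_equal(pz$tau_VT, 15)
  pz$tau_VT <- pc$tau_VT
  expect_equal(pc, pz)
  expect_equal(run_c$syn, run_z$syn)
})

test_that("burst detection recovers planted burst epochs", {
  set.seed(19)
  n <- 60
  starts <- c(1000, 4000, 7000, 10000, 13000)
  times <- c()
  neurons <- c()
  for (s in starts) {
    m <- 400
    times <- c(times, runif(m, s, s + 150))
    neurons <- c(neurons, sample.int(n, m, replace = TRUE))
  }
  # sparse background
  times <- c(times, runif(40, 0, 15000))
  neurons <- c(neurons, sample.int(n, 40, replace = TRUE))
  run <- list(raster = data.frame(neuron = neurons, time = times,
                                  release = 0.1),
              duration_ms = 15000, n = n)
  b <- detect_population_bursts(run)
  expect_equal(nrow(b), 5)
  expect_lt(max(abs(b$start - starts)), 60)
  expect_lt(max(abs(b$end - (starts + 150))), 60)
  # silent raster
  empty <- list(raster = data.frame(neuron = integer(0), time = numeric(0),
                                    release = numeric(0)),
                duration_ms = 1000, n = n)
  expect_equal(nrow(detect_population_bursts(empty)), 0)
})

test_that("detected bursts in a default network recruit most neurons", {
  run <- simulate_network(n = 100, duration_s = 30, condition = "control",
                          conn_seed = 21, noise_seed = 23)
  b <- detect_population_bursts(run)
  b <- b[b$n_spikes > 50, ]
  expect_gte(nrow(b), 1)
  expect_true(all(b$n_neurons > 50))
})

test_that("summarize_run handles constructed burst tables and flags", {
  # constructed raster in which release is proportional to the next interval
  mk_run <- function() {
    starts <- cumsum(c(500, 2000, 3000, 4000, 2500, 3500))
    rel <- c(2, 3, 4, 2.5, 3.5, 3) / 10
    times <- c(); neurons <- c(); release <- c()
    for (i in seq_along(starts)) {
      times <- c(times, rep(starts[i] + 1:100, 1))
      neurons <- c(neurons, rep(1:10, 10))
      release <- c(release, rep(rel[i] / 10, 100))
    }
    list(raster = data.frame(neuron = neurons, time = times,
                             release = release),
         duration_ms = max(starts) + 500, n = 10, bursts = NULL)
  }
  run <- mk_run()
  b <- detect_population_bursts(run, min_gap_ms = 500)
  expect_equal(nrow(b), 6)
  bt <- reifburst:::burst_table_stats(run, b)
  # intervals follow starts spacing; release tracks the planted proportional
  # pattern -> strong positive correlation
  ok <- !is.na(bt$next_interval)
  expect_gt(cor(bt$release[ok], bt$next_interval[ok]), 0.9)
  # single-burst runs are flagged and excluded from interval summaries
  one <- run
  one$raster <- one$raster[one$raster$time < 2000, ]
  one$duration_ms <- 2000
  s <- summarize_run(list(one), list(run), min_gap_ms = 500)
  expect_true(s$per_run$flagged[s$per_run$condition == "control"])
  expect_true(is.na(s$per_run$mean_ibi_s[s$per_run$condition == "control"]))
})

test_that("network runs persist to a text directory and back", {
  run <- simulate_network(n = 8, duration_s = 2, condition = "cbz",
                          p = reif_params(sigma = 0),
                          sp = synapse_params(gamma_max = 0, I_0 = 200),
                          conn_seed = 31, sigma = 0)
  run$bursts <- detect_population_bursts(run)
  d <- file.path(tempdir(), "runx")
  write_network_run(run, d)
  back <- read_network_run(d)
  expect_equal(back$raster$time, run$raster$time)
  expect_equal(back$condition, "cbz")
  expect_equal(back$params$tau_VT, 15)
  expect_equal(dim(back$N_dec), dim(run$N_dec))
  expect_equal(back$meanG_dec, run$meanG_dec, tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})
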