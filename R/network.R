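#' Draw a random all-to-all connectivity matrix
#'
#' Connection weights are i.i.d. uniform on \[0, 1\]; the diagonal is zeroed
#' (no autapses).  Entry `W[i, j]` is the weight of the synapse from neuron
#' `j` onto neuron `i`.
#'
#' @param n network size (>= 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return `n x n` numeric matrix with attribute `seed`.
#' @export
sample_connectivity <- function(n, seed = NULL) {
  if (n < 2) stop("network size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  diag(W) <- 0
  attr(W, "seed") <- seed
  W
}

#' Simulate the excitatory burst network
#'
#' Integrates `n` rEIF neurons coupled all-to-all through excitatory
#' conductance-based synapses with presynaptic glutamate-vesicle depletion,
#' by Euler-Maruyama at a fixed step (default 0.1 ms).  Each neuron carries
#' a normalised available-vesicle pool `N` recovering as `(1 - N)/tau_N` and
#' releasing the fraction `r` of the pool at each of its spikes; the
#' released fraction is added to the neuron's normalised efferent
#' conductance, which decays with `tau_GE`.  Neuron `i` receives
#' `I_i = gamma_max * (W %*% G_E)_i * (V_E - V_i) + I_0`.
#'
#' Under the default parameters the network produces recurrent population
#' bursts: background noise-driven spikes ignite a regenerative burst once
#' the vesicle pools have recovered enough, and the burst terminates by
#' depleting them.  The CBZ condition changes only the soft-threshold
#' recovery `tau_VT` (13 to 15 ms) of every neuron.
#'
#' One standard normal per neuron per step is consumed in neuron-index
#' order, so a plain-R integrator given the same seed reproduces the run.
#'
#' The synaptic coupling applied per synapse is
#' `gamma_eff = gamma_max / n * coupling_scale` (with `normalize_n = TRUE`):
#' the connectivity scaling is interpreted per afferent, and
#' `coupling_scale` together with `sigma` form the bursting-regime
#' calibration — they are set so that the control network produces
#' recurrent population bursts with seconds-scale interburst intervals,
#' partial vesicle depletion per burst and quiescent recovery between
#' bursts (see the methods vignette for the calibration analysis).
#'
#' @param n network size.
#' @param duration_s simulated time (s).
#' @param dt step (ms).
#' @param condition `"control"` or `"cbz"` (sets `tau_VT` via
#'   [apply_condition()]).
#' @param p a [reif_params()] object (condition is applied on top).
#' @param sp a [synapse_params()] object.
#' @param W connectivity matrix from [sample_connectivity()]; drawn from
#'   `conn_seed` if `NULL`.
#' @param conn_seed seed for the connectivity draw.
#' @param noise_seed seed for the voltage noise stream.
#' @param sigma network voltage-noise intensity (mV/sqrt(s)); `NULL` uses
#'   `p$sigma`.
#' @param coupling_scale dimensionless calibration factor on
#'   `gamma_max / n`.
#' @param normalize_n divide the connectivity scaling by the network size
#'   (per-afferent interpretation).
#' @param decim_ms decimation interval (ms) for the stored vesicle and
#'   conductance traces.
#' @return Object of class `network_run`: raster data.frame
#'   (`neuron`, `time` ms, `release`), decimated `N` traces, population
#'   mean efferent conductance, final state and the full configuration;
#'   attribute `gamma_eff` records the per-synapse coupling used.
#' @export
simulate_network <- function(n = 100, duration_s = 20, dt = 0.1,
                             condition = c("control", "cbz"),
                             p = reif_params(), sp = synapse_params(),
                             W = NULL, conn_seed = NULL, noise_seed = NULL,
                             sigma = 12.5, coupling_scale = 0.75,
                             normalize_n = TRUE, decim_ms = 10) {
  condition <- match.arg(condition)
  stopifnot(duration_s > 0, dt > 0, decim_ms >= dt)
  p <- apply_condition(p, condition)
  if (is.null(W)) W <- sample_connectivity(n, seed = conn_seed)
  stopifnot(nrow(W) == n)
  if (!is.null(noise_seed)) set.seed(noise_seed)

  gamma_eff <- sp$gamma_max * coupling_scale / (if (normalize_n) n else 1)
  n_steps <- round(duration_s * 1000 / dt)
  decim <- max(1L, round(decim_ms / dt))
  out <- sim_network_cpp(pack_params(p, sigma_override = sigma), W,
                         tauN_ms = sp$tau_N * 1000, r = sp$r,
                         tauGE = sp$tau_GE, gmax = gamma_eff,
                         I0 = sp$I_0, VE = sp$V_E,
                         n_steps = n_steps, dt = dt,
                         V0 = rep(p$V_L0, n), decim = decim)

  structure(list(
    raster = data.frame(neuron = out$spike_neuron, time = out$spike_time,
                        release = out$spike_release),
    t_dec = out$t_dec, N_dec = out$N_dec, meanG_dec = out$meanG_dec,
    V_end = out$V_end, N_end = out$N_end,
    n = n, duration_ms = n_steps * dt, dt = dt, condition = condition,
    params = p, syn = sp,
    sigma_net = if (is.null(sigma)) p$sigma else sigma,
    seeds = list(connectivity = attr(W, "seed"), noise = noise_seed),
    bursts = NULL
  ), class = "network_run", gamma_eff = gamma_eff)
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("network_run: %d neurons, %.1f s at dt = %g ms, condition = %s\n",
              x$n, x$duration_ms / 1000, x$dt, x$condition))
  cat(sprintf("  %d spikes", nrow(x$raster)))
  if (!is.null(x$bursts)) cat(sprintf(", %d detected bursts", nrow(x$bursts)))
  cat("\n")
  invisible(x)
}

#' Detect population bursts in a network run
#'
#' Bursts are the maximal intervals during which the smoothed population
#' spike rate exceeds a threshold set as a fraction of its peak; intervals
#' separated by gaps shorter than `min_gap_ms` are merged and bursts with
#' fewer than `min_spikes` raster spikes are dropped.  The rule is
#' deterministic and all knobs are recorded on the returned table.
#'
#' @param run a `network_run` (or any list with a `raster` data.frame and
#'   `duration_ms`, `n` fields).
#' @param bin_ms histogram bin (ms) for the population rate.
#' @param smooth_ms width (ms) of the moving-average smoother.
#' @param onset_frac onset/offset threshold as a fraction of the peak
#'   smoothed rate.
#' @param min_gap_ms merge bursts separated by less than this gap.
#' @param min_spikes minimum raster spikes for a burst to be kept.
#' @return data.frame with one row per burst: `start`, `end` (ms),
#'   `n_spikes`, `n_neurons` (distinct neurons firing inside the burst).
#' @export
detect_population_bursts <- function(run, bin_ms = 5, smooth_ms = 50,
                                     onset_frac = 0.2, min_gap_ms = 300,
                                     min_spikes = 10) {
  raster <- run$raster
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_neurons = integer(0))
  if (is.null(raster) || nrow(raster) == 0) return(empty)

  edges <- seq(0, run$duration_ms + bin_ms, by = bin_ms)
  counts <- graphics::hist(raster$time, breaks = edges, plot = FALSE)$counts
  w <- max(1L, round(smooth_ms / bin_ms))
  kern <- rep(1 / w, w)
  rate <- stats::filter(counts, kern, sides = 2)
  rate[is.na(rate)] <- 0
  rate <- as.numeric(rate)
  thr <- onset_frac * max(rate)
  if (thr <= 0) return(empty)

  above <- rate > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = edges[starts[r$values]],
                    end = edges[ends[r$values] + 1])
  if (nrow(seg) == 0) return(empty)

  # merge segments separated by short gaps
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - merged$end[nrow(merged)] < min_gap_ms) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  merged$n_spikes <- vapply(seq_len(nrow(merged)), function(i) {
    sum(raster$time >= merged$start[i] & raster$time <= merged$end[i])
  }, integer(1))
  merged$n_neurons <- vapply(seq_len(nrow(merged)), function(i) {
    length(unique(raster$neuron[raster$time >= merged$start[i] &
                                  raster$time <= merged$end[i]]))
  }, integer(1))
  merged <- merged[merged$n_spikes >= min_spikes, , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "detection") <- list(bin_ms = bin_ms, smooth_ms = smooth_ms,
                                    onset_frac = onset_frac,
                                    min_gap_ms = min_gap_ms,
                                    min_spikes = min_spikes)
  merged
}

# Per-burst summaries of one run: spikes/neuron and mean released vesicle
# fraction per neuron inside each burst window, plus the interval from each
# burst's end to the next burst's start.
burst_table_stats <- function(run, bursts) {
  if (nrow(bursts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      spikes_per_neuron = numeric(0), release = numeric(0),
                      next_interval = numeric(0)))
  }
  raster <- run$raster
  spn <- numeric(nrow(bursts)); rel <- numeric(nrow(bursts))
  for (i in seq_len(nrow(bursts))) {
    sel <- raster$time >= bursts$start[i] & raster$time <= bursts$end[i]
    spn[i] <- sum(sel) / run$n
    rel[i] <- sum(raster$release[sel]) / run$n
  }
  nxt <- c(bursts$start[-1] - bursts$end[-nrow(bursts)], NA)
  data.frame(start = bursts$start, end = bursts$end,
             spikes_per_neuron = spn, release = rel, next_interval = nxt)
}

#' Summarise paired control/CBZ network runs
#'
#' For each run: mean interburst interval (end-of-burst to start-of-next),
#' mean spikes per neuron per burst, and mean per-burst normalised vesicle
#' release (the released fraction summed over a burst's spikes, averaged
#' over neurons).  Pooled across runs of a condition, the correlation
#' between a burst's release and the following interburst interval is
#' reported; runs with fewer than 2 bursts contribute no interval and are
#' flagged.
#'
#' @param runs_control,runs_cbz lists of `network_run` objects, paired by
#'   connectivity seed (same order).
#' @param ... detection knobs passed to [detect_population_bursts()].
#' @return List with `per_run` (one row per run and condition),
#'   `correlations` (per condition: Pearson r, n pairs) and `burst_tables`
#'   (per-burst detail).
#' @export
summarize_run <- function(runs_control, runs_cbz, ...) {
  stopifnot(length(runs_control) >= 1, length(runs_cbz) >= 1,
            length(runs_control) == length(runs_cbz))
  conds <- list(control = runs_control, cbz = runs_cbz)
  per_run <- NULL
  burst_tables <- list(control = list(), cbz = list())
  for (cond in names(conds)) {
    for (k in seq_along(conds[[cond]])) {
      run <- conds[[cond]][[k]]
      bursts <- if (is.null(run$bursts)) detect_population_bursts(run, ...)
                else run$bursts
      bt <- burst_table_stats(run, bursts)
      burst_tables[[cond]][[k]] <- bt
      flagged <- nrow(bt) < 2
      per_run <- rbind(per_run, data.frame(
        seed_index = k, condition = cond, n_bursts = nrow(bt),
        mean_ibi_s = if (flagged) NA_real_ else
          mean(bt$next_interval, na.rm = TRUE) / 1000,
        spikes_per_neuron_per_burst = if (nrow(bt)) mean(bt$spikes_per_neuron)
                                      else NA_real_,
        mean_release = if (nrow(bt)) mean(bt$release) else NA_real_,
        flagged = flagged))
    }
  }
  correlations <- do.call(rbind, lapply(names(conds), function(cond) {
    pooled <- do.call(rbind, burst_tables[[cond]])
    ok <- stats::complete.cases(pooled[, c("release", "next_interval")])
    r <- if (sum(ok) >= 3)
      stats::cor(pooled$release[ok], pooled$next_interval[ok]) else NA_real_
    data.frame(condition = cond, pearson_r = r, n_pairs = sum(ok))
  }))
  list(per_run = per_run, correlations = correlations,
       burst_tables = burst_tables)
}

#' Persist / restore a network run as a plain-text directory
#'
#' Writes `raster.tsv`, `traces.tsv` (decimated vesicle and mean-conductance
#' traces), `bursts.tsv` (if detected) and `config.json`.
#'
#' @param run a `network_run`.
#' @param dir directory to create.
#' @return `write_network_run()` returns `dir` invisibly;
#'   `read_network_run()` returns the restored `network_run` (traces and
#'   raster; parameters from the config snapshot).
#' @export
write_network_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$raster, file.path(dir, "raster.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- data.frame(time = run$t_dec, meanG = run$meanG_dec,
                   t(run$N_dec))
  names(tr) <- c("time", "meanG", paste0("N", seq_len(run$n)))
  utils::write.table(tr, file.path(dir, "traces.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$bursts))
    utils::write.table(run$bursts, file.path(dir, "bursts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- list(n = run$n, duration_ms = run$duration_ms, dt = run$dt,
              condition = run$condition, params = unclass(run$params),
              syn = unclass(run$syn), seeds = run$seeds)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_network_run
#' @export
read_network_run <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  raster <- utils::read.table(file.path(dir, "raster.tsv"), header = TRUE,
                              sep = "\t",
                              colClasses = c("integer", "numeric", "numeric"))
  tr <- utils::read.table(file.path(dir, "traces.tsv"), header = TRUE,
                          sep = "\t")
  bursts_path <- file.path(dir, "bursts.tsv")
  bursts <- if (file.exists(bursts_path))
    utils::read.table(bursts_path, header = TRUE, sep = "\t") else NULL
  structure(list(
    raster = raster, t_dec = tr$time,
    N_dec = t(as.matrix(tr[, grep("^N", names(tr)), drop = FALSE])),
    meanG_dec = tr$meanG, V_end = NULL, N_end = NULL,
    n = cfg$n, duration_ms = cfg$duration_ms, dt = cfg$dt,
    condition = cfg$condition,
    params = do.call(reif_params, cfg$params),
    syn = do.call(synapse_params, cfg$syn),
    seeds = cfg$seeds, bursts = bursts
  ), class = "network_run")
}
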