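#' Experiment configuration
#'
#' Bundles everything needed to rerun one of the two headline experiments
#' bit-for-bit: parameter sources, template source, conditions, seeds and
#' protocol sizes.
#'
#' @param name experiment label.
#' @param p a [reif_params()] object.
#' @param sp a [synapse_params()] object (network experiment).
#' @param template a [conductance_template()], or `NULL` to generate one
#'   from `template_cfg`.
#' @param template_cfg a [template_gen_config()] used when `template` is
#'   `NULL`.
#' @param conditions subset of `c("control", "cbz")`.
#' @param seeds integer seeds, one per round (>= 1).
#' @param repeats playback repetitions per condition (the standard protocol
#'   uses 30).
#' @param sigma_playback noise intensity during playback (mV/sqrt(s)); 0
#'   makes the playback deterministic.
#' @param scale_mult template scaling as a multiple of the calibrated
#'   conductance threshold.  The default 1.8 places the per-burst AP counts
#'   of the calibrated model neuron in the 1-5 range seen in recorded
#'   playback.
#' @param n network size.
#' @param duration_s per-run simulated time (s); 20 s is the quick desk
#'   scale, 200 s the full scale.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(name = "experiment",
                              p = reif_params(), sp = synapse_params(),
                              template = NULL,
                              template_cfg = template_gen_config(),
                              conditions = c("control", "cbz"),
                              seeds = 1:10, repeats = 30,
                              sigma_playback = 0, scale_mult = 1.8,
                              n = 100, duration_s = 20) {
  stopifnot(length(seeds) >= 1, scale_mult > 0,
            all(conditions %in% c("control", "cbz")))
  structure(list(name = name, p = p, sp = sp, template = template,
                 template_cfg = template_cfg, conditions = conditions,
                 seeds = as.integer(seeds), repeats = repeats,
                 sigma_playback = sigma_playback, scale_mult = scale_mult,
                 n = n, duration_s = duration_s),
            class = "experiment_config")
}

#' Single-neuron activity-clamp experiment (control versus CBZ)
#'
#' The full playback pipeline on one neuron: obtain a conductance template
#' (generating a synthetic recording if none is supplied), calibrate the
#' neuron's conductance threshold with the unitary AMPA waveform, scale the
#' template to that threshold, play it back `repeats` times under each
#' condition, and compute per-burst counts, first-AP latencies, jitter,
#' ordinal AP reliability and paired condition contrasts.  Everything is a
#' pure function of the configuration and its seeds.
#'
#' @param cfg an [experiment_config()]; `seeds[1]` seeds the template
#'   generator and the playback noise streams.
#' @param u a [unitary_epsc()] used for threshold calibration.
#' @return List: `template` (scaled), `threshold`, `per_condition` (for
#'   each condition: per-repeat [burst_metrics()], [repeat_metrics()]
#'   summaries, mean APs/burst), `contrasts` (paired tests over windows),
#'   `config`.
#' @export
run_activity_clamp_experiment <- function(cfg = experiment_config(),
                                          u = unitary_epsc()) {
  stopifnot(inherits(cfg, "experiment_config"))
  template <- cfg$template
  if (is.null(template)) {
    rec <- gen_epileptiform_recording(cfg$template_cfg, seed = cfg$seeds[1])
    template <- template_from_recording(rec)
  }
  if (is.null(template$windows)) stop("template has no burst windows")

  thr <- find_conductance_threshold(cfg$p, u, method = "bisect")
  template <- scale_template(template, cfg$scale_mult * thr$threshold_nS)

  per_condition <- list()
  for (cond in cfg$conditions) {
    p_c <- apply_condition(cfg$p, cond)
    played <- play_template(p_c, template, repeats = cfg$repeats,
                            seed = cfg$seeds[1],
                            sigma = cfg$sigma_playback)
    bm <- lapply(played$spikes, burst_metrics, windows = template$windows)
    rm_ <- repeat_metrics(bm)
    counts <- vapply(bm, function(b) b$n_ap, numeric(nrow(template$windows)))
    if (nrow(template$windows) == 1) counts <- matrix(counts, 1)
    per_condition[[cond]] <- list(
      burst_metrics = bm, repeat_metrics = rm_,
      mean_ap_per_burst = rowMeans(counts),
      # fraction of playbacks (pooling windows as repeats when the run is
      # deterministic) containing at least i APs
      ordinal_fraction = vapply(1:3, function(i) mean(counts >= i),
                                numeric(1)))
  }

  contrasts <- NULL
  if (all(c("control", "cbz") %in% names(per_condition))) {
    ctl <- per_condition$control; cbz <- per_condition$cbz
    contrasts <- rbind(
      cbind(metric = "ap_per_burst",
            compare_paired(ctl$mean_ap_per_burst, cbz$mean_ap_per_burst,
                           test = "wilcoxon")),
      cbind(metric = "first_ap_latency",
            compare_paired(ctl$repeat_metrics$latency$latency_mean_ms,
                           cbz$repeat_metrics$latency$latency_mean_ms,
                           test = "wilcoxon")))
  }
  list(template = template, threshold = thr, per_condition = per_condition,
       contrasts = contrasts, config = cfg)
}

#' Paired control/CBZ network experiment
#'
#' For each seed: draw one connectivity matrix, simulate the network under
#' control and under CBZ on that same structure with the same noise seed
#' (so the only difference between the pair is the soft-threshold recovery
#' constant), detect population bursts, and summarise.  Across seeds,
#' paired sign tests contrast mean interburst interval and spikes per
#' neuron per burst, and the pooled per-burst vesicle release versus the
#' following interburst interval is correlated per condition.
#'
#' @param cfg an [experiment_config()]; one simulation round per seed.
#'   Connectivity uses `seed` and both conditions use the noise stream
#'   seeded by `seed + 10000`: each pair is a controlled comparison in
#'   which the network structure and the noise realisation are identical
#'   and literally nothing but `tau_VT` differs.
#' @param ... burst-detection knobs passed to
#'   [detect_population_bursts()].
#' @return List: `summary` (from [summarize_run()]), `paired` (wide
#'   per-seed table), `tests` (sign tests), `runs_flagged`, `config`.
#' @export
run_network_experiment <- function(cfg = experiment_config(), ...) {
  stopifnot(inherits(cfg, "experiment_config"),
            all(c("control", "cbz") %in% cfg$conditions))
  runs_control <- list(); runs_cbz <- list()
  for (k in seq_along(cfg$seeds)) {
    s <- cfg$seeds[k]
    W <- sample_connectivity(cfg$n, seed = s)
    runs_control[[k]] <- simulate_network(
      n = cfg$n, duration_s = cfg$duration_s, condition = "control",
      p = cfg$p, sp = cfg$sp, W = W, noise_seed = s + 10000L)
    runs_cbz[[k]] <- simulate_network(
      n = cfg$n, duration_s = cfg$duration_s, condition = "cbz",
      p = cfg$p, sp = cfg$sp, W = W, noise_seed = s + 10000L)
  }
  smry <- summarize_run(runs_control, runs_cbz, ...)
  pr <- smry$per_run
  paired <- merge(pr[pr$condition == "control",
                     c("seed_index", "n_bursts", "mean_ibi_s",
                       "spikes_per_neuron_per_burst", "mean_release")],
                  pr[pr$condition == "cbz",
                     c("seed_index", "n_bursts", "mean_ibi_s",
                       "spikes_per_neuron_per_burst", "mean_release")],
                  by = "seed_index", suffixes = c("_control", "_cbz"))
  ok <- stats::complete.cases(paired)
  tests <- NULL
  if (sum(ok) >= 3) {
    tests <- rbind(
      cbind(metric = "mean_ibi_s",
            compare_paired(paired$mean_ibi_s_control[ok],
                           paired$mean_ibi_s_cbz[ok], test = "sign",
                           alternative = "less")),
      cbind(metric = "spikes_per_neuron_per_burst",
            compare_paired(paired$spikes_per_neuron_per_burst_control[ok],
                           paired$spikes_per_neuron_per_burst_cbz[ok],
                           test = "sign", alternative = "less")))
  }
  list(summary = smry, paired = paired, tests = tests,
       runs_flagged = which(!ok), config = cfg,
       seeds = list(connectivity = cfg$seeds, noise = cfg$seeds + 10000L))
}
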