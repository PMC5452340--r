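# reifburst

Why would a sodium-channel-blocking anti-epileptic drug make an epileptic
network burst *more* often?  `reifburst` is an R package for studying that
paradox in silico, at the two levels where it plays out:

* **Single neuron — "activity clamp".**  Excitatory and inhibitory synaptic
  conductance templates, as recorded in voltage clamp during epileptiform
  bursts, are replayed into a model neuron through the dynamic-clamp law
  `I = g_E(t)(E_E − V) + g_I(t)(E_I − V)`, so that identical input can be
  compared across drug conditions.  The neuron is a refractory exponential
  integrate-and-fire (rEIF) model: after each spike its leak conductance,
  leak reversal, spike-width parameter and soft threshold `V_T` relax
  exponentially back to rest.  Carbamazepine (CBZ) is modelled by one
  parameter change — the soft-threshold recovery constant `τ_VT` slows from
  13 to 15 ms — a phenomenological stand-in for use-dependent sodium-channel
  block.
* **Network — vesicle-depletion bursting.**  100 rEIF neurons, coupled
  all-to-all through excitatory synapses whose efficacy is limited by a
  releasable glutamate-vesicle pool `N ∈ [0,1]` (fraction `r = 0.3` released
  per spike, recovery constant `τ_N = 8` s).  Bursts ignite when the
  recovered pool crosses the regeneration threshold and terminate as it
  depletes, so *fewer spikes per burst* (the single-cell CBZ effect) means
  *less release per burst* and hence a *shorter wait* until the next burst.

The package covers the full pipeline: conductance conversion with
driving-force and liquid-junction-potential arithmetic, unitary-EPSC
threshold calibration and template scaling, playback, a compiled
Euler–Maruyama network integrator, burst detection, spike metrics (first-AP
latency, jitter CV, ordinal AP reliability, interburst interval CV), paired
statistics, and synthetic generators for every input a slice recording
would otherwise provide.

## Worked example

```r
library(reifburst)

# a synthetic dual voltage-clamp recording: 24 epileptiform bursts
rec <- gen_epileptiform_recording(template_gen_config(), seed = 1)
head(compute_charge_ratio(rec$I_E, rec$I_I, rec$windows, rec$dt_ms), 3)
#>   start  end Q_E_pC Q_I_pC ratio flagged
#> 1   500 1048  130.7  146.1 1.119   FALSE
#> 2  3134 3682  140.9  173.9 1.234   FALSE
#> 3  8185 8733  107.3  149.3 1.391   FALSE

# conductance conversion: driving forces 93.6 / -41.4 mV
current_to_conductance(0, recording_meta(-80, 13.6, 0))$driving_force_mV
#> [1] 93.6

# calibrate, scale, play back under both conditions
p   <- reif_params(sigma = 0)
thr <- find_conductance_threshold(p, unitary_epsc(), method = "bisect")
thr$k; thr$threshold_nS
#> [1] 108
#> [1] 17.28

tm  <- scale_template(template_from_recording(rec), 1.8 * thr$threshold_nS)
ctl <- play_template(apply_condition(p, "control"), tm)
cbz <- play_template(apply_condition(p, "cbz"), tm)
mean(burst_metrics(ctl$spikes[[1]], tm$windows)$n_ap)  # control APs/burst
mean(burst_metrics(cbz$spikes[[1]], tm$windows)$n_ap)  # CBZ APs/burst
#> [1] 2
#> [1] 1.833333
```

The CBZ condition never gains a spike on identical input, and the loss is
concentrated on the *second* AP of each burst — the model's rendering of
the drug's use-dependent action.  The network-level consequence comes from
the paired experiment:

```r
net <- run_network_experiment(experiment_config(seeds = 1:10,
                                                duration_s = 120))
net$paired          # per-seed interburst interval, spikes/burst, release
net$tests           # paired sign tests across seeds
net$summary$correlations  # per-burst release vs next interval, per condition
```

## Documentation

The methods vignette (`vignettes/activity-clamp-methods.Rmd`) describes the
model equations and assumptions, the unit system, the synthetic-data
generators and what they do and do not emulate, the network calibration
(coupling normalisation and noise intensity) and its rationale, numerical
safeguards, and known limitations — including which published observations
this model structurally cannot reproduce and why.
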