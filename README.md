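# circaplast

Analysis toolkit for circadian synaptic plasticity experiments in rodents:
the kind of study that couples **wheel-running locomotor monitoring** under
different lighting regimes (LD 12:12, long photoperiod LD 16:8, constant
darkness DD, constant light LL) with **double-immunofluorescence confocal
imaging** of presynaptic/postsynaptic marker pairs in brain tissue. The
package is aimed at chronobiologists and neuroanatomists who want those two
pipelines as tested, scriptable R functions instead of a chain of desktop
tools.

It provides:

* **Rhythm analysis** of binned wheel-running records: the Sokolove–Bushell
  chi-square periodogram
  `Qp(P) = N · s_h² / s²` (variance of the P circular-phase column means over
  the variance of all N bins, complete cycles only, so `0 ≤ Qp ≤ N`), a
  Fourier periodogram cross-check, the period **tau**, the 0–100 robustness
  index **%Qp** `= 100·(Qp − c)/(N − c)` (c = 0.95 chi-square line at the
  peak), a calibrated rhythmic/arrhythmic classifier, per-cycle activity
  **onset/offset** detection, activity-phase duration **alpha**, cumulative
  onset shift **delta** over 8 cycles (advances negative), rest phase
  **rho = tau − alpha**, overall/day/night/phase activity splits, and
  mid-activity **break** ("siesta") durations. Double-plotted actograms
  included.
* **Puncta quantification** of two-channel fields: rolling-ball-style
  background correction + median filtering, Otsu or fixed thresholding with
  watershed splitting, immunopuncta **counts** and **area fractions**,
  object-based **AND colocalization**, **synapse density**
  `= count / (area × section thickness)` in µm⁻³, **percent participation**
  of each marker in co-labeled synapses, and the expression-change
  classifier (expression increase/decrease, change within existing clusters,
  dispersion, aggregation).
* **Statistics**: distribution-gated group comparisons (Shapiro–Wilk +
  Levene choosing ANOVA/Tukey or Kruskal–Wallis/Dunn-Holm) with direction
  verdicts, and Pearson/Spearman correlation selection.
* **Synthetic-data generators** with planted ground truth for both data
  types, and an end-to-end **study pipeline** (4 conditions × 8 animals;
  4 time points × 8 fields × 3 protein pairs) that is deterministic under a
  master seed.

## Worked example

Simulate a free-running DD animal (period 23.6 h, activity phase 12.7 h, a
2.34 h siesta planted 5 h into the activity phase), then analyze the record
at 6-min bins:

```r
library(circaplast)

p <- sim_activity_params(tau_h = 23.6, alpha_h = 12.7,
                         rate_active = 9, rate_rest = 0.6,
                         break_offset_h = 5, break_duration_h = 2.34,
                         masking = FALSE, seed = 11)
sim <- simulate_activity(p, light_schedule("DD"), n_days = 12)
analyze_rhythm(bin_activity(sim$record, 6))
#> Rhythm parameters for 'animal' (rhythmic)
#>   tau 23.60 h  Qp 2503.0  %Qp 96.0
#>   alpha 12.74 h  rho 10.86 h  delta -192.0 min (8 cycles)
#>   overall 6074 rev/cycle  day 1683  night 4437  (%day 27.5)
#>   mean mid-activity break 2.28 h
```

The planted truth is recovered: tau 23.6 h on the 0.1 h periodogram grid;
alpha 12.74 vs 12.7 h planted; delta −192 min = 8 cycles × the −24 min/cycle
drift implied by tau; the siesta within 4 min of its planted 2.34 h. %Qp 96
says the rhythm is nearly as robust as the statistic allows; "day" here is
the subjective day (CT0–CT12), anchored at the acclimation lights-on.

Same idea for imaging — plant 100 puncta per channel with 60 true synapses
and quantify:

```r
fld <- simulate_puncta_field(sim_image_params(n_puncta_a = 100, n_puncta_b = 100,
                                              coloc_fraction = 0.6, seed = 5))
quantify_field(fld)
#>   count_pre count_post co_labeled_count density_per_um3 participation_pre_pct
#>         100        100               60           0.296                    60
```

All 100/100 puncta and all 60 planted synapses are recovered despite shot
noise and a background ramp; 0.296 µm⁻³ is 60 synapses over the
21 µm × 21 µm × 0.46 µm sampled volume.

The full synthetic study (both arms, comparisons, expression-change labels):

```r
report <- run_full_study(default_study_config(master_seed = 1))
write_study_report(report, "out")   # CSV tables under out/{activity,imaging,stats}
```

A thin command-line wrapper lives at `inst/scripts/circaplast.R`
(`simulate`, `analyze`, `full-run` subcommands over a YAML config).

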