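---
title: "Methods: circadian rhythm analysis and synaptic puncta quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rhythm analysis and synaptic puncta quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaplast)
```

circaplast implements the two analysis stages of a circadian synaptic
plasticity experiment in mice housed under four lighting regimes — standard
light-dark (LD 12:12), long photoperiod (LD 16:8), constant darkness (DD) and
constant light (LL): (1) extraction of daily/circadian rhythm parameters from
wheel-running records, and (2) quantification of synaptic protein immunopuncta
and colocalization-based excitatory synapse density from two-channel confocal
fields. Because such studies rarely deposit raw recordings or micrographs,
both stages come with synthetic-data generators that plant known ground truth,
and the package's correctness claims are phrased as recovery and calibration
properties against that truth.

## 1. Locomotor rhythm analysis

### Data model

A wheel-running record is a complete series of non-negative counts per time
bin (`activity_record`), tied to a `light_schedule` that carries the regime,
the lights-on clock time, and — crucially for constant conditions — the
lights-on anchor of the LD 12:12 acclimation phase that every animal
experiences before the experiment. Zeitgeber time (ZT0 = lights-on) and
circadian time (CT0 = former lights-on) are derived from these anchors;
the subjective day under DD/LL is CT0–CT12. Records are simulated at 1-min
bins (the dominant granularity of wheel-running counters) and analyzed at
6-min bins; 30-min bins are convenient for actogram plotting.

### Chi-square periodogram and Qp

The period estimate uses the Sokolove–Bushell chi-square periodogram. For a
candidate period of $P$ bins, only the first $\lfloor N_{tot}/P\rfloor \cdot P$
bins are used (complete cycles only — partial columns would bias the column
means), and

$$Q_p(P) = N\,\frac{s_h^2}{s^2},$$

where $s_h^2$ is the variance of the $P$ circular-phase column means around
the grand mean and $s^2$ the variance of all $N$ used bins. With this
normalization $0 \le Q_p \le N$, which the robustness index below relies on;
a constant series is defined to have $Q_p = 0$. Under the null, $Q_p(P)$ is
approximately $\chi^2_{P-1}$, and the periodogram carries the pointwise 0.95
quantile as its significance line. The default search grid is 20–28 h in
steps of one bin: it brackets murine daily and free-running periods under all
four regimes with margin, and one-bin steps are the finest resolution the
statistic supports. Peak ties are broken toward the period closest to 24 h.
A plain mean-subtracted Fourier power spectrum (no tapering, no zero-padding)
is available as a cross-check for the period estimate; it has coarser
resolution near 24 h and no distributional significance line, so rhythmicity
decisions and %Qp always use the chi-square method.

### Rhythmicity classification

Declaring a record rhythmic when the periodogram peak crosses the pointwise
0.95 line is anti-conservative to the point of uselessness on a dense grid:
in our null simulations (iid Poisson counts, 10-day records at 6-min bins,
81 tested periods) it flags 97% of pure-noise series. A full Bonferroni
correction over the grid overshoots in the other direction (2.4% at nominal
5%), because adjacent integer-bin periods give highly correlated statistics.
Simulation shows the 81-period grid behaves like roughly half as many
independent tests, under both Poisson and overdispersed (negative-binomial)
nulls, so `classify_rhythmicity()` uses a Šidák correction with
$m_\mathrm{eff} = \lceil m/2 \rceil$: the per-period level is
$1-(1-\alpha)^{1/m_\mathrm{eff}}$. Measured null flagged fractions are 0.057
(Poisson) and 0.048 (negative-binomial) at nominal 0.05.

### %Qp

The robustness index rescales the peak statistic to a 0–100 range. The
rescaling convention used in the source literature for this index is not
published in closed form, so the package defines and documents its own:

$$\%Q_p = 100 \cdot \mathrm{clip}_{[0,1]}
  \frac{Q_p^{peak} - c}{N - c},$$

with $c$ the pointwise 0.95 chi-square line at the peak period and $N$ the
bins used there. Zero therefore means "no more rhythmic than noise", 100
means the statistic attains its algebraic maximum ($Q_p = N$, a perfectly
repeating waveform).

### Onsets, alpha, delta, rho, breaks

Activity onsets are detected per cycle on windows of length tau tiled from
the first detected onset (with a 2-h search margin for jitter). The onset is
the start of the first run of at least 3 bins above threshold preceded by a
6-bin quiescent window; the offset is found symmetrically from the cycle's
end. The threshold is 25% of the record mean. Two robustness choices matter
at realistic noise levels: quiescence is gated on the *mean* of the window
rather than on every bin (a single chance supra-threshold rest bin should not
veto an onset), and candidate runs must have a mean count of at least twice
the threshold (a run of marginally supra-threshold rest bins is not sustained
activity). These defaults are exposed as arguments; the detector's exact
published counterpart is proprietary to the usual desktop tools, so the rule
here is a documented stand-in validated by recovery tests. Cycles without a
qualifying run are flagged missing; more than 25% missing is an error.

From the onset series: alpha is the mean onset-to-offset duration over the
first eight usable cycles; delta is the cumulative onset shift over eight
successive cycles *measured against the 24-h clock* (the way drift is read
off an actogram), which telescopes to
$\mathrm{onset}_9 - \mathrm{onset}_1 - 192\,\mathrm{h}$; advances are
negative, delays positive. rho is defined as $\tau - \alpha$ exactly — the
identity is preserved by construction, not re-estimated. Whether delta under
constant conditions should be accumulated against clock time or against tau
is genuinely ambiguous; the clock-time convention is used because it matches
the actogram-slope reading and makes delta of a 24-h-entrained animal exactly
zero.

Mid-activity breaks ("siestas") are maximal interior runs within an
onset-offset span that stay below 25% of the activity-phase mean for at least
15 min; the 15-min floor is set to catch the ~0.3 h breaks seen under long
photoperiod while ignoring bin-level dropouts.

Activity totals are computed on three partitions: overall activity per tau
cycle; the (subjective) day/night split on 24-h cycles anchored at
(acclimation) lights-on — under LD 16:8, day is still ZT0–ZT12; and the
activity/rest-phase split, which folds the record at tau and takes the
half-cycle circular window of maximal summed activity as the activity phase
(ties broken at phase zero). Day plus night activity equals overall activity
per 24-h cycle exactly, since the windows partition the same span.

For arrhythmic records (expected under LL), tau, Qp, %Qp and all activity
totals are still reported, but alpha, delta, rho and breaks are withheld; the
activity/rest split is computed against an arbitrary anchor and flagged.
Analysis of every record discards the first 24 h after the lighting switch.

### Activity generator

`simulate_activity()` renders a nocturnal activity phase of duration alpha
recurring with period tau, Poisson (default), negative-binomial or
deterministic counts, an optional one-break-per-cycle siesta, onset locking
to lights-off under light-driven regimes with masking, and a
rate-homogeneous mode for arrhythmic animals (same expected total, no phase
structure). The generator couples onset drift and period: under
constant conditions successive onsets are tau apart, so drift per cycle
against the 24-h clock is $(\tau - 24)\cdot 60$ min and the two
parameterizations are interchangeable (supplying both requires consistency).
The generator does not model a phase-response clock, splitting, or
ultradian structure; masking is a simple onset lock. Recovery tests should
therefore be read as validating the estimators on idealized but
noise-realistic records, not as evidence about pathological real-world
actograms.

## 2. Puncta quantification

### Preprocessing and segmentation

Each channel is background-corrected by subtracting a grayscale morphological
opening with a disk of radius 8 px (a rolling-ball-style estimate; the disk
must exceed the spot radius, and the image is edge-replicated before the
opening so borders carry no artifact), then median-filtered (3 px window).
Segmentation thresholds with Otsu's method per channel by default — the
original desktop workflow's manual threshold is not reproducible — with a
fixed-value option for cross-field comparability; touching puncta are
separated by a distance-transform watershed; components below 4 px² are
discarded as noise (no upper size limit by default). Counts and area
fraction (percent of field covered) are measured on the filtered mask.

### Colocalization, density, participation

Excitatory synapses are proxied object-wise: the two binary masks are
conjoined pixelwise (the "AND" operation) and the connected components of the
intersection with at least 1 px of overlap are counted (the minimum overlap
is configurable). The count is converted to synapse density by dividing by
the sampled volume, field area × optical-section thickness; the z-step of
the acquisition (0.46 µm) is used as the thickness. Percent participation of
a marker is the share of its puncta that belong to co-labeled sites,
undefined when the channel is empty. Intensity-correlation measures
(Pearson/Manders) are deliberately out of scope — the workflow is
object-based.

### Expression-change classification

Changes in expression are interpreted from the joint direction verdicts of
the puncta count and the covered area between two time points: concordant
significant changes confirm an expression-level change; area-only changes
are confined to pre-existing clusters; count-only changes are redistribution
(more puncta at equal area = dispersion; fewer = aggregation); opposing
significant directions are indeterminate. The mapping is total over the nine
verdict pairs.

### Image generator

`simulate_puncta_field()` plants Gaussian spots (σ = 2 px) at
rejection-sampled positions with a minimum center separation of 8 px across
both channels, makes a chosen fraction of channel-B puncta concentric (within
1 px) with channel-A puncta — these are the ground-truth synapses, exactly
`round(coloc_fraction × n_B)` of them — and adds a background plane with a
linear ramp plus Poisson shot noise (200 photons per intensity unit). Packing
is bounded at 100 attempts per punctum; infeasible requests error rather than
silently degrade. Default geometry mimics a high-zoom confocal section:
256 × 256 px at 0.082 µm/px (a ~21 µm field) and 0.46 µm section thickness.
The generator renders single optical sections; a stack is a list of sections.
It does not emulate optical blur between channels, chromatic offsets,
intensity-dependent spot size, or clustered (non-Poisson) spatial layouts, so
segmentation performance on real micrographs with those features is not
certified by the recovery tests.

## 3. Statistics layer

Group comparisons reproduce the distribution-gated scheme standard in this
literature: Shapiro–Wilk per group and median-centered Levene across groups,
both at 0.05, select one-way ANOVA with Tukey's HSD, or Kruskal–Wallis with
Dunn's rank post-hoc test. Dunn's z statistics use the tie-corrected variance
and are Holm-adjusted by default (the adjustment is configurable to
Bonferroni or none, since desktop statistics packages differ silently here).
Direction verdicts — up, down, non-significant at adjusted p < 0.05, oriented
second group minus first — are what the expression-change classifier
consumes. Correlations likewise gate on Shapiro–Wilk: Pearson when both
variables pass, Spearman otherwise. Groups of fewer than three observations
are rejected; a degenerate (near-constant) group is treated as non-normal
rather than crashing the gate.

## 4. The synthetic study

`default_study_config()` encodes the emulated design: 4 conditions × 8
animals recorded 12 days (analysis skips the first day; 6-min analysis
bins), and 4 sacrifice time points (ZT/CT 0, 6, 12, 18) × 8 fields × 3
presynaptic/postsynaptic pairs (Syp1/PSD95, Piccolo/Homer 1, NRXN/PICK1).
Per-condition activity parameters follow the reported phenotypes: LD 12:12
with alpha 11.8 h and ~1.5 h breaks; DD free-running with a 19 min/cycle
advance (tau 23.68 h), alpha 12.7 h, ~2.3 h breaks; LD 16:8 with short,
intense activity (alpha 8.2 h, ~0.3 h breaks); LL delayed by 46.3 min/cycle
with alpha 9.1 h, ~60% lower overall activity, and half the animals
arrhythmic. (The study this emulates reports an LL period about 1.2 h longer
than LD alongside the 46-min onset delay; with drift and period coupled the
generator follows the onset-delay figure, which is what delta measures.)
Imaging abundances and colocalized fractions vary by condition and time
point in the reported qualitative patterns — e.g. higher Syp1 counts and
synapse density in the (subjective) day under LD and DD, flat LL — with
colocalized fractions in the 0.55–0.78 range so that percent participation
lands in the reported 50–80% band per protein (Piccolo lowest among
postsynaptic partners via a higher puncta count, NRXN below 50% likewise).

Every stochastic stage derives its seed from the master seed by a stable
string hash of (module, entity id), so the whole study is reproducible
table-for-table and the report writer emits byte-identical CSVs on re-runs.
The full study (32 animals, 384 fields) runs in about a minute on one core;
these sizes were chosen so the complete test battery, including a double
end-to-end run, stays comfortably interactive.

## 5. Numerical conventions and limitations

* Time is handled in hours from record start internally; windows are
  half-open `[start, end)`. Pixel coordinates are 0-based, row-major; areas
  in px² convert via the squared pixel size.
* Re-binning requires integer bin ratios and conserves totals; readers
  reject timestamp gaps unless explicitly asked to zero-fill.
* The chi-square periodogram needs at least two complete cycles of the
  longest tested period; tau estimates inherit the one-bin grid resolution
  (0.1 h at 6-min bins).
* Delta requires nine detected onsets (eight shifts); weakly rhythmic
  records may report tau and totals but no phase parameters.
* Otsu thresholds each field independently; between-field intensity
  normalization is out of scope, which is one reason the fixed-threshold
  option exists.
* The statistics layer performs no multiplicity correction *across*
  variables or protein pairs, matching the emulated workflow; p-values from
  the many tests of the pipeline's report should be read accordingly.
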