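---
title: "Decoding elapsed time during learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding elapsed time during learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timedecode)
```

# The problem

In a differential reinforcement of response duration (DRRD) task an animal
starts a trial by a sustained response (a nose poke or lever press) and is
rewarded only when the hold duration exceeds a criterion, 1.5 s by default.
Naive animals release early; within a single session the distribution of
hold durations shifts rightwards as they learn the interval. `timedecode`
implements the analyses used to track where in the brain elapsed time is
encoded while this learning happens: a mixture model of the behaviour, a
population decoder of the within-trial time bin applied to recordings from
medial prefrontal cortex (mPFC) and dorsal striatum (STR), single-unit
climbing (ramping) detection, and between-animal jackknife inference. A
synthetic-data generator with known ground truth exercises every stage.

# The double-Gaussian duration model

Hold durations are bimodal: a premature mode of short releases and a
temporally controlled mode near or beyond the criterion. The model is the
unnormalised two-Gaussian mixture

$$ f(t_i) = (1-\gamma)\, e^{-(t_i-\mu_1)^2 / 2\sigma_1^2}
          + \gamma\, e^{-(t_i-\mu_2)^2 / 2\sigma_2^2}, $$

normalised discretely on the grid $t_i = i\,\Delta t$, $i = 0\ldots 60$,
$\Delta t = 0.1$ s:

$$ p(t_i) = f(t_i)/\xi, \qquad \xi = \Delta t \sum_i f(t_i), $$

so that $\sum_i p(t_i)\,\Delta t = 1$ exactly. $\gamma \in [0,1]$ is the
*amplitude ratio* of the second mode in $f$, not a mixture weight of
normalised components: because the modes in $f$ are unnormalised, the
probability mass of the timed mode is $\gamma\sigma_2 / ((1-\gamma)\sigma_1 +
\gamma\sigma_2)$. `sampleDurations()` uses exactly this mass when drawing
from the model, so fitted and generating parameters are directly comparable.

`fitDoubleGaussian()` histograms the durations on the same grid (0.1 s bins
centred on the grid points, range 0–6 s, normalised to a density) and fits
$p(t_i)$ to the histogram by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), starting from the conventional initial values
$\gamma = 0.5, \mu_1 = 0.2, \sigma_1 = 0.1, \mu_2 = 1, \sigma_2 = 0.5$, with
bounds $\gamma \in [0,1]$ and $\sigma \ge 0.01$. The least-squares target is
the binned *density* (not counts), matching the grid on which the model is
normalised. Numerical choices worth knowing about:

* **Mode order is canonical.** If the optimum has $\mu_1 > \mu_2$, the modes
  are swapped and $\gamma \mapsto 1-\gamma$, so returned parameters always
  satisfy $\mu_1 \le \mu_2$.
* **Restarts.** The bounds make $\gamma = 0$ and $\gamma = 1$ absorbing
  stationary points of the iteration: with one mode silenced, its parameters
  have zero gradient and the optimiser can stall there. The fit therefore
  restarts from a fixed set of four initial values and keeps the smallest
  residual norm. When several solutions tie to within 5% — which happens
  exactly when the data are effectively unimodal and $\gamma$ is
  unidentifiable — the conventional start's solution is kept, which
  represents a unimodal sample as a dominant second mode ($\gamma$ near 1)
  rather than an arbitrary split between coinciding modes.
* Durations above 6 s lie outside the grid; they are excluded from the fit
  histogram (with a message) but retained in behavioural means.
* Fewer than 30 durations is an error: the 61-bin histogram is too sparse to
  constrain five parameters.

# From spike trains to rate tensors

Spikes are epoched per trial into $[\mathrm{onset} - 0.5\ \mathrm{s},
\mathrm{offset}]$ and re-referenced to the onset (times run from $-0.5$ s to
the duration) or the offset (all times $\le 0$). Rate estimation convolves
each spike with a Gaussian kernel ($\sigma = 100$ ms, truncated at
$\pm 3\sigma$ and renormalised within the analysis window so no mass is
invented or lost at the edges), integrates over 100 ms bins and divides by
the bin width. The total smoothed mass per trial and unit equals the spike
count inside the window, and the operation is linear in spike trains; both
properties are asserted by tests.

Decoding uses *reinforced* trials only: durations in $[1.5, 3.5)$ s (closed
lower bound — a hold of exactly the criterion is rewarded; the 3.5 s cap
excludes outlier holds). Each such trial is truncated at 1.5 s, giving 15
bins from onset.

# The time-bin decoder

The decoder asks how well the population firing-rate vector identifies
*which* 100 ms bin of the trial it came from.

* **Classes.** Trials are truncated at 1.5 s (15 bins); the first 2 and last
  3 bins are dropped, leaving $K = 10$ decoded classes spanning 0.2–1.2 s
  after onset. Dropping the edges removes response-locked motor transients
  at both ends of the hold and reconciles the 15-bin truncation with a
  10-class decoder; both counts are configurable in `DecoderConfig()`.
* **Pseudo-population.** Units are pooled across animals into one "average
  animal". With $N$ the smallest per-animal reinforced-trial count, every
  animal contributes its first $\lfloor N/2 \rfloor$ reinforced trials to
  the early stage and its last $\lfloor N/2 \rfloor$ to the late stage;
  pseudo-trial $k$ concatenates the $k$-th selected trial's unit rates
  across animals. Taking each animal's *last* trials for the late stage
  (rather than trials $N/2+1 \ldots N$) preserves the early/late contrast
  for animals with many more trials than $N$.
* **Cross-validation.** 1000 random folds; in each, 80% of pseudo-trials
  train and the rest test. The $K$ bins of one trial stay together in either
  set, so the classifier can never train and test on bins of the same trial.
  Each trial contributes exactly one sample per class, making the empirical
  class priors uniform by construction. If the train fraction would leave
  fewer than 2 test trials, the training set is reduced to $n-2$ trials with
  a warning.
* **Normalisation.** Per unit, features are centred by the training-set
  median and scaled by the training-set interquartile range (IQR); IQR-0
  units are centred only. Test data reuse the training statistics.
* **Classifier.** A multiclass linear discriminant with one shared
  covariance matrix estimated from the pooled class-centred training rows
  and regularised by Ledoit–Wolf analytic shrinkage toward the scaled
  identity $\hat\mu I$, $\hat\mu = \operatorname{tr}(S)/p$. The shrinkage
  intensity is the closed-form optimum recomputed on each fold's training
  set; no tuning. Shrinkage keeps the fit well-posed even with collinear
  units or more unit-features than training trials. Class probabilities are
  the softmax of the discriminant scores.
* **Performance.** Per fold, the Pearson correlation between the true bin
  index and the highest-probability bin index over the test samples (ties
  broken toward the lowest bin, making decoding deterministic given the
  fold split; a constant prediction scores 0 by convention). The per-class
  probability profiles are averaged across folds into a $K \times K$
  confusion matrix whose rows sum to 1. `foldSummary()` reports the fold-R
  mean, SD, and a 2.5–97.5 percentile interval of bootstrap means
  ($10^4$ seeded resamples).

# Climbing (ramping) activity

A unit climbs when its trial-averaged rate rises or falls roughly linearly
across the interval. `detectClimbing()` fits an OLS line to the
trial-averaged rate versus bin-centre time and flags units whose slope
differs from 0 at $\alpha = 0.05$ (two-sided, either sign). The input tensor
should be built **without** kernel smoothing (`TaskConfig(kernelSigma = 0)`,
plain 100 ms binned counts): smoothing spreads each spike over neighbouring
bins, which correlates the per-bin errors and empirically inflates the null
flagging rate from the nominal 0.05 to roughly 0.19. On unsmoothed bins the
test is calibrated (measured null rate 0.057 over 1000 simulated untuned
units, inside the binomial 99% band). Degenerate inputs are resolved by
convention: a constant trial-averaged rate gives slope 0, $p = 1$; an exact
noise-free line gives $p = 0$.

# Jackknife between-animal inference

Pseudo-population decoding yields one number per condition, not one per
animal, so condition differences are tested with a leave-one-animal-out
jackknife: the statistic's A−B difference is recomputed $N$ times, omitting
one animal per run, and the $N$ differences are tested with a one-sample t.
Because leave-one-out runs are strongly dependent, the raw t is divided by
$N-1$ before looking up significance. The p-value uses $N-1$ degrees of
freedom (configurable — the appropriate df for the corrected statistic is a
convention, not a derivation). The statistic function receives an explicit
seed so that jackknife runs of the stochastic decoder are reproducible. Zero
variance across runs is an error (t undefined), never silently $t = 0$.
Under a null simulation the corrected test is conservative (empirical
type-I rate at or below 0.05), which the suite asserts over 500 replicates.

# The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, with ground truth known by construction.

* **Behaviour.** Hold durations are drawn from the double-Gaussian model
  with parameters interpolated (linearly, or by a mid-session logistic)
  from a start to an end parameter set across the trial index. The defaults
  emulate single-session acquisition: $\gamma$ 0.04 → 0.90, timed mode
  1.5 s → 2.05 s, premature mode near 0.3 s throughout, 600 trials, and
  yield half-session mean durations near 1.0 s (early) and 1.7 s (late),
  the group behaviour typical of this task. Draws below 0.05 s are rejected
  and redrawn (shorter pokes are not registered by the task hardware).
  Inter-trial intervals are exponential, mean 2 s; the analysis uses them
  only through epoch non-overlap.
* **Spike trains.** Each unit follows a parametric archetype — time cell
  (Gaussian bump at a preferred latency), linear ramp up/down, onset- or
  offset-locked bump, or untuned — with an encoding-strength knob in
  $[0,1]$ scaling the modulation depth toward baseline; strength 0 makes
  every archetype an untuned Poisson unit. Within the trial epoch spikes
  are drawn from an inhomogeneous Poisson process by exact thinning of the
  continuous rate function (no time binning); outside trials units fire at
  baseline. The per-stage strength switches at the session midpoint (first
  half of trials at the early value, second half at the late value) — the
  simplest schedule consistent with a per-stage knob.
* **Experiments.** `simulateExperiment()` writes per-animal sessions in the
  package's on-disk format (trials CSV, spikes CSV, JSON manifest). Region
  archetype proportions are free parameters of the caller, not claims about
  real tissue.

What the generator does *not* emulate: spike-sorting artifacts and unit
instability, correlated noise across units (units are conditionally
independent Poisson given the rate), within-stage drift of encoding
strength, reward-consumption and licking dynamics, and any dependence of
firing on the upcoming response duration beyond the offset-locked
archetype. Passing tests therefore show that the pipeline recovers known
structure from idealised data of realistic size and rate; they do not show
robustness to correlated or non-Poisson variability in real recordings.

# Reproducibility and problem sizes

Every stochastic component takes an explicit integer seed, and all
generators are bit-reproducible given one. `runPipeline()` fans a single
global seed out to per-stage seeds through a fixed affine counter scheme,
so individual stages can be rerun in isolation. Derived seeds stay below
$2^{31}$.

The test suite and the acceptance script run the pipeline at sizes chosen
to keep Monte-Carlo error well inside the asserted margins while remaining
desk-scale: 600-trial behavioural sessions (8 animals) for the group
behaviour summary; 2000 samples for parameter recovery; 60 trials × 20
time cells with 1000 folds for the decoder ceiling; a 4-animal, 120-trial,
10-units-per-region experiment with 500 folds for the encoding-migration
check; 1000 untuned units for the climbing calibration. The jackknife over
decoder runs uses 200 folds per leave-one-out subset.

# Known limitations

* The decoder is linear; a failure to decode bounds only what a linear
  readout can extract.
* Pseudo-populations ignore trial-by-trial co-fluctuations across animals
  by construction (trials from different animals are concatenated by rank,
  not by simultaneity).
* The double-Gaussian fit is a least-squares fit to a binned density, not a
  likelihood fit; with very few trials the binning dominates the error.
* `validateSession()` checks internal consistency only; it cannot detect
  clock offsets between behavioural and electrophysiological acquisition.
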