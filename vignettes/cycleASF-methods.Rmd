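---
title: "Quantifying cell-cycle desynchronization with the auto-similarity function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cycle desynchronization with the auto-similarity function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleASF)
```

## The problem

A population of cultured cells released from a synchronizing arrest (for
example a double-thymidine block) does not stay synchronized: cell-to-cell
variability in cycle duration spreads the cells' positions in the cycle
until the population is indistinguishable from an untreated, asynchronous
culture. The speed of that decay carries information: if each cell's cycle
period is an independent draw with standard deviation $\sigma_\tau$, then
after $k$ cycles the spread of cycle positions grows like
$\sigma_\tau\sqrt{k}$, so the desynchronization rate observed in a
DNA-content timecourse is a readout of $\sigma_\tau$ itself. cycleASF
implements that chain of reasoning end to end: a single-cell DNA-content
model, a population simulator, a nonparametric synchrony statistic, a
logistic summary of its decay, and a simulation-based estimator that
inverts the decay back to $\sigma_\tau$.

## The auto-similarity function

Flow cytometry with a stoichiometric DNA stain (e.g. propidium iodide)
measures, per cell, a fluorescence value proportional to DNA content. At
each sampling time $t_i$ the experiment yields a sample $X_{t_i}$ from the
population's DNA-content distribution. The auto-similarity function (ASF)
between two timepoints is the two-sample Kuiper statistic of their
empirical CDFs $F_1, F_2$:

$$\Sigma(t_i, t_j) \;=\; \sup_v\,[F_1(v) - F_2(v)]_+ \;+\;
  \sup_v\,[F_2(v) - F_1(v)]_+ .$$

$\Sigma = 0$ for indistinguishable distributions (the asynchronous steady
state) and $\Sigma = 1$ for fully separated ones (perfect synchrony caught
in motion between two distinct states). Each supremum is floored at zero,
which keeps $\Sigma(x, x)$ exactly 0 and $\Sigma \in [0, 1]$ always; both
suprema are attained at pooled data points, so `kuiper_statistic()`
evaluates only there. Because the statistic is rank-based it is invariant
under any strictly increasing transformation of the measurement axis —
gain settings, staining efficiency, or units do not matter — and, unlike
the one-sided Kolmogorov–Smirnov supremum, it weights both tails of the
cyclic DNA-content axis symmetrically, which is why the Kuiper form (the
rotation-invariant variant) suits cyclical data. `asf_successive()` applies
$\Sigma$ to each consecutive timepoint pair; a synchronized population
starts near 1 and decays toward a finite-sample floor, while an
asynchronous control stays flat near that floor.

The finite-sample floor deserves emphasis: with $n$ cells per timepoint,
two draws from the *same* distribution still give
$\Sigma \sim O(1/\sqrt{n})$, about 0.05–0.08 at $n = 1000$. "Full
asynchrony" in practice means the successive-pair ASF has fallen to this
floor, not to zero.

## The single-cell interphase model

DNA content over one interphase of period $\tau$ is modeled as a logistic
synthesis curve:

$$\mathrm{dna}(t) \;=\; \mathrm{dna}_0\left(1 +
  \frac{1}{1 + e^{-\beta (t - s)}}\right), \qquad 0 \le t \le \tau,$$

with $\beta = 24/(3\tau) = 8/\tau$ and $s = 2\tau/3$, so that the
S-phase window is the middle third of the cycle centered on $s$: at
$\tau = 24$ h, S lasts 8 h with midpoint 16 h, matching commonly reported
human-cell phase durations. Phase labels follow half-open intervals — G1
on $[0, \tau/2)$, S on $[\tau/2, 5\tau/6)$, G2 on $[5\tau/6, \tau)$ — so
durations are exactly $\tau/2$, $\tau/3$, $\tau/6$. Synthesis is assumed
faithful, $\mathrm{dna}_{max} = 2\,\mathrm{dna}_0$; note the sigmoid
*approaches* but never reaches doubling (at $t = \tau$ the content is
$\approx 1.935\,\mathrm{dna}_0$), which matters for the classifier (below).

Population variability enters as error-in-variables noise on the two free
parameters, applied per cell per cycle:
$\tau' = \bar\tau + \varepsilon_\tau$ with
$\varepsilon_\tau \sim N(0, \sigma_\tau^2)$, and
$\mathrm{dna}_0' = \mathrm{dna}_0 + \varepsilon_{dna}$ with
$\varepsilon_{dna} \sim N(0, \sigma_{dna}^2)$ (the latter produces the
broadened G1/G2 peaks familiar from real histograms). Draws are
rejection-resampled until $\tau' \ge \tau_{min}$ (default 4 h) and
$\mathrm{dna}_0' > 0$, capped at 1000 rounds: unbounded normal noise would
otherwise occasionally produce non-physical negative periods, and
rejection preserves the bulk of the distribution essentially unchanged
(at $\sigma_\tau = 5$, $P(\tau' < 4) \approx 3\times10^{-5}$). A Poisson
comparison mode ($\tau' \sim \mathrm{Pois}(\bar\tau)$ in integer hours;
$\mathrm{dna}_0' = \mathrm{dna}_0 \cdot P/\lambda$, $P \sim
\mathrm{Pois}(\lambda)$, $\lambda = 100$) is provided as the simplest
mean-preserving reading of "Poisson-distributed error"; its variance is
pinned to its mean, so it cannot be tuned independently, and it produces
measurably different ASF trajectories than variance-matched normal noise.

## The population simulator as a stated world

`simulate_population()` advances a fixed cohort (no birth, no death —
consistent with the absence of a sub-G1 population in the motivating
experiments) through repeated cycles. Division is instantaneous
re-initialization: when a cell's age reaches its current $\tau'$, the
division counter increments and a fresh $(\tau', \mathrm{dna}_0')$ pair is
drawn. We deliberately do *not* halve the mother's final content: the
sigmoid tops out below doubling, so literal halving would drift the
population baseline downward by ~3% per cycle. Periods are independent
across cycles and lineages by default; a `tau_correlation` knob (AR(1)
inheritance of period deviations, default 0) is exposed for exploration
because mother–daughter correlation is biologically plausible but not
constrained by the data this package emulates.

Defaults restate the reference experiment: 1000 cells, sampled every 8 h
from 0 to 88 h, $\bar\tau = 24$ h, $\sigma_\tau = 3$ h,
$\sigma_{dna} = 0.05$ a.u. on a baseline of 1, fluorescence scale 50 a.u.
per DNA unit (cosmetic). Asynchronous initialization draws each cell's
initial age uniformly on $[0, \tau')$; the age bias of an exponentially
growing culture is ignored because the cohort does not grow.

**Where synchronized release starts.** `simulation_config()` defaults to
`init_age_fraction = 0`, i.e. release at the start of G1. The experiment
emulator `emulate_synchronized_experiment()` instead defaults to
`init_age_fraction = 0.5` — release at the G1/S boundary — because that is
where a double-thymidine block actually arrests cells, and because the
age-0 choice interacts pathologically with the 8-h sampling grid: near age
0 the synthesis sigmoid is nearly flat, so consecutive samples taken
inside early G1 have almost identical DNA distributions, and with
$\tau \approx 24$ h every third successive pair is such a pair. The
resulting period-3 oscillation in the ASF series (dipping to ~0.45) is an
aliasing artifact of the model's smooth "synthesis" during G1, not a
feature of any release experiment, and it destroys the logistic rate as a
summary. With the G1/S start the first sampling interval spans active
synthesis and the series decays smoothly from ~1. Users who want the
age-0 convention can request it explicitly.

## Fitting the desynchronization rate

`fit_logistic_decay()` summarizes an ASF series by least squares on

$$\Sigma(t) \;=\; \mathrm{lower} + \frac{\mathrm{upper} -
  \mathrm{lower}}{1 + e^{\mathrm{rate}\,(t - t_{1/2})}},$$

with each successive pair $(t_i, t_{i+1})$ plotted at $t_{i+1}$, the time
the comparison becomes available. The fitted `rate` (1/h) is the package's
desynchronization-rate summary; `t_half` is reported alongside because
neither alone pins down "how fast" in all regimes. Fitting is multi-start
(Nelder–Mead polished by BFGS) from data-driven initializations, with
`lower >= 0` and, for unnormalized series, `upper <= 1`.

One numerical choice needs defending. On an 11-point series sampled every
8 h, the 4-parameter logistic's rate is unidentifiable whenever the decay
envelope is weak: unpenalized least squares will happily fit a
near-vertical step between two adjacent points (rates of 5–10 /h) to chase
a single fluctuation, and such fits dominated at $\sigma_\tau \le 1$ h.
The objective therefore carries a mild ridge penalty
$\lambda\,\mathrm{rate}^2$ with $\lambda = 0.1$, chosen a priori against
the typical residual scale (RSS $\approx$ 0.005–0.03): the penalty is
negligible for physically plausible rates below ~0.3/h
($\lambda\,0.1^2 = 10^{-3}$) and dominant above ~0.5/h, where a rate on
this grid is indistinguishable from a step anyway. Exact-recovery on
noise-free synthetic series is verified with `rate_penalty = 0`; all
comparative results (variance-monotonicity, LPS contrast) use the default.

Normalization (`normalize_series()`) divides a series by its first value
so replicate experiments with different absolute initial ASF become
comparable; asynchronous controls are never normalized, since their raw
flat trend is the control's content.

## Inverse inference of period variability

`estimate_sigma_tau()` inverts an observed desynchronization curve by
grid-search simulation: for each candidate $\sigma_\tau$ it simulates
`reps` synchronized releases, averages their normalized successive-pair
ASF series, and scores the sum of squared differences against the
normalized observed series; the arg-min is the estimate and the full
profile is returned so the user can judge identifiability. Both sides are
normalized so the estimator keys on curve *shape*, not the absolute
initial ASF (which depends on $n$ and staining). The estimator's
simulations default to the same G1/S-boundary release as the experiment
emulator; they should always mirror the observed experiment's design. In
self-recovery tests ($\sigma_\tau = 3$ h truth, grid $\{1,\dots,5\}$,
1000 cells) the profile is sharply convex around the truth and the
arg-min is correct in $\ge 8/10$ repetitions.

## Phase classification

`djf_fit()` deconvolves a DNA histogram into G1/S/G2 percentages with the
classic univariate three-component model: Gaussian G1 at $\mu_1$,
Gaussian G2 at $\mu_2 \in [1.7, 2.2]\,\mu_1$, and a broadened S component
— a constant-height rectangle on $[\mu_1, \mu_2]$ convolved with a
Gaussian whose width interpolates $\sigma_1 \to \sigma_2$ (approximated by
16 kernels). Two simplifications relative to the original
Dean–Jett–Fox formulation: the S height is a single parameter rather than
a quadratic polynomial, and debris/doublet modeling is omitted (events
below $0.5\,\mu_1$ are reported as an unclassified fraction). Both reflect
the package's role: a transparent, testable stand-in validated against
synthetic ground truth, not a re-implementation of any commercial tool
whose exact constraint set is unpublished. The fit uses variable
projection — the three amplitudes are profiled out by non-negative least
squares at each step, so only the four shape parameters are optimized —
which makes a 256-bin fit run in ~0.2 s. Fractions are component areas
*within the histogram window*, so a broad component cannot claim events
that were never observed. The G2 window's lower edge is 1.7 (not 1.8)
because G2 fluorescence commonly sits slightly below exact doubling, and
in this package's own simulator the saturating sigmoid puts late-cycle
cells at 1.79–1.93$\times$ baseline.

That last point is also the classifier's main caveat on simulated data:
the interphase model spreads "G1" cells (ages $[0, \tau/2)$) over DNA
contents 1.00–1.21$\times$ baseline and "G2" cells over
1.79–1.93$\times$, whereas the mixture model — like real biology — expects
G1 at a tight 2n peak. Fitted fractions on simulated asynchronous data
therefore disagree with the age-based truth labels by 10–20 percentage
points *systematically* (DJF assigns slowly-synthesizing early-"S"-by-DNA
cells to S while the age convention calls them G1). The classifier is
validated instead on synthetic mixtures that satisfy its own assumptions
(60/25/15 recovered within ±3 points at 20,000 events), and truth labels
are carried alongside fitted fractions so users can see both conventions.
A green classifier test establishes recovery of DJF-structured mixtures —
it does not establish agreement between age-based and content-based phase
definitions, which genuinely differ under this model.

## What the synthetic world does and does not establish

The generator emulates: release-synchronized and asynchronous PI-style
timecourses on the 0–88 h/8 h grid; period noise with the stated normal
(and comparison Poisson) families; time-lapse duration assays with the
measured treated/untreated parameterizations (23.7 ± 4.73 h,
21.7 ± 3.42 h). It does not emulate: staining/instrument artifacts beyond
a single optional measurement CV, mitotic duration (division is
instantaneous), cell death or growth, mother–daughter correlation (off by
default), or the loss of mitotic cells during harvesting that real
timecourses show as slow ASF drift in the asynchronous control. Green
tests therefore establish internal consistency of method and model — e.g.
that the estimator recovers the generator's own $\sigma_\tau$ — not
agreement with any particular wet-lab measurement.

One negative result is retained deliberately: at fixed $\sigma_\tau$ (in
hours), the fitted desynchronization rate *does* depend on the mean period
(about 15% across 22/24/26 h, clearly resolvable at 20 replicates),
because desynchronization is paced per cycle and a shorter period packs
more cycles into the same wall-clock window. A mean-insensitivity check at
replicate power fails accordingly; treating rate differences at matched
$\sigma_\tau$ but different mean periods as pure noise differences would
be a misreading. The LPS-style contrast (23.7/4.73 vs 21.7/3.42) is
dominated by the $\sigma_\tau$ difference and survives this caveat: the
treated parameterization desynchronizes faster both per cycle and per
hour.

## Numerical conventions, in brief

Ties across samples use at-or-below CDF semantics at shared points; CDF
difference suprema are floored at 0. Histogram bins are uniform with
out-of-range events clipped to edge bins (counts conserved). All
stochastic entry points take explicit integer seeds and restore the
caller's RNG state; child seeds are derived arithmetically and stay below
$2^{31}$. Degenerate inputs fail as classed conditions
(`cycleASF_invalid_input`, `cycleASF_out_of_domain`,
`cycleASF_degenerate_normalization`, `cycleASF_fit_failure`,
`cycleASF_classifier_failure`) rather than generic errors.
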