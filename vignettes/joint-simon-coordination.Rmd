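---
title: "Decomposing the joint Simon effect and measuring inter-agent response coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the joint Simon effect and measuring inter-agent response coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointcoord)
```

## The scientific problem

When two people split a go/no-go Simon task — each responding to one stimulus
color, sitting left and right of the screen — a spatial-compatibility effect
re-emerges that is absent when the same go/no-go task is performed alone.
This *joint Simon effect* (JSE) is commonly read as an index of shared task
representations. A complementary question is whether co-agents' response
times become *coordinated* over the course of a session: whether slow
fluctuations in one agent's RTs track the other's. `jointcoord` implements
both sides of that analysis as a reusable pipeline:

1. **Effect decompositions** — condition × correspondence mean tables,
   quartile-bin (Vincentized) distributional analysis, and the 2×2×2
   trial-transition table that exposes conflict-adaptation (sequential)
   modulation.
2. **Coordination analysis** — instantaneous cross-correlation of the two
   agents' centered RT series across trial lags, summarized as the
   proportion of locally correlated activity, benchmarked against
   *pseudo-pairs* (the same two people performing individual sessions in
   parallel rooms).
3. **Inference** — paired t-tests with Bonferroni correction,
   within-subject ANOVA with partial eta squared, and a mixed-model
   comparison asking whether a pair-level random effect of coordination
   improves the fit.
4. **A synthetic dyad generator** providing ground truth for all of the
   above.

Because raw data from dyadic Simon experiments are rarely deposited, every
stage is validated against the generator (parameter recovery, calibration)
and against worked examples computed from published-style summary tables
shipped with the package (`reference_summary_tables()`).

## The task design being emulated

A session has 384 experimental trials in 4 blocks of 96. Exactly half of
the trials are *corresponding* (stimulus on the same side as the response
key); each agent responds to one color only, so each agent has 192 go
trials per session. Dyads perform an individual session (both members in
parallel, separate rooms) followed by a joint session. The generator
enforces this balance exactly — correspondence and responder assignment are
shuffled multisets within each block, not Bernoulli draws — so acceptance
checks are free of binomial schedule noise.

## The trial-level RT model

For a go trial of agent $a$ at schedule position $t$:

$$RT = \mu + \tfrac{\beta}{2}\,s(t) + seq(t) + z_a(t) + \varepsilon_t,$$

with $s(t) = +1$ for non-corresponding and $-1$ for corresponding trials.
The symmetric $\pm\beta/2$ parameterization keeps the grand mean
independent of the Simon effect, so `beta_simon` is exactly the expected
NC − C difference and parameter recovery is unbiased by construction.

**Sequential term.** Conflict adaptation is modeled as
$seq(t) = g(t)\left[\tfrac{\lambda}{2} s(t)\,I(t\!-\!1 = C) -
\tfrac{\lambda_{rev}}{2} s(t)\,I(t\!-\!1 = NC)\right]$: an enlarged
correspondence effect after corresponding trials, a reversed one after
non-corresponding trials. The gate $g(t)$ restricts the modulation to
Nogo/go transitions (trial $n-1$ required the *other* agent's response),
the empirically dominant pattern. On a transition table this predicts that
the gated rows spread by $\lambda + \lambda_{rev}$ while Go/go rows stay at
$\beta$ — the identity the recovery tests exploit.

**Latent fluctuation and coupling.** Each agent carries
$z_a = \sqrt{c}\,u + \sqrt{1-c}\,v_a$, where $u$ (shared) and $v_a$
(private) are AR(1) processes with autocorrelation $\phi$ and *stationary*
SD $\sigma_{lat}$, and $c \in [0,1]$ is the coupling share. Two choices
matter here:

- $\sigma_{lat}$ is the stationary SD (innovation SD
  $\sigma_{lat}\sqrt{1-\phi^2}$), so the marginal SD of correct RTs is
  $\approx\sqrt{\sigma^2 + \sigma_{lat}^2}$ for every $\phi$ and $c$ — the
  dispersion of the data does not move when coupling or autocorrelation
  are varied.
- The latent process is indexed over the *full* 384-trial pair schedule
  and each agent samples it on their own go trials. Coupling must survive
  the go-trial subsetting that the analysis performs; a latent process
  defined only on an agent's own series would decouple the dyad as soon as
  series are aligned by ordinal go-trial index.

Defaults: $\mu = 340$ ms, $\sigma = 30$ ms, $\beta = 10$ ms,
$\lambda = \lambda_{rev} = 15$ ms, $\phi = 0.8$, $\sigma_{lat} = 10$ ms,
error/miss probability 0.005, RT floor 100 ms. The dispersion values
produce correct-RT SDs of ≈ 32 ms and error rates below 1%, typical of
this task family. $\phi$ and $\sigma_{lat}$ are *choices*: inter-trial RT
autocorrelation is not reported in the summary tables this package works
from, and both values are documented, tunable, and deliberately modest.
Misses and wrong-key presses are pooled into one error probability (only
pooled error percentages are typically reported); the ground-truth object
keeps them distinct.

## Filtering and coding rules

- Mean/distributional analyses keep correct go trials of the perspective
  agent only.
- Sequential analyses additionally drop the first trial of each block and
  any trial whose immediate predecessor — *by either member of the pair* —
  was an error. The pair-level reading is an assumption: the filter is
  defined on the pair's trial stream, and in a joint session an error by
  the co-agent plausibly disturbs the next trial just as one's own does.
- Trial-level correspondence is coded from the *required responder's* key
  side regardless of who (if anyone) responded, so the previous-trial
  correspondence factor is defined on no-go trials too; in individual
  sessions the no-go color is coded from the absent complementary role's
  side. Without this convention the 2×2 (previous × current) design would
  have empty cells.
- Participant exclusion uses Tukey fences ($Q3 + 1.5\,IQR$) on
  per-participant error counts, computed per condition by default (a
  pooled variant is available — summaries rarely state which was used),
  with quartiles by linear interpolation of order statistics
  (`quantile` type 7). Either member flagged in either condition excludes
  the whole pair. Exclusion applies the *upper* fence only: per-participant
  error counts at sub-1% error rates are small discrete numbers whose IQR
  can collapse to near zero, and a two-sided rule would then flag
  participants for making *too few* errors — high accuracy is not a defect.
  `tukey_error_outliers()` itself offers both sides.

## Aggregation conventions

All group tables use **two-stage averaging**: participant cell means
first, then an unweighted mean across participants. This matches the
ANOVA framework the tables accompany, makes cells insensitive to unequal
trial counts, and is asserted against brute-force recomputation in the
tests. Quartile bins are formed within participant × condition ×
correspondence (rank order, split into 4 equal-count bins, remainders to
the earliest bins); binning pooled across correspondence is available as
an option since table captions are often ambiguous on this point. Reported
tables round half-away-from-zero to integer ms; all computation is done in
double precision and rounding is applied only at the formatting stage.

## The instantaneous cross-correlation

The coordination measure needs a correlation that is resolved in *time*
(coordination can wax and wane within a session) and in *lag* (one agent
may track the other a few trials behind). The construction:

1. **Series.** Each agent's go-trial RTs in collection order; missed and
   incorrect responses are replaced by the mean of that participant's
   correct RTs in that condition, and that same mean is subtracted from
   every point. Imputed points therefore sit exactly at zero — they are
   neutral for covariance rather than outliers. Centering on the
   correct-trial mean (equivalent to the post-imputation series mean) is
   the default; the two candidate readings differ only through the
   imputed points and coincide when there are none.
2. **Smoothing.** All local moments are produced by a zero-phase
   first-order exponential filter: the recursion
   $y_t = \eta x_t + (1-\eta) y_{t-1}$ run forward and then backward. Its
   effective impulse response is the normalized two-sided exponential
   $(1-\eta)^{|k|}$, an effective window of roughly $2/\eta - 1 \approx 19$
   trials at the default $\eta = 0.1$. Each pass is initialized with the
   first value it sees, which equals constant extension beyond the edge;
   the tests pin these semantics with a closed-form weight-matrix oracle
   (exact) and an ideal-kernel comparison away from the edges.
3. **Local correlation.** For each lag $\delta \in [-9, +9]$ the five
   moment series $\langle x\rangle, \langle y\rangle, \langle x^2\rangle,
   \langle y^2\rangle, \langle xy\rangle$ of the lagged pair
   $(x_t, y_{t+\delta})$ are smoothed and combined into a local Pearson
   coefficient. Filtering the *moments* rather than a correlation series
   keeps every cell a genuine correlation bounded in $[-1, 1]$. Cells with
   an out-of-range partner index or a vanishing variance denominator
   (below $10^{-12}$) are invalid — there is no zero padding, which would
   manufacture spurious correlation at the edges.
4. **Index.** The coordination index is the fraction of valid
   (time × lag) cells with $r > 0.25$. The threshold is applied to signed
   $r$ (an `absolute` option exists); the proportion is taken over all
   valid cells rather than per-lag maxima, the most literal reading of
   "proportion of correlated activity". A per-lag summary remains
   available via the exported matrix.

The baseline is the *pseudo-pair*: the same two people, individually
measured in parallel, aligned by ordinal go-trial index — the only
alignment that yields equal-length series in both conditions. The ±9 lag
range is kept fixed as the default; where a proportional reduction rule
for shorter series would be needed, it must be supplied by the user, since
no canonical rule exists.

### What the generator does and does not establish

With coupling 0.8 at the default noise levels, the shared component
accounts for only ≈ 8% of RT variance, so simulated coordination indices
(≈ 7–8%) sit below empirically reported values (≈ 13–15%) and the
joint-vs-pseudo-pair gap is ≈ 0.7 percentage points. The acceptance suite
therefore aggregates 10-dyad experiments (the canonical sample unit)
across 100 seeds when testing discrimination. Passing these tests shows
that the pipeline *detects coupling when present and not otherwise*; it
does not show that real dyads couple through a single slow AR(1) channel,
nor calibrate the absolute index level of real data — real RT series have
heavier tails, drifts, and fatigue structure the generator deliberately
omits.

## Inference layer

Paired t-tests use the closed-form statistic with $d_z$ = mean difference
/ SD of differences and Bonferroni correction capped at 1; degenerate
inputs (zero-variance differences) are reported as $t = 0$ or $t = \pm\infty$
explicitly rather than erroring. The repeated-measures ANOVA is the
standard error-stratum decomposition (`stats::aov` with `Error(id/...)`)
plus partial eta squared within each term's own stratum; all design
factors here have 2 levels except the bin factor, for which a
Greenhouse–Geisser-corrected p is available on request (uncorrected df are
the default, matching common reporting practice).

The mixed-model comparison is fitted with `lme4` by **maximum
likelihood**, not REML: the two models differ in random structure, and an
LRT between REML fits with identical fixed effects but different random
terms is not generally valid. Model 1 is
`rt ~ condition * correspondence + (1 | participant)`; Model 2 adds
`(0 + coordination | pair)` — a pair-level random effect scaled by the
centered coordination covariate. "Coordination as a random effect" admits
more than one formalization; the scaled-slope structure is the default
because it uses the covariate's actual values, and a random intercept
grouped by covariate level is selectable. Centering matters: it makes a
constant covariate carry exactly zero information (variance 0, chi-square
0, reported without refitting) instead of aliasing a pair intercept. The
1-df chi-square for a variance component tested at its boundary is
conservative; the plain chi-square is reported as primary with the
boundary note attached. Non-convergence and singular fits are surfaced in
the result's status fields, never silently absorbed.

## Numerical and degenerate-input policy

- Local correlations are clipped to $[-1, 1]$ against floating-point
  overshoot; variances are floored at 0 before the square root.
- Series shorter than the lag span + 2 are rejected; unequal series are
  truncated to the shorter with a warning (a second warning if the
  mismatch exceeds 10%).
- Quartile binning requires at least 4 RTs per cell; empty table cells
  raise errors naming the participant and cell.
- Tukey fences require at least 4 participants (quartiles are unstable
  below that).
- All batch randomness flows from one root seed via child seeds drawn once
  (`sample.int` on the seeded root RNG), so every run is reproducible and
  pairs are mutually independent.

## Problem sizes used in validation

The shipped validation suite uses: 200 dyads for effect-parameter
recovery (recovering $\beta$ within ±2 ms and $\lambda$ within ±20%);
100 seeds × 10-dyad experiments for coordination discrimination at
coupling 0.8 and 0; 1000 replicates of 10-dyad null experiments for
type-I calibration of the correspondence test (5% ± 2%); and 100
simulated datasets for the model-comparison LRT, with the pair-level
perturbation set to 100 ms per unit covariate so that the random effect
to be detected is unambiguously present. These sizes were chosen so each
Monte-Carlo check has comfortable statistical margin relative to its
assertion.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(sim = design_preset("cooperative", seed = 7),
                  n_pairs = 10, out_dir = "out")
res <- run_pipeline(cfg)
res$effects$condition_means
res$coordination$joint_vs_pseudo
res$models
```

`run_pipeline()` executes exclusion → coding → filtering → tables →
coordination → tests → model comparison, writes every table as CSV plus a
versioned JSON summary, and is byte-identical on rerun with the same seed.
`simulate` output is valid `analyze` input (`read_trial_log()`) with no
manual edits.

## Known limitations

- The generator's error process is stationary, homogeneous across
  participants, and independent across trials; post-error slowing is not
  modeled. One visible consequence: real per-participant error counts are
  overdispersed (participants differ), which widens the Tukey fences,
  whereas homogeneous binomial counts concentrate tightly and the upper
  fence then flags small absolute deviations — simulated runs can exclude
  more pairs than comparable real datasets would.
- The coordination index inherits the threshold's arbitrariness
  ($r > 0.25$); it is kept as the field's convention, and sensitivity can
  be probed via `corr_config()`.
- The package does not fit distributional RT models (ex-Gaussian, delta
  plots) — bin means only — and performs no detrended-fluctuation or
  cross-recurrence analysis of RT series.
- Handedness/seating counterbalance, practice trials, and motivational
  constructs are out of scope for the generator.
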