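---
title: "Quantifying rhythm in behavioural display sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rhythm in behavioural display sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioiratio)
```

## The problem

Great apes and many other animals produce structured sequences of
vocalizations (pants, hoots, grunts, screams, barks) and movements (swaying,
stomping, drumming) during display behaviour. A music-derived toolkit makes
the timing of such sequences quantifiable: from the onset times
$o_1 < o_2 < \dots < o_n$ of the elements in one display sequence, the
inter-onset intervals are $t_k = o_{k+1} - o_k$, and each adjacent pair of
intervals is summarised by the interval ratio

$$r_k = \frac{t_k}{t_k + t_{k+1}} \in (0, 1).$$

Equal consecutive intervals give $r = 0.5$ — isochrony, the 1:1 rhythm.
Small-integer rhythm ratios (SIR) appear at $r = 1/4$ (1:3), $1/3$ (1:2),
$2/3$ (2:1) and $3/4$ (3:1). Ratios are unitless and scale-free: stretching a
whole sequence in time changes no $r_k$, which is what lets individuals with
different personal tempi be compared on the same footing.

Regularity of a sequence is measured by the coefficient of variation of its
intervals, corrected for small samples:

$$\widehat{\mathrm{CV}} = \Bigl(1 + \frac{1}{4n}\Bigr)\frac{s}{\bar t},$$

with $s$ the $n-1$-divisor standard deviation. Sequences here are short
(often fewer than ten intervals), which is why the correction factor
matters; a single-interval sequence has no defined CV and is excluded from
regularity analyses, with the exclusion logged.

`ioiratio` implements this pipeline end to end: annotation readers (Praat
TextGrid, BORIS-style event logs, a unified event CSV), interval and ratio
extraction, rhythm-category classification, a simulated uniform null with a
Kolmogorov–Smirnov comparison, a paired Wilcoxon on/off-integer battery,
and mixed models for regularity and isochrony rate. A synthetic-colony
generator with known ground truth makes every stage testable.

## Rhythm categories

Ratios are classified into alternating on-integer (rhythmic) and off-integer
(arrhythmic) bins. The on-integer centres are the exact fractions
$\{1/4, 1/3, 1/2, 2/3, 3/4\}$ (not their 3-decimal printed roundings); an
off-integer bin sits between each adjacent pair of on-bins, centred at their
midpoint. Bin edges fall midway between adjacent centres of the merged
centre list, and the outermost on-bins are made symmetric about their
centres. The default scheme therefore covers $[11/48, 37/48] \approx
[0.229, 0.771]$; the isochrony bin is $[11/24, 13/24)$, width $1/12$.

Because published descriptions of these category boundaries defer to
"pre-set" ranges without printing them, the scheme is fully configurable
(`rhythm_scheme()` accepts arbitrary centres), and the midpoint construction
is the package's reproducible default. Bins are half-open $[l, u)$ with the
final bin closed, so classification is deterministic at shared edges.
Ratios outside the outermost bins are labelled `"outside"`: they stay in the
KS comparison (which uses all ratios) but do not enter the binned on/off
comparisons.

Counts per bin are divided by bin width before any comparison
(`density_profile()`), because the construction makes bin widths unequal;
densities, not raw counts, are comparable across categories.

## The uniform null

Is an observed ratio distribution distinguishable from chance? The chance
reference is simulated: draw two interval durations independently and
uniformly between the minimum and maximum of the observed interval range,
form their ratio, and repeat (100 000 draws by default). The observed ratios
are then compared with this simulated sample by a two-sided asymptotic
two-sample Kolmogorov–Smirnov test (`ks_compare()`); the per-mode analyses
each build their own null from their own observed interval range.

Two properties of this null are worth keeping in view:

* It depends on the interval range only through the ratio min/max, and with
  a lower bound of zero it has the closed form
  $F(r) = r / (2(1-r))$ for $r \le 1/2$ (symmetric above). The package
  carries this oracle (`null_ratio_cdf()`, numeric integration for positive
  lower bounds) purely for validation of the simulator.
* It is *not* flat: ratios of two comparable random durations pile up near
  0.5, so the null density is unimodal at isochrony. Observed rhythmicity
  must therefore exceed what ratio arithmetic alone produces, which is
  exactly what the KS comparison measures — and it is also why uniform
  random intervals are not a true null for the binned on/off comparisons
  (see *Limitations*).

## Inference battery and mixed models

Per individual, the density of each on-integer category is compared with
its neighbouring off-integer counterpart(s) across individuals with paired
Wilcoxon signed-rank tests (`on_off_battery()`). Adjacent off-bins are
pooled by default (counts summed over summed widths) — pooling preserves
density conservation — with a `"mean"` option; the outermost categories
have only their single interior neighbour. Two further comparisons target
isochrony: 1:1 against the pooled density of all other in-scheme ratios,
and 1:1 against each adjacent on-integer category. The signed-rank p-values
are exact (from the signed-rank distribution) whenever the absolute
differences are tie-free; zero differences are dropped before ranking and
their count reported. All p-values of one battery form a single
Benjamini–Hochberg family at $\alpha = 0.05$; the model coefficient tables
form their own families. Published analyses do not state their correction
families, so the package fixes these two conservatively and records the
choice here.

Two mixed models assess what shapes rhythmicity (`fit_cv_lmm()`,
`fit_isochrony_glmm()`), with housing zoo, production mode and directedness
as fixed effects:

* a Gaussian LMM (REML) of per-sequence $\widehat{\mathrm{CV}}$ with a
  random intercept per individual; p-values use the Satterthwaite
  approximation, and the mechanism is recorded in the result;
* a binomial-logit GLMM of the per-ratio isochrony indicator (1 = ratio in
  the 1:1 bin) with random intercepts for individual and display. Modelling
  Bernoulli rows is likelihood-equivalent to aggregated binomial counts and
  attaches the display-level intercept to the right rows. Display ids are
  unique to one individual, so individual/display intercepts are nested by
  construction.

Singular or non-converged fits are flagged in the result object, never
silently accepted. Covariate screening follows AIC
(`compare_models_aic()`): an addition that fails to lower AIC is reported
as non-improving.

Inclusion filters precede all of this (`apply_inclusion_filters()`):
individuals need at least 50 ratios overall for the pooled analyses, at
least 25 in a mode for that mode's analyses, and — of the mode-included
individuals — at least 4 displays in the mode for the between-individual
tempo comparison, which otherwise rewards individuals who simply displayed
rarely.

## The synthetic colony generator

`simulate_colony()` draws a colony with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `n_zoos`, `groups_per_zoo` | 2, 2 | colony structure |
| `n_individuals` | 30 | displaying individuals |
| `displays_per_individual_mean` | 5 | Poisson mean, min 1 |
| `elements_per_sequence_mean` | 8 | Poisson mean, min 3 |
| `mode_mix` | (22, 59, 51)/132 | vocal-only / motoric-only / bimodal displays |
| `p_directed` | 0.4 | directed-display probability |
| `mean_vocal_s`, `mean_motoric_s` | 0.45, 0.9 | median IOI per mode (s) |
| `sd_log_tempo_individual` | 0.25 | between-individual tempo spread |
| `sigma_vocal`, `sigma_motoric` | 0.15, 0.08 | undirected log-IOI jitter |
| `directed_multiplier` | 1.6 | jitter scaling of directed displays |
| `p_sir_insertion` | 0.05 | doubling/halving of a local interval |

Intervals are generated as $t_k = \tau \exp(\varepsilon_k)$ with
$\varepsilon_k \sim N(0, \sigma(\text{mode}, \text{context}))$ and $\tau$
the display-level tempo (individual base tempo times a log-normal wobble,
`sd_log_tempo_display` 0.1). The jitter is multiplicative so intervals stay
positive and CV is scale-free. Directedness scales $\sigma$, not $\tau$:
"undirected displays are more isochronous" is the generative truth while
mean tempo stays context-free, which isolates the context effect for
recovery tests. SIR insertions double or halve one interval so genuine
1:2/2:1 ratios arise from a realisable onset sequence rather than being
sampled directly. Setting `arrhythmic_fraction` makes that share of
individuals draw iid uniform intervals on `arrhythmic_range_s` (default
0.3–1.5 s, spanning the vocal-to-motoric tempo range) — the chance regime.

The defaults emulate the observed study system: two colonies, about thirty
displaying individuals, on the order of 130 displays with more motoric than
vocal sequences, motoric sequences slower and tighter than vocal ones, and
directed displays noisier than undirected ones. The mode mix reproduces the
observed composition of 132 displays splitting into 73 vocal and 110
motoric sequences. Default tempi (0.45 s vocal, 0.9 s motoric) and jitters
were fixed once, as plausible magnitudes for call-sequence versus
whole-body-movement timing; they are study conditions, not tuning knobs.

What the generator does *not* emulate: annotation noise and the coarser
temporal precision of video (one frame, 0.04 s at 25 fps) versus audio
(1 ms); call-type-dependent interval structure within a sequence; social
interaction between displaying individuals; drift of tempo within one
display. Passing recovery tests on this generator therefore shows the
estimators work under a clean, known data-generating process — not that
real annotation pipelines are free of systematic timing error.

## Numerical and design choices

* Duplicate onsets within a sequence are merged to one event (first label
  kept) with a warning: a zero interval has no defined ratio or CV share.
* No maximum-gap rule splits sequences by default; none is part of the
  method. Sequence boundaries come from the annotation (display ids).
* Intervals and ratios are never computed across displays or modes; a
  bimodal display contributes two separate sequences.
* Seed management: one pipeline seed; each stochastic subset analysis
  (pooled / vocal / motoric null) derives a child seed deterministically
  from it, so any single number in a report is reproducible from the
  manifest alone.
* Exact signed-rank p-values switch to a tie-corrected normal approximation
  when absolute differences tie (flagged in the result); ties are common in
  count-derived densities only when individuals have identical bin counts,
  which is rare at realistic sample sizes.
* The test suite validates the heavy stochastic claims at fixed sizes:
  parameter recovery over 50 simulated colonies of 30 individuals with
  about 10 displays each, and the battery's chance-regime operating
  characteristics over 500 arrhythmic colonies. These sizes are the
  package's validation conditions and are stated in the tests themselves.

## Limitations

* Category boundaries are a reproducible reconstruction (midpoint rule),
  not a verbatim copy of any published boundary table; analyses sensitive
  to the exact edges should inject their own scheme.
* The asymptotic two-sample KS p-value is anti-conservative for very small
  observed samples; the package follows the published protocol and reports
  sample sizes so readers can judge.
* Because the uniform-IOI ratio density is peaked at 0.5, the binned
  on/off comparisons have non-zero expected differences even under
  uniform random intervals: the battery detects deviation from *local
  flatness*, not from the uniform-interval process. Conclusions about
  chance-level rhythm should rest on the KS comparison against the
  simulated null, with the battery characterising *where* in the ratio
  scale the structure lies.
* The LMM treats per-sequence CV values as exchangeable given the random
  intercept; sequences of very different lengths estimate CV with very
  different precision, and no length weighting is applied (matching the
  published analysis).

## A worked miniature

```{r example}
sim <- simulate_colony(simulation_config(), seed = 1)
report <- run_full_analysis(sim$observations,
                            pipeline_config(n_null_draws = 20000, seed = 1))
report
```

The KS statistics separate the simulated colonies' rhythmic structure from
their uniform nulls; the GLMM recovers a negative vocal (mode) coefficient
— vocal sequences, given their larger jitter, are less isochronous — and a
positive undirected (context) coefficient, the generative truth of the
simulator.
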