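# ioiratio

Rhythm analysis of annotated behavioural event sequences — chimpanzee-style
display behaviour in particular — using the music-derived inter-onset-interval
(IOI) ratio toolkit. The package is for behavioural researchers who have
time-aligned annotations of vocal or motoric event sequences (Praat
TextGrids, BORIS event logs, or a tidy event CSV) and want to quantify
whether, and where, those sequences are rhythmically structured.

## The method

For one display sequence with element onsets `o_1 < ... < o_n`:

* **Inter-onset intervals**: `t_k = o_{k+1} − o_k`.
* **Interval ratios**: `r_k = t_k / (t_k + t_{k+1})` in (0, 1). Equal
  consecutive intervals give `r = 0.500` (isochrony, 1:1); the
  small-integer rhythms 1:3, 1:2, 2:1, 3:1 sit at 0.250, 1/3, 2/3, 0.750.
* **Regularity**: the small-sample-corrected coefficient of variation
  `(1 + 1/(4n)) · s / mean(t)` per sequence; lower is more regular.
* **Rhythm categories**: ratios are binned into alternating on-integer
  (rhythmic) and off-integer (arrhythmic) bins around those centres; counts
  are divided by bin width so the unequal bins are comparable.
* **Chance reference**: a simulated uniform null — ratios of pairs of
  durations drawn uniformly from the observed interval range (100 000
  draws) — compared with the observed ratios by an asymptotic two-sample
  Kolmogorov–Smirnov test.
* **Inference**: paired exact Wilcoxon signed-rank tests of on- vs
  off-integer densities across individuals (Benjamini–Hochberg corrected);
  a linear mixed model of sequence CV and a binomial-logit mixed model of
  the per-ratio isochrony indicator, with zoo, production mode and display
  directedness as fixed effects and individual (and display) random
  intercepts.

A synthetic-colony generator (`simulate_colony()`) with known ground truth
drives validation: every estimator is tested against the generative
parameters it should recover. See the vignette
(`vignettes/rhythm-analysis-methods.Rmd`) for the full model description
and design rationale.

## Worked example

```r
library(ioiratio)

sim <- simulate_colony(simulation_config(), seed = 1)
report <- run_full_analysis(sim$observations, pipeline_config(seed = 1))
report
#> <rhythm_report>
#>   sequences: 161  ratios: 986
#>   included individuals (overall/vocal/motoric): 6/6/9
#>   KS vs uniform null:
#>     all      D = 0.256, p = 0
#>     vocal    D = 0.206, p = 3.8e-07
#>     motoric  D = 0.255, p = 0
#>   mixed-model terms:
#>     cv_lmm           (Intercept)        est =   0.199, se = 0.031, t =  6.468, p = 2.79e-08
#>     cv_lmm           zooB               est =   0.025, se = 0.036, t =  0.703, p = 0.485
#>     cv_lmm           modevocal          est =   0.088, se = 0.032, t =  2.744, p = 0.00817
#>     cv_lmm           contextundirected  est =  -0.062, se = 0.034, t = -1.821, p = 0.0741
#>     isochrony_glmm   (Intercept)        est =   0.464, se = 0.275, Z =  1.690, p = 0.091
#>     isochrony_glmm   zooB               est =  -0.330, se = 0.350, Z = -0.942, p = 0.346
#>     isochrony_glmm   modevocal          est =  -0.983, se = 0.232, Z = -4.238, p = 2.25e-05
#>     isochrony_glmm   contextundirected  est =   0.760, se = 0.308, Z =  2.465, p = 0.0137
```

Reading the output: each analysis subset (pooled, vocal, motoric) is
compared with a uniform null built on its own observed interval range — the
large `D` values with vanishing p say the simulated colonies' ratio
distributions are far from chance. In the mixed models, the negative
`modevocal` coefficient of the isochrony GLMM says vocal sequences have
lower odds of an isochronous ratio than motoric ones (the generator gives
vocal sequences larger timing jitter), and the positive
`contextundirected` coefficient says undirected displays are more
isochronous than directed ones — the generative truth of the simulator. The
CV model shows the same structure on the regularity scale (vocal sequences
have higher CV). `write_report(report, "results/")` writes every stage
table (intervals, ratios, density profiles, KS, Wilcoxon battery, model
terms, tempo summaries) as tidy CSV plus a JSON manifest that fully
reproduces the run.

A command-line front end with `simulate` and `all` subcommands lives at
`inst/scripts/ioiratio-pipeline.R`.

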