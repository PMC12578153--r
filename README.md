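# glenosim

Simulation of glenohumeral joint stability and compensatory scapulohumeral
muscle forces under rotator cuff tears of graded severity, during six
activities of daily living, with the repeated-measures statistics to analyze
the results. The package is aimed at shoulder biomechanists and
methods-minded clinicians who want a self-contained, fully scriptable
counterpart to commercial musculoskeletal pipelines for tear-scenario
studies — every stage, from synthetic motion capture to the final
significance bars, is open code on a single master seed.

## What it computes

At each 10° of arm elevation the muscle forces solve the classical static
optimization (muscle redundancy) problem

    minimize    Σᵢ (fᵢ / Fᵢᵐᵃˣ)³
    subject to  R f = M_net,   0 ≤ fᵢ ≤ Fᵢᵐᵃˣ,
                the JRF line passes through the glenoid ellipse

over a simplified eight-muscle shoulder model (SSP, ISP, SSC, Tm, AD, MD,
PD, LHB) with posture-dependent moment arms `R` and lines of action `U`.
The joint reaction force is `JRF = −(U f + F_ext)`, and joint stability is
scored from where its line crosses the 28 × 38 mm glenoid ellipse:

    stability = 1 − d_center / d_edge

with `d_edge` measured from the glenoid centre to the rim along the same
ray — 1 for a perfectly centred JRF, 0 on the rim, aborted beyond it. Tears
are reductions of maximum strength: eight scenarios from intact to a massive
three-muscle tear (`scenario_table()`), teres minor always spared.

A synthetic cohort module generates the study population (15 virtual
participants, mass 63.5 ± 7.1 kg, height 1.715 ± 0.063 m, 5 trials per
activity with smooth trial-to-trial kinematic noise, 100 Hz sampling, 6 Hz
zero-phase Butterworth filtering), and a statistics module reproduces the
standard battery: Shapiro–Wilk gated RM-ANOVA/Friedman per elevation bin,
paired t / Wilcoxon post hoc comparisons against the intact model with
Bonferroni correction, η²/Kendall's W effect sizes, and classification of
"compensatory" muscles from negative Δforce–Δstability correlations.

## Worked example

```r
library(glenosim)

g <- glenoid_ellipse()                 # default 28 x 38 mm glenoid
stability_index(c(0, 0), g)            # 1    (JRF through the centre)
stability_index(c(0, 19), g)           # 0    (on the superior rim)
stability_index(c(0, 9.5), g)          # 0.5  (half-way out)

cfg <- study_config(master_seed = 11, n_participants = 4, n_trials = 2,
                    activities = "Abduction",
                    scenarios = c("Intact", "S0", "S0/IS25"))
study <- simulate_study(cfg)
summary(study)
#> Synthetic tear-severity study (seed 11 )
#> cells: 288  infeasible: 0
#> mean stability by activity and scenario:
#>   activity Intact    S0 S0/IS25
#>  Abduction  0.369 0.261   0.107

analyze(study)
#> <glenosim_stats> 108 omnibus cells, 216 post hoc comparisons
#>   significant post hoc (Bonferroni p < 0.05): 162
#>   compensatory classifications: 6 (LHB, Tm)
```

The numbers read as follows: no simulation cell aborted (the JRF stayed
inside the glenoid in every scenario); mean stability falls from 0.37
(intact) to 0.11 as the tear grows from none to a severe
supraspinatus-plus-infraspinatus pattern; and the correlation stage flags
teres minor and the long head of biceps as compensatory — their forces rise
where stability falls. `plot(study)` draws the stability-versus-elevation
profiles per scenario. The full-scale study of the packaged defaults
(15 participants × 5 trials × 6 activities × 8 scenarios; 27,000 recruitment
solves) runs in a few minutes:

```r
out <- run_study(study_config(master_seed = 1), "study_out")
```

writing trial-level and participant-mean results CSVs, the three statistics
CSVs, a Markdown report of significant changes, and a JSON manifest. The
same can be driven from a shell via the thin CLI in `inst/cli/glenosim`
(subcommands `simulate`, `stats`, `report`, `make-fixtures`).

The methods vignette (`vignettes/glenosim-methods.Rmd`) documents the model,
its assumptions, every tunable parameter, and what the synthetic cohort does
and does not emulate.

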