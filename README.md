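# mslrt

Likelihood-ratio-test (LRT) methods for drug safety signal detection
from **multiple studies**.

Safety evidence about a drug is usually spread over several trials or
observational sources: each study reports event counts for one or more
rows (drug groups, or adverse-event terms) together with an exposure
denominator — person-time, subject counts, or raw report counts.
`mslrt` answers the question *"does any row have an elevated event rate,
taking all studies together?"* for biostatisticians and safety reviewers
doing pre- or post-market signal detection.

## The statistics

Within a study, row *i* (count *n<sub>i</sub>*, exposure
*P<sub>i</sub>*) is compared with the pooled complement of all other
rows under a Poisson rate model.  With *N* = Σ*n<sub>i</sub>*,
*P<sub>.</sub>* = Σ*P<sub>i</sub>* and expected count
*E<sub>i</sub> = P<sub>i</sub> N / P<sub>.</sub>*, the one-sided log
likelihood ratio is

```
logLR_i = n_i log(n_i / E_i) + (N − n_i) log((N − n_i)/(N − E_i)),   zeroed unless rate_i > rate_complement
```

and the study statistic is `MLLR = max_i logLR_i`.  Inference is Monte
Carlo: null tables are drawn from the multinomial conditional on the
observed total, giving an empirical 95% threshold and a rank-based
p-value.  Three combiners extend this to S studies:

| method | statistic | signal unit | level |
|---|---|---|---|
| `pooled_lrt` | MLLR of the summed table | row | can exceed nominal (documented) |
| `mmlr`       | `max_s MLLR_s`           | (row, study) | controlled |
| `wlrn`       | `max_i Σ_s w_s logLR_is / Σ_s w_s` (exposure weights) | row | controlled |

The traditional comparator — fixed-effect and DerSimonian–Laird
random-effects meta-analysis of per-study log relative risks — is
included (`study_effects`, `fixed_effect`, `random_effects_dl`), along
with a simulation harness for type-I error and power on conditioned
study grids (`scenario`, `estimate_type1`, `estimate_power`,
`estimate_meta_test`).

## Worked example

The package embeds a six-trial dataset comparing a composite
osteoporosis-related AE between patients on placebo plus concomitant
proton pump inhibitors (`PLandPPI`) and placebo alone (`PL`), with
person-day exposures (here the repeated-occurrences endpoint):

```r
library(mslrt)
ppi <- ppi_fixture("all_occurrences")
ppi[["s2"]]
#> Study table: s2  (2 rows, 246 events)
#>       row count exposure         rate
#>  PLandPPI    67   196698 0.0003406237
#>        PL   179  1575058 0.0001136466

wlrn(ppi, n_draws = 10000, seed = 42)
#> Multi-study LRT, method 'wlrn'  (10000 MC draws)
#>   statistic = 14.0249  (PLandPPI),  p = 0,  95% threshold = 1.2237
```

The weighted statistic 14.02 is the exposure-weighted average of the
six per-study log likelihood ratios for the `PLandPPI` row; a p-value
of 0 means the observed value exceeded all 10,000 null draws, so the
concomitant-PPI group is a clear signal.  The maximum-over-studies
method additionally locates the evidence, and its step-down reports
which studies carry it:

```r
global_step_down(mmlr(ppi, n_draws = 10000, seed = 42))
#>         row study       stat    p_value signal signal_rank
#> 1  PLandPPI    s2 24.2792666 0.00000000   TRUE           1
#> 2  PLandPPI    s5  4.8812951 0.01039896   TRUE           2
#> 3  PLandPPI    s4  4.6322236 0.01199880   TRUE           3
#> 4  PLandPPI    s6  3.9687854 0.02309769   TRUE           4
#> 5  PLandPPI    s3  1.1754740 0.64923508  FALSE          NA
#> ...
```

Four of the six studies independently cross the global threshold.  The
traditional meta-analysis of the same data agrees on direction:

```r
fixed_effect(study_effects(ppi))
#> fixed-effect meta-analysis of 6 studies
#>   rr = 2.432 (2.020, 2.929), tau2 = 0.0000, z = 9.379, p = 6.648e-21
```

a pooled relative risk of 2.43 (95% CI 2.02–2.93).

A thin command-line front end is included at `inst/cli/mslrt.R`
(`detect`, `meta`, `simulate` subcommands over long-format CSV/TSV
files; exit code 1 flags detected signals).

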