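---
title: "Likelihood ratio tests for safety signal detection across studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood ratio tests for safety signal detection across studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslrt)
```

## The problem

Safety reviews of a drug rarely rest on one study.  Event counts for a
drug group (or for many adverse-event terms) arrive from several trials
or observational sources, each with its own exposure denominator --
person-time, subject counts, or, in passive surveillance, raw report
counts.  The question is whether any row of the table (a drug among
drugs, or an AE among AEs) has an event *rate* elevated above the rate
of everything else, and whether the evidence holds up when the studies
are combined without ignoring that they differ in size, population and
design.

`mslrt` implements a family of likelihood-ratio tests for this problem:
the single-study ("regular") LRT with a Monte-Carlo empirical null, and
three multi-study combiners, alongside the traditional fixed/random
effects meta-analysis of log relative risks that practitioners would
otherwise use.

## The single-study statistic

Within one study, row $i$ has event count $n_i$ and exposure $P_i$;
write $n_. = \sum_i n_i$ and $P_. = \sum_i P_i$.  Events are modelled as
independent Poisson counts, $n_i \sim \mathrm{Pois}(p_i P_i)$ against
the pooled complement $n_. - n_i \sim \mathrm{Pois}(q_i (P_. - P_i))$.
The null is a common rate $p_i = q_i$; the alternative of interest is
one-sided, $p_i > q_i$.  With $E_i = P_i \, n_. / P_.$ the expected
count under the null, the per-row log likelihood ratio is

$$\log LR_i \;=\; n_i \log\frac{n_i}{E_i}
  \;+\; (n_. - n_i) \log\frac{n_. - n_i}{n_. - E_i},$$

taken as 0 whenever the row's observed rate does not exceed the
complement's rate (the one-sided indicator), with the convention
$0 \log 0 = 0$ so zero cells are harmless.  The study's test statistic
is the maximum over rows, `MLLR`.  Because the null distribution of a
maximum of correlated statistics is intractable, inference is by Monte
Carlo: conditional on the observed total $n_.$, null tables are drawn
from $\mathrm{Mult}(n_., (P_1/P_., \dots, P_I/P_.))$ and the empirical
distribution of their MLLR values supplies the 95% threshold and a
rank-based p-value.  In the report-counts dialect (no true exposure),
the marginal report counts stand in for $P_i$ and the same formulas
compare relative reporting rates instead of risks.

## Combining studies

Three combiners are provided, all sharing the Monte-Carlo machinery:

* **Pooled** (`pooled_lrt`): sum counts and exposures over studies and
  run the regular LRT on the collapsed table.  Its null is drawn from
  the *pooled* table, which ignores between-study structure; when the
  exposure composition differs across studies this null understates the
  variance of the pooled counts, and the test's type-I error can exceed
  the nominal level.  It is the naive baseline, kept because it is what
  pooling-minded analyses actually do.
* **MMLR** (`mmlr`): the maximum of the per-study MLLR values.  The
  detected signal is a (row, study) pair.  Its null regenerates *every*
  study from its own conditional multinomial per draw, so heterogeneity
  is respected and the level is controlled.
* **wLRn** (`wlrn`): for each row, a weighted average of its one-sided
  per-study log likelihood ratios,
  $wLR_i = \sum_s w_{is} \log LR_{is} / \sum_s w_{is}$, maximised over
  rows.  Studies where the row is not rate-elevated contribute zero.
  The null is the same per-study regeneration as for MMLR.

Secondary signals come from a step-down: rank all units by their
statistic and test each against the *same* null sample of the maximum,
stopping at the first non-significant unit.  Reusing the null of the
maximum makes the later tests conservative; halting at the first
failure is the cautious reading of a ranked procedure (testing past a
failure would invite cherry-picking further down the list).

### The weight in wLRn

The natural candidates for $w_{is}$ are the row's own exposure
$P_{is}$ and the study's total exposure $P_{.s}$.  The package default
is the **study total exposure**: on the bundled six-trial example this
choice reproduces the combined statistics that the per-study analyses
imply (2.81 for the first-occurrence endpoint, 14.02 for repeated
occurrences -- the package's test suite recomputes both from the raw
counts), whereas row-specific weights give 3.21 and 16.84.  Weighting a
study, rather than a row, also has a cleaner interpretation: it scales
each study's evidence by the information the study carries, and it
keeps the weights identical across rows so that rows compete on their
statistics alone.  `weight_mode = "row_exposure"` and custom per-study
weights (e.g. sample sizes) remain available.

## Ties, thresholds and discreteness

The statistics are functions of integer counts, so their Monte-Carlo
null distributions have atoms, and two conventions must be fixed.

* **Reported p-values** use the rank form
  $p = \#\{\text{null draws} > \text{observed}\} / (1 + M)$: the
  observed value ranks above draws equal to it.  An observed statistic
  beyond every draw gets exactly $p = 0$.
* **Simulation rejections** (`estimate_type1`, `estimate_power`) use
  the threshold form: a replicate rejects when its statistic strictly
  exceeds the empirical 95% point of the null sample.  At boundary
  atoms this is slightly more conservative than `p < alpha` under the
  tie convention above; the threshold form is the package's operative
  definition of the test.

Discreteness has a visible consequence: on grids where all rows of a
study share one exposure (the AE-by-study layout with subject-count
denominators), the study's MLLR is a function of the maximum cell count
alone and takes only a handful of values.  Rank p-values on such grids
are far from uniform -- no rank-based p-value can do better -- and
empirical thresholds can sit on large atoms.  The uniformity property
test therefore uses a heterogeneous-exposure table, where the statistic
is nearly continuous; achieved levels on equal-exposure grids remain
close to nominal but should be read with the atom structure in mind.

## The meta-analysis comparator

For two compared rows, each study contributes
$\log rr_s = \log\{(n_{1s}/P_{1s})/(n_{2s}/P_{2s})\}$ with the
person-time variance $1/n_{1s} + 1/n_{2s}$ and a 95% interval
$\exp(\log rr_s \pm 1.96 \sqrt{var_s})$.  Fixed-effect pooling is
inverse-variance; the random-effects model estimates the between-study
variance $\tau^2$ by the DerSimonian-Laird moment estimator truncated
at zero, the standard textbook default.  Studies with a zero count in
either row have an undefined variance and are excluded with a warning
(a 0.5 continuity correction is available as an option).  The Z test
rejects when the pooled log relative risk exceeds 1.96 standard errors.
The test suite cross-checks both models against an independent
meta-analysis package on the bundled data.

## The simulation harness

A `scenario` fixes the per-study totals $n_{.s}$ and exposures
$P_{is}$ of an observed grid and draws replicates per study from

$$ (n_{1s}, \dots, n_{Is}) \mid n_{.s} \sim
   \mathrm{Mult}\!\left(n_{.s},
   \frac{\eta_{is} P_{is}}{\sum_i \eta_{is} P_{is}}\right), $$

which is the common-rate null when all $\eta$ within a study are equal,
and plants a relative risk $\eta_{1s}$ on a row otherwise ($\eta$ may
vary by study).  Because every replicate conditions on the same
$(n_{.s}, P_{is})$, each method's Monte-Carlo null depends only on the
grid, so it is computed **once per scenario** (10,000 draws by default)
and shared by all replicates; this is what makes 10,000-replicate
studies desk-scale.  The conventional sizes are 10,000 replicates for
type-I error and 1,000 for power; the package's property tests scale
down to a few hundred replicates with 2,000-10,000 draw nulls, which is
enough to check level control bands and power orderings, while the
acceptance script runs the full-size estimates.  The zero-count rule
for the meta-analysis benchmark drops affected *studies* from a
replicate (not the replicate itself): on the smaller first-occurrence
grid roughly 40% of null replicates contain a zero-count study, so
skipping whole replicates would discard most of the sample.

## The synthetic AE grid

`lipiodol_like()` generates the shape of a one-drug, many-AE literature
review: 13 studies with subject counts drawn uniformly from 11-257 that
serve as the shared exposure of every row, 27 AE terms with baseline
frequencies from a skewed gamma draw (a few fever-like terms dominate,
many are rare), about 1.5 AE reports per subject, and single cells
capped at 128.  Optional $\eta$ multipliers plant elevated-risk terms.
It emulates the *shape* of such data -- enough to exercise wide tables,
shared denominators and planted signals -- but not its clinical
structure: no within-subject correlation between AE terms, no repeated
events per subject, no reporting or follow-up differences between
studies.  Passing tests on this grid show the machinery behaves on wide
equal-exposure tables, not that real reviews of this kind are free of
those complications.

## Degenerate inputs and numerical choices

* Single-row tables are accepted; their statistic is 0 and
  `regular_lrt` warns that no signal can be detected.
* A study with zero total events contributes all-zero null draws.
* $0 \log 0 = 0$ throughout; every statistic is finite on any valid
  table.
* The one-sided indicator zeroes a row's statistic rather than
  removing the row from the maximum, so the maximum is always defined
  and non-negative.
* Mixing denominator dialects (true exposure vs report counts) in one
  analysis is refused; relative risks and relative reporting rates are
  not comparable quantities.
* When a long-format file lacks the exposure column in the
  report-counts dialect, each row's denominator is filled with its
  marginal count summed over the studies in the file -- the only
  marginal computable from that schema.  Supplying true marginals
  explicitly is always preferred.

## Known limitations

The combiners assume the studies are independent and comparable in
denominator definition and population; they do not model missing or
delayed reporting.  Monte-Carlo p-values inherit the granularity of
$1/(1+M)$ and the atom structure of discrete statistics.  The pooled
method is included deliberately despite its inflated level; it should
be read as a descriptive summary, not a calibrated test.
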