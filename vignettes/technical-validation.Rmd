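---
title: "Technical validation of an array methylation assay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Technical validation of an array methylation assay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvalid)
```

## The problem

A clinical laboratory that measures genome-wide DNA methylation on a
bead-array platform and reports *aberrant methylation* — per-CpG levels
that fall outside a population-derived normal range — must characterize
the assay before using it diagnostically: how repeatable the calls are,
how little DNA it tolerates, whether contaminants corrupt it silently,
over which range the measured beta values respond linearly to truth, and
how well they agree with a gold standard. `methvalid` packages the
statistical machinery for each of those questions, together with a
synthetic-data generator so the whole pipeline can be exercised, tested
and demonstrated end-to-end without access to patient methylomes.

The measurement unit throughout is the beta value: the fraction of cells
in a sample methylated at a CpG, in $[0, 1]$, recovered from methylated
and unmethylated fluorescence intensities as $M / (M + U + 100)$.

## Reference intervals and aberrant calls

For each locus the normal range is the empirical 95% interval — the 2.5th
and 97.5th percentiles — of beta values in a reference population (156
samples by default), alongside the min, quartiles and max
(`build_reference()`). Quantiles interpolate linearly between order
statistics at position $(n-1)p$ (`stats::quantile` type 7); the
convention matters little at $n = 156$ but is fixed so results are
reproducible to the digit.

A sample's level at a locus is called aberrant when it is more than a
threshold $t$ (default 0.2) outside that interval: `hyper` when
$\beta > \text{upper} + t$, `hypo` when $\beta < \text{lower} - t$
(`call_sample()`). Inequalities are strict, so a value exactly at the
boundary is normal — the conservative reading. Values below the
reportable-range floor $R_\text{low}$ cannot be quantified, only bounded
above; we therefore compare them worst-case: a hypo call requires
$\max(\beta, R_\text{low}) < \text{lower} - t$, i.e. the entire interval
$[0, R_\text{low}]$ must sit below the call threshold. Whether a
sub-reportable value can ever support a hypo call was genuinely open; the
worst-case bound is the resolution implemented here, and since reference
intervals at hypomethylated loci hug zero it is almost never exercised.

Each locus is also classified by *detectability*
(`classify_detectability()`): hypermethylation is detectable only when
$\text{upper} + t < 1$ leaves room for a call, hypomethylation only when
$\text{lower} - t$ stays above $\max(0, R_\text{low})$. With tight
unimodal reference distributions almost every locus is detectable, nearly
always in exactly one direction.

## Precision

With $n_j$ technical replicates of sample $j$ and $x_{ijt}$ of them
called aberrant at CpG $i$ under threshold $t$, the per-locus call
similarity is

$$S_{ijt} = \max(x_{ijt},\; n_j - x_{ijt}) / n_j,$$

ranging from 1 (unanimous) to 0.5 (the threshold bisects the calls), and
the per-sample summary is the average over all $m$ evaluated loci,
$S_{jt} = \sum_i S_{ijt} / m$ — the empirical probability that one more
replicate would agree with the existing calls at a random CpG
(`locus_similarity()`, `sample_similarity()`, `threshold_sweep()`). Loci
never aberrant in any replicate contribute $S = 1$ and are deliberately
kept in $m$.

Dissimilarity between two replicates is the cardinality of the symmetric
difference of their aberrant-locus sets (`call_set_difference()`), over
loci and ignoring direction — a hyper call in one replicate and hypo in
the other is a disagreement about direction, not about aberrance, and
counts as zero. This makes the statistic a metric on call sets, which the
test suite checks as a property.

Proficiency testing (`pt_evaluate()`) re-runs known samples and allows
each new replicate $\lfloor m \cdot r \cdot (1 + s) \rfloor$ differences,
where $r$ is the established per-call inconsistency rate (0.003 at the
default operating point) and $s$ a 20% slack; the run passes when at
least 80% of replicates pass. Two choices were open: the allowance is
floored rather than rounded (conservative), and each replicate's
statistic is the *median* of its pairwise differences against all prior
replicates — robust to a single bad prior, whereas comparison against one
fixed baseline would silently inherit that baseline's defects.

## Sensitivity and specificity QC

Detection p-values follow an explicit normal-background model: background
control probes carry channel intensities $\sim N(\mu, \sigma^2)$;
$(\hat\mu, \hat\sigma)$ are estimated from the pooled control channels;
and a probe's total signal under the background-only null is the sum of
two background draws, giving

$$p = 1 - \Phi\!\left(\frac{M + U - 2\hat\mu}{\sqrt{2}\,\hat\sigma}\right).$$

A probe fails at $p > 0.01$ and a sample fails with more than 5% failed
probes (strict inequalities at both cut-offs, so boundary values pass).
On pure background the p-values are uniform, which the suite verifies
with a Kolmogorov–Smirnov test.

Contamination that depresses *all* intensities — background controls
included — escapes this check, so a second statistic summarizes overall
sample intensity:

$$MU_j = \log_2 \sqrt{M_j \times U_j},$$

the log-geometric mean of the median methylated and unmethylated probe
intensities (medians over non-control probes only). Samples whose
aberrant-call counts fall outside the 99% normal range of uncontaminated
replicates (normal approximation $\bar{x} \pm z_{0.995}\,s$, floored at
0 — with a handful of replicates empirical 0.5/99.5 percentiles are
meaningless) are labelled failed, and the MU failure threshold is the
one-dimensional max-margin separator between failed and passed groups:
the midpoint between the largest failed and smallest passed $MU$
(`learn_mu_threshold()`). Non-separable groups raise an error rather than
returning a best-effort cut.

## Reportable range and accuracy

Against per-site whole-genome bisulfite sequencing (WGBS) levels $y_i$,
array levels $x_i$ are modelled as $y_i = a + b x_i + e$ by ordinary
least squares (`fit_reportable_range()`). The reportable range is where
the fit stays inside $[0,1]$:

$$R_\text{low} = \max(0, -a/b), \qquad R_\text{high} = \min(1, (1-a)/b),$$

and the laboratory-wide range is the largest interval common to all
samples: max of the lower cut-offs, min of the upper
(`aggregate_reportable_range()`). Sites enter the comparison only with
WGBS coverage in $[30, 100]$ inclusive — below 30 reads the level is too
discretized (3 reads can only report 0, 1/3, 2/3, 1), above 100 reads
technical artifacts become likely. The bounds are taken inclusive; the
alternative strict reading shifts results by a negligible sliver of the
coverage distribution. Accuracy is the Pearson product-moment correlation
of the filtered pairs (`accuracy_correlation()`).

The default fit is a single OLS pass. An optional iterative mode refits
restricted to $x \in [R_\text{low}, R_\text{high}]$ until the cut-offs
move by less than $10^{-4}$, for data whose tails bend away from the
straight line; on data that is linear throughout, both modes coincide, so
single-pass is the default.

## What the synthetic data emulates

`sim_config()` fixes the study conditions; all generators are
deterministic given its `seed`.

* **Reference population** (`gen_reference_population()`): each locus
  draws its mean near a hypomethylated mode (0.04) or hypermethylated
  mode (0.95), with between-sample SD 0.022 — putting the mode of the
  per-locus IQR distribution at $1.349 \times 0.022 \approx 0.03$. A 6%
  fraction of loci get intermediate means (uniform in $[0.35, 0.65]$),
  the loci where both call directions remain detectable, and 0.3% get an
  inflated SD of 0.25, whose reference ranges are too wide for any call —
  so that roughly 99.7% of loci are detectable and about 94% of those in
  one direction only. Values are Gaussian around the locus mean,
  truncated to $[0, 1]$; truncation (rather than a logit-normal) is the
  simplest model matching tight unimodal intervals, at the cost of small
  probability atoms at the boundaries.
* **Technical replicates** (`gen_technical_replicates()`): truth plus
  additive noise (SD 0.01), with a 5.6% chance per replicate of being an
  outlier at SD 0.06 — emulating the occasional noisy replicate a
  long-running assay encounters. At these settings the mean $S_{jt}$ at
  $t = 0.2$ sits at the intended operating point, $\ge 0.997$.
* **Paired WGBS/array** (`gen_paired_wgbs_array()`): WGBS levels are
  binomial at coverage $\sim \text{round } N(45, 20^2)$ clipped to
  $\ge 1$; array levels are $0.052 + 0.948 \times \text{truth}$ plus
  noise (SD 0.01), so the regression of WGBS on array recovers a
  reportable range of $[0.052, 1]$ by construction — a known truth the
  acceptance suite demands back within $\pm 0.01$.
* **Intensities** (`gen_intensities()`): per-probe total signal is
  normal with mean
  $15000 \times \text{concentration} \times (1 - 1.9 \times \text{contamination})$
  and CV 0.1, split between channels by the truth level, plus
  per-channel background $N(200, 20^2)$; background controls carry pure
  background. The signal mean places the detection-p failure boundary of
  the dilution series between 0.05 and 0.1 ng/µl (so the conservative
  concentration threshold lands at 0.5 ng/µl), and the decay rate makes
  only the 50% contamination level produce mass aberrant calls and a
  collapsed $MU$. The CV was set by a margin analysis of the
  intensity-to-beta map: at 0.1, intermediate contamination levels stay
  several standard deviations away from every call threshold, so the
  count-based failure labelling and the MU separator behave identically
  for every seed, while 50% contamination still yields hundreds of calls.

Features of real arrays deliberately *not* modelled: probe chemistry
(type I/II) and between-probe affinity differences, chip-position and
run batch effects (the validation design stratifies them away
physically, not computationally), bacterial cross-hybridization (the
contamination failure mode is intensity loss), and genome coordinates
beyond a nominal spacing. Passing tests on this generator demonstrate
that the statistics and decision rules are implemented correctly and
behave sensibly under realistic magnitudes — not that a particular real
laboratory will reproduce any specific number.

## The orchestrated run

`run_validation()` executes the stages in dependency order — reference
population → reportable range (which supplies $R_\text{low}$) →
detectability → aberrant calls → precision and QC → accuracy — on sizes
chosen to keep a full run in a few seconds: 6,690 loci, 156 reference
samples, 8 paired WGBS/array samples, 6 precision samples × 6
replicates, a 6-sample × 8-concentration dilution series and an
8-sample × 6-level contamination series. The sensitivity threshold rule
picks the smallest concentration at which it and every higher level show
zero failed samples, then steps one grid level up as a safety margin —
mirroring how a laboratory would prefer a conservative operating limit
over the bare empirical boundary — and converts it to DNA mass and
minimum cell counts via `sensitivity_arithmetic()`.

```{r, eval = FALSE}
report <- run_validation(sim_config(seed = 1))
report
write_validation_report(report, "validation.json")
```

Reports serialize to JSON with full numeric precision and no timestamps;
a write–read–write cycle is byte-identical, which is how the test suite
operationalizes lossless serialization.

## Numerical choices and degenerate inputs

* Missing beta values are `NA` end-to-end and mean *excluded*, never
  zero: reference statistics use available-case $n$ per locus (loci with
  fewer than 2 values are emitted flagged), calls at missing loci are
  `not_evaluable`, and per-locus similarity uses the evaluable replicate
  count.
* Ties and boundaries: every pass/fail comparison in the QC rules is
  strict in the direction quoted above; `locus_similarity` is symmetric
  in $x \mapsto n - x$ by construction.
* Degenerate inputs fail loudly: zero-variance background controls,
  empty matrices, non-positive fitted slopes, non-overlapping per-sample
  ranges, non-separable MU groups, and a contamination decay
  $\gamma \cdot c \ge 1$ are all explicit errors, not warnings.
* Beta values are written with 15 significant digits; round-trips through
  the TSV formats reproduce doubles to within one ulp.

## Known limitations

The generator's truncated-Gaussian populations place small atoms at 0
and 1 that a logit-normal model would avoid; per-locus unimodality holds
in the interior but a density estimate will show the boundary atom at
heavily clipped loci. The MU statistic's median over a strongly bimodal
intensity mix is noisier than on real arrays, where probe-level affinity
variation fills the intensity range. And the specificity experiment's
clean replicates produce aberrant-call counts at or near zero, making
the 99% normal range much tighter than a real laboratory would observe;
the decision rules are exercised all the same, but the learned MU
threshold, like every learned threshold here, is a property of the data
that trained it.
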