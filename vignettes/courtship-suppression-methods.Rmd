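---
title: "Methods: courtship-suppression statistics and DE set concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: courtship-suppression statistics and DE set concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtsupp)
```

## The assay and its statistics

In the conditioned courtship suppression paradigm, a *Drosophila* male that
has been rejected by a mated female reduces his subsequent courtship; the
size of that reduction indexes learning and memory. The primary measurement
is the **courtship index** (CI): the percentage of a fixed observation
window (300 s by default) the male spends courting. From two independent
cohorts of the same strain — naive males and trained (rejected) males — the
**learning index** is

$$\mathrm{LI} = \left(1 - \frac{\overline{CI}_{tr}}{\overline{CI}_{na}}\right) \times 100,$$

computed from the *sample means*, not per-male ratios, because the naive and
trained males are different animals. LI is 0 when training has no effect,
100 at complete suppression, can be negative, and is undefined when naive
males did not court at all (`learning_index()` raises an explicit error in
that case rather than returning an arbitrary value).

### Bout handling

CIs are computed from scored bout intervals. Overlapping bouts are merged as
an interval union, never summed — summation would allow CI > 100 whenever a
scorer logs nested or overlapping events. Bouts extending past the window
are clipped with a warning (not an error: trailing bouts are a normal
scoring artefact), and a male present in the file with no bout rows gets
CI = 0, which is deliberately distinct from a male absent from the file.
Times are seconds stored as doubles; interval comparisons use an absolute
tolerance of 1e-9 s.

## Randomization inference

All behavioural comparisons use two-sided randomization tests that estimate
$\alpha_R$, the probability of rejecting the null hypothesis, directly from
the permutation distribution. With $m$ sampled permutations (default
10,000) and $b$ permuted statistics at least as extreme as the observed one,

$$\alpha_R = \frac{b + 1}{m + 1},$$

which can never be zero and keeps the sampled test valid; ties
($|T_{perm}| = |T_{obs}|$ within 1e-12) count as extreme. When the number of
distinct label assignments is small (at most 10,000 by default),
`randomization_two_sample()` switches to full enumeration and reports the
exact tail proportion instead; `exact_randomization()` exposes the
enumerated version directly (up to 200,000 assignments) and is the internal
oracle the sampled mode converges to.

Three contrast families share this machinery:

1. **Within strain** (`randomization_two_sample`): trained vs naive CIs,
   statistic $T = \bar{x} - \bar{y}$ — the classical difference-of-means
   randomization statistic. This answers "did the strain learn?".
2. **Between strains** (`randomization_li_contrast`): $T = LI_A - LI_B$ at
   a common time point. The null permutation is *stratified*: strain labels
   are shuffled among the naive males and, independently, among the trained
   males. Training status is never exchanged, because naive and trained
   cohorts are independent samples and only the strain label is exchangeable
   under the null. The permutation is at the level of individual males (not
   whole samples); this is the package's declared choice where the
   male-level vs sample-level question is genuinely open, because male-level
   exchange is the finer and more conservative exchangeability assumption
   and gives the test a non-trivial null distribution at realistic cohort
   sizes.
3. **Retention** (`retention_contrast`): $T = LI_{delayed} - LI_{immediate}$
   within one strain — identical machinery with the occasion label permuted
   within the training-status strata. This answers "did memory persist?".

A permutation that hands all zero-courtship naive males to one side makes
that LI undefined; such permutations are redrawn and counted, with a warning
if more than 1% of draws had to be redrawn (a sign the data barely support
the contrast). The statistic choice itself ($T$ as the difference of the
quantity the figures display) is a design decision: the randomization
framework is agnostic, and the difference of means / of LIs is the quantity
of scientific interest.

No multiplicity correction is applied across the behavioural contrasts —
each $\alpha_R$ is reported per contrast, matching how such experiments are
conventionally reported. `li_timecourse()` assembles the full strain ×
time-point table, attaches flags (one symbol per control strain when LI is
significantly *below* that control; `#` when the delayed LI is significantly
below the strain's own baseline), and reports rows whose cohorts are missing
or too small as `not_testable` rather than failing.

Every test records its seed; per-test child seeds inside `li_timecourse()`
are drawn from a seeded pool so the whole table is bit-reproducible.

## Olfactory preference

The T-maze preference index is $V(\%) = 100 \cdot N_{odor} / N_{total}$ per
replicate; the replicate (one run of ~15 males), not the fly, is the unit of
analysis. Genotypes are compared with the control by the Mann–Whitney test:
`mwu_test()` computes $U$ as the number of pairs with $x_i > y_j$ plus half
the tied pairs, uses the exact null distribution when the samples are
tie-free and small enough (at most 20,000 arrangements by default), and the
normal approximation with midrank tie correction and continuity correction
otherwise. Exact mode refuses tied data and falls back with a message. The
nonparametric test is applied unconditionally — no normality pre-test gates
it, since percentage-bounded counts of this kind are generically non-normal
and a data-dependent test switch complicates the error rate for no benefit.

## DE set concordance and enrichment

The transcriptomic stage consumes per-contrast DE result tables (gene,
log2FC, raw p, BH FDR) produced upstream; it does not refit expression
models. "A similar pattern of expression change" across replicate deletion
strains is operationalized as **strict concordance**: significant
(FDR < 0.05) in *every* replicate table with the same fold-change sign. A
**lenient** mode (significant in at least one, sign-concordant in all) is
provided because the strict reading is not the only defensible one; strict
is the default. Genes absent from any table are treated as not significant
there and logged.

`venn_partition()` splits 1–4 named sets into their disjoint membership
regions; counts always sum to the union and marginalize back to per-set
cardinalities (both are tested properties).

`fisher_enrichment()` scores each annotation term by the one-sided Fisher
exact probability of the 2×2 table, i.e. the hypergeometric upper tail
$P(X \ge k)$ with $k$ study genes among the $K$ term genes, study size $n$,
universe $N$, BH-adjusted across terms. The universe defaults to the genes
present in the DE table (the expressed-gene background) rather than the
whole annotation — the standard choice, since unexpressed genes were never
candidates. Enrichment with down- and up-regulated study sets run separately
gives the two-directional display; the annotation is flat (no
ontology-graph propagation — term lists are consumed as given). Each row
carries the dot-plot metrics: mean logFC over the term's significant genes
(omitted when there are none) and the proportion of the term's genes
altered.

qPCR validation fold changes use the standard
$2^{-\Delta\Delta C_t}$ computation, invariant under global Ct shifts.

## The synthetic generator

The generator exists so every stage is testable without the study's
external sequencing data; its defaults *are* the study conditions and are
not tuned per run.

* **Courtship**: per-male courtship propensity is
  $\mathrm{Beta}(\mu c, (1-\mu)c)$ — bounded on [0, 1] with one
  concentration parameter $c$ controlling between-male spread. $\mu$ is the
  strain's naive mean (default 50%, a typical naive CI in this assay, with
  $c = 10$ giving an SD of ~15 percentage points); trained males have
  $\mu$ multiplied by the time point's **suppression multiplier** $m$, so
  the expected LI is $100(1 - m)$. The default effect multiplier is 0.33
  (expected LI ≈ 67, a normal-learner magnitude comfortably detectable at
  n = 20). Bouts are laid down as an alternating exponential on/off renewal
  process (mean bout 5 s) rescaled to cover exactly the drawn fraction of
  the window — the simplest process consistent with interval data; as a
  consequence the analysis-side CI recovers the drawn propensity exactly,
  which the tests exploit.
* **Profiles**: `control` ($m = 0.33$ at days 0/2/8), `cbs_like`
  ($m = 1$ everywhere: no learning at any time point), `cse_like`
  ($m = 0.33$ at days 0 and 2, $m = 1$ at day 8: learning and 2-day
  retention intact, retention lost by day 8). Cohort size defaults to 20
  males, the study design. The short-term (minutes-scale) layout is
  supported as data; the built-in fixture uses the day-scale retention
  design, which exercises all three contrast families.
* **Olfactory**: $N_{odor} \sim \mathrm{Binomial}(15, p)$ per replicate,
  31 replicates, $p = 0.2$ for every genotype (strong repulsion retained by
  all strains — the negative-control structure the assay is meant to
  confirm).
* **DE tables**: 8,000 genes; null genes draw $logFC \sim N(0, se)$ with
  $se = 0.25$ and Wald p-values $2\Phi(-|logFC|/se)$, making null p-values
  exactly uniform; planted genes (drawn from designated annotation terms
  with probability 0.8, plus optional extras) draw $|logFC|$ around 2 with
  a per-gene sign held concordant across contrasts, a configurable fraction
  down-regulated (0.85 in the built-in fixture, mirroring the predominance
  of down-regulation in the deletion strains). FDR is BH within each table.

What the generator does **not** emulate: real bout autocorrelation and
diurnal structure, male-to-male variance heterogeneity beyond the Beta
family, inter-replicate overdispersion in the T-maze (true binomial
sampling only), correlated genes and logFC-dependent variance in DE tables.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the declared model, not that the model captures
every feature of real behavioural or expression data.

## Numerical and design choices

* Sampled $\alpha_R$ uses $(b+1)/(m+1)$; exhaustive mode reports the exact
  proportion; both count ties as extreme at tolerance 1e-12.
* `exhaustive_threshold` 10,000 (auto-enumeration), enumeration hard limit
  200,000 assignments; Mann–Whitney exact limit 20,000 arrangements.
* Degenerate inputs: empty bout sets are valid (CI 0); zero naive means
  raise errors at the point of definition; permutations that create them
  are redrawn and logged; groups that cannot be tested yield
  `not_testable` rows, not failures.
* Determinism: every stochastic entry point takes a seed, results record
  it, and the pipeline drivers derive child seeds from one master seed;
  rerunning any driver with the same configuration and seed reproduces its
  output files byte for byte.
* Problem sizes used by the test-suite calibration runs: the type-I check
  uses 1,000 simulated null experiments at 2,000 permutations each, and
  the power/phenotype checks use 200 runs at 1,000 permutations — sizes at
  which the smallest attainable p-value (1/2001 resp. 1/1001) is far below
  the 0.05 decision level, so the scaled-down permutation count does not
  affect the decisions being counted.

## Known limitations

* The LI contrast permutes male-level labels; if the original analyses
  permuted at a different level, exact $\alpha_R$ values may differ even
  though the test logic coincides.
* Exact Mann–Whitney mode declines tied data entirely instead of
  enumerating the conditional permutation distribution of midranks.
* The enrichment module treats annotation terms as independent flat sets;
  hierarchically related terms will co-fire.
* The generator's renewal bout process makes CI recover the drawn
  propensity exactly; real scoring noise would add measurement error the
  pipeline currently sees only through the Beta spread.
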