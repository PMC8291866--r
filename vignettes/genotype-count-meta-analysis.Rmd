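---
title: "Meta-analysis of case-control genotype counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of case-control genotype counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmeta)
```

## The problem

A case-control association study of a biallelic SNP is summarized by six
integers: the genotype counts MM, MW, WW in cases and in controls, where M
denotes the effect allele. A meta-analysis of such studies must (i) reduce
each study to a 2×2 exposure table under a chosen genetic model, (ii)
estimate a per-study odds ratio and its uncertainty, (iii) combine the
studies under a fixed- or random-effects assumption, and (iv) probe the
robustness of the pooled estimate. `gcmeta` implements this pipeline for
the five standard genetic models and demonstrates it on the packaged
CDKN2B-AS1 (9p21.3) coronary heart disease panel: 33 studies of rs1333049
(effect allele C) and 17 of rs4977574 (effect allele G).

## Per-study effects

For a table with cells a (exposed cases), b (unexposed cases), c (exposed
controls), d (unexposed controls), the estimate is the cross-product odds
ratio with the Woolf standard error on the log scale,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  se(\log \widehat{OR}) = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},$$

and a 95% Wald interval $\exp(\log\widehat{OR} \pm 1.959964\,se)$. The
allelic model counts alleles (2n per arm); the four genotype models count
persons, because their definitions compare genotype groups. The
heterozygous and homozygous contrasts exclude the third genotype class, so
their tables do not sum to the person total — this is by construction, not
an error.

Zero cells receive the Haldane–Anscombe correction: 0.5 added to all four
cells, flagged in the output. A table with an entire margin equal to zero
carries no information about the contrast; such records are dropped from
that contrast with a warning naming them. The packaged panel has no zero
cells at all (minimum cell count 4), so the correction is a robustness
feature exercised only by synthetic inputs.

## Heterogeneity and pooling

With inverse-variance weights $w_i = 1/se_i^2$ and the fixed-effect mean
$\hat\theta = \sum w_i \theta_i / \sum w_i$, Cochran's
$Q = \sum w_i (\theta_i - \hat\theta)^2$ is referred to $\chi^2_{k-1}$;
$I^2 = \max(0, (Q - df)/Q)$ and the DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right).$$

`pool_auto()` applies the selection rule of the source analysis: when the
Q-test P value is below `alpha_het` (default 0.05, as stated there; many
meta-analyses use 0.10 — it is configurable), the DerSimonian–Laird
random-effects model is used, with weights $1/(se_i^2 + \hat\tau^2)$;
otherwise a fixed-effects model. The fixed-effects estimator is
Mantel–Haenszel by default — the conventional choice for sparse count
data and the default of the major meta-analysis software for binary
outcomes — with the Robins–Breslow–Greenland variance for its log;
inverse-variance pooling is selectable, and the test suite verifies the
two agree within 2% relative on every contrast of the packaged panel, so
the choice is immaterial for this reproduction. With $\hat\tau^2 = 0$ the
random-effects pool collapses to inverse-variance fixed effects to
machine precision, which the tests assert.

Association P values are two-sided normal tests of the pooled log OR.
Single-study strata (the African stratum of the rs1333049 panel) are
reported with the study's own Wald estimate and flagged
`single_study` rather than dropped.

## Hardy–Weinberg screening

Control-arm genotype frequencies are screened against Hardy–Weinberg
proportions as a genotyping-quality check. Two tests are provided: the
1-df chi-square goodness-of-fit against expected counts
$(\hat p^2 n,\; 2\hat p\hat q n,\; \hat q^2 n)$ with no continuity
correction, and the exact conditional test that enumerates all
heterozygote counts compatible with the observed allele counts and sums
the probabilities no larger than that of the observed configuration.

The chi-square version is the default because it is the test the packaged
table's printed HWE column actually tracks: 46 of its 47 numeric entries
reproduce to printed precision under the chi-square (and the spot-check
rows 0.595 and 0.917 exactly), while the exact test gives visibly
different mid-range values (e.g. 0.747 where 0.595 is printed). Which
software produced the remaining printed entry (0.810; we compute 0.800 by
chi-square, 0.806 exact) cannot be determined from the counts. The two
tests differ by up to 0.08 on the panel's mid-p rows — discreteness of
the exact null — so agreement between them should not be over-asserted.

Studies failing the control-arm screen are *retained* in all pools by
default, because the published study counts (33 and 17) include them;
`exclude_hwe_violations = TRUE` re-pools without them.

## Stratification, sensitivity, publication bias

`stratify()` partitions by ethnicity (West Asian, East Asian, Caucasian,
African), control source (hospital-based, population-based, and the
literal stratum "NA" for studies that state no source — a real category
here, deliberately not parsed as missing), or phenotype (CAD vs MI), and
pools each stratum with the same selection rule. `leave_one_out()`
re-pools k times with one study omitted and reports whether statistical
significance (95% CI excluding 1) ever flips relative to the full pool.

`begg_test()` is the Begg–Mazumdar rank correlation between
variance-stabilized deviations
$t_i = (\theta_i - \hat\theta)/\sqrt{v_i - 1/\sum v_j^{-1}}$ and the
variances $v_i$: the Kendall score over all pairs (ties contribute zero)
is referred to the normal approximation with variance $k(k-1)(2k+5)/18$
and continuity correction $|S|-1$. The allele contrast feeds the default
funnel/bias outputs, as the natural primary contrast; any model's effects
can be passed instead. `funnel_data()` emits plot-ready coordinates with
the pooled center line and $\pm 1.96\,se$ pseudo-confidence guides;
no figures are rendered by the package.

## The synthetic-data generator

`sim_scenario()`/`simulate_set()` generate study sets with the structure
the pipeline assumes. Controls draw genotypes multinomially from
Hardy–Weinberg proportions at effect-allele frequency `maf_control`,
optionally distorted by an inbreeding-type coefficient `hwe_fis` (F > 0:
heterozygote deficit). Each study draws a true log OR from
$N(\log or_{allelic}, \tau^2)$, and case genotype probabilities follow
the multiplicative per-allele odds model: control probabilities tilted by
$e^{g\theta}$ for $g \in \{2,1,0\}$ effect-allele copies, renormalized —
so the allelic-contrast OR targets `or_allelic` and the genotype-contrast
ORs follow analytically ($e^{2\theta}$ homozygous, $e^{\theta}$
heterozygous). Sampling is count-conditioned (fixed n per arm), matching
case-control ascertainment. A single integer seed determines the whole
set; per-study substreams are derived by indexed offsets so any study can
be regenerated alone.

Defaults mirror the observed conditions of the rs1333049 panel: k = 33,
control effect-allele frequency 0.49, allelic OR 1.13, between-study
variance 0.03 (the DL estimate on the panel's allele contrast recomputes
to 0.033), arm sizes spanning the observed 50–2950 range, and strata
labels drawn with the observed row proportions.

What the generator does *not* emulate: genotyping error and differential
misclassification, covariate structure (age, sex, smoking — the source
analysis itself is unadjusted), linkage disequilibrium between the two
variants, and any publication-suppression mechanism. Passing calibration
tests therefore demonstrates statistical correctness of the pipeline
under its own model, not robustness to those real-data features.

## Numerical and design choices

- CI level fixed at 95% (z = 1.959964); the source reports nothing else.
- $I^2$ is reported on the 0–100 scale; $Q = 0$ gives $I^2 = 0$.
- Exact-test tie handling: probabilities within a relative $10^{-7}$ of
  the observed configuration's count as "as extreme", guarding against
  floating-point ties in the enumeration.
- The allelic contrast is pooled on allele counts (2n per study), the
  reading supported by the "C-allele versus G-allele" definition; the
  published table reproduces within ±0.02 under this choice, so no
  person-level approximation is entertained.
- Report CSVs keep full precision in `pooled_results.csv` and a printed
  view (`%.2f` ORs, `<0.001`-style P values) in
  `pooled_results_printed.csv`; every fixed/random selection decision is
  logged per stratum in `run_log.txt`.
- Where the printed reference table is internally inconsistent (three
  cells whose OR is not the geometric mean of its own CI), the
  recomputation is taken as authoritative and the comparison records the
  discrepancy rather than chasing the typo.

## Problem sizes

The packaged analyses are desk-scale (50 studies) and run in seconds.
Calibration suites use 200 replicates of k = 30, n = 1000/arm for
parameter recovery, 500 null replicates of k = 10 for CI coverage, and
500 replicates of k = 15 for the Begg false-positive rate — sizes at
which the binomial envelopes on the checked rates are a few percentage
points wide, tight enough to detect real miscalibration while keeping the
whole suite under a minute.

## Limitations

Count-level meta-analysis cannot adjust for within-study confounding; it
inherits whatever bias the primary studies carry. The DL estimator is the
only $\tau^2$ method offered (matching the source; REML or
Hartung–Knapp adjustments are deliberately out of scope), and DL is known
to underestimate $\tau^2$ when k is small. The Begg test has low power at
small k; a non-significant result does not establish absence of
publication bias. The five genetic models are correlated analyses of the
same data and are not corrected for multiplicity, mirroring standard
practice in this literature.
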