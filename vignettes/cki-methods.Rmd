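---
title: "Central kinase inference: methods, assumptions and design decisions"
author: "cki package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Central kinase inference: methods, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cki)
```

# Overview

`cki` identifies *central kinases* — kinases whose activity change is supported
by several statistically independent lines of evidence, consistently across
many pairwise comparisons of a study design. The inputs are:

* a quantitative phosphosite profile (site × sample intensity matrix, with
  protein accession, position, residue S/T/Y and optionally a
  localization-probability class per site), wrapped in a `PhosphoProfile`
  (a `SummarizedExperiment`);
* a site-specific kinase–substrate relation (ssKSR) network, `KSRNetwork`:
  predicted kinase → phosphosite edges;
* per-comparison differential mRNA expression results for the kinase genes;
* a `KinaseCatalog` restricting the analysis to a defined kinase universe.

The output is a ranked kinase table with per-channel hit counts and a boolean
`passes` column applying the design's minimum-hit threshold.

# The three evidence channels

## mRNA channel

For a condition pair, a kinase is a hit when the supplied
differential-expression p-value for its own transcript is below the mRNA
threshold. The package deliberately consumes *precomputed* DE p-values
(from any established DE method) rather than recomputing them: the channel's
role is integration, not expression modelling. Direction is the sign of the
reported fold change.

**Assumption:** transcript change is a usable proxy for a change in available
kinase protein. This is the weakest channel individually — which is exactly why
it contributes at most a few of the design's comparison units.

## Intensity channel (total substrate intensity)

For kinase $i$ and sample $A$,

$$\mathrm{TSI}_A(i) = \sum_{s \in \mathrm{sub}(i),\; q_A(s)} \sqrt{I_A(s)},$$

summing over the kinase's substrate sites quantified in $A$ (positive,
non-missing intensity). The square root compresses the right tail of reporter
intensities, which span several orders of magnitude, so that a single intense
site cannot dominate a kinase's index. A site targeted by several kinases
contributes to each of them; the per-sample total
$\mathrm{TSI}_A = \sum_i \mathrm{TSI}_A(i)$ therefore counts shared sites once
per targeting kinase, and the package maintains the conservation law
`tsiTotals(tsi) == colSums(tsiMatrix(tsi))` (tested).

For a sample pair $(A, B)$ the 2×2 table is

|              | sample A                    | sample B                    |
|--------------|-----------------------------|-----------------------------|
| kinase $i$   | $a = \mathrm{TSI}_A(i)$     | $b = \mathrm{TSI}_B(i)$     |
| other kinases| $c = \mathrm{TSI}_A - a$    | $d = \mathrm{TSI}_B - b$    |

tested with the Yates-continuity-corrected chi-squared statistic

$$\chi^2 = \frac{T\,\bigl[\max(0, |ad-bc| - T/2)\bigr]^2}
                {T_i\,T_o\,T_A\,T_B}, \qquad T = a+b+c+d,$$

with one degree of freedom. The test asks whether kinase $i$'s *share* of the
total substrate signal shifts between the samples — it is invariant to global
intensity scaling of a sample in the sense discussed under *Numerical choices*.
Direction is $+1$ when $a/T_A > b/T_B$.

**Assumption:** substrate phosphorylation intensity is a monotone readout of
upstream kinase activity, and normalization has removed sample-level loading
differences (any residual global factor mostly cancels because the test uses
shares, not absolute values).

## Network channel (up/down sub-networks)

Only sites quantified (positive) in *both* samples enter. Each such substrate
site gets a relative intensity ratio $\mathrm{RIR} = I_A(s)/I_B(s)$ and is
assigned to the kinase's up-regulated sub-network when $\mathrm{RIR} > 1$
(weight $\mathrm{RIR}$) or down-regulated sub-network when $\mathrm{RIR} < 1$
(weight $1/\mathrm{RIR}$); ties ($\mathrm{RIR} = 1$) belong to neither and are
counted separately. The kinase network indices are

$$\mathrm{KNI}_U(i) = \sum_{\mathrm{RIR}>1} \mathrm{RIR}, \qquad
  \mathrm{KNI}_D(i) = \sum_{\mathrm{RIR}<1} 1/\mathrm{RIR},$$

and the 2×2 table (kinase $i$ vs others) × (up vs down), with $c$ and $d$ the
remaining totals, is tested with the same Yates-corrected chi-squared. A kinase
whose substrate RIRs are all ties is degenerate for this comparison and is
excluded (with a message) rather than reported with a meaningless p-value.

**Assumption:** the *imbalance* between the weighted sizes of a kinase's up-
and down-shifted substrate sub-networks, relative to the network-wide
imbalance, indicates directional activity change. Using the reciprocal for the
down side makes the two weights symmetric on the log-ratio scale.

# Designs, hit counting and ranking

`enumerateUnits()` expands a design into comparison units. Each channel runs at
either `"condition"` level (one profile per condition; exactly one sample per
condition is required) or `"replicate"` level (all cross-condition replicate
pairs, $r_A \times r_B$ per condition pair). Condition pairs are oriented
**later vs earlier** in the order the conditions are supplied, so supplying a
time course in temporal order yields comparisons that read as progression
(e.g. `treated_vs_control`). Four standard layouts ship as presets:

| preset          | layout                                   | units | min hits | thresholds (mrna / intensity / network) |
|-----------------|------------------------------------------|------:|---------:|-----------------------------------------|
| `dox`           | 2 cond., cond.-level mRNA, 3v3 phospho   |    19 |       14 | 0.01 / 1e-5 / 1e-5                       |
| `genistein`     | 2 cond., 2v2 everywhere                  |    12 |        6 | 1e-4 / 0.05 / 0.01                       |
| `maturation`    | 2 cond., 3v3 everywhere                  |    27 |       15 | 0.01 / 1e-5 / 1e-5                       |
| `reprogramming` | 3 cond., condition level everywhere      |     9 |        5 | 0.01 / 1e-5 / 0.01                       |

A kinase's hit count is the number of units in which it is significant at that
unit's channel threshold. Ranking is by hits (descending), then by
$\sum -\log_{10} p$ over hit units (descending), then alphabetically by symbol
— a deterministic total order, so results are invariant to input row order
(tested). `passes` applies the design's `minHits`. Custom designs round-trip
through a small YAML file (`readDesignFile`/`writeDesignFile`): YAML was chosen
because a design is a nested structure (conditions → sample labels) that maps
naturally onto YAML and the `yaml` package is a standard dependency; the format
stores conditions, channel levels, thresholds and `min_hits`.

# Parameters and defaults

* **Channel thresholds** default to mRNA $p<0.01$, intensity $p<10^{-5}$,
  network $p<10^{-5}$. The phospho-channel thresholds are deliberately strict:
  with thousands of substrate sites the chi-squared tables have enormous
  totals, so null fluctuations already reach "nominally significant" p-values;
  $10^{-5}$ keeps the per-unit false-hit rate low enough that the min-hits rule
  (below) drives specificity. Smaller designs with fewer sites (the
  `genistein`-style 2v2 layout) use lenient thresholds because their tables are
  smaller and the number of units is lower.
* **`minHits`** defaults to roughly 3/4 of the number of units in the presets
  (14/19, 6/12, 15/27, 5/9). Requiring a majority of *independent* comparisons
  is the integration step: a kinase that is extreme in one replicate pair but
  silent elsewhere does not pass.
* **TSI transform** defaults to `sqrt` (variance-stabilizing for
  intensity-like data); `identity` and `log` are available for sensitivity
  analysis.
* **p-value floor**: p-values are floored at `.Machine$double.xmin` so that
  $-\log_{10} p$ used in ranking is always finite.

# The synthetic generator

`syntheticConfig()` / `simulateCKIData()` produce a complete, self-consistent
dataset: a kinase catalog, an ssKSR network (edges per kinase ~ Poisson(20),
with a 0.2 probability of substrate sharing between kinases), a phosphosite
profile, per-condition-pair DE tables and a planted-kinase truth list.

Defaults (chosen once, before any result was inspected, and never tuned):
100 kinases, 2000 sites, baseline log-intensity $\mathcal N(\log 10^6, 1)$,
replicate noise sd 0.25 on the log scale, 10% missingness completely at
random, two conditions with 3 replicates each, 5 planted kinases whose
substrate sites are multiplied by $\kappa = 8$ in the non-first conditions and
whose transcripts get DE p-values $\sim \mathrm{Beta}(1, 200)$; null genes get
uniform p-values.

What it emulates: realistic intensity scales and dispersion, shared substrates,
missing quantifications, the coupling of transcript and substrate evidence for
truly active kinases, and a clean null ($\kappa = 1$, nothing planted) under
which planted and unplanted kinases are exchangeable (tested). What it does
**not** emulate: peptide-level effects (missed cleavages, co-isolation),
intensity-dependent missingness, correlated kinase activities, network
prediction errors (all edges are "true"), or batch structure. Conclusions
about absolute error rates on real data should not be read off the generator;
it validates the *mechanics* (recovery monotone in $\kappa$, calibrated null,
determinism given a seed — all tested). The generator saves and restores
`.Random.seed`, so simulation never perturbs the caller's RNG state, and
`writeFixture`/`readFixtureConfig` round-trip a config through YAML with full
floating-point precision, making fixtures byte-reproducible.

# Numerical choices

* **Zero and missing intensities.** A zero intensity is treated as *not
  quantified*, the same as a missing value: a reporter intensity of exactly 0
  is an absence of evidence, not evidence of absence, and admitting it would
  create spurious RIRs of 0 or ∞ in the network channel. `readPhosphoTable`
  converts zeros to `NA` with a message so the decision is visible. Negative
  intensities are an input error. This is a modelling choice, and the main
  open question of the data model: a sensitivity analysis distinguishing
  "missing at random" from "below detection limit" is out of scope here.
* **Scale homogeneity of the chi-squared.** The *uncorrected* 2×2 statistic
  $T(ad-bc)^2/(T_iT_oT_AT_B)$ is exactly degree-1 homogeneous: scaling all
  four cells by $k$ multiplies it by $k$. The Yates continuity correction
  breaks exactness, because $|ad-bc|$ scales as $k^2$ while the correction
  $T/2$ scales as $k$. The tests therefore assert *exact* homogeneity of the
  uncorrected statistic and *approximate* (2% relative) homogeneity of the
  corrected statistic on large cells, where the correction's share of
  $|ad-bc|$ vanishes. Practically: the corrected test is slightly conservative
  for small tables, which is the correction's purpose.
* **Degenerate tables.** Any 2×2 table with a zero margin has $\chi^2 = 0$ and
  $p = 1$ by convention and is flagged `degenerate`; kinases that are
  degenerate in the network channel are excluded from that unit.
* **Rounding.** Reported percentages use `roundHalfUp()` (half away from
  zero), matching how such tables are conventionally printed; R's `round()`
  uses banker's rounding and would disagree on exact halves. One consequence:
  for the reference 10,818-site profile the threonine share is
  $1251/10818 = 11.5641\% \to 11.56$, not 11.57.
* **Gene symbols** are uppercased on input so that catalog, network and DE
  tables join case-insensitively.

# Evaluation

`benchmarkRanking()` scores a ranking against a truth list: the confusion
matrix uses `passes` as the prediction, Sn $=$ TP/(TP+FN), Sp $=$ TN/(TN+FP),
and the ROC curve sweeps the hit-count threshold with a rank-based,
tie-corrected AUC (equal to the pairwise concordance probability; tested
against a brute-force oracle). `hypergeomEnrichment()` reports the enrichment
ratio $E = (m/M)/(n/N)$ and a one-sided hypergeometric p-value, upper-tailed
when $E \ge 1$ and lower-tailed otherwise; `enrichTerms()` adds
Benjamini–Hochberg adjustment over terms.

# Test problem sizes

The test and acceptance suites run the full pipeline at the package's chosen
reference scale — the generator defaults above, 20 seeds, 19-unit design — for
planted-kinase recovery (median planted-in-top-10 ≥ 4) and null calibration
(pass fraction < 1%), and at smaller sizes (10–50 kinases, 120–600 sites) for
property tests, keeping the whole suite around one minute. These sizes are the
package's own choices, balancing statistical resolution against runtime.

# Limitations

* The channels are treated as independent lines of evidence; in reality mRNA
  and substrate intensity are correlated, so the effective number of
  independent units is smaller than the nominal count.
* The ssKSR network is taken at face value; prediction errors propagate
  directly into both phospho channels.
* Chi-squared p-values on very large intensity totals are extremely small and
  should be read as ordering devices within the hit-count framework, not as
  calibrated tail probabilities.
* The condition-pair orientation (later vs earlier) affects only direction
  signs, never significance — swapping $A$ and $B$ preserves $\chi^2$ and $p$
  and negates direction in both phospho channels (tested).

# Session info

```{r}
sessionInfo()
```
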