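---
title: "Methods: expression balance, dosage sensitivity and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression balance, dosage sensitivity and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeobalance)
```

# The model and its assumptions

`homeobalance` studies duplicate gene pairs created by a single
whole-genome duplication (WGD). Because every pair in such a genome has
the same age, differences between pairs in how far the two copies have
diverged in expression can be attributed to differences in selective
constraint rather than to time. The working hypothesis is the
dosage-balance model: genes whose products participate in stoichiometric
complexes are under selection to keep the *relative* output of the two
copies matched, which simultaneously predicts

* low expression divergence between copies,
* retention of duplicates after WGDs across lineages (copy numbers that
  track each lineage's multiplication history),
* low propensity for gene loss over a species tree,
* slow accumulation of cis/trans regulatory mutations, and
* few nonfunctionalizing (premature-stop) variants.

The package quantifies each arm of that prediction and couples them
through shared tabular inputs.

## Expression balance

For copies with FPKM values $E_1, E_2$ in a tissue,
$$R_{\mathrm{FPKM}} = \frac{|E_1 - E_2|}{E_1 + E_2} \in [0, 1],$$
0 for perfect balance, 1 for complete silencing of one copy. Tissues with
$E_1 + E_2 = 0$ carry no balance information and are excluded rather than
scored 0 or 1; the per-pair summary is the arithmetic mean over
informative tissues (`pair_balance()`), and a pair with no informative
tissue is flagged instead of silently dropped. No minimum-expression
filter is applied by default; `min_fpkm` exposes one because annotations
differ in how aggressively they call low expression.

Tissue specificity uses the standard index
$\tau = \sum_i (1 - x_i/x_{\max})/(N-1)$ computed on $x_i =
\log_2(\mathrm{FPKM}_i + 1)$. The log base and the +1 pseudocount are the
most common convention for FPKM matrices; $\tau$ is exactly 0 for uniform
profiles and 1 for single-tissue expression, and undefined for all-zero
rows.

When several syntenic anchor pairs involve the same tandem array they are
redundant observations of one duplication; `dedup_tandem_anchor_pairs()`
keeps the pair with the lowest anchor e-value, breaking exact ties by
input order so the filter is deterministic.

## Associations with gene features

`pearson_test()` reports $r$, $t = r\sqrt{(n-2)/(1-r^2)}$, the two-sided
$p$ from the $t_{n-2}$ distribution, and a 95% CI from the Fisher z
transform (the CI construction is not prescribed elsewhere; Fisher z is
the default choice and is stated here explicitly). Pair-level feature
values are the arithmetic mean of the two copies' values; substitution
rates (dN, dS, ω) are naturally pair-level quantities estimated on the
duplicate pair itself.

Features that plausibly act multiplicatively are allowed a log
transform: both `y ~ x` and `y ~ log x` are fit by least squares and
compared with the least-squares AIC $n\ln(\mathrm{RSS}/n) + 2k$, $k = 3$.
Only AIC *differences* matter for the choice, so the constant convention
is irrelevant; the chosen transform's Pearson statistics are reported
together with both AICs. Count features containing zeros use
$\log(x+1)$ so zero-count genes are kept; features with negative values
(for example an orthogroup's observed-vs-expected correlation) skip the
log model. No multiple-testing correction is applied across the feature
table by default, matching the raw-p presentation conventional for this
table; `fdr = TRUE` adds BH-adjusted values.

A caveat we verified by simulation: re-selecting the transform *within
each dataset* keeps the better-fitting of two highly correlated
predictors and therefore inflates the type-I error of the reported
Pearson p slightly (from 0.05 to roughly 0.05–0.08 at $n = 500$ under the
null generator). In a real analysis the transform is chosen once on the
observed data, so downstream procedures that re-use the fit — the
deletion-robustness module in particular — freeze the transform chosen on
the full data rather than re-selecting per replicate. The calibration of
the underlying Pearson test itself is exact (verified against a
brute-force oracle and by null simulation).

## Dosage sensitivity from copy numbers

The expected copy number of a single ancestral gene in a lineage is the
product of the lineage's multiplication factors (2 per WGD, 3 per WGT):
an event history 3,2,2,3 expects 36 copies; a lineage without events
expects 1. `r_copy_number` correlates observed with expected counts per
orthogroup across the species panel; raw counts are used (not counts
normalized to an outgroup), since the Pearson correlation is invariant to
the affine rescaling such normalization applies uniformly.

The propensity for gene loss (`pgl()`) is re-specified here as a
Dollo-parsimony quantity, preserving the intent of loss propensity
normalized by opportunity: a single gain is placed at the most recent
common ancestor of the carrier species, losses are inferred on every
branch whose parent clade still contains a carrier but whose own subtree
does not, and PGL is the summed length of loss branches divided by the
total branch length below the gain node. This minimal placement (fewest,
deepest losses) is unique under Dollo parsimony — the implementation is
checked against exhaustive enumeration over all loss placements on small
trees — and the statistic is invariant to rescaling all branch lengths.
An orthogroup carried by a single species has no loss opportunity below
its gain node and scores 0. This is an explicit approximation: it is a
parsimony statistic, not a birth–death likelihood.

## Regulatory divergence and nonfunctionalization

Allele-specific expression contributes two log-scale components per gene
and stage: the parental difference $A$ and the allelic (cis) difference
$B$; the trans component is $A - B$ by construction and is never stored
separately, so the decomposition identity is exact. The package consumes
$A$ and $B$ as precomputed values (their estimation from read counts is a
separate experimental pipeline) and associates $|B|$, $|A-B|$ and their
sum with average R_FPKM, per stage by default since stages are distinct
biological samples.

Premature-stop incidence is compared between balanced
($R_{\mathrm{FPKM}} \le 0.6$, the boundary counting as balanced) and
biased pairs with a Pearson χ² test, Yates-uncorrected by default (a
correction flag exists). A pair is stop-bearing when either copy carries
a stop; the per-copy question — do *low* copies accumulate stops? — is
answered separately in the copy-fate module, where each copy's high/low
label is resolved by majority vote across tissues (exact per-tissue FPKM
ties, which carry no rank information, are excluded, as are copies with a
tied vote). Paired t tests compare per-copy features between high and low
copies within a focal tissue; per-copy feature values (e.g. per-copy dN)
are required for these comparisons.

# The synthetic study

`simulate_study()` generates every input table from one latent
dosage-sensitivity parameter $s \sim \mathrm{Beta}(2,2)$ per orthogroup
(no empirical estimate of constraint strength exists to calibrate against,
so a symmetric, moderately concentrated prior on $[0,1]$ is used; the
shape parameters are configurable and `s_fixed` pins $s$ for degenerate
checks). The default scale — 2000 orthogroups, 10 tissues, 25 species,
2 ASE stages — is the study size at which all downstream analyses are
exercised and completes in seconds on one CPU.

* **Expression.** Both copies share a lognormal pair mean (log-mean 3,
  sd 1, i.e. a median around 20 FPKM) and a per-tissue effect whose sd,
  $0.3 + 0.35(1-s)$, makes insensitive genes more tissue-specific. Copy 2
  is downscaled by $\exp(-2(1-s)|z|)$, $z \sim N(0,1)$, and both copies
  receive lognormal noise (sd 0.25). This produces the characteristic
  right-skewed R_FPKM distribution without asserting a mechanistic model
  of expression degeneration; with $s = 1$ or zero effect size the pairs
  are exactly balanced up to noise.
* **Copy numbers.** Each lineage applies its event history to one
  ancestral copy; after every event each surviving copy is lost
  independently on the post-event branch with probability
  $0.4(1-s)$. Branch-wise Bernoulli loss (rather than rate × length) is
  the simplest process with a closed-form survival probability,
  $(1-q)^{k}$ for $k$ events, which the tests use as an oracle.
  Lineages without events always retain their copy.
* **Features.** Substitution rates grow log-linearly with the *realized*
  average R_FPKM (slopes 0.8 for dN, 0.7 for dS, so ω inherits a weak
  positive trend — deliberately weak, as ω is the least consistent
  correlate in real data); structural and functional features
  (protein/CDS length, exon, Pfam, PPI counts, lethal score) grow with
  $s$ itself on log or logit scales. τ and dN/dS are drawn as summary
  values rather than recomputed from the expression matrix: computing τ
  from the matrix would couple it to R_FPKM through shared sampling noise
  even with all effects off, corrupting the null mode that the
  calibration tests rely on. The slopes were fixed once so the realized
  correlations sit in the magnitude range reported for real
  paleopolyploid datasets (|r| ≈ 0.05–0.5 depending on the feature).
* **ASE.** $B$ and $A-B$ are drawn with sd
  $\mathrm{scale}\times(0.15 + 0.8\,\bar R_{\mathrm{FPKM}})$, so their
  magnitudes rise with expression bias; a zero scale gives exactly zero
  components. Records are real-valued summaries, not read counts.
* **Stops and fates.** Each copy's stop probability is
  $\mathrm{logit}^{-1}(-3.2 + 2.2(\bar R + 0.4\cdot\mathbb{1}_{low}))$;
  the downscaled copy also carries slightly higher dN and ω, shorter
  protein and higher τ, so fate comparisons have a known direction.
* **Determinism.** The master seed is split into one stream per
  sub-generator (sensitivity, expression, features, copies, ASE, stops,
  GO), so changing e.g. the number of stages cannot perturb the
  copy-number draws, and identical configs reproduce studies bit for bit.

## What the generator does and does not emulate

It reproduces the joint *statistical* structure the analyses assume:
skewed balance, feature couplings of realistic sign and magnitude,
copy-number erosion shaped by sensitivity, regulatory magnitudes and stop
incidence rising with bias. It does not emulate read-level noise,
replicate structure within tissues, sequence evolution (dN/dS are summary
draws), subgenome dominance (both copies are exchangeable up to the
downscaling), tandem arrays (the field defaults to none; the filter is
tested on constructed cases), or hybrid-cross ASE genetics. Passing tests
therefore demonstrate that the estimators recover known couplings from
data with the right correlation structure — not that any particular
biological dataset will show them.

# Numerical choices and degenerate inputs

* Undefined quantities (0/0 balance, zero-variance tests, empty bins,
  all-zero τ rows) are flagged `computable = FALSE`/`NA`, never silently
  dropped and never raised as errors once inputs are structurally valid.
* Pearson CIs require $n > 3$ (the Fisher z standard error is undefined
  below); $|r| = 1$ reports $p = 0$ with an infinite t statistic.
* All TSV output uses "." for missing, LF endings and 12 significant
  digits, which is what makes repeated pipeline runs byte-identical.
* The deletion-robustness grid (2.5–40% deletions, 50 replicates,
  sampling without replacement, one shared draw set per fraction across
  features) measures annotation-incompleteness sensitivity; replicates
  share subsamples across features so feature columns remain comparable
  within a replicate.

# Problem sizes used by the test suite

Unit tests run on studies of 100–2000 orthogroups. The end-to-end
property checks use the default study (2000 orthogroups, 10 tissues,
25 species) across 20 seeds for the sign pattern, 2000 replicates of a
500-orthogroup null study for calibration, and 1000 random instances per
statistic for oracle equivalence — sizes at which every check is
statistically decisive yet the whole suite runs in a few minutes on one
CPU.

# Known limitations

* PGL is a parsimony approximation; orthogroups absent outside the gain
  clade contribute no loss signal, and single-carrier groups score 0.
* The AIC transform selection is mildly anticonservative when applied
  per dataset (documented above).
* Expected copy numbers ignore segmental duplication and
  re-diploidization; they are pure event products.
* `simulate_study()` generates one focal species; cross-species balance
  correlation is exercised by simulating a second study with a shared
  seed for the sensitivity stream.
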