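---
title: "Methods: models, parameters and design choices in spacemir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in spacemir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacemir)
```

`spacemir` analyzes multi-tissue small-RNA count matrices from a
three-condition design — spaceflight (FL), habitat ground control (HGC) and
vivarium ground control (VGC) — crossed with two age groups (3M, 8M) and
two euthanasia cohorts (LAR, TERM). This vignette documents the models the
package implements, the parameters that matter, and the choices made where
the design was genuinely open.

## Preprocessing

**Detection filter.** A miRNA is considered detected in a sample when its
raw count is at least `min_count` (default 5). Within a tissue, a feature
is retained only if *every* condition group of that tissue detects it in at
least `min_fraction` (default 0.10, inclusive at the boundary) of the
group's samples. The filter is evaluated per tissue and cross-tissue
analyses use the union of the per-tissue sets: requiring all groups of all
tissues to pass simultaneously would be implausibly strict, since detection
profiles are strongly tissue-specific. The boundary is inclusive — "at
least 10%" retains a feature detected in exactly 1 of 10 samples — and the
filter is idempotent.

**Normalization.** rpmm (reads per million mapped) divides each sample by
a library-size denominator and multiplies by $10^6$. The default
denominator is the column sum of the count matrix, which makes every sample
sum to exactly one million and is reproducible from the matrix alone. When
the metadata carries a complete `mapped_reads` column (total genome-mapped
reads per sample), `metadata_mapped_reads` reproduces normalization against
mapped totals instead; which total a given upstream quantification used is
often ambiguous, so both are supported. A log2 transform with pseudocount 1
(`log2(x + 1)`) follows; the pseudocount keeps zeros at zero and all
transformed values non-negative.

## Differential expression

Per contrast (e.g. FL vs HGC within one tissue, optionally restricted to an
age stratum), each retained feature is tested with a two-sided Wilcoxon
rank-sum test on the log2 values (ranks are invariant to the monotone
transform, so this equals testing the rpmm values):

* **exact mode** enumerates the permutation distribution of the rank sum
  over all $\binom{n_a+n_b}{n_a}$ group assignments, with mid-ranks for
  ties, and reports $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$. Base R's
  exact path refuses ties, so this enumeration is implemented in-package
  and verified against a brute-force bitmask oracle.
* **normal_approx** uses the tie-corrected variance with a 0.5 continuity
  correction.
* **auto** (the default) chooses exact when $n_a + n_b \le 12$ and no tied
  value spans the two groups, else the approximation; the suite checks the
  two modes disagree by less than 0.03 on tie-free groups of 8 vs 8.

P values are BH-adjusted *per tissue × contrast family*, matching how
per-tissue, per-comparison results are reported downstream.

The **fold change** is the difference of medians of `log2(rpmm + 1)`
(group A minus group B). In one dimension the geometric median is the
median, and the median commutes with the monotone log, so this equals the
log2 ratio of (pseudocount-shifted) geometric medians; a geometric-mean
mode (`fc_mode = "geomean"`) is exposed for replication attempts but the
median is the default because it is robust to single outlying samples at
the small group sizes typical of flight experiments. **Cohen's d** uses the
pooled SD on the same log2 scale as the test and fold change; a
zero-variance split with unequal means returns a signed infinite sentinel
that passes any magnitude threshold, and groups smaller than
`min_group_size` (default 3 — the smallest size for which a rank test and a
pooled SD are meaningful) skip the contrast with a warning rather than
silently.

The two calls are deliberately distinct:

* *deregulated*: $|\log_2 FC| > 1$ and $|d| > 0.5$ — an effect-size
  criterion robust to small group sizes;
* *significant*: $|\log_2 FC| > 1$ and BH-adjusted $p < 0.05$.

Both are pure functions of the record's numeric fields and the tests
re-derive them independently.

## PVCA

Principal variance component analysis decomposes expression variance over
design factors. Features are centered, a PCA over samples retains the
smallest set of leading components whose cumulative explained-variance
fraction reaches `pc_coverage` (default 0.90), and each retained PC score
is modeled with random intercepts for every factor and (by default) every
pairwise label interaction. Variance components are estimated by REML via
`lme4::lmer` — the standard fitter behind reference PVCA implementations —
which constrains components to be non-negative; boundary estimates come
back as zero, single-level groupings are fixed at zero with a warning, and
a constant response returns all zeros. Per-PC components are normalized to
fractions and averaged with eigenvalue weights renormalized over the
retained PCs, so the output fractions are non-negative and sum to one
(checked to $10^{-9}$). Fractions are invariant to positive rescaling of
the data. A two-factor convenience mode
(`include_pairwise_interactions = FALSE`) reproduces analyses that compare
exactly two named factors, e.g. spaceflight (FL vs not) against
environment (VGC vs not).

Exact numerical agreement with any particular external PVCA implementation
is not a goal; the contract is recovery-level: a planted dominant factor
must capture > 0.9 of the variance, collapse below 0.1 under label
permutation, and two-factor designs with planted variance ratio
4 : 1 : 0.25 must recover the planted rank order in at least 18 of 20
replicates.

## Attribution set logic

A fold change has a direction only if it is nonzero (`direction_match`
requires $fc_1 \cdot fc_2 > 0$; a zero never matches — a sign test needs a
sign). All attribution reuses one primitive, `intersect_directional`:
features deregulated in both inputs with agreeing directions.

* **Spaceflight set** per tissue: FL vs HGC ∩ FL vs VGC. A cross-tissue
  multiplicity table flags features called in more than one tissue as
  systemic.
* **Housing set**: FL vs VGC ∩ HGC vs VGC — the same code path with
  different inputs.
* **Age-dependent flight sets**: `flight_3m` pairs FL vs HGC within 3M
  with 3M vs 8M within FL; `flight_8m` pairs FL vs HGC within 8M with the
  *sign-flipped* age contrast (8M vs 3M). A match table categorizes every
  feature as equal-direction, no-match, or only-one-comparison.
* **Cohort consistency** (LAR/TERM) and multi-way external comparisons use
  `directional_support`, a generalized n-way intersection with a
  `min_support` parameter, since tie/direction handling across three or
  more sets is otherwise under-specified.

Fold-change correlations between contrasts use Pearson's r over shared
finite fold changes, a two-sided p from the t transform
($t = r\sqrt{(n-2)/(1-r^2)}$, $p = 0$ at exact collinearity), and BH
adjustment across whichever batch of records is computed together. Two
pass criteria coexist in the literature-style outputs — adjusted p alone,
or additionally $|r| > 0.5$ — so both sit behind a `criterion` switch
defaulting to the adjusted-p rule. Records with fewer than 3 shared
features or zero variance carry an undefined r and never pass.

MIR families are reported when at least two deregulated members occur in a
tissue, with a direction-concordance fraction. Circulating detectability
is inclusive: mean rpmm of at least 10 in blood, plasma or serum.

## miRNA–mRNA integration

Cell-level mRNA counts are aggregated per sample by summation
(`pseudobulk`), conserving per-gene totals, and the gene-level matrix goes
through the identical normalization and differential-expression machinery.
Predicted target tables carry weighted context++-style scores, which are
non-positive with *more negative = stronger*; the percentile filter
therefore defaults to |score| — taking raw values above the 75th percentile
would select the weakest quartile — with a `raw_score` mode kept for exact
replication. The threshold is the type-7 (linear-interpolation) quantile
over the loaded table, and retention is strict (> threshold), so an
all-equal table retains nothing. Whether the percentile should be computed
over a full-species table or a pre-filtered one is left to the caller, who
controls what is loaded.

For tissues with more than 100 deregulated mRNAs, the top
$\lceil 0.10 \cdot n \rceil$ by $|\log_2 FC|$ are kept (ties broken by
smaller raw p, then id — a total, reproducible order); otherwise all are
kept, and exactly 100 means all. Pair hits join deregulated miRNAs, top
mRNAs and filtered target pairs *without* a direction-concordance filter,
because miRNA–target regulation is not always anti-correlated (indirect
regulation, co-regulation with transcription factors). `most_targeted`
counts distinct regulators per gene and tissue; `validated_crosscheck`
flags hits present in a user-supplied validated-pair table.

## Enrichment

* **ORA**: one-sided hypergeometric upper tail
  $P(X \ge k)$ with `stats::phyper`, member sets intersected with the
  universe first. The universe defaults to the features detected in the
  analyzed tissue/contrast — the conservative convention.
* **Ranked list**: $-\log_{10}(\max(p_{raw}, 10^{-300})) \cdot
  \mathrm{sign}(\log_2 FC)$, ordered descending with ties broken by
  $|\log_2 FC|$ then id, so the order is total and reproducible. The floor
  keeps scores finite.
* **GSEA**: unweighted Kolmogorov–Smirnov-style running sum (+1/|S| at
  members, −1/(N−|S|) elsewhere). The walk is accumulated in integers
  (member step $N-|S|$, non-member step $-|S|$, one division at the end),
  so the enrichment score is rounding-free and a tie between a positive
  and a negative extremum is resolved exactly, in favor of the earliest.
  The permutation null redraws the term's membership uniformly from the
  ranked universe — the standard null for a single pre-ranked list —
  with $p = (1 + \#\{|ES^*| \ge |ES|\})/(1 + n_{perm})$, reproducible
  given a seed. Terms covering the whole list are skipped with a warning.
* **Redundancy and labels**: `minimal_set` removes every term that is a
  transitive ancestor of another term in the set, over a user-supplied
  acyclic child→parent edge table. Term clustering uses the Jaccard index
  of member sets with average-linkage hierarchical clustering cut at
  similarity 0.25; this replaces information-content semantic similarity,
  which requires an external ontology-graph apparatus, while preserving
  the observable contract — group redundant terms, label each cluster with
  the words occurring at least twice in its term names (lowercased,
  stop-worded, ordered by frequency then alphabetically).

## The synthetic-data generator

`sim_params()` defaults describe the reference recovery experiment: two
tissues, 300 miRNAs, 400 genes, 8 samples per tissue × condition × age
cell, negative-binomial counts with shared dispersion 0.1 (a standard
overdispersed RNA-seq model), per-feature baseline log2 means uniform on
[3, 10] (expected counts from ~8 to ~1000 at nominal depth, spanning the
detection boundary), planted log2 shifts of magnitude 2, and effect
fractions 10% spaceflight, 10% housing, 5% per age-dependent class, 70%
null. Library sizes are log-normal around $10^6$ (log-sd 0.3) so rpmm is
exercised non-trivially.

Effects are assigned at the *family* level (family sizes 1–4 with
probabilities 0.7/0.15/0.10/0.05), so family members share class and sign.
Spaceflight features shift in FL only; housing features in FL and HGC;
age-dependent features in FL within one age group. Planted target pairs
receive |scores| above the table's 75th percentile (background pairs are
kept at no less than four times the planted count so this holds by
construction), and genes with planted regulators shift in exactly the
samples where their regulators shift, by default in the opposite direction
(canonical repression; configurable, since anti-correlation is not a safe
assumption).

What the generator does *not* emulate: compositional coupling between
features within a sample, batch or extraction effects, tissue-specific
baselines, strain differences, or realistic miRNA family sequence
structure. Recovery results on synthetic data therefore demonstrate the
correctness of the pipeline's logic and its power under the stated model,
not performance on any particular real cohort.

**Recovery scoring is sign-aware**: a called feature counts only if it is
planted with a matching direction, and an empty call set has FDP 0 by the
$\max(|called|, 1)$ convention. Age-dependent flight effects are genuine
spaceflight effects — a shift of 2 in half the FL samples moves the
all-ages median by about 1, exactly at the fold-change gate — so the
spaceflight set's false discoveries are assessed against the union of
flight-affected classes, while sensitivity is scored on the pure
spaceflight class, which is the stricter combination.

## Numerical conventions and degenerate inputs

* TSV interchange: tab-separated, UTF-8, `#` comments ignored, first
  column is the identifier; reals serialized with 12 significant digits.
  Parsers reject — never coerce — negative, non-integer, duplicated or
  out-of-enum input, naming the offending cell.
* Ontology edge tables are verified acyclic (Kahn's algorithm) at load.
* BH families, PCA retention (cumulative fraction compared with a
  $10^{-12}$ slack), quantile type 7, and all tie-breaks are fixed and
  documented so that reruns are byte-identical.
* All simulation functions are pure functions of (parameters, seed);
  `run_all` derives per-stage seeds from the master seed by fixed offsets.

## Problem sizes used by the test suite

The suite exercises the exact Wilcoxon test against full enumeration for
all group sizes up to $n_a + n_b = 10$ including ties; BH on 1000 random
vectors; ORA against brute-force enumeration on universes up to 16 with a
1000-replicate null-uniformity check; GSEA against a running-sum oracle on
200 random lists up to length 50; PVCA recovery on 20 two-factor
replicates of 50 features × 40 samples; and attribution recovery on 20
replicates at the reference conditions (one tissue, 300 miRNAs, 8 samples
per group). These sizes give stable pass/fail behavior while keeping a
full run to well under a minute per module.

## Known limitations

* The Wilcoxon exact mode enumerates $\binom{n}{n_a}$ assignments and is
  only selected automatically up to $n = 12$; larger groups use the
  tie-corrected approximation, which is the method's own convention.
* PVCA fractions depend on PC retention and REML boundary behavior; they
  are comparable between runs of this package, not across PVCA
  implementations.
* GSEA p values are permutation-based and coarse at small `n_perm`
  (a warning fires below 100); the smallest attainable p is
  $1/(1+n_{perm})$.
* The pipeline starts from count matrices; read mapping, quantification
  and single-cell preprocessing are out of scope, as is any live query to
  enrichment web services — their logic runs on user-supplied tables.
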