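---
title: "oncoswitch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncoswitch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoswitch)
```

This vignette explains what each stage of the pipeline computes, why the
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open and a choice
had to be made.

## The analysis problem

The package targets experiments in which the same tumor is profiled by
single-cell RNA-seq under two conditions — an oncogene-driven state
("ON") and the state after oncogene withdrawal ("OFF"), typically a
doxycycline-controlled driver such as Kras^G12D^ — and the questions are
compositional and communicative: which cell types expand or contract
after withdrawal, which T-cell subpopulations activate, which
ligand–receptor axes between tumor and immune clusters strengthen, and
which pathways the receiver clusters' marker genes point to. Alignment,
normalization-for-clustering, integration and graph clustering are
upstream concerns; this package takes cluster labels as input and does
the downstream statistics explicitly and reproducibly.

## Quality control and normalization

A cell is retained when it has at least `min_genes = 200` detected genes
(raw count > 0) **and** a mitochondrial count fraction of at most
`max_mito = 0.10`. The exclusion rules are phrased as "fewer than 200"
and "more than 10%", so the boundaries belong to the retained side; the
filter is idempotent and never touches the gene axis. Mitochondrial
genes are recognised by the mouse `mt-` name prefix unless an explicit
list is given. Counts are then scaled per cell to counts-per-million
(CPM). CPM is used deliberately — the interaction score below is defined
on cluster mean CPM, and CPM's per-cell scaling cancels library size, so
the score is invariant to depth rescaling within a cluster (a property
the test suite asserts).

One consequence worth knowing: a gene with constant *raw* counts is not
constant in CPM when library sizes differ systematically between
clusters. The marker finder therefore sees (true) compositional effects;
the fold-change filter suppresses the small ones.

## Cluster annotation

Each cluster is scored against each panel entry as the mean of
`log1p(mean CPM)` over the entry's markers. The `log1p` keeps a single
very highly expressed marker from dominating a multi-gene panel; the
mean (rather than sum) makes panels of different sizes comparable. The
top type is assigned only when its score is at least `margin = 1.2`
times the runner-up's, otherwise the cluster is labelled `"ambiguous"`.
No tie-breaking rule for near-ties is defensible from first principles,
so the package refuses to guess; 1.2 was chosen as a margin wide enough
to absorb panel-score noise at a few hundred cells per cluster while
still separating lineages whose panels share genes (the immune-wide
Ptprc entry is the closest competitor in practice).

## Composition testing

For each cell type, the 2×2 table (in-type / out-of-type × condition)
is tested with the two-sided Fisher exact test, using the
point-probability rule: the p-value sums the probabilities of all tables
with the observed margins that are no more likely than the observed
table. T-cell subpopulations (Cd8a⁺, Cd69⁺, and the double-positive
conjunction) are counted *within* the annotated T-cell population, with
positivity defined as raw count ≥ 1 — the simplest rule that is robust
to dropout; the threshold is exposed. The sidedness and the
per-type-vs-rest construction are conventions of this package: the
analysis being reproduced states only that Fisher tests were used, so
both choices are documented rather than claimed. Multiple testing across
types uses Benjamini–Hochberg by default ("none" is available). The
reported odds ratio is the sample OR with the Haldane–Anscombe 0.5
correction when a cell is zero — finite, conventional, and exactly
reciprocal under column swap (asserted as a property test).

## Ligand–receptor scoring

For ligand *L*, receptor *R*, sender cluster *s*, receiver cluster *r*
and condition *c*:

$$\mathrm{score} = \overline{\mathrm{CPM}}_c(L \mid s)\;\times\;
\overline{\mathrm{CPM}}_c(R \mid r)$$

where the bar is the arithmetic mean over the cluster's cells, zeros
included. The score is computed for **all ordered** cluster pairs,
self-pairs included (autocrine signalling is real). Three thresholds
shape the output:

* **detection**, strictly `> 0.1` CPM on *both* means — a dropout guard;
  undetected records are kept with score 0 so the table stays auditable;
* **prioritization**, strictly `> 20` on the unscaled score in at least
  one condition — both conditions of a kept triple are retained so the
  contrast remains computable;
* **visualization scaling** ×10, applied last and never consulted by any
  threshold.

Whether the 0.1-CPM gate should apply to the cluster mean or to a
per-cell detection fraction is not decidable from the score's
definition; this package gates the mean and says so. Condition contrasts
are the arithmetic delta `score_OFF − score_ON` and a pseudocounted
ratio `(score_OFF + 1)/(score_ON + 1)`; ε = 1 is negligible against CPM
products (typically ≥ 10³) yet keeps zero-score triples finite. The
score is a deterministic statistic, not a test — permutation nulls in
the style of CellPhoneDB are out of scope by design.

## Marker genes and pathway enrichment

Markers are found one-vs-rest per cluster with a two-sided Wilcoxon
rank-sum test on `log1p(CPM)`, implemented as the normal approximation
with tie and continuity correction (the `wilcox.test(exact = FALSE)`
behaviour, vectorised across genes; the per-gene agreement with
`wilcox.test` is pinned by a test). Selection requires BH-adjusted
p < `alpha = 0.05` **and** `log2((mean_in+1)/(mean_out+1)) ≥ 0.25`,
up-regulated only. These are the familiar defaults of the standard
single-cell marker finders; the exact upstream settings of any given
study are rarely stated, so this finder is a documented stand-in of the
same statistical family, not a claim of equivalence. Note the
pseudocounted fold change is not invariant to a global CPM rescaling
(the rank-sum p-values are); since CPM is a fixed scale this matters
only if one feeds the finder pre-scaled data.

Clusters with fewer than 50 cells lack power for over-representation,
so their marker sets are pooled (union of markers, sum of sizes) before
testing — strictly below 50, all small clusters into one group by
default, with a user-controllable pooling map.

Each (group, pathway) combination is then tested with the exact
hypergeometric upper tail

$$p \;=\; 1 - \sum_{i=0}^{k-1}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

computed as the complementary sum from *k* upward, in log space
(log-gamma binomial coefficients, log-sum-exp reduction): at
N = 20,000 naive binomials overflow long before K or n are exhausted.
`k = 0` is the empty sum, p = 1, by construction. Marker or pathway
genes outside the declared universe are dropped (and counted in the
output) so the (N, K, n, k) quadruple stays self-consistent.

**Choosing N.** The default background is 20,000 — the conventional
protein-coding gene count of a mammalian genome, appropriate when
markers are drawn from a full transcriptome. The demonstration pipeline
instead sets `background = "observed"`: its simulated universe has only
~1,300 genes, and testing 1,300-gene draws against a fictitious 20,000
background would make every one-gene overlap look surprising. The rule
of thumb: N should be the universe the markers were *actually* drawn
from. Both options are exposed and logged.

## Tumor-burden metrics

Caliper volume uses the ellipsoid approximation `V = π·L·W²/6` (mm³).
Because W enters squared, the convention L = max axis, W = min axis is
enforced (with a warning on swap) — which physical axis was "length" is
an unstated convention in most protocols. Relative series divide each
subject by its own value at the chosen baseline day (baseline exactly 1,
the "day X set as 1" presentation); percent change is
`100 × (v_to − v_from)/v_from`, so a 100 → 1 decline is −99%. Group
summaries report mean ± SD. Mixed-effects growth modelling and survival
analysis are intentionally out of scope.

## The synthetic-data generator

`simulate_counts()` draws gene-wise negative-binomial counts with
variance μ + μ²·α (the standard scRNA-seq parameterization, chosen
because its moments are directly checkable), means equal to a per-gene
baseline times cluster- and condition-specific fold changes, then thins
every entry by independent Bernoulli dropout. Cluster sizes are
multinomial; one RNG stream per dataset, seeded once with a fixed draw
order, makes output bit-identical under a fixed (config, seed).

The shipped study conditions (`demo_sim_config()`): 2,000 cells per
condition, 15 clusters covering the marker panel's cell types, a
1,300-gene universe (22 panel markers, Cd8a/Cd69/Ncr1, the IL-15 axis
genes, 13 `mt-` genes, gamma-distributed background baselines), and
three planted effects:

* **composition** — the T-cell cluster "4" at 5% (ON) vs 20% (OFF),
  with two clusters ("9", "11") kept near 1% so the n < 50 pooling rule
  has something to pool;
* **T activation** — Cd8a and Cd69 fold changes in cluster 4 rise from
  4→10 and 1.5→8 between ON and OFF, shifting positivity fractions;
* **crosstalk** — Il15 in tumor cluster "13" and Il2rb in cluster "4"
  carry a per-condition fold change of 2 (ON) vs 40 (OFF), a strong
  planted axis sized at design time so that its OFF−ON product delta
  clears the sampling noise of decoy-pair deltas (products of two
  cluster means are noisy: the worst decoy delta scales with
  mean × SE of the highest-expressed background genes).

Marker fold changes are 30× (4× for the shared immune marker Ptprc —
large enough to annotate, small enough that "immune cells" does not
swallow the lineage-specific panels). Dispersion α = 0.8 and dropout
0.15 are ordinary droplet-data magnitudes; 6% of cells are simulated as
damaged (depth ×0.08, mitochondrial load ×3) to give QC a realistic
two-sided job. Two config fields go beyond the minimal generator
contract — the damaged-cell rate and a per-condition column in the
marker-effect table — because QC structure and the Cd8a/Cd69 positivity
shift cannot be expressed without them.

`simulate_genesets()` plants one pathway containing a stated fraction
(default all) of a designated cluster's marker genes padded to size with
random genes; the remaining sets are uniform draws.
`simulate_lr_pairs()` emits the planted pair (plus the Il15–Il15ra
alpha-chain pairing when applicable) and uniform decoy pairs from
non-marker background genes. `simulate_tumor_series()` produces
piecewise log-linear growth/decay with Gaussian noise on the log scale.

**What the generator does not emulate** — ambient RNA, doublets, batch
effects, UMI saturation, cell-cycle structure, and any correlation
between genes beyond the shared library size. Passing the recovery tests
therefore demonstrates that the *statistics* behave as specified under
a clean planted-signal model, not that the pipeline is robust to every
artefact of real droplet data.

## Numerical and engineering choices

* Hypergeometric and Fisher p-values are exact; the test suite pins them
  against independent enumeration oracles (all hypergeometric instances
  with N ≤ 30 against exact binomial-coefficient sums; 2×2 tables
  exhaustively to total 24 and a seeded sample up to total 200 against
  fixed-margin enumeration).
* Problem sizes in the tests were chosen to keep the full suite fast on
  a single core: the recovery checks run at 400–2,000 cells per
  condition, where the planted effects are unambiguous.
* All tabular output is tab-delimited UTF-8 with a header and LF
  endings; readers tolerate CRLF. The pipeline writes a run log carrying
  every threshold and the seed, and a checksum manifest — two runs with
  the same config and seed are byte-identical, which is also the
  cheapest possible regression test for downstream consumers.
* Degenerate inputs have defined behaviour rather than NA surprises:
  zero-margin Fisher tables give p = 1 and a missing OR; constant genes
  give p = 1 in the marker test; empty QC output warns instead of
  erroring; unknown genes/clusters/conditions error with the offending
  name.

## Known limitations

Cluster labels are trusted as given — mislabelled clusters propagate
into every downstream table. The Fisher tests treat cells as independent
draws, which overstates confidence when cells within an animal are
correlated (a single pair of tumors cannot support animal-level
inference; that caveat applies to the reproduced analysis as much as to
this package). The interaction score has no null model by construction.
The marker finder's pseudocount conventions are stated, not sacred; any
serious comparison to a specific upstream tool should set its thresholds
explicitly.
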