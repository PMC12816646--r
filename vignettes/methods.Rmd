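---
title: "Methods: topology tests, compositional bias, and organelle MAG quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology tests, compositional bias, and organelle MAG quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leptokit)
```

# Scope

`leptokit` packages the statistical machinery used when a new
deep-branching organellar lineage is pulled out of marine metagenomes:
deciding where its plastid sits among the established algal groups,
checking whether that placement is an artefact of amino-acid
compositional heterogeneity, quality-controlling and dereplicating the
organelle genomes themselves, linking a candidate mitochondrial genome
to a plastid by coverage correlation, and comparing gene-content
evolution under competing host-tree scenarios. Every stage can be
exercised on synthetic data with known ground truth, so the whole
pipeline is testable on a desktop with no external programs or
downloads.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions that were genuinely open.

# Constrained-topology testing

## The chi-squared test with consensus-derived degrees of freedom

Two fully optimized topologies are compared by the likelihood ratio
statistic LRS = 2|lnL_a − lnL_b|. Because the competing trees are not
nested models in the usual sense, the reference distribution is taken
as chi-squared with degrees of freedom equal to the number of branches
collapsed in the strict consensus of the two trees: each collapsed
branch is one topological "parameter" on which the trees disagree. The
p-value is the upper tail at the LRS.

Multiple comparisons are handled by a Bonferroni-type correction over
the set of trees compatible with the strict consensus:
p' = 1 − (1 − p)^A, where A is the number of *fully binary* trees
compatible with the consensus, computed exactly as the product over
polytomies of degree d of (2d − 5)!!. Counting only binary resolutions
(rather than all partially resolved trees) matches the intent of the
correction — the competitors are fully resolved ML trees; this was an
open choice and is recorded here.

When one input tree is itself multifurcating, "branches collapsed" is
taken as the split count of the more resolved input minus the shared
split count; the `inputs_binary` flag in the result marks when the
clean binary-case identity (n − 3 − shared) applies.

`lrs_chisq_test()` refuses `df = 0` with a positive LRS: identical
topologies cannot differ in maximized log-likelihood under one model,
so that situation is a usage error, not a p-value.

## The AU test

The approximately unbiased test is implemented as the standard RELL
multiscale bootstrap: per-site log-likelihoods are resampled
multinomially at scales r ∈ {0.5, …, 1.4} (B = 10,000 replicates per
scale by default), the bootstrap proportion BP_r of each topology being
best is recorded, and probit(1 − BP_r) is regressed on d·√r + c/√r by
weighted least squares with the usual variance weights
B·φ(z)²/(BP(1 − BP)). The reported p is 1 − Φ(d − c). Scales with
degenerate BP (0 or 1) are excluded from the fit; if fewer than two
informative scales remain the p-value saturates at 0 or 1 and the
result is flagged `degenerate`. Exact ties in a replicate are split
uniformly among the tied topologies, which keeps BP unbiased and makes
the run deterministic given the seed; two topologies with identical
site log-likelihood vectors therefore get p = 0.5 each.

The rejection flags in `run_battery()` use alpha = 0.05 (configurable),
mirroring the single/double-asterisk convention of constrained-search
reports.

## The six constraint topologies

`build_constraint_set()` encodes the three candidate placements of the
leptophyte plastid clade within the cryptophyte–haptophyte–leptophyte
(CHL) group — sister to haptophytes+cryptophytes, to haptophytes only,
or to cryptophytes only — crossed with either constraining all
complex-plastid lineages to be monophyletic or leaving them free,
giving exactly six multifurcating constraint trees. Group interiors
are deliberately unresolved so only the named relationships are
constrained.

# The likelihood engine

The engine is a deliberately small fixed-topology evaluator so that the
test battery runs without external ML programs. It implements
Felsenstein pruning under reversible models Q = S·diag(π), scaled to
one expected substitution per site at equilibrium. LG and cpREV
exchangeabilities ship as plain-text files of the standard published
matrices; `poisson_model()` builds equal-rate models on arbitrary
alphabets (useful for recoded data and fast tests).

Numerical choices:

* transition probabilities via symmetric eigendecomposition of
  diag(√π) Q diag(1/√π), exact identity returned at t = 0;
* discrete gamma with m equal-probability categories, category rate =
  mean of its quantile bin, renormalized to mean exactly 1;
* the "+I" invariant-sites component is omitted (gamma-only), a
  documented limitation — the analyses the battery is aimed at use +G
  mixtures;
* gaps and ambiguity codes (B, Z, X, J, U, O) are missing data: partial
  likelihood 1 in every state;
* partial likelihoods run unscaled for speed (safe at the tens-of-taxa
  scale this engine targets) and any site whose likelihood underflows
  to zero is automatically recomputed with per-node log-scaling;
* optional PMSF-style fixed site-frequency profiles replace π per site
  class, keeping shared exchangeabilities.

Branch lengths are optimized coordinate-wise (golden-section via
`optimize()` on [0, 10], boundary 0 checked explicitly, tolerance 1e-6),
sweeping all branches until the log-likelihood improves by less than
1e-4 or 100 sweeps. All branches start at 0.1. The log-likelihood is
non-decreasing across sweeps by construction. Coordinate-wise search is
adequate here because topologies are fixed and the engine is used on
hundreds to a few thousands of sites; it is not a tree-search tool.

The engine is verified two independent ways in the test suite: against
exhaustive summation over internal-node states on trees with up to five
leaves (with transition matrices cross-checked against a generic matrix
exponential), and against an independent phylogenetics library on
simulated amino-acid data.

# Alignment treatments

## SR4 recoding

The four-class reduction AGNPST / CHWY / DEKQR / FILMV (class symbols
'1'–'4') dampens compositional heterogeneity and saturation. The class
membership follows the standard published four-class scheme; recoding
is idempotent and gap-preserving.

## Stuart's test and stationarity trimming

For a pair of sequences, the k×k table N of paired states over
co-ungapped sites is tested for marginal homogeneity with Stuart's
statistic W = dᵀV⁻¹d, where d holds the first k−1 marginal differences
and V the corresponding covariance matrix (V_uu = row_u + col_u −
2N_uu, V_uv = −(N_uv + N_vu)). Sparse tables are routinely singular,
so V is inverted by Moore–Penrose pseudo-inverse with df = numerical
rank (relative tolerance 1e-10) and the result flagged. W is invariant
to the order of the pair.

`stationary_trim()` is a greedy stand-in for stationarity-based
trimmers whose exact internals are not published: while any taxon pair
is significant at `alpha` (default 0.05, no cross-pair correction) and
less than `max_removed_fraction` (default 0.5) of columns have been
removed, it deletes the single column whose removal most reduces the
summed W over currently significant pairs (ties to the lowest index)
and retests. Columns only enter a pair's table through one cell, which
makes the per-column re-evaluation cheap. Because the procedure is a
documented stand-in, published site-removal counts from other trimmers
are not exact-match targets for it. Site indices are 0-based original
coordinates throughout, and the per-round log records the objective
before and after each removal.

# Compositional-bias classification

The five-step procedure feeding branch-specific frequency-shift models:
(1) per-taxon residue counts; (2) chi-squared test against the
independence expectation, keeping the Pearson residuals; (3) UPGMA on
Euclidean distances between residual rows, cut at the root into two
taxon groups; (4) per-residue two-sided exact binomial test of the
group-1 count among the pooled count with success probability equal to
group 1's share of all residues; (5) classification by the signed score
sign(f₁ − f₂)·(−log10 p) with threshold 2 (p ≤ 0.01).

Open choices, decided and fixed here: the score form (signed −log10 of
the exact binomial p; monotone in evidence and rank-consistent), the
threshold default of 2, Euclidean distance on residuals for the UPGMA
step, and group orientation (group 1 contains the alphabetically first
taxon) so "enriched" is reproducible. The binomial p-values are floored
at 1e-300 before taking logs. The class file format is two lines —
enriched then depleted residues, alphabetical, no separators.

# Organelle MAG quality control

* **Completeness/redundancy**: completeness is the percentage of
  marker genes present at least once; redundancy is the percentage of
  extra copies (sum over markers of copies beyond the first, over the
  set size). A genome is near complete when at least 40 of the 44
  plastid core markers are present. The 44-gene plastid core list and
  the 25-gene mitochondrial contamination screen ship as editable
  plain-text defaults — the lists are configuration, not hard-coded
  truth.
* **Dereplication**: genomes are redundant when ANI > 98 with aligned
  fraction of the smaller genome > 25 (both strict, matching the
  "greater than" wording of the thresholds); clusters are single-linkage
  connected components; representatives prefer reference genomes (the
  longest reference on ties), otherwise the longest genome,
  lexicographic id as the final tie-break.
* **k-mer ANI**: an internal estimator for fixtures and small studies —
  canonical 21-mer Jaccard similarity converted through the Mash
  distance D = −(1/k)·ln(2J/(1+J)), ANI = 100(1 − D), aligned fraction
  approximated by the shared-k-mer fraction of the smaller genome. It
  is an approximation, validated to land 3%-mutated sequences in the
  95.5–98.5 ANI band.
* **Detection rule**: a genome is detected in a sample only when more
  than 25% of its length is covered; mean coverage is zeroed at
  detection ≤ 0.25. The rule is idempotent, and whole-genome mean
  coverage (not covered-positions mean) is assumed.
* **Coverage linking**: ordinary least squares of candidate coverage on
  target coverage across samples, reporting R² and the two-sided t-test
  of the slope (df = n − 2), with no multiple-comparison correction, and
  computed both with and without the detection rule; candidates are
  ranked by the rule-off R², the variant such studies report.

# Gene content and Dollo parsimony

Presence/absence matrices come from ortholog tables (presence = copy
count ≥ 1); genes in fewer than 3 taxa are dropped by default,
mirroring the usual orthogroup filter. Taxa and genes are clustered by
UPGMA on Euclidean distances between binary vectors (Jaccard offered),
the common default of the heatmap tools used for such figures.

Dollo parsimony assumes each gene present at the origin (the root of
the supplied scenario tree) with no regain; the minimum loss count per
gene is then exactly the number of maximal clades whose leaves all lack
the gene, computed in one postorder pass and verified against
brute-force minimization over loss-edge subsets on small trees. A gene
absent everywhere scores one loss at the origin and is flagged, since
its single loss cannot be placed. Scenario comparison reports per-gene
and total losses under two host trees; treating the origin as the
scenario root records the single-plastid-gain assumption as the user's
modelling choice.

# Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, seeded and
bit-reproducible:

* `sim_alignment()` evolves sites down a known tree under the engine's
  own models with discrete-gamma rates; an optional compositional shift
  substitutes π′ ∝ π·exp(δ) into Q on every branch of a named clade
  (including its stem), so the shifted clade remains a proper Markov
  process rather than a post-hoc residue swap.
* `sim_genome_complement()` plants exact completeness/redundancy
  fractions, making the QC estimator exactly invertible.
* `sim_coverage()` draws per-genome log-normal coverage with planted
  latent-factor correlations for linked organelle pairs, a saturating
  noisy detection curve, and random dropouts below the detection
  boundary.
* `sim_dollo()` drops genes by Poisson loss events along branches and
  records the true event count, which upper-bounds the parsimony
  estimate.

These generators deliberately do not emulate alignment error, indels,
model misspecification (e.g. site-heterogeneous composition within
groups), read-level noise, or assembly chimerism. A green test battery
therefore demonstrates correctness of the statistics under their own
assumptions, not robustness of the original biological conclusions to
real-data pathologies.

# Problem sizes used in the shipped checks

The shipped test suite and the acceptance script run entirely on
synthetic data at desk scale, chosen as the smallest sizes at which the
statistical behaviour is clearly visible: 8-taxon, 500-site alignments
for the null calibration of the corrected chi-squared test
(200 replicates on the unresolved consensus of an NNI pair — the null
where both resolutions are equally right); 10-taxon, 800-site
alignments over the six constraint topologies for end-to-end battery
recovery (20 seeds); 4-state equal-rate models for speed in the
simulation-heavy checks, with the 20-state LG model exercised in the
engine verification and compositional-bias checks; 35 genomes × 120
samples for organelle linking (one planted pair among 33 decoys,
matching the one-true-candidate-among-34 setting); full enumeration of
all unrooted binary topologies on 5 and 6 taxa for the consensus and
resolution-count oracles.

# Known limitations

* The engine has no +I component, no mixture-weight estimation, no
  heterotachy, and box-constrains branch lengths to [0, 10]; it is a
  verification harness, not a tree-search program.
* The stationarity trimmer is a documented greedy stand-in; its removal
  set need not match other implementations column-for-column.
* UPGMA inherits `hclust`'s deterministic tie handling, which may
  differ from smallest-pair-index tie-breaking on exactly tied merges.
* The k-mer ANI estimator underestimates the aligned fraction for
  diverged genomes and is not a substitute for alignment-based ANI on
  real data.
* The compositional-bias score reproduces a rank-consistent
  enriched/depleted partition; exact class agreement with other scoring
  scripts is not guaranteed and not claimed.
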