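---
title: "Multi-omics signaling analysis of macrophage polarization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics signaling analysis of macrophage polarization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`macsig` implements a desk-scale, fully testable version of a multi-omics
analysis of macrophage polarization states (proinflammatory M1 versus
immunosuppressive M2a/M2c phenotypes): label-free (phospho)proteomics
differential analysis with a PTM-versus-protein adjustment, kinase-activity
footprint inference, cross-dataset consensus of bulk RNA-seq results,
integrative protein-interaction network analysis with current-flow
betweenness and module decomposition, and signature-based classification of
single-cell macrophages. A seeded synthetic-data generator supplies inputs
with the statistical structure each stage assumes, together with the planted
ground truth that the test suite uses for recovery checks.

```{r, eval = FALSE}
library(macsig)
report <- run_pipeline(NULL, outdir = "macsig_out")
```

# Proteomics and phosphoproteomics preprocessing

**Cleaning.** Proteome tables drop contaminants, decoy (reversed-sequence)
matches, and protein groups with fewer than 2 measured peptides
(`clean_proteome()`). Phosphosite tables drop non-phosphorylated peptides,
contaminants and decoys, and keep features with at least 2 measurements in at
least one condition (`clean_phospho()`). The *motif set* additionally
requires a localization probability strictly above 0.75 (class I sites);
only those sites enter kinase-motif analyses, because below that confidence
the phosphorylated residue itself is uncertain. Phosphopeptides carrying
one, two or three phosphogroups are treated as separate features throughout
(the feature key is the pair of site id and multiplicity).

**Transformation.** Intensities are log2-transformed and mean-centered per
feature across all samples (`log2_center()`). Centering per feature (rather
than per sample) was an open choice; per feature was adopted because the
differential tests operate on within-feature contrasts and per-feature
centering leaves them untouched while making the imputation reference scale
comparable across features.

**Imputation.** Missingness in label-free data is left-censored: low-abundance
measurements fall below the detection limit. `impute_missing()` uses a
two-tier downshifted-normal scheme applied per condition. Let mu and sigma be
the mean and SD of the present log2 intensities of the *sample* (column) in
which the missing entry lies. If the feature is measured in more than 50% of
that condition's replicates, the entry is drawn from
Normal(mu − 0.5 sigma, (0.3 sigma)^2) — the feature is detectable and the
missing value is likely just below the limit. If measured in 50% or fewer
(including none), it is drawn from Normal(mu − 1.8 sigma, (0.3 sigma)^2) —
the feature is plausibly absent in that condition. The boundary is strict:
exactly half measured falls in the deep-shift tier.

The reference statistics are per-sample rather than per-feature because a
per-feature SD is undefined for a condition that was never measured, which
the scheme explicitly must impute; a `reference = "feature"` switch is
provided. Draws are consumed in row-major order (feature, then sample), so a
given seed yields a bit-identical matrix regardless of storage layout.

# Differential testing and the PTM adjustment

`moderated_ttest()` performs pooled-variance two-sample t-tests per feature.
With `moderation = "on"` (default), feature variances are shrunk toward an
empirical-Bayes prior estimated from the distribution of all feature
variances by moment matching on the log variances (Smyth's method, via
limma's `squeezeVar`), and the residual degrees of freedom are augmented by
the prior degrees of freedom. With 4 replicates per condition the residual
df is 6; moderation borrows strength across features and stabilizes the
denominator. P-values are BH-adjusted over the family of all tests of one
omics layer (all contrasts and multiplicity classes jointly), and
significance requires an FDR strictly below 5% together with an absolute
log2 fold change of at least 1. Sites whose multiplicity classes are
*significantly* regulated in opposite directions are removed entirely
(`reconcile_multiplicity()`); discordance with a non-significant opposite
class is tolerated, since the non-significant direction may be noise.

**PTM adjustment.** A phosphopeptide can change either because its
phosphorylation changed or because its parent protein's abundance changed.
`adjust_ptm()` tests the difference of the two fold changes:

t = (log2FC_ptm − log2FC_protein) / SE, with
SE = SP sqrt(1/df_protein + 1/df_ptm) and
SP^2 = (SE_protein^2 (df_protein − 1) + SE_ptm^2 (df_ptm − 1)) /
(df_protein + df_ptm − 2).

The two-sided p-value uses df_protein + df_ptm − 2 degrees of freedom (the
natural df of the pooled-SD construction), and BH correction at 5% across
all adjusted tests defines the `phospho_driven` flag. Two design choices
deserve note:

* The df entering SP and SE are the *residual* df of each t-test
  (n_a + n_b − 2). The moderated df can be prior-inflated (in the limit,
  infinite when the variances are consistent with a single prior), which
  would drive SE to zero; the moderated df therefore serves only the
  site-level p-values.
* Sites whose protein was not quantified pass through with
  `phospho_driven = TRUE` and a `no_protein_evidence` flag: absence of
  protein evidence cannot demonstrate abundance driving, and dropping such
  sites would discard exactly the low-abundance regulatory proteins of
  interest.

**Keep rule.** For every protein with at least one phosphorylation-driven
site, *all* of that protein's raw-significant phosphopeptides are kept for
downstream analyses (`apply_keep_rule()`): once one site shows regulation
beyond abundance, the protein's phosphorylation state as a whole is of
interest.

**A calibration caveat.** The pooled SE above is not the sampling SD of the
fold-change difference (which is sqrt(SE_protein^2 + SE_ptm^2)); with equal
SEs and df = 6 it is smaller by a factor of about 2.4, so the adjusted t is
anticonservative and the `phospho_driven` flag is liberal. The test suite
therefore asserts what the construction can deliver — essentially all
planted phosphorylation-driven sites are flagged, and the adjusted statistic
for protein-abundance-driven sites is centered at zero — rather than a
false-positive rate the statistic does not control. Downstream stages
intersect the flag with raw significance (the keep rule) before any
biological interpretation, which restores practical specificity.

# Kinase-activity inference

A kinase's *footprint* is the set of measured class I phosphosites it is
known (curated relations) or predicted (family-level site predictions) to
recognize. `enrich_curated_substrates()` builds, per kinase, the 2x2 table
of upregulated versus other measured sites crossed with recognized versus
not, and applies a two-sided Fisher's exact test. "Two-sided" follows the
point-probability convention (the sum of the probabilities of all tables at
the observed margins that are no more probable than the observed one) —
conventions differ, so this is stated explicitly; it is the convention of
R's `fisher.test`. A kinase is called upregulated when p < 0.05 *and* the
odds ratio exceeds 1 (a depleted footprint also yields a small two-sided p,
but does not indicate activity). No multiple-testing correction is applied
to the curated analysis by default (a `correct` switch exists); the
family-level analysis (`enrich_predicted_families()`) is BH-corrected and
additionally requires at least 10 upregulated substrates, since family
predictions are noisier and families recognize many sites.

Site predictions are filtered (`filter_site_predictions()`) to posterior
probability > 0.035, posterior greater than the prior, and the top 3
families per site by posterior; ties at rank 3 are all kept, so the result
does not depend on storage order.

`build_signaling_network()` assembles a directed kinase-kinase / kinase-TF
graph. An edge is drawn only when the target protein carries an upregulated
phosphosite that the source kinase recognizes (exact-site rule); edges carry
their evidence class. Unmeasured kinases enter only as bridges between an
upregulated kinase and another measured kinase; in the large-network mode,
measured non-upregulated kinases enter only when they connect two or more
upregulated kinases.

# Over-representation analysis

`hypergeometric_ora()` is a single ORA engine shared by the phospho,
network-module, transcriptome and single-cell stages: upper-tail
hypergeometric p-values against an *explicit* background (no genome-wide
default), BH-corrected across sets. An EASE-style variant (overlap minus
one) is available for compatibility with modified-Fisher conventions.
`prune_and_filter()` then walks the results from most to least significant
and retains a set only if it is significant, has enough hit members, is not
oversized, and contributes at least 2 hit members not already covered by a
previously retained set. "Covered" counts hit members only — a pruning
decision should depend on what the sets explain about the hit list, not on
their full membership. Stage defaults: phospho and modules 5 hits / 300 max
size; transcriptome and single-cell hallmark stages 2 hits with no size cap.

# Bulk consensus and the integrative network

`consensus_de()` reproduces the cross-study consensus logic: a gene must be
expressed above the dataset median in at least 3 datasets of the phenotype,
significant per dataset (adjusted p < 0.05 and fold ratio above 4), and
significant in at least 3 datasets overall; a union mode covers the
two-study comparison. Direction consistency across datasets is recorded but
not required. `consensus_dtu()` keeps genes with transcript-usage evidence
in at least half of the comparisons.

`merge_interactions()` merges the three interaction sources: combined-score
and confidence-scored lists are cut strictly above 0.7; the
physical-interaction list only requires a confidence value to be present
(its scores are not comparable to the other two). `build_integrative_network()`
keeps edges whose both endpoints are significant in at least one omics
layer, drops connected components in which more than 75% of nodes carry
only transcript-usage evidence (applied per component — the rule's target
graph was an open question, and per-component application is what makes a
"network composed exclusively of DTU hits" well-defined), and returns the
largest remaining component.

**Current-flow betweenness** (`current_flow_betweenness()`) treats the
network as a resistor network: for every source-target pair a unit current
is injected and extracted, edge currents follow from the graph Laplacian,
and a node's score is its total current throughput over all pairs
(endpoints excluded, unnormalized — the downstream use is a top-30% ranking,
which normalization cannot change). The implementation grounds one node and
solves the reduced Laplacian once, then accumulates per-pair edge currents
with a sparse node-edge incidence product. On trees the measure coincides
with shortest-path betweenness (all current takes the unique path), which
the tests exploit as an oracle alongside a dense per-pair solver.

**Module decomposition** (`detect_modules()`) uses seeded multi-level
(Louvain) modularity optimization with a resolution sweep. The
average-degree parameter of the original module extractor is interpreted as
a density constraint: among sweep partitions whose mean within-module degree
reaches the target (default 10), the one with the highest standard
modularity is kept; when even the whole graph is sparser than the target the
constraint cannot bind and the best-modularity partition is used. Modules
are reported sorted by size, with those under 10 members flagged
sub-threshold rather than silently dropped.

# Single-cell classification

Quality control (`qc_filter()`) removes cells with fewer than 500 or more
than 9000 expressed genes, cells with more than 10% mitochondrial counts,
and then genes expressed in fewer than 3 surviving cells. Counts are
normalized per cell to 10,000 and natural-log transformed as ln(1 + x)
(`normalize_log()`); the log1p form keeps zeros at zero, where a bare
logarithm would be undefined.

`score_signature()` computes a control-matched signature activity per cell:
all genes are binned into 24 equal-frequency bins by average expression
across the analyzed cells (macrophage-subset binning; ties broken by
average-expression rank then lexicographic gene id, for determinism), and
each signature gene is compared against the mean of 100 control genes drawn
from its own bin (with replacement when a bin holds fewer than 100 genes —
small bins are not covered by the original description, and sampling with
replacement preserves the bin's expression profile). The per-cell score is
the mean over signature genes of (gene expression − control mean).

`classify_macrophages()` assigns M1-like when the M1 score is the larger
and positive, M2-like symmetrically, and Na (unknown) when neither score is
positive. A score of exactly zero counts as non-positive (the boundary was
unstated; zero signals indistinguishability from the control draw, which is
the Na semantics), and an exact positive tie is Na with a tie flag. A
single-marker mode (`classify_by_marker()`, e.g. CD163) assigns M2-like on
any expression by default, with a threshold sweep available.

`sc_differential_expression()` tests genes expressed in at least 10% of
either group with pooled-variance (Student) t-tests on the normalized
values, Bonferroni-corrected over the tested genes; significance requires
adjusted p < 0.05 and average log2FC > 0.75 (one direction, as the rule is
printed). The average log2FC is computed as the difference of
log2(mean(expm1(x)) + 1) between groups, i.e. on de-logged means, matching
the convention of the single-cell toolkit this step emulates; a
difference-of-means variant is a documented alternative.

# The synthetic-data generator

Each generator is a pure function of its parameters and seed.

* `gen_phosphoproteome()`: per-protein baseline log2 intensities
  Normal(25, 2) (a realistic label-free dynamic range, so the two imputation
  tiers both matter), phosphosites nested in proteins, two conditions with 4
  replicates by default. Substrates of active kinases shift by
  `effect_log2` at the phospho level only; a *disjoint* protein set shifts
  at the protein level and propagates to its sites — every planted effect
  has exactly one mechanism, which is what makes adjustment recovery
  testable. Missingness is logistic left-censoring in true log2 intensity.
* `gen_bulk_de_tables()`: six studies by default; truly differential genes
  reach per-dataset significance independently with probability
  `concordance` = 0.9, nulls at a 1% false-positive rate; expression tables
  place true genes in the upper half so the median prefilter passes them;
  transcript-usage calls are emitted per dataset the same way.
* `gen_interaction_network()`: stochastic-block-model graph (4 blocks of 40,
  p_in 0.3, p_out 0.01 by default — within-block degree about 11.7), edges
  distributed over the three source roles with a 20% fraction drawn to fail
  the confidence rules.
* `gen_single_cells()`: negative-binomial counts over log-normal gene means
  and log-normal library-size factors; planted M1-like/M2-like cells have
  their signature genes' means multiplied by 2^shift (default 1.5);
  planted QC failures (mitochondrial outliers, collapsed libraries)
  exercise the filters.

What the generator does *not* emulate: correlated co-regulation beyond the
planted structure, peptide-level identification artifacts, batch effects,
ambient RNA or doublets, and any real biological pathway structure. Passing
recovery tests therefore demonstrates that the statistical machinery is
implemented correctly and recovers planted structure under its own model
assumptions — not that the pipeline's biological conclusions on real data
are correct.

# Problem sizes and determinism

The default pipeline configuration runs 300 proteins x 2 sites, 4v4
replicates, 6 bulk datasets of 2000 genes, a 160-node interaction graph and
600 cells x 1500 genes — sizes chosen so a full run finishes in seconds and
the complete test suite in about a minute on a single core, while every
stage still has enough features for its thresholds to bind. All stage seeds
derive from the single config seed by fixed offsets; two runs with the same
config produce byte-identical outputs, and the JSON run report carries the
resolved-config hash for provenance.

# Known limitations

* The PTM-adjustment SE is anticonservative by construction (see above);
  its flag should be read as a screen, not an error-controlled test.
* The curated-substrate Fisher analysis is uncorrected for multiple testing
  by default (a documented switch enables BH), mirroring the p < 0.05 rule
  it reproduces.
* Symbol matching is case-sensitive and exact; alias resolution is out of
  scope.
* The module extractor approximates an external tool's average-degree
  parameter by a resolution sweep; the achieved mean within-module degree is
  reported alongside the partition rather than guaranteed.
* The pipeline orchestrator currently drives synthetic inputs end to end;
  individual stages accept user data through the documented readers.
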