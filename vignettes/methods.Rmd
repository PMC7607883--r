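---
title: "Methods: discordance census, curation and the quartet mixture estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordance census, curation and the quartet mixture estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalcensus)
```

# Scope

`coalcensus` implements a complete desk-scale analysis of gene-tree
heterogeneity in a BUSCO-based phylogenomic dataset: curation of the
per-gene ortholog sets, quality control of the gene trees, a census of
rooted topologies with respect to subfamily monophyly, and a coalescent
mixture estimator that separates incomplete lineage sorting (ILS) from
introgression in a four-taxon reduction. A multispecies-coalescent (MSC)
simulator with one optional reticulation generates all test data, so the
whole pipeline is verifiable without external downloads or external
inference software.

# Ortholog curation

## Intersection of Complete genes

`collect_complete_orthologs()` retains exactly the genes scored
`Complete` in every taxon's BUSCO table *and* present in every taxon's
FASTA. Everything else is kept in the table's `removed` ledger with a
reason (`not_complete_in:<taxon>` or `missing_sequence:<taxon>`), so
downstream counts are always reconstructible. Statuses outside
`{Complete, Duplicated, Fragmented, Missing}` are a hard error: BUSCO
table dialects differ, and silently mapping unknown tokens would corrupt
the intersection.

## Reading-frame correction

BUSCO sometimes extracts a CDS starting at frame +2 or +3. For each
sequence `fix_frame()` evaluates the three possible leading offsets,
trims the trailing remainder so output length is divisible by three (the
downstream codon-aware steps assume whole codons), and picks the offset
with the fewest internal stop codons. Ties are broken in a fixed order:

1. presence of a terminal stop codon (a real CDS usually ends in one);
2. highest identity between the candidate translation and an optional
   reference protein;
3. the smallest offset.

Codons containing `N` never count as stops — an ambiguous base must not
doom a frame. If the best offset still contains internal stops the cell
is flagged `unfixable`; `fix_table_frames()` then (by default) removes
the gene, since a CDS that cannot be framed cleanly is evidence of a
deeper annotation problem.

## Protein-size CV filter

Orthologs whose protein sizes differ wildly across taxa usually reflect
mis-annotation. `cv_filter()` computes, per gene, the coefficient of
variation of `protein_length()` (`floor(len/3)`, minus one for a
terminal stop) across taxa and removes genes with CV strictly above the
threshold (default 0.10). Two conventions had to be fixed because the
filter's description alone does not determine them: the standard
deviation is the *sample* flavor (n − 1), and the boundary is strict —
a CV of exactly 10% is retained. A one-taxon table is rejected (CV is
undefined), and an all-zero mean length is an error rather than a
division by zero.

# Gene-tree quality control

Two per-tree statistics drive outlier removal:

* **SBL**, the sum of branch lengths (substitutions/site summed over
  edges) — rooting-independent, inflated by frame errors and paralogs;
* **root-to-tip variance**, the sample variance of root-to-leaf path
  lengths — a rate-heterogeneity and misannotation diagnostic that *does*
  depend on the rooting.

`root_on_outgroup()` roots on the outgroup clade's stem edge, splitting
its length equally (the split point is unidentifiable from the tree, so
the midpoint is the symmetric choice). When the outgroup is not
monophyletic the tree is rooted on the first outgroup taxon's terminal
edge and flagged; such trees still receive a root-to-tip variance from
the fallback rooting rather than being discarded at this stage — they are
diagnosed, not silently dropped, and the census records them in a
separate column.

`filter_outliers()` removes the union of the top `1 - q` tails of both
statistics (default `q = 0.95`). The tail is the nearest-rank top
`ceiling((1-q) n)` per criterion; ties are resolved by stable ordering.
When `(1-q) n < 1` nothing is removed and a warning is issued — a 5%
rule on a handful of genes would remove an arbitrary gene. The union
therefore removes between `k` and `2k` genes, with equality at `k`
exactly when the two criteria select identical sets. An epsilon guard
(`1e-9`) around the integer boundary protects the rank computation from
floating-point noise (`0.05 * 20` is not exactly 1 in binary).

`flag_long_terminal_branches()` flags taxa whose terminal branch exceeds
`k` times the tree's *median* terminal branch (default `k = 10`); the
median is used precisely because the outlier being screened for would
contaminate a mean. Absolute-SBL thresholds are deliberately not a
filter here: they are exposed in the QC table for inspection, while the
operative filter is the quantile rule.

# Topology census

`classify_topology()` assigns each outgroup-rooted tree one of the
labels `A`, `B`, `C`, `E`, `F`, `other_para_steg`, `dros_para`,
`unclassifiable`, checked in a fixed order: Drosophilinae paraphyly
first; then, with Steganinae monophyletic, the three possible pairings
within Steganinae (`A` = the species-tree pair, `E`/`F` the
alternatives); then the two structured paraphyly classes (`B`: the pair
clade is sister to Drosophilinae to the exclusion of the basal
candidate; `C`: the basal candidate is sister to Drosophilinae). All
remaining paraphyletic arrangements are pooled into `other_para_steg`;
the per-gene table carries a canonical newick of the genus-collapsed
topology as a detail column for anyone needing the sub-classes.
Cladehood is an exact leaf-set match against the rooted tree's nodes;
an exhaustive test verifies agreement with brute-force bipartition
enumeration on all 945 rooted six-leaf trees.

The four-taxon reduction (`prune_to_quartet()`) restricts a tree to four
representative taxa and reports which ingroup pair is sister after
rooting on the outgroup representative: `match`, `mismatch_PD` or
`mismatch_RD`. Only three classes exist, and the classification is a
function of the unrooted quartet split, so it commutes with pruning — a
property the tests check directly.

`symmetry_test()` is the exact two-sided binomial test of equal mismatch
frequencies (H0: p = 1/2), summing all outcome probabilities not
exceeding the observed outcome's. The underlying expectation names no
particular test; the exact binomial is the minimal assumption-free
choice at these counts. `stratify_by_muller()` tests homogeneity of the
three quartet classes across Muller elements with a chi-square test; any
expected count below 5 switches to a Monte-Carlo p-value with a fixed
seed (default 1) and 10,000 permutations, so sparse tables stay both
valid and reproducible. Unmapped genes are excluded from the test and
reported.

# The synthetic-data engine

## What it emulates

`simulate_gene_tree()` runs the standard MSC: one haploid lineage per
species (matching a one-genome-per-species design), coalescence at rate
`j(j-1)/2` within each species-tree branch (coalescent units, time/2N),
survivors passed rootward, full coalescence in the root population. On a
`species_network()`, each lineage present on the recipient edge at the
reticulation age independently switches to the donor population with
probability γ — instantaneous admixture at a point, the standard
network-MSC convention. Zero-length internal branches (simultaneous
divergences) are handled by breaking age ties child-before-parent in the
merge schedule.

`evolve_jc69()` (via `phangorn::simSeq`) provides Jukes-Cantor sequences
and `infer_nj_tree()` re-infers trees from JC-corrected distances with
neighbor joining, with saturated pairs (`p >= 3/4`) capped at a
configurable distance (default 5 substitutions/site). This is a
deliberately light stand-in for maximum-likelihood inference: it
reproduces the qualitative behavior the pipeline needs (branch-length
inflation under artifacts, topology recovery at long branches) at a
vanishing fraction of the cost.

`inject_artifacts()` mimics the two documented BUSCO failure modes:
frame shifts (one or two random bases prepended to a sampled fraction of
gene-taxon cells) and paralog substitution (one taxon's sequence
re-evolved along an extra branch, default 1.5 expected
substitutions/site — an order of magnitude above the typical terminal
branch at the default benchmark settings). Every injection is recorded
in a ground-truth ledger, which is what makes the curation benchmark an
oracle test rather than a plausibility check.

## Calibration of the default models

The defaults *are* the study conditions. `quartet_network()` defaults to
`T = 0.734`, `γ = 0.390`: the moment inversion of the published quartet
topology percentages (47.7 / 36.3 / 16.0). The ten-taxon
`drosophilid_species_tree()` keeps that Steganinae stem (0.734
coalescent units) and sets the remaining branches once, from coarse
closed-form reasoning rather than fitting: the Phortica+Cacoxenus stem
at 3.1 units so alternative Steganinae pairings are rare (a fraction of
a percent each), a compact Drosophilinae crown under a long stem so
subfamily paraphyly stays around a percent, and a deep outgroup. The
reticulation (`drosophilid_network()`, γ = 0.390) runs from the
ancestral Drosophilinae lineage into the Phortica+Cacoxenus stem at the
Steganinae crown age, mirroring the four-taxon model. The quartet class
distribution depends only on (T, T′, γ), not on the pair age or outgroup
depth, which is why the four-taxon calibration transfers.

The benchmark's sequence settings (300 sense codons per gene,
substitution rate 0.02 per site per coalescent unit, so roughly 0.19
substitutions/site root-to-tip) are chosen once as realistic for
conserved single-copy orthologs. One departure from the bare JC model is
deliberate: internal stop codons arising during the codon-blind
simulation are repaired to sense codons at the tips, standing in for the
purifying selection that keeps real coding genes open — without it,
"true reading frame" would be ill-defined for a sizable fraction of
genes and the frame-recovery oracle would be vacuous.

## What passing tests do and do not show

The generator omits recombination, substitution models beyond JC69,
rate variation across sites, alignment error and ML tree inference.
Passing the round-trip tests therefore shows the *pipeline logic* is
correct under its stated model, not that real drosophilid data meet the
model. In particular the census on real trees inherits whatever biases
the upstream alignment and ML inference carry.

# The mixture estimator

Three observed frequencies cannot identify three parameters (T, T′, γ)
plus the labeling; `fit_quartet_mix()` therefore fixes `T′ = T`. This is
parsimony, not biology — nothing in a quartet census pins down a second
timescale — and it is the reason the resulting γ̂ is **not comparable**
to inheritance probabilities from network pseudolikelihood analyses of
the same data, which resolve the reticulation's age from richer
information. The major mismatch class is taken from the data (labeling
convention `f_major >= f_minor`); biological directionality of the gene
flow is not inferred.

Moment inversion is exact: two free frequencies, two parameters, so
`predict()` reproduces the observed frequencies to machine precision
whenever the preconditions hold (`f_minor` in (0, 1/3]; equality of the
mismatches returns the pure-ILS submodel with γ̂ = 0). Frequencies with
`f_match < 1/3` or `f_minor > 1/3` are *anomalous* — inconsistent with
any (T, γ) in this family — and raise errors rather than being clamped.
`f_match = 1` returns an infinite-T flag. Standard errors come from a
nonparametric bootstrap (multinomial resampling of gene-level labels,
default 200 replicates): assumption-light, and consistent with treating
genes as the independent sampling unit. Replicates falling outside the
preconditions are dropped from the summaries rather than clamped, which
slightly understates uncertainty near the boundary.

`simulate()` on a fitted object regenerates topology counts through the
actual MSC network simulator, not the closed form, so fit and simulator
cross-validate each other; the test suite checks simulated frequencies
against the closed form at several T values within three binomial
standard deviations at n = 30,000, and parameter recovery within three
bootstrap standard errors at n = 50,000.

# Problem sizes and reproducibility

The shipped tests use n = 30,000 gene trees for the simulator-vs-closed
form checks, 100 seeded replicates of n = 1,000 for the symmetry null,
n = 50,000 for parameter recovery, and a 200-gene, 10-taxon benchmark
for the curation oracle; these sizes put the Monte-Carlo noise well
below the assertion tolerances while keeping the whole suite in the
minutes range. All randomness flows through R's global RNG via explicit
seeds; `run_pipeline()` writes a manifest (config hash, seed, package
version) and reruns with the same triple reproduce artifacts
byte-identically.

# Known limitations

* One reticulation at most, and γ̂ depends on the `T′ = T` restriction.
* JC69 only; no codon model despite codon-aware bookkeeping in the
  curation stage.
* `root_to_tip_variance` on non-monophyletic-outgroup trees uses the
  fallback rooting; a different rooting convention would shift those
  genes' ranks in the outlier filter.
* The internal newick/FASTA handling is deliberately thin (plain FASTA,
  single-tree-per-line newick); NEXUS and alignment formats are out of
  scope.
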