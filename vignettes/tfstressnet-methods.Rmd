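---
title: "Models and methods in tfstressnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tfstressnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfstressnet)
```

This vignette explains the models behind each pipeline stage, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made where the
design was genuinely open.

## Family classification rules

TF families are called from domain-hit tables (the output of an upstream
Pfam/SMART-style scan, which is outside this package's scope). A family needs
one qualifying signature hit with E-value below the cutoff (default `1e-5`):
AP2 → AP2/EREBP, bZIP_1/bZIP_2 → bZIP, MYB → MYB, NAM → NAC, WRKY → WRKY.
Subfamilies come from domain counts: two AP2 domains → AP2; one AP2 plus B3 →
RAV; a lone AP2 is left as `EREBP-unresolved`, because the DREB/ERF split and
their lettered subgroups are clade assignments that require a phylogeny — the
package consumes them as optional annotations rather than computing them. MYB
repeat counts 1–4 map to 1R/R2R3/3R/4R. WRKY calls are deliberately strict:
a WRKY domain alone is rejected without a zinc-finger motif, matching the
biology (the DNA-binding fold needs the finger) and the practice of pruning
mis-annotated database entries. The accepted degenerate WRKY cores are WRRY,
WSKY, WKRY, WVKY, WKKY and WKNY; anything else is not a WRKY hit. Zinc-finger
typing (C2H2 vs C2HC, which separates groups I/II from III) is read from the
hit table's `variant` field, not re-derived from sequence.

Chromosome-distribution comparisons use the χ² homogeneity test on the pooled
margins, without Yates correction — every real comparison has more than two
categories, and the continuity correction would only bias the 2-category
degenerate case used in unit tests. Zero-pooled chromosomes are dropped
(logged) since they contribute no information and would break the expected
counts. Count-vector clustering uses 1 − Pearson correlation with average
linkage; a constant row has no defined correlation and is placed at distance
1 from everything, which is the agnostic choice.

## Cis-element scanning

Promoters are fixed 1500-bp windows upstream of the TSS. Motifs are IUPAC
consensus strings compiled to regular expressions; a zero-width lookahead
makes overlapping occurrences visible. Two decisions matter here. First, an
`N` in the *sequence* never matches a non-N consensus code: an unknown base
is evidence of nothing. (Biostrings' ambiguity matching lets a subject N
match every code, which is why the scanner is hand-rolled.) Second, both
strands are scanned by default, implemented by scanning the
reverse-complemented consensus on the forward sequence so all positions stay
in forward coordinates. The shipped motif table is configuration, not ground
truth: public element definitions vary between databases, and the table
should be replaced for real promoter sets. Distribution summaries count a
gene once per motif regardless of hit multiplicity — occurrence-weighted
counting is a defensible alternative, but presence/absence is the
interpretation that matches per-family "proportion of genes" plots.

## Synteny categories

Calls are made purely from homologous-set membership: novel (focal gene, no
ancestor member), conserved (exactly one copy in the focal species and in
each of the two ancestors), multi-copy (any member species contributes ≥ 2
copies), lost (ancestor gene in a set with no focal member, attributed to
that ancestor's sub-genome). Outgroup members are carried for reporting but
never affect the logic. Two open points were decided: when a set is both
ancestor-free and multi-copy, multi-copy wins (ancestral absence with a
*single* focal copy is what "novel" means) and the case is flagged; and a
focal gene fitting no definition (single copy, only one ancestor present) is
returned as `unclassified` rather than forced into a category — the
partition property then holds exactly on generated data, where such sets do
not occur, without lying about real data. Summary fractions are reported
under two definitions (unweighted mean of per-family fractions, and pooled
counts) because the two disagree in general and the source material mixes
them; the package does not force agreement.

## Differential expression

Relative expression is log2((mean treatment FPKM + c)/(mean control FPKM +
c)) with pseudocount c = 1 FPKM, which bounds fold changes at zero counts
without materially distorting genes expressed above a few FPKM. The DE
probability is a simplified noise-distribution analogue, not a
re-implementation of NOIseq: per gene, signal M = |log2 ratio of condition
means| and D = |difference of condition means|; the noise cloud pools (M, D)
over every within-condition replicate pair across all genes; the probability
is the fraction of noise points *strictly* dominated in both coordinates.
This keeps the defining monotonicity (probability nondecreasing in M and D),
is exactly enumerable on toy fixtures, and needs only ≥ 2 replicates in some
condition. Probabilities computed elsewhere can be supplied from file. The
DEG rule is probability ≥ 0.6 and |log2FC| ≥ 1, both boundaries inclusive —
the fold-change boundary is stated inconsistently ("greater than" vs "≥") in
the source material; the inclusive reading governs the reproduced counts, and
a switch (`inclusive_fc = FALSE`) provides the strict one. A log2FC of
exactly 0 gets no direction (it cannot be a DEG anyway). Crucial-DEG
selection is an explicit configured list of stimulus-response BP terms or
name keywords; the shipped default list is a labelled reconstruction of a
manual curation step, and an empty list is an error rather than a silent
pass-through.

## The grey correlation co-expression network

The grey correlation coefficient (GCC) is designed for very short profiles —
here n = 5 treatments, where Pearson or Spearman estimates are unstable. For
reference x₀ and comparison xᵢ, with global extrema of |x₀(k) − xᵢ(k)| taken
over the whole comparison set of that reference,

ξᵢ(k) = (gmin + ρ·gmax) / (|x₀(k) − xᵢ(k)| + ρ·gmax),  r₀ᵢ = mean over k.

ρ = 0.5 is the conventional resolution ratio: smaller ρ sharpens the
contrast between small and large deviations, larger ρ flattens it. Because
the extrema are recomputed per reference row, the matrix is asymmetric.
Numerical choices: the reference is excluded from its own comparison set
(the standard grey-relational convention; including it forces gmin = 0
always, which changes nothing when some comparison profile ties the
reference, as planted clusters guarantee, but would silently alter isolated
rows); if gmax = 0 the whole comparison set is identical to the reference
and ξ ≡ 1 by convention; and when each row's minimum deviation is 0, all
entries lie in [1/3, 1] at ρ = 0.5. The network rule is OR + max: an
undirected edge when either direction reaches τ, weighted by the larger
coefficient, with a per-edge reciprocal flag. This reading reconciles a
directed-edge count of 2·(reciprocal) + (one-directional) with the
undirected pair count, so both counts are always reported. τ = 0.94 is the
sparsity-preserving default. The GCC input is the relative-expression
matrix, not raw FPKM, and no pre-normalization is applied (a min–max option
exists but is off by default); the statistic is translation-invariant by
construction.

## Process–gene projection and enrichment

The bipartite gene↔GO-BP graph is projected onto genes; the edge weight is
the shared-term count, so Σ weights = Σ_terms C(k_t, 2) — an identity the
tests exploit. Enrichment is the one-sided hypergeometric upper tail with
Bonferroni adjustment over the tested terms; "tested" defaults to terms with
at least one foreground gene (testing unobservable terms only dilutes the
correction; a switch tests all annotated terms). Significance is inclusive
at the adjusted 0.05. Annotations are used as given — no ontology ancestor
propagation, which would require an ontology graph the pipeline does not
consume.

## Regulatory network analysis

DEG labels transfer across a many-to-many homology map by OR over partners,
and the transfer is monotone (adding pairs never removes labels). Triangle
motifs are counted on the underlying undirected skeleton, with directed
orientation (cyclic / feed-forward / with-mutual-edges) reported separately,
because "triangle motif" in the source usage mixes orientations; reporting
both avoids guessing one definition. Network intersection symmetrizes
directed inputs (with a message) and intersects edge sets.

## The synthetic-data generator

The generator states a world and the tests measure recovery in it. It
emulates: five families with rule-consistent domain architectures (so
classification recovery is exact by construction — a green test establishes
the rules are implemented faithfully, not that real annotations are clean);
a 10 + 9 chromosome layout with ~19% unanchored genes; 1500-bp promoters
with motifs planted at recorded forward-strand positions, where background
occurrences are scrambled away so gene-level presence matches the planting
table (a property real promoters do not have — real scans include chance
hits); homologous sets built *directly* in category proportions (7.6% novel,
9.4% conserved, ~4% lost, remainder multi-copy) rather than via simulated
evolution, because the pipeline consumes sets, not alignments; an FPKM
matrix that is log-normal around cluster-specific treatment means — baseline
log2 FPKM ~ N(log2 100, 1), cluster j carrying +effect at treatment j and
−effect at the next (cyclically), a 20% flat-profile fraction, replicate
noise N(0, noise_sd) on the log2 scale with effect size 2 and noise 0.25 by
default; family-biased GO annotations (bias 0.7 — high enough to make the
within-family projection visibly denser, far from the degenerate 1); and a
regulatory graph whose random part is bipartite between TFs and non-TF
neighbors with planted same-family triangles kept edge-disjoint from it, so
the skeleton's triangle count equals the planted count exactly. What a green
recovery test does *not* establish: robustness to count overdispersion,
batch effects, unbalanced designs, or annotation noise — none of which the
generator produces. All outputs are bit-reproducible under a fixed seed
(sub-seeds seed, seed+1, seed+2 for the three generators so they are
individually deterministic).

## Known limitations

- The DE probability is a strict-dominance simplification; it is not
  calibrated against NOIseq and its absolute values should not be compared
  across datasets with different replicate structures.
- Subfamily labels requiring phylogeny (DREB/ERF subgroups, bZIP/NAC
  subfamilies, WRKY II a–e) are pass-through annotations.
- The GCC has no significance calibration; τ is a sparsity choice, not a
  p-value.
- The CLI takes explicit flags rather than a YAML config file.
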