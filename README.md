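# tfstressnet

Characterizing the five large transcription-factor (TF) families —
AP2/EREBP, bZIP, MYB, NAC and WRKY — in an allopolyploid crop genome, and
their responsiveness to abiotic stress. The package is aimed at plant
genomicists who have per-gene domain-hit tables, promoter sequences, FPKM
expression matrices across stress treatments, GO annotations and
cross-species homologous sets, and want a tested, scriptable version of the
standard downstream analysis:

- **Rule-based family/subfamily classification** from domain architecture
  (e.g. two AP2 domains → AP2 subfamily; one AP2 + B3 → RAV; WRKY calls
  require a WRKY domain *and* a C2H2/C2HC zinc finger, with the published
  degenerate cores WRRY/WSKY/WKRY/WVKY/WKKY/WKNY accepted), plus χ²
  chromosome-distribution homogeneity tests and count-vector clustering.
- **Cis-element scanning** of 1500-bp promoters against an editable table of
  IUPAC consensi (ABRE, HSE, MBS, LTR, ...), both strands, overlapping hits.
- **Synteny categories**: novel / conserved / multi-copy / lost calls from
  homologous-set tables against the two diploid ancestors, with sub-genome
  (A/C) attribution and per-family preference summaries.
- **Differential expression**: log2 fold changes vs control, a
  noise-distribution DE probability (for each gene, the fraction of pooled
  replicate-pair noise points strictly dominated by its signal statistics
  M = |log2 ratio of condition means| and D = |difference of means|), DEG
  calling at probability ≥ 0.6 and |log2FC| ≥ 1, threshold sweeps, Venn set
  summaries, GO-based crucial-DEG selection, and the qRT-PCR 2^−ΔCt
  transform.
- **Three networks over the crucial DEGs**:
  1. a *grey correlation* co-expression network — for reference profile
     x₀ and comparison xᵢ over n treatments,
     ξᵢ(k) = (minᵢminₖ|x₀(k)−xᵢ(k)| + ρ·maxᵢmaxₖ|x₀(k)−xᵢ(k)|) /
     (|x₀(k)−xᵢ(k)| + ρ·maxᵢmaxₖ|x₀(k)−xᵢ(k)|), r₀ᵢ = mean over k, with
     ρ = 0.5; an undirected edge {i,j} is set iff rᵢⱼ ≥ τ or rⱼᵢ ≥ τ
     (τ = 0.94) with weight max{rᵢⱼ, rⱼᵢ};
  2. a *process–gene* network: the one-mode projection of the gene↔GO-BP
     bipartite graph, edge weight = number of shared terms, with
     hypergeometric enrichment under Bonferroni control (FDR ≤ 0.05);
  3. a *regulatory* network: directed edges in a model species, homolog
     DEG-label transfer, hub/degree reports, triangle-motif counting and
     cross-network edge intersection.
- **A synthetic-data generator** that emits every input above with planted
  ground truth (clusters, DE effects, categories, motif positions, triangle
  motifs), so the whole pipeline is testable offline.

## Worked example

```r
library(tfstressnet)

cfg <- synth_config(n_genes_per_family = 20, seed = 7)
syn <- generate_all(cfg)

# classify and verify against planted truth
calls <- classify_families(syn$inventory$hits)
mean(calls$family[match(syn$inventory$records$gene_id, calls$gene_id)] ==
     syn$inventory$records$family)
#> [1] 1

# DEG calling
rel   <- relative_expression(syn$expression$em)
probs <- noise_probability_matrix(syn$expression$em)
deg   <- call_degs(rel, probs, prob_threshold = 0.6, log2fc_threshold = 1)
sum(deg$is_deg & syn$expression$truth$is_de[cbind(deg$gene_id, deg$treatment)]) /
  sum(syn$expression$truth$is_de)
#> [1] 0.99375

# grey-correlation co-expression network at the default threshold
net <- build_coexpression(gcc_matrix(rel, rho = 0.5), tau = 0.94)
net$metrics$n_edges      # edges passing the OR/max rule
graph_components(net$graph)$largest_size

# triangle motifs in the synthetic regulatory graph (6 planted)
count_triangles_motifs(syn$go_reg$regulatory)$count
#> [1] 6
```

The recovery rates above are what the code actually prints for seed 7: family
classification is exact by construction (the generator plants rule-consistent
hits) and planted-DE recall is 0.99 at effect size 2 and replicate noise 0.25.
At `noise_sd = 0` the τ = 0.94 network's connected components reproduce the
planted clusters exactly (adjusted Rand index 1; see
`tests/testthat/test-acceptance.R`).

A CLI wraps the stages over TSV/FASTA files:

```sh
Rscript -e 'tfstressnet::main()' synth --outdir demo --seed 1
Rscript -e 'tfstressnet::main()' classify --hits demo/domain_hits.tsv --out demo/calls.tsv
Rscript -e 'tfstressnet::main()' gcc-net --fpkm demo/fpkm.tsv --meta demo/samples.tsv --out demo/edges.tsv
```

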