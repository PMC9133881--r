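# placodeCeRNA

Nominating stage- and tissue-specific **ceRNA triples** (lncRNA–miRNA–mRNA)
for embryonic hair placode formation.

A competing endogenous RNA (ceRNA) is a transcript — here a long non-coding
RNA — that sequesters a miRNA through shared binding sites, relieving the
repression of that miRNA's mRNA targets. In hairless pig embryos, hair
follicle morphogenesis is blocked at the placode-induction stage (E41 in
skin), and candidate regulatory triples behind that block can be nominated
by integrating several layers of bulk transcriptomic evidence. This package
implements that integration as a tested, reusable pipeline, together with a
synthetic-data generator that plants known triples, modules and
differentially expressed genes so that every stage — and the pipeline end to
end — can be validated against ground truth without any external data.

## The method

For a design of two phenotypes (normal / hairless, defined by hair follicle
density below 1 or above 4 follicles/cm²) across multiple tissues and
embryonic stages, with replicates:

1. **Differential expression** per tissue at the focal stage: median-of-ratios
   size factors, per-gene negative-binomial dispersions (method of moments,
   shrunk 50/50 toward a fitted mean–dispersion trend), a Wald test on the
   log2 fold change of normalized group means with a delta-method standard
   error, Benjamini–Hochberg FDR, and the calls
   FDR < 0.05 and |log2FC| > 1 (both strict).
2. **Tissue specificity**: features DE in the focal tissue and in no other
   tissue (direction-agnostic exclusion).
3. **lncRNA candidate filtering**: length ≥ 200 nt, ≥ 2 exons, FPKM > 0.5
   and read coverage ≥ 3 in at least one sample, no protein-coding
   annotation, and a consensus non-coding vote from pluggable
   coding-potential scorers (one ORF-fraction scorer built in).
4. **Target assignment**: *cis* lncRNA targets within a 100 kb genomic
   window; *trans* targets with expression Pearson |r| ≥ 0.95; miRNA targets
   by exact seed match — the reverse complement of miRNA nucleotides 2–8 in
   the target sequence; plus an intersection operator over predictor edge
   sets.
5. **Triple assembly** under the two sponge-logic trend models
   `lncRNA−|miRNA+|mRNA−` and `lncRNA+|miRNA−|mRNA+`, requiring seed edges
   miRNA↔lncRNA and miRNA→mRNA (and, by default, a direct lncRNA–mRNA
   cis/trans edge).
6. **Weighted co-expression** on the focal tissue's stage series:
   sum-count > 10 gene filter, log2 variance-stabilizing transform,
   soft-threshold power chosen by scale-free topology fit (target R² 0.8),
   unsigned adjacency |cor|^β, topological overlap (TOM), average-linkage
   modules by static tree cut, module eigengenes (first principal
   components), module–stage correlation, and kME ≥ 0.8 hub genes.
7. **Prioritization**: retain triples whose mRNA is a hub of a module with
   p < 0.05 at the focal stage.

## Worked example

```r
library(placodeCeRNA)

p <- simParams(nMrna = 300, nLnc = 40, nMir = 12, nTriples = 3,
               nDecoyTriples = 2, moduleSizes = c(25, 25), seed = 7)
sim <- simulatePlacodeData(p)
sim
#> PlacodeSim with 352 features x 150 samples
#>   biotypes: lncRNA_candidate (40), miRNA (12), mRNA (300)
#>   design:  2 conditions x 5 tissues x 5 stages x 3 replicates
#>   planted truth: 3 ceRNA triples, 2 modules, 5 cis pairs

rep <- runPlacodePipeline(sim, minModuleSize = 15, verbose = TRUE)
#> [placodeCeRNA] DE skin/E41: 53 features
#> [placodeCeRNA] DE heart/E41: 33 features
#> ...
#> [placodeCeRNA] focal-specific DE: 26 mRNA, 10 lncRNA, 8 miRNA
#> [placodeCeRNA] lncRNA candidates: 32 of 40
#> [placodeCeRNA] edges: 5 cis, 0 trans, 20 miRNA-lncRNA seed, 260 miRNA-mRNA seed
#> [placodeCeRNA] assembled triples: 4
#> [placodeCeRNA] final triples: 3

as.data.frame(rep$finalTriples)
#>   lncRNA miRNA  mRNA  model hasLncMrnaEdge
#> 1   L001  M001 G0001 model1           TRUE
#> 2   L002  M002 G0002 model2           TRUE
#> 3   L003  M003 G0003 model1           TRUE

rep$recovery[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

The three planted triples are recovered exactly (precision = recall = 1);
the fourth assembled triple is a planted decoy whose mRNA does not carry the
E41 module factor, and prioritization removes it. `rep$attrition` reports,
for each planted triple, the first pipeline stage at which it would have
been lost.

Useful entry points: `simulatePlacodeData()` / `writeSimData()` (generator;
GTF + FASTA + TSV + truth JSON), `runDE()`, `filterLncRNACandidates()`,
`cisTargets()` / `transTargets()` / `seedTargets()`, `assembleTriples()`,
`runCoexpression()`, `prioritizeTriples()`, `runPlacodePipeline()` and
`scoreRecovery()`. The methods vignette
(`vignettes/placode-cerna-methods.Rmd`) documents the models, defaults and
design choices.

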