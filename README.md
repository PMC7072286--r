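# glioscore

Transcriptomic scoring of newly diagnosed versus recurrent glioblastoma:
single-sample pathway activation, AUC-based differential ranking, and
expression-driven drug-response scores — with a seeded synthetic cohort
generator so the whole chain is testable without any external data.

## The problem

Glioblastoma (GB) almost always recurs, and recurrent tumors (recGB) respond
differently to therapy than newly diagnosed ones (ndGB). Bulk RNA-seq of
multi-region tumor samples, matched glioma stem-cell (GSC) cultures and
normal-brain controls makes it possible to ask, per patient and per sample:
which signaling pathways change activity at recurrence, do cultured stem
cells recapitulate those changes, and which drugs does the transcriptome
predict to gain or lose efficacy? This package implements that analysis
chain for anyone working with gene-level expression matrices (HGNC symbols),
a signed pathway database, and a drug→target table.

## The scores

**CNR (case-to-normal ratio).** After median-of-ratios library-size
normalization, each gene *n* in each tumor sample gets
`CNR_n = (x_n + q) / m_n`, where `m_n` is the (geometric-mean, pseudocounted)
average of the gene in a normal-brain control group and `q` a pseudocount
(default 1).

**PAL (pathway activation level).** Each pathway *p* maps member genes to a
discrete activator/repressor role `ARR ∈ {−1, −0.5, 0, 0.5, 1}`. Per sample:

```
PAL_p = Σ_n ARR_np · ln(CNR_n)  /  Σ_n |ARR_np|
```

summed over measured members. PAL is 0 for a sample indistinguishable from
normal, positive when activators are up / repressors down.

**Differential ranking.** Features (genes, pathways, drug scores) are ranked
between groups by the tie-corrected Mann–Whitney AUC with the recurrent-like
group as positive class; a feature is differential when
`max(AUC, 1 − AUC) ≥ 0.7`, with direction reported. Gene-level DEGs use
per-gene rank-sum tests with Benjamini–Hochberg FDR and a fold-change filter.

**BES (balanced efficiency score).** Per drug and sample, a gene component
(weighted mean of target-gene `ln CNR`, weight −1 for resistance factors such
as MGMT for temozolomide) and a pathway component (signed mean PAL of
pathways containing the drug's targets) are z-standardized across the drug
panel within each sample and averaged. Higher BES = predicted more effective;
scores are panel-relative.

## Worked example

Simulate a cohort of 20 ndGB and 20 recGB tissue samples plus 6 normal
controls, with one pathway planted up at recurrence, one planted down, and
one resistance-factor gene planted up; then score it end to end:

```r
library(glioscore)

cfg <- synthetic_config(seed = 7, n_genes = 2000, n_pathways = 100,
                        n_patients = 40, regions_per_tumor = 1,
                        paired_fraction = 0, gsc_fraction = 0, n_normals = 6,
                        planted_pathways = data.frame(
                          pathway_id = c("PW001", "PW002"),
                          group = c("recGB-up", "recGB-down"), delta = 1),
                        planted_genes = data.frame(
                          gene_id = "G00042", group = "recGB-up", delta = 1))
sim <- simulate_cohort(cfg)

sc <- score_cohort(sim$expression, sim$metadata, sim$pathway_db)
labels <- sc$case_meta$stage == "recGB"
res <- rank_auc(sc$pal$pal, labels, threshold = 0.7)
head(res[order(-pmax(res$auc, 1 - res$auc)), ], 3)
#>    feature_id   auc direction median_pos median_neg significant
#> 1       PW001 1.000        up      0.928     0.0632        TRUE
#> 2       PW002 0.000      down     -0.907     0.0496        TRUE
#> 33      PW033 0.915        up      0.308    -0.1270        TRUE
```

The two planted pathways top the ranking with perfect separation (AUC 1 and
0); pathways such as PW033 that share member genes with a planted pathway
inherit part of the shift. A drug whose only target is the planted-up
resistance gene (weight −1) scores significantly lower at recurrence:

```r
drugs <- c(list(drug_definition("TMZ-like", c(G00042 = -1))), sim$drugs)
bes <- compute_bes(sc$cnr, sc$pal, drugs, sim$pathway_db)
compare_bes_groups(bes, labels)[1, ]
#>   drug_name median_pos median_neg wilcoxon_p   auc direction significant
#> 1  TMZ-like      -1.26     -0.316   1.83e-05 0.128      down        TRUE
```

The recurrent-group median BES is lower (−1.26 vs −0.32, Wilcoxon
p ≈ 2 × 10⁻⁵) — the transcriptome predicts reduced efficacy of the drug in
recurrent tumors, driven entirely by the planted resistance factor.

File-based workflows use `read_expression_tsv()`, `read_metadata_tsv()`,
`read_pathway_gmtx()` and `read_drug_tsv()`; `make_fixture("tiny", dir)`
writes a complete self-checking example bundle.

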