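# crossmac

Cross-species analysis of renal **resident** versus **infiltrated**
macrophages from single-cell RNA-seq: transcriptional-divergence scoring of
differentially expressed genes across human, mouse and rat, promoter
architecture (TATA-box / CpG-island) association, distance-to-median (DM)
cell-to-cell variability, and regulon analytics (activity scoring and
binarization, DEG selectivity, normalized binary entropy, cross-species
regulon mapping and joint clustering). The package targets computational
biologists comparing a two-subtype contrast across species on one-to-one
orthologs, and ships a fully parameterised three-species synthetic-data
generator with recorded ground truth so the entire pipeline is testable
without any external download.

## The statistics at the core

For each ortholog triple with subtype log fold changes
L<sub>h</sub>, L<sub>m</sub>, L<sub>r</sub> (resident vs infiltrated,
natural log, Seurat `FindMarkers` contract), transcriptional divergence is

    D = log[ 1/2 * ( (L_h - L_m)^2 + (L_h - L_r)^2 ) ]

the log mean squared human-versus-rodent fold-change discrepancy. Genes are
classified into the top 25% (high), middle 50% (medium) and bottom 25%
(low) of the D distribution. Around this sit:

* **DM** — per-gene log10 CV² minus its running median over genes ordered
  by mean expression, a variability measure decoupled from expression
  level;
* **Selectivity** — |DEG ∩ targets| / |targets| per regulon, with
  cumulative DEG-coverage curves over selectivity-ranked TFs;
* **Normalized binary entropy** — −p·log₂p − (1−p)·log₂(1−p) with p the
  resident share of a regulon's active-cell percentages (1 = subtype-
  agnostic, 0 = fully subtype-specific);
* **Joint clustering** — Ward linkage on 1 − Spearman ρ between cells'
  binary regulon-activity profiles, merged across species through
  one-to-one orthologs.

## Worked example

Simulate a three-species dataset, run per-species differential expression,
and score cross-species divergence:

```r
library(crossmac)

cfg <- simulation_config(n_genes = 600, n_cells_per_subtype_per_species = 80,
                         seed = 42)
ds  <- generate_dataset(cfg)

de <- lapply(c("human", "mouse", "rat"), function(sp) {
  counts <- qc_filter(ds$counts[[sp]])
  find_markers(log_normalize(counts),
               ds$annotation[ds$annotation$species == sp, ])
})
names(de) <- c("human", "mouse", "rat")
sapply(de, function(d) sum(d$p_adjusted < 0.05))
#> human mouse   rat
#>   120   144   115

triples <- fold_change_triples(de$human, de$mouse, de$rat, ds$orthologs)
div <- divergence_table(triples)
table(div$group)
#>   high    low medium
#>     24     24     49

fc <- as.matrix(triples[, c("log_fc_human", "log_fc_mouse", "log_fc_rat")])
colnames(fc) <- c("human", "mouse", "rat")
species_dendrogram(fc)
#> Species dendrogram (1 - Spearman rho, average linkage)
#>   newick: (human:0.0775824604,(mouse:0.04940130978,rat:0.04940130978):0.02818115062);
#>   first join: mouse + rat
```

The DEG counts are the per-species resident-vs-infiltrated genes at
FDR < 0.05; the 24/49/24 split is the 25/50/25 divergence classification of
the 97 cross-species DEGs; and the dendrogram joins mouse and rat first —
fold changes are more similar within the rodent clade than between clades,
as the clade-structured noise in the generator dictates. The whole pipeline
(QC → DE → divergence → promoter tests → DM → regulon analytics, all
outputs as files plus a manifest) runs with:

```r
cfg <- pipeline_config(outdir = "out", simulation = simulation_config(seed = 1))
run_pipeline(cfg)
```

Re-running with the same configuration reproduces every output
byte-identically. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R all --outdir out --seed 1`).

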