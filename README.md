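# ontomap

Ontogenic expression profiling of coding and long non-coding RNAs.

`ontomap` is an R package for analysing replicated multi-age RNA-seq time
courses — the kind of design used to study postnatal organ maturation, where
liver tissue is sampled at a dozen ages from just before birth to adulthood
and both protein-coding genes (PC) and long non-coding RNAs (NC, lncRNAs)
are quantified as FPKM. The package covers the full analysis path:

1. **Annotation** — read Ensembl-style GTF, merge a primary biotype-bearing
   annotation with a secondary lncRNA model set keeping only models that
   overlap no primary gene (strand-agnostic), classify genes into coding /
   lncRNA / small structural RNA, and query genomic gaps and nearest coding
   neighbours.
2. **Expression filtering** — replicate-averaged age means; a gene is
   *expressed* when its mean FPKM exceeds 1 at any age (strictly).
3. **Differential expression** — per-gene one-way ANOVA across ages on
   log2(FPKM + 1). A gene changes significantly when all of
   (i) overall mean FPKM > 1, (ii) max/min age-mean fold change > 1.5
   (pseudocount 1), and (iii) Benjamini–Hochberg adjusted p < 0.05.
4. **Ontogenic patterns** — z-scored log profiles, average-linkage
   hierarchical clustering on Pearson correlation distance (d = 1 − r),
   cut into k = 3 clusters labelled *neonatal*, *adolescent* or *adult*
   by the stage window containing the cluster-centroid peak.
5. **Inter-age similarity** — Pearson r between age-mean expression vectors
   of any gene subset (all / coding / lncRNA).
6. **Neighbour pairs** — for every anchor gene, its nearest coding
   neighbour (PC-PC and PC-NC pairs); a high-stringency tier keeps pairs
   within 10 kb whose lncRNA (PC-NC) or either member (PC-PC) is expressed;
   each pair gets the Pearson correlation of the two ontogenic profiles,
   compared against a seeded 10,000-draw random coding-pair null.
   *Concordant cis candidates* are hi-tier PC-NC pairs whose lncRNA changes
   significantly and whose two genes share the same pattern label.
7. **Enrichment** — one-sided hypergeometric over-representation of a gene
   set against a flat gene→term map, BH-corrected.
8. **Synthetic data** — a generator that emulates the study design
   (12 ages × 3 replicates, ~10-fold less abundant lncRNAs, three planted
   pattern classes plus flat genes, cis-coupled neighbour pairs within
   10 kb, discordant decoys, and overlapping secondary annotation models),
   with complete ground-truth bookkeeping.

## Worked example

```r
library(ontomap)

sim <- simulate_ontogeny(sim_config(seed = 2))      # 500 PC + 150 NC genes
gs  <- classify_genes(sim$genes)
es  <- sim$expr
am  <- age_means(es)

length(expressed_genes(am))        # 648 genes with mean FPKM > 1 at some age
de  <- call_de(es)
sum(de$significant)                # 443 genes changing across development

z   <- zscore_profiles(am[de$gene_id[de$significant], ])
pat <- cluster_patterns(z, k = 3)
table(pat$label)
#> adolescent      adult   neonatal
#>         83        120        240

expressed <- expressed_genes(am)
pcnc_hi <- pair_correlations(
  filter_hi(build_pairs(gs, "lncRNA"), expressed), am)
concordant <- concordant_pairs(pcnc_hi, de, pat)
nrow(concordant)                   # 44 concordant cis-candidate pairs
```

The same run is available end to end, with all stage TSVs and a count
report, as:

```r
run_pipeline(list(outdir = "out", simulate = sim_config(seed = 2),
                  params = list(seed = 2)))
```

which prints (from `out/report.txt`):

```
ontomap pipeline report
genes: 670 (coding 500, lncRNA 150, small RNA 20)
expressed: 648 (coding 500, lncRNA 144)
differentially expressed: coding 325, lncRNA 117
cluster sizes: adolescent=82 adult=120 neonatal=240
pairs: PC-PC all=500 PC-NC all=150 PC-PC hi=253 PC-NC hi=122 random-PC=10000
concordant cis pairs: 44
```

(The report's cluster sizes differ by one gene from the snippet above
because `run_pipeline()` excludes small structural RNAs before clustering.)

Reading the report: most coding genes and most of the (deliberately less
abundant) lncRNAs pass the expression filter; the three pattern clusters
recover the planted neonatal > adult > adolescent size ordering; and of the
150 lncRNA anchors, 122 survive the 10 kb + expressed filter, of which 44
are concordant with their coding neighbour — close to the 40 planted
cis-coupled pairs.

A thin command-line wrapper is installed under
`inst/scripts/ontomap.R` (`simulate` and `run-all` subcommands).

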