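# sysgen

A three-stage systems-genetics pipeline for prioritizing candidate causal
genes for a complex trait, built for the setting where GWAS risk loci,
tissue expression profiles (mRNA and miRNA), and independent replication
cohorts must be integrated into a single ranked story — the motivating
application being obesity studied in human subcutaneous adipose tissue.

**Stage I (discovery).** SNP-level GWAS summary statistics are collapsed to
gene-wide p-values (minimum p over LD proxy clusters within the transcript
plus a 1-kb promoter window, candidate genes at p ≤ 0.05). Candidates seed
a weighted gene coexpression network with adjacency
a<sub>ij</sub> = |cor(x<sub>i</sub>, x<sub>j</sub>)|<sup>β</sup> (β chosen
so the network is approximately scale-free, signed fit R² ≥ 0.8), modules
detected by average-linkage clustering of 1 − TOM (topological overlap),
module eigengenes (first principal components) tested for age-adjusted
trait association, hub genes called by module membership (kME > 0.8) and
gene significance (GS > 0.2) or by maximal intramodular connectivity. A
causal structure over the module is learned with the stable PC algorithm
(Gaussian partial-correlation tests, α = 0.01) and key drivers nominated by
downstream-neighbourhood size (μ > μ̄ + σ) and out-degree (d > d̄ + 2σ).
miRNA–mRNA interactions are database-supported pairs with significant
negative correlation (BH FDR within the supported set).

**Stage II (replication).** Module preservation in independent datasets is
scored by permutation Zsummary (density + connectivity composites;
< 2 no evidence, ≥ 10 strong evidence).

**Stage III (validation).** Per-dataset moderated-t / moderated-F
differential expression (limma) is combined across datasets by Fisher's
method (−2Σln p on 2k df, k counted per gene) and by pooled Hedges-g
standardized mean differences (fixed effects, or DerSimonian–Laird random
effects when Q-p < 0.05 or I² > 50%), with within-study permutation
p-values.

A synthetic-data generator (`simulate_bundle()`) produces every input with
the statistical structure the analysis assumes — latent-factor modules, a
trait driven by one module's factor plus age, a planted linear-SEM causal
DAG, miRNAs negatively coupled to targets, replicate case/control datasets
with a planted standardized shift, and GWAS summary statistics with LD
structure — so the whole pipeline is testable offline. See the vignette
(`vignettes/systems-genetics-pipeline.Rmd`) for the models, parameters and
design decisions.

## Worked example

```r
library(sysgen)

cfg    <- sim_config(seed = 7)        # 200 samples, 1000 genes, 5 planted modules
bundle <- simulate_bundle(cfg)

adj    <- adjacency(bundle$expression, beta = 6)
labels <- cluster_modules(1 - tom(adj), expr = bundle$expression)
table(labels)
#> labels
#>      blue     brown     green      grey turquoise    yellow
#>        40        40        40       800        40        40

mes <- module_eigengenes(bundle$expression, labels)
do.call(rbind, lapply(colnames(mes), function(m)
  cbind(module = m,
        module_trait_association(mes[, m], bundle$traits$obesity,
                                 bundle$traits$age))))
#>      module        r        p r_squared
#> 1    yellow  0.50554 2.62e-14  2.56e-01
#> 2 turquoise  0.00725 9.19e-01  5.26e-05
#> 3     green -0.06346 3.73e-01  4.03e-03
#> 4      blue  0.01691 8.13e-01  2.86e-04
#> 5     brown  0.10588 1.37e-01  1.12e-02
```

All five planted modules are recovered exactly (the 800 background genes
stay grey), and only the module whose latent factor drives the trait
(labelled yellow here) associates with obesity after age adjustment,
explaining ~26% of its variance.

```r
mm <- module_membership(bundle$expression, mes)
gs <- vapply(rownames(bundle$expression), function(g)
  gene_significance(bundle$expression[g, ], bundle$traits$obesity)$gs,
  numeric(1))
identify_hub_genes(labels, gs = gs, kme = mm$kme)$yellow
#>  [1] "gene_0001" "gene_0002" "gene_0005" "gene_0006" "gene_0014" "gene_0017"
#>  [7] "gene_0021" "gene_0023" "gene_0028" "gene_0032" "gene_0034" "gene_0037"
#> [13] "gene_0038" "gene_0039"

graph <- pc_algorithm(bundle$causal$expression, alpha = 0.01)
key_driver_analysis(graph, rownames(bundle$causal$expression), h = 3)$key_drivers
#> [1] "gene_0001"     # the planted root regulator of the module's SEM

meta <- meta_analyze(bundle$studies)
head(meta[order(meta$fisher_p),
          c("gene_id", "fisher_chi2", "fisher_p", "smd", "ci_low",
            "ci_high", "model")], 3)
#>       gene_id fisher_chi2 fisher_p   smd ci_low ci_high  model
#> 44  gene_0044         353 9.73e-70 -1.13  -1.36  -0.892 random
#> 52  gene_0052         352 1.68e-69 -1.12  -1.26  -0.991  fixed
#> 111 gene_0111         345 5.02e-68 -1.13  -1.26  -0.992  fixed
```

Fourteen yellow genes pass the hub criteria (kME > 0.8, GS > 0.2); the
planted SEM root is the sole key driver; and across the five replicate
datasets the planted standardized shift of −1 is recovered by the pooled
SMD with tight confidence intervals.

The same analysis runs end to end from TSV files:

```r
write_bundle(bundle, "fixtures/")
run_pipeline(pipeline_config("fixtures/", "out/"))   # writes TSVs + MANIFEST
```

or from a shell via the thin CLI wrapper
(`Rscript inst/cli/sysgen.R run --in fixtures/ --out out/`).

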