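# pathmark

Network-constrained discovery of dysregulated pathway biomarkers from
case/control gene expression data.

Gene-level biomarkers from expression studies are notoriously unstable:
disease perturbs coordinated functional modules, not isolated
transcripts. `pathmark` identifies *dysregulated pathways* instead. It
is written for computational biologists analysing labelled (disease vs
control) expression matrices with an annotated gene-set collection
(e.g. MSigDB canonical pathways in GMT format) and a protein–protein
interaction (PPI) edge list.

## Method

Three stages, each exposed as ordinary functions over tibbles:

1. **Pathway activity.** Expression is standardized per gene,
   $z_{ij} = (g_{ij}-\bar g_i)/s_i$, and each pathway $k$ is summarized
   per sample as the projection onto the first principal component of
   its member genes:
   $P_{kj} = \mathbf{w}_k^\top \mathbf{z}_{\cdot j}$ with
   $\mathbf{w}_k$ the unit-norm leading eigenvector of the member-gene
   covariance — one "meta-gene" score per pathway per sample.
2. **Pathway interaction network (PIN).** Pathways are candidate
   neighbors if they share a gene or their genes interact in the PPI.
   A candidate edge survives only with condition-specific support: a
   shared gene differentially expressed (Student's t-test, p < 0.05) or
   a cross-pathway PPI pair strongly co-expressed (|Pearson r| > 0.8).
3. **Marker selection.** Forward greedy search over pathway activities,
   constrained to the PIN: the best single pathway by repeated five-fold
   cross-validated RBF-SVM AUC seeds the panel, then the best PIN
   neighbor of the growing panel is added while it improves the mean
   AUC. The result is a small, connected pathway panel plus its
   cross-validated AUC.

A latent-factor simulator (`simulate_dataset()`) with planted
dysregulated pathways, a deterministic hand-traceable toy instance
(`make_toy_fixture()`), a gene-level t-test baseline
(`rank_genes_ttest()`), and hold-out evaluation
(`evaluate_holdout()`) round out the package. See the vignette
`vignettes/pathway-markers.Rmd` for the full model description.

## Worked example

```r
library(pathmark)

sim <- simulate_dataset(sim_design(seed = 11))   # 2 planted pathways: PW01, PW02
res <- run_pipeline(sim$expression, sim$labels, sim$gene_sets, sim$ppi,
                    cfg = eval_config(seed = 11))
#> [pathmark] standardized 400 genes x 200 samples
#> [pathmark] kept 30/30 pathways covering 286 measured genes
#> [pathmark] computed 30 pathway activity scores
#> [pathmark] PIN: 30 pathways, 10 condition-supported edges
#> [pathmark] selected 3 marker pathway(s), final CV-AUC 0.880

res$selection
#> <pathway_selection> 3 marker(s), final CV-AUC 0.880 (100 repeats)
#> # A tibble: 3 x 5
#>    step pathway pool_size mean_auc  auc_sd
#>   <int> <chr>       <int>    <dbl>   <dbl>
#> 1     1 PW02           30    0.810 0.0111
#> 2     2 PW01            4    0.875 0.00629
#> 3     3 PW05            3    0.880 0.00845
```

The trace reads: the planted pathway `PW02` is the best single
discriminator (mean CV-AUC 0.810 over its 30-pathway scan); adding its
PIN neighbor `PW01` — the other planted pathway — lifts the panel to
0.875; one further neighbor adds a marginal gain, then no candidate
improves and the search stops. The final panel re-scored at 100 CV
repeats gives AUC 0.880. `tidy()`, `glance()` and `autoplot()` work on
the selection, the network and the activity objects; a thin CLI wrapper
lives at `inst/cli/pathmark.R`.

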