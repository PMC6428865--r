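# riboTE

Differential translation-efficiency analysis for paired ribosome
profiling, for researchers asking whether a perturbation changes how
well transcripts are *translated* — not just how abundant they are.
Given gene-level mRNA-seq and ribosome-protected-fragment (RPF) counts
for two conditions, riboTE tests each gene's translational-efficiency
(TE) change, classifies the affected genes into behavioral subgroups,
and characterizes those groups by gene architecture, 5'UTR structure
(PARS-style scores around the translation initiation site), codon-level
footprint metagenes, and genomic-run-on derived synthesis-rate /
half-life balance. A fully seeded synthetic-data generator with known
ground truth makes the entire pipeline testable end to end.

## The model

Counts for gene *g* across samples *j* are negative binomial with

```
log mu_j = log s_j + b0 + bA·A_j + bC·C_j + bI·A_j·C_j
```

where `A = 1` for RPF samples, `C = 1` for the perturbed condition, and
`s_j` are median-of-ratios size factors. Then

* `log2fc_mrna = bC / ln 2` — mRNA abundance change,
* `log2fc_rpf = (bC + bI) / ln 2` — ribosome occupancy change,
* `delta_te  = bI / ln 2` — the TE change (interaction term).

`bI` is tested with a Wald test (per-gene method-of-moments dispersion
moderated toward the across-gene mean; standard errors from the
observed Fisher information) and controlled by Benjamini–Hochberg FDR.
Significant genes (`fdr < 0.05`) are classified by TE direction
(`activated_*`: TE falls upon depletion of the regulator;
`repressed_*`: TE rises) and mRNA status (`buffered` when
`|log2fc_mrna| < 0.433 = log2(1.35)`, else `decreased`/`increased`).

See `vignettes/differential-translation.Rmd` for the statistical
details, generator design, and the package's numerical conventions.

## Worked example

```r
library(riboTE)

cfg <- pipeline_config(overrides = list(
  seed = 20, simulation = list(n_genes = 800, n_reps = 4,
                               dispersion = 0.02)))
pipeline_simulate(cfg, "demo/bundle")     # counts, GFF3, PARS, GRO, truth
pipeline_analyze(cfg, "demo/bundle", "demo/results")
pipeline_report("demo/results")
```

which prints (`demo/results/report.txt`):

```
genes tested: 800
significant: 114
activated_buffered         30  (median delta-TE -1.01979)
activated_decreased        16  (median delta-TE  -1.053)
activated_increased         3  (median delta-TE -1.18892)
repressed_buffered         26  (median delta-TE 1.01758)
repressed_decreased        29  (median delta-TE 1.04159)
repressed_increased        10  (median delta-TE 1.02325)
not_regulated             686  (median delta-TE -0.00116319)
membrane_enrichment_ratio        1.51807
activated_overlap_k                   46
activated_overlap_expected        3.3075
activated_overlap_p              1.09713e-62
regulated_detected_fraction          0.9
detected_correct_class_fraction  0.962963
false_positive_fraction          0.00882353
```

Reading this: 114 of 800 genes show a significant TE change, split into
the five occupied subgroups plus a handful of `activated_increased`
genes; median `delta_te` per group recovers the simulated ±1 log2-unit
effects. With four replicates and low dispersion, 90% of truly
regulated genes are detected, 96% of detections carry the exact truth
label, and the overlap between detected and true activated sets (46
genes vs 3.3 expected) has a hypergeometric p of ~1e-62. The membrane
enrichment ratio compares the membrane-protein fraction among activated
genes to the unregulated background. Under the default study design
(two replicates, dispersion 0.1) per-gene power is intrinsically low —
the vignette derives why — and the same report shows a recovery
fraction near zero while calibration and direction accuracy hold.

The analysis stages are also available directly: `read_counts()` /
`run_te_test()` / `classify_genes()`, `rpf_metagene()`,
`pars_tis_profile()`, `pars_region_means()`, `compare_group_feature()`,
`simulate_gro()` / `group_rate_comparison()`, plus
`overlap_significance()`, `membrane_enrichment()`,
`decay_half_life_fit()` and `polysome_distribution()`. A thin CLI over
the pipeline functions ships as `inst/scripts/ribote`
(`ribote simulate|analyze|report --config cfg.yaml ...`).

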