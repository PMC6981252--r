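# dmlpipe

Paired differential-methylation analysis for Infinium 450K-style beta-value
matrices, built around the kind of question asked when mesenchymal stem cells
(MSCs) are differentiated into chondrocytes: which CpG loci change
methylation between paired Day0 and Day14 samples, where do those loci sit in
the genome, how do they relate to gene expression, and are the same loci
hypomethylated in mature cartilage and in disease?

The package is aimed at epigenomics analysts who have probe-level beta
matrices and a probe manifest (rather than raw IDATs) and want a compact,
fully testable pipeline. A synthetic-data module generates complete
experiments with planted ground truth — planted differentially methylated
loci (DMLs) and regions (DMRs), a hidden cartilage-hypomethylated probe
subset in a multi-tissue panel, and a disease DML set with a known overlap —
so every stage can be validated without any external download.

## The model

Methylation fractions (beta values, `β ∈ [0,1]`) are transformed to
M values, `M = log2(β/(1−β))` (clamped at `β = 0.001`), the
variance-stabilised scale on which testing is done. For probe *g* with
donor-wise paired differences `Δ_gj = M14_gj − M0_gj`, *j = 1…n*:

- paired fit: `d̄_g = mean(Δ_gj)`, `s²_g = var(Δ_gj)`, `df_g = n − 1`;
- empirical-Bayes prior: the per-probe variances are modelled as
  `s²_g ~ s0² F(df_g, d0)`; `(d0, s0²)` are estimated by moment matching on
  `log s²_g` with trigamma inversion;
- moderation: `s̃²_g = (d0·s0² + df_g·s²_g)/(d0 + df_g)`,
  `t̃_g = d̄_g / (s̃_g/√n)`, two-sided p from t with `d0 + df_g` df
  (the single-contrast moderated F is `t̃²` with identical p);
- DML call: Benjamini–Hochberg adjusted `p < 0.05` **and**
  `|Δβ| > 0.10`, where `Δβ` is the difference of group mean betas
  (the ">10% methylation change" rule); `Δβ < 0` is hypomethylation.

Around that core: DMRs are maximal runs of ≥2 significant CpGs with
consecutive gaps ≤1000 bp; probes are annotated by CpG-island relation
(island / shore ≤2 kb / shelf 2–4 kb / open sea), 450K gene-feature class,
and chromHMM 15-state segments collapsed to five functional categories
(TSS, flanking TSS, transcribed, enhancer, repressed); enrichment uses
upper-tail hypergeometric tests; tissue-specific hypomethylated CpGs are
probes with reference beta < 0.5 and beta > 0.8 in > 90% of the other
(quantile-normalised) tissues; and two DML sets are compared by an exact
hypergeometric overlap test on the jointly tested universe.

## Worked example

```r
library(dmlpipe)

cfg <- sim_config(n_probes = 4000, seed = 11)
sim <- simulate_manifest(cfg)
pr  <- simulate_paired_betas(sim, cfg)

b0  <- filter_probes(pr$beta_day0,
                     cbind(pr$detection_day0, pr$detection_day14),
                     sim$manifest)
#> filter_probes: removed 20 (detection p > 0.05), 80 (sex chromosome),
#>                80 (SNP); 3820/4000 probes retained

fit <- dm_fit(b0, pr$beta_day14[rownames(b0), ], pr$samples)
fit
#> Paired empirical-Bayes differential methylation fit
#>   probes: 3820, donor pairs: 4
#>   variance prior: d0 = Inf, s0^2 = 0.505
#>   probes with adjusted p < 0.05: 205

dml <- call_dmls(fit)
dml
#> DML calls: 202 significant of 3820 probes (190 hypo, 12 hyper)

dmr <- call_dmrs(dml, sim$manifest)
dmr
#> DMRs: 30 region(s), 2-4 CpGs each, median span 713 bp
```

205 probes pass the adjusted-significance filter alone; 202 also change by
more than 10 percentage points of methylation and become DMLs, 94% of them
hypomethylated — the planted imbalance (95% hypo) recovered from noisy data.
Because all probes share one residual variance in this simulation the prior
degrees of freedom are estimated as infinite (complete shrinkage), which is
the correct limit. The 30 DMRs are runs of nearby significant CpGs; their
negative mean `Δβ` gives each region's net direction.

Cross-tissue comparison and disease overlap:

```r
pan <- simulate_tissue_panel(sim, cfg, pr$truth, pr$baseline_m)
qn  <- quantile_normalize(pan$panel[rownames(b0), ])
length(call_tissue_specific(qn, pan$reference))
#> [1] 194

dis <- simulate_disease_dmls(sim, cfg, pan$truth)
overlap_test(dml$probe_id[dml$significant],
             intersect(dis$disease_probes, rownames(b0)), rownames(b0))
#> Hypergeometric overlap: k = 50 of n_a = 202, n_b = 497 in N = 3820
#>   (expected 26.28)
#>   upper-tail p = 2.332e-06
```

The marker caller recovers 194 of the 200 planted cartilage-hypomethylated
probes, and the disease set shares 50 probes with the called DMLs where 26
would be expected by chance — a significant excess, as the generator
planted.

The full pipeline — all of the above plus annotation, enrichment and
expression integration, with TSV/BED/JSON outputs — runs from one call:

```r
run_pipeline(list(simulate = list(), seed = 1), outdir = "out")
```

or from a shell via `inst/scripts/run-pipeline.R --config run.yaml`.

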