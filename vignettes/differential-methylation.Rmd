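---
title: "Paired differential methylation with dmlpipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential methylation with dmlpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmlpipe)
```

## The problem

During chondrogenic differentiation of mesenchymal stem cells (MSCs),
paired Day0/Day14 450K-style methylation profiles show a strong, mostly
hypomethylating shift at a few thousand CpGs, concentrated at enhancer
chromatin and converging toward the methylation state of mature articular
chondrocytes. dmlpipe implements that analysis pattern as reusable,
testable components: a paired moderated test for differentially methylated
loci (DMLs), gap-based merging into regions (DMRs), genomic and
chromatin-state annotation with enrichment, integration with expression
changes, cross-tissue marker calling, and overlap testing against a second
DML set. A synthetic-data generator with planted truth makes every claim
checkable.

## The statistical core

Testing is done on M values, `M = log2(β/(1−β))`, because beta values are
heteroskedastic near their bounds; effect reporting uses `Δβ` (difference
of group mean betas) because percentage methylation is the interpretable
scale. The clamp `β ∈ [0.001, 0.999]` before the logit bounds M and is
invertible to 1e-9 inside the clamp range.

With donor-paired samples the fit reduces to per-probe differences
`Δ_gj = M14_gj − M0_gj`: mean `d̄_g`, variance `s²_g`, `df_g = n−1`.
Donor baselines (modelled, and generated, as additive on M and shared
between timepoints) cancel exactly — that is what the paired design buys.

With few donors, per-probe variances are unstable, so they are shrunk
toward a pooled prior estimated from all probes: assuming
`s²_g ~ s0² F(df_g, d0)`, moments of `log s²_g` identify `(d0, s0²)`;
the trigamma equation is inverted by Newton iteration to relative
tolerance 1e-8. Two limits need care and are both tested: when the
observed spread of `log s²` does not exceed its pure sampling component
the prior is degenerate (`d0 = ∞`, full pooling, normal-limit reference
distribution); with `d0 = 0` the machinery reproduces the ordinary paired
t-test exactly, which the suite verifies to 1e-10 against `t.test()` and
against the reference Bioconductor implementation of the same
empirical-Bayes scheme.

The single-contrast moderated F is reported as `t̃²` with an identical
p-value — an exact equivalence, kept as one code path.

A probe is a DML when its Benjamini–Hochberg adjusted p is below `alpha`
(default 0.05) **and** `|Δβ|` strictly exceeds `delta_min` (default 0.10,
the ">10% change" rule; a change of exactly 0.10 does not qualify). The
two thresholds play different roles: the adjusted p controls the error
rate, the `Δβ` filter imposes practical effect size — in null data it is
the `Δβ` filter that removes the handful of BH false positives.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted significance cutoff (strict <) |
| `delta_min` | 0.10 | minimum absolute beta change (strict >) |
| `max_gap` | 1000 bp | maximum separation of consecutive DMR member CpGs |
| `min_cpgs` | 2 | minimum CpGs per DMR (">1 DML") |
| `lo`, `hi`, `tissue_frac` | 0.5, 0.8, 0.9 | tissue-marker rule: reference β < lo, other-tissue β > hi in a fraction > tissue_frac of tissues (all strict) |
| `bin_width` | 0.5 | log2 fold-change bin width for expression integration |
| `eps` | 0.001 | beta clamp before the logit |

"Maximum separation" is read as the distance between consecutive
significant CpG positions, not the region span — the only reading under
which greedy merging is well-defined and the standard convention of DMR
callers. The merge is exactly the printed definition (runs of >1
significant CpG within 1000 bp); no kernel smoothing is applied, so DMR
counts are not comparable to smoothing-based callers.

Island relation uses the 2 kb / 4 kb shore/shelf cutoffs without a
north/south split. De-novo island detection slides a 200 bp window and
requires observed/expected CpG ratio > 0.6, unioning qualifying windows
and keeping runs longer than 200 bp; no GC-content criterion is applied.
The chromHMM 15-state collapse (TssA, TssBiv → TSS; TssAFlnk, BivFlnk →
flanking TSS; Tx, TxFlnk, TxWk → transcribed; Enh, EnhG, EnhBiv →
enhancer; ZNF/Rpts, Het, ReprPC, ReprPCWk, Quies → repressed) is
table-driven and asserted state-by-state in the tests.

Coordinates: manifests are 1-based; interval tracks are BED, 0-based
half-open, so a segment `[s, e)` covers 1-based positions `s+1 … e`.
Strand is ignored everywhere except gene-feature assignment (TSS windows
are upstream of the strand-aware start; multi-gene overlaps resolve by
precedence TSS200 > TSS1500 > 5'UTR > Body > 3'UTR).

Quantile normalisation is applied to per-tissue mean beta profiles (one
column per tissue/condition) before marker calling, not within the paired
differential analysis — between-array correction of the paired design is
out of scope here, and the synthetic data need none. The implementation
delegates to the standard rank-mean procedure with tie-averaging; the
hand-computable 3×2 example and the idempotence and equal-sorted-column
postconditions are asserted in the tests.

The hypergeometric overlap test takes as its universe the probes tested
in **both** analyses (only jointly tested probes can overlap); p-values
use the log-stable survival form, with exact enumeration as a test-only
oracle.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions: 10,000 probes on two
autosomes plus small sex-chromosome (2%) and SNP-flagged (2%)
contingents; 4 paired donors; 5% planted DMLs of which 95%
hypomethylated (deterministic count); planted effects `|δ| ~ N(2, 0.4)`
on M, giving typical `|Δβ| ≈ 0.3` at mid-range baselines; 25 planted DMR
regions as runs of 2–6 planted probes with gaps < 1000 bp; a 12-tissue
panel with 200 planted cartilage-hypomethylated probes; a 500-probe
disease set sharing 50 probes with the planted DMLs. Baseline M values
are drawn from a bimodal mixture mimicking the 450K beta distribution.
Per-donor variance components are not published for this design;
`residual_sd = 0.5` and `donor_effect_sd = 0.5` on M are this package's
calibration choices, picked once as realistic for 450K replicates and
not revisited. Noise is logit-normal: Gaussian on M, mapped to β by the
logistic, so β is always in (0,1) and the noise lives on the scale the
statistics use.

The panel plants convergence: at planted DMLs the reference (cartilage)
tissue sits at the Day14 methylation level while other tissues sit at
the Day0 level, reusing the same baselines as the paired matrices.
Planted tissue-specific probes use wide margins (reference M ≈ −2,
others ≈ 3.8) so the reference-low/others-high construction holds for
essentially every planted probe after tissue noise — the marker-recovery
tests measure the caller, not the generator's noise.

Deliberately not simulated: Infinium type I/II probe chemistry, dye
bias, control probes, IDAT files, batch structure, cell-type
composition, and spatial correlation of methylation beyond the planted
DMR runs. Passing tests therefore demonstrate correctness of the
algorithms under a clean noise model, not robustness to array artefacts
— on real data the upstream normalisation this package does not provide
(e.g. functional normalisation from raw IDATs) still matters.

Expression coupling is generative, not mechanistic: genes overlapping a
planted DML draw log2 fold-changes shifted by `expression_coupling`
(default 1.5; 0 decouples). Monotonicity of the per-bin DML fraction is
assessed over bins holding at least 20 genes; over arbitrarily thin bins
strict monotonicity of an empirical fraction is not a meaningful
property.

## Numerical and degenerate-input choices

- `estimate_prior` excludes zero/non-finite variances; all-equal
  variances give `d0 = ∞` (a limit, not an error); fewer than two
  positive variances is an error.
- `moderate` with `d0 = ∞` uses the normal-limit t (df = Inf), which R's
  `pt` handles natively; `s² = 0` probes with a nonzero effect get
  infinite t and p = 0 only when `d0 = 0` — with any pooling they are
  regularised.
- BH adjustment delegates to `stats::p.adjust`; domain validation and
  the step-up examples are asserted around it.
- `filter_probes` fails a probe on detection p > 0.05 in **any** sample
  (the per-sample rule is a choice; it is the conservative, standard
  one). Filtering is idempotent.
- Probes outside all chromHMM segments are returned as "Unassigned" and
  excluded from enrichment denominators (counted and reported, never
  silently dropped).
- Ties in quantile normalisation receive the mean of the reference
  values at the tied ranks.
- Zero effects in direction concordance count as discordant and are
  reported separately.
- The ECDF dominance summary (signed area between a category's curve and
  the pooled curve, computed as the difference of means) is defined by
  this package and labelled as such in output.

## Pipeline and interface design

The package follows the classic R modelling idiom: `dm_fit()` returns a
classed object with `print`, `summary`, `coef`, `residuals` and `plot`
methods, and the thresholding step (`call_dmls`) is separate so the same
fit can be re-thresholded. There are no `predict`/`simulate` methods:
the model is per-probe with no new-data notion. `run_pipeline()`
orchestrates the stages from a validated config (exactly one of a
simulation block or input paths), writes TSV/BED/JSON outputs
atomically, and echoes config and seed — but not the output directory —
in `run_manifest.json`, so identical config + seed gives byte-identical
output trees wherever they land. The per-stage entry points are the
exported functions themselves; a thin `Rscript` wrapper
(`inst/scripts/run-pipeline.R`) covers the full-run case for shell use.

Problem sizes in the test suite (10,000 probes for calibration and
recovery runs, 50,000 draws for prior recovery, 500 random instances for
the DMR oracle) were chosen as the smallest scales at which the measured
properties are stable; they are the package's own verification
conditions.

## Known limitations

- No IDAT ingestion or raw-array normalisation; inputs start at beta
  matrices plus manifest.
- The DMR caller reproduces the printed gap rule only; counts are not
  comparable to kernel-smoothing callers.
- The empirical-Bayes scheme is mean-only (no variance trend, no robust
  down-weighting of hypervariable probes).
- Missing values are rejected, not imputed; real-data adapters must
  handle them upstream.
- The hypergeometric overlap test assumes exchangeable probes; it
  ignores probe-density differences between genomic contexts.
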