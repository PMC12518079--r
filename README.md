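# ithscore

Gene-level intra-tumor heterogeneity (ITH) scoring from multi-region bulk
RNA-seq, and low-heterogeneity prognostic signature construction with
survival evaluation.

Multi-region sequencing shows that many genes vary as much between regions of
one tumor as between patients, which makes single-biopsy biomarkers fragile.
`ithscore` quantifies that instability per gene and channels it into
biomarker selection. For each gene it computes:

- **ITVS** = `W / (W + B)`, from a one-way random-intercept decomposition of
  expression variance into within-tumor (`W`) and between-tumor (`B`)
  components (closed-form ANOVA method-of-moments by default, REML optional);
- **CCS** = `1 − AUPC / (N − 1)`, where the PGOR curve records, for every
  hierarchical-clustering cut level k = 1..N, the fraction of multi-region
  patients whose regions stay in one cluster, and AUPC is its trapezoidal
  integral — low CCS means regions cluster by patient, i.e. low ITH;
- **IHS** = `sqrt(ITVS × CCS)`, with `IHS ≤ 0.5` defining the low-ITH class;
- **MATH** = `100 × MAD / median` of a sample's variant allele fractions
  (1.4826 MAD constant), the genomic-heterogeneity counterpart.

On top of the scores sits a signature-selection funnel — differential
expression (`|log2FC| > 0.137`, FDR < 0.05), univariate Cox screening with a
Schoenfeld-residual proportional-hazards check, cross-cohort hazard-direction
consistency, and intersection with the low-ITH class — and a linear risk
model (default: the published two-gene signature
`0.024 × CYP4B1 + 0.02 × GBP1`) evaluated by median-split Kaplan–Meier /
log-rank, IPCW time-dependent AUC, and Harrell's C-index. A seeded
synthetic-data module generates multi-region expression, survival and VAF
data with known ground truth, so the entire pipeline is testable without
external cohorts. See the vignette
(`vignettes/heterogeneity-scoring.Rmd`) for the model details and design
choices.

## Worked example

The `analysis/` scripts run the whole study on synthetic data. Step 1
simulates a 10-patient, 32-sample multi-region cohort (2000 genes, true
heterogeneity drawn right-skewed) plus VAF sets; step 2 scores every gene:

```sh
$ Rscript analysis/01_simulate.R --seed 1
simulated 2000 genes x 32 samples (10 patients), 960 VAF rows
true rho: median 0.804 (IQR 0.657-0.918)

$ Rscript analysis/02_heterogeneity.R
scored 2000 genes: median ITVS 0.81, median IHS 0.88
57 genes (2.9%) classified low-ITH at IHS <= 0.5
Spearman with generating rho: ITVS 0.62, CCS 0.29, IHS 0.62
```

Most genes are heterogeneity-dominated (median ITVS 0.81) and only ~3% fall
below the IHS 0.5 cut — the regime multi-region tumor studies report. Steps
3–5 compute MATH, run the selection funnel on a two-cohort study with two
planted low-ITH prognostic genes, and evaluate the resulting risk score on
the held-out cohort:

```sh
$ Rscript analysis/03_math.R
MATH for 32 samples: median 28.7 (range 14.4-46.3), median n_variants 30

$ Rscript analysis/04_signature.R --seed 1
funnel: 500 DEGs -> 2 direction-consistent -> 2 low-ITH selected
selected: G0001, G0002 | planted: G0001, G0002

$ Rscript analysis/05_evaluate.R --seed 1
risk groups: 100 high / 100 low; log-rank chi2 = 63.4 (p = 1.6e-15)
AUC at t = 6.66/24.4/61.5: 0.755/0.779/0.809; C-index = 0.715
```

The funnel recovers exactly the two planted genes, and their risk score
separates the held-out cohort (high-risk patients die sooner; AUC well above
0.5 at every horizon). Equivalent functionality is available
programmatically — `score_all_genes()`, `math_by_sample()`,
`select_signature_genes()`, `risk_score()`, `km_logrank()`,
`time_dependent_auc()`, `concordance_index()` — or as one configured run via
`run_pipeline(yaml::read_yaml(system.file("extdata/demo_config.yaml",
package = "ithscore")))`.

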