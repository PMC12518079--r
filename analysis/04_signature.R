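#!/usr/bin/env Rscript
# The low-heterogeneity signature-selection funnel on a simulated two-cohort
# study with two planted signature genes: DE thresholds (|log2FC| > 0.137,
# FDR < 0.05) -> univariate Cox + PH screen in each cohort -> cross-cohort
# hazard-direction consistency -> intersection with the low-IHS class.
# Writes the selected genes and both screens; 05_evaluate.R consumes them.

suppressPackageStartupMessages({library(optparse); library(ithscore)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "results"))))

study <- generate_signature_study(n_genes = 500, n_cohort = 200, seed = opt$seed)
het <- score_all_genes(study$het$expr, study$het$map)
sel <- select_signature_genes(study$de,
                              study$cohortA$expr, study$cohortA$surv,
                              study$cohortB$expr, study$cohortB$surv, het)

dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(gene_id = sel$genes),
            file.path(opt$outdir, "selected_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sel$screen_a, file.path(opt$outdir, "cox_screen_a.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sel$screen_b, file.path(opt$outdir, "cox_screen_b.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("funnel: %d DEGs -> %d direction-consistent -> %d low-ITH selected",
                length(sel$degs), length(sel$consistent), length(sel$genes)))
message(sprintf("selected: %s | planted: %s",
                paste(sel$genes, collapse = ", "),
                paste(study$planted, collapse = ", ")))
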