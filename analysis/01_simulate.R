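#!/usr/bin/env Rscript
# Simulate the multi-region cohort that every downstream analysis consumes:
# 10 patients, an unbalanced 32-sample region design, 2000 genes whose true
# intra-tumoral variability (rho = W/(W+B)) is drawn right-skewed the way
# multi-region tumor RNA-seq looks, plus per-sample VAF sets for MATH.
# Writes TSVs + the ground-truth table under results/data/.

suppressPackageStartupMessages({library(optparse); library(ithscore)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "results/data"))))

dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- synth_config(n_genes = 2000, seed = opt$seed)
d <- generate_expression(cfg)
vaf <- generate_vaf(cfg, n_samples = 32)

write_expression(d$expr, file.path(opt$outdir, "expression.tsv"))
for (nm in c("map", "truth")) write.table(
  d[[nm]], file.path(opt$outdir, paste0(nm, ".tsv")),
  sep = "\t", quote = FALSE, row.names = FALSE)
write.table(vaf, file.path(opt$outdir, "mutations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d genes x %d samples (%d patients), %d VAF rows",
                nrow(d$expr), ncol(d$expr),
                length(unique(d$map$patient_id)), nrow(vaf)))
message(sprintf("true rho: median %.3f (IQR %.3f-%.3f)",
                median(d$truth$rho), quantile(d$truth$rho, .25),
                quantile(d$truth$rho, .75)))
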