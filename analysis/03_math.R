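#!/usr/bin/env Rscript
# Per-sample MATH genomic heterogeneity (100 * MAD / median of the VAFs,
# 1.4826 MAD constant) for the simulated mutation table.

suppressPackageStartupMessages({library(optparse); library(ithscore)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--datadir", type = "character", default = "results/data"),
  make_option("--out", type = "character", default = "results/math.tsv"))))

muts <- read_mutations(file.path(opt$datadir, "mutations.tsv"))
mt <- math_by_sample(muts, min_variants = 3)
dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)
write.table(mt, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("MATH for %d samples: median %.1f (range %.1f-%.1f), median n_variants %d",
                nrow(mt), median(mt$math, na.rm = TRUE),
                min(mt$math, na.rm = TRUE), max(mt$math, na.rm = TRUE),
                as.integer(median(mt$n_variants))))
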