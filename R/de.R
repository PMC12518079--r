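#' Built-in two-group differential expression test
#'
#' Per-gene Welch t-test between two sample groups on the normalized (log-like)
#' scale, with the mean difference reported as log2 fold change and
#' Benjamini-Hochberg adjustment across all tested genes. This is a simple
#' built-in screen; a moderated-statistics differential table computed
#' elsewhere can be supplied to [filter_degs()] instead.
#'
#' @param expr_a,expr_b expression matrices (genes x samples) for the two
#'   groups, sharing the same genes in the same order; >= 2 samples each.
#' @return data.frame: gene_id, log2fc (mean of `a` minus mean of `b`),
#'   p_value, fdr.
#' @export
simple_de <- function(expr_a, expr_b) {
  validate_expression(expr_a); validate_expression(expr_b)
  assert_that(identical(rownames(expr_a), rownames(expr_b)),
              "the two groups must share the same genes in the same order")
  assert_that(ncol(expr_a) >= 2 && ncol(expr_b) >= 2,
              "each group needs >= 2 samples")
  na <- ncol(expr_a); nb <- ncol(expr_b)
  ma <- rowMeans(expr_a); mb <- rowMeans(expr_b)
  va <- apply(expr_a, 1, stats::var); vb <- apply(expr_b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero-variance genes: no evidence either way
  data.frame(gene_id = rownames(expr_a), log2fc = ma - mb,
             p_value = p, fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Threshold a differential table into a DEG list
#'
#' Keeps genes with `|log2fc| > fc_cut` and `fdr < fdr_cut` — both
#' inequalities strict, so a gene sitting exactly on a boundary is excluded.
#' The default fold-change cut 0.137 corresponds to a lenient >10% expression
#' change (2^0.137 ~ 1.10).
#'
#' @param de data.frame with columns gene_id, log2fc, fdr.
#' @param fc_cut absolute log2 fold-change cut (default 0.137).
#' @param fdr_cut FDR cut (default 0.05).
#' @return character vector of surviving gene ids.
#' @export
filter_degs <- function(de, fc_cut = 0.137, fdr_cut = 0.05) {
  assert_that(all(c("gene_id", "log2fc", "fdr") %in% names(de)),
              "differential table needs columns gene_id, log2fc, fdr")
  assert_that(!anyDuplicated(de$gene_id), "duplicate gene ids in differential table")
  de$gene_id[abs(de$log2fc) > fc_cut & de$fdr < fdr_cut]
}
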