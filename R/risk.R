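#' Linear gene-expression risk model
#'
#' An ordered gene list with one finite linear weight per gene and a
#' stratification rule. The default model is the published two-gene
#' low-heterogeneity signature
#' `risk = 0.024 * CYP4B1 + 0.02 * GBP1` with a median split; the weights are
#' consumed as configuration (they came from an externally trained random
#' survival forest) and can be replaced by any externally derived weights.
#'
#' @param weights named numeric vector: names are gene ids, values weights.
#' @param split_rule `"median"` (default), `"tertile"`, or a fixed numeric
#'   cut value.
#' @return list of class `"risk_model"`.
#' @export
risk_model <- function(weights = c(CYP4B1 = 0.024, GBP1 = 0.02),
                       split_rule = "median") {
  assert_that(length(weights) >= 1 && !is.null(names(weights)) &&
                all(nzchar(names(weights))), "weights must be a named vector")
  assert_that(all(is.finite(weights)), "weights must be finite")
  assert_that(!anyDuplicated(names(weights)), "duplicate genes in weights")
  ok_rule <- (is.character(split_rule) && split_rule %in% c("median", "tertile")) ||
    is_scalar_number(split_rule)
  assert_that(ok_rule, "split_rule must be 'median', 'tertile' or a number")
  structure(list(genes = names(weights), weights = unname(weights),
                 split_rule = split_rule), class = "risk_model")
}

#' Per-sample linear risk scores
#'
#' `score_s = sum_g w_g * expr[g, s]` over the model genes; every model gene
#' must be present in the matrix.
#'
#' @param expr expression matrix (genes x samples).
#' @param model a [risk_model()].
#' @return named numeric vector of scores, one per sample.
#' @export
risk_score <- function(expr, model = risk_model()) {
  validate_expression(expr)
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$genes, rownames(expr))
  assert_that(length(missing) == 0, "model gene(s) absent from matrix: %s",
              paste(missing, collapse = ", "))
  colSums(expr[model$genes, , drop = FALSE] * model$weights)
}

#' Stratify scores into high/low risk groups
#'
#' Default median split: scores strictly above the cut are `"high"`, at or
#' below it `"low"`. `"tertile"` cuts at the upper tertile; a numeric rule is
#' used as a fixed cut value. All-identical scores cannot be stratified.
#'
#' @param scores named numeric vector.
#' @param split_rule `"median"`, `"tertile"`, or a numeric cut.
#' @return named character vector of `"high"` / `"low"` labels.
#' @export
stratify_risk <- function(scores, split_rule = "median") {
  assert_that(length(scores) >= 2, "need >= 2 samples to stratify")
  assert_that(all(is.finite(scores)), "scores must be finite")
  assert_that(stats::var(scores) > 0, "all scores identical: no stratification possible")
  cut <- if (identical(split_rule, "median")) stats::median(scores)
         else if (identical(split_rule, "tertile")) stats::quantile(scores, 2 / 3, names = FALSE)
         else if (is_scalar_number(split_rule)) split_rule
         else stop_ith("split_rule must be 'median', 'tertile' or a number")
  stats::setNames(ifelse(scores > cut, "high", "low"), names(scores))
}

#' Intersect prognostic genes with the low-heterogeneity class
#'
#' Deduplicated set intersection of a prognostic gene list with the genes
#' classified `"low"` in a heterogeneity table, ordered by gene id. An empty
#' intersection is allowed but warned about.
#'
#' @param prognostic_genes character vector of gene ids.
#' @param het_table [score_all_genes()] output (needs gene_id, ith_class).
#' @return sorted character vector of gene ids.
#' @export
intersect_low_ith <- function(prognostic_genes, het_table) {
  assert_that(length(prognostic_genes) > 0, "prognostic gene list is empty")
  assert_that(all(c("gene_id", "ith_class") %in% names(het_table)),
              "heterogeneity table needs gene_id and ith_class")
  low <- het_table$gene_id[!is.na(het_table$ith_class) & het_table$ith_class == "low"]
  out <- sort(intersect(unique(prognostic_genes), low))
  if (length(out) == 0)
    warn_ith("intersect_low_ith: empty intersection")
  out
}

#' The full low-heterogeneity signature-selection funnel
#'
#' Composes the selection stages: differential-expression thresholds
#' ([filter_degs()]) -> univariate Cox + PH screen in each of two cohorts
#' ([cox_screen()]) restricted to the DEGs -> cross-cohort hazard-direction
#' consistency ([consistent_direction()]) -> intersection with the low-IHS
#' gene class ([intersect_low_ith()]).
#'
#' @param de differential table (gene_id, log2fc, fdr).
#' @param expr_a,surv_a training-cohort expression and survival.
#' @param expr_b,surv_b validation-cohort expression and survival.
#' @param het_table heterogeneity table from [score_all_genes()].
#' @param fc_cut,fdr_cut DEG thresholds.
#' @param alpha Cox significance level.
#' @return list: `genes` (final selection), plus the intermediate sets
#'   `degs`, `consistent`.
#' @export
select_signature_genes <- function(de, expr_a, surv_a, expr_b, surv_b, het_table,
                                   fc_cut = 0.137, fdr_cut = 0.05, alpha = 0.05) {
  degs <- filter_degs(de, fc_cut, fdr_cut)
  assert_that(length(degs) > 0, "no genes survive the DE thresholds")
  keep_a <- intersect(degs, rownames(expr_a))
  keep_b <- intersect(degs, rownames(expr_b))
  scr_a <- cox_screen(expr_a[keep_a, , drop = FALSE], surv_a)
  scr_b <- cox_screen(expr_b[keep_b, , drop = FALSE], surv_b)
  cons <- consistent_direction(scr_a, scr_b, alpha = alpha)
  genes <- if (length(cons) > 0) intersect_low_ith(cons, het_table) else character(0)
  list(genes = genes, degs = degs, consistent = cons,
       screen_a = scr_a, screen_b = scr_b)
}
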