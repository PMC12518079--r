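#' Patient-grouping curve for one gene
#'
#' Hierarchically clusters the samples on a single gene's expression values
#' (1-D, absolute-difference distance) and, for every cut level k = 1..N,
#' asks which multi-region patients still have all their regions inside one
#' cluster. `PGOR(k)` is the fraction of evaluable (multi-region) patients
#' correctly grouped at level k; single-region patients carry no grouping
#' information and are excluded from the denominator. `AUPC` is the
#' trapezoidal integral of the PGOR curve over the unit steps in k, so
#' `AUPC <= N - 1`. Genes whose regions cluster by patient keep PGOR high for
#' many k and have a large AUPC.
#'
#' @param values named numeric vector, one expression value per sample.
#' @param map sample map covering those samples.
#' @param linkage agglomeration rule for [stats::hclust()]: `"ward.D2"`
#'   (default; variance-minimizing merges suit the patient-grouping question
#'   and avoid the chaining noise of average linkage on 1-D values),
#'   `"average"`, `"complete"`, or `"single"`.
#' @return list of class `"pgor_curve"`: `k`, `pgor`, `aupc`, `n_samples`,
#'   `n_evaluable_patients`.
#' @export
pgor_curve <- function(values, map, linkage = "ward.D2") {
  assert_that(!is.null(names(values)), "values must be named by sample id")
  assert_that(all(is.finite(values)), "values must be finite")
  map <- validate_sample_map(map)
  assert_that(all(names(values) %in% map$sample_id),
              "every sample in values must appear in the sample map")
  patient <- map$patient_id[match(names(values), map$sample_id)]
  N <- length(values)
  assert_that(N >= 2, "need at least 2 samples")
  multi <- names(which(table(patient) >= 2))
  assert_that(length(multi) > 0,
              "no multi-region patient; the grouping curve is undefined")

  hc <- stats::hclust(stats::dist(values), method = linkage)
  cuts <- stats::cutree(hc, k = seq_len(N))  # N x N membership matrix
  pgor <- vapply(seq_len(N), function(k) {
    cl <- cuts[, k]
    ok <- vapply(multi, function(p) {
      length(unique(cl[patient == p])) == 1L
    }, logical(1))
    mean(ok)
  }, numeric(1))
  aupc <- sum((pgor[-1] + pgor[-N]) / 2)
  structure(list(k = seq_len(N), pgor = pgor, aupc = aupc,
                 n_samples = N, n_evaluable_patients = length(multi)),
            class = "pgor_curve")
}

#' Clustering consistency score
#'
#' `CCS = 1 - AUPC/(N - 1)`, clipped to `[0, 1]`. Genes that keep each
#' patient's regions together across many cut levels have large AUPC and
#' therefore *small* CCS: low CCS means low intra-tumor heterogeneity.
#'
#' @param curve a [pgor_curve()] result.
#' @return CCS in `[0, 1]`.
#' @export
ccs <- function(curve) {
  stopifnot(inherits(curve, "pgor_curve"))
  assert_that(curve$n_samples >= 2, "CCS needs N >= 2")
  min(max(1 - curve$aupc / (curve$n_samples - 1), 0), 1)
}

#' Integrated heterogeneity score
#'
#' Geometric mean of ITVS and CCS: `IHS = sqrt(ITVS * CCS)`. Both inputs live
#' on `[0, 1]` and agree in orientation (larger = more heterogeneous), so the
#' geometric mean demands that a gene look homogeneous on *both* the variance
#' and the clustering axis before it gets a low score. Undefined (`NA`)
#' inputs propagate.
#'
#' @param itvs_value,ccs_value scores in `[0, 1]` (vectorized).
#' @return IHS in `[0, 1]` or `NA`.
#' @export
ihs <- function(itvs_value, ccs_value) {
  ok <- !is.na(itvs_value) & !is.na(ccs_value)
  assert_that(all(itvs_value[ok] >= 0 & itvs_value[ok] <= 1), "ITVS outside [0,1]")
  assert_that(all(ccs_value[ok] >= 0 & ccs_value[ok] <= 1), "CCS outside [0,1]")
  sqrt(itvs_value * ccs_value)
}

#' Classify genes as low- or high-heterogeneity by IHS threshold
#'
#' `IHS <= threshold` (inclusive) is `"low"`; above it `"high"`; undefined IHS
#' stays unclassified (`NA`) and is counted in a warning.
#'
#' @param ihs_values numeric vector of IHS scores (may contain `NA`).
#' @param threshold cut-off in `[0, 1]`, default 0.5.
#' @return character vector of `"low"` / `"high"` / `NA`.
#' @export
classify_ith <- function(ihs_values, threshold = 0.5) {
  assert_that(is_scalar_number(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must be in [0, 1]")
  n_na <- sum(is.na(ihs_values))
  if (n_na > 0)
    warn_ith("classify_ith: %d gene(s) with undefined IHS left unclassified", n_na)
  ifelse(is.na(ihs_values), NA_character_,
         ifelse(ihs_values <= threshold, "low", "high"))
}

#' Score every gene: ITVS, CCS, IHS and heterogeneity class
#'
#' Batch driver over the rows of an expression matrix: variance partition
#' ([partition_variance()]) plus per-gene clustering consistency
#' ([pgor_curve()], [ccs()]), combined into IHS and thresholded into
#' low/high classes. Deterministic given inputs and options.
#'
#' @param expr expression matrix (genes x samples).
#' @param map sample map.
#' @param method variance estimator, `"mom"` or `"reml"`.
#' @param linkage clustering linkage rule.
#' @param threshold IHS class boundary (inclusive-low), default 0.5.
#' @param min_mean_expr optional minimum per-gene mean expression; genes below
#'   it are dropped before scoring (default `NULL`, no filter).
#' @return data.frame: gene_id, W, B, ITVS, AUPC, CCS, IHS, ith_class,
#'   degenerate_flag.
#' @export
score_all_genes <- function(expr, map, method = "mom", linkage = "ward.D2",
                            threshold = 0.5, min_mean_expr = NULL) {
  al <- align_samples(validate_expression(expr), map)
  expr <- al$expr; map <- al$map
  if (!is.null(min_mean_expr)) {
    keep <- rowMeans(expr) >= min_mean_expr
    assert_that(any(keep), "min_mean_expr filter removed every gene")
    expr <- expr[keep, , drop = FALSE]
  }
  vp <- partition_variance(expr, map, method = method)
  clu <- vapply(seq_len(nrow(expr)), function(i) {
    cv <- pgor_curve(expr[i, ], map, linkage = linkage)
    c(aupc = cv$aupc, ccs = ccs(cv))
  }, numeric(2))
  out <- data.frame(gene_id = vp$gene_id, W = vp$W, B = vp$B, ITVS = vp$ITVS,
                    AUPC = clu["aupc", ], CCS = clu["ccs", ],
                    stringsAsFactors = FALSE)
  out$IHS <- ihs(out$ITVS, out$CCS)
  out$ith_class <- suppressWarnings(classify_ith(out$IHS, threshold))
  out$degenerate_flag <- vp$degenerate_flag
  n_und <- sum(is.na(out$IHS))
  if (n_und > 0)
    warn_ith("score_all_genes: %d gene(s) with undefined IHS", n_und)
  out
}
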