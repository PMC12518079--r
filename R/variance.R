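#' Intra-tumoral variability score from variance components
#'
#' `ITVS = W / (W + B)` where `W` is the within-tumor (residual) variance and
#' `B` the between-tumor (patient-level) variance of a gene's expression. A
#' value near 1 means region-to-region variation inside tumors dominates the
#' gene's variability; near 0 means the gene mostly separates patients.
#'
#' @param W within-tumor variance (>= 0).
#' @param B between-tumor variance (>= 0).
#' @return `W/(W+B)`, or `NA` when `W + B == 0` (undefined).
#' @export
itvs <- function(W, B) {
  assert_that(all(is.finite(W)) && all(is.finite(B)), "W and B must be finite")
  assert_that(all(W >= 0) && all(B >= 0), "W and B must be non-negative")
  ifelse(W + B > 0, W / (W + B), NA_real_)
}

#' Per-gene decomposition of expression variance into W and B
#'
#' For each gene, fits the one-way random-intercept model
#' `expression ~ grand mean + patient effect` and reports the within-tumor
#' variance `W` (residual), the between-tumor variance `B` (patient effect)
#' and `ITVS = W/(W+B)`.
#'
#' The default `"mom"` estimator is the closed-form one-way ANOVA
#' method-of-moments with the unbalanced-design effective group size
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`: `W = MSW`,
#' `B = max(0, (MSB - MSW)/n0)` (negative moment estimates truncated to 0 and
#' flagged). `"reml"` fits the same model by restricted maximum likelihood via
#' \pkg{lme4}. Per-gene failures are flagged rows, never batch aborts.
#'
#' @param expr expression matrix (genes x samples) or a single gene's named
#'   numeric vector.
#' @param map sample map covering the expression samples.
#' @param method `"mom"` (default) or `"reml"`.
#' @return data.frame: gene_id, W, B, ITVS, estimator_tag, degenerate_flag.
#'   Flags: `"ok"`, `"truncated_B"` (negative moment estimate of B set to 0),
#'   `"constant"` (zero total variance, ITVS undefined), `"failed"`.
#' @export
partition_variance <- function(expr, map, method = c("mom", "reml")) {
  method <- match.arg(method)
  if (!is.matrix(expr)) expr <- matrix(expr, nrow = 1, dimnames = list("gene", names(expr)))
  al <- align_samples(validate_expression(expr), map)
  expr <- al$expr; map <- al$map
  groups <- factor(map$patient_id)
  assert_that(nlevels(groups) >= 2, "at least 2 patients required")
  assert_that(any(tabulate(groups) >= 2),
              "no patient has >= 2 regions; within-tumor variance is inestimable")

  fit_one <- if (method == "mom") {
    function(y) mom_one_way(y, groups)
  } else {
    function(y) reml_one_way(y, groups)
  }
  res <- lapply(seq_len(nrow(expr)), function(i) {
    out <- tryCatch(fit_one(expr[i, ]),
                    error = function(e) list(W = NA_real_, B = NA_real_, flag = "failed"))
    data.frame(gene_id = rownames(expr)[i], W = out$W, B = out$B,
               ITVS = if (is.na(out$W)) NA_real_ else itvs(out$W, out$B),
               estimator_tag = method, degenerate_flag = out$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# closed-form one-way ANOVA method-of-moments, unbalanced correction
mom_one_way <- function(y, groups) {
  n_i <- tabulate(groups)
  a <- length(n_i); N <- length(y)
  gm <- mean(y)
  means <- tapply(y, groups, mean)
  ssb <- sum(n_i * (means - gm)^2)
  ssw <- sum((y - means[as.integer(groups)])^2)
  if (ssb + ssw <= .Machine$double.eps * max(1, sum(y^2)))
    return(list(W = 0, B = 0, flag = "constant"))
  msw <- ssw / (N - a)
  msb <- ssb / (a - 1)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  B <- (msb - msw) / n0
  flag <- "ok"
  if (B < 0) { B <- 0; flag <- "truncated_B" }
  list(W = msw, B = B, flag = flag)
}

# REML one-way random-intercept fit via lme4
reml_one_way <- function(y, groups) {
  if (stats::var(y) <= .Machine$double.eps * max(1, mean(y^2)))
    return(list(W = 0, B = 0, flag = "constant"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = groups),
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  B <- vc$vcov[vc$grp == "g"]
  W <- vc$vcov[vc$grp == "Residual"]
  list(W = W, B = B, flag = if (B <= 0) "truncated_B" else "ok")
}
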