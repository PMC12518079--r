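#' Univariate Cox screen over genes with a proportional-hazards check
#'
#' Fits, per gene, a univariate Cox proportional-hazards model of survival on
#' continuous expression (partial likelihood, Efron ties) and tests the PH
#' assumption via the scaled Schoenfeld-residual correlation-with-time test
#' ([survival::cox.zph()]); `ph_ok` is `TRUE` when that test does not reject
#' at `ph_alpha`. Because rejecting the assumption *discards* the gene, the
#' check defaults to the conservative diagnostic level 0.01: at 0.05 the
#' screen would falsely exclude ~5% of genuinely proportional genes per
#' cohort, which compounds across multi-cohort funnels. Constant covariates
#' are flagged and skipped; fewer than 10 events triggers a warning. Per-gene
#' failures never abort the batch.
#'
#' @param expr expression matrix (genes x samples); columns must match the
#'   survival table's sample ids.
#' @param surv survival data.frame (sample_id, time, event).
#' @param ph_alpha rejection level of the PH assumption check (default 0.01).
#' @return data.frame: gene_id, hr, ci_low, ci_high, p_value, ph_ok, flag.
#' @export
cox_screen <- function(expr, surv, ph_alpha = 0.01) {
  validate_expression(expr); validate_survival(surv)
  shared <- intersect(colnames(expr), surv$sample_id)
  assert_that(length(shared) >= 3, "expression and survival share too few samples")
  expr <- expr[, shared, drop = FALSE]
  surv <- surv[match(shared, surv$sample_id), ]
  assert_that(sum(surv$event) >= 1, "no events in the survival table")
  if (sum(surv$event) < 10)
    warn_ith("cox_screen: only %d events; estimates will be unstable", sum(surv$event))
  S <- survival::Surv(surv$time, surv$event)

  rows <- lapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    if (stats::var(x) == 0) {
      return(data.frame(gene_id = rownames(expr)[i], hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, ph_ok = NA, flag = "constant",
                        stringsAsFactors = FALSE))
    }
    tryCatch({
      fit <- survival::coxph(S ~ x, ties = "efron")
      sm <- summary(fit)
      zph <- survival::cox.zph(fit, transform = "km")
      data.frame(gene_id = rownames(expr)[i],
                 hr = unname(sm$conf.int[1, "exp(coef)"]),
                 ci_low = unname(sm$conf.int[1, "lower .95"]),
                 ci_high = unname(sm$conf.int[1, "upper .95"]),
                 p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
                 ph_ok = zph$table["x", "p"] > ph_alpha,
                 flag = "ok", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene_id = rownames(expr)[i], hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_, ph_ok = NA,
                 flag = "failed", stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Genes with consistent hazard direction in two cohorts
#'
#' Keeps genes that are significant (at `alpha`), pass the PH check in both
#' screens, and whose hazard ratios sit on the same side of 1 in both cohorts
#' (`hr == 1` exactly has no direction and is dropped).
#'
#' @param res_a,res_b [cox_screen()] results sharing gene ids.
#' @param alpha per-screen significance level (default 0.05).
#' @return character vector of gene ids, sorted.
#' @export
consistent_direction <- function(res_a, res_b, alpha = 0.05) {
  shared <- intersect(res_a$gene_id, res_b$gene_id)
  assert_that(length(shared) > 0, "the two screens share no genes")
  a <- res_a[match(shared, res_a$gene_id), ]
  b <- res_b[match(shared, res_b$gene_id), ]
  keep <- !is.na(a$hr) & !is.na(b$hr) &
    a$p_value < alpha & b$p_value < alpha &
    !is.na(a$ph_ok) & a$ph_ok & !is.na(b$ph_ok) & b$ph_ok &
    sign(a$hr - 1) * sign(b$hr - 1) > 0
  sort(shared[keep])
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group plus the standard two-sample
#' log-rank chi-squared statistic (1 df).
#'
#' @param surv survival data.frame (sample_id, time, event).
#' @param labels group label per sample (two levels), aligned with `surv`
#'   rows or named by sample_id.
#' @return list: `fit` ([survival::survfit] object), `chisq`, `p_value`,
#'   `n_per_group`.
#' @export
km_logrank <- function(surv, labels) {
  validate_survival(surv)
  if (!is.null(names(labels))) labels <- labels[surv$sample_id]
  assert_that(length(labels) == nrow(surv), "one label per survival row required")
  g <- factor(labels)
  assert_that(nlevels(g) == 2, "log-rank comparison needs exactly 2 groups")
  assert_that(all(tapply(surv$event, g, sum) >= 1), "each group needs >= 1 event")
  S <- survival::Surv(surv$time, surv$event)
  sd_ <- survival::survdiff(S ~ g)
  list(fit = survival::survfit(S ~ g),
       chisq = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       n_per_group = as.vector(table(g)))
}

#' Time-dependent cumulative/dynamic AUC with IPCW weights
#'
#' For each horizon t, cases are subjects with an observed event by t and
#' controls are subjects still at risk beyond t; the AUC is the weighted
#' probability that a case scores higher than a control (ties count 1/2),
#' with cases weighted by the inverse Kaplan-Meier estimate of the censoring
#' survival function at their event time (left-continuous). With no censoring
#' the weights are 1 and the estimator reduces to the plain case/control AUC.
#'
#' @param scores named numeric risk scores (higher = higher risk).
#' @param surv survival data.frame covering the scored samples.
#' @param horizons evaluation times, each within the observed follow-up range.
#' @return data.frame: horizon, auc, n_cases, n_controls.
#' @export
time_dependent_auc <- function(scores, surv, horizons) {
  validate_survival(surv)
  if (!is.null(names(scores))) {
    shared <- intersect(names(scores), surv$sample_id)
    assert_that(length(shared) > 0, "scores and survival share no samples")
    scores <- scores[shared]
    surv <- surv[match(shared, surv$sample_id), ]
  }
  assert_that(length(scores) == nrow(surv), "one score per survival row required")
  assert_that(all(horizons > 0) && all(horizons <= max(surv$time)),
              "each horizon must lie within the observed follow-up range")
  time <- surv$time; event <- surv$event
  G <- censoring_km(time, event)

  out <- lapply(horizons, function(t) {
    case <- which(time <= t & event == 1)
    ctrl <- which(time > t)
    if (length(case) == 0 || length(ctrl) == 0)
      return(data.frame(horizon = t, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl)))
    w <- 1 / G(time[case])
    num <- 0
    for (j in seq_along(case)) {
      cmp <- sign(scores[case[j]] - scores[ctrl]) / 2 + 0.5  # 1, 0.5, 0
      num <- num + w[j] * sum(cmp)
    }
    data.frame(horizon = t, auc = num / (sum(w) * length(ctrl)),
               n_cases = length(case), n_controls = length(ctrl))
  })
  do.call(rbind, out)
}

# left-continuous KM estimator of the censoring survival function G(t-) =
# P(C >= t); censoring is the "event" (indicator flipped)
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- fit$time; ss <- fit$surv
  function(t) {
    # G evaluated just before t: step function of censoring times < t
    idx <- findInterval(t - .Machine$double.eps^0.5, st)
    g <- ifelse(idx == 0, 1, ss[pmax(idx, 1)])
    pmax(g, .Machine$double.eps)
  }
}

#' Harrell's concordance index
#'
#' Probability, over usable subject pairs, that the higher-risk subject fails
#' first; tied scores count 1/2. Computed via [survival::concordance()] with
#' risk orientation (higher score = shorter survival).
#'
#' @param scores named numeric risk scores.
#' @param surv survival data.frame covering the scored samples.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(scores, surv) {
  validate_survival(surv)
  if (!is.null(names(scores))) {
    shared <- intersect(names(scores), surv$sample_id)
    assert_that(length(shared) > 0, "scores and survival share no samples")
    scores <- scores[shared]
    surv <- surv[match(shared, surv$sample_id), ]
  }
  assert_that(length(scores) == nrow(surv), "one score per survival row required")
  fit <- survival::concordance(survival::Surv(surv$time, surv$event) ~ scores,
                               reverse = TRUE)
  unname(fit$concordance)
}
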