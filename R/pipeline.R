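#' Validate a pipeline configuration
#'
#' Exhaustive, side-effect-free field checking for [run_pipeline()] configs
#' (typically parsed from YAML). All problems are collected and reported
#' together rather than failing at the first.
#'
#' @param config named list; see [run_pipeline()] for the layout.
#' @return invisibly `TRUE` if valid; otherwise the character vector of
#'   error messages (and `ok = FALSE` attribute). Use [run_pipeline()] to
#'   fail hard.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  chk(is.list(config), "config must be a list")
  if (!is.list(config)) return(structure(errs, ok = FALSE))
  seed <- config$seed %||% 1L
  chk(is_scalar_number(seed) && seed >= 0 && seed == round(seed),
      "seed must be a non-negative integer")
  chk(is.character(config$outdir %||% "results") , "outdir must be a path")
  chk(!is.null(config$synthetic) || !is.null(config$inputs),
      "config needs a 'synthetic' or an 'inputs' section")
  if (!is.null(config$inputs)) {
    for (f in c("expression", "sample_map")) {
      p <- config$inputs[[f]]
      chk(!is.null(p), sprintf("inputs.%s is required", f))
      if (!is.null(p)) chk(file.exists(p), sprintf("inputs.%s: file not found: %s", f, p))
    }
    for (f in c("mutations", "de_table", "expr_a", "surv_a", "expr_b", "surv_b")) {
      p <- config$inputs[[f]]
      if (!is.null(p)) chk(file.exists(p), sprintf("inputs.%s: file not found: %s", f, p))
    }
  }
  het <- config$heterogeneity %||% list()
  thr <- het$threshold %||% 0.5
  chk(is_scalar_number(thr) && thr >= 0 && thr <= 1, "heterogeneity.threshold outside [0,1]")
  chk((het$method %||% "mom") %in% c("mom", "reml"), "heterogeneity.method must be mom|reml")
  chk((het$linkage %||% "ward.D2") %in% c("ward.D2", "average", "complete", "single"),
      "heterogeneity.linkage unknown")
  mth <- config$math %||% list()
  chk(is_scalar_number(mth$min_variants %||% 3) && (mth$min_variants %||% 3) >= 1,
      "math.min_variants must be >= 1")
  vf <- mth$vaf_floor %||% 0
  chk(is_scalar_number(vf) && vf >= 0 && vf < 1, "math.vaf_floor outside [0,1)")
  sig <- config$signature %||% list()
  chk(is_scalar_number(sig$fc_cut %||% 0.137) && (sig$fc_cut %||% 0.137) >= 0,
      "signature.fc_cut must be >= 0")
  fdr <- sig$fdr_cut %||% 0.05
  chk(is_scalar_number(fdr) && fdr > 0 && fdr <= 1, "signature.fdr_cut outside (0,1]")
  alpha <- sig$alpha %||% 0.05
  chk(is_scalar_number(alpha) && alpha > 0 && alpha < 1, "signature.alpha outside (0,1)")
  sr <- sig$split_rule %||% "median"
  chk((is.character(sr) && sr %in% c("median", "tertile")) || is_scalar_number(sr),
      "signature.split_rule must be median|tertile|number")

  if (length(errs) == 0) invisible(TRUE) else structure(errs, ok = FALSE)
}

#' Run the heterogeneity -> selection -> model -> evaluation pipeline
#'
#' Executes the stages in dependency order on either generated data
#' (`config$synthetic`, via [generate_signature_study()] and
#' [generate_vaf()]) or files (`config$inputs`). Every stage writes its table
#' under `config$outdir`, and a `manifest.json` records the parameters, seed,
#' package version and an MD5 hash of every output, so a rerun with the same
#' config is byte-identical and verifiably so.
#'
#' Config layout (all parameters optional unless noted):
#' \preformatted{
#' seed: 1
#' outdir: results/pipeline
#' synthetic: {n_genes: 300, planted: [1, 2], n_cohort: 150, log_hr: 1,
#'             n_vaf_samples: 10}
#' inputs:    {expression:, sample_map:, mutations:, de_table:,
#'             expr_a:, surv_a:, expr_b:, surv_b:}   # alternative to synthetic
#' heterogeneity: {method: mom, linkage: ward.D2, threshold: 0.5}
#' math:          {min_variants: 3, vaf_floor: 0}
#' signature:     {fc_cut: 0.137, fdr_cut: 0.05, alpha: 0.05,
#'                 split_rule: median, horizons: [...], weights: {gene: w}}
#' }
#' In synthetic mode the signature stage runs the full selection funnel on the
#' generated two-cohort study and evaluates the resulting model (configured
#' `weights` if given, else unit weights over the selected genes) on cohort B.
#'
#' @param config named list (e.g. [yaml::read_yaml()] output).
#' @return invisible list of stage results (heterogeneity table, math table,
#'   selection, evaluation, manifest path).
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (!isTRUE(v)) stop_ith("invalid pipeline config:\n  - %s", paste(v, collapse = "\n  - "))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% "results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  het_cfg <- config$heterogeneity %||% list()
  sig_cfg <- config$signature %||% list()
  math_cfg <- config$math %||% list()
  results <- list()
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                                 sprintf(fmt, ...)))

  # ---- stage: data ----
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    log_stage("stage data: generating synthetic study (seed %d)", seed)
    study <- generate_signature_study(n_genes = sy$n_genes %||% 300,
                                      planted = unlist(sy$planted %||% 1:2),
                                      n_cohort = sy$n_cohort %||% 150,
                                      log_hr = sy$log_hr %||% 1, seed = seed)
    expr <- study$het$expr; map <- study$het$map
    muts <- generate_vaf(synth_config(seed = seed), n_samples = sy$n_vaf_samples %||% 10)
    de <- study$de
    cohorts <- list(a = study$cohortA, b = study$cohortB)
  } else {
    log_stage("stage data: reading inputs")
    expr <- read_expression(config$inputs$expression)
    map <- read_sample_map(config$inputs$sample_map)
    muts <- if (!is.null(config$inputs$mutations)) read_mutations(config$inputs$mutations)
    de <- if (!is.null(config$inputs$de_table))
      data.table::fread(config$inputs$de_table, data.table = FALSE)
    cohorts <- if (!is.null(config$inputs$expr_a))
      list(a = list(expr = read_expression(config$inputs$expr_a),
                    surv = read_survival(config$inputs$surv_a)),
           b = list(expr = read_expression(config$inputs$expr_b),
                    surv = read_survival(config$inputs$surv_b)))
  }

  # ---- stage: heterogeneity ----
  log_stage("stage heterogeneity: scoring %d genes x %d samples", nrow(expr), ncol(expr))
  het <- suppressWarnings(
    score_all_genes(expr, map, method = het_cfg$method %||% "mom",
                    linkage = het_cfg$linkage %||% "ward.D2",
                    threshold = het_cfg$threshold %||% 0.5))
  write_tsv_out(het, file.path(outdir, "heterogeneity.tsv"))
  results$heterogeneity <- het
  log_stage("stage heterogeneity: %d low / %d high / %d unclassified",
            sum(het$ith_class == "low", na.rm = TRUE),
            sum(het$ith_class == "high", na.rm = TRUE), sum(is.na(het$ith_class)))

  # ---- stage: math ----
  if (!is.null(muts)) {
    mt <- suppressWarnings(math_by_sample(muts, min_variants = math_cfg$min_variants %||% 3,
                                          vaf_floor = math_cfg$vaf_floor %||% 0))
    write_tsv_out(mt, file.path(outdir, "math.tsv"))
    results$math <- mt
    log_stage("stage math: %d samples scored", nrow(mt))
  }

  # ---- stage: signature selection + evaluation ----
  if (!is.null(de) && !is.null(cohorts)) {
    log_stage("stage signature: selection funnel")
    sel <- suppressWarnings(
      select_signature_genes(de, cohorts$a$expr, cohorts$a$surv,
                             cohorts$b$expr, cohorts$b$surv, het,
                             fc_cut = sig_cfg$fc_cut %||% 0.137,
                             fdr_cut = sig_cfg$fdr_cut %||% 0.05,
                             alpha = sig_cfg$alpha %||% 0.05))
    write_tsv_out(data.frame(gene_id = sel$genes), file.path(outdir, "selected_genes.tsv"))
    results$selection <- sel
    log_stage("stage signature: %d DEGs -> %d direction-consistent -> %d low-ITH",
              length(sel$degs), length(sel$consistent), length(sel$genes))

    model_genes <- if (!is.null(sig_cfg$weights)) names(sig_cfg$weights) else sel$genes
    if (length(model_genes) > 0 && all(model_genes %in% rownames(cohorts$b$expr))) {
      w <- if (!is.null(sig_cfg$weights)) unlist(sig_cfg$weights)
           else stats::setNames(rep(1, length(model_genes)), model_genes)
      model <- risk_model(w, split_rule = sig_cfg$split_rule %||% "median")
      scores <- risk_score(cohorts$b$expr, model)
      groups <- stratify_risk(scores, model$split_rule)
      surv_b <- cohorts$b$surv
      km <- km_logrank(surv_b, groups)
      horizons <- unlist(sig_cfg$horizons) %||%
        unname(stats::quantile(surv_b$time, c(0.25, 0.5, 0.75)))
      auc <- time_dependent_auc(scores, surv_b, horizons)
      cidx <- concordance_index(scores, surv_b)
      write_tsv_out(data.frame(sample_id = names(scores), score = unname(scores),
                               group = unname(groups)),
                    file.path(outdir, "risk_groups.tsv"))
      write_tsv_out(cbind(auc, logrank_chisq = km$chisq, logrank_p = km$p_value,
                          c_index = cidx),
                    file.path(outdir, "evaluation.tsv"))
      results$evaluation <- list(km = km, auc = auc, c_index = cidx,
                                 scores = scores, groups = groups)
      log_stage("stage evaluation: log-rank p = %.3g, C-index = %.3f", km$p_value, cidx)
    } else {
      log_stage("stage evaluation: skipped (no usable model genes)")
    }
  }

  # ---- manifest ----
  outs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("ithscore")),
                   parameters = config[setdiff(names(config), c("inputs"))],
                   input_files = if (!is.null(config$inputs))
                     as.list(tools::md5sum(unlist(config$inputs))),
                   outputs = as.list(tools::md5sum(outs)),
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- mpath
  invisible(results)
}

write_tsv_out <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
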