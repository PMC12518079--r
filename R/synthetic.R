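#' Configuration for the multi-region synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_expression()],
#' [generate_survival()] and [generate_vaf()]. Per-gene expression follows a
#' one-way random-effects (random-intercept) model on a VST-like scale:
#'
#'   x_{g,p,s} = mu_g + b_{g,p} + e_{g,p,s},
#'   b_{g,p} ~ N(0, B_g),  e_{g,p,s} ~ N(0, W_g),
#'
#' so the true intra-tumoral variability of gene g is rho_g = W_g/(W_g + B_g).
#' Defaults emulate a small multi-region tumor cohort: 10 patients with an
#' unbalanced region design of 32 samples total, gene means ~ N(8, 2), per-gene
#' total variance lognormal around 0.5, and rho_g ~ Beta(3.2, 1) (median ~0.81,
#' the right-skewed ITVS regime typical of multi-region tumor RNA-seq).
#'
#' @param n_patients number of patients P (>= 2).
#' @param regions_per_patient regions per patient: scalar or length-P vector.
#'   Default is the unbalanced pattern `c(4,4,4,4,3,3,3,3,2,2)` (32 samples).
#' @param n_genes number of genes G.
#' @param mu per-gene grand mean; scalar, length-G vector, or `NULL` to draw
#'   N(8, 2).
#' @param rho per-gene true ITVS W/(W+B); scalar, length-G vector, or `NULL`
#'   to draw Beta(3.2, 1).
#' @param total_var per-gene total variance W + B; scalar, length-G vector, or
#'   `NULL` to draw lognormal(log 0.5, 0.5).
#' @param baseline_hazard exponential baseline hazard (events per time unit)
#'   for [generate_survival()].
#' @param censor_rate target fraction of censored subjects in `[0, 1)`.
#' @param vaf_center mean VAF for [generate_vaf()] (Beta mean).
#' @param vaf_spread VAF standard deviation (Beta sd); must satisfy
#'   `vaf_spread^2 < vaf_center * (1 - vaf_center)`.
#' @param variants_per_sample variants drawn per sample (>= 3).
#' @param seed integer seed; the seed fully determines every draw.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(n_patients = 10,
                         regions_per_patient = c(4, 4, 4, 4, 3, 3, 3, 3, 2, 2),
                         n_genes = 500,
                         mu = NULL, rho = NULL, total_var = NULL,
                         baseline_hazard = 0.02, censor_rate = 0.3,
                         vaf_center = 0.35, vaf_spread = 0.10,
                         variants_per_sample = 30,
                         seed = 1L) {
  assert_that(is_scalar_number(n_patients) && n_patients >= 2, "n_patients must be >= 2")
  n_patients <- as.integer(n_patients)
  r <- recycle_to(regions_per_patient, n_patients, "regions_per_patient")
  assert_that(all(r >= 1) && all(r == round(r)), "regions_per_patient must be positive integers")
  assert_that(is_scalar_number(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  assert_that(is_scalar_number(baseline_hazard) && baseline_hazard > 0,
              "baseline_hazard must be > 0")
  assert_that(is_scalar_number(censor_rate) && censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  assert_that(is_scalar_number(vaf_center) && vaf_center > 0 && vaf_center < 1,
              "vaf_center must be in (0, 1)")
  assert_that(is_scalar_number(vaf_spread) && vaf_spread >= 0 &&
                vaf_spread^2 < vaf_center * (1 - vaf_center),
              "vaf_spread^2 must be < vaf_center * (1 - vaf_center)")
  assert_that(is_scalar_number(variants_per_sample) && variants_per_sample >= 3,
              "variants_per_sample must be >= 3")
  assert_that(is_scalar_number(seed) && seed == round(seed) && seed >= 0,
              "seed must be a non-negative integer")
  if (!is.null(rho)) {
    rho <- recycle_to(rho, n_genes, "rho")
    assert_that(all(rho >= 0 & rho <= 1), "rho must be in [0, 1]")
  }
  if (!is.null(total_var)) {
    total_var <- recycle_to(total_var, n_genes, "total_var")
    assert_that(all(total_var >= 0), "total_var must be >= 0")
  }
  if (!is.null(mu)) mu <- recycle_to(mu, n_genes, "mu")
  structure(list(n_patients = n_patients, regions_per_patient = as.integer(r),
                 n_genes = as.integer(n_genes), mu = mu, rho = rho,
                 total_var = total_var,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 vaf_center = vaf_center, vaf_spread = vaf_spread,
                 variants_per_sample = as.integer(variants_per_sample),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a multi-region expression matrix with known heterogeneity truth
#'
#' Samples the one-way random-effects model described in [synth_config()]:
#' each gene gets a grand mean, a per-patient random intercept with variance
#' `B_g` and per-region Gaussian noise with variance `W_g`. The returned truth
#' table carries the generating `W_g`, `B_g` and `rho_g = W_g/(W_g+B_g)` that
#' downstream estimators should recover.
#'
#' @param config a [synth_config()] object.
#' @return list with `expr` (genes x samples matrix), `map` (sample map
#'   data.frame) and `truth` (data.frame gene_id, W, B, rho).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  P <- config$n_patients; r <- config$regions_per_patient; G <- config$n_genes
  N <- sum(r)
  patient <- rep(sprintf("P%02d", seq_len(P)), times = r)
  region <- unlist(lapply(r, seq_len), use.names = FALSE)
  map <- data.frame(sample_id = sprintf("%s_R%d", patient, region),
                    patient_id = patient,
                    region_id = sprintf("R%d", region),
                    stringsAsFactors = FALSE)

  mu <- config$mu %||% stats::rnorm(G, mean = 8, sd = 2)
  rho <- config$rho %||% stats::rbeta(G, 3.2, 1)
  tv <- config$total_var %||% stats::rlnorm(G, meanlog = log(0.5), sdlog = 0.5)
  W <- rho * tv
  B <- (1 - rho) * tv

  # G x P patient effects, expanded to G x N; then per-cell residuals
  bmat <- matrix(stats::rnorm(G * P), nrow = G) * sqrt(B)
  emat <- matrix(stats::rnorm(G * N), nrow = G) * sqrt(W)
  pat_idx <- rep(seq_len(P), times = r)
  expr <- mu + bmat[, pat_idx, drop = FALSE] + emat
  dimnames(expr) <- list(sprintf("G%04d", seq_len(G)), map$sample_id)

  list(expr = expr, map = map,
       truth = data.frame(gene_id = rownames(expr), W = W, B = B,
                          rho = ifelse(W + B > 0, W / (W + B), NA_real_),
                          stringsAsFactors = FALSE))
}

#' Generate exponential survival times driven by a linear risk score
#'
#' Event times are exponential with per-subject log-hazard
#' `log(baseline_hazard) + score`; censoring times are uniform on `(0, u)`
#' with `u` calibrated numerically so the expected censored fraction equals
#' `config$censor_rate` (no censoring when the target is 0).
#'
#' @param scores named numeric vector, one linear-predictor value per subject;
#'   names become `sample_id`s (generated if absent).
#' @param config a [synth_config()] object (uses `baseline_hazard`,
#'   `censor_rate`, `seed`).
#' @return survival data.frame: sample_id, time, event.
#' @export
generate_survival <- function(scores, config) {
  stopifnot(inherits(config, "synth_config"))
  assert_that(length(scores) > 0, "scores must be non-empty")
  assert_that(all(is.finite(scores)), "scores must be finite")
  ids <- names(scores) %||% sprintf("S%04d", seq_along(scores))
  set.seed(config$seed + 1L)
  rate <- config$baseline_hazard * exp(scores)
  t_event <- stats::rexp(length(scores), rate = rate)
  if (config$censor_rate == 0) {
    time <- t_event; event <- rep(1, length(scores))
  } else {
    u <- calibrate_uniform_censoring(rate, config$censor_rate)
    c_time <- stats::runif(length(scores), 0, u)
    event <- as.numeric(t_event <= c_time)
    time <- pmin(t_event, c_time)
  }
  validate_survival(data.frame(sample_id = ids, time = pmax(time, .Machine$double.eps),
                               event = event, stringsAsFactors = FALSE))
}

# expected censored fraction with C ~ U(0,u), T_i ~ Exp(rate_i):
#   P(T_i > C) = (1 - exp(-rate_i * u)) / (rate_i * u), averaged over i.
# Decreasing in u from 1 to 0; solve for the target by bisection.
calibrate_uniform_censoring <- function(rate, target) {
  f <- function(u) mean(-expm1(-rate * u) / (rate * u)) - target
  hi <- 1 / min(rate)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(.Machine$double.eps, hi), tol = 1e-10)$root
}

#' Generate per-sample variant-allele-fraction sets
#'
#' Each sample receives `variants_per_sample` VAFs drawn from a Beta
#' distribution with mean `vaf_center` and standard deviation `vaf_spread`
#' (clipped away from exact 0/1). `vaf_spread = 0` yields constant VAFs, the
#' MATH = 0 limit; larger spread yields larger expected MATH.
#'
#' @param config a [synth_config()] object.
#' @param n_samples number of mutation samples to draw.
#' @return mutation data.frame: sample_id, variant_id, vaf.
#' @export
generate_vaf <- function(config, n_samples = 10) {
  stopifnot(inherits(config, "synth_config"))
  assert_that(is_scalar_number(n_samples) && n_samples >= 1, "n_samples must be >= 1")
  set.seed(config$seed + 2L)
  m <- config$vaf_center; s <- config$vaf_spread; k <- config$variants_per_sample
  n <- as.integer(n_samples)
  if (s == 0) {
    vaf <- rep(m, n * k)
  } else {
    conc <- m * (1 - m) / s^2 - 1   # Beta concentration from mean/sd
    assert_that(conc > 0, "vaf_spread too large for vaf_center")
    vaf <- stats::rbeta(n * k, shape1 = m * conc, shape2 = (1 - m) * conc)
    vaf <- pmin(pmax(vaf, 1e-6), 1 - 1e-6)
  }
  data.frame(sample_id = rep(sprintf("M%03d", seq_len(n)), each = k),
             variant_id = rep(sprintf("v%03d", seq_len(k)), times = n),
             vaf = vaf, stringsAsFactors = FALSE)
}

#' Simulate a two-cohort signature-discovery study with planted genes
#'
#' Builds the full substrate for the gene-selection funnel: a multi-region
#' expression matrix for heterogeneity scoring in which a small set of planted
#' genes is low-heterogeneity (low rho, strong patient separation) while the
#' background is high-heterogeneity, plus two independent patient-level
#' cohorts (expression + survival) in which only the planted genes carry a
#' survival effect, with a shared hazard direction.
#'
#' The planted genes' patient-level expressions load on a shared latent factor
#' (pairwise correlation 0.9), as co-regulated signature genes do; the hazard
#' is proportional in their sum, so each gene's *marginal* univariate Cox
#' model is also very nearly proportional-hazards. (With independent planted
#' effects the omitted-covariate attenuation would make each marginal model
#' non-PH and the screen would discard true genes by design.)
#'
#' @param n_genes total genes.
#' @param planted indices of planted signature genes (default first 2).
#' @param n_cohort subjects per survival cohort.
#' @param log_hr log hazard ratio per unit of each planted gene's centered
#'   expression (shared direction across cohorts).
#' @param seed integer seed.
#' @return list with `het` inputs (`expr`, `map`, `truth`), per-cohort
#'   patient-level `expr` and `surv` (`cohortA`, `cohortB`), `de` (a complete
#'   differential table in which every gene passes the default thresholds, so
#'   selection is decided by the survival screen and the heterogeneity class),
#'   and `planted` gene ids.
#' @export
generate_signature_study <- function(n_genes = 500, planted = 1:2,
                                     n_cohort = 200, log_hr = 0.5, seed = 1L) {
  assert_that(all(planted >= 1 & planted <= n_genes), "planted indices out of range")
  rho <- rep(0.9, n_genes); rho[planted] <- 0.05
  cfg <- synth_config(n_patients = 10, regions_per_patient = 3, n_genes = n_genes,
                      rho = rho, total_var = 1, seed = seed)
  het <- generate_expression(cfg)

  make_cohort <- function(sub_seed) {
    set.seed(sub_seed)
    x <- matrix(stats::rnorm(n_genes * n_cohort, mean = 8), nrow = n_genes,
                dimnames = list(rownames(het$expr), sprintf("C%s_%03d", sub_seed, seq_len(n_cohort))))
    # planted genes share a latent factor (r = 0.9), unit marginal variance
    f <- stats::rnorm(n_cohort)
    for (g in planted)
      x[g, ] <- 8 + sqrt(0.9) * f + sqrt(0.1) * stats::rnorm(n_cohort)
    score <- colSums(x[planted, , drop = FALSE] - 8) * log_hr
    surv <- generate_survival(stats::setNames(score, colnames(x)),
                              synth_config(seed = sub_seed, censor_rate = 0.2))
    list(expr = x, surv = surv)
  }
  gene_ids <- rownames(het$expr)
  # DE table passing all genes: selection pressure comes from Cox + heterogeneity
  de <- data.frame(gene_id = gene_ids, log2fc = 1, fdr = 0.001,
                   stringsAsFactors = FALSE)
  list(het = het,
       cohortA = make_cohort(seed * 1000L + 7L),
       cohortB = make_cohort(seed * 1000L + 8L),
       de = de, planted = gene_ids[planted])
}
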