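test_that("generator is deterministic and honors the design layout", {
  cfg <- synth_config(n_genes = 20, seed = 7)
  d1 <- generate_expression(cfg)
  d2 <- generate_expression(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$truth, d2$truth)
  expect_equal(ncol(d1$expr), 32)                        # default unbalanced design
  expect_equal(length(unique(d1$map$patient_id)), 10)
  expect_equal(as.vector(table(d1$map$patient_id)), c(4, 4, 4, 4, 3, 3, 3, 3, 2, 2))
})

test_that("zero within-patient variance makes regions identical; zero between collapses patients", {
  cfg <- synth_config(n_patients = 4, regions_per_patient = 3, n_genes = 5,
                      rho = 0, total_var = 2, seed = 1)
  d <- generate_expression(cfg)
  for (p in unique(d$map$patient_id)) {
    sub <- d$expr[, d$map$patient_id == p, drop = FALSE]
    expect_lt(max(apply(sub, 1, function(x) diff(range(x)))), 1e-12)
  }
  # B = 0: patient means differ only by sampling error, ITVS -> 1 with many regions
  cfgB <- synth_config(n_patients = 10, regions_per_patient = 30, n_genes = 50,
                       rho = 1, total_var = 1, seed = 2)
  dB <- generate_expression(cfgB)
  vp <- partition_variance(dB$expr, dB$map)
  expect_gt(mean(vp$ITVS), 0.93)
})

test_that("empirical variance components converge to the generating W and B", {
  cfg <- synth_config(n_patients = 50, regions_per_patient = 6, n_genes = 100,
                      rho = 0.4, total_var = 1, seed = 3)
  d <- generate_expression(cfg)
  vp <- partition_variance(d$expr, d$map)
  expect_lt(abs(mean(vp$W) - 0.4), 0.04)   # 10% of the true W
  expect_lt(abs(mean(vp$B) - 0.6), 0.06)
})

test_that("survival generator calibrates censoring and encodes the score effect", {
  cfg0 <- synth_config(censor_rate = 0, seed = 5)
  s0 <- generate_survival(rnorm(100), cfg0)
  expect_true(all(s0$event == 1))

  cfg3 <- synth_config(censor_rate = 0.3, seed = 5)
  s3 <- generate_survival(rnorm(2000), cfg3)
  expect_lt(abs(mean(1 - s3$event) - 0.3), 0.05)

  # +2 log-hazard group dies sooner in nearly every replicate
  worse <- logical(40)
  for (i in seq_len(40)) {
    cfg <- synth_config(censor_rate = 0, seed = 100 + i)
    sv <- generate_survival(rep(c(0, 2), each = 100), cfg)
    med <- tapply(sv$time, rep(c("lo", "hi"), each = 100), median)
    worse[i] <- med["hi"] < med["lo"]
  }
  expect_gte(mean(worse), 0.95)
})

test_that("equal scores give an exchangeable null for the log-rank test", {
  cfg <- synth_config(censor_rate = 0.2, seed = 11)
  sv <- generate_survival(rep(0, 200), cfg)
  set.seed(1)
  lr <- km_logrank(sv, sample(rep(c("a", "b"), 100)))
  expect_gt(lr$p_value, 0.001)  # any random split is null
})

test_that("VAF generator: zero spread gives MATH 0, larger spread larger MATH", {
  cfg0 <- synth_config(vaf_spread = 0, seed = 4)
  v0 <- generate_vaf(cfg0, n_samples = 3)
  m0 <- math_by_sample(v0)
  expect_true(all(m0$math == 0))

  means <- sapply(c(0.05, 0.15), function(s) {
    cfg <- synth_config(vaf_spread = s, seed = 21)
    mean(math_by_sample(generate_vaf(cfg, n_samples = 50))$math)
  })
  expect_gt(means[2], means[1])
})

test_that("config validation rejects impossible parameters", {
  expect_error(synth_config(n_patients = 1), "n_patients")
  expect_error(synth_config(rho = 1.2, n_genes = 1), "rho")
  expect_error(synth_config(censor_rate = 1), "censor_rate")
  expect_error(synth_config(vaf_center = 0.5, vaf_spread = 0.6), "vaf_spread")
  expect_error(synth_config(regions_per_patient = c(2, 2, 2)), "regions_per_patient")
})
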