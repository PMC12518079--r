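test_that("itvs follows its defining ratio and flags the degenerate case", {
  expect_equal(itvs(1, 0), 1)
  expect_equal(itvs(0, 3), 0)
  expect_equal(itvs(2, 2), 0.5)
  expect_true(is.na(itvs(0, 0)))
  expect_error(itvs(-1, 2), "non-negative")
})

test_that("method-of-moments matches the hand-computed balanced ANOVA example", {
  map <- toy_map(c("P1", "P1", "P2", "P2"))
  e <- matrix(c(0, 2, 10, 12), 1, dimnames = list("g1", map$sample_id))
  vp <- partition_variance(e, map)
  expect_equal(vp$W, 2)
  expect_equal(vp$B, 49)           # (MSB - MSW)/n0 = (100 - 2)/2
  expect_equal(vp$ITVS, 2 / 51)
  expect_equal(vp$degenerate_flag, "ok")

  # zero within-patient spread
  e0 <- matrix(c(0, 0, 1, 1), 1, dimnames = list("g1", map$sample_id))
  vp0 <- partition_variance(e0, map)
  expect_equal(vp0$W, 0); expect_gt(vp0$B, 0); expect_equal(vp0$ITVS, 0)

  # constant gene is degenerate, not an error
  ec <- matrix(5, 1, 4, dimnames = list("g1", map$sample_id))
  vpc <- partition_variance(ec, map)
  expect_equal(vpc$degenerate_flag, "constant")
  expect_true(is.na(vpc$ITVS))
})

test_that("MoM equals the independent closed-form oracle on unbalanced designs", {
  set.seed(42)
  for (rep in 1:20) {
    sizes <- sample(1:4, 5, replace = TRUE)
    if (!any(sizes >= 2)) sizes[1] <- 2
    pats <- rep(paste0("P", 1:5), sizes)
    y <- rnorm(length(pats), mean = rep(rnorm(5), sizes))
    map <- toy_map(pats)
    e <- matrix(y, 1, dimnames = list("g", map$sample_id))
    vp <- partition_variance(e, map)
    orc <- anova_vc_oracle(y, pats)
    expect_equal(vp$W, unname(orc["W"]), tolerance = 1e-10)
    expect_equal(vp$B, unname(orc["B"]), tolerance = 1e-10)
    expect_equal(vp$ITVS, unname(orc["ITVS"]), tolerance = 1e-10)
  }
})

test_that("negative moment estimates of B are truncated to zero and flagged", {
  set.seed(7)
  # patients drawn from one distribution -> B estimate often negative
  map <- toy_map(rep(paste0("P", 1:3), each = 2))
  found <- FALSE
  for (i in 1:50) {
    e <- matrix(rnorm(6), 1, dimnames = list("g", map$sample_id))
    vp <- partition_variance(e, map)
    expect_gte(vp$B, 0)
    expect_true(vp$ITVS >= 0 && vp$ITVS <= 1)
    if (vp$degenerate_flag == "truncated_B") {
      found <- TRUE
      expect_equal(vp$ITVS, 1)  # B = 0 forces the ratio to 1
    }
  }
  expect_true(found)
})

test_that("ITVS is invariant under positive affine transforms of a gene", {
  set.seed(9)
  map <- toy_map(rep(paste0("P", 1:5), each = 3))
  y <- rnorm(15, rep(rnorm(5, sd = 2), each = 3))
  e1 <- matrix(y, 1, dimnames = list("g", map$sample_id))
  e2 <- matrix(3.7 * y + 11, 1, dimnames = list("g", map$sample_id))
  v1 <- partition_variance(e1, map)$ITVS
  v2 <- partition_variance(e2, map)$ITVS
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("REML agrees with MoM on balanced designs and flags failures gracefully", {
  cfg <- synth_config(n_patients = 8, regions_per_patient = 3, n_genes = 40,
                      rho = runif(40, 0.1, 0.9), total_var = 1, seed = 13)
  d <- generate_expression(cfg)
  mom <- partition_variance(d$expr, d$map, method = "mom")
  reml <- partition_variance(d$expr, d$map, method = "reml")
  expect_lt(max(abs(mom$ITVS - reml$ITVS)), 0.02)
  expect_true(all(reml$estimator_tag == "reml"))
})

test_that("designs without replication are rejected", {
  map <- toy_map(c("P1", "P2", "P3"))
  e <- matrix(rnorm(3), 1, dimnames = list("g", map$sample_id))
  expect_error(partition_variance(e, map), "no patient has")
  map1 <- toy_map(c("P1", "P1"))
  e1 <- matrix(rnorm(2), 1, dimnames = list("g", map1$sample_id))
  expect_error(partition_variance(e1, map1), "2 patients")
})
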