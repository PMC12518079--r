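test_that("PGOR curve reproduces the hand-traced two-patient example", {
  map <- toy_map(c("P1", "P1", "P2", "P2"), ids = c("a", "b", "c", "d"))
  cv <- pgor_curve(c(a = 0, b = 0.1, c = 10, d = 10.2), map)
  expect_equal(cv$pgor, c(1, 1, 0.5, 0))
  expect_equal(cv$aupc, 2)
  expect_equal(ccs(cv), 1 / 3)
  expect_equal(cv$n_evaluable_patients, 2)
})

test_that("PGOR endpoints are forced: 1 at k=1, 0 at k=N for all-multi-region designs", {
  set.seed(31)
  for (i in 1:10) {
    pats <- rep(paste0("P", 1:3), each = 2)
    map <- toy_map(pats)
    v <- setNames(rnorm(6), map$sample_id)
    cv <- pgor_curve(v, map)
    expect_equal(cv$pgor[1], 1)
    expect_equal(cv$pgor[6], 0)
    expect_lte(cv$aupc, 5)
  }
})

test_that("PGOR at every cut level matches the naive agglomerative oracle (N <= 6)", {
  set.seed(17)
  layouts <- list(c("P1", "P1", "P2", "P2"),
                  c("P1", "P1", "P1", "P2", "P2"),
                  c("P1", "P1", "P2", "P2", "P3", "P3"),
                  c("P1", "P1", "P1", "P2", "P2", "P3"))  # P3 single-region
  for (pats in layouts) {
    for (rep in 1:10) {
      map <- toy_map(pats)
      v <- setNames(rnorm(length(pats), sd = 3), map$sample_id)
      cv <- pgor_curve(v, map)
      expect_equal(cv$pgor, naive_pgor_oracle(unname(v), pats))
    }
  }
})

test_that("single-region patients are excluded from the PGOR denominator", {
  map <- toy_map(c("P1", "P1", "P2"))
  cv <- pgor_curve(setNames(c(0, 0.1, 5), map$sample_id), map)
  expect_equal(cv$n_evaluable_patients, 1)
  expect_equal(cv$pgor, c(1, 1, 0))  # only P1 evaluated
  map_none <- toy_map(c("P1", "P2"))
  expect_error(pgor_curve(setNames(c(0, 1), map_none$sample_id), map_none),
               "no multi-region patient")
})

test_that("CCS arithmetic follows 1 - AUPC/(N-1) with clipping", {
  mk <- function(pgor) structure(list(k = seq_along(pgor), pgor = pgor,
                                      aupc = sum((pgor[-1] + pgor[-length(pgor)]) / 2),
                                      n_samples = length(pgor),
                                      n_evaluable_patients = 2),
                                 class = "pgor_curve")
  expect_equal(ccs(mk(rep(1, 5))), 0)              # maximal consistency
  expect_equal(ccs(mk(c(1, 0, 0, 0, 0))), 1 - 0.5 / 4)
})

test_that("IHS is the symmetric geometric mean with NA propagation", {
  expect_equal(ihs(0.25, 0.25), 0.25)
  expect_equal(ihs(1, 0), 0)
  expect_equal(ihs(0.9, 0.4), 0.6)
  expect_equal(ihs(0.3, 0.8), ihs(0.8, 0.3))
  expect_true(is.na(ihs(NA, 0.5)))
  expect_error(ihs(1.2, 0.5), "outside")
})

test_that("classification uses an inclusive-low boundary and reports undefined scores", {
  expect_equal(classify_ith(c(0.2, 0.5, 0.7)), c("low", "low", "high"))
  expect_equal(classify_ith(c(0, 0.2), threshold = 0), c("low", "high"))
  expect_warning(cl <- classify_ith(c(NA, NA)), "unclassified")
  expect_true(all(is.na(cl)))
  expect_error(classify_ith(0.5, threshold = 2), "threshold")
})

test_that("score_all_genes is order-invariant and handles a single gene", {
  cfg <- synth_config(n_patients = 5, regions_per_patient = 3, n_genes = 8, seed = 23)
  d <- generate_expression(cfg)
  t1 <- score_all_genes(d$expr, d$map)
  perm <- sample(ncol(d$expr))
  t2 <- score_all_genes(d$expr[, perm], d$map)
  expect_equal(t1, t2)
  one <- score_all_genes(d$expr[1, , drop = FALSE], d$map)
  expect_equal(nrow(one), 1)
  expect_equal(one$IHS, t1$IHS[1])
})

test_that("low- and high-heterogeneity genes separate cleanly end to end", {
  cfg <- synth_config(n_patients = 10, regions_per_patient = 3, n_genes = 100,
                      rho = rep(c(0.05, 0.95), each = 50), total_var = 1, seed = 29)
  d <- generate_expression(cfg)
  ht <- score_all_genes(d$expr, d$map)
  expect_gte(mean(ht$ith_class[1:50] == "low"), 0.95)
  expect_gte(mean(ht$ith_class[51:100] == "high"), 0.95)
})
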