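make_surv <- function(n, scores = rep(0, n), seed = 1, censor = 0.2) {
  cfg <- synth_config(censor_rate = censor, seed = seed)
  generate_survival(setNames(scores, sprintf("s%03d", seq_len(n))), cfg)
}

test_that("cox screen recovers a strong planted effect with direction and significance", {
  detected <- logical(20)
  for (i in seq_len(20)) {
    set.seed(2000 + i)
    x <- rnorm(200)
    sv <- make_surv(200, scores = x, seed = 2000 + i)
    e <- matrix(x, 1, dimnames = list("g", sv$sample_id))
    r <- cox_screen(e, sv)
    detected[i] <- !is.na(r$hr) && r$hr > 1 && r$p_value < 0.05
    expect_true(r$ci_low <= r$hr && r$hr <= r$ci_high)
  }
  expect_gte(mean(detected), 0.95)
})

test_that("constant covariates are flagged and the batch continues", {
  sv <- make_surv(50, seed = 3)
  e <- rbind(g_const = rep(1, 50), g_ok = rnorm(50))
  colnames(e) <- sv$sample_id
  r <- cox_screen(e, sv)
  expect_equal(r$flag, c("constant", "ok"))
  expect_true(is.na(r$hr[1]) && !is.na(r$hr[2]))
})

test_that("direction consistency keeps same-side significant PH-passing genes only", {
  mk <- function(hr, p, ph = TRUE) data.frame(
    gene_id = paste0("g", seq_along(hr)), hr = hr,
    ci_low = hr * 0.8, ci_high = hr * 1.2, p_value = p, ph_ok = ph,
    flag = "ok")
  a <- mk(c(1.5, 1.5, 1.0, 0.7, 1.4), c(0.01, 0.01, 0.01, 0.01, 0.2))
  b <- mk(c(1.2, 0.8, 1.3, 0.5, 1.4), c(0.01, 0.01, 0.01, 0.01, 0.01))
  # g1 consistent; g2 opposite; g3 hr exactly 1 (no direction); g4 consistent
  # protective; g5 not significant in cohort A
  expect_equal(consistent_direction(a, b), c("g1", "g4"))
  a$ph_ok[1] <- FALSE
  expect_equal(consistent_direction(a, b), "g4")
  expect_error(consistent_direction(mk(1, 1), mk(1, 1)[0, ]), "share no genes")
})

test_that("log-rank statistic matches the textbook risk-table oracle", {
  # small two-group fixture with ties and censoring
  sv <- data.frame(sample_id = paste0("s", 1:12),
                   time = c(3, 5, 7, 7, 9, 12, 2, 4, 4, 6, 10, 11),
                   event = c(1, 1, 1, 0, 1, 0, 1, 1, 1, 1, 0, 1))
  g <- rep(c("a", "b"), each = 6)
  lr <- km_logrank(sv, g)
  expect_equal(lr$chisq, logrank_oracle(sv$time, sv$event, g), tolerance = 1e-6)

  # duplicated groups are exactly null
  sv2 <- data.frame(sample_id = paste0("s", 1:10),
                    time = rep(c(1, 2, 3, 4, 5), 2), event = 1)
  lr2 <- km_logrank(sv2, rep(c("a", "b"), each = 5))
  expect_equal(lr2$chisq, 0, tolerance = 1e-10)
  expect_equal(lr2$p_value, 1, tolerance = 1e-6)
  expect_error(km_logrank(sv2, rep("a", 10)), "2 groups")
})

test_that("perfectly separating scores give AUC 1 and C-index 1; ties give 0.5", {
  sv <- data.frame(sample_id = sprintf("s%02d", 1:40), time = 40:1, event = 1)
  sc <- setNames(as.numeric(1:40), sv$sample_id)  # monotone risk
  auc <- time_dependent_auc(sc, sv, c(10, 20, 30))
  expect_equal(auc$auc, c(1, 1, 1))
  expect_equal(concordance_index(sc, sv), 1)
  expect_equal(concordance_index(setNames(rep(1, 40), sv$sample_id), sv), 0.5)
})

test_that("without censoring the IPCW AUC equals the pair-enumeration oracle", {
  set.seed(8)
  n <- 60
  sc <- rnorm(n)
  sv <- make_surv(n, scores = sc, seed = 8, censor = 0)
  names(sc) <- sv$sample_id
  for (t in quantile(sv$time, c(0.3, 0.6))) {
    got <- time_dependent_auc(sc, sv, t)$auc
    expect_equal(got, auc_nocens_oracle(unname(sc), sv$time, t), tolerance = 1e-10)
  }
})

test_that("horizons beyond follow-up are rejected", {
  sv <- make_surv(30, seed = 9)
  sc <- setNames(rnorm(30), sv$sample_id)
  expect_error(time_dependent_auc(sc, sv, max(sv$time) * 2), "follow-up")
})

test_that("the true generating score is more concordant than a random one", {
  wins <- logical(30)
  for (i in seq_len(30)) {
    set.seed(3000 + i)
    x <- rnorm(120)
    sv <- make_surv(120, scores = x, seed = 3000 + i)
    c_true <- concordance_index(setNames(x, sv$sample_id), sv)
    c_rand <- concordance_index(setNames(rnorm(120), sv$sample_id), sv)
    wins[i] <- c_true > c_rand
  }
  expect_gte(mean(wins), 0.9)
})
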