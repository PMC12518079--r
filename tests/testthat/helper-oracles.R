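# Shared fixtures and independent oracles. Every oracle here is written from
# first principles (naive loops, textbook formulas) and never calls the
# package functions it is used to check.

# sample map for one sample per entry of `patients`
toy_map <- function(patients, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(patients))
  data.frame(sample_id = ids, patient_id = patients, region_id = NA_character_,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced one-way ANOVA variance components, textbook closed form
anova_vc_oracle <- function(values, groups) {
  groups <- factor(groups)
  n_i <- tabulate(groups); a <- nlevels(groups); N <- length(values)
  means <- tapply(values, groups, mean)
  msw <- sum((values - means[as.integer(groups)])^2) / (N - a)
  msb <- sum(n_i * (means - mean(values))^2) / (a - 1)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  W <- msw; B <- max((msb - msw) / n0, 0)
  c(W = W, B = B, ITVS = W / (W + B))
}

# naive agglomerative clustering with the Ward (ward.D2) Lance-Williams
# update, tracking the partition after every merge; returns the PGOR value at
# each cut level k = 1..N by direct enumeration of the partitions
naive_pgor_oracle <- function(values, patients) {
  N <- length(values)
  d2 <- outer(values, values, function(a, b) (a - b)^2)  # squared distances
  active <- as.list(seq_len(N))
  sizes <- rep(1, N)
  partitions <- vector("list", N)
  partitions[[N]] <- seq_len(N)               # k = N: singletons
  cl <- seq_len(N)
  for (step in seq_len(N - 1)) {
    m <- length(active)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (d2[i, j] < best[1] - 1e-15) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    ni <- sizes[i]; nj <- sizes[j]
    # Lance-Williams ward.D2 on squared distances
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                                 nk * d2[i, j]) / (ni + nj + nk)
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    active[[j]] <- NULL
    sizes <- sizes[-j]
    d2 <- d2[-j, -j, drop = FALSE]
    cl <- integer(N)
    for (c_idx in seq_along(active)) cl[active[[c_idx]]] <- c_idx
    partitions[[N - step]] <- cl               # k clusters remain
  }
  multi <- names(which(table(patients) >= 2))
  vapply(seq_len(N), function(k) {
    cl <- partitions[[k]]
    mean(vapply(multi, function(p) length(unique(cl[patients == p])) == 1L,
                logical(1)))
  }, numeric(1))
}

# textbook two-sample log-rank chi-squared from the risk table
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# case/control AUC at horizon t by pair enumeration (valid without censoring)
auc_nocens_oracle <- function(scores, time, t) {
  case <- which(time <= t); ctrl <- which(time > t)
  s <- 0
  for (i in case) for (j in ctrl)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(case) * length(ctrl))
}

# write a small data.frame as a temp TSV, return the path
tmp_tsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
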