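#' Read a genes-by-samples expression matrix from TSV/CSV
#'
#' The first column holds gene identifiers; remaining columns are samples on a
#' normalized, variance-stabilized-like scale. Input is validated strictly:
#' duplicate gene or sample identifiers, non-numeric cells, missing values and
#' empty matrices are errors, never silently repaired.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param genes_in_rows if `FALSE` the file is samples-by-genes and is
#'   transposed after reading.
#' @return a numeric matrix (genes x samples) with rownames = gene ids and
#'   colnames = sample ids.
#' @export
read_expression <- function(path, sep = "\t", genes_in_rows = TRUE) {
  assert_that(file.exists(path), "expression file not found: %s", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  assert_that(nrow(dt) > 0 && ncol(dt) > 1, "expression file is empty: %s", path)
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_ith("expression file contains non-numeric cells: %s", path)
  rownames(m) <- ids
  validate_expression(if (genes_in_rows) m else t(m))
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique gene and sample ids, finite numeric
#' values, non-degenerate dimensions.
#'
#' @param m numeric matrix, genes x samples, with dimnames.
#' @return `m`, invisibly validated (returned unchanged).
#' @export
validate_expression <- function(m) {
  assert_that(is.matrix(m) && is.numeric(m), "expression must be a numeric matrix")
  assert_that(nrow(m) >= 1 && ncol(m) >= 1, "expression matrix is empty")
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "expression matrix needs gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(m)), "duplicate gene ids in expression matrix")
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample ids in expression matrix")
  assert_that(all(is.finite(m)), "expression matrix contains NA/NaN/Inf values")
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; round-trips values to full double precision.
#'
#' @param m validated expression matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(m, path, sep = "\t") {
  validate_expression(m)
  dt <- data.table::data.table(gene_id = rownames(m), m)
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read a sample-to-patient map
#'
#' Columns `sample_id`, `patient_id` are required; `region_id` is optional free
#' text. Heterogeneity scoring needs at least two patients.
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return data.frame with columns sample_id, patient_id, region_id.
#' @export
read_sample_map <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep, required = c("sample_id", "patient_id"))
  if (is.null(df$region_id)) df$region_id <- NA_character_
  validate_sample_map(df[, c("sample_id", "patient_id", "region_id")])
}

#' @rdname read_sample_map
#' @param map data.frame to validate in place of a file.
#' @export
validate_sample_map <- function(map) {
  assert_that(all(c("sample_id", "patient_id") %in% names(map)),
              "sample map needs columns sample_id, patient_id")
  map$sample_id <- as.character(map$sample_id)
  map$patient_id <- as.character(map$patient_id)
  assert_that(!anyDuplicated(map$sample_id), "duplicate sample_id in sample map")
  assert_that(!anyNA(map$sample_id) && !anyNA(map$patient_id),
              "sample map has missing sample_id/patient_id")
  map
}

#' Read a MAF-like mutation table
#'
#' Requires `sample_id`, `variant_id` and either a `vaf` column (fractions in
#' \[0,1\]) or `alt_count` + `total_count` columns from which VAF is derived.
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return data.frame with columns sample_id, variant_id, vaf.
#' @export
read_mutations <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep, required = c("sample_id", "variant_id"))
  if (!is.null(df$vaf)) {
    vaf <- as.numeric(df$vaf)
  } else {
    assert_that(!is.null(df$alt_count) && !is.null(df$total_count),
                "mutation table needs either 'vaf' or 'alt_count'+'total_count'")
    alt <- as.numeric(df$alt_count); tot <- as.numeric(df$total_count)
    assert_that(all(is.finite(alt)) && all(is.finite(tot)), "non-numeric allele counts")
    assert_that(all(tot > 0), "total_count must be positive")
    assert_that(all(alt >= 0 & alt <= tot), "alt_count must be in [0, total_count]")
    vaf <- alt / tot
  }
  assert_that(all(is.finite(vaf)) && all(vaf >= 0 & vaf <= 1), "vaf outside [0,1]")
  data.frame(sample_id = as.character(df$sample_id),
             variant_id = as.character(df$variant_id),
             vaf = vaf, stringsAsFactors = FALSE)
}

#' Read a survival table
#'
#' Requires `sample_id`, `time` (> 0, any consistent unit) and `event`
#' (1 = event observed, 0 = censored). Extra numeric columns are kept as
#' covariates.
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return data.frame with sample_id, time, event plus any covariate columns.
#' @export
read_survival <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep, required = c("sample_id", "time", "event"))
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  validate_survival(df)
}

#' @rdname read_survival
#' @param surv data.frame to validate in place of a file.
#' @export
validate_survival <- function(surv) {
  assert_that(all(c("sample_id", "time", "event") %in% names(surv)),
              "survival table needs columns sample_id, time, event")
  assert_that(all(is.finite(surv$time)) && all(surv$time > 0), "survival time must be > 0")
  assert_that(all(surv$event %in% c(0, 1)), "event must be 0 or 1")
  assert_that(!anyDuplicated(surv$sample_id), "duplicate sample_id in survival table")
  surv
}

#' Align an expression matrix with a sample map
#'
#' Restricts both objects to their shared samples, in the expression matrix's
#' column order. Unmatched samples on either side are dropped with a warning;
#' zero overlap is an error.
#'
#' @param expr expression matrix (genes x samples).
#' @param map sample map data.frame.
#' @return list with elements `expr`, `map` (same sample order) and
#'   `n_dropped` (samples discarded from either input).
#' @export
align_samples <- function(expr, map) {
  validate_expression(expr)
  map <- validate_sample_map(map)
  shared <- intersect(colnames(expr), map$sample_id)
  assert_that(length(shared) > 0, "expression matrix and sample map share no samples")
  dropped <- (ncol(expr) - length(shared)) + (nrow(map) - length(shared))
  if (dropped > 0)
    warn_ith("align_samples: dropped %d unmatched sample record(s); %d retained",
             dropped, length(shared))
  keep <- colnames(expr)[colnames(expr) %in% shared]
  list(expr = expr[, keep, drop = FALSE],
       map = map[match(keep, map$sample_id), , drop = FALSE],
       n_dropped = dropped)
}

#' Log2 counts-per-million transform for raw counts
#'
#' Convenience stand-in for users arriving with raw counts: per-sample
#' library-size normalization to counts per million followed by log2(x + 1).
#' This is not a variance-stabilizing transformation; heterogeneity scores are
#' intended for expression already normalized and variance-stabilized upstream
#' (e.g. DESeq2 + VST).
#'
#' @param counts non-negative integer-like matrix (genes x samples).
#' @return numeric matrix of log2(CPM + 1) values.
#' @export
log2_cpm <- function(counts) {
  assert_that(is.matrix(counts) && all(is.finite(counts)) && all(counts >= 0),
              "counts must be a finite non-negative matrix")
  libs <- colSums(counts)
  assert_that(all(libs > 0), "every sample needs a positive library size")
  log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
}

# shared reader: TSV/CSV with required named columns
read_table_checked <- function(path, sep, required) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0, "missing required column(s): %s",
              paste(missing, collapse = ", "))
  df
}
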