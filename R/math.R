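#' MATH score for one sample's variant allele fractions
#'
#' Mutant-Allele Tumor Heterogeneity: `MATH = 100 * MAD / median` of the
#' sample's VAFs, where the MAD carries the standard 1.4826
#' normal-consistency constant ([stats::mad()] default). Omitting that
#' constant rescales every score by ~2/3, so it is applied always. The score
#' is undefined (`NA`) below `min_variants` VAFs or when the median VAF is 0.
#'
#' @param vafs numeric vector of variant allele fractions in `[0, 1]`.
#' @param min_variants minimum VAF count for a defined score (default 3).
#' @return one-row data.frame: n_variants, median_vaf, mad_vaf, math.
#' @export
math_score <- function(vafs, min_variants = 3) {
  assert_that(all(is.finite(vafs)), "VAFs must be finite")
  assert_that(all(vafs >= 0 & vafs <= 1), "VAFs must be in [0, 1]")
  n <- length(vafs)
  if (n < min_variants) {
    return(data.frame(n_variants = n, median_vaf = NA_real_,
                      mad_vaf = NA_real_, math = NA_real_))
  }
  med <- stats::median(vafs)
  madv <- stats::mad(vafs)  # constant = 1.4826
  data.frame(n_variants = n, median_vaf = med, mad_vaf = madv,
             math = if (med > 0) 100 * madv / med else NA_real_)
}

#' MATH scores for every sample of a mutation table
#'
#' Groups the mutation table by sample, optionally drops variants below a VAF
#' floor (sequencing-noise filter) before counting, and scores each sample
#' with [math_score()]. Samples left with too few variants get `NA` scores and
#' are reported.
#'
#' @param mutations data.frame with columns sample_id, vaf (see
#'   [read_mutations()]).
#' @param min_variants minimum variants per sample (default 3).
#' @param vaf_floor variants with `vaf < vaf_floor` are excluded before
#'   scoring (default 0, keep all).
#' @return data.frame: sample_id, n_variants, median_vaf, mad_vaf, math.
#' @export
math_by_sample <- function(mutations, min_variants = 3, vaf_floor = 0) {
  assert_that(all(c("sample_id", "vaf") %in% names(mutations)),
              "mutation table needs columns sample_id, vaf")
  assert_that(is_scalar_number(vaf_floor) && vaf_floor >= 0 && vaf_floor < 1,
              "vaf_floor must be in [0, 1)")
  mutations <- mutations[mutations$vaf >= vaf_floor, , drop = FALSE]
  ids <- unique(mutations$sample_id)
  out <- do.call(rbind, lapply(ids, function(s) {
    cbind(sample_id = s,
          math_score(mutations$vaf[mutations$sample_id == s], min_variants))
  }))
  n_flag <- sum(is.na(out$math))
  if (n_flag > 0)
    warn_ith("math_by_sample: %d sample(s) without a defined MATH score", n_flag)
  out
}
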