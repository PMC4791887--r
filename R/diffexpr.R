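# Per-miRNA differential expression between AD and control on REL values.

#' Two-sided Mann-Whitney test p-value
#'
#' Missing values are excluded first. With pooled n <= `exact_max_n` and no
#' ties the exact null distribution of the rank sum is used; otherwise the
#' normal approximation with mid-ranks, tie correction and continuity
#' correction. Returns `NA` when either group is empty after exclusion.
#'
#' @param x,y numeric REL values for the two groups.
#' @param exact_max_n largest pooled sample size for the exact branch.
#' @return two-sided p-value, or `NA_real_`.
#' @export
mann_whitney_two_sided <- function(x, y, exact_max_n = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  pooled <- c(x, y)
  exact <- (length(pooled) <= exact_max_n) && !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure: with the p-values sorted ascending,
#' `adj_i = min_{j >= i} (m * p_j / j)` clipped at 1, returned in input order.
#' `m` may exceed the number of supplied p-values to account for tests whose
#' p-values are not listed (they are treated as 1).
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` passed through).
#' @param m total number of tests (defaults to `length(pvalues)`).
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(pvalues, m = length(pvalues)) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < sum(ok)) stop("m must be at least the number of p-values")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH", n = m)
  out
}

#' Differential expression table (fold change of medians + Mann-Whitney)
#'
#' One row per miRNA detected in at least `min_detect` samples of each group.
#' Medians and ranges are taken over detected values only; `FC` is the ratio
#' of full-precision group medians (AD / control); p-values are two-sided
#' Mann-Whitney; `p_adj` is Benjamini-Hochberg over the rows of the table.
#' Rows are sorted by ascending p (undefined p last, flagged via `p = NA`).
#'
#' @param rel a [rel_matrix()].
#' @param det matching [detection_matrix()].
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @param min_detect minimum per-group detection count for inclusion.
#' @return data.frame with columns `miRNA, N_AD, N_control, M_AD,
#'   range_AD_min, range_AD_max, M_control, range_control_min,
#'   range_control_max, FC, p, p_adj`.
#' @export
differential_table <- function(rel, det, groups, min_detect = 9) {
  stopifnot(inherits(rel, "rel_matrix"), inherits(det, "detection_matrix"))
  g <- as_group_vector(groups, rel$sample_ids)
  ad <- names(g)[g == "AD"]; ctrl <- names(g)[g == "CONTROL"]
  vals <- rel$rel
  vals[!det$detected] <- NA_real_

  n_ad <- rowSums(!is.na(vals[, ad, drop = FALSE]))
  n_ct <- rowSums(!is.na(vals[, ctrl, drop = FALSE]))
  keep <- which(n_ad >= min_detect & n_ct >= min_detect)
  if (!length(keep)) {
    out <- data.frame(miRNA = character(), N_AD = integer(),
                      N_control = integer(), M_AD = numeric(),
                      range_AD_min = numeric(), range_AD_max = numeric(),
                      M_control = numeric(), range_control_min = numeric(),
                      range_control_max = numeric(), FC = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(keep, function(i) {
    xa <- vals[i, ad]; xa <- xa[!is.na(xa)]
    xc <- vals[i, ctrl]; xc <- xc[!is.na(xc)]
    data.frame(miRNA = rel$assay_ids[i],
               N_AD = length(xa), N_control = length(xc),
               M_AD = stats::median(xa),
               range_AD_min = min(xa), range_AD_max = max(xa),
               M_control = stats::median(xc),
               range_control_min = min(xc), range_control_max = max(xc),
               FC = stats::median(xa) / stats::median(xc),
               p = mann_whitney_two_sided(xa, xc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p)
  out <- out[order(out$p, out$miRNA, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
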