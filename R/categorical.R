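# Presence/absence marker analysis: Fisher tests, odds ratios,
# detection-based sensitivity/specificity, the categorical screen, and the
# CSF/blood fluid partition.
#
# 2x2 table convention throughout: row 1 = AD (a detected, b undetected),
# row 2 = control (c detected, d undetected).

check_counts <- function(a, b, c, d) {
  v <- unname(c(a, b, c, d))
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("cell counts must be nonnegative integers")
  }
}

#' Two-sided Fisher's exact test p-value
#'
#' Probability method: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (ties within relative tolerance). A
#' table with any zero margin carries no information and returns p = 1.
#'
#' @param a,b,c,d cell counts (AD detected / AD undetected / control detected
#'   / control undetected).
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Odds ratio with zero-cell continuity correction
#'
#' `OR = (a d) / (b c)` when all cells are positive; when any cell is zero,
#' the Haldane-Anscombe correction adds `zero_cell_correction` to all four
#' cells first.
#'
#' @param a,b,c,d cell counts.
#' @param zero_cell_correction value added to every cell when a zero occurs.
#' @return odds ratio.
#' @export
odds_ratio <- function(a, b, c, d, zero_cell_correction = 0.5) {
  check_counts(a, b, c, d)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + zero_cell_correction; b <- b + zero_cell_correction
    c <- c + zero_cell_correction; d <- d + zero_cell_correction
  }
  (a * d) / (b * c)
}

#' Sensitivity and specificity of detection as a diagnostic call
#'
#' Detection is the positive call for AD: sensitivity = detected fraction of
#' AD patients, specificity = undetected fraction of controls, in percent.
#'
#' @param a,b,c,d cell counts (see module convention).
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
detection_marker_performance <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  if ((a + b) == 0 || (c + d) == 0) stop("empty group")
  c(sensitivity = unname(100 * a / (a + b)),
    specificity = unname(100 * d / (c + d)))
}

#' Categorical (presence/absence) marker screen
#'
#' Flags miRNAs detected more frequently among AD patients than controls with
#' a two-sided Fisher p at or below `p_threshold`. Reports the odds ratio
#' (zero-cell corrected), sensitivity and specificity of detection, and a
#' significance star at p < `star_threshold`.
#'
#' @param det a [detection_matrix()].
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @param p_threshold inclusion threshold on the Fisher p-value.
#' @param star_threshold significance threshold for the star flag.
#' @return data.frame with columns `miRNA, N_AD, N_control, n_AD_total,
#'   n_control_total, OR, sensitivity, specificity, p, significant`, sorted
#'   by ascending p.
#' @export
categorical_screen <- function(det, groups, p_threshold = 0.1,
                               star_threshold = 0.05) {
  stopifnot(inherits(det, "detection_matrix"))
  g <- as_group_vector(groups, det$sample_ids)
  ad <- names(g)[g == "AD"]; ctrl <- names(g)[g == "CONTROL"]
  nA <- length(ad); nC <- length(ctrl)
  a <- rowSums(det$detected[, ad, drop = FALSE])
  c_ <- rowSums(det$detected[, ctrl, drop = FALSE])
  keep <- which(a / nA > c_ / nC)
  rows <- lapply(keep, function(i) {
    b <- nA - a[i]; d <- nC - c_[i]
    p <- fisher_exact_two_sided(a[i], b, c_[i], d)
    perf <- detection_marker_performance(a[i], b, c_[i], d)
    data.frame(miRNA = det$assay_ids[i], N_AD = a[i], N_control = c_[i],
               n_AD_total = nA, n_control_total = nC,
               OR = odds_ratio(a[i], b, c_[i], d),
               sensitivity = perf[["sensitivity"]],
               specificity = perf[["specificity"]],
               p = p, significant = p < star_threshold,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(miRNA = character(), N_AD = integer(), N_control = integer(),
               n_AD_total = integer(), n_control_total = integer(),
               OR = numeric(), sensitivity = numeric(), specificity = numeric(),
               p = numeric(), significant = logical(), stringsAsFactors = FALSE)
  out <- out[!is.na(out$p) & out$p <= p_threshold, , drop = FALSE]
  out <- out[order(out$p, out$miRNA), ]
  rownames(out) <- NULL
  out
}

#' Partition the detected miRNAs between the two fluids
#'
#' A miRNA is "in" a fluid if detected in at least one sample of that fluid.
#' Per-miRNA frequency categories compare the number of samples with
#' detection in each fluid.
#'
#' @param det_csf,det_blood [detection_matrix()] objects (assay universes may
#'   differ; the union is used).
#' @return list with `counts` (`both`, `blood_only`, `csf_only`, `total`) and
#'   `categories`, a data.frame of per-miRNA detection frequencies and a
#'   category among `blood>CSF`, `CSF>blood`, `blood=CSF`.
#' @export
fluid_partition <- function(det_csf, det_blood) {
  stopifnot(inherits(det_csf, "detection_matrix"),
            inherits(det_blood, "detection_matrix"))
  universe <- union(det_csf$assay_ids, det_blood$assay_ids)
  n_csf <- stats::setNames(rep(0L, length(universe)), universe)
  n_blood <- n_csf
  n_csf[det_csf$assay_ids] <- rowSums(det_csf$detected)
  n_blood[det_blood$assay_ids] <- rowSums(det_blood$detected)
  detected_any <- universe[n_csf + n_blood > 0]
  in_csf <- n_csf[detected_any] > 0
  in_blood <- n_blood[detected_any] > 0
  counts <- c(both = sum(in_csf & in_blood),
              blood_only = sum(in_blood & !in_csf),
              csf_only = sum(in_csf & !in_blood),
              total = length(detected_any))
  category <- ifelse(n_blood[detected_any] > n_csf[detected_any], "blood>CSF",
                     ifelse(n_csf[detected_any] > n_blood[detected_any],
                            "CSF>blood", "blood=CSF"))
  list(counts = counts,
       categories = data.frame(miRNA = detected_any,
                               n_csf = as.integer(n_csf[detected_any]),
                               n_blood = as.integer(n_blood[detected_any]),
                               category = category,
                               stringsAsFactors = FALSE, row.names = NULL))
}
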