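# Cohort demographics (Table-1-style comparisons) and blood-brain-barrier
# integrity checks.

#' Compare a continuous variable between control and AD groups
#'
#' Two-sided Student t-test with pooled variance by default (Welch optional).
#' The reported difference follows the AD-minus-control sign convention, with
#' a 95% confidence interval from the (pooled) standard error.
#'
#' @param control,ad numeric values per group (`NA` dropped).
#' @param variable label for the output row.
#' @param welch if `TRUE`, use the Welch unequal-variance test.
#' @param conf_level confidence level for the interval.
#' @return one-row data.frame: `variable, mean_control, mean_AD, difference,
#'   ci_low, ci_high, p, significant`.
#' @export
compare_continuous <- function(control, ad, variable = "", welch = FALSE,
                               conf_level = 0.95) {
  control <- control[!is.na(control)]; ad <- ad[!is.na(ad)]
  if (length(control) < 2L || length(ad) < 2L) {
    stop("each group needs >= 2 non-missing values")
  }
  diff <- mean(ad) - mean(control)
  if (stats::var(control) == 0 && stats::var(ad) == 0) {
    # degenerate: no variance; difference still reported, p undefined unless 0
    p <- if (diff == 0) 1 else NA_real_
    return(data.frame(variable = variable, mean_control = mean(control),
                      mean_AD = mean(ad), difference = diff,
                      ci_low = diff, ci_high = diff, p = p,
                      significant = isTRUE(p < 0.05), stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(ad, control, var.equal = !welch,
                      conf.level = conf_level)
  data.frame(variable = variable, mean_control = mean(control),
             mean_AD = mean(ad), difference = diff,
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             p = tt$p.value, significant = tt$p.value < 0.05,
             stringsAsFactors = FALSE)
}

#' Compare a categorical variable between groups (Fisher's exact test)
#'
#' @param a,b,c,d 2x2 cell counts (row 1 = AD, row 2 = control).
#' @param variable label for the output row.
#' @return one-row data.frame: `variable, p, significant`.
#' @export
compare_categorical <- function(a, b, c, d, variable = "") {
  p <- fisher_exact_two_sided(a, b, c, d)
  data.frame(variable = variable, p = p, significant = p < 0.05,
             stringsAsFactors = FALSE)
}

#' Flag an elevated CSF/serum albumin quotient (Qalb)
#'
#' Qalb above the age-dependent reference limit `(age/15 + 4) * 1e-3`
#' (dimensionless; strict inequality) marks a leaky blood-brain barrier. A
#' fixed `threshold` can be supplied instead of the age formula. Missing Qalb
#' gives `NA`.
#'
#' @param qalb CSF/serum albumin quotient(s), dimensionless.
#' @param age age(s) in years (recycled against `qalb`).
#' @param threshold optional fixed threshold overriding the age formula.
#' @return logical vector: elevated or not (`NA` where qalb missing).
#' @export
flag_qalb <- function(qalb, age, threshold = NULL) {
  if (is.null(threshold)) {
    if (any(is.na(age) & !is.na(qalb))) stop("age required where qalb present")
    threshold <- (age / 15 + 4) * 1e-3
  }
  if (any(qalb[!is.na(qalb)] <= 0)) stop("qalb must be > 0")
  qalb > threshold
}

#' CSF/blood expression association per miRNA
#'
#' Spearman rank correlation between paired CSF and blood REL values over a
#' sample subset (e.g. patients with elevated Qalb). Descriptive only: no
#' p-value is attached; the correlation is undefined (`NA`) with fewer than
#' 3 complete pairs.
#'
#' @param rel_csf,rel_blood [rel_matrix()] objects sharing sample ids.
#' @param mirna_ids miRNAs to correlate (default: assays present in both).
#' @param sample_subset sample ids to restrict to (default: all shared).
#' @return data.frame `miRNA, n, rho`.
#' @export
csf_blood_association <- function(rel_csf, rel_blood, mirna_ids = NULL,
                                  sample_subset = NULL) {
  stopifnot(inherits(rel_csf, "rel_matrix"), inherits(rel_blood, "rel_matrix"))
  shared <- intersect(rel_csf$sample_ids, rel_blood$sample_ids)
  if (!is.null(sample_subset)) shared <- intersect(shared, sample_subset)
  if (is.null(mirna_ids)) {
    mirna_ids <- intersect(rel_csf$assay_ids, rel_blood$assay_ids)
  }
  missing_assays <- setdiff(mirna_ids,
                            intersect(rel_csf$assay_ids, rel_blood$assay_ids))
  if (length(missing_assays)) {
    stop("miRNA(s) absent from one fluid: ",
         paste(missing_assays, collapse = ", "))
  }
  rows <- lapply(mirna_ids, function(id) {
    x <- rel_csf$rel[id, shared]; y <- rel_blood$rel[id, shared]
    ok <- !is.na(x) & !is.na(y)
    rho <- if (sum(ok) >= 3) stats::cor(x[ok], y[ok], method = "spearman")
           else NA_real_
    data.frame(miRNA = id, n = sum(ok), rho = rho, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
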