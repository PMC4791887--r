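# Detection calling and run-level QC.
#
# Inclusion rule: a measurement counts as detected only when it amplified
# below the Ct ceiling (default 37) and, in addition, lies at least
# `control_margin` cycles (default 3) below the assay's negative control.
# Everything else is masked from downstream analysis.

#' Construct a detection matrix
#'
#' @param detected logical matrix, assays x samples; never `NA`.
#' @param assay_ids,sample_ids dimension names.
#' @param fluid `"CSF"` or `"BLOOD"`.
#' @return object of class `detection_matrix`.
#' @export
detection_matrix <- function(detected, assay_ids = rownames(detected),
                             sample_ids = colnames(detected),
                             fluid = c("CSF", "BLOOD")) {
  fluid <- match.arg(toupper(fluid), c("CSF", "BLOOD"))
  detected <- as.matrix(detected)
  if (!is.logical(detected) || anyNA(detected)) {
    stop("detected must be logical with no missing entries")
  }
  assay_ids <- as.character(assay_ids); sample_ids <- as.character(sample_ids)
  if (nrow(detected) != length(assay_ids) || ncol(detected) != length(sample_ids)) {
    stop("detected dimensions must match assay_ids x sample_ids")
  }
  if (anyDuplicated(assay_ids) || anyDuplicated(sample_ids)) {
    stop("assay and sample ids must be unique")
  }
  dimnames(detected) <- list(assay_ids, sample_ids)
  structure(list(assay_ids = assay_ids, sample_ids = sample_ids,
                 detected = detected, fluid = fluid),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("detection_matrix: %d assays x %d samples [%s], %.1f%% detected\n",
              length(x$assay_ids), length(x$sample_ids), x$fluid,
              100 * mean(x$detected)))
  invisible(x)
}

#' Spike-in control QC
#'
#' Spike-ins are synthetic RNA/DNA templates added at a fixed amount to every
#' sample; steady Ct levels across samples indicate a reliable RT reaction
#' and qPCR run. A spike-in passes when it amplified in every sample and its
#' Ct standard deviation is at most `sd_threshold` cycles (1 cycle is about a
#' two-fold difference in template).
#'
#' @param ct a [ct_matrix()] whose assays include the spike-ins.
#' @param spikein_ids assay ids of the spike-in channels.
#' @param sd_threshold maximum allowed SD in cycles.
#' @return data.frame of class `spikein_report` with one row per spike-in and
#'   attribute `run_pass` (all spike-ins pass).
#' @export
assess_spikeins <- function(ct, spikein_ids, sd_threshold = 1.0) {
  stopifnot(inherits(ct, "ct_matrix"))
  unknown <- setdiff(spikein_ids, ct$assay_ids)
  if (length(unknown)) {
    stop("unknown spike-in id(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(spikein_ids, function(id) {
    v <- ct$ct[id, ]
    n_missing <- sum(is.na(v))
    mean_ct <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    sd_ct <- if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE) else NA_real_
    pass <- n_missing == 0L && !is.na(sd_ct) && sd_ct <= sd_threshold
    data.frame(spikein = id, mean_ct = mean_ct, sd_ct = sd_ct,
               n_missing = n_missing, pass = pass, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "run_pass") <- all(report$pass)
  attr(report, "sd_threshold") <- sd_threshold
  class(report) <- c("spikein_report", "data.frame")
  report
}

#' Call detected / undetected per measurement
#'
#' A cell is detected iff the Ct is present, `Ct < ct_max`, the negative
#' control allows it (control missing counts as "no amplification in the
#' control", which always passes; otherwise `negctrl - Ct >= control_margin`,
#' boundary inclusive), and any externally supplied QC flag passes.
#'
#' @param ct a [ct_matrix()].
#' @param ct_max detection ceiling in cycles.
#' @param control_margin required clearance below the negative control, cycles.
#' @param margin_strict if `TRUE`, require `negctrl - Ct > control_margin`
#'   (strict) instead of the default inclusive comparison.
#' @return a [detection_matrix()].
#' @export
call_detection <- function(ct, ct_max = 37, control_margin = 3,
                           margin_strict = FALSE) {
  stopifnot(inherits(ct, "ct_matrix"))
  det <- !is.na(ct$ct) & ct$ct < ct_max
  if (!is.null(ct$negctrl_ct)) {
    clearance <- ct$negctrl_ct - ct$ct  # NA where either side missing
    ctrl_ok <- if (margin_strict) clearance > control_margin
               else clearance >= control_margin
    # missing control = cleanest control outcome: passes
    ctrl_ok[is.na(ct$negctrl_ct), ] <- TRUE
    ctrl_ok[is.na(ctrl_ok)] <- FALSE
    det <- det & ctrl_ok
  }
  if (!is.null(ct$qc_flags)) det <- det & ct$qc_flags
  detection_matrix(det, ct$assay_ids, ct$sample_ids, ct$fluid)
}

#' Mask Ct values where not detected
#'
#' @param ct a [ct_matrix()].
#' @param det matching [detection_matrix()].
#' @return numeric matrix with undetected cells set to `NA`.
#' @export
mask_ct <- function(ct, det) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(det, "detection_matrix"))
  if (!identical(ct$assay_ids, det$assay_ids) ||
      !identical(ct$sample_ids, det$sample_ids)) {
    stop("ct and detection matrices do not match")
  }
  out <- ct$ct
  out[!det$detected] <- NA_real_
  out
}

#' Detection count summaries
#'
#' @param det a [detection_matrix()].
#' @param groups cohort metadata (or named AD/CONTROL vector) covering all
#'   samples.
#' @return list with `per_sample` (named counts of assays detected per
#'   sample), `mean_per_sample`, `per_assay` (data.frame of N_AD / N_control
#'   per assay), `detected_in_all` (assay ids detected in every sample) and
#'   `group_sizes`.
#' @export
detection_counts <- function(det, groups) {
  stopifnot(inherits(det, "detection_matrix"))
  g <- as_group_vector(groups, det$sample_ids)
  per_sample <- colSums(det$detected)
  ad <- names(g)[g == "AD"]; ctrl <- names(g)[g == "CONTROL"]
  if (!length(ad) || !length(ctrl)) stop("empty group")
  per_assay <- data.frame(
    miRNA = det$assay_ids,
    N_AD = rowSums(det$detected[, ad, drop = FALSE]),
    N_control = rowSums(det$detected[, ctrl, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_sample = per_sample,
       mean_per_sample = mean(per_sample),
       per_assay = per_assay,
       detected_in_all = det$assay_ids[rowSums(det$detected) == ncol(det$detected)],
       group_sizes = c(AD = length(ad), CONTROL = length(ctrl)))
}
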