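# End-to-end pipeline driver: QC -> detection -> normalization ->
# differential + categorical screens -> classification -> cohort summary,
# per fluid, with all result tables written as CSV plus a plain-text run log.

#' Run the full two-fluid analysis pipeline
#'
#' `config` is a list (or path to a YAML file) with either
#' `sim:` (arguments for [cohort_config()]; a synthetic cohort is generated)
#' or `files:` (`ct_csf`, `ct_blood`, `metadata` paths), plus optional
#' `params:` overriding `ct_max` (37), `margin` (3), `min_detect` (9),
#' `p_threshold` (0.1), `sd_threshold` (1.0), `spikein_ids`, `normalizer`
#' (`"global_mean"`), `ratio_numerator`/`ratio_denominator` (default: the two
#' best LOO predictors per fluid), and `outdir` (no files written when
#' `NULL`).
#'
#' Per fluid the bundle contains the spike-in report, detection summary,
#' normalizer stability ranking, differential table, categorical screen, LOO
#' accuracies and the ratio model; plus the fluid partition and, when the
#' metadata carries demographics, a cohort comparison with Qalb flags. Every
#' number in the written tables is the module output; the renderer only
#' formats. Deterministic given inputs.
#'
#' @param config list or YAML path.
#' @return (invisibly) the report bundle, a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(
    list(ct_max = 37, margin = 3, min_detect = 9, p_threshold = 0.1,
         sd_threshold = 1.0, spikein_ids = NULL, normalizer = "global_mean",
         ratio_numerator = NULL, ratio_denominator = NULL),
    config$params %||% list())
  outdir <- config$outdir

  if (!is.null(config$sim)) {
    cfg <- do.call(cohort_config, config$sim)
    cohort <- generate_cohort(cfg)
    ct_csf <- cohort$csf; ct_blood <- cohort$blood
    metadata <- cohort$metadata
    if (is.null(params$spikein_ids)) params$spikein_ids <- cfg$spikein_ids
  } else if (!is.null(config$files)) {
    ct_csf <- read_ct_table(config$files$ct_csf, "CSF")
    ct_blood <- read_ct_table(config$files$ct_blood, "BLOOD")
    metadata <- read_metadata(config$files$metadata)
  } else {
    stop("config must provide either sim: or files:")
  }

  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(obj, name) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, paste0(name, ".csv"))
    if (is.data.frame(obj)) {
      utils::write.table(obj, path, sep = ",", row.names = FALSE, quote = FALSE)
    }
    invisible(NULL)
  }

  analyse_fluid <- function(ct, label) {
    spike <- NULL
    spikein_ids <- intersect(params$spikein_ids %||% character(), ct$assay_ids)
    if (length(spikein_ids)) {
      spike <- tryCatch(
        assess_spikeins(ct, spikein_ids, params$sd_threshold),
        error = function(e) stop("stage spikein_qc [", label, "]: ",
                                 conditionMessage(e)))
      # spike-ins are controls, not analytes: drop before analysis
      keep <- setdiff(ct$assay_ids, spikein_ids)
      ct <- ct_matrix(ct$ct[keep, , drop = FALSE], keep, ct$sample_ids,
                      ct$fluid,
                      negctrl_ct = if (!is.null(ct$negctrl_ct))
                        ct$negctrl_ct[keep],
                      qc_flags = if (!is.null(ct$qc_flags))
                        ct$qc_flags[keep, , drop = FALSE])
    }
    det <- tryCatch(
      call_detection(ct, ct_max = params$ct_max,
                     control_margin = params$margin),
      error = function(e) stop("stage detection [", label, "]: ",
                               conditionMessage(e)))
    counts <- detection_counts(det, metadata)
    ranking <- tryCatch(rank_normalizers(ct, det, metadata),
                        error = function(e) NULL)
    rel <- tryCatch(
      compute_rel(ct, det, normalizer = params$normalizer),
      error = function(e) stop("stage normalization [", label, "]: ",
                               conditionMessage(e)))
    diff_tab <- differential_table(rel, det, metadata,
                                   min_detect = params$min_detect)
    cat_tab <- categorical_screen(det, metadata,
                                  p_threshold = params$p_threshold)
    loo <- if (nrow(diff_tab)) {
      sub <- rel_matrix(rel$rel[diff_tab$miRNA, , drop = FALSE],
                        diff_tab$miRNA, rel$sample_ids, rel$fluid,
                        rel$normalizer_desc)
      loo_accuracy(sub, metadata)
    } else NULL
    ratio <- NULL
    num <- params$ratio_numerator; den <- params$ratio_denominator
    if (is.null(num) && !is.null(loo) && nrow(loo) >= 2) {
      num <- loo$miRNA[2]; den <- loo$miRNA[1]
    }
    if (!is.null(num) && !is.null(den) &&
        all(c(num, den) %in% rel$assay_ids)) {
      ratio <- fit_ratio_model(rel, num, den, metadata)
    }
    detection_summary <- data.frame(
      fluid = label,
      n_assays = length(det$assay_ids),
      mean_detected_per_sample = counts$mean_per_sample,
      n_detected_in_all = length(counts$detected_in_all),
      n_detected_any = sum(rowSums(det$detected) > 0),
      stringsAsFactors = FALSE)
    emit(spike, paste0("spikein_qc_", tolower(label)))
    emit(detection_summary, paste0("detection_summary_", tolower(label)))
    emit(ranking, paste0("normalizer_ranking_", tolower(label)))
    if (!is.null(outdir)) {
      write_marker_table(diff_tab,
                         file.path(outdir,
                                   paste0("differential_", tolower(label), ".csv")))
      write_marker_table(cat_tab,
                         file.path(outdir,
                                   paste0("categorical_", tolower(label), ".csv")))
    }
    emit(loo, paste0("loo_", tolower(label)))
    list(spikein = spike, detection = det, counts = counts,
         detection_summary = detection_summary, normalizer_ranking = ranking,
         rel = rel, differential = diff_tab, categorical = cat_tab,
         loo = loo, ratio = ratio)
  }

  csf <- analyse_fluid(ct_csf, "CSF")
  blood <- analyse_fluid(ct_blood, "BLOOD")
  partition <- fluid_partition(csf$detection, blood$detection)
  emit(partition$categories, "fluid_partition")

  cohort_table <- NULL
  cont_vars <- intersect(c("age", "duration", "mmse", "ace", "abeta42",
                           "total_tau", "p_tau"), names(metadata))
  if (length(cont_vars)) {
    g <- as_group_vector(metadata, metadata$sample_id)
    rows <- lapply(cont_vars, function(v) {
      x <- metadata[[v]][g == "CONTROL"]; y <- metadata[[v]][g == "AD"]
      if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2) {
        compare_continuous(x, y, variable = v)
      } else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) cohort_table <- do.call(rbind, rows)
    emit(cohort_table, "cohort_comparison")
  }
  qalb_flags <- NULL
  if (all(c("qalb", "age") %in% names(metadata))) {
    qalb_flags <- data.frame(sample_id = metadata$sample_id,
                             group = metadata$group,
                             qalb = metadata$qalb,
                             elevated = flag_qalb(metadata$qalb, metadata$age),
                             stringsAsFactors = FALSE)
    emit(qalb_flags, "qalb_flags")
  }

  bundle <- list(csf = csf, blood = blood, partition = partition,
                 cohort_comparison = cohort_table, qalb_flags = qalb_flags,
                 metadata = metadata, params = params)
  if (!is.null(outdir)) {
    log_lines <- c(
      "mirfluid pipeline run",
      sprintf("parameters: ct_max=%g margin=%g min_detect=%g p_threshold=%g normalizer=%s",
              params$ct_max, params$margin, params$min_detect,
              params$p_threshold, params$normalizer),
      if (!is.null(config$sim)) sprintf("simulated cohort, seed=%s",
                                        config$sim$seed %||% "default"),
      sprintf("CSF: %d assays detected in all samples, mean %.1f per sample",
              csf$detection_summary$n_detected_in_all,
              csf$detection_summary$mean_detected_per_sample),
      sprintf("BLOOD: %d assays detected in all samples, mean %.1f per sample",
              blood$detection_summary$n_detected_in_all,
              blood$detection_summary$mean_detected_per_sample),
      sprintf("fluid partition: both=%d blood_only=%d csf_only=%d",
              partition$counts[["both"]], partition$counts[["blood_only"]],
              partition$counts[["csf_only"]]))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  invisible(bundle)
}

#' Human-readable rendering of a marker table
#'
#' Display convenience only: medians and fold changes to 2 decimals, p-values
#' to 3 decimals with `n.s.` above the significance threshold. Machine-
#' readable CSVs written by the pipeline keep full precision.
#'
#' @param table a differential or categorical data.frame.
#' @param alpha significance threshold for the `n.s.` replacement.
#' @return data.frame of formatted strings.
#' @export
render_marker_table <- function(table, alpha = 0.05) {
  out <- table
  num2 <- intersect(c("M_AD", "M_control", "FC", "OR", "sensitivity",
                      "specificity"), names(out))
  for (v in num2) out[[v]] <- sprintf("%.2f", out[[v]])
  for (v in intersect(c("p", "p_adj"), names(out))) {
    out[[v]] <- ifelse(is.na(table[[v]]), "NA",
                       ifelse(table[[v]] > alpha, "n.s.",
                              sprintf("%.3f", table[[v]])))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
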