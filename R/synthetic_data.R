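# Synthetic two-fluid RT-qPCR cohorts.
#
# The generator emulates the study design the analysis assumes: a 372-assay
# miRNA panel measured once per sample in two biofluids on 10 AD + 10
# other-dementia patients, with normally distributed Ct noise on the log2
# (cycle) scale, per-sample global shifts (RNA content / loading), planted
# group effects expressed as delta-delta-Ct shifts, censoring at the limit of
# detection, stable spike-in channels and high negative-control Ct values.

#' Configuration for a synthetic two-fluid cohort
#'
#' @param n_ad,n_control group sizes (default 10 + 10).
#' @param n_assays miRNA panel size excluding spike-ins (default 372).
#' @param baseline_range per-assay mean Ct drawn uniformly from this range
#'   (cycles; default 22-36).
#' @param noise_sd within-group measurement SD in cycles (default 0.5).
#' @param sample_shift_sd SD of the per-sample global Ct offset (default 1.0
#'   cycle); global-mean normalization is expected to remove it.
#' @param effects data.frame with columns `assay` (index or id), `ddct`
#'   (Ct shift added to AD samples; negative = up-regulated in AD) and
#'   `fluid`; or `NULL` for a null cohort.
#' @param lod_ct limit of detection: Ct values at or above this are censored
#'   to missing (default 37).
#' @param dropout extra dropout probability scale near the LOD (default 0;
#'   censoring alone already produces non-detection).
#' @param negctrl_ct negative-control mean Ct (default 40 cycles).
#' @param negctrl_missing_rate fraction of assays whose negative control does
#'   not amplify at all (default 0.25).
#' @param spikein_ids spike-in channel names (RNA Sp2/Sp4/Sp5/Sp6, DNA Sp3).
#' @param spikein_sd SD of spike-in Ct across samples (default 0.15 cycles).
#' @param seed RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_ad = 10, n_control = 10, n_assays = 372,
                          baseline_range = c(22, 36), noise_sd = 0.5,
                          sample_shift_sd = 1.0, effects = NULL, lod_ct = 37,
                          dropout = 0, negctrl_ct = 40,
                          negctrl_missing_rate = 0.25,
                          spikein_ids = c("Sp2", "Sp3", "Sp4", "Sp5", "Sp6"),
                          spikein_sd = 0.15, seed = 1) {
  stopifnot(n_ad >= 1, n_control >= 1, n_assays >= 1,
            length(baseline_range) == 2, baseline_range[1] < baseline_range[2],
            noise_sd >= 0, sample_shift_sd >= 0, lod_ct > 0,
            dropout >= 0, dropout <= 1, negctrl_missing_rate >= 0,
            negctrl_missing_rate <= 1, spikein_sd >= 0)
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    if (!all(c("assay", "ddct", "fluid") %in% names(effects))) {
      stop("effects needs columns assay, ddct, fluid")
    }
    effects$fluid <- toupper(effects$fluid)
    if (!all(effects$fluid %in% c("CSF", "BLOOD"))) {
      stop("effects fluid must be CSF or BLOOD")
    }
    if (is.numeric(effects$assay) &&
        any(effects$assay < 1 | effects$assay > n_assays)) {
      stop("planted assay index out of range 1..", n_assays)
    }
  }
  structure(list(n_ad = n_ad, n_control = n_control, n_assays = n_assays,
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 sample_shift_sd = sample_shift_sd, effects = effects,
                 lod_ct = lod_ct, dropout = dropout, negctrl_ct = negctrl_ct,
                 negctrl_missing_rate = negctrl_missing_rate,
                 spikein_ids = spikein_ids, spikein_sd = spikein_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic two-fluid cohort
#'
#' Per fluid, `Ct(a, s) = baseline(a) + sample_shift(s) + group_effect(a,
#' group(s)) + noise`, with values at or above the LOD censored to missing
#' and optional extra dropout near the LOD. Spike-in channels carry no sample
#' shift (they are added at a fixed amount after extraction). Per-patient
#' shifts are drawn independently per fluid: no shared CSF/blood offset is
#' imposed. Identical seed gives identical output.
#'
#' @param config a [cohort_config()].
#' @return list with elements `csf` and `blood` ([ct_matrix()] objects
#'   including spike-in rows), `metadata` (a `cohort_metadata` data.frame)
#'   and `truth` (planted effects, assay ids and seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_ad + config$n_control
  sample_ids <- c(sprintf("AD%02d", seq_len(config$n_ad)),
                  sprintf("CTRL%02d", seq_len(config$n_control)))
  group <- c(rep("AD", config$n_ad), rep("CONTROL", config$n_control))
  assay_ids <- sprintf("miR-sim-%03d", seq_len(config$n_assays))

  effects <- config$effects
  if (!is.null(effects) && is.numeric(effects$assay)) {
    effects$assay <- assay_ids[effects$assay]
  }

  metadata <- data.frame(
    sample_id = sample_ids, group = group,
    age = round(stats::rnorm(n, mean = 70, sd = 7)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    qalb = exp(stats::rnorm(n, mean = log(5.5e-3), sd = 0.35)),
    stringsAsFactors = FALSE)
  class(metadata) <- c("cohort_metadata", "data.frame")

  one_fluid <- function(fluid) {
    baseline <- stats::runif(config$n_assays, config$baseline_range[1],
                             config$baseline_range[2])
    shift <- stats::rnorm(n, 0, config$sample_shift_sd)
    ct <- outer(baseline, shift, `+`) +
      matrix(stats::rnorm(config$n_assays * n, 0, config$noise_sd),
             config$n_assays, n)
    if (!is.null(effects)) {
      sel <- effects$fluid == fluid
      for (k in which(sel)) {
        i <- match(effects$assay[k], assay_ids)
        ct[i, group == "AD"] <- ct[i, group == "AD"] + effects$ddct[k]
      }
    }
    if (config$dropout > 0) {
      # extra missingness concentrated within ~2 cycles of the LOD
      p_miss <- config$dropout *
        stats::plogis((ct - (config$lod_ct - 2)) / 0.5)
      drop <- matrix(stats::runif(length(ct)) < p_miss, nrow(ct))
      ct[drop] <- NA_real_
    }
    ct[!is.na(ct) & ct >= config$lod_ct] <- NA_real_

    n_spike <- length(config$spikein_ids)
    spike_means <- 19 + seq_len(n_spike)
    spikes <- matrix(stats::rnorm(n_spike * n, rep(spike_means, n),
                                  config$spikein_sd),
                     n_spike, n)
    full <- rbind(ct, spikes)
    all_ids <- c(assay_ids, config$spikein_ids)
    negctrl <- stats::rnorm(length(all_ids), config$negctrl_ct, 0.5)
    negctrl[stats::runif(length(all_ids)) < config$negctrl_missing_rate] <- NA
    negctrl[all_ids %in% config$spikein_ids] <- NA
    ct_matrix(full, all_ids, sample_ids, fluid, negctrl_ct = negctrl)
  }

  csf <- one_fluid("CSF")
  blood <- one_fluid("BLOOD")
  list(csf = csf, blood = blood, metadata = metadata,
       truth = list(effects = effects, assay_ids = assay_ids,
                    spikein_ids = config$spikein_ids, seed = config$seed))
}

#' Deterministic detection fixture reproducing the published categorical screen
#'
#' Builds a 20-sample (10 AD + 10 control) CSF detection matrix whose
#' per-group detection counts match the three published presence/absence
#' markers (5/10 vs 0/10 twice and 6/10 vs 1/10) on top of background assays
#' with equal detection frequency in both groups, plus an all-detected blood
#' matrix for the same samples.
#'
#' @param n_background_full number of background assays detected in every
#'   sample.
#' @param n_background_half number of background assays detected in exactly
#'   half of each group.
#' @return list with `csf` and `blood` [detection_matrix()] objects and
#'   `metadata`.
#' @export
generate_table3_fixture <- function(n_background_full = 15,
                                    n_background_half = 5) {
  sample_ids <- c(sprintf("AD%02d", 1:10), sprintf("CTRL%02d", 1:10))
  metadata <- data.frame(sample_id = sample_ids,
                         group = rep(c("AD", "CONTROL"), each = 10),
                         stringsAsFactors = FALSE)
  class(metadata) <- c("cohort_metadata", "data.frame")

  pattern <- function(n_ad, n_ctrl) {
    c(rep(TRUE, n_ad), rep(FALSE, 10 - n_ad),
      rep(TRUE, n_ctrl), rep(FALSE, 10 - n_ctrl))
  }
  markers <- rbind(`miR-199b-5p` = pattern(5, 0),
                   `miR-22-5p` = pattern(5, 0),
                   `miR-206` = pattern(6, 1))
  bg_full <- matrix(TRUE, n_background_full, 20,
                    dimnames = list(sprintf("miR-bgF-%02d",
                                            seq_len(n_background_full)), NULL))
  bg_half <- matrix(rep(pattern(5, 5), n_background_half),
                    n_background_half, 20, byrow = TRUE,
                    dimnames = list(sprintf("miR-bgH-%02d",
                                            seq_len(n_background_half)), NULL))
  det <- rbind(markers, bg_full, bg_half)
  colnames(det) <- sample_ids
  csf <- detection_matrix(det, rownames(det), sample_ids, "CSF")
  blood <- detection_matrix(matrix(TRUE, nrow(det), 20,
                                   dimnames = dimnames(det)),
                            rownames(det), sample_ids, "BLOOD")
  list(csf = csf, blood = blood, metadata = metadata)
}
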