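# Normalizer selection and relative expression.
#
# Ct is a log2-domain quantity (one cycle = one doubling), so stability is
# assessed on Ct directly and relative expression is REL = 2^-dCt with
# dCt = Ct(assay, sample) - normalizer(sample). The default normalizer is the
# per-sample arithmetic mean Ct over the assays detected in every sample of
# that fluid (the "global mean").

#' NormFinder-style stability ranking of candidate normalizers
#'
#' Candidates are all assays detected in every sample, plus the
#' pseudo-candidate `"global_mean"` whose per-sample value is the mean Ct over
#' that set. For each candidate a model-based stability value combines the
#' inter-group bias (difference of group means after centering each sample
#' and each candidate within its group) and the intra-group variance:
#'
#' stability = sqrt( max(bias^2 - sampling_var(bias), 0) + mean intra-group variance )
#'
#' Within-group variances come from the two-way (candidate + sample) residuals
#' with the unbiased small-sample scaling k/((k-1)(n_g-1)); the bias term is
#' shrunk by its own sampling variance so that noisy candidates are not
#' rewarded for an apparently small bias. Lower stability = better normalizer.
#'
#' @param ct a [ct_matrix()].
#' @param det matching [detection_matrix()].
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @return data.frame of class `stability_ranking`, sorted by ascending
#'   stability, with the bias and per-group variance components.
#' @export
rank_normalizers <- function(ct, det, groups) {
  stopifnot(inherits(ct, "ct_matrix"))
  g <- as_group_vector(groups, ct$sample_ids)
  masked <- mask_ct(ct, det)
  dia <- rownames(masked)[rowSums(is.na(masked)) == 0L &
                            rowSums(det$detected) == ncol(det$detected)]
  if (length(dia) < 2L) stop("fewer than 2 assays detected in all samples")
  X <- masked[dia, , drop = FALSE]
  X <- rbind(X, global_mean = colMeans(X))
  k <- nrow(X)
  if (k < 3L) stop("fewer than 3 candidates; variance decomposition degenerate")
  ad <- names(g)[g == "AD"]; ctrl <- names(g)[g == "CONTROL"]
  if (length(ad) < 2L || length(ctrl) < 2L) {
    stop("each group needs >= 2 samples for the stability model")
  }

  group_fit <- function(cols) {
    Xg <- X[, cols, drop = FALSE]
    n <- ncol(Xg)
    rm_ <- rowMeans(Xg); cm <- colMeans(Xg); gm <- mean(Xg)
    resid <- Xg - outer(rm_, rep(1, n)) - outer(rep(1, k), cm) + gm
    s2 <- rowSums(resid^2) * k / ((k - 1) * (n - 1))
    list(n = n, row_means = rm_, centered = rm_ - mean(rm_), s2 = pmax(s2, 0))
  }
  fa <- group_fit(ad); fb <- group_fit(ctrl)

  bias <- fa$centered - fb$centered
  v_bias <- fa$s2 / fa$n + fb$s2 / fb$n
  intra <- (fa$s2 + fb$s2) / 2
  stability <- sqrt(pmax(bias^2 - v_bias, 0) + intra)

  out <- data.frame(candidate = rownames(X), stability = stability,
                    group_bias = bias, var_AD = fa$s2, var_control = fb$s2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$stability, out$candidate), ]
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Construct a relative-expression matrix
#'
#' @param rel numeric matrix of relative expression levels (REL), `NA` where
#'   undetected; all present values must be > 0.
#' @param assay_ids,sample_ids dimension names.
#' @param fluid `"CSF"` or `"BLOOD"`.
#' @param normalizer_desc description of the normalizer used.
#' @return object of class `rel_matrix`.
#' @export
rel_matrix <- function(rel, assay_ids = rownames(rel),
                       sample_ids = colnames(rel), fluid = c("CSF", "BLOOD"),
                       normalizer_desc = "") {
  fluid <- match.arg(toupper(fluid), c("CSF", "BLOOD"))
  rel <- as.matrix(rel)
  storage.mode(rel) <- "double"
  if (any(rel[!is.na(rel)] <= 0)) stop("all present REL values must be > 0")
  dimnames(rel) <- list(as.character(assay_ids), as.character(sample_ids))
  structure(list(assay_ids = as.character(assay_ids),
                 sample_ids = as.character(sample_ids), rel = rel,
                 fluid = fluid, normalizer_desc = normalizer_desc),
            class = "rel_matrix")
}

#' Compute relative expression levels (REL = 2^-dCt)
#'
#' Per sample, the normalizer is the mean Ct of the assays detected in all
#' samples (`normalizer = "global_mean"`) or the Ct of one such assay. Then
#' `dCt(a, s) = Ct(a, s) - norm(s)` and `REL = 2^-dCt`. Cells masked by the
#' detection matrix stay missing.
#'
#' @param ct a [ct_matrix()].
#' @param det matching [detection_matrix()].
#' @param normalizer `"global_mean"` or an assay id detected in all samples.
#' @return a [rel_matrix()].
#' @export
compute_rel <- function(ct, det, normalizer = "global_mean") {
  stopifnot(inherits(ct, "ct_matrix"))
  masked <- mask_ct(ct, det)
  dia <- rownames(masked)[rowSums(is.na(masked)) == 0L]
  if (identical(normalizer, "global_mean")) {
    if (!length(dia)) {
      stop("no assays detected in all samples; global-mean normalizer undefined")
    }
    norm <- colMeans(masked[dia, , drop = FALSE])
    desc <- sprintf("global mean Ct of %d assays detected in all samples",
                    length(dia))
  } else {
    if (!normalizer %in% dia) {
      stop("normalizer '", normalizer, "' is not detected in all samples")
    }
    norm <- masked[normalizer, ]
    desc <- paste0("single-assay normalizer ", normalizer)
  }
  dct <- sweep(masked, 2L, norm, `-`)
  rel_matrix(2^(-dct), ct$assay_ids, ct$sample_ids, ct$fluid,
             normalizer_desc = desc)
}
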