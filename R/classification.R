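# Leave-one-out logistic classification per miRNA and the two-miRNA ratio
# biomarker with Youden-optimal cutoff.

# Deterministic univariate logistic fit (intercept + slope) by iteratively
# reweighted least squares with a tiny ridge penalty. The ridge keeps the
# normal equations solvable under complete separation and collinearity
# (constant predictor); with n = 20 and LOO, separation is routine. Returns
# the coefficients after at most max_iter updates together with a separation
# flag (fitted probabilities saturated).
logistic_irls <- function(x, y, ridge = 1e-6, max_iter = 50, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtWX <- crossprod(X, w * X) + diag(ridge, 2)
    beta_new <- drop(solve(XtWX, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  p <- stats::plogis(drop(X %*% beta))
  separated <- all(p[y == 1] > 1 - 1e-4) && all(p[y == 0] < 1e-4)
  list(beta = beta, separated = separated)
}

#' Leave-one-out classification accuracy per miRNA
#'
#' For each miRNA, missing REL values are replaced by `missing_fill`, then
#' each sample in turn is held out, a univariate logistic model
#' (intercept + slope) is fitted on the remaining samples with a
#' deterministic ridge-stabilized IRLS fitter, and the held-out sample is
#' predicted AD when its fitted probability exceeds 0.5. Accuracy is the
#' fraction of correctly classified held-out samples. Folds with complete
#' separation are fitted with bounded iterations so the prediction follows
#' the diverging sign; they are counted in `separated_folds`, not errors.
#'
#' @param rel a [rel_matrix()].
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @param missing_fill value substituted for missing REL (default 0,
#'   i.e. "not expressed").
#' @return data.frame with columns `miRNA, accuracy, above_random,
#'   separated_folds`, sorted by decreasing accuracy.
#' @export
loo_accuracy <- function(rel, groups, missing_fill = 0) {
  stopifnot(inherits(rel, "rel_matrix"))
  g <- as_group_vector(groups, rel$sample_ids)
  y <- as.integer(g == "AD")
  if (sum(y) < 2L || sum(1 - y) < 2L) stop("each group needs >= 2 samples")
  n <- length(y)
  rows <- lapply(seq_along(rel$assay_ids), function(i) {
    x <- rel$rel[i, ]
    x[is.na(x)] <- missing_fill
    correct <- 0L
    sep_folds <- 0L
    for (s in seq_len(n)) {
      fit <- logistic_irls(x[-s], y[-s])
      if (fit$separated) sep_folds <- sep_folds + 1L
      p_hat <- stats::plogis(fit$beta[1] + fit$beta[2] * x[s])
      pred <- as.integer(p_hat > 0.5)
      if (pred == y[s]) correct <- correct + 1L
    }
    data.frame(miRNA = rel$assay_ids[i], accuracy = correct / n,
               above_random = (correct / n) > 0.5,
               separated_folds = sep_folds, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, out$miRNA), ]
  rownames(out) <- NULL
  out
}

# Evaluate one cutoff/direction: rule "ratio < cutoff => AD" (direction "lt")
# or "ratio > cutoff => AD" (direction "gt").
ratio_confusion <- function(ratio, y, cutoff, direction) {
  call_ad <- if (direction == "lt") ratio < cutoff else ratio > cutoff
  sens <- 100 * sum(call_ad & y == 1) / sum(y == 1)
  spec <- 100 * sum(!call_ad & y == 0) / sum(y == 0)
  c(sensitivity = sens, specificity = spec, J = sens + spec - 100)
}

#' Fit a two-miRNA ratio biomarker with Youden-optimal cutoff
#'
#' The per-sample predictor is `REL[num] / REL[den]`; samples missing either
#' value are excluded and reported. Candidate cutoffs are the midpoints
#' between consecutive distinct observed ratios plus one point beyond each
#' extreme; both decision directions (`ratio < cutoff => AD` and
#' `ratio > cutoff => AD`) are scanned and the cutoff maximizing Youden's
#' J = sensitivity + specificity - 100 is returned. Ties in J are broken
#' toward higher specificity, then toward the lower cutoff.
#'
#' @param rel a [rel_matrix()].
#' @param num_id,den_id numerator and denominator miRNA ids.
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @return object of class `ratio_model`: a list with the ratios, cutoff,
#'   decision direction, sensitivity, specificity, Youden J and the excluded
#'   sample ids.
#' @export
fit_ratio_model <- function(rel, num_id, den_id, groups) {
  stopifnot(inherits(rel, "rel_matrix"))
  if (!all(c(num_id, den_id) %in% rel$assay_ids)) {
    stop("numerator or denominator miRNA not present in the REL matrix")
  }
  g <- as_group_vector(groups, rel$sample_ids)
  num <- rel$rel[num_id, ]; den <- rel$rel[den_id, ]
  ok <- !is.na(num) & !is.na(den)
  excluded <- rel$sample_ids[!ok]
  ratio <- (num / den)[ok]
  y <- as.integer(g[ok] == "AD")
  if (sum(y) == 0L || sum(1 - y) == 0L) {
    stop("both groups must retain samples after exclusion")
  }
  u <- sort(unique(ratio))
  pad <- if (length(u) > 1) min(diff(u)) / 2 else max(abs(u[1]) / 2, 0.5)
  cutoffs <- c(u[1] - pad,
               if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
               u[length(u)] + pad)
  best <- NULL
  for (direction in c("lt", "gt")) {
    for (cf in cutoffs) {
      res <- ratio_confusion(ratio, y, cf, direction)
      cand <- list(cutoff = cf, direction = direction,
                   sensitivity = res[["sensitivity"]],
                   specificity = res[["specificity"]], J = res[["J"]])
      if (is.null(best) ||
          cand$J > best$J + 1e-12 ||
          (abs(cand$J - best$J) <= 1e-12 &&
           (cand$specificity > best$specificity + 1e-12 ||
            (abs(cand$specificity - best$specificity) <= 1e-12 &&
             cand$cutoff < best$cutoff)))) {
        best <- cand
      }
    }
  }
  structure(list(numerator = num_id, denominator = den_id,
                 ratios = stats::setNames(ratio, rel$sample_ids[ok]),
                 groups = g[ok], cutoff = best$cutoff,
                 direction = best$direction, sensitivity = best$sensitivity,
                 specificity = best$specificity, J = best$J,
                 n_excluded = length(excluded), excluded = excluded),
            class = "ratio_model")
}

#' @export
print.ratio_model <- function(x, ...) {
  rule <- if (x$direction == "lt") "<" else ">"
  cat(sprintf(
    "ratio model REL[%s]/REL[%s]: AD if ratio %s %.4g; sens %.0f%%, spec %.0f%% (J = %.0f), %d excluded\n",
    x$numerator, x$denominator, rule, x$cutoff, x$sensitivity, x$specificity,
    x$J, x$n_excluded))
  invisible(x)
}

#' Screen all ordered miRNA pairs as ratio biomarkers
#'
#' Evaluates [fit_ratio_model()] for every ordered pair of candidates and
#' ranks by Youden's J (descending), then by fewer excluded samples, then by
#' pair name.
#'
#' @param rel a [rel_matrix()].
#' @param groups cohort metadata or named AD/CONTROL vector.
#' @param candidate_ids at least two assay ids.
#' @return data.frame with one row per ordered pair.
#' @export
screen_ratio_pairs <- function(rel, groups, candidate_ids) {
  if (length(candidate_ids) < 2L) stop("need >= 2 candidates")
  pairs <- expand.grid(numerator = candidate_ids, denominator = candidate_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, ]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    m <- fit_ratio_model(rel, pairs$numerator[k], pairs$denominator[k], groups)
    data.frame(numerator = m$numerator, denominator = m$denominator,
               cutoff = m$cutoff, direction = m$direction,
               sensitivity = m$sensitivity, specificity = m$specificity,
               J = m$J, n_excluded = m$n_excluded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$J, out$n_excluded, out$numerator, out$denominator), ]
  rownames(out) <- NULL
  out
}
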