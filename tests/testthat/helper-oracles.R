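# Independent brute-force oracles and small fixture builders shared by the
# suite. Every oracle is written from the definition, not from the code path
# it checks.

# Exact two-sided Mann-Whitney p by full enumeration of all rank assignments.
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) sum(seq_len(n)[idx]) - nx * (nx + 1) / 2)
  m <- nx * ny / 2
  p <- if (u_obs > m) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Two-sided Fisher p by enumerating every table with the observed margins and
# summing hypergeometric probabilities <= the observed one (probability
# method, relative tie tolerance 1e-7).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- function(aa) {
    exp(lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(n, c1))
  }
  p_obs <- prob(a)
  sum(vapply(support, prob, numeric(1))[
    vapply(support, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Naive double-loop Benjamini-Hochberg step-up.
bh_naive_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in i:n) {
      vals <- c(vals, m * p[ord[j]] / j)
    }
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# Spearman rho via the Pearson product-moment formula on mid-ranks.
spearman_rank_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Independent LOO logistic accuracy via stats::glm.
loo_glm_oracle <- function(x, y) {
  n <- length(y)
  correct <- 0L
  for (s in seq_len(n)) {
    fit <- suppressWarnings(
      stats::glm(y[-s] ~ x[-s], family = stats::binomial()))
    eta <- fit$coefficients[1] + fit$coefficients[2] * x[s]
    if (is.na(eta)) eta <- fit$coefficients[1]
    if (as.integer(stats::plogis(eta) > 0.5) == y[s]) correct <- correct + 1L
  }
  correct / n
}

# Small ct_matrix builder: values by row, optional negative controls.
make_ct <- function(values, n_assays, n_samples, fluid = "CSF",
                    negctrl = NULL, assay_ids = NULL, sample_ids = NULL) {
  if (is.null(assay_ids)) assay_ids <- sprintf("miR-t-%02d", seq_len(n_assays))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n_samples))
  m <- matrix(values, n_assays, n_samples, byrow = TRUE,
              dimnames = list(assay_ids, sample_ids))
  ct_matrix(m, assay_ids, sample_ids, fluid, negctrl_ct = negctrl)
}

# Balanced two-group metadata.
make_meta <- function(n_ad = 10, n_control = 10) {
  data.frame(sample_id = c(sprintf("AD%02d", seq_len(n_ad)),
                           sprintf("CTRL%02d", seq_len(n_control))),
             group = rep(c("AD", "CONTROL"), c(n_ad, n_control)),
             stringsAsFactors = FALSE)
}

# Detection-matrix wrapper for fully detected data.
all_detected <- function(ct) {
  detection_matrix(matrix(TRUE, length(ct$assay_ids), length(ct$sample_ids),
                          dimnames = list(ct$assay_ids, ct$sample_ids)),
                   ct$assay_ids, ct$sample_ids, ct$fluid)
}

# Randomized probability-integral transform for exact two-sided Wilcoxon
# p-values. Exact-test p-values are discrete and super-uniform; mapping each
# observed p through u = F0(p-) + V * (F0(p) - F0(p-)), with F0 the exact
# null CDF of the p-value (from dwilcox), yields exactly uniform values under
# the null, which a KS test can then assess at its nominal level.
wilcox_p_pit <- function(p_obs, nx, ny) {
  m <- nx * ny
  u_vals <- 0:m
  dens <- stats::dwilcox(u_vals, nx, ny)
  lev <- vapply(u_vals, function(u) {
    if (u > m / 2) min(1, 2 * (1 - stats::pwilcox(u - 1, nx, ny)))
    else min(1, 2 * stats::pwilcox(u, nx, ny))
  }, numeric(1))
  vapply(p_obs, function(p) {
    F0 <- sum(dens[lev <= p + 1e-12])
    F0m <- sum(dens[lev < p - 1e-12])
    F0m + stats::runif(1) * (F0 - F0m)
  }, numeric(1))
}
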