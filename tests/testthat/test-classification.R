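# Leave-one-out logistic accuracies and the ratio biomarker.

make_rel <- function(values, assay_ids, samples) {
  rel_matrix(matrix(values, length(assay_ids), length(samples), byrow = TRUE,
                    dimnames = list(assay_ids, samples)),
             assay_ids, samples, "CSF")
}

balanced_groups <- function(n = 10) {
  samples <- c(sprintf("AD%02d", seq_len(n)), sprintf("CTRL%02d", seq_len(n)))
  stats::setNames(rep(c("AD", "CONTROL"), each = n), samples)
}

test_that("a perfectly separated predictor reaches accuracy 1", {
  g <- balanced_groups(10)
  rel <- make_rel(c(seq(5, 6, length.out = 10), seq(0.5, 1, length.out = 10)),
                  "sep", names(g))
  res <- loo_accuracy(rel, g)
  expect_equal(res$accuracy, 1)
  expect_true(res$above_random)
})

test_that("a constant predictor scores 0 in a balanced design", {
  # each LOO training set is 9 vs 10: the held-out sample is always the
  # minority class of its own training set and gets the majority prediction
  g <- balanced_groups(10)
  rel <- make_rel(rep(1, 20), "const", names(g))
  res <- loo_accuracy(rel, g)
  expect_equal(res$accuracy, 0)
})

test_that("missing values are imputed with the configured fill", {
  g <- balanced_groups(5)
  vals <- c(seq(5, 6, length.out = 5), seq(0.5, 1, length.out = 5))
  vals[1] <- NA  # filled with 0 -> lands in the control range side
  rel <- make_rel(vals, "m", names(g))
  res0 <- loo_accuracy(rel, g, missing_fill = 0)
  res_big <- loo_accuracy(rel, g, missing_fill = 5.5)
  expect_lt(res0$accuracy, res_big$accuracy)
})

test_that("LOO accuracy agrees with an independent glm fitter", {
  set.seed(33)
  disagreements_over_one_fold <- 0L
  for (rep in 1:50) {
    n <- sample(c(5, 6), 1)
    g <- balanced_groups(n)
    x <- c(rnorm(n, 1.5, 0.8), rnorm(n, 0.8, 0.8))
    x <- pmax(x, 0.01)
    rel <- make_rel(x, "r", names(g))
    acc <- loo_accuracy(rel, g)$accuracy
    oracle <- loo_glm_oracle(x, as.integer(g == "AD"))
    if (abs(acc - oracle) > 1 / (2 * n) + 1e-9) {
      disagreements_over_one_fold <- disagreements_over_one_fold + 1L
    }
    expect_true(acc >= 0 && acc <= 1)
    expect_equal(acc * 2 * n, round(acc * 2 * n), tolerance = 1e-9)
  }
  expect_equal(disagreements_over_one_fold, 0L)
})

test_that("the ratio model separates separable groups completely", {
  g <- balanced_groups(5)
  rel <- make_rel(c(rep(0.5, 5), rep(1.5, 5),   # numerator
                    rep(1.0, 10)),              # denominator
                  c("num", "den"), names(g))
  m <- fit_ratio_model(rel, "num", "den", g)
  expect_gt(m$cutoff, 0.5); expect_lt(m$cutoff, 1.5)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$direction, "lt")
})

test_that("one AD outlier gives the published 90/100 sens/spec structure", {
  g <- balanced_groups(10)
  num <- c(rep(0.3, 9), 1.2, rep(1.0, 10))
  den <- rep(1, 20)
  rel <- make_rel(c(num, den), c("num", "den"), names(g))
  m <- fit_ratio_model(rel, "num", "den", g)
  expect_equal(m$direction, "lt")
  expect_gt(m$cutoff, 0.3); expect_lt(m$cutoff, 1.0)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 100)

  # reported sens/spec equal a brute-force confusion matrix at the cutoff
  ratio <- num / den
  call_ad <- ratio < m$cutoff
  truth <- g == "AD"
  expect_equal(m$sensitivity, 100 * sum(call_ad & truth) / sum(truth))
  expect_equal(m$specificity, 100 * sum(!call_ad & !truth) / sum(!truth))
})

test_that("the Youden-optimal cutoff beats every observed-value cutoff", {
  set.seed(71)
  g <- balanced_groups(8)
  ratio <- c(rlnorm(8, -0.3, 0.5), rlnorm(8, 0.3, 0.5))
  rel <- make_rel(c(ratio, rep(1, 16)), c("num", "den"), names(g))
  m <- fit_ratio_model(rel, "num", "den", g)
  truth <- g == "AD"
  for (cf in ratio) {
    for (dir in c(TRUE, FALSE)) {
      call_ad <- if (dir) ratio < cf else ratio > cf
      J <- 100 * sum(call_ad & truth) / sum(truth) +
        100 * sum(!call_ad & !truth) / sum(!truth) - 100
      expect_gte(m$J, J - 1e-9)
    }
  }
})

test_that("ratio-model performance is invariant to monotone transforms", {
  set.seed(13)
  g <- balanced_groups(6)
  num <- rlnorm(12, 0, 0.6); den <- rlnorm(12, 0.4, 0.6)
  rel <- make_rel(c(num, den), c("num", "den"), names(g))
  m1 <- fit_ratio_model(rel, "num", "den", g)
  # cube the ratio by transforming numerator and denominator consistently
  rel2 <- make_rel(c(num^3, den^3), c("num", "den"), names(g))
  m2 <- fit_ratio_model(rel2, "num", "den", g)
  expect_equal(m1$J, m2$J)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
})

test_that("samples missing either REL are excluded and reported", {
  g <- balanced_groups(5)
  vals <- c(rep(0.5, 5), rep(1.5, 5), rep(1, 10))
  rel <- make_rel(vals, c("num", "den"), names(g))
  rel$rel["num", "AD01"] <- NA
  m <- fit_ratio_model(rel, "num", "den", g)
  expect_equal(m$n_excluded, 1L)
  expect_equal(m$excluded, "AD01")
  expect_length(m$ratios, 9L)
})

test_that("pair screening evaluates ordered pairs with reciprocal symmetry", {
  set.seed(29)
  g <- balanced_groups(6)
  a <- rlnorm(12, 0, 0.5); b <- rlnorm(12, 0.3, 0.5)
  rel <- make_rel(c(a, b), c("A", "B"), names(g))
  screen <- screen_ratio_pairs(rel, g, c("A", "B"))
  expect_equal(nrow(screen), 2L)
  expect_equal(screen$J[1], screen$J[2])  # (A,B) and (B,A) reciprocal ratios
})

test_that("the screen recovers a planted up/down pair", {
  # 2 planted (one up, one down in AD) + 2 null candidates; with larger
  # candidate sets ties at complete separation blur the top pair
  effects <- data.frame(assay = 1:2, ddct = c(-1, 1), fluid = "CSF")
  hits <- 0L
  n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    cohort <- generate_cohort(cohort_config(n_assays = 4, effects = effects,
                                            seed = 2000 + seed))
    det <- call_detection(cohort$csf)
    rel <- compute_rel(cohort$csf, det)
    screen <- screen_ratio_pairs(rel, cohort$metadata,
                                 cohort$truth$assay_ids)
    planted <- cohort$truth$effects$assay
    top <- c(screen$numerator[1], screen$denominator[1])
    if (setequal(top, planted)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})
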