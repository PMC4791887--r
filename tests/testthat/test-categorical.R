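# Fisher tests, odds ratios, detection-marker performance, the categorical
# screen and the fluid partition.

test_that("Fisher two-sided p reproduces the published contingency values", {
  expect_equal(round(fisher_exact_two_sided(5, 5, 0, 10), 2), 0.03)
  expect_equal(round(fisher_exact_two_sided(6, 4, 1, 9), 2), 0.06)
  expect_equal(fisher_exact_two_sided(5, 5, 0, 10), 0.03250774,
               tolerance = 1e-6)
})

test_that("zero margins give p = 1 and bad counts error", {
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_two_sided(2, 0, 3, 0), 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_two_sided(1.5, 2, 3, 4), "nonnegative")
})

test_that("Fisher p equals hypergeometric enumeration for all margins <= 12", {
  for (a in 0:6) for (b in 0:(6 - 0)) for (c_ in 0:6) for (d in 0:6) {
    if (a + b > 6 || c_ + d > 6) next
    expect_equal(fisher_exact_two_sided(a, b, c_, d),
                 fisher_enum_oracle(a, b, c_, d), tolerance = 1e-9,
                 info = sprintf("(%d,%d/%d,%d)", a, b, c_, d))
  }
  # a spread of larger tables with margins up to 12
  set.seed(4)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1, sample(4:24, 1), rep(1, 4)))
    if (cells[1] + cells[2] > 12 || cells[3] + cells[4] > 12) next
    expect_equal(do.call(fisher_exact_two_sided, as.list(cells)),
                 do.call(fisher_enum_oracle, as.list(cells)),
                 tolerance = 1e-9)
  }
})

test_that("odds ratio follows the zero-cell correction rule", {
  expect_equal(odds_ratio(6, 4, 1, 9), 13.5)          # no zero cell
  expect_equal(odds_ratio(5, 5, 0, 10), 21)           # Haldane 0.5 on zeros
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
})

test_that("odds ratio is transpose-invariant and inverts under row swap", {
  set.seed(9)
  for (rep in 1:20) {
    cells <- sample(0:8, 4, replace = TRUE)
    or1 <- do.call(odds_ratio, as.list(cells))
    or_t <- odds_ratio(cells[1], cells[3], cells[2], cells[4])
    or_swap <- odds_ratio(cells[3], cells[4], cells[1], cells[2])
    expect_equal(or1, or_t, tolerance = 1e-12)
    expect_equal(or1, 1 / or_swap, tolerance = 1e-12)
  }
})

test_that("detection sensitivity/specificity match the published rows", {
  expect_equal(detection_marker_performance(5, 5, 0, 10),
               c(sensitivity = 50, specificity = 100))
  expect_equal(detection_marker_performance(6, 4, 1, 9),
               c(sensitivity = 60, specificity = 90))
  expect_equal(detection_marker_performance(10, 0, 0, 10),
               c(sensitivity = 100, specificity = 100))
  expect_error(detection_marker_performance(0, 0, 5, 5), "empty group")
})

test_that("the categorical screen reproduces the published marker table", {
  fx <- generate_table3_fixture()
  screen <- categorical_screen(fx$csf, fx$metadata, p_threshold = 0.1)
  expect_equal(nrow(screen), 3L)
  expect_setequal(screen$miRNA, c("miR-199b-5p", "miR-22-5p", "miR-206"))
  expect_equal(sum(screen$significant), 2L)  # two starred rows at p < 0.05
  r199 <- screen[screen$miRNA == "miR-199b-5p", ]
  expect_equal(r199$OR, 21)
  expect_equal(r199$sensitivity, 50)
  expect_equal(r199$specificity, 100)
  expect_equal(round(r199$p, 2), 0.03)
  r206 <- screen[screen$miRNA == "miR-206", ]
  expect_equal(r206$OR, 13.5)
  expect_equal(round(r206$p, 2), 0.06)
  expect_false(r206$significant)
  # background assays with symmetric frequencies never enter the screen
  expect_false(any(grepl("bg", screen$miRNA)))
})

test_that("swapping group labels reverses the screen direction", {
  samples <- c(sprintf("AD%02d", 1:10), sprintf("CTRL%02d", 1:10))
  det <- rbind(`up-in-AD` = c(rep(TRUE, 8), rep(FALSE, 2),
                              rep(TRUE, 1), rep(FALSE, 9)),
               `up-in-CTRL` = c(rep(TRUE, 1), rep(FALSE, 9),
                                rep(TRUE, 8), rep(FALSE, 2)))
  colnames(det) <- samples
  dm <- detection_matrix(det, rownames(det), samples, "CSF")
  g <- stats::setNames(rep(c("AD", "CONTROL"), each = 10), samples)
  g_swapped <- stats::setNames(rep(c("CONTROL", "AD"), each = 10), samples)
  expect_equal(categorical_screen(dm, g)$miRNA, "up-in-AD")
  expect_equal(categorical_screen(dm, g_swapped)$miRNA, "up-in-CTRL")
})

test_that("fluid partition counts conserve the union and match set algebra", {
  samples <- sprintf("S%d", 1:4)
  det_c <- rbind(a = c(TRUE, TRUE, FALSE, FALSE),
                 b = c(FALSE, FALSE, FALSE, FALSE),
                 c = c(TRUE, TRUE, TRUE, TRUE))
  det_b <- rbind(a = rep(TRUE, 4),
                 b = c(TRUE, FALSE, FALSE, FALSE),
                 d = c(TRUE, TRUE, FALSE, FALSE))
  colnames(det_c) <- samples; colnames(det_b) <- samples
  dc <- detection_matrix(det_c, rownames(det_c), samples, "CSF")
  db <- detection_matrix(det_b, rownames(det_b), samples, "BLOOD")
  part <- fluid_partition(dc, db)
  expect_equal(unname(part$counts["both"]), 1L)        # a
  expect_equal(unname(part$counts["blood_only"]), 2L)  # b (CSF 0 samples), d
  expect_equal(unname(part$counts["csf_only"]), 1L)    # c
  expect_equal(sum(part$counts[c("both", "blood_only", "csf_only")]),
               unname(part$counts["total"]))
  cats <- part$categories
  expect_equal(cats$category[cats$miRNA == "a"], "blood>CSF")  # 4 > 2
  expect_equal(cats$category[cats$miRNA == "c"], "CSF>blood")

  # brute-force set algebra on a synthetic cohort
  cohort <- generate_cohort(cohort_config(n_assays = 50, seed = 17,
                                          baseline_range = c(28, 40)))
  p2 <- fluid_partition(call_detection(cohort$csf),
                        call_detection(cohort$blood))
  in_csf <- rownames(call_detection(cohort$csf)$detected)[
    rowSums(call_detection(cohort$csf)$detected) > 0]
  in_blood <- rownames(call_detection(cohort$blood)$detected)[
    rowSums(call_detection(cohort$blood)$detected) > 0]
  expect_equal(unname(p2$counts["both"]), length(intersect(in_csf, in_blood)))
  expect_equal(unname(p2$counts["blood_only"]), length(setdiff(in_blood, in_csf)))
  expect_equal(unname(p2$counts["csf_only"]), length(setdiff(in_csf, in_blood)))
})
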