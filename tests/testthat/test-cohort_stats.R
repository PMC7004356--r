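test_that("pH bins are lower-closed, upper-open, and partition the line", {
  expect_equal(as.character(bin_ph(7.1)), "7.1_7.2")
  expect_equal(as.character(bin_ph(7.399)), "7.3_7.4")
  expect_equal(as.character(bin_ph(6.95)), "lt7.0")
  expect_equal(as.character(bin_ph(7.4)), "ge7.4")
  expect_equal(as.character(bin_ph(7.0)), "7.0_7.1")
  ph <- seq(6.5, 7.8, by = 0.001)
  b <- bin_ph(ph)
  expect_false(anyNA(b))
  expect_equal(sum(table(b)), length(ph))
})

test_that("BE bins split at -12 with -12 in the upper bin", {
  expect_equal(as.character(bin_be(-12)), "ge_m12")
  expect_equal(as.character(bin_be(-12.01)), "lt_m12")
  expect_equal(as.character(bin_be(0)), "ge_m12")
})

test_that("frequency tables normalise per covered segment", {
  cl <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                   segment = rep(c(60, 50, 40, 30, 20, 10), 2),
                   covered = TRUE, category = "I", level = 1L)
  cl$category_value <- 1L; cl$level_value <- 1L
  ft <- frequency_table(cl, 3)
  expect_equal(unlist(ft[ft$class == "I", -1], use.names = FALSE),
               rep(100, 6))
  # mixed cohort columns sum to 100 +/- 0.1 and NAs drop from denominators
  withr::local_seed(2)
  n <- 400
  cl2 <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 6),
                    segment = rep(c(60, 50, 40, 30, 20, 10), n),
                    covered = TRUE,
                    level = sample(c(1:5, NA), 6 * n, replace = TRUE))
  cl2$category <- c("I", "II", "II", "II", "III")[pmin(cl2$level, 5)]
  cl2$category_value <- category_value(cl2$category)
  cl2$level_value <- cl2$level
  ft5 <- frequency_table(cl2, 5)
  expect_true(all(abs(colSums(ft5[, -1]) - 100) <= 0.1))
  expect_equal(unname(attr(ft5, "n")),
               unname(as.vector(tapply(!is.na(cl2$level),
                                       factor(cl2$segment,
                                              levels = c(60, 50, 40, 30, 20, 10)),
                                       sum))))
})

toy_cohort <- function() {
  cl <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                   segment = rep(c(60, 50, 40, 30, 20, 10), 2),
                   covered = TRUE,
                   category = rep(c("I", "II"), each = 6),
                   level = rep(c(3L, 2L), each = 6))
  cl$category_value <- category_value(cl$category)
  cl$level_value <- cl$level
  out <- data.frame(subject_id = c("a", "b"), ph = c(7.35, 7.25),
                    be_mmol_l = c(-15, -5))
  list(cl = cl, out = out)
}

test_that("outcome summaries report group n, mean, sd", {
  tc <- toy_cohort()
  s <- outcome_by_class(tc$cl, tc$out, 3)
  i <- s$segment == 60 & s$class == "I"
  expect_equal(s$mean_ph[i], 7.35)
  expect_equal(s$n[i], 1)
  ii <- s$segment == 60 & s$class == "II"
  expect_equal(s$mean_ph[ii], 7.25)
  # single-observation groups have undefined sd, not zero-filled noise
  expect_true(is.na(s$sd_ph[i]))
  # group n sums to covered subjects
  expect_equal(sum(s$n[s$segment == 60]), 2)
})

test_that("pooled means equal the weighted mean of group means", {
  withr::local_seed(10)
  n <- 120
  cl <- data.frame(subject_id = sprintf("s%03d", 1:n), segment = 10,
                   covered = TRUE,
                   category = sample(c("I", "II"), n, replace = TRUE),
                   level = sample(1:3, n, replace = TRUE))
  cl$category_value <- category_value(cl$category)
  cl$level_value <- cl$level
  out <- data.frame(subject_id = cl$subject_id, ph = runif(n, 7.0, 7.5),
                    be_mmol_l = runif(n, -15, 0))
  s <- outcome_by_class(cl, out, 3)
  s <- s[s$n > 0, ]
  expect_equal(sum(s$mean_ph * s$n) / sum(s$n), mean(out$ph))
  # invariant to subject ordering
  perm <- sample(n)
  s2 <- outcome_by_class(cl[perm, ], out, 3)
  expect_equal(s2[s2$n > 0, ], s, ignore_attr = TRUE)
})

test_that("classification value by outcome group separates BE bins", {
  tc <- toy_cohort()
  g <- class_value_by_outcome_group(tc$cl, tc$out, 5, "by_be_bin")
  lo <- g$segment == 60 & g$group == "lt_m12"
  hi <- g$segment == 60 & g$group == "ge_m12"
  expect_equal(g$mean_value[lo], 3)
  expect_equal(g$mean_value[hi], 2)
  expect_equal(g$n[lo] + g$n[hi], 2)
})

test_that("Kruskal-Wallis matches the hand-computed toy and the oracle", {
  r <- kw_test(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(r$statistic, 3.857, tolerance = 1e-3)
  expect_equal(r$df, 1L)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, oracle_kw_p(c(1, 2, 3, 4, 5, 6),
                                      rep(c("g1", "g2"), each = 3)),
               tolerance = 0.005)
  # degenerate all-tied data
  r0 <- kw_test(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_warning(kw_test(1:5, c("a", "a", "b", "b", "c")), "n < 2")
})

test_that("exact small-sample p-values match brute-force oracles", {
  withr::local_seed(77)
  for (i in 1:12) {
    # Kruskal-Wallis with ties, n <= 7 (oracle enumerates n! orderings)
    n <- sample(5:7, 1)
    v <- sample(1:4, n, replace = TRUE)
    g <- sample(rep(c("a", "b", "c"), length.out = n))
    if (min(table(g)) < 2 || length(unique(v)) == 1) next
    expect_equal(kw_test(v, g)$p_value, oracle_kw_p(v, g), tolerance = 0.005)
  }
  for (i in 1:15) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(1:5, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    for (alt in c("two.sided", "less", "greater"))
      expect_equal(rank_sum_test(x, y, alt)$p_value,
                   oracle_ranksum_p(x, y, alt), tolerance = 0.005)
    np <- sample(3:6, 1)
    a <- sample(1:6, np, replace = TRUE)
    b <- sample(1:6, np, replace = TRUE)
    expect_equal(signed_rank_test(a, b)$p_value, oracle_signedrank_p(a, b),
                 tolerance = 0.005)
  }
  for (i in 1:6) {
    y <- matrix(sample(1:3, 9, replace = TRUE), 3, 3)
    if (all(apply(y, 1, function(r) length(unique(r)) == 1))) next
    expect_equal(friedman_test_seg(y)$p_value, oracle_friedman_p(y),
                 tolerance = 0.005)
  }
})

test_that("asymptotic paths agree with stats:: reference implementations", {
  withr::local_seed(55)
  v <- sample(1:5, 40, replace = TRUE)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  r <- kw_test(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  x <- sample(1:5, 25, replace = TRUE)
  y <- sample(2:6, 30, replace = TRUE)
  expect_equal(rank_sum_test(x, y)$p_value,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE))$p.value)
})

test_that("Friedman handles ties and identical rows", {
  y <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3), 3, byrow = TRUE)
  r <- friedman_test_seg(y)
  expect_equal(r$statistic, 12 / (3 * 3 * 4) * (16 + 36 + 64) - 3 * 3 * 4)
  expect_equal(friedman_test_seg(matrix(2, 5, 3))$statistic, 0)
  expect_equal(friedman_test_seg(matrix(2, 5, 3))$p_value, 1)
})

test_that("the battery runs end to end and flags significance correctly", {
  withr::local_seed(3)
  cfg <- ctg_config()
  sim <- simulate_cohort(cfg, seed = 31, n = 300, render = FALSE)
  tt <- run_tests(sim$classifications, sim$outcomes)
  expect_true(all(c("friedman", "kruskal_wallis", "wilcoxon_rank_sum",
                    "wilcoxon_signed_rank", "tukey_hsd") %in% tt$test))
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1, na.rm = TRUE))
  expect_true(all(tt$alpha == 0.05))
  # the class mix shifts massively toward delivery: Friedman must reject
  fr <- tt[tt$test == "friedman" & tt$tier == 5, ]
  expect_lt(fr$p_value, 0.05)
})

test_that("the analysis output set is written as tidy CSVs", {
  withr::local_seed(4)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(ctg_config(), seed = 9, n = 120, render = FALSE)
  files <- write_analysis(sim$classifications, sim$outcomes, dir)
  expect_setequal(basename(files),
                  c("frequency_3.csv", "frequency_5.csv",
                    "outcome_by_class_3.csv", "outcome_by_class_5.csv",
                    "class_value_by_group_3.csv", "class_value_by_group_5.csv",
                    "tests.csv"))
  ft <- read.csv(file.path(dir, "frequency_5.csv"))
  expect_equal(nrow(ft), 5)
})
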