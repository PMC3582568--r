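# Independent tail-summation oracle for the Audic-Claverie test: direct
# summation of p(k | x) over the relevant tail, in plain arithmetic.
ac_point <- function(x, k, N1, N2) {
  r <- N2 / N1
  exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log(1 + r))
}

ac_oracle <- function(x, y, N1, N2) {
  lower <- sum(ac_point(x, 0:y, N1, N2))
  upper <- 1 - lower  # strictly-greater tail: sum_{k > y} p(k | x)
  min(1, 2 * min(lower, upper))
}

test_that("normalize_rpm reproduces the worked values and rejects bad totals", {
  expect_equal(normalize_rpm(5, 1e6), 5)
  expect_equal(normalize_rpm(0, 1e6), 0)
  expect_equal(round(normalize_rpm(130, 285117), 2), 455.95)
  expect_error(normalize_rpm(5, 0), "total")
})

test_that("audic_claverie_p is symmetric and equal at the mode", {
  expect_equal(audic_claverie_p(7, 7, 1e6, 1e6), 1)
  set.seed(31)
  for (k in 1:100) {
    x <- rpois(1, 40); y <- rpois(1, 40)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    expect_equal(audic_claverie_p(x, y, N1, N2),
                 audic_claverie_p(y, x, N2, N1), tolerance = 1e-12)
  }
})

test_that("audic_claverie_p matches the direct tail-summation oracle", {
  # x = 5, y = 0, equal totals: lower tail is the single term p(0 | 5)
  expect_equal(audic_claverie_p(5, 0, 1e6, 1e6),
               2 * choose(5, 0) / 2^6, tolerance = 1e-12)
  for (x in 0:10) {
    for (y in 0:(20 - x)) {
      expect_equal(audic_claverie_p(x, y, 5e5, 8e5),
                   ac_oracle(x, y, 5e5, 8e5), tolerance = 1e-10,
                   label = sprintf("AC(%d, %d)", x, y))
    }
  }
})

test_that("fisher_exact_2x2 matches fisher.test and the hand example", {
  # [[3,1],[1,3]]: x=3, y=1, N1=N2=4
  expect_equal(fisher_exact_2x2(3, 1, 4, 4),
               fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # equal proportions -> p = 1
  expect_equal(fisher_exact_2x2(5, 10, 50, 100), 1)
  set.seed(17)
  for (k in 1:50) {
    N1 <- sample(5:200, 1); N2 <- sample(5:200, 1)
    x <- sample(0:N1, 1); y <- sample(0:N2, 1)
    expect_equal(fisher_exact_2x2(x, y, N1, N2),
                 fisher.test(matrix(c(x, N1 - x, y, N2 - y), 2,
                                    byrow = TRUE))$p.value,
                 tolerance = 1e-9,
                 label = sprintf("fisher(%d/%d, %d/%d)", x, N1, y, N2))
  }
})

test_that("chi2_2x2 matches chisq.test and flags zero expecteds", {
  expect_equal(chi2_2x2(10, 10, 20, 20), 1)
  # [[20,80],[80,20]] -> statistic 72
  expect_equal(chi2_2x2(20, 80, 100, 100),
               pchisq(72, 1, lower.tail = FALSE), tolerance = 1e-12)
  set.seed(23)
  for (k in 1:100) {
    N1 <- sample(20:500, 1); N2 <- sample(20:500, 1)
    x <- sample(1:(N1 - 1), 1); y <- sample(1:(N2 - 1), 1)
    # small expecteds trip chisq.test's approximation warning; the p-value
    # itself is still the exact Pearson formula being compared
    ref <- suppressWarnings(
      chisq.test(matrix(c(x, N1 - x, y, N2 - y), 2, byrow = TRUE),
                 correct = FALSE))
    expect_equal(chi2_2x2(x, y, N1, N2), unname(ref$p.value),
                 tolerance = 1e-10)
  }
  expect_warning(p <- chi2_2x2(0, 0, 10, 10), "expected")
  expect_true(is.na(p))
})

test_that("call_differential applies the dual threshold and direction", {
  counts <- tibble::tibble(
    name = c("miR398a", "flatA", "absent"),
    Wm_Wm = c(130L, 1000L, 0L),
    Wm_BG = c(5444L, 1000L, 0L))
  expect_message(
    de <- call_differential(counts, "Wm_Wm", "Wm_BG",
                            totals = c(Wm_Wm = 285117, Wm_BG = 300000)),
    "excluded")
  expect_s3_class(de, "clamir_de")
  expect_equal(nrow(de), 2L)
  r <- de[de$id == "miR398a", ]
  expect_true(r$significant)
  expect_equal(r$direction, 1L)
  expect_gt(r$log2_ratio, 1)
  flat <- de[de$id == "flatA", ]
  expect_false(flat$significant)
  expect_equal(flat$direction, 0L)
})

test_that("identical counts and totals are never significant", {
  counts <- tibble::tibble(name = paste0("m", 1:5),
                           a = c(10L, 100L, 1000L, 3L, 0L),
                           b = c(10L, 100L, 1000L, 3L, 0L))
  suppressMessages(
    de <- call_differential(counts, "a", "b",
                            totals = c(a = 1e6, b = 1e6)))
  expect_true(all(de$log2_ratio == 0))
  expect_false(any(de$significant))
})

test_that("call_differential is invariant to row order", {
  set.seed(9)
  counts <- tibble::tibble(name = paste0("m", 1:20),
                           a = rpois(20, 200), b = rpois(20, 200))
  counts$b[3] <- counts$a[3] * 10L
  de1 <- call_differential(counts, "a", "b")
  de2 <- call_differential(counts[sample.int(20), ], "a", "b")
  de2 <- de2[match(de1$id, de2$id), ]
  expect_equal(as.data.frame(de2), as.data.frame(de1))
})

test_that("the zero-count RPM floor produces large finite log ratios", {
  counts <- tibble::tibble(name = "m1", a = 0L, b = 400L)
  de <- call_differential(counts, "a", "b",
                          totals = c(a = 1e6, b = 1e6))
  expect_equal(de$rpm_control, 0)  # reported RPM is untouched
  expect_true(is.finite(de$log2_ratio))
  expect_equal(de$log2_ratio, log2(400 / 0.01))
})

test_that("significance gates any/all/named behave as documented", {
  counts <- tibble::tibble(name = c("m1", "m2"),
                           a = c(100L, 10L), b = c(900L, 11L))
  de_any <- call_differential(counts, "a", "b", gate = "any")
  de_all <- call_differential(counts, "a", "b", gate = "all")
  de_ac <- call_differential(counts, "a", "b", gate = "ac")
  pm <- cbind(de_any$p_ac, de_any$p_fisher, de_any$p_chi2)
  expect_equal(de_any$p_gate, apply(pm, 1, min))
  expect_equal(de_all$p_gate, apply(pm, 1, max))
  expect_equal(de_ac$p_gate, de_any$p_ac)
})

test_that("tidy and glance summarize a DE result", {
  counts <- tibble::tibble(name = c("m1", "m2", "m3"),
                           a = c(100L, 50L, 400L), b = c(900L, 52L, 30L))
  de <- call_differential(counts, "a", "b")
  td <- tidy(de)
  expect_false(inherits(td, "clamir_de"))
  expect_equal(nrow(td), 3L)
  gl <- glance(de)
  expect_equal(gl$n, 3L)
  expect_equal(gl$n_significant, gl$n_up + gl$n_down)
  expect_equal(gl$p_threshold, 0.001)
})

test_that("ddct_relative_expression implements the closed form", {
  expect_equal(ddct_relative_expression(18, 15, 18, 15), 1)
  expect_equal(ddct_relative_expression(19, 15, 18, 15), 0.5)
  expect_equal(ddct_relative_expression(20, 15, 23, 15), 8)
  expect_error(ddct_relative_expression(NA, 15, 18, 15))
  expect_error(ddct_relative_expression(-1, 15, 18, 15))
})

test_that("DE tables round-trip through TSV", {
  counts <- tibble::tibble(name = c("m1", "m2"),
                           a = c(100L, 50L), b = c(900L, 52L))
  de <- call_differential(counts, "a", "b")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, path)
  back <- read.delim(path)
  expect_equal(back$id, de$id)
  expect_equal(back$significant, de$significant)
})
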