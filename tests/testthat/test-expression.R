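make_expr <- function(m) {
  # m: protein x sample count matrix -> long expression tibble
  tibble::tibble(
    sample_id = rep(colnames(m), each = nrow(m)),
    protein = rep(rownames(m), times = ncol(m)),
    raw = as.numeric(m)
  )
}

test_that("raw expression is the column sum over single vesicles", {
  counts <- tibble::tibble(
    sample_id = "s1",
    ev_id = c("E1", "E2", "E2"),
    protein = c("CDCP1", "CDCP1", "EPCAM"),
    count = c(2L, 3L, 1L)
  )
  expr <- aggregate_expression(counts)
  expect_equal(expr$raw[expr$protein == "CDCP1"], 5)
  expect_equal(expr$raw[expr$protein == "EPCAM"], 1)

  panel <- ev_panel(c("CDCP1", "EPCAM", "CD9"))
  full <- aggregate_expression(counts, panel)
  expect_equal(full$protein, panel$protein)
  expect_equal(full$raw[full$protein == "CD9"], 0)
  expect_error(aggregate_expression(counts, ev_panel("CD9")), "not in panel")
})

test_that("TMM factors are 1 for identical and depth-scaled samples", {
  set.seed(1)
  m <- matrix(rpois(40, 50), nrow = 20,
              dimnames = list(paste0("P", 1:20), c("a", "b")))
  m[, 2] <- m[, 1]
  f <- tmm_norm_factors(make_expr(m))
  expect_equal(f$norm_factor, c(1, 1))

  m[, 2] <- 2 * m[, 1]  # pure depth difference is absorbed by library size
  f2 <- tmm_norm_factors(make_expr(m))
  expect_equal(f2$norm_factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the established reference implementation", {
  set.seed(42)
  m <- matrix(rnbinom(113 * 6, mu = 80, size = 1.2), nrow = 113,
              dimnames = list(paste0("P", 1:113), paste0("s", 1:6)))
  m[1:10, 1:3] <- m[1:10, 1:3] * 5  # asymmetric composition shift
  ours <- tmm_norm_factors(make_expr(m))
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(ours$norm_factor[match(colnames(m), ours$sample_id)],
               unname(ref), tolerance = 1e-6)
})

test_that("TMM factors have geometric mean one and resist depth rescaling", {
  set.seed(5)
  m <- matrix(rnbinom(50 * 5, mu = 60, size = 2), nrow = 50,
              dimnames = list(paste0("P", 1:50), paste0("s", 1:5)))
  f <- tmm_norm_factors(make_expr(m))
  expect_equal(exp(mean(log(f$norm_factor))), 1, tolerance = 1e-12)

  # scaling every sample's depth by the same factor changes nothing:
  # log-ratios, trims and relative precision weights are all preserved
  f2 <- tmm_norm_factors(make_expr(m * 4L))
  expect_equal(f2$norm_factor, f$norm_factor, tolerance = 1e-10)

  zero <- m; zero[, 2] <- 0
  expect_error(tmm_norm_factors(make_expr(zero)), "all-zero")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }

  # NA p-values pass through without inflating the family
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], brute_bh(c(0.01, 0.04)))
})

test_that("Mann-Whitney agrees with enumeration and the normal approximation", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  y <- c(0.8, 2.0, 2.2, 4.1)
  got <- mann_whitney_test(x, y)

  # independent enumeration over all 8-choose-4 group assignments
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  splits <- combn(8, 4)
  us <- apply(splits, 2, function(i) sum(r[i]) - 10)
  p_exact <- mean(abs(us - 8) >= abs(u_obs - 8) - 1e-12)
  expect_equal(got$statistic, u_obs)
  expect_equal(got$p_value, p_exact)

  # large-sample path: tie-corrected normal approximation
  set.seed(3)
  x2 <- rnorm(15); y2 <- rnorm(12, 0.5)
  got2 <- mann_whitney_test(x2, y2)
  ref2 <- wilcox.test(x2, y2, exact = FALSE, correct = FALSE)
  expect_equal(got2$p_value, unname(ref2$p.value), tolerance = 1e-10)
})

test_that("the test-selection tree picks the prescribed test", {
  groups <- tibble::tibble(sample_id = paste0("s", 1:12),
                           group = rep(c("case", "ctrl"), each = 6))
  set.seed(2)
  gauss_eq <- c(rnorm(6, 10, 1), rnorm(6, 12, 1))
  gauss_het <- c(rnorm(6, 10, 0.05), rnorm(6, 12, 6))
  skewed <- c(rexp(6, 1)^4, rexp(6, 0.2)^4)
  expr <- tibble::tibble(
    sample_id = rep(groups$sample_id, times = 3),
    protein = rep(c("norm_eq", "norm_het", "skew"), each = 12),
    normalized = c(gauss_eq, gauss_het, skewed)
  )
  de <- differential_expression(expr, groups, case = "case")
  de <- de[match(c("norm_eq", "norm_het", "skew"), de$protein), ]

  # recompute the gates independently and check consistency
  for (i in 1:3) {
    vals <- expr$normalized[expr$protein == de$protein[i]]
    x <- vals[1:6]; y <- vals[7:12]
    swx <- shapiro.test(x)$p.value
    swy <- shapiro.test(y)$p.value
    expected <- if (min(swx, swy) < 0.05) "mann_whitney" else {
      if (var.test(x, y)$p.value < 0.05) "welch_t" else "student_t"
    }
    expect_equal(de$test_used[i], expected)
  }
  expect_setequal(de$test_used, c("student_t", "welch_t", "mann_whitney"))
  expect_true(all(de$q_value >= de$p_value, na.rm = TRUE))
})

test_that("constant features are flagged and excluded from the BH family", {
  groups <- tibble::tibble(sample_id = paste0("s", 1:8),
                           group = rep(c("case", "ctrl"), each = 4))
  set.seed(4)
  expr <- tibble::tibble(
    sample_id = rep(groups$sample_id, times = 2),
    protein = rep(c("flat", "varying"), each = 8),
    normalized = c(rep(5, 8), rnorm(8))
  )
  de <- differential_expression(expr, groups, case = "case")
  flat <- de[de$protein == "flat", ]
  expect_equal(flat$test_used, "none")
  expect_true(is.na(flat$p_value) && is.na(flat$q_value))
  varying <- de[de$protein == "varying", ]
  expect_equal(varying$q_value, varying$p_value)  # family of one
})

test_that("a planted case shift is detected with the right direction", {
  groups <- tibble::tibble(sample_id = sprintf("s%02d", 1:26),
                           group = rep(c("OVCA", "Control"), c(8, 18)))
  set.seed(17)
  panel <- paste0("P", 1:20)
  base <- matrix(rnbinom(20 * 26, mu = 100, size = 8), nrow = 20,
                 dimnames = list(panel, groups$sample_id))
  base["P1", groups$group == "OVCA"] <- base["P1", groups$group == "OVCA"] * 10
  expr <- tmm_normalize(make_expr(base))
  de <- differential_expression(expr, groups, case = "OVCA")
  p1 <- de[de$protein == "P1", ]
  expect_lt(p1$q_value, 0.05)
  expect_equal(p1$direction, "up")
})
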