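#' Aggregate single-EV counts to sample-level expression
#'
#' The sum of a protein's molecule counts over all single vesicles in a
#' sample is its raw expression value.
#'
#' @param counts Long-form single-EV matrix tibble (`sample_id`, `ev_id`,
#'   `protein`, `count`).
#' @param panel Optional panel tibble; when supplied, every panel protein
#'   appears for every sample (zero-filled) and panel order is kept.
#'
#' @return A tibble with columns `sample_id`, `protein`, `raw`.
#' @export
aggregate_expression <- function(counts, panel = NULL) {
  expr <- counts |>
    dplyr::group_by(.data$sample_id, .data$protein) |>
    dplyr::summarise(raw = sum(.data$count), .groups = "drop")
  if (!is.null(panel)) {
    extra <- setdiff(unique(expr$protein), panel$protein)
    if (length(extra) > 0) {
      stop("counts contain proteins not in panel: ",
           paste(head(extra, 5), collapse = ", "), call. = FALSE)
    }
    expr <- expr |>
      tidyr::complete(sample_id = unique(counts$sample_id),
                      protein = panel$protein,
                      fill = list(raw = 0)) |>
      dplyr::mutate(protein = factor(.data$protein, levels = panel$protein)) |>
      dplyr::arrange(.data$sample_id, .data$protein) |>
      dplyr::mutate(protein = as.character(.data$protein))
  }
  expr
}

# expression tibble -> protein x sample matrix
expression_matrix <- function(expr, value = "raw") {
  wide <- expr |>
    dplyr::select("sample_id", "protein", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(value),
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$protein
  m
}

# Trimmed mean of M-values between one sample and the reference: log-ratios
# (M) and average log-abundances (A) of proteins with nonzero counts in
# both, doubly trimmed (30% of M, 5% of A from each tail), averaged with
# inverse approximate-variance (delta-method binomial) weights.
tmm_pair_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0 || max(abs(log_r)) < 1e-6) return(1)

  n <- length(log_r)
  lo_l <- floor(n * trim_m) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors across samples: each
#' sample's factor is the precision-weighted mean log-ratio against a
#' reference sample after trimming the most extreme 30% of log-ratios (M)
#' and 5% of log-abundances (A), and factors are rescaled so their
#' geometric mean is 1. The reference is the sample whose upper-quartile
#' count fraction is closest to the mean upper-quartile fraction.
#'
#' @param expr Expression tibble from [aggregate_expression()].
#' @param trim_m,trim_a Trim fractions for log-ratios and log-abundances.
#' @param ref_sample Optional reference sample id (overrides the
#'   upper-quartile rule).
#'
#' @return A tibble with columns `sample_id`, `lib_size`, `norm_factor`;
#'   the geometric mean of `norm_factor` is 1.
#' @export
tmm_norm_factors <- function(expr, trim_m = 0.30, trim_a = 0.05,
                             ref_sample = NULL) {
  m <- expression_matrix(expr, "raw")
  if (ncol(m) < 2) stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  m <- m[rowSums(m > 0) > 0, , drop = FALSE]

  if (is.null(ref_sample)) {
    f75 <- apply(m, 2, quantile, probs = 0.75) / lib
    ref_idx <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_idx <- match(ref_sample, colnames(m))
    if (is.na(ref_idx)) stop("unknown reference sample", call. = FALSE)
  }

  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref_idx], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample_id = colnames(m), lib_size = unname(lib),
                 norm_factor = unname(f))
}

#' TMM-normalize sample expression
#'
#' Adds effective-library-size scaled values: `normalized = raw /
#' (lib_size * norm_factor) * 1e6` (counts per million on the TMM-adjusted
#' library).
#'
#' @inheritParams tmm_norm_factors
#' @return `expr` with added columns `lib_size`, `norm_factor`,
#'   `normalized`.
#' @export
tmm_normalize <- function(expr, trim_m = 0.30, trim_a = 0.05,
                          ref_sample = NULL) {
  fac <- tmm_norm_factors(expr, trim_m, trim_a, ref_sample)
  expr |>
    dplyr::inner_join(fac, by = "sample_id") |>
    dplyr::mutate(normalized = .data$raw / (.data$lib_size * .data$norm_factor) * 1e6)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: order the m p-values
#' increasingly, set `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1.
#' `NA` p-values are passed through and do not count toward the family
#' size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  q <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok][o] <- q
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both groups of size at most
#' 8) the p-value is exact, by enumeration of all group assignments of the
#' pooled values; otherwise the tie-corrected normal approximation is used
#' (no continuity correction).
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Use exact enumeration when both groups have at most
#'   this many observations.
#' @return A list with `statistic` (U for the `x` group) and `p_value`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    # exact permutation distribution of U under exchangeability (valid with
    # ties since ranks are recomputed on the fixed pooled sample)
    mu <- n1 * n2 / 2
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = u, p_value = min(p, 1))
}

# Shapiro-Wilk normality p, degenerate inputs treated as non-normal
safe_shapiro_p <- function(x) {
  if (length(x) < 3 || length(unique(x)) == 1) return(0)
  tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
}

#' Two-group differential testing with adaptive test selection
#'
#' Per feature, the test is chosen by the selection tree used throughout
#' the analysis: Shapiro-Wilk normality per group, then an F-test of
#' variance homogeneity; non-normal data (either group p below
#' `alpha_assumption`) go to the Mann-Whitney U test, normal data with
#' unequal variances to Welch's t-test, and normal homoscedastic data to
#' Student's t-test. P-values are Benjamini-Hochberg adjusted across the
#' tested features. Features constant within both groups are flagged
#' (`test_used = "none"`) and excluded from the adjustment family.
#'
#' @param expr Expression tibble with columns `sample_id`, `protein` and the
#'   value column, typically from [tmm_normalize()].
#' @param groups Tibble with columns `sample_id`, `group` (two groups, each
#'   with at least 3 samples).
#' @param case Case group label; directions are reported relative to it.
#' @param value Column tested (default `"normalized"`; set `"raw"` to test
#'   unnormalized sums).
#' @param alpha_assumption Gate threshold for the normality and
#'   variance-homogeneity checks.
#'
#' @return A tibble with one row per feature: group means, `test_used`,
#'   the gate p-values, `p_value`, `q_value` and `direction` (`"up"`/
#'   `"down"` in the case group).
#' @export
differential_expression <- function(expr, groups, case,
                                    value = "normalized",
                                    alpha_assumption = 0.05) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  glev <- unique(groups$group)
  if (length(glev) != 2) stop("exactly two groups are required", call. = FALSE)
  if (!case %in% glev) stop("unknown case label: ", case, call. = FALSE)
  control <- setdiff(glev, case)
  if (any(table(groups$group) < 3)) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }

  dat <- dplyr::inner_join(expr, groups, by = "sample_id")
  res <- dat |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      x <- d[[value]][d$group == case]
      y <- d[[value]][d$group == control]
      two_group_test(x, y, alpha_assumption)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(mean_case = "mean_x", mean_control = "mean_y")
  res$q_value <- bh_adjust(res$p_value)
  res
}

two_group_test <- function(x, y, alpha_assumption = 0.05) {
  mean_x <- mean(x); mean_y <- mean(y)
  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(
      mean_x = mean_x, mean_y = mean_y, test_used = "none",
      normality_p_case = NA_real_, normality_p_control = NA_real_,
      variance_p = NA_real_, p_value = NA_real_,
      direction = "none"
    ))
  }
  sw_x <- safe_shapiro_p(x)
  sw_y <- safe_shapiro_p(y)
  if (sw_x < alpha_assumption || sw_y < alpha_assumption) {
    test <- "mann_whitney"
    var_p <- NA_real_
    p <- mann_whitney_test(x, y)$p_value
  } else {
    var_p <- var.test(x, y)$p.value
    if (var_p < alpha_assumption) {
      test <- "welch_t"
      p <- t.test(x, y)$p.value
    } else {
      test <- "student_t"
      p <- t.test(x, y, var.equal = TRUE)$p.value
    }
  }
  tibble::tibble(
    mean_x = mean_x, mean_y = mean_y, test_used = test,
    normality_p_case = sw_x, normality_p_control = sw_y,
    variance_p = var_p, p_value = p,
    direction = if (mean_x > mean_y) "up" else if (mean_x < mean_y) "down" else "equal"
  )
}
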