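#' ROC analysis of a per-sample score
#'
#' Builds the ROC curve over all score thresholds and computes the AUC as
#' the tie-corrected Mann-Whitney concordance: the fraction of
#' (case, control) sample pairs in which the case sample scores higher,
#' ties counted one half. Orientation is chosen so the reported AUC is at
#' least 0.5; `direction` records whether cases score high or low.
#'
#' @param scores Tibble with columns `sample_id`, `group`, `score`.
#' @param case Case group label.
#' @param marker Descriptive marker label carried into the result.
#'
#' @return An object of class `ev_roc`: `marker`, `auc`, `direction`
#'   (`"case-high"`/`"case-low"`), `n_case`, `n_control`, `points` (tibble
#'   of `threshold`, `sensitivity`, `specificity`) and `scores`.
#' @export
ev_roc <- function(scores, case, marker = "score") {
  stopifnot(all(c("sample_id", "group", "score") %in% names(scores)))
  is_case <- scores$group == case
  if (!any(is_case) || all(is_case)) {
    stop("both case and control samples are required", call. = FALSE)
  }
  x <- scores$score[is_case]
  y <- scores$score[!is_case]
  auc <- auc_concordance(x, y)
  direction <- "case-high"
  if (length(unique(c(x, y))) == 1) {
    warning("constant scores; AUC is 0.5")
  }
  if (auc < 0.5) {
    direction <- "case-low"
    x <- -x; y <- -y
    auc <- 1 - auc
  }

  # curve over all thresholds: predict case when score >= t
  thr <- c(Inf, sort(unique(c(x, y)), decreasing = TRUE), -Inf)
  points <- tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(x >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(y < t), numeric(1))
  )

  structure(
    list(marker = marker, auc = auc, direction = direction,
         n_case = length(x), n_control = length(y),
         points = points, scores = scores, case = case),
    class = "ev_roc"
  )
}

#' Tie-corrected concordance AUC
#'
#' `P(case > control) + P(case = control)/2` over all case-control pairs;
#' equals U / (n1 * n2).
#'
#' @param x,y Case and control score vectors.
#' @return AUC in `[0, 1]` (unoriented).
#' @export
auc_concordance <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Trapezoidal AUC from a ROC curve
#'
#' @param points Tibble with `sensitivity` and `specificity` columns.
#' @return Trapezoidal area under the curve.
#' @export
auc_trapezoid <- function(points) {
  fpr <- 1 - points$specificity
  o <- order(fpr, points$sensitivity)
  fpr <- fpr[o]; tpr <- points$sensitivity[o]
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Single-protein ROC
#'
#' Uses the protein's normalized sample-level expression as the score.
#'
#' @param expr Expression tibble from [tmm_normalize()].
#' @param groups Tibble with `sample_id`, `group`.
#' @param protein Marker protein.
#' @param case Case group label.
#' @param value Score column (default `"normalized"`).
#' @return An `ev_roc` object.
#' @export
roc_single <- function(expr, groups, protein, case, value = "normalized") {
  sub <- expr[expr$protein == protein, ]
  if (nrow(sub) == 0) stop("protein not found: ", protein, call. = FALSE)
  scores <- sub |>
    dplyr::inner_join(groups, by = "sample_id") |>
    dplyr::transmute(.data$sample_id, .data$group, score = .data[[value]])
  ev_roc(scores, case, marker = protein)
}

#' Protein-pair ROC
#'
#' Two composite scores are available. `"coexpression"` (default) scores a
#' sample by the CPM of the unordered pair in its vesicle-pair combination
#' table (0 when the pair is unobserved) - i.e. how often the two proteins
#' sit together on the same vesicle. `"logistic"` scores by the in-sample
#' linear combination of the two proteins' normalized expressions fitted by
#' logistic likelihood (apparent, not cross-validated).
#'
#' @param data For `"coexpression"`, a CPM combination tibble
#'   ([cpm_normalize_pairs()]); for `"logistic"`, a normalized expression
#'   tibble.
#' @param groups Tibble with `sample_id`, `group`.
#' @param protein_a,protein_b The marker pair.
#' @param case Case group label.
#' @param mode `"coexpression"` or `"logistic"`.
#' @return An `ev_roc` object.
#' @export
roc_pair <- function(data, groups, protein_a, protein_b, case,
                     mode = c("coexpression", "logistic")) {
  mode <- match.arg(mode)
  key <- sort(c(protein_a, protein_b))
  if (mode == "coexpression") {
    if (!"cpm" %in% names(data)) data <- cpm_normalize_pairs(data)
    sub <- data[data$protein_a == key[1] & data$protein_b == key[2], ]
    if (nrow(sub) == 0) {
      stop("pair ", key[1], "+", key[2], " not observed in any sample",
           call. = FALSE)
    }
    scores <- groups |>
      dplyr::left_join(sub[, c("sample_id", "cpm")], by = "sample_id") |>
      dplyr::transmute(.data$sample_id, .data$group,
                       score = tidyr::replace_na(.data$cpm, 0))
  } else {
    wide <- data[data$protein %in% key, ] |>
      dplyr::select("sample_id", "protein", "normalized") |>
      tidyr::pivot_wider(names_from = "protein", values_from = "normalized") |>
      dplyr::inner_join(groups, by = "sample_id")
    if (!all(key %in% names(wide))) {
      stop("pair proteins missing from expression table", call. = FALSE)
    }
    y <- as.integer(wide$group == case)
    fit <- suppressWarnings(
      glm(y ~ a + b, family = binomial(),
          data = data.frame(y = y, a = wide[[key[1]]], b = wide[[key[2]]]))
    )
    scores <- tibble::tibble(sample_id = wide$sample_id, group = wide$group,
                             score = predict(fit, type = "link"))
  }
  ev_roc(scores, case, marker = paste(key, collapse = "+"))
}

#' @exportS3Method generics::tidy
tidy.ev_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.ev_roc <- function(x, ...) {
  tibble::tibble(marker = x$marker, auc = x$auc, direction = x$direction,
                 n_case = x$n_case, n_control = x$n_control)
}

#' @export
print.ev_roc <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC = %.4f (%s; %d case vs %d control)\n",
              x$marker, x$auc, x$direction, x$n_case, x$n_control))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ev_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s (AUC = %.4f)", object$marker, object$auc)
    ) +
    ggplot2::theme_minimal()
}
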