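#' Count co-expressed protein pairs per vesicle
#'
#' For every unordered protein pair, counts the vesicles in each sample on
#' which both proteins are detected (each with at least `min_count`
#' molecules). Pairs are keyed lexicographically (`protein_a < protein_b`)
#' and pairs never observed are omitted.
#'
#' @param counts Long-form single-EV matrix tibble.
#' @param min_count Molecule floor for a protein to count as detected on a
#'   vesicle.
#'
#' @return A tibble with columns `sample_id`, `protein_a`, `protein_b`,
#'   `count`.
#' @export
count_combinations <- function(counts, min_count = 1L) {
  counts <- counts[counts$count >= min_count, ]
  out <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      proteins <- sort(unique(d$protein))
      evs <- unique(d$ev_id)
      m <- Matrix::sparseMatrix(
        i = match(d$ev_id, evs),
        j = match(d$protein, proteins),
        x = 1,
        dims = c(length(evs), length(proteins))
      )
      cp <- as.matrix(Matrix::crossprod(m))  # pair co-detection counts
      idx <- which(upper.tri(cp) & cp > 0, arr.ind = TRUE)
      tibble::tibble(
        protein_a = proteins[idx[, 1L]],
        protein_b = proteins[idx[, 2L]],
        count = cp[idx]
      )
    }) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$sample_id, .data$protein_a, .data$protein_b)
}

#' CPM-normalize a combination table
#'
#' Scales each sample's pair counts to counts per million over the sample's
#' total pair observations.
#'
#' @param pairs Combination tibble from [count_combinations()].
#' @return `pairs` with an added `cpm` column.
#' @export
cpm_normalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty combination table", call. = FALSE)
  pairs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(cpm = .data$count / sum(.data$count) * 1e6) |>
    dplyr::ungroup()
}

#' Differential protein-pair co-expression between groups
#'
#' Applies the adaptive two-group test (see [differential_expression()]) to
#' per-sample CPM values of each protein pair. Samples where a pair was not
#' observed contribute a CPM of 0; pairs observed in fewer than
#' `min_samples` samples are excluded and counted.
#'
#' @param pairs Combination tibble (CPM added if missing).
#' @param groups Tibble with columns `sample_id`, `group`.
#' @param case Case group label.
#' @param min_samples Minimum samples a pair must be observed in.
#' @inheritParams differential_expression
#'
#' @return A tibble with one row per tested pair (`protein_a`, `protein_b`,
#'   group means, `test_used`, `p_value`, `q_value`, `direction`), with
#'   attribute `n_excluded`.
#' @export
differential_combinations <- function(pairs, groups, case,
                                      min_samples = 2L,
                                      alpha_assumption = 0.05) {
  if (!"cpm" %in% names(pairs)) pairs <- cpm_normalize_pairs(pairs)
  observed_in <- pairs |>
    dplyr::count(.data$protein_a, .data$protein_b, name = "n_samples")
  keep <- observed_in[observed_in$n_samples >= min_samples, ]
  n_excluded <- nrow(observed_in) - nrow(keep)
  if (n_excluded > 0) {
    message(n_excluded, " pair(s) observed in fewer than ", min_samples,
            " samples excluded")
  }

  full <- pairs |>
    dplyr::semi_join(keep, by = c("protein_a", "protein_b")) |>
    dplyr::mutate(pair = paste(.data$protein_a, .data$protein_b, sep = "|")) |>
    dplyr::select("sample_id", "pair", "cpm") |>
    tidyr::complete(sample_id = groups$sample_id, pair = unique(.data$pair),
                    fill = list(cpm = 0)) |>
    dplyr::rename(protein = "pair", normalized = "cpm")

  res <- differential_expression(full, groups, case,
                                 value = "normalized",
                                 alpha_assumption = alpha_assumption) |>
    tidyr::separate_wider_delim("protein", "|",
                                names = c("protein_a", "protein_b"))
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Significant co-expression partners of a focal protein
#'
#' @param de_pairs Result of [differential_combinations()].
#' @param protein Focal protein.
#' @param q_max Significance cut-off on the adjusted p-value.
#' @param direction Optional direction filter (`"up"`/`"down"`).
#' @return Tibble of the focal protein's significant partners, ordered by
#'   q-value.
#' @export
focal_partners <- function(de_pairs, protein, q_max = 0.05, direction = NULL) {
  hit <- de_pairs |>
    dplyr::filter(.data$protein_a == protein | .data$protein_b == protein,
                  !is.na(.data$q_value), .data$q_value < q_max)
  if (!is.null(direction)) {
    hit <- hit[hit$direction == direction, ]
  }
  hit |>
    dplyr::mutate(partner = ifelse(.data$protein_a == protein,
                                   .data$protein_b, .data$protein_a)) |>
    dplyr::arrange(.data$q_value) |>
    dplyr::select("partner", "mean_case", "mean_control", "test_used",
                  "p_value", "q_value", "direction")
}
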