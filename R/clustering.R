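#' Pool single-EV matrices into a feature matrix
#'
#' One feature vector per vesicle over the panel proteins. The default
#' binary representation (detected / not detected) reflects that single-EV
#' molecule counts are shallow and that downstream cluster profiles are
#' detection frequencies; raw or log1p counts are available as options.
#'
#' @param counts Long-form single-EV matrix tibble.
#' @param groups Tibble with columns `sample_id`, `group`.
#' @param panel Optional panel tibble fixing the protein axis and order.
#' @param features `"binary"`, `"counts"` or `"log1p"`.
#'
#' @return A list of class `ev_features`: `x` (vesicles x proteins sparse
#'   matrix), `presence` (logical sparse matrix of detection) and `meta`
#'   (tibble: `sample_id`, `group`, `ev_id`).
#' @export
featurize_evs <- function(counts, groups, panel = NULL,
                          features = c("binary", "counts", "log1p")) {
  features <- match.arg(features)
  proteins <- if (is.null(panel)) sort(unique(counts$protein)) else panel$protein
  if (!all(counts$protein %in% proteins)) {
    stop("counts contain proteins not in panel", call. = FALSE)
  }
  key <- paste(counts$sample_id, counts$ev_id, sep = "\1")
  ev_keys <- unique(key)
  i <- match(key, ev_keys)
  j <- match(counts$protein, proteins)

  x_val <- switch(features,
    binary = rep(1, nrow(counts)),
    counts = as.numeric(counts$count),
    log1p = log1p(counts$count)
  )
  x <- Matrix::sparseMatrix(i = i, j = j, x = x_val,
                            dims = c(length(ev_keys), length(proteins)))
  colnames(x) <- proteins
  presence <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                   dims = c(length(ev_keys), length(proteins)))
  colnames(presence) <- proteins

  first <- !duplicated(key)
  meta <- tibble::tibble(
    sample_id = counts$sample_id[first],
    ev_id = counts$ev_id[first]
  )
  if (!is.null(groups)) {
    meta <- dplyr::left_join(meta, groups[, c("sample_id", "group")],
                             by = "sample_id")
  } else {
    meta$group <- NA_character_
  }
  structure(list(x = x, presence = presence,
                 meta = meta[, c("sample_id", "group", "ev_id")]),
            class = "ev_features")
}

# best-matching unit per row of x; ties broken to the lowest node index
bmu_assign <- function(x, codebook) {
  # argmin_j |x - w_j|^2 = argmax_j (x . w_j - |w_j|^2 / 2); row terms drop
  score <- as.matrix(x %*% t(codebook))
  score <- sweep(score, 2, rowSums(codebook^2) / 2)
  max.col(score, ties.method = "first")
}

#' Train a self-organizing map
#'
#' Batch SOM on a rectangular grid with a Gaussian neighborhood whose
#' radius decays linearly over epochs (from half the larger grid dimension
#' to 0.5). Prototypes are initialized from a seeded sample of the data, so
#' training is deterministic under a fixed seed, and every prototype is a
#' convex combination of data points.
#'
#' @param x Numeric matrix or sparse Matrix (vesicles x proteins).
#' @param grid_w,grid_h Grid dimensions.
#' @param epochs Batch update rounds.
#' @param seed Integer seed.
#'
#' @return A list of class `som_fit`: `codebook` (nodes x proteins),
#'   `grid_w`, `grid_h`, `node_xy`, `seed`.
#' @export
som_train <- function(x, grid_w = 10L, grid_h = 10L, epochs = 10L, seed = 1L) {
  n_nodes <- grid_w * grid_h
  if (nrow(x) < n_nodes) {
    stop("need at least as many vesicles as SOM nodes", call. = FALSE)
  }
  node_xy <- cbind(
    x = rep(seq_len(grid_w), times = grid_h),
    y = rep(seq_len(grid_h), each = grid_w)
  )
  grid_d2 <- as.matrix(dist(node_xy))^2

  set.seed(seed)
  init_idx <- sample.int(nrow(x), n_nodes)
  codebook <- as.matrix(x[init_idx, , drop = FALSE])

  degenerate <- all(apply(as.matrix(x[seq_len(min(nrow(x), 1000L)), , drop = FALSE]),
                          2, function(v) length(unique(v)) == 1)) &&
    nrow(unique(as.matrix(codebook))) == 1
  if (degenerate) warning("all feature vectors identical; SOM is a single point")

  r0 <- max(grid_w, grid_h) / 2
  radii <- seq(r0, 0.5, length.out = epochs)
  for (e in seq_len(epochs)) {
    bmu <- bmu_assign(x, codebook)
    h <- exp(-grid_d2 / (2 * radii[e]^2))          # nodes x nodes
    node_n <- tabulate(bmu, nbins = n_nodes)
    node_sum <- matrix(0, n_nodes, ncol(x))
    occ <- sort(unique(bmu))
    sums <- Matrix::crossprod(
      Matrix::sparseMatrix(i = seq_along(bmu), j = bmu, x = 1,
                           dims = c(nrow(x), n_nodes)),
      x
    )
    node_sum <- as.matrix(sums)
    num <- h %*% node_sum
    den <- as.numeric(h %*% node_n)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  colnames(codebook) <- colnames(x)
  structure(list(codebook = codebook, grid_w = grid_w, grid_h = grid_h,
                 node_xy = node_xy, seed = seed),
            class = "som_fit")
}

#' Meta-cluster SOM nodes
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean) of
#' the node prototypes, cut at `k`. Labels are later reordered by
#' descending vesicle count in [ev_cluster()].
#'
#' @param codebook Node prototype matrix.
#' @param k Number of meta-clusters.
#' @return Integer vector: meta-cluster id per node.
#' @export
metacluster_nodes <- function(codebook, k) {
  if (k > nrow(codebook)) stop("k exceeds node count", call. = FALSE)
  hc <- hclust(dist(codebook), method = "average")
  cutree(hc, k = k)
}

#' Discover vesicle subpopulations by SOM metaclustering
#'
#' FlowSOM-style pipeline: pool vesicles into feature vectors, train a SOM,
#' meta-cluster the node prototypes by average-linkage hierarchical
#' clustering cut at `k`, and assign every vesicle the meta-cluster of its
#' best-matching node. Meta-cluster ids are ordered by descending size
#' (vesicle count).
#'
#' @inheritParams featurize_evs
#' @inheritParams som_train
#' @param k Number of meta-clusters (must not exceed the number of occupied
#'   nodes).
#'
#' @return An object of class `ev_som` with elements `codebook`,
#'   `metacluster_of_node`, `assignment` (tibble: `sample_id`, `group`,
#'   `ev_id`, `node`, `metacluster`), `presence`, `k`, `grid_w`, `grid_h`,
#'   `features`, `seed`.
#' @export
ev_cluster <- function(counts, groups, panel = NULL,
                       grid_w = 10L, grid_h = 10L, k = 28L,
                       epochs = 10L, features = "binary", seed = 1L) {
  feats <- featurize_evs(counts, groups, panel, features)
  fit <- som_train(feats$x, grid_w, grid_h, epochs, seed)
  bmu <- bmu_assign(feats$x, fit$codebook)

  n_occupied <- length(unique(bmu))
  if (k > n_occupied) {
    stop("k (", k, ") exceeds occupied node count (", n_occupied, ")",
         call. = FALSE)
  }
  mc_raw <- metacluster_nodes(fit$codebook, k)

  # order meta-cluster ids by descending vesicle count
  sizes <- tabulate(mc_raw[bmu], nbins = k)
  relabel <- integer(k)
  relabel[order(sizes, decreasing = TRUE)] <- seq_len(k)
  metacluster_of_node <- relabel[mc_raw]

  assignment <- feats$meta
  assignment$node <- bmu
  assignment$metacluster <- metacluster_of_node[bmu]

  structure(
    list(codebook = fit$codebook, node_xy = fit$node_xy,
         metacluster_of_node = metacluster_of_node,
         assignment = assignment, presence = feats$presence,
         k = k, grid_w = grid_w, grid_h = grid_h,
         features = features, seed = seed),
    class = "ev_som"
  )
}

#' @exportS3Method generics::tidy
tidy.ev_som <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.ev_som <- function(x, ...) {
  tibble::tibble(
    n_ev = nrow(x$assignment),
    n_nodes = x$grid_w * x$grid_h,
    n_occupied = length(unique(x$assignment$node)),
    k = x$k,
    features = x$features,
    seed = x$seed
  )
}

#' @export
print.ev_som <- function(x, ...) {
  cat("Single-EV SOM metaclustering\n")
  cat(sprintf("  %d vesicles, %dx%d grid, k = %d (%s features, seed %d)\n",
              nrow(x$assignment), x$grid_w, x$grid_h, x$k, x$features, x$seed))
  invisible(x)
}

#' Meta-cluster size and group composition
#'
#' @param fit An `ev_som` object.
#' @return A tibble with one row per (metacluster, group): cluster size,
#'   overall size fraction, and the fraction of member vesicles from the
#'   group.
#' @export
cluster_profiles <- function(fit) {
  total <- nrow(fit$assignment)
  fit$assignment |>
    dplyr::count(.data$metacluster, .data$group, name = "n_group") |>
    dplyr::group_by(.data$metacluster) |>
    dplyr::mutate(n_ev = sum(.data$n_group),
                  size_frac = .data$n_ev / total,
                  group_frac = .data$n_group / .data$n_ev) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$metacluster, .data$group)
}

#' Per-cluster protein detection frequencies
#'
#' Fraction of a meta-cluster's vesicles on which each protein is detected
#' (at least one molecule).
#'
#' @param fit An `ev_som` object.
#' @return A tibble: `metacluster`, `protein`, `freq`, sorted by descending
#'   frequency within cluster.
#' @export
detection_frequencies <- function(fit) {
  mc <- fit$assignment$metacluster
  ind <- Matrix::sparseMatrix(i = seq_along(mc), j = mc, x = 1,
                              dims = c(length(mc), fit$k))
  hits <- as.matrix(Matrix::crossprod(ind, fit$presence))  # k x proteins
  sizes <- tabulate(mc, nbins = fit$k)
  freq <- hits / sizes
  tibble::tibble(
    metacluster = rep(seq_len(fit$k), times = ncol(freq)),
    protein = rep(colnames(fit$presence), each = fit$k),
    freq = as.numeric(freq)
  ) |>
    dplyr::arrange(.data$metacluster, dplyr::desc(.data$freq), .data$protein)
}

#' Top detection-frequency markers per meta-cluster
#'
#' @param fit An `ev_som` object.
#' @param n Markers per cluster.
#' @return Tibble of the `n` highest detection-frequency proteins per
#'   meta-cluster (ties broken alphabetically).
#' @export
top_markers <- function(fit, n = 10L) {
  detection_frequencies(fit) |>
    dplyr::group_by(.data$metacluster) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}

#' Group-enrichment test per meta-cluster
#'
#' Tests each meta-cluster's case-group member count against the pooled
#' case proportion with a two-sided exact binomial test (so mirror-composed
#' clusters receive identical p-values), then adjusts across clusters by
#' Benjamini-Hochberg. The binomial model treats member vesicles as
#' independent draws from the pool.
#'
#' @param fit An `ev_som` object.
#' @param case Case group label.
#' @return A tibble: `metacluster`, `n_ev`, `n_case`, `case_frac`,
#'   `pool_frac`, `enriched_group`, `p_value`, `q_value`.
#' @export
cluster_enrichment <- function(fit, case) {
  a <- fit$assignment
  if (!case %in% a$group) stop("unknown case label: ", case, call. = FALSE)
  p0 <- mean(a$group == case)
  res <- a |>
    dplyr::group_by(.data$metacluster) |>
    dplyr::summarise(n_ev = dplyr::n(), n_case = sum(.data$group == case),
                     .groups = "drop") |>
    dplyr::mutate(
      case_frac = .data$n_case / .data$n_ev,
      pool_frac = p0,
      enriched_group = ifelse(.data$case_frac >= p0, case, "other"),
      p_value = purrr::map2_dbl(.data$n_case, .data$n_ev,
                                ~ binom.test(.x, .y, p = p0)$p.value)
    )
  res$q_value <- bh_adjust(res$p_value)
  res
}
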