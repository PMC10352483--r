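two_blob_counts <- function(n_per_blob = 80L, seed = 5L) {
  # blob A detects P1-P3, blob B detects P4-P6; disjoint marker sets
  set.seed(seed)
  mk <- function(evs, prots) {
    tibble::tibble(
      sample_id = rep(rep(c("case_1", "ctrl_1"), length.out = length(evs)),
                      each = length(prots)),
      ev_id = rep(evs, each = length(prots)),
      protein = rep(prots, times = length(evs)),
      count = 1L
    )
  }
  a <- mk(sprintf("A%03d", seq_len(n_per_blob)), paste0("P", 1:3))
  b <- mk(sprintf("B%03d", seq_len(n_per_blob)), paste0("P", 4:6))
  dplyr::bind_rows(a, b)
}

blob_groups <- tibble::tibble(sample_id = c("case_1", "ctrl_1"),
                              group = c("case", "ctrl"))

test_that("featurization produces one vector per vesicle in panel order", {
  counts <- tibble::tibble(sample_id = "s1", ev_id = "E1",
                           protein = "CDCP1", count = 3L)
  panel <- ev_panel(c("CDCP1", "EPCAM", "CD9"))
  fb <- featurize_evs(counts, NULL, panel, features = "binary")
  expect_equal(as.numeric(fb$x[1, ]), c(1, 0, 0))
  fc <- featurize_evs(counts, NULL, panel, features = "counts")
  expect_equal(as.numeric(fc$x[1, ]), c(3, 0, 0))

  fx <- tiny_sim(evs = 50L, seed = 41L)
  f <- featurize_evs(fx$sim$counts, fx$sim$samples, fx$panel)
  n_obs <- dplyr::n_distinct(paste(fx$sim$counts$sample_id, fx$sim$counts$ev_id))
  expect_equal(nrow(f$x), n_obs)          # pooling preserves vesicle count
  expect_equal(ncol(f$x), nrow(fx$panel))
  expect_equal(nrow(f$meta), n_obs)
})

test_that("identical feature vectors collapse the SOM to a fixed point", {
  x <- matrix(rep(c(1, 0, 1), each = 30), nrow = 30)
  expect_warning(fit <- som_train(x, 3, 3, epochs = 3, seed = 1), "identical")
  expect_true(all(apply(fit$codebook, 1, function(w) all(w == c(1, 0, 1)))))
})

test_that("SOM training is deterministic under a fixed seed", {
  counts <- two_blob_counts()
  f <- featurize_evs(counts, blob_groups)
  a <- som_train(f$x, 4, 4, epochs = 5, seed = 3)
  b <- som_train(f$x, 4, 4, epochs = 5, seed = 3)
  expect_identical(a$codebook, b$codebook)
  c2 <- ev_cluster(counts, blob_groups, k = 2, grid_w = 4, grid_h = 4, seed = 3)
  d2 <- ev_cluster(counts, blob_groups, k = 2, grid_w = 4, grid_h = 4, seed = 3)
  expect_identical(tidy(c2), tidy(d2))
})

test_that("well-separated blobs are split with zero confusion", {
  counts <- two_blob_counts()
  fit <- ev_cluster(counts, blob_groups, grid_w = 4, grid_h = 4, k = 2, seed = 2)
  assign <- tidy(fit)
  blob <- substr(assign$ev_id, 1, 1)
  expect_equal(dplyr::n_distinct(paste(blob, assign$metacluster)), 2)
})

test_that("metaclustering at k = node count is the identity partition", {
  set.seed(9)
  cb <- matrix(rnorm(12 * 4), nrow = 12)
  mc <- metacluster_nodes(cb, 12)
  expect_equal(length(unique(mc)), 12)
  expect_error(metacluster_nodes(cb, 13), "exceeds")
})

test_that("dendrogram cut matches brute-force average-linkage agglomeration", {
  set.seed(11)
  for (k in c(2, 4)) {
    cb <- matrix(rnorm(10 * 3), nrow = 10)
    expect_true(same_partition(metacluster_nodes(cb, k),
                               brute_average_linkage(cb, k)))
  }
})

test_that("every vesicle's metacluster equals its best node's metacluster", {
  fx <- tiny_sim(evs = 150L, seed = 43L)
  fit <- ev_cluster(fx$sim$counts, fx$sim$samples, fx$panel,
                    grid_w = 5, grid_h = 5, k = 6, seed = 4)
  a <- tidy(fit)
  expect_equal(a$metacluster, fit$metacluster_of_node[a$node])
  # ids ordered by descending size
  sizes <- table(factor(a$metacluster, levels = seq_len(fit$k)))
  expect_true(all(diff(as.numeric(sizes)) <= 0))
})

test_that("cluster profiles match a longhand recomputation", {
  fx <- tiny_sim(evs = 120L, seed = 47L)
  fit <- ev_cluster(fx$sim$counts, fx$sim$samples, fx$panel,
                    grid_w = 5, grid_h = 5, k = 5, seed = 4)
  prof <- cluster_profiles(fit)
  freq <- detection_frequencies(fit)
  a <- tidy(fit)

  for (mc in unique(a$metacluster)) {
    members <- a[a$metacluster == mc, ]
    for (g in unique(members$group)) {
      row <- prof[prof$metacluster == mc & prof$group == g, ]
      expect_equal(row$group_frac, mean(members$group == g))
      expect_equal(row$n_ev, nrow(members))
    }
    # detection frequency of one marker recomputed from the raw counts
    member_key <- paste(members$sample_id, members$ev_id)
    cdcp1 <- fx$sim$counts |>
      dplyr::filter(protein == "CDCP1",
                    paste(sample_id, ev_id) %in% member_key)
    expect_equal(freq$freq[freq$metacluster == mc & freq$protein == "CDCP1"],
                 nrow(cdcp1) / nrow(members))
  }
  # group fractions sum to one per cluster
  sums <- prof |>
    dplyr::group_by(metacluster) |>
    dplyr::summarise(s = sum(group_frac))
  expect_equal(sums$s, rep(1, nrow(sums)))
})

test_that("group enrichment follows the binomial tail and is symmetric", {
  fit <- structure(list(
    assignment = tibble::tibble(
      group = rep(c("case", "ctrl"), each = 500),
      metacluster = c(rep(1, 475), rep(2, 25), rep(2, 475), rep(1, 25))
    ),
    k = 2
  ), class = "ev_som")
  enr <- cluster_enrichment(fit, case = "case")
  # 95%-case cluster of 500 vesicles in a 50/50 pool
  expect_lt(enr$p_value[1], 1e-3)
  expect_equal(enr$p_value[1],
               binom.test(475, 500, 0.5)$p.value)
  # mirror-composed clusters get identical p-values
  expect_equal(enr$p_value[1], enr$p_value[2])
  expect_equal(enr$enriched_group, c("case", "other"))
})

test_that("a uniformly drawn cluster is not called enriched", {
  set.seed(13)
  fit <- structure(list(
    assignment = tibble::tibble(
      group = sample(rep(c("case", "ctrl"), each = 400)),
      metacluster = rep(1:4, each = 200)
    ),
    k = 4
  ), class = "ev_som")
  enr <- cluster_enrichment(fit, case = "case")
  expect_true(all(enr$q_value > 0.05))
})
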