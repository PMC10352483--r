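# Small panels / cohorts used across tests, plus brute-force reference
# implementations kept independent of the package's code paths.

tiny_panel <- function(n = 6L) default_panel(n)

tiny_sim <- function(n_per_group = c(OVCA = 3L, Control = 3L), evs = 120L,
                     seed = 7L, panel = default_panel(12), weight = 0.3) {
  cfg <- sim_config(n_samples_per_group = n_per_group, evs_per_sample = evs,
                    seed = seed)
  sub <- default_subclusters(panel, disease_weight = weight,
                             markers = intersect(c("CDCP1", "TACSTD2", "EPCAM",
                                                   "ITGA6", "ERBB2"),
                                                 panel$protein))
  list(sim = simulate_population(cfg, panel, sub), cfg = cfg, panel = panel)
}

# write a FASTQ from explicit sequences / quality strings
write_fastq <- function(seqs, quals, path = tempfile(fileext = ".fastq")) {
  lines <- character(4L * length(seqs))
  lines[seq(1, by = 4, length.out = length(seqs))] <- paste0("@r", seq_along(seqs))
  lines[seq(2, by = 4, length.out = length(seqs))] <- seqs
  lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
  lines[seq(4, by = 4, length.out = length(seqs))] <- quals
  writeLines(lines, path)
  path
}

# brute-force pair table: double loop over vesicles and protein pairs
brute_pair_counts <- function(counts) {
  out <- list()
  for (sid in unique(counts$sample_id)) {
    cs <- counts[counts$sample_id == sid, ]
    for (ev in unique(cs$ev_id)) {
      prot <- sort(unique(cs$protein[cs$ev_id == ev & cs$count >= 1]))
      if (length(prot) < 2) next
      for (i in seq_len(length(prot) - 1)) {
        for (j in seq(i + 1, length(prot))) {
          k <- paste(sid, prot[i], prot[j], sep = "\1")
          out[[k]] <- (out[[k]] %||% 0L) + 1L
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sample_id = character(), protein_a = character(),
                          protein_b = character(), count = integer()))
  }
  parts <- strsplit(names(out), "\1", fixed = TRUE)
  tibble::tibble(
    sample_id = vapply(parts, `[`, "", 1),
    protein_a = vapply(parts, `[`, "", 2),
    protein_b = vapply(parts, `[`, "", 3),
    count = as.integer(unlist(out))
  ) |>
    dplyr::arrange(sample_id, protein_a, protein_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force concordance AUC by explicit pair enumeration
brute_auc <- function(case, control) {
  s <- 0
  for (x in case) for (y in control) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(case) * length(control))
}

# step-up BH from the definition, checked index by index
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q
}

# product-limit estimator computed longhand over pooled event times
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

# log-rank chi-square from hypergeometric moments at each event time
brute_logrank <- function(time, event, stratum) {
  g <- unique(stratum)
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & stratum == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & stratum == g[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# naive average-linkage agglomeration over explicit cluster sets
brute_average_linkage <- function(x, k) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- function(a, b) {
    s <- 0
    for (i in a) for (j in b) s <- s + sqrt(sum((x[i, ] - x[j, ])^2))
    s / (length(a) * length(b))
  }
  while (length(clusters) > k) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dd <- d(clusters[[i]], clusters[[j]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(nrow(x))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
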