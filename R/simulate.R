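#' Simulation configuration
#'
#' Collects the knobs of the synthetic single-EV cohort generator: cohort
#' layout, sequencing-read layout and error model. Defaults reflect an
#' ascites cohort of 8 case and 18 control samples with on the order of
#' 20,000 vesicles per sample and a handful of detected proteins per
#' vesicle.
#'
#' @param n_samples_per_group Named integer vector, samples per group. The
#'   first group is treated as the case group by downstream helpers.
#' @param evs_per_sample Vesicles generated per sample.
#' @param mean_molecules Mean of the zero-truncated Poisson molecule count
#'   per detected protein on a vesicle (UMI deduplication collapses the
#'   extra reads these molecules generate).
#' @param umi_length,ev_tag_length Molecular-tag and EV-tag lengths (nt).
#' @param reads_per_molecule Mean reads emitted per molecule; every molecule
#'   yields at least one read (`1 + rpois(reads_per_molecule - 1)`).
#' @param base_error_rate Per-base substitution probability in emitted reads.
#' @param q_fail_rate Fraction of reads emitted with all bases below Q20
#'   (the decoder's quality filter removes exactly these).
#' @param seed Integer seed; fixes the whole generator output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_group = c(OVCA = 8L, Control = 18L),
                       evs_per_sample = 20000L,
                       mean_molecules = 2,
                       umi_length = 8L,
                       ev_tag_length = 15L,
                       reads_per_molecule = 1,
                       base_error_rate = 0,
                       q_fail_rate = 0,
                       seed = 1L) {
  stopifnot(
    length(n_samples_per_group) >= 1, all(n_samples_per_group >= 1),
    !is.null(names(n_samples_per_group)),
    evs_per_sample >= 1, mean_molecules > 0,
    umi_length >= 1, ev_tag_length >= 1,
    reads_per_molecule >= 1,
    base_error_rate >= 0, base_error_rate < 1,
    q_fail_rate >= 0, q_fail_rate <= 1
  )
  structure(
    list(
      n_samples_per_group = n_samples_per_group,
      evs_per_sample = as.integer(evs_per_sample),
      mean_molecules = mean_molecules,
      umi_length = as.integer(umi_length),
      ev_tag_length = as.integer(ev_tag_length),
      reads_per_molecule = reads_per_molecule,
      base_error_rate = base_error_rate,
      q_fail_rate = q_fail_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Define a vesicle subcluster
#'
#' A subcluster is a latent vesicle population: each protein is detected on
#' a member vesicle independently with its `marker_probs` probability, and
#' `group_weights` gives the subcluster's mixture proportion among each
#' sample group's vesicles.
#'
#' @param name Subcluster label.
#' @param marker_probs Named numeric vector, protein -> detection
#'   probability in `[0, 1]`. Proteins absent from the vector have
#'   probability 0.
#' @param group_weights Named numeric vector, group -> mixture proportion.
#'
#' @return A list of class `subcluster_spec`.
#' @export
subcluster_spec <- function(name, marker_probs, group_weights) {
  stopifnot(
    is.character(name), length(name) == 1,
    !is.null(names(marker_probs)), all(marker_probs >= 0), all(marker_probs <= 1),
    !is.null(names(group_weights)), all(group_weights >= 0), all(group_weights <= 1)
  )
  structure(
    list(name = name, marker_probs = marker_probs, group_weights = group_weights),
    class = "subcluster_spec"
  )
}

#' Default two-subcluster cohort structure
#'
#' Builds the mixture the generator emulates: a background vesicle
#' population shared by both groups (tetraspanin-rich, low-rate detection of
#' everything else, tuned so a vesicle carries ~3 proteins on average) plus
#' one disease-specific subcluster present only in the case group and
#' co-expressing a set of epithelial/ovarian-cancer markers at high
#' detection probability.
#'
#' @param panel Panel tibble from [ev_panel()].
#' @param groups Group labels; the first is the case group.
#' @param disease_weight Mixture proportion of the disease subcluster among
#'   case-group vesicles.
#' @param markers Marker proteins of the disease subcluster (must be in the
#'   panel).
#' @param marker_prob Detection probability of each marker on a
#'   disease-subcluster vesicle.
#' @param background_mean Target mean proteins per vesicle in the background
#'   population.
#'
#' @return A list of two `subcluster_spec` objects (`background`, `disease`).
#' @export
default_subclusters <- function(panel,
                                groups = c("OVCA", "Control"),
                                disease_weight = 0.2,
                                markers = c("CDCP1", "TACSTD2", "EPCAM", "ERBB2",
                                            "ITGA3", "ITGA6", "ITGB1", "ITGB4",
                                            "EGFR", "LAMP1", "CD151", "CD9"),
                                marker_prob = 0.8,
                                background_mean = 3) {
  stopifnot(disease_weight >= 0, disease_weight <= 1, length(groups) == 2)
  proteins <- panel$protein
  markers <- intersect(markers, proteins)
  if (length(markers) == 0) stop("no disease markers present in panel", call. = FALSE)

  tetraspanins <- intersect(c("CD9", "CD63", "CD81"), proteins)
  common <- intersect(c("LAMP1", "ITGB1", "CD151", "CD44", "FLOT1", "B2M"), proteins)
  bg <- setNames(rep(0, length(proteins)), proteins)
  bg[tetraspanins] <- 0.35
  bg[common] <- 0.15
  rest <- setdiff(proteins, c(tetraspanins, common))
  residual <- background_mean - sum(bg)
  if (length(rest) > 0 && residual > 0) {
    bg[rest] <- min(residual / length(rest), 0.1)
  }

  disease <- setNames(rep(0.01, length(proteins)), proteins)
  disease[markers] <- marker_prob

  list(
    background = subcluster_spec(
      "background", bg,
      setNames(c(1 - disease_weight, 1), groups)
    ),
    disease = subcluster_spec(
      "disease", disease,
      setNames(c(disease_weight, 0), groups)
    )
  )
}

# protein detection probability matrix (subcluster x panel protein)
subcluster_prob_matrix <- function(subclusters, panel) {
  unknown <- setdiff(
    unique(unlist(lapply(subclusters, function(s) names(s$marker_probs)))),
    panel$protein
  )
  if (length(unknown) > 0) {
    stop("marker proteins not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- matrix(0, nrow = length(subclusters), ncol = nrow(panel),
              dimnames = list(vapply(subclusters, `[[`, "", "name"), panel$protein))
  for (i in seq_along(subclusters)) {
    mp <- subclusters[[i]]$marker_probs
    p[i, names(mp)] <- mp
  }
  p
}

# zero-truncated Poisson draws via inverse CDF conditioned on x >= 1
rztpois <- function(n, lambda) {
  as.integer(qpois(runif(n, dpois(0, lambda), 1), lambda))
}

# vectorised random nucleotide strings
random_nt <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, ncol = len)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

int_to_nt <- function(i, len) {
  out <- matrix("A", nrow = length(i), ncol = len)
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(len)) {
    out[, p] <- bases[(i %% 4) + 1L]
    i <- i %/% 4
  }
  do.call(paste0, lapply(seq_len(len), function(j) out[, j]))
}

#' Simulate a single-EV cohort
#'
#' Draws each sample's vesicles from its group's subcluster mixture, detects
#' proteins independently per vesicle with the subcluster's probabilities,
#' and assigns each detected protein a zero-truncated Poisson molecule
#' count. Vesicles on which no protein was detected are kept in the ground
#' truth (flagged by `n_proteins = 0`) but are unobservable and carry no
#' counts.
#'
#' @param config A [sim_config()].
#' @param panel A panel tibble.
#' @param subclusters List of [subcluster_spec()] objects; per group, the
#'   mixture weights must sum to 1.
#'
#' @return A list of class `ev_simulation` with elements `counts`
#'   (tibble: `sample_id`, `ev_id`, `protein`, `count`), `ev_truth`
#'   (tibble: `sample_id`, `group`, `ev_id`, `subcluster`, `n_proteins`),
#'   `samples` (tibble: `sample_id`, `group`), `panel` and `config`.
#' @export
simulate_population <- function(config, panel, subclusters) {
  stopifnot(inherits(config, "sim_config"))
  prob <- subcluster_prob_matrix(subclusters, panel)
  sub_names <- rownames(prob)
  groups <- names(config$n_samples_per_group)

  weights <- vapply(groups, function(g) {
    vapply(subclusters, function(s) {
      w <- s$group_weights[g]
      if (is.na(w)) 0 else unname(w)
    }, numeric(1))
  }, numeric(length(subclusters)))
  weights <- matrix(weights, ncol = length(groups),
                    dimnames = list(sub_names, groups))
  bad <- abs(colSums(weights) - 1) > 1e-8
  if (any(bad)) {
    stop("subcluster mixture weights must sum to 1 per group (violated for: ",
         paste(groups[bad], collapse = ", "), ")", call. = FALSE)
  }

  samples <- tibble::tibble(
    group = rep(groups, config$n_samples_per_group),
    sample_id = sprintf("%s_%02d", group,
                        unlist(lapply(config$n_samples_per_group, seq_len)))
  )[, c("sample_id", "group")]

  set.seed(config$seed)
  n_prot <- nrow(panel)
  truth_list <- vector("list", nrow(samples))
  count_list <- vector("list", nrow(samples))

  for (s in seq_len(nrow(samples))) {
    n_ev <- config$evs_per_sample
    g <- samples$group[s]
    sub_idx <- sample.int(length(sub_names), n_ev, replace = TRUE,
                          prob = weights[, g])
    ev_tag <- random_nt(n_ev, config$ev_tag_length)
    while (anyDuplicated(ev_tag) > 0) {
      dup <- duplicated(ev_tag)
      ev_tag[dup] <- random_nt(sum(dup), config$ev_tag_length)
    }

    present <- matrix(runif(n_ev * n_prot), nrow = n_ev) < prob[sub_idx, , drop = FALSE]
    hit <- which(present, arr.ind = TRUE)
    n_per_ev <- tabulate(hit[, 1L], nbins = n_ev)

    truth_list[[s]] <- tibble::tibble(
      sample_id = samples$sample_id[s],
      group = g,
      ev_id = ev_tag,
      subcluster = sub_names[sub_idx],
      n_proteins = n_per_ev
    )
    count_list[[s]] <- tibble::tibble(
      sample_id = samples$sample_id[s],
      ev_id = ev_tag[hit[, 1L]],
      protein = panel$protein[hit[, 2L]],
      count = rztpois(nrow(hit), config$mean_molecules)
    )
  }

  structure(
    list(
      counts = dplyr::arrange(dplyr::bind_rows(count_list),
                              .data$sample_id, .data$ev_id, .data$protein),
      ev_truth = dplyr::bind_rows(truth_list),
      samples = samples,
      panel = panel,
      config = config
    ),
    class = "ev_simulation"
  )
}

#' Emit FASTQ reads for a simulated cohort
#'
#' Writes one FASTQ file per sample. Each molecule in the simulation yields
#' at least one read; a read is the concatenation EV tag | protein tag |
#' molecular tag. Substitution errors are injected per base at
#' `base_error_rate`, and a `q_fail_rate` fraction of reads is emitted with
#' all bases at Q15 (below the Q20 filter) while the rest carry Q30.
#' Molecular tags are drawn without replacement within each (vesicle,
#' protein) pair, so at zero error rate decoding reproduces the simulated
#' counts exactly.
#'
#' @param sim An `ev_simulation` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @param config Simulation configuration; defaults to the one stored in
#'   `sim`.
#'
#' @return A tibble with columns `sample_id`, `group`, `path`, `n_reads`.
#' @export
emit_reads <- function(sim, dir, config = sim$config) {
  stopifnot(inherits(sim, "ev_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)

  panel_tag <- setNames(sim$panel$tag, sim$panel$protein)
  umi_space <- 4^config$umi_length
  out <- vector("list", nrow(sim$samples))

  for (s in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[s]
    cs <- sim$counts[sim$counts$sample_id == sid, ]

    # one row per molecule; distinct UMIs within each (ev, protein) pair
    mol_ev <- rep.int(cs$ev_id, cs$count)
    mol_prot <- rep.int(cs$protein, cs$count)
    mol_grp <- rep.int(seq_len(nrow(cs)), cs$count)  # (ev, protein) pair id
    umi_int <- floor(runif(length(mol_ev)) * umi_space)
    key <- mol_grp * umi_space + umi_int
    while (anyDuplicated(key) > 0) {
      dup <- duplicated(key)
      umi_int[dup] <- floor(runif(sum(dup)) * umi_space)
      key <- mol_grp * umi_space + umi_int
    }
    umi <- int_to_nt(umi_int, config$umi_length)

    n_reads_per_mol <- if (config$reads_per_molecule > 1) {
      1L + rpois(length(mol_ev), config$reads_per_molecule - 1)
    } else {
      rep(1L, length(mol_ev))
    }
    idx <- rep.int(seq_along(mol_ev), n_reads_per_mol)
    seqs <- paste0(mol_ev[idx], panel_tag[mol_prot[idx]], umi[idx])
    n <- length(seqs)
    read_len <- nchar(seqs[1])

    if (config$base_error_rate > 0 && n > 0) {
      n_err <- rbinom(n, read_len, config$base_error_rate)
      for (r in which(n_err > 0)) {
        pos <- sample.int(read_len, n_err[r])
        chars <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
        seqs[r] <- paste(chars, collapse = "")
      }
    }

    fail <- runif(n) < config$q_fail_rate
    qual <- ifelse(fail, strrep("0", read_len), strrep("?", read_len))  # Q15 / Q30

    lines <- character(4L * n)
    lines[seq(1, by = 4, length.out = n)] <- sprintf("@%s_read%d", sid, seq_len(n))
    lines[seq(2, by = 4, length.out = n)] <- seqs
    lines[seq(3, by = 4, length.out = n)] <- "+"
    lines[seq(4, by = 4, length.out = n)] <- qual
    path <- file.path(dir, paste0(sid, ".fastq"))
    writeLines(lines, path)

    out[[s]] <- tibble::tibble(
      sample_id = sid, group = sim$samples$group[s], path = path, n_reads = n
    )
  }
  dplyr::bind_rows(out)
}

#' Write the ground-truth tables of a simulation
#'
#' @param sim An `ev_simulation`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    truth = file.path(dir, "ev_truth.tsv"),
    counts = file.path(dir, "counts.tsv"),
    panel = file.path(dir, "panel.tsv")
  )
  readr::write_tsv(sim$ev_truth, paths[["truth"]])
  readr::write_tsv(sim$counts, paths[["counts"]])
  readr::write_tsv(sim$panel, paths[["panel"]])
  invisible(paths)
}
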