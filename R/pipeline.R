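PIPELINE_STAGES <- c("simulate", "decode", "diffexp", "combos", "cluster", "roc")

#' Run the single-EV analysis workflow
#'
#' Executes a configured prefix of the pipeline
#' simulate -> decode -> diffexp -> combos -> cluster -> roc, each stage
#' reading the previous stage's outputs, and writes every result as TSV
#' plus a JSON manifest recording files, row counts, the seed and a
#' parameter hash.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised top-level fields: `stages` (character vector, a
#'   prefix of the pipeline order), `seed`, `out_dir`, and one optional
#'   parameter block per stage (`simulate`, `decode`, `diffexp`, `combos`,
#'   `cluster`, `roc`). See the vignette for a worked configuration.
#' @param out_dir Output directory (overrides the config field).
#'
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages %||% PIPELINE_STAGES
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)])) {
    stop("stages must be a prefix of: ",
         paste(PIPELINE_STAGES, collapse = " -> "), call. = FALSE)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  manifest <- list(seed = seed, stages = list())
  add_stage <- function(name, files, params, notes = list()) {
    manifest$stages[[name]] <<- list(
      files = lapply(files, function(f) {
        list(path = f, n_rows = tsv_rows(f))
      }),
      params_hash = rlang::hash(params),
      notes = notes
    )
  }

  sim_params <- config$simulate %||% list()
  if (is.list(sim_params$n_samples_per_group)) {
    # YAML maps arrive as named lists; sim_config expects a named vector
    sim_params$n_samples_per_group <- unlist(sim_params$n_samples_per_group)
  }
  sim_cfg <- do.call(sim_config, c(sim_params, list(seed = seed)))
  panel <- if (!is.null(config$panel)) read_panel(config$panel) else default_panel()
  groups <- NULL; counts <- NULL; expr <- NULL; pairs_cpm <- NULL

  if ("simulate" %in% stages) {
    logf("simulate: ", sum(sim_cfg$n_samples_per_group), " samples, ",
         sim_cfg$evs_per_sample, " EVs/sample, seed ", seed)
    subcl <- default_subclusters(panel, groups = names(sim_cfg$n_samples_per_group))
    sim <- simulate_population(sim_cfg, panel, subcl)
    fq_dir <- file.path(out_dir, "fastq")
    fq <- emit_reads(sim, fq_dir)
    truth_paths <- write_truth(sim, file.path(out_dir, "truth"))
    sheet <- file.path(out_dir, "samples.tsv")
    readr::write_tsv(sim$samples, sheet)
    groups <- sim$samples
    add_stage("simulate", c(unname(truth_paths), sheet, fq$path),
              c(unclass(sim_cfg)))
  }

  if ("decode" %in% stages) {
    if (!exists("fq", inherits = FALSE)) {
      stop("decode requires the simulate stage's FASTQ output", call. = FALSE)
    }
    layout <- do.call(read_layout, c(
      list(ev_tag = sim_cfg$ev_tag_length, umi = sim_cfg$umi_length,
           protein_tag = nchar(panel$tag[1])),
      config$decode %||% list()
    ))
    logf("decode: ", nrow(fq), " FASTQ file(s)")
    dec <- decode_samples(fq, panel, layout)
    counts <- dec$counts
    counts_path <- file.path(out_dir, "ev_counts.tsv")
    stats_path <- file.path(out_dir, "decode_stats.tsv")
    readr::write_tsv(counts, counts_path)
    readr::write_tsv(dec$stats, stats_path)
    add_stage("decode", c(counts_path, stats_path), c(unclass(layout)),
              notes = list(
                n_quality_filtered = sum(dec$stats$n_quality_filtered),
                n_unmatched = sum(dec$stats$n_unmatched)
              ))
  }

  case <- names(sim_cfg$n_samples_per_group)[1]

  if ("diffexp" %in% stages) {
    if (is.null(counts)) stop("diffexp requires decoded counts", call. = FALSE)
    logf("diffexp: TMM + adaptive two-group tests")
    expr <- tmm_normalize(aggregate_expression(counts, panel))
    de <- differential_expression(expr, groups, case = case)
    expr_path <- file.path(out_dir, "expression.tsv")
    de_path <- file.path(out_dir, "differential_expression.tsv")
    readr::write_tsv(expr, expr_path)
    readr::write_tsv(de, de_path)
    add_stage("diffexp", c(expr_path, de_path),
              config$diffexp %||% list(),
              notes = list(n_significant = sum(de$q_value < 0.05, na.rm = TRUE)))
  }

  if ("combos" %in% stages) {
    logf("combos: vesicle pair co-expression")
    pairs_cpm <- cpm_normalize_pairs(count_combinations(counts))
    de_pairs <- differential_combinations(pairs_cpm, groups, case = case)
    pairs_path <- file.path(out_dir, "combinations.tsv")
    depairs_path <- file.path(out_dir, "differential_combinations.tsv")
    readr::write_tsv(pairs_cpm, pairs_path)
    readr::write_tsv(de_pairs, depairs_path)
    add_stage("combos", c(pairs_path, depairs_path),
              config$combos %||% list(),
              notes = list(n_excluded = attr(de_pairs, "n_excluded")))
  }

  if ("cluster" %in% stages) {
    pc <- config$cluster %||% list()
    logf("cluster: SOM metaclustering")
    fit <- ev_cluster(counts, groups, panel,
                      grid_w = pc$grid_w %||% 10L, grid_h = pc$grid_h %||% 10L,
                      k = pc$k %||% 28L, seed = seed)
    assign_path <- file.path(out_dir, "cluster_assignment.tsv")
    prof_path <- file.path(out_dir, "cluster_profiles.tsv")
    enr_path <- file.path(out_dir, "cluster_enrichment.tsv")
    readr::write_tsv(tidy(fit), assign_path)
    readr::write_tsv(cluster_profiles(fit), prof_path)
    readr::write_tsv(cluster_enrichment(fit, case = case), enr_path)
    add_stage("cluster", c(assign_path, prof_path, enr_path), pc)
  }

  if ("roc" %in% stages) {
    rc <- config$roc %||% list()
    marker <- rc$marker %||% "CDCP1"
    pair <- rc$pair %||% c("CDCP1", "ITGA6")
    logf("roc: ", marker, " and ", paste(pair, collapse = "+"))
    r1 <- roc_single(expr, groups, marker, case = case)
    r2 <- roc_pair(pairs_cpm, groups, pair[1], pair[2], case = case)
    roc_path <- file.path(out_dir, "roc_auc.tsv")
    readr::write_tsv(dplyr::bind_rows(glance(r1), glance(r2)), roc_path)
    add_stage("roc", roc_path, rc)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  logf("done; manifest at ", manifest_path)
  invisible(manifest)
}

tsv_rows <- function(path) {
  if (!grepl("\\.tsv$", path)) return(NA_integer_)
  length(readr::read_lines(path, progress = FALSE)) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
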