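#' Read layout for barcoded single-EV reads
#'
#' Reads are fixed-offset concatenations of an EV tag, a protein tag and a
#' molecular tag (UMI). The layout records the three segment lengths and
#' the quality-filter settings.
#'
#' @param ev_tag,protein_tag,umi Segment lengths in nucleotides.
#' @param quality_threshold Phred threshold; reads scoring below it are
#'   eliminated by [quality_filter()].
#' @param quality_metric How a read's quality score is summarised:
#'   `"min"` (default, strictest: minimum per-base Phred) or `"mean"`.
#'
#' @return A list of class `read_layout`.
#' @export
read_layout <- function(ev_tag = 15L, protein_tag = 8L, umi = 8L,
                        quality_threshold = 20,
                        quality_metric = c("min", "mean")) {
  quality_metric <- match.arg(quality_metric)
  stopifnot(ev_tag >= 1, protein_tag >= 1, umi >= 1, quality_threshold >= 0)
  structure(
    list(ev_tag = as.integer(ev_tag), protein_tag = as.integer(protein_tag),
         umi = as.integer(umi), quality_threshold = quality_threshold,
         quality_metric = quality_metric),
    class = "read_layout"
  )
}

# Per-read quality summary (Phred+33), chunked so the integer expansion of
# millions of quality strings stays bounded. Fixed-width batches take a
# vectorised path (pmin/colMeans over the position-major code matrix).
read_quality <- function(qual, metric = "min", chunk = 200000L) {
  n <- length(qual)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    s <- qual[i:j]
    w <- nchar(s)
    if (length(unique(w)) == 1L) {
      codes <- matrix(utf8ToInt(paste(s, collapse = "")) - 33L,
                      nrow = w[1], ncol = length(s))
      out[i:j] <- if (metric == "min") {
        do.call(pmin, asplit(codes, 1))
      } else {
        colMeans(codes)
      }
    } else {
      fun <- if (metric == "min") min else mean
      codes <- utf8ToInt(paste(s, collapse = "\n"))
      grp <- rep.int(seq_along(s), w + 1L)
      grp <- grp[seq_along(codes)]
      keep <- codes != 10L
      out[i:j] <- vapply(split(codes[keep] - 33L, grp[keep]), fun, numeric(1))
    }
    i <- j + 1L
  }
  out
}

#' Parse barcoded reads from a FASTQ file
#'
#' Splits each read at the fixed layout offsets into EV tag, protein tag and
#' molecular tag, and computes the read's quality score. Reads shorter than
#' the layout are skipped and counted; a structurally malformed FASTQ is a
#' hard error.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param layout A [read_layout()].
#'
#' @return A tibble with columns `ev_tag`, `protein_tag`, `umi`,
#'   `min_quality`, with attribute `n_skipped` (truncated reads). A warning
#'   is raised for an empty file.
#' @export
parse_reads <- function(fastq, layout = read_layout()) {
  stopifnot(inherits(layout, "read_layout"))
  con <- gzfile(fastq, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) {
    warning("no reads in ", fastq, call. = FALSE)
    out <- tibble::tibble(ev_tag = character(), protein_tag = character(),
                          umi = character(), min_quality = numeric())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ (line count not a multiple of 4): ", fastq,
         call. = FALSE)
  }
  headers <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(headers, 1, 1) != "@") || any(substr(plus, 1, 1) != "+") ||
      any(nchar(seqs) != nchar(quals))) {
    stop("malformed FASTQ records in ", fastq, call. = FALSE)
  }

  need <- layout$ev_tag + layout$protein_tag + layout$umi
  ok <- nchar(seqs) >= need
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " truncated read(s) skipped in ", basename(fastq))
    seqs <- seqs[ok]
    quals <- quals[ok]
  }

  out <- tibble::tibble(
    ev_tag = substr(seqs, 1L, layout$ev_tag),
    protein_tag = substr(seqs, layout$ev_tag + 1L,
                         layout$ev_tag + layout$protein_tag),
    umi = substr(seqs, layout$ev_tag + layout$protein_tag + 1L, need),
    min_quality = if (length(seqs)) {
      read_quality(substr(quals, 1L, need), layout$quality_metric)
    } else numeric()
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Quality-filter read records
#'
#' Retains exactly the reads whose quality score is at or above the
#' threshold; reads scoring below 20 (the default) are eliminated.
#'
#' @param records Tibble from [parse_reads()].
#' @param threshold Phred threshold.
#' @return The filtered tibble, with attribute `n_filtered`.
#' @export
quality_filter <- function(records, threshold = 20) {
  keep <- records$min_quality >= threshold
  out <- records[keep, ]
  attr(out, "n_filtered") <- sum(!keep)
  out
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
}

#' Assign protein identities to reads
#'
#' Matches each read's protein tag against the panel, exactly by default or
#' within a Hamming-distance tolerance when `max_mismatch > 0` and the
#' nearest panel tag is unique. Unmatched and ambiguous reads are dropped
#' and counted.
#'
#' @param records Tibble from [parse_reads()]/[quality_filter()].
#' @param panel Panel tibble from [ev_panel()].
#' @param max_mismatch Maximum Hamming distance for a rescue match.
#'
#' @return `records` with a `protein` column; attributes `n_unmatched` and
#'   `n_ambiguous` count dropped reads.
#' @export
assign_tags <- function(records, panel, max_mismatch = 0L) {
  lookup <- setNames(panel$protein, panel$tag)
  protein <- unname(lookup[records$protein_tag])
  n_ambiguous <- 0L

  if (max_mismatch > 0 && anyNA(protein)) {
    unk <- unique(records$protein_tag[is.na(protein)])
    rescue <- setNames(rep(NA_character_, length(unk)), unk)
    for (u in unk) {
      d <- hamming(rep(u, nrow(panel)), panel$tag)
      best <- which(d == min(d))
      if (min(d) <= max_mismatch) {
        if (length(best) == 1L) {
          rescue[u] <- panel$protein[best]
        } else {
          n_ambiguous <- n_ambiguous + sum(records$protein_tag == u)
        }
      }
    }
    miss <- is.na(protein)
    protein[miss] <- rescue[records$protein_tag[miss]]
  }

  keep <- !is.na(protein)
  out <- records[keep, ]
  out$protein <- protein[keep]
  attr(out, "n_unmatched") <- sum(!keep) - n_ambiguous
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Build a single-EV count matrix from assigned reads
#'
#' Counts, per (EV tag, protein) pair, the number of distinct molecular
#' tags among its reads (UMI deduplication; tags are identical only if
#' byte-identical). Vesicles with fewer detected proteins or molecules than
#' the floors are removed.
#'
#' @param records Tibble from [assign_tags()].
#' @param sample_id Sample label attached to the result.
#' @param min_proteins_per_ev,min_molecules_per_ev Per-vesicle floors.
#'
#' @return A tibble with columns `sample_id`, `ev_id`, `protein`, `count`
#'   (long/triplet form; absent combinations are zero).
#' @export
build_ev_matrix <- function(records, sample_id,
                            min_proteins_per_ev = 1L,
                            min_molecules_per_ev = 1L) {
  counts <- records |>
    dplyr::distinct(.data$ev_tag, .data$protein, .data$umi) |>
    dplyr::count(.data$ev_tag, .data$protein, name = "count")

  keep <- counts |>
    dplyr::group_by(.data$ev_tag) |>
    dplyr::summarise(n_prot = dplyr::n(), n_mol = sum(.data$count)) |>
    dplyr::filter(.data$n_prot >= min_proteins_per_ev,
                  .data$n_mol >= min_molecules_per_ev)

  counts |>
    dplyr::semi_join(keep, by = "ev_tag") |>
    dplyr::transmute(sample_id = sample_id, ev_id = .data$ev_tag,
                     .data$protein, .data$count) |>
    dplyr::arrange(.data$ev_id, .data$protein)
}

#' Decode one sample's FASTQ into a single-EV matrix
#'
#' Chains [parse_reads()], [quality_filter()], [assign_tags()] and
#' [build_ev_matrix()].
#'
#' @inheritParams parse_reads
#' @inheritParams assign_tags
#' @inheritParams build_ev_matrix
#' @return A list with `counts` (the matrix tibble) and `stats` (one-row
#'   tibble of read accounting: parsed, skipped, quality-filtered,
#'   unmatched, ambiguous, retained).
#' @export
decode_sample <- function(fastq, panel, layout = read_layout(),
                          sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq)),
                          max_mismatch = 0L,
                          min_proteins_per_ev = 1L, min_molecules_per_ev = 1L) {
  parsed <- parse_reads(fastq, layout)
  filtered <- quality_filter(parsed, layout$quality_threshold)
  assigned <- assign_tags(filtered, panel, max_mismatch)
  counts <- build_ev_matrix(assigned, sample_id,
                            min_proteins_per_ev, min_molecules_per_ev)
  list(
    counts = counts,
    stats = tibble::tibble(
      sample_id = sample_id,
      n_parsed = nrow(parsed),
      n_skipped = attr(parsed, "n_skipped"),
      n_quality_filtered = attr(filtered, "n_filtered"),
      n_unmatched = attr(assigned, "n_unmatched"),
      n_ambiguous = attr(assigned, "n_ambiguous"),
      n_retained = nrow(assigned)
    )
  )
}

#' Decode a set of sample FASTQs
#'
#' @param manifest Tibble with columns `sample_id` and `path` (e.g. the
#'   output of [emit_reads()]).
#' @inheritParams decode_sample
#' @return A list with `counts` (all samples, long form) and `stats`.
#' @export
decode_samples <- function(manifest, panel, layout = read_layout(), ...) {
  res <- purrr::map2(manifest$path, manifest$sample_id,
                     function(p, s) decode_sample(p, panel, layout, sample_id = s, ...))
  list(
    counts = purrr::list_rbind(purrr::map(res, "counts")),
    stats = purrr::list_rbind(purrr::map(res, "stats"))
  )
}

#' Summarise a single-EV matrix
#'
#' @param counts Long-form matrix tibble (`sample_id`, `ev_id`, `protein`,
#'   `count`).
#' @return One row per sample: number of vesicles, total molecules, and the
#'   mean/median proteins and molecules per vesicle.
#' @export
summarize_ev_matrix <- function(counts) {
  if (nrow(counts) == 0) {
    return(tibble::tibble(
      sample_id = character(), n_ev = integer(), total_molecules = numeric(),
      mean_proteins_per_ev = numeric(), median_proteins_per_ev = numeric(),
      mean_molecules_per_ev = numeric()
    ))
  }
  counts |>
    dplyr::group_by(.data$sample_id, .data$ev_id) |>
    dplyr::summarise(n_prot = dplyr::n(), n_mol = sum(.data$count),
                     .groups = "drop_last") |>
    dplyr::summarise(
      n_ev = dplyr::n(),
      total_molecules = sum(.data$n_mol),
      mean_proteins_per_ev = mean(.data$n_prot),
      median_proteins_per_ev = median(.data$n_prot),
      mean_molecules_per_ev = mean(.data$n_mol),
      .groups = "drop"
    )
}
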