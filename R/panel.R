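#' Construct an antibody panel
#'
#' A panel maps each surface protein in the assay to the unique DNA tag
#' sequence carried by its antibody's probe. All tags must share one length
#' and be pairwise distinct.
#'
#' @param proteins Character vector of protein names (unique, non-empty).
#' @param tags Optional character vector of tag sequences, one per protein,
#'   all the same length over the alphabet A/C/G/T. When `NULL`, tags of
#'   `tag_length` nucleotides are generated deterministically.
#' @param tag_length Tag length in nucleotides used when `tags` is `NULL`.
#'
#' @return A tibble with columns `protein` and `tag`.
#' @export
#' @examples
#' ev_panel(c("CDCP1", "EPCAM", "CD9"))
ev_panel <- function(proteins, tags = NULL, tag_length = 8L) {
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins) || any(!nzchar(proteins))) {
    stop("panel proteins must be unique, non-empty names", call. = FALSE)
  }
  if (is.null(tags)) {
    tags <- generate_tags(length(proteins), tag_length)
  }
  tags <- toupper(as.character(tags))
  if (length(tags) != length(proteins)) {
    stop("one tag per protein is required", call. = FALSE)
  }
  if (length(unique(nchar(tags))) > 1L) {
    stop("all panel tags must have the same length", call. = FALSE)
  }
  if (anyDuplicated(tags)) stop("panel tags must be unique", call. = FALSE)
  if (any(grepl("[^ACGT]", tags))) {
    stop("panel tags must use only A/C/G/T", call. = FALSE)
  }
  tibble::tibble(protein = proteins, tag = tags)
}

# Deterministic, collision-free tag set: indices spread over the 4^len space
# mapped to base-4 nucleotide strings. Not error-correcting by design; the
# default decoder matches tags exactly.
generate_tags <- function(n, len = 8L) {
  if (4^len < n) stop("tag length too short for panel size", call. = FALSE)
  idx <- floor(seq(0, 4^len - 1, length.out = n))
  vapply(idx, function(i) {
    digits <- integer(len)
    for (p in seq_len(len)) {
      digits[p] <- i %% 4
      i <- i %/% 4
    }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

#' Default 113-protein cancer-biomarker panel
#'
#' The assay profiles 113 EV surface proteins, most of them established
#' cancer biomarkers. The exact commercial panel is proprietary, so the
#' default panel names the canonical epithelial/ovarian-cancer markers the
#' analysis focuses on (CDCP1, TACSTD2, EPCAM, ERBB2, the integrins, EGFR,
#' LAMP1 and the tetraspanins CD9/CD63/CD81/CD151, among others) and fills
#' the remainder with generic placeholder antigens so the panel size and
#' data shapes match the real assay.
#'
#' @param n_proteins Panel size (default 113).
#' @param tag_length Protein-tag length in nucleotides.
#'
#' @return A tibble with columns `protein` and `tag`.
#' @export
default_panel <- function(n_proteins = 113L, tag_length = 8L) {
  named <- c(
    "CDCP1", "TACSTD2", "EPCAM", "ERBB2", "ITGA3", "ITGA6", "ITGB1",
    "ITGB4", "EGFR", "LAMP1", "CD151", "CD9", "CD63", "CD81", "ITGAL",
    "MUC16", "MUC1", "CEACAM5", "FOLR1", "MSLN", "CD24", "CD44", "CD47",
    "VEGFA", "KIT", "MET", "AXL", "CDH1", "CDH2", "VIM", "PDPN", "THBS1",
    "ICAM1", "VCAM1", "SELE", "CD40", "CD70", "PDCD1LG2", "CD274", "FAS",
    "TNFRSF10B", "HLA-A", "HLA-DRA", "B2M", "TFRC", "FLOT1", "SDC1",
    "GPC1", "NT5E", "ENG", "PECAM1", "KDR", "PROM1", "ALCAM", "NCAM1",
    "L1CAM", "EPHA2", "EFNB2", "NOTCH1", "DLL4"
  )
  if (n_proteins <= length(named)) {
    proteins <- named[seq_len(n_proteins)]
  } else {
    fillers <- sprintf("AG%03d", seq_len(n_proteins - length(named)))
    proteins <- c(named, fillers)
  }
  ev_panel(proteins, tag_length = tag_length)
}

#' Read or write a panel TSV
#'
#' Panels are exchanged as two-column TSV files (`protein`, `tag`).
#'
#' @param path File path.
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("protein", "tag") %in% names(x))) {
    stop("panel file needs 'protein' and 'tag' columns", call. = FALSE)
  }
  ev_panel(x$protein, x$tag)
}

#' @rdname read_panel
#' @param panel A panel tibble as returned by [ev_panel()].
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}
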