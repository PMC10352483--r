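layout6 <- read_layout(ev_tag = 4, protein_tag = 4, umi = 2)

test_that("reads are split at fixed offsets with per-read quality", {
  # Q30 throughout ('?' is Phred 30 at +33 offset)
  path <- write_fastq("AAAACCCCGT", strrep("?", 10))
  rec <- parse_reads(path, layout6)
  expect_equal(rec$ev_tag, "AAAA")
  expect_equal(rec$protein_tag, "CCCC")
  expect_equal(rec$umi, "GT")
  expect_equal(rec$min_quality, 30)

  # minimum is taken over the read: one Q19 base ('4') drags it down
  path2 <- write_fastq("AAAACCCCGT", "????4?????")
  expect_equal(parse_reads(path2, layout6)$min_quality, 19)
})

test_that("empty and truncated FASTQ inputs are handled", {
  empty <- write_fastq(character(), character())
  expect_warning(rec <- parse_reads(empty, layout6), "no reads")
  expect_equal(nrow(rec), 0)

  seqs <- c(rep("AAAACCCCGT", 93), rep("AAAC", 7))
  quals <- c(rep(strrep("?", 10), 93), rep("????", 7))
  path <- write_fastq(seqs, quals)
  expect_message(rec <- parse_reads(path, layout6), "7 truncated")
  expect_equal(nrow(rec), 93)
  expect_equal(attr(rec, "n_skipped"), 7)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(parse_reads(bad, layout6), "malformed")
})

test_that("quality filter keeps Q20 and drops Q19", {
  rec <- tibble::tibble(ev_tag = c("A", "B", "C"), protein_tag = "x",
                        umi = "y", min_quality = c(19, 20, 35))
  kept <- quality_filter(rec, 20)
  expect_equal(kept$ev_tag, c("B", "C"))
  expect_equal(attr(kept, "n_filtered"), 1)
  all_pass <- quality_filter(rec, 0)
  expect_equal(nrow(all_pass), 3)
})

test_that("tag assignment matches exactly or within a unique Hamming ball", {
  panel <- ev_panel(c("P1", "P2", "P3"),
                    tags = c("AAAA", "TTTT", "AATT"))
  rec <- tibble::tibble(
    ev_tag = "EEEE",
    protein_tag = c("AAAA", "AAAG", "GGGG", "TTTG"),
    umi = "GG", min_quality = 30
  )
  exact <- assign_tags(rec, panel, max_mismatch = 0)
  expect_equal(exact$protein, "P1")
  expect_equal(attr(exact, "n_unmatched"), 3)

  fuzzy <- assign_tags(rec, panel, max_mismatch = 1)
  # AAAG -> P1 (unique at distance 1); TTTG -> P2 (unique); GGGG unmatched
  expect_equal(fuzzy$protein, c("P1", "P1", "P2"))
  expect_equal(attr(fuzzy, "n_unmatched"), 1)

  # equidistant neighbours are ambiguous and dropped
  panel2 <- ev_panel(c("P1", "P2"), tags = c("AAAA", "AATT"))
  rec2 <- tibble::tibble(ev_tag = "EEEE", protein_tag = "AAAT",
                         umi = "GG", min_quality = 30)
  amb <- assign_tags(rec2, panel2, max_mismatch = 1)
  expect_equal(nrow(amb), 0)
  expect_equal(attr(amb, "n_ambiguous"), 1)
})

test_that("matrix counts are distinct molecular tags per (vesicle, protein)", {
  rec <- tibble::tibble(
    ev_tag = "EV01",
    protein_tag = "AAAA",
    protein = "P1",
    umi = c("AA", "AA", "AB"),
    min_quality = 30
  )
  m <- build_ev_matrix(rec, "s1")
  expect_equal(m$count, 2L)

  # duplicate reads of one molecule collapse to one
  dup <- rec[c(1, 1, 1), ]
  expect_equal(build_ev_matrix(dup, "s1")$count, 1L)
})

test_that("per-vesicle floors remove shallow vesicles", {
  rec <- tibble::tibble(
    ev_tag = c("E1", "E1", "E2"),
    protein = c("P1", "P2", "P1"),
    umi = c("AA", "AB", "AC"),
    min_quality = 30
  )
  m <- build_ev_matrix(rec, "s1", min_proteins_per_ev = 2)
  expect_equal(unique(m$ev_id), "E1")
})

test_that("decoding its own emitted reads is a fixed point equal to truth", {
  fx <- tiny_sim(evs = 80L, seed = 13L)
  fq <- emit_reads(fx$sim, withr::local_tempdir())
  layout <- read_layout(protein_tag = 8)
  dec <- decode_samples(fq, fx$panel, layout)
  truth <- dplyr::arrange(fx$sim$counts, sample_id, ev_id, protein)
  got <- dplyr::arrange(dec$counts, sample_id, ev_id, protein)
  expect_identical(as.data.frame(got), as.data.frame(truth))
})

test_that("lowering the quality threshold never decreases any count", {
  panel <- tiny_panel(6)
  cfg <- sim_config(n_samples_per_group = c(G = 1L), evs_per_sample = 100L,
                    q_fail_rate = 0.2, seed = 21L)
  sub <- list(subcluster_spec("bg", setNames(rep(0.5, 6), panel$protein), c(G = 1)))
  sim <- simulate_population(cfg, panel, sub)
  fq <- emit_reads(sim, withr::local_tempdir())
  parsed <- parse_reads(fq$path, read_layout(protein_tag = 8))
  m_strict <- build_ev_matrix(assign_tags(quality_filter(parsed, 20), panel), "s")
  m_loose <- build_ev_matrix(assign_tags(quality_filter(parsed, 0), panel), "s")
  joined <- dplyr::left_join(m_strict, m_loose,
                             by = c("sample_id", "ev_id", "protein"),
                             suffix = c("_strict", "_loose"))
  expect_true(all(joined$count_loose >= joined$count_strict))
})

test_that("total molecule count equals the distinct surviving triples", {
  fx <- tiny_sim(evs = 50L, seed = 3L)
  fq <- emit_reads(fx$sim, withr::local_tempdir())
  layout <- read_layout(protein_tag = 8)
  for (i in seq_len(2)) {
    parsed <- parse_reads(fq$path[i], layout)
    rec <- assign_tags(quality_filter(parsed, 20), fx$panel)
    m <- build_ev_matrix(rec, fq$sample_id[i])
    triples <- unique(paste(rec$ev_tag, rec$protein, rec$umi))
    expect_equal(sum(m$count), length(triples))
  }
})

test_that("matrix summaries report vesicle counts and proteins per vesicle", {
  counts <- tibble::tibble(
    sample_id = "s1",
    ev_id = c(rep("E1", 2), rep("E2", 2), rep("E3", 5)),
    protein = paste0("P", c(1, 2, 1, 2, 1:5)),
    count = 1L
  )
  s <- summarize_ev_matrix(counts)
  expect_equal(s$n_ev, 3)
  expect_equal(s$median_proteins_per_ev, 2)
  expect_equal(s$total_molecules, 9)

  empty <- summarize_ev_matrix(counts[0, ])
  expect_equal(nrow(empty), 0)
})
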