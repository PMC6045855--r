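write_call_table <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

toy_calls <- function() {
  tibble::tibble(
    gene = "FGFX", transcript_strand = "+", chromosome = "1",
    cleavage_site = c(2005L, 2410L),
    length_of_tail_in_contig = c(5L, 0L),
    number_of_bridge_reads = c(2L, 0L),
    max_bridge_read_tail_length = c(6L, 0L)
  )
}

test_that("KLEAT tables parse, keep the seven fields, and validate", {
  p <- write_call_table(toy_calls() |> dplyr::mutate(extra = "x"))
  calls <- read_cs_calls(p, sample_ids = "S1")
  expect_equal(nrow(calls), 2)
  expect_false("extra" %in% names(calls))
  expect_equal(calls$sample_id, c("S1", "S1"))

  p2 <- write_call_table(toy_calls() |> dplyr::select(-cleavage_site))
  expect_error(read_cs_calls(p2), "cleavage_site")

  p3 <- write_call_table(toy_calls() |> dplyr::mutate(number_of_bridge_reads = c(1.5, 2)))
  expect_error(read_cs_calls(p3), "non-integer")
  unlink(c(p, p2, p3))
})

test_that("off-target calls are dropped and retention is recorded", {
  gtf <- write_archetype_gtf(
    archetype_tx("FGFX", "G1", "+", cs_pos = 2000, stop_pos = 1500),
    tempfile(fileext = ".gtf")
  )
  ann <- parse_gene_annotation(gtf, "FGFX")
  calls <- dplyr::bind_rows(
    toy_calls() |> dplyr::mutate(sample_id = "S1"),
    toy_calls() |> dplyr::mutate(sample_id = "S1", gene = "NOTTARGET")
  )
  kept <- filter_on_target(calls, ann)
  expect_equal(nrow(kept), 2)
  expect_equal(unique(kept$gene), "FGFX")
  expect_equal(attr(kept, "retention"), 0.5)
  expect_equal(nrow(filter_on_target(calls[0, ], ann)), 0)
  unlink(gtf)
})

test_that("nearest-annotated assignment minimizes |distance| with upstream ties", {
  gtf <- write_archetype_gtf(
    dplyr::bind_rows(
      archetype_tx("FGFX", "G1", "+", cs_pos = 1000, stop_pos = 900),
      archetype_tx("FGFX", "G1", "+", cs_pos = 1100, stop_pos = 900),
      archetype_tx("RNFX", "G2", "-", cs_pos = 1000, stop_pos = 1500)
    ),
    tempfile(fileext = ".gtf")
  )
  ann <- parse_gene_annotation(gtf, c("FGFX", "RNFX"))
  calls <- tibble::tibble(
    gene_id = c("G1", "G1", "G2"),
    cleavage_site = c(1010, 1050, 1010)
  )
  out <- assign_nearest_annotated(calls, ann)
  # plain nearest, positive = transcript-downstream
  expect_equal(out$signed_distance[1], 10)
  f_ids <- ann$cs$cs_id[ann$cs$gene_id == "G1"]
  expect_equal(out$nearest_annotated_cs[1], f_ids[ann$cs$representative_pos[ann$cs$gene_id == "G1"] == 1000])
  # exact tie at 1050 resolves to the upstream (smaller coordinate) site
  expect_equal(out$signed_distance[2], 50)
  expect_equal(out$nearest_annotated_cs[2], out$nearest_annotated_cs[1])
  # minus strand: call at larger coordinate is transcript-upstream -> negative
  expect_equal(out$signed_distance[3], -10)
  unlink(gtf)
})

test_that("PAS search returns the strongest, closest hexamer in the window", {
  # genome with AATAAA occupying upstream offsets 26..21 of cs = 100
  bg <- strrep("C", 200)
  seq <- paste0(substr(bg, 1, 73), "AATAAA", substr(bg, 80, 200))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "1"
  hit <- find_pas_hexamer(genome, "1", "+", 100)
  expect_equal(hit$hexamer, "AATAAA")
  expect_equal(hit$distance, 21)

  # ATTAAA closer to the CS, but AATAAA outranks it
  seq2 <- paste0(substr(bg, 1, 60), "AATAAA", "CCCC", "ATTAAA", substr(bg, 77, 200))
  genome2 <- Biostrings::DNAStringSet(seq2)
  names(genome2) <- "1"
  hit2 <- find_pas_hexamer(genome2, "1", "+", 100)
  expect_equal(hit2$hexamer, "AATAAA")

  # featureless window -> no hit
  expect_null(find_pas_hexamer(genome, "1", "+", 60))
  expect_error(find_pas_hexamer(genome, "2", "+", 100), "Chromosome")
})

test_that("window scan agrees with a brute-force sweep of every offset", {
  set.seed(31)
  motifs <- pas_motifs()
  for (i in 1:300) {
    w <- paste(sample(c("A", "C", "G", "T"), sample(c(10, 30, 50), 1),
                      replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4)),
               collapse = "")
    got <- apacohort:::scan_window_for_pas(w, motifs)
    want <- brute_force_pas(w, motifs)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$hexamer, want$hexamer)
      expect_equal(got$distance, want$distance)
      expect_equal(got$rank, want$rank)
    }
  }
})

test_that("the two-criterion filter retains exactly the designed calls", {
  fixture <- tibble::tibble(
    signed_distance = c(10, -25, -26, 40, 40, 40, 40, 40, NA, 0),
    pas_hexamer = c(NA, NA, NA, "AATAAA", "AATAAA", "ATTAAA", "TATAAA", "AATAAA", "ATTAAA", "AATAAA"),
    length_of_tail_in_contig = c(0L, 0L, 9L, 3L, 4L, 0L, 9L, 3L, 3L, 0L),
    number_of_bridge_reads = c(0L, 0L, 9L, 1L, 0L, 2L, 9L, 1L, 2L, 2L),
    max_bridge_read_tail_length = c(0L, 0L, 3L, 3L, 0L, 0L, 9L, 3L, 0L, 0L)
  )
  out <- confidence_filter(fixture)
  # designed outcomes:
  #  1 A (|d|=10, no evidence)         2 A (boundary |d|=25)
  #  3 dropped (|d|=26, strong evidence but no hexamer)
  #  4 dropped (hexamer, all evidence below thresholds)
  #  5 B (tail = 4)                    6 B (bridges = 2)
  #  7 dropped (evidence, but weak-ranked hexamer)
  #  8 dropped                         9 B (unassignable but hexamer+bridges)
  # 10 A+B (both criteria)
  expect_equal(out$retained,
               c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$criterion,
               c("A", "A", NA, NA, "B", "B", NA, NA, "B", "A+B"))
})

test_that("retention is monotone in every evidence field", {
  set.seed(32)
  for (i in 1:100) {
    base <- tibble::tibble(
      signed_distance = sample(c(NA, 10, 30, 60), 1),
      pas_hexamer = sample(c(NA, "AATAAA", "ATTAAA", "TATAAA"), 1),
      length_of_tail_in_contig = sample(0:6, 1),
      number_of_bridge_reads = sample(0:4, 1),
      max_bridge_read_tail_length = sample(0:6, 1)
    )
    bumped <- base
    f <- sample(c("length_of_tail_in_contig", "number_of_bridge_reads",
                  "max_bridge_read_tail_length"), 1)
    bumped[[f]] <- bumped[[f]] + sample(1:5, 1)
    expect_true(confidence_filter(bumped)$retained >= confidence_filter(base)$retained)
  }
})
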