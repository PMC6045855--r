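detail_row <- function(direction, stop_id, utr_len) {
  tibble::tibble(direction = direction, stop_id = stop_id, utr_len = utr_len)
}

test_that("trend archetypes resolve as shortening/lengthening/complex", {
  # FGF2-like: one stop codon, shorter-UTR site up, longer-UTR site down
  fgf2 <- dplyr::bind_rows(
    detail_row("up", "s1", 500L),
    detail_row("down", "s1", 1800L)
  )
  expect_equal(resolve_trend(fgf2), "shortening")

  # CCNE1-like: two shorter-UTR sites down, the longest-UTR site up
  ccne1 <- dplyr::bind_rows(
    detail_row("down", "s1", 300L),
    detail_row("down", "s1", 700L),
    detail_row("up", "s1", 1500L)
  )
  expect_equal(resolve_trend(ccne1), "lengthening")

  # CDKN2A-like: significant sites split across separate stop codons
  cdkn2a <- dplyr::bind_rows(
    detail_row("up", "s1", 400L),
    detail_row("down", "s3", 900L)
  )
  expect_equal(resolve_trend(cdkn2a), "complex")

  # PTCH1-like: multi-stop site ignored (NA stop), dominant stop resolves
  ptch1 <- dplyr::bind_rows(
    detail_row("up", NA_character_, NA_integer_),   # mapped to several stops
    detail_row("up", "s1", 350L),                   # shorter UTR gains
    detail_row("down", "s1", 1200L),
    detail_row("down", "s1", 2000L),
    detail_row("down", "s2", 600L)                  # separate stop, outvoted
  )
  expect_equal(resolve_trend(ptch1), "shortening")

  # after restriction only one direction remains -> complex
  one_dir <- dplyr::bind_rows(
    detail_row("up", "s1", 400L),
    detail_row("up", "s1", 700L),
    detail_row("down", "s2", 900L)
  )
  expect_equal(resolve_trend(one_dir), "complex")

  # interleaved lengths -> complex
  inter <- dplyr::bind_rows(
    detail_row("up", "s1", 400L),
    detail_row("up", "s1", 1500L),
    detail_row("down", "s1", 900L)
  )
  expect_equal(resolve_trend(inter), "complex")
})

test_that("reversing all directions swaps shortening and lengthening", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    d <- tibble::tibble(
      direction = sample(c("up", "down"), n, replace = TRUE),
      stop_id = sample(c("s1", "s2"), n, replace = TRUE, prob = c(0.8, 0.2)),
      utr_len = sample(100:2000, n)
    )
    if (!any(d$direction == "up") || !any(d$direction == "down")) next
    fwd <- resolve_trend(d)
    rev <- resolve_trend(d |> dplyr::mutate(
      direction = ifelse(direction == "up", "down", "up")
    ))
    swapped <- c(shortening = "lengthening", lengthening = "shortening",
                 complex = "complex")[fwd]
    expect_equal(rev, unname(swapped))
  }
})

rnf43_annotation <- function() {
  # minus-strand gene, three CSs sharing one stop codon (R1 longest UTR),
  # plus a fourth CS on its own stop codon
  gtf <- write_archetype_gtf(
    dplyr::bind_rows(
      archetype_tx("RNFX", "G9", "-", cs_pos = 1000, stop_pos = 5000),
      archetype_tx("RNFX", "G9", "-", cs_pos = 2000, stop_pos = 5000),
      archetype_tx("RNFX", "G9", "-", cs_pos = 3000, stop_pos = 5000),
      archetype_tx("RNFX", "G9", "-", cs_pos = 6000, stop_pos = 8000)
    ),
    tempfile(fileext = ".gtf")
  )
  ann <- parse_gene_annotation(gtf, "RNFX")
  unlink(gtf)
  ann
}

test_that("strand-aware trends via the full mapping path match the archetype", {
  ann <- rnf43_annotation()
  clusters <- tibble::tibble(
    gene_id = "G9",
    cs_label = c("R1", "R2", "R3"),
    representative_pos = c(1004, 2003, 2995) # jittered predicted reps
  )
  shifts_base <- tibble::tibble(
    gene_id = "G9", cancer_type = "KIRC",
    cs_label = c("R2", "R3"),
    p_value = c(1e-4, 2e-4)
  )
  events <- tibble::tibble(gene_id = "G9", cancer_type = "KIRC")

  # higher-coordinate site (shorter 3' UTR on minus strand) gains -> shortening
  shortening <- classify_trends(
    events, shifts_base |> dplyr::mutate(direction = c("down", "up")),
    clusters, ann
  )
  expect_equal(shortening$events$trend, "shortening")

  # mirrored significance -> lengthening
  lengthening <- classify_trends(
    events, shifts_base |> dplyr::mutate(direction = c("up", "down")),
    clusters, ann
  )
  expect_equal(lengthening$events$trend, "lengthening")
})

test_that("novel and multi-stop sites never influence the label", {
  ann <- rnf43_annotation()
  clusters <- tibble::tibble(
    gene_id = "G9",
    cs_label = c("R0", "R2", "R3"),
    representative_pos = c(7000, 2003, 2995) # R0 is 1000 bp from any annotated CS
  )
  shifts <- tibble::tibble(
    gene_id = "G9", cancer_type = "KIRC",
    cs_label = c("R0", "R2", "R3"),
    p_value = c(1e-9, 1e-4, 2e-4),
    direction = c("down", "down", "up")
  )
  events <- tibble::tibble(gene_id = "G9", cancer_type = "KIRC")
  out <- classify_trends(events, shifts, clusters, ann)
  expect_equal(out$events$trend, "shortening")
  r0 <- out$detail[out$detail$cs_label == "R0", ]
  expect_equal(r0$exclusion, "novel")
})

test_that("mapping flags sites beyond the cutoff as novel", {
  ann <- rnf43_annotation()
  clusters <- tibble::tibble(
    gene_id = "G9",
    cs_label = c("A", "B", "C"),
    representative_pos = c(1000, 1030, 3200) # exact, 30 bp off, far novel
  )
  mapped <- map_for_trend(clusters, ann, max_dist = 25)
  expect_false(mapped$novel[1])
  expect_true(mapped$novel[2])
  expect_true(mapped$novel[3])
  expect_true(is.na(mapped$annotated_cs[2]))
})
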