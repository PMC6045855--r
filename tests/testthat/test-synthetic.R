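test_that("the same seed reproduces byte-identical simulated outputs", {
  cfg <- sim_config(seed = 101, cohorts = tibble::tibble(
    cancer_type = "SIM", n_normal = 20, n_tumor = 20
  ))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, build_toy_reference(cfg, dir = d1), dir = d1)
  s2 <- simulate_cohort(cfg, build_toy_reference(cfg, dir = d2), dir = d2)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(
    readLines(file.path(d1, "annotation.gtf")),
    readLines(file.path(d2, "annotation.gtf"))
  )
  expect_identical(
    readLines(file.path(d1, "genome.fa")),
    readLines(file.path(d2, "genome.fa"))
  )
  one <- s1$manifest$sample_id[1]
  expect_identical(
    readLines(file.path(d1, "calls", paste0(one, ".tsv"))),
    readLines(file.path(d2, "calls", paste0(one, ".tsv")))
  )
})

test_that("every planted site carries the hexamer at the planted offset", {
  cfg <- sim_config(seed = 102, genes = tibble::tibble(
    gene_name = c("GENA", "GENB", "GENC"),
    strand = c("+", "-", "+"),
    n_cs = c(2L, 3L, 2L),
    n_stops = c(1L, 2L, 2L),
    topology = c("one_to_one", "one_to_one", "one_to_many"),
    nmd_fraction = c(0, 0.5, 0)
  ), usage = tibble::tibble(
    gene_name = rep(c("GENA", "GENB", "GENC"), c(2, 3, 2)),
    cs_index = c(1:2, 1:3, 1:2),
    p_normal = 0.5, p_tumor = 0.5
  ))
  ref <- build_toy_reference(cfg)
  for (r in seq_len(nrow(ref$sites))) {
    hit <- find_pas_hexamer(ref$genome, "1", ref$sites$strand[r], ref$sites$pos[r])
    expect_equal(hit$hexamer, "AATAAA")
    expect_equal(hit$distance, 21)
  }
  # NMD fraction of 0.5 with two stops flags exactly one
  bstops <- ref$stops[ref$stops$gene_name == "GENB", ]
  expect_equal(sum(bstops$is_nmd), 1L)
  # one_to_many topology maps the first CS to several stop codons and
  # leaves the rest one-to-one
  genc <- ref$sites[ref$sites$gene_name == "GENC" & !ref$sites$novel, ]
  expect_equal(genc$n_stops_mapped, c(2L, 1L))
})

test_that("the generated annotation realizes the configured topology", {
  cfg <- sim_config(seed = 103)
  dir <- withr::local_tempdir()
  ref <- build_toy_reference(cfg, dir = dir)
  ann <- parse_gene_annotation(ref$gtf_path, cfg$genes$gene_name)
  # two CSs and one shared stop codon per gene; NF decoys contribute nothing
  expect_equal(nrow(ann$cs), 4)
  expect_equal(nrow(ann$stops), 2)
  expect_equal(nrow(ann$cs_stop_map), 4)
  expect_setequal(
    ann$cs$representative_pos,
    ref$sites$pos[!ref$sites$novel]
  )
})

test_that("realized usage frequencies converge to the planted probabilities", {
  cfg <- sim_config(
    seed = 104,
    cohorts = tibble::tibble(cancer_type = "SIM", n_normal = 2000, n_tumor = 2000),
    novel_rate = 0, offtarget_rate = 0
  )
  ref <- build_toy_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  rates <- sim$calls |>
    dplyr::inner_join(sim$manifest, by = "sample_id") |>
    dplyr::inner_join(
      ref$sites |> dplyr::filter(!novel) |>
        dplyr::select(gene_name, cs_index, pos),
      by = c(gene = "gene_name"),
      relationship = "many-to-many"
    ) |>
    dplyr::filter(abs(cleavage_site - pos) < 50) |>
    dplyr::count(gene, cs_index, condition)
  truth <- cfg$usage |>
    tidyr::pivot_longer(c(p_normal, p_tumor),
                        names_to = "condition", values_to = "p") |>
    dplyr::mutate(condition = sub("p_", "", condition))
  joined <- rates |>
    dplyr::inner_join(truth, by = c(gene = "gene_name", "cs_index", "condition"))
  n_grp <- 2000
  expect_true(all(
    abs(joined$n / n_grp - joined$p) <=
      3 * sqrt(joined$p * (1 - joined$p) / n_grp) + 1e-9
  ))
})

test_that("planted truth reflects the configured shifts and topology", {
  cfg <- sim_config(seed = 105)
  ref <- build_toy_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  tr <- sim$truth$per_gene
  expect_true(tr$event_planted[tr$gene_name == "GENA"])
  expect_false(tr$event_planted[tr$gene_name == "GENB"])
  # GENA: down site has the shorter UTR, up site the longer -> lengthening
  expect_equal(tr$expected_trend[tr$gene_name == "GENA"], "lengthening")
})

test_that("weak-evidence mode draws every field below the criterion-B bounds", {
  cfg <- sim_config(seed = 106, weak_evidence = TRUE, novel_rate = 0,
                    cohorts = tibble::tibble(
                      cancer_type = "SIM", n_normal = 10, n_tumor = 10
                    ))
  sim <- simulate_cohort(cfg, build_toy_reference(cfg))
  on_target <- sim$calls |> dplyr::filter(gene != "OFFTARGET1")
  expect_true(all(on_target$length_of_tail_in_contig < 4))
  expect_true(all(on_target$number_of_bridge_reads < 2))
  expect_true(all(on_target$max_bridge_read_tail_length < 4))
})
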