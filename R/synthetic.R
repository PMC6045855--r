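#' Configuration for the synthetic APA test universe
#'
#' Describes a toy study: genes with planted cleavage sites (CSs), stop
#' codons and a CS-to-stop topology; cohorts of normal and tumor samples;
#' and per-CS usage probabilities in each condition (the planted effect).
#' Defaults reproduce the package's reference study conditions: two genes on
#' opposite strands, each with two CSs sharing one stop codon; one cohort of
#' 100 normal and 100 tumor samples; a planted regulation event in the first
#' gene (one CS 0.9 to 0.4, the other 0.3 to 0.85 from normal to tumor) and
#' a null second gene.
#'
#' @param seed Mandatory integer seed; every draw derives from it.
#' @param genes Tibble with one row per gene: `gene_name`, `strand`
#'   (`"+"`/`"-"`), `n_cs`, `n_stops`, `topology` (`one_to_one`,
#'   `one_to_many`, `mixed`), `nmd_fraction` (fraction of stop codons
#'   flagged as NMD-transcript stops).
#' @param usage Tibble with `gene_name`, `cs_index` (ascending genomic
#'   coordinate within the gene), `p_normal`, `p_tumor`: per-sample
#'   probability that the CS is predicted in a sample of each condition.
#' @param cohorts Tibble with `cancer_type`, `n_normal`, `n_tumor`.
#' @param cs_spacing Distance in bp between neighbouring planted CSs
#'   (default 200, several times the clustering cutoff so clusters stay
#'   separable under jitter).
#' @param jitter_sd Standard deviation (bp) of the rounded Gaussian
#'   positional jitter added to each call (default 3).
#' @param novel_rate Per-sample, per-gene probability of a decoy call at the
#'   gene's unannotated (novel) site, which carries a planted PAS hexamer
#'   (default 0.05).
#' @param novel_offset Distance (bp) of the novel site from the outermost
#'   annotated CS (default 300).
#' @param offtarget_rate Per-sample probability of a call attributed to a
#'   gene outside the target list (default 0.05).
#' @param weak_evidence When `TRUE`, poly(A)-evidence fields are drawn below
#'   every criterion-B threshold instead of above (default `FALSE`:
#'   tail length 4 plus a geometric tail, bridge reads Poisson with mean 3,
#'   so criterion B passes).
#' @param pas_offset Distance (bp, hexamer-3'-end anchor) at which the
#'   AATAAA hexamer is planted upstream of every CS (default 21).
#' @param cds_end_nf_decoys Plant one `cds_end_NF`-tagged decoy transcript
#'   per gene to exercise annotation filtering (default `TRUE`).
#' @return An `apa_sim_config` list.
#' @export
sim_config <- function(seed,
                       genes = NULL,
                       usage = NULL,
                       cohorts = tibble(
                         cancer_type = "SIM", n_normal = 100, n_tumor = 100
                       ),
                       cs_spacing = 200,
                       jitter_sd = 3,
                       novel_rate = 0.05,
                       novel_offset = 300,
                       offtarget_rate = 0.05,
                       weak_evidence = FALSE,
                       pas_offset = 21,
                       cds_end_nf_decoys = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  genes <- genes %||% tibble(
    gene_name = c("GENA", "GENB"),
    strand = c("+", "-"),
    n_cs = c(2L, 2L),
    n_stops = c(1L, 1L),
    topology = "one_to_one",
    nmd_fraction = 0
  )
  usage <- usage %||% tibble(
    gene_name = rep(genes$gene_name, times = genes$n_cs),
    cs_index = unlist(lapply(genes$n_cs, seq_len)),
    p_normal = c(0.9, 0.3, rep(0.6, sum(genes$n_cs) - 2)),
    p_tumor = c(0.4, 0.85, rep(0.6, sum(genes$n_cs) - 2))
  )
  stopifnot(
    all(genes$strand %in% c("+", "-")),
    all(genes$topology %in% c("one_to_one", "one_to_many", "mixed")),
    all(usage$p_normal >= 0 & usage$p_normal <= 1),
    all(usage$p_tumor >= 0 & usage$p_tumor <= 1),
    cs_spacing > 0, jitter_sd >= 0,
    novel_offset > 25 # novel decoys must sit beyond the mapping cutoff
  )
  structure(
    list(
      seed = as.integer(seed), genes = genes, usage = usage,
      cohorts = cohorts, cs_spacing = cs_spacing, jitter_sd = jitter_sd,
      novel_rate = novel_rate, novel_offset = novel_offset,
      offtarget_rate = offtarget_rate, weak_evidence = weak_evidence,
      pas_offset = pas_offset, cds_end_nf_decoys = cds_end_nf_decoys
    ),
    class = "apa_sim_config"
  )
}

# cs index -> stop indices, per topology
topology_map <- function(topology, n_cs, n_stops) {
  base <- lapply(seq_len(n_cs), function(i) min(i, n_stops))
  if (topology == "one_to_many" && n_stops > 1) {
    base[[1]] <- seq_len(n_stops)
  } else if (topology == "mixed" && n_stops > 1) {
    base[[1]] <- seq_len(min(2, n_stops))
  }
  base
}

#' Build the toy genome and annotation for a simulated study
#'
#' Lays the configured genes out on one chromosome (Ensembl-style name
#' `"1"`), plants an AATAAA hexamer at the configured upstream offset of
#' every cleavage site (including each gene's unannotated novel site), and
#' writes an Ensembl-dialect GTF realizing the configured CS-to-stop-codon
#' topology through one transcript per (CS, stop codon) pair. A
#' `cds_end_NF`-tagged decoy transcript per gene exercises the annotation
#' filter. The 50 bp immediately upstream of each planted CS is scrubbed of
#' accidental PAS motifs so the planted hexamer is the only hit.
#'
#' @param config An [sim_config()] object.
#' @param dir Optional directory; when given, `genome.fa`, `annotation.gtf`,
#'   and `genes.txt` are written there.
#' @return An `apa_sim_reference` list: `genome` (DNAStringSet), `gtf_lines`
#'   (character), `sites` (tibble of planted CSs: gene, strand, cs_index,
#'   pos, novel flag, true 3' UTR length where unique), `stops`,
#'   `gene_names`, and file paths when `dir` was given.
#' @export
build_toy_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "apa_sim_config"))
  withr::local_seed(config$seed)
  sp <- config$cs_spacing
  gap <- 500L
  offset <- 0L
  sites <- list()
  stops <- list()
  gtf <- character()
  max_end <- 0L

  for (gi in seq_len(nrow(config$genes))) {
    g <- config$genes[gi, ]
    gene_id <- sprintf("SIMG%04d", gi)
    if (g$strand == "+") {
      gene_start <- offset + 100L
      stop_pos <- gene_start + 300L + (seq_len(g$n_stops) - 1L) * 120L # 3'-most base
      cs_pos <- gene_start + 300L + g$n_stops * 120L + seq_len(g$n_cs) * sp
      novel_pos <- max(cs_pos) + config$novel_offset
      decoy_end <- cs_pos[1] + floor(sp / 2)
      gene_end <- novel_pos + 100L
    } else {
      anchor <- offset + 100L + config$novel_offset
      novel_pos <- offset + 100L
      cs_pos <- anchor + seq_len(g$n_cs) * sp
      stop_pos <- max(cs_pos) + 400L + (seq_len(g$n_stops) - 1L) * 120L # 3'-most base (min start)
      decoy_end <- cs_pos[1] + floor(sp / 2)
      gene_start <- novel_pos - 50L
      gene_end <- max(stop_pos) + 300L
    }
    n_nmd <- round(g$nmd_fraction * g$n_stops)
    is_nmd <- seq_len(g$n_stops) > g$n_stops - n_nmd

    cs2stop <- topology_map(g$topology, g$n_cs, g$n_stops)
    utr_true <- vapply(seq_len(g$n_cs), function(i) {
      if (length(cs2stop[[i]]) != 1) {
        return(NA_integer_)
      }
      utr_length(cs_pos[i], stop_pos[cs2stop[[i]]], g$strand)
    }, integer(1))

    attr_str <- function(tx, biotype, tags = character()) {
      paste0(
        'gene_id "', gene_id, '"; transcript_id "', tx,
        '"; gene_name "', g$gene_name,
        '"; gene_biotype "protein_coding"; transcript_biotype "', biotype, '";',
        paste0(' tag "', tags, '";', collapse = "")
      )
    }
    gtf_row <- function(type, start, end, strand, attrs) {
      # sprintf keeps large coordinates out of scientific notation
      paste("1", "sim", type, sprintf("%d", as.integer(start)),
            sprintf("%d", as.integer(end)), ".", strand, ".", attrs,
            sep = "\t")
    }
    k <- 0L
    for (i in seq_len(g$n_cs)) {
      for (j in cs2stop[[i]]) {
        k <- k + 1L
        tx <- sprintf("%s.t%02d", gene_id, k)
        biotype <- if (is_nmd[j]) "nonsense_mediated_decay" else "protein_coding"
        at <- attr_str(tx, biotype, "basic")
        if (g$strand == "+") {
          gtf <- c(
            gtf,
            gtf_row("transcript", gene_start, cs_pos[i], "+", at),
            gtf_row("exon", gene_start, cs_pos[i], "+", at),
            gtf_row("stop_codon", stop_pos[j] - 2L, stop_pos[j], "+", at)
          )
        } else {
          gtf <- c(
            gtf,
            gtf_row("transcript", cs_pos[i], gene_end, "-", at),
            gtf_row("exon", cs_pos[i], gene_end, "-", at),
            gtf_row("stop_codon", stop_pos[j], stop_pos[j] + 2L, "-", at)
          )
        }
      }
    }
    if (config$cds_end_nf_decoys) {
      tx <- paste0(gene_id, ".tNF")
      # cds_end_NF first, another tag after it: exercises attribute masking
      at <- attr_str(tx, "protein_coding", c("cds_end_NF", "basic"))
      if (g$strand == "+") {
        gtf <- c(
          gtf,
          gtf_row("transcript", gene_start, decoy_end, "+", at),
          gtf_row("exon", gene_start, decoy_end, "+", at),
          gtf_row("stop_codon", stop_pos[1] - 2L, stop_pos[1], "+", at)
        )
      } else {
        gtf <- c(
          gtf,
          gtf_row("transcript", decoy_end, gene_end, "-", at),
          gtf_row("exon", decoy_end, gene_end, "-", at),
          gtf_row("stop_codon", stop_pos[1], stop_pos[1] + 2L, "-", at)
        )
      }
    }

    sites[[gi]] <- tibble(
      gene_id = gene_id, gene_name = g$gene_name, strand = g$strand,
      cs_index = c(seq_len(g$n_cs), NA_integer_),
      pos = c(cs_pos, novel_pos),
      novel = c(rep(FALSE, g$n_cs), TRUE),
      utr_true = c(utr_true, NA_integer_),
      n_stops_mapped = c(vapply(cs2stop, length, integer(1)), 0L)
    )
    stops[[gi]] <- tibble(
      gene_id = gene_id, gene_name = g$gene_name, strand = g$strand,
      stop_index = seq_len(g$n_stops), pos = stop_pos, is_nmd = is_nmd
    )
    max_end <- max(max_end, gene_end)
    offset <- gene_end + gap
  }

  sites <- list_rbind(sites)
  stops <- list_rbind(stops)
  chrlen <- max_end + 200L
  seq <- sample(c("A", "C", "G", "T"), chrlen, replace = TRUE)

  # scrub each upstream window to C/G, then plant the hexamer at pas_offset
  d <- config$pas_offset
  for (r in seq_len(nrow(sites))) {
    pos <- sites$pos[r]
    if (sites$strand[r] == "+") {
      win <- (pos - 50):(pos - 1)
      seq[win] <- sample(c("C", "G"), length(win), replace = TRUE)
      seq[(pos - d - 5):(pos - d)] <- c("A", "A", "T", "A", "A", "A")
    } else {
      win <- (pos + 1):(pos + 50)
      seq[win] <- sample(c("C", "G"), length(win), replace = TRUE)
      seq[(pos + d):(pos + d + 5)] <- c("T", "T", "T", "A", "T", "T")
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- "1"

  out <- structure(
    list(
      genome = genome, gtf_lines = gtf, sites = sites, stops = stops,
      gene_names = config$genes$gene_name
    ),
    class = "apa_sim_reference"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$genome_path <- file.path(dir, "genome.fa")
    out$gtf_path <- file.path(dir, "annotation.gtf")
    out$gene_list_path <- file.path(dir, "genes.txt")
    Biostrings::writeXStringSet(genome, out$genome_path)
    readr::write_lines(gtf, out$gtf_path)
    readr::write_lines(config$genes$gene_name, out$gene_list_path)
  }
  out
}

# evidence fields drawn to pass (or, when weak, fail) criterion B
draw_evidence <- function(n, weak) {
  if (weak) {
    tibble(
      length_of_tail_in_contig = sample(0:3, n, replace = TRUE),
      number_of_bridge_reads = sample(0:1, n, replace = TRUE),
      max_bridge_read_tail_length = sample(0:3, n, replace = TRUE)
    )
  } else {
    tibble(
      length_of_tail_in_contig = 4L + rgeom(n, 0.5),
      number_of_bridge_reads = rpois(n, 3),
      max_bridge_read_tail_length = 4L + rgeom(n, 0.5)
    )
  }
}

#' Simulate a cohort of per-sample cleavage-site call tables
#'
#' For each sample and planted cleavage site, a Bernoulli draw with the
#' group's usage probability decides whether the site is called; called
#' sites get the true coordinate plus rounded Gaussian jitter and
#' poly(A)-evidence fields from the configured distributions. Decoy calls at
#' each gene's unannotated novel site and off-target calls on a non-target
#' gene are injected at the configured rates. Fully reproducible from the
#' config seed.
#'
#' @param config An [sim_config()] object.
#' @param reference Output of [build_toy_reference()] for the same config.
#' @param dir Optional directory; when given, `manifest.tsv` and one
#'   `calls/<sample_id>.tsv` per sample are written there.
#' @return A list: `manifest` (sample_id, cancer_type, condition), `calls`
#'   (all samples' KLEAT-style calls with `sample_id`), and `truth` (per
#'   gene x cancer type: planted event flag, per-CS directions, expected
#'   trend label where the topology determines one).
#' @export
simulate_cohort <- function(config, reference, dir = NULL) {
  stopifnot(inherits(config, "apa_sim_config"),
            inherits(reference, "apa_sim_reference"))
  withr::local_seed(config$seed + 1L)

  manifest <- config$cohorts |>
    pmap(function(cancer_type, n_normal, n_tumor) {
      tibble(
        sample_id = c(
          sprintf("%s_N%03d", cancer_type, seq_len(n_normal)),
          sprintf("%s_T%03d", cancer_type, seq_len(n_tumor))
        ),
        cancer_type = cancer_type,
        condition = rep(c("normal", "tumor"), c(n_normal, n_tumor))
      )
    }) |>
    list_rbind()

  site_info <- reference$sites |>
    filter(!.data$novel) |>
    left_join(config$usage, by = c("gene_name", "cs_index"))
  if (anyNA(site_info$p_normal)) {
    abort("Usage table does not cover every planted (gene, cs_index).")
  }

  draws <- crossing(
    manifest |> select("sample_id", "cancer_type", "condition"),
    site_info |> select("gene_name", "strand", "cs_index", "pos")
  ) |>
    left_join(
      config$usage, by = c("gene_name", "cs_index")
    ) |>
    mutate(
      p = ifelse(.data$condition == "normal", .data$p_normal, .data$p_tumor),
      present = rbinom(n(), 1, .data$p) == 1
    ) |>
    filter(.data$present)

  calls <- draws |>
    mutate(
      gene = .data$gene_name,
      transcript_strand = .data$strand,
      chromosome = "1",
      cleavage_site = as.integer(
        .data$pos + round(rnorm(n(), 0, config$jitter_sd))
      )
    ) |>
    bind_cols(draw_evidence(nrow(draws), config$weak_evidence)) |>
    select("sample_id", all_of(kleat_fields))

  # novel-site decoys: planted hexamer, strong evidence, no annotation
  novel_sites <- reference$sites |> filter(.data$novel)
  novel_draws <- crossing(
    manifest |> select("sample_id"),
    novel_sites |> select("gene_name", "strand", "pos")
  ) |>
    filter(rbinom(n(), 1, config$novel_rate) == 1)
  if (nrow(novel_draws) > 0) {
    novel_calls <- novel_draws |>
      mutate(
        gene = .data$gene_name,
        transcript_strand = .data$strand,
        chromosome = "1",
        cleavage_site = as.integer(
          .data$pos + round(rnorm(n(), 0, config$jitter_sd))
        )
      ) |>
      bind_cols(draw_evidence(nrow(novel_draws), weak = FALSE)) |>
      select("sample_id", all_of(kleat_fields))
    calls <- bind_rows(calls, novel_calls)
  }

  # off-target decoys: a gene outside the target list
  off <- manifest |>
    filter(rbinom(n(), 1, config$offtarget_rate) == 1)
  if (nrow(off) > 0) {
    off_calls <- off |>
      mutate(
        gene = "OFFTARGET1", transcript_strand = "+", chromosome = "1",
        cleavage_site = 60L
      ) |>
      bind_cols(draw_evidence(nrow(off), weak = TRUE)) |>
      select("sample_id", all_of(kleat_fields))
    calls <- bind_rows(calls, off_calls)
  }
  calls <- calls |> arrange(.data$sample_id, .data$gene, .data$cleavage_site)

  truth <- sim_truth(config, reference)

  out <- list(manifest = manifest, calls = calls, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    calls_dir <- file.path(dir, "calls")
    if (!dir.exists(calls_dir)) dir.create(calls_dir)
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    for (sid in manifest$sample_id) {
      readr::write_tsv(
        calls |> filter(.data$sample_id == sid) |> select(-"sample_id"),
        file.path(calls_dir, paste0(sid, ".tsv"))
      )
    }
    out$manifest_path <- file.path(dir, "manifest.tsv")
    out$calls_dir <- calls_dir
  }
  out
}

# planted ground truth per (gene, cancer type), from the config alone
sim_truth <- function(config, reference) {
  per_cs <- config$usage |>
    mutate(direction = case_when(
      .data$p_tumor > .data$p_normal ~ "up",
      .data$p_tumor < .data$p_normal ~ "down",
      .default = "none"
    )) |>
    left_join(
      reference$sites |> filter(!.data$novel) |>
        select("gene_name", "cs_index", "utr_true"),
      by = c("gene_name", "cs_index")
    )
  per_gene <- per_cs |>
    group_by(.data$gene_name) |>
    summarise(
      event_planted = any(.data$direction == "up") && any(.data$direction == "down"),
      expected_trend = {
        up <- .data$utr_true[.data$direction == "up"]
        down <- .data$utr_true[.data$direction == "down"]
        if (!any(.data$direction == "up") || !any(.data$direction == "down") ||
            anyNA(up) || anyNA(down)) {
          NA_character_
        } else if (max(up) < min(down)) {
          "shortening"
        } else if (min(up) > max(down)) {
          "lengthening"
        } else {
          "complex"
        }
      },
      .groups = "drop"
    )
  list(
    per_gene = crossing(per_gene, cancer_type = config$cohorts$cancer_type),
    per_cs = per_cs
  )
}
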