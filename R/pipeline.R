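#' Pipeline parameters
#'
#' All thresholds of the analysis in one list, with the published defaults:
#' 20 bp clustering gap, 25 bp annotated-site proximity for retention and
#' for trend mapping, 50 bp PAS search window, AATAAA/ATTAAA as the strong
#' motifs, poly(A) evidence thresholds (tail >= 4, bridge reads >= 2,
#' bridge tail >= 4), per-site significance alpha = 0.01, and at least 15
#' normal samples for a cohort to be compared.
#'
#' @param cluster_cutoff Single-linkage gap cutoff in bp.
#' @param max_annot_dist Criterion-A distance bound in bp.
#' @param pas_window PAS hexamer search window in bp.
#' @param strong_motifs Motifs eligible for criterion B.
#' @param pas_motifs Full ranked motif list for reporting.
#' @param tail_min,bridge_min,bridge_tail_min Criterion-B evidence bounds.
#' @param alpha Per-site Fisher-test significance level.
#' @param min_normal Minimum normal samples per eligible cancer type.
#' @param trend_map_dist Trend-stage mapping distance in bp.
#' @return A named list of parameters.
#' @export
apa_params <- function(cluster_cutoff = 20, max_annot_dist = 25,
                       pas_window = 50,
                       strong_motifs = c("AATAAA", "ATTAAA"),
                       pas_motifs = apacohort::pas_motifs(),
                       tail_min = 4, bridge_min = 2, bridge_tail_min = 4,
                       alpha = 0.01, min_normal = 15, trend_map_dist = 25) {
  p <- list(
    cluster_cutoff = cluster_cutoff, max_annot_dist = max_annot_dist,
    pas_window = pas_window, strong_motifs = strong_motifs,
    pas_motifs = pas_motifs, tail_min = tail_min, bridge_min = bridge_min,
    bridge_tail_min = bridge_tail_min, alpha = alpha,
    min_normal = min_normal, trend_map_dist = trend_map_dist
  )
  num <- p[c(
    "cluster_cutoff", "max_annot_dist", "pas_window", "tail_min",
    "bridge_min", "bridge_tail_min", "alpha", "min_normal", "trend_map_dist"
  )]
  stopifnot(all(unlist(num) > 0))
  p
}

#' Run the APA event-detection pipeline end to end
#'
#' Stages: off-target and confidence filtering of raw calls
#' ([process_calls()]), per-gene clustering of retained sites
#' ([cluster_predicted_cs()]), usage frequencies per group
#' ([cs_frequencies()]), normal-versus-tumor shifts
#' ([cs_frequency_shifts()]), co-occurrence event detection
#' ([detect_events()]) with BH q-values over the full gene-by-eligible-
#' cohort grid ([bh_fdr()]), and 3' UTR trend classification
#' ([classify_trends()]). Deterministic for fixed inputs and parameters.
#'
#' @param calls Raw calls ([read_cs_calls()]) for all samples.
#' @param annotation An `apa_annotation` ([parse_gene_annotation()]).
#' @param genome `DNAStringSet` or FASTA path.
#' @param manifest Sample manifest (sample_id, cancer_type, condition).
#' @param params Parameter list from [apa_params()].
#' @param n_genes Number of genes in the hypothesis grid; defaults to the
#'   number of genes in the annotation. Supply the full target-list length
#'   when some target genes are absent from the annotation.
#' @return An `apa_result` object: tibbles `events` (with `q_value` and
#'   `trend`), `shifts`, `trend_detail`, `frequencies`, `clusters`, plus
#'   `eligible_types`, `m` (grid size), `stage_counts`, `genes`, `params`.
#' @export
run_apa_pipeline <- function(calls, annotation, genome, manifest,
                             params = apa_params(), n_genes = NULL) {
  manifest <- validate_manifest(manifest)
  n_genes <- n_genes %||% nrow(annotation$genes)
  eligible <- eligible_cancer_types(manifest, min_normal = params$min_normal)
  m <- n_genes * length(eligible)

  if (nrow(calls) == 0) {
    warn("No cleavage-site calls supplied; returning empty result tables.")
    processed <- calls
    clustered <- cluster_predicted_cs(
      tibble(sample_id = character(), gene_id = character(),
             cleavage_site = integer()),
      annotation, cutoff = params$cluster_cutoff
    )
    stage_counts <- list(raw = 0L, on_target = 0L, off_target = 0L,
                         strand_consistent = 0L, retained = 0L, dropped = 0L)
  } else {
    processed <- process_calls(calls, annotation, genome, params)
    stage_counts <- attr(processed, "stage_counts")
    clustered <- cluster_predicted_cs(
      processed, annotation, cutoff = params$cluster_cutoff
    )
  }

  freqs <- cs_frequencies(clustered$calls, manifest)
  shifts <- cs_frequency_shifts(
    freqs |> filter(.data$cancer_type %in% eligible),
    alpha = params$alpha
  )
  events <- detect_events(shifts, alpha = params$alpha)
  events$q_value <- bh_fdr(events$pair_p, m = max(m, nrow(events)))
  trend <- classify_trends(
    events, shifts, clustered$clusters, annotation,
    max_dist = params$trend_map_dist
  )
  events <- trend$events |>
    left_join(annotation$genes |> select("gene_id", "gene_name"), by = "gene_id") |>
    select("gene_id", "gene_name", everything())

  structure(
    list(
      events = events,
      shifts = shifts,
      trend_detail = trend$detail,
      frequencies = freqs,
      clusters = clustered$clusters,
      clustered_calls = clustered$calls,
      eligible_types = eligible,
      m = m,
      n_genes_grid = n_genes,
      stage_counts = stage_counts,
      genes = annotation$genes,
      params = params
    ),
    class = "apa_result"
  )
}

#' Run the pipeline from files on disk
#'
#' File-based front end: reads the GTF, genome FASTA, target-gene list,
#' manifest TSV, and a directory of per-sample KLEAT-style call tables,
#' runs [run_apa_pipeline()], and (optionally) writes `shifts.tsv`,
#' `events.tsv`, `clusters.bed`, and `report.txt` to `out_dir`.
#'
#' @param gtf,fasta,calls_dir,manifest,gene_list Input paths; `calls_dir`
#'   holds one `.tsv` per sample, named by sample ID.
#' @param out_dir Optional output directory.
#' @param params Parameter list from [apa_params()].
#' @return The `apa_result`, invisibly when `out_dir` is given.
#' @export
run_apa_pipeline_files <- function(gtf, fasta, calls_dir, manifest, gene_list,
                                   out_dir = NULL, params = apa_params()) {
  targets <- read_gene_list(gene_list)
  annotation <- parse_gene_annotation(gtf, targets,
                                      cluster_cutoff = params$cluster_cutoff)
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  paths <- sort(list.files(calls_dir, pattern = "\\.tsv$", full.names = TRUE))
  calls <- if (length(paths) == 0) {
    warn("Empty calls directory.")
    tibble(
      sample_id = character(), gene = character(),
      transcript_strand = character(), chromosome = character(),
      cleavage_site = integer(), length_of_tail_in_contig = integer(),
      number_of_bridge_reads = integer(),
      max_bridge_read_tail_length = integer()
    )
  } else {
    read_cs_calls(paths)
  }
  res <- run_apa_pipeline(calls, annotation, fasta, man,
                          params = params, n_genes = length(targets))
  if (!is.null(out_dir)) {
    write_apa_results(res, out_dir)
    return(invisible(res))
  }
  res
}

#' Write pipeline outputs with fixed filenames
#'
#' Writes `shifts.tsv`, `events.tsv`, `clusters.bed`, `trend_detail.tsv`,
#' and a plain-text `report.txt` (stage record counts, eligible cohorts,
#' grid size, parameter echo) under `out_dir`.
#'
#' @param result An `apa_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_apa_results <- function(result, out_dir) {
  stopifnot(inherits(result, "apa_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(result$shifts, file.path(out_dir, "shifts.tsv"))
  readr::write_tsv(result$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(
    result$trend_detail |> as_tibble(),
    file.path(out_dir, "trend_detail.tsv")
  )
  write_clusters_bed(
    result$clusters, result$genes, file.path(out_dir, "clusters.bed")
  )
  sc <- result$stage_counts
  report <- c(
    "APA pipeline run report",
    "=======================",
    paste0("raw calls:            ", sc$raw),
    paste0("on-target:            ", sc$on_target),
    paste0("off-target removed:   ", sc$off_target),
    paste0("strand-consistent:    ", sc$strand_consistent),
    paste0("confidence-retained:  ", sc$retained),
    paste0("predicted CS clusters:", " ", nrow(result$clusters)),
    paste0("eligible cancer types: ", paste(result$eligible_types, collapse = ", ")),
    paste0("genes in grid:        ", result$n_genes_grid),
    paste0("hypothesis tests (m): ", result$m),
    paste0("events detected:      ", nrow(result$events)),
    "",
    "parameters:",
    paste0(
      "  ", names(result$params), " = ",
      vapply(result$params, function(x) paste(x, collapse = ","), character(1))
    )
  )
  readr::write_lines(report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.apa_result <- function(x, ...) {
  cat(
    "<apa_result> ", nrow(x$events), " APA event(s) over m = ", x$m,
    " gene x cancer-type tests\n",
    "  eligible cancer types: ", paste(x$eligible_types, collapse = ", "), "\n",
    "  predicted CS clusters: ", nrow(x$clusters), "\n",
    sep = ""
  )
  if (nrow(x$events) > 0) {
    print(x$events |> select(any_of(c(
      "gene_name", "cancer_type", "n_up", "n_down", "pair_p", "q_value", "trend"
    ))), n = 10)
  }
  invisible(x)
}

#' @export
tidy.apa_result <- function(x, type = c("events", "shifts", "frequencies",
                                        "clusters", "trend_detail"), ...) {
  type <- match.arg(type)
  as_tibble(x[[type]])
}

#' @export
glance.apa_result <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_genes_with_events = length(unique(x$events$gene_id)),
    n_cancer_types = length(unique(x$events$cancer_type)),
    n_eligible_types = length(x$eligible_types),
    m = x$m,
    n_shortening = sum(x$events$trend == "shortening"),
    n_lengthening = sum(x$events$trend == "lengthening"),
    n_complex = sum(x$events$trend == "complex"),
    max_pair_p = if (nrow(x$events)) max(x$events$pair_p) else NA_real_,
    max_q = if (nrow(x$events)) max(x$events$q_value) else NA_real_
  )
}
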