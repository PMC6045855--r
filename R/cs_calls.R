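kleat_fields <- c(
  "gene", "transcript_strand", "chromosome", "cleavage_site",
  "length_of_tail_in_contig", "number_of_bridge_reads",
  "max_bridge_read_tail_length"
)
evidence_fields <- c(
  "length_of_tail_in_contig", "number_of_bridge_reads",
  "max_bridge_read_tail_length"
)

#' Read KLEAT-style cleavage-site call tables
#'
#' Each file is a tab-separated table with a header naming at least the seven
#' fields `gene`, `transcript_strand`, `chromosome`, `cleavage_site`,
#' `length_of_tail_in_contig`, `number_of_bridge_reads`, and
#' `max_bridge_read_tail_length`. Extra columns are dropped. Evidence fields
#' must be non-negative integers; offending rows raise an error reporting
#' their count.
#'
#' @param paths One or more file paths (one file per sample).
#' @param sample_ids Sample identifiers, one per path; defaults to the file
#'   basename without extension.
#' @return A tibble of raw calls with a leading `sample_id` column.
#' @export
read_cs_calls <- function(paths, sample_ids = NULL) {
  sample_ids <- sample_ids %||%
    stringr::str_remove(basename(paths), "\\.(tsv|txt)$")
  stopifnot(length(sample_ids) == length(paths))
  purrr::map2(paths, sample_ids, function(p, sid) {
    x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(kleat_fields, names(x))
    if (length(missing) > 0) {
      abort(paste0(
        "Call table ", p, " is missing required column(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    x <- x[kleat_fields]
    bad <- rep(FALSE, nrow(x))
    for (f in c("cleavage_site", evidence_fields)) {
      v <- x[[f]]
      bad <- bad | is.na(suppressWarnings(as.numeric(v))) |
        (suppressWarnings(as.numeric(v)) %% 1 != 0) |
        (suppressWarnings(as.numeric(v)) < 0)
    }
    if (any(bad)) {
      abort(paste0(
        "Call table ", p, ": ", sum(bad),
        " row(s) with non-integer or negative coordinate/evidence values."
      ))
    }
    x |>
      mutate(
        sample_id = sid,
        across(all_of(c("cleavage_site", evidence_fields)), as.integer),
        across(all_of(c("gene", "transcript_strand", "chromosome")), as.character)
      ) |>
      select("sample_id", all_of(kleat_fields))
  }) |>
    list_rbind()
}

#' Keep calls belonging to the target genes
#'
#' Drops off-target calls, i.e. calls whose `gene` is neither a gene name
#' nor a gene ID of the annotation's target set. The retained fraction is
#' recorded in the `retention` attribute of the result.
#'
#' @param calls Raw-call tibble (see [read_cs_calls()]).
#' @param annotation An `apa_annotation`.
#' @return The on-target subset, with a `gene_id` column resolved from the
#'   annotation.
#' @export
filter_on_target <- function(calls, annotation) {
  stopifnot(inherits(annotation, "apa_annotation"))
  key <- bind_rows(
    annotation$genes |> select("gene_id", gene = "gene_name"),
    annotation$genes |> select("gene_id", gene = "gene_id")
  ) |> distinct()
  out <- calls |> inner_join(key, by = "gene", relationship = "many-to-one")
  attr(out, "retention") <- if (nrow(calls) > 0) nrow(out) / nrow(calls) else NA_real_
  out
}

#' Assign each predicted cleavage site to its closest annotated one
#'
#' For every call, finds the clustered annotated cleavage site of the call's
#' gene minimizing the absolute genomic distance; ties are broken toward the
#' transcript-upstream candidate (smaller coordinate on the plus strand,
#' larger on the minus strand). The signed distance is positive when the
#' predicted site lies transcript-downstream of the annotated one. Calls for
#' genes without any annotated cleavage site get `NA` in both columns and
#' are flagged unassignable.
#'
#' @param calls Tibble with `gene_id` and `cleavage_site` columns.
#' @param annotation An `apa_annotation`.
#' @return `calls` with `nearest_annotated_cs` and `signed_distance` added.
#' @export
assign_nearest_annotated <- function(calls, annotation) {
  if (nrow(calls) == 0) {
    return(calls |> mutate(
      nearest_annotated_cs = character(), signed_distance = double()
    ))
  }
  reps <- annotation$cs |>
    left_join(annotation$genes |> select("gene_id", "strand"), by = "gene_id") |>
    select("gene_id", "cs_id", "representative_pos", "strand")
  sites <- calls |>
    distinct(.data$gene_id, .data$cleavage_site) |>
    left_join(reps, by = "gene_id", relationship = "many-to-many") |>
    mutate(
      signed_distance = ifelse(
        .data$strand == "+",
        .data$cleavage_site - .data$representative_pos,
        .data$representative_pos - .data$cleavage_site
      ),
      # tie-break rank: upstream = smaller coordinate on +, larger on -
      upstream_rank = ifelse(
        .data$strand == "+", .data$representative_pos, -.data$representative_pos
      )
    ) |>
    group_by(.data$gene_id, .data$cleavage_site) |>
    arrange(abs(.data$signed_distance), .data$upstream_rank, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(
      "gene_id", "cleavage_site",
      nearest_annotated_cs = "cs_id", "signed_distance"
    )
  calls |> left_join(sites, by = c("gene_id", "cleavage_site"))
}

#' Ranked polyadenylation-signal hexamers
#'
#' The twelve canonical PAS hexamer variants in decreasing order of usage,
#' with AATAAA and ATTAAA (the two strongest signals) first. Only the top
#' two participate in the evidence-based retention criterion; the rest are
#' reported when found.
#'
#' @return Character vector of 6-mers, strongest first.
#' @export
pas_motifs <- function() {
  c(
    "AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA"
  )
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- stringr::str_extract(names(genome), "^\\S+")
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

# transcript-sense upstream window of `window` bases ending adjacent to the CS
upstream_window <- function(genome, chrom, strand, cs_pos, window) {
  if (!chrom %in% names(genome)) {
    abort(paste0("Chromosome ", chrom, " not present in the genome."))
  }
  chrlen <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    from <- max(1, cs_pos - window)
    to <- cs_pos - 1
    if (to < from) return("")
    as.character(Biostrings::subseq(genome[[chrom]], from, to))
  } else {
    from <- cs_pos + 1
    to <- min(chrlen, cs_pos + window)
    if (to < from) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], from, to)
    ))
  }
}

#' Search the upstream window for a polyadenylation-signal hexamer
#'
#' Scans the `window` bases immediately transcript-upstream of a cleavage
#' site (truncated at the chromosome boundary) for the ranked PAS motifs.
#' The hexamer must lie entirely within the window. Among all hits the
#' highest-ranked motif wins; among hits of the same motif, the one closest
#' to the cleavage site. The reported distance is anchored at the hexamer's
#' transcript-3' end: distance d means the hexamer occupies upstream
#' positions d+5 through d, so a hexamer abutting the cleavage site has
#' distance 1.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cs_pos 1-based cleavage-site coordinate.
#' @param window Upstream window size in bp (default 50).
#' @param motifs Ranked motif list, strongest first (default [pas_motifs()]).
#' @return A one-row tibble (`hexamer`, `distance`, `rank`) or `NULL` when no
#'   motif occurs in the window.
#' @export
find_pas_hexamer <- function(genome, chrom, strand, cs_pos, window = 50,
                             motifs = pas_motifs()) {
  genome <- load_genome(genome)
  w <- upstream_window(genome, chrom, strand, cs_pos, window)
  scan_window_for_pas(w, motifs)
}

scan_window_for_pas <- function(w, motifs) {
  L <- nchar(w)
  if (L < 6) return(NULL)
  subject <- Biostrings::DNAString(w)
  for (r in seq_along(motifs)) {
    # matchPattern reports overlapping occurrences, which gregexpr would skip
    starts <- Biostrings::start(Biostrings::matchPattern(motifs[r], subject))
    if (length(starts) == 0) next
    dists <- L - (starts + 5) + 1
    return(tibble(hexamer = motifs[r], distance = min(dists), rank = r))
  }
  NULL
}

# vectorized PAS annotation over the distinct sites of a call table
annotate_pas <- function(calls, genome, window = 50, motifs = pas_motifs()) {
  genome <- load_genome(genome)
  sites <- calls |>
    distinct(.data$chromosome, .data$transcript_strand, .data$cleavage_site)
  hits <- pmap(
    list(sites$chromosome, sites$transcript_strand, sites$cleavage_site),
    function(chrom, strand, pos) {
      h <- scan_window_for_pas(
        upstream_window(genome, chrom, strand, pos, window), motifs
      )
      if (is.null(h)) {
        tibble(pas_hexamer = NA_character_, pas_distance = NA_integer_,
               pas_rank = NA_integer_)
      } else {
        tibble(pas_hexamer = h$hexamer, pas_distance = as.integer(h$distance),
               pas_rank = as.integer(h$rank))
      }
    }
  ) |> list_rbind()
  calls |> left_join(
    bind_cols(sites, hits),
    by = c("chromosome", "transcript_strand", "cleavage_site")
  )
}

#' Two-criterion confidence filter for predicted cleavage sites
#'
#' A call is retained when it satisfies at least one of:
#' \describe{
#'   \item{A (annotation proximity)}{its absolute distance to the closest
#'     clustered annotated cleavage site is at most `max_annot_dist` bp;}
#'   \item{B (independent poly(A) evidence)}{one of the two strongest PAS
#'     hexamers lies in the upstream window AND at least one evidence field
#'     passes: `length_of_tail_in_contig >= tail_min`,
#'     `number_of_bridge_reads >= bridge_min`, or
#'     `max_bridge_read_tail_length >= bridge_tail_min`.}
#' }
#' Criterion A recovers already-annotated sites; criterion B is
#' annotation-independent and admits potentially novel sites.
#'
#' @param calls Tibble carrying `signed_distance`, `pas_hexamer`, and the
#'   three evidence fields (see [assign_nearest_annotated()] and
#'   [find_pas_hexamer()]).
#' @param max_annot_dist Criterion-A distance bound in bp (default 25).
#' @param strong_motifs Motifs eligible for criterion B (default AATAAA,
#'   ATTAAA).
#' @param tail_min,bridge_min,bridge_tail_min Criterion-B evidence thresholds
#'   (defaults 4, 2, 4).
#' @return `calls` with logical `retained` and label `criterion` (`"A"`,
#'   `"B"`, `"A+B"`, or `NA` for dropped calls) columns added.
#' @export
confidence_filter <- function(calls, max_annot_dist = 25,
                              strong_motifs = c("AATAAA", "ATTAAA"),
                              tail_min = 4, bridge_min = 2,
                              bridge_tail_min = 4) {
  crit_a <- !is.na(calls$signed_distance) &
    abs(calls$signed_distance) <= max_annot_dist
  crit_b <- !is.na(calls$pas_hexamer) &
    calls$pas_hexamer %in% strong_motifs &
    (calls$length_of_tail_in_contig >= tail_min |
       calls$number_of_bridge_reads >= bridge_min |
       calls$max_bridge_read_tail_length >= bridge_tail_min)
  calls |>
    mutate(
      retained = crit_a | crit_b,
      criterion = case_when(
        crit_a & crit_b ~ "A+B",
        crit_a ~ "A",
        crit_b ~ "B",
        .default = NA_character_
      )
    )
}

#' Post-process raw cleavage-site calls
#'
#' Runs the full call-level pipeline stage: off-target removal, strand
#' consistency check against the gene model, nearest-annotated-site
#' assignment, PAS hexamer search, and the two-criterion confidence filter.
#' Per-stage record counts are recorded in the `stage_counts` attribute.
#'
#' @param calls Raw calls from [read_cs_calls()].
#' @param annotation An `apa_annotation`.
#' @param genome A `DNAStringSet` or FASTA path.
#' @param params Parameter list from [apa_params()].
#' @return Tibble of retained calls with assignment, PAS, and criterion
#'   columns; dropped calls are excluded.
#' @export
process_calls <- function(calls, annotation, genome, params = apa_params()) {
  counts <- list(raw = nrow(calls))
  on_target <- filter_on_target(calls, annotation)
  counts$on_target <- nrow(on_target)
  counts$off_target <- counts$raw - counts$on_target

  strands <- annotation$genes |> select("gene_id", model_strand = "strand")
  checked <- on_target |> left_join(strands, by = "gene_id")
  mismatch <- checked$transcript_strand != checked$model_strand
  if (any(mismatch)) {
    warn(paste0(
      sum(mismatch), " call(s) dropped: transcript_strand disagrees with the gene model."
    ))
  }
  checked <- checked |> filter(!mismatch) |> select(-"model_strand")
  counts$strand_consistent <- nrow(checked)

  assigned <- assign_nearest_annotated(checked, annotation)
  n_unassignable <- sum(is.na(assigned$nearest_annotated_cs))
  if (n_unassignable > 0) {
    warn(paste0(n_unassignable, " call(s) unassignable: gene has no annotated cleavage site."))
  }
  with_pas <- annotate_pas(
    assigned, genome,
    window = params$pas_window, motifs = params$pas_motifs
  )
  filtered <- confidence_filter(
    with_pas,
    max_annot_dist = params$max_annot_dist,
    strong_motifs = params$strong_motifs,
    tail_min = params$tail_min,
    bridge_min = params$bridge_min,
    bridge_tail_min = params$bridge_tail_min
  )
  counts$retained <- sum(filtered$retained)
  counts$dropped <- counts$strand_consistent - counts$retained
  out <- filtered |> filter(.data$retained)
  attr(out, "stage_counts") <- counts
  out
}

#' Cluster retained predicted cleavage sites per gene
#'
#' Pools the retained calls of each gene across all samples, clusters their
#' coordinates with [single_linkage_clusters()] (multiplicity = number of
#' supporting calls), labels clusters by the first letter of the gene name
#' followed by the ascending-coordinate index (e.g. `F2`), and merges calls
#' of the same sample that map to one representative
#' ([assign_to_representatives()]).
#'
#' @param calls Retained calls from [process_calls()] (needs `sample_id`,
#'   `gene_id`, `cleavage_site`).
#' @param annotation An `apa_annotation` (for gene names and strand).
#' @param cutoff Clustering gap cutoff in bp (default 20).
#' @return A list with `clusters` (gene_id, cs_label, representative_pos,
#'   n_calls, members) and `calls` (per sample × cluster: sample_id, gene_id,
#'   cs_label, representative_pos, merged evidence).
#' @export
cluster_predicted_cs <- function(calls, annotation, cutoff = 20) {
  empty <- list(
    clusters = tibble(
      gene_id = character(), cs_label = character(),
      representative_pos = double(), n_calls = integer(), members = list()
    ),
    calls = tibble(
      sample_id = character(), gene_id = character(), cs_label = character(),
      representative_pos = double()
    )
  )
  if (nrow(calls) == 0) {
    return(empty)
  }
  per_gene <- calls |>
    group_by(.data$gene_id) |>
    group_map(function(g, key) {
      gene_id <- key$gene_id
      gene_name <- annotation$genes$gene_name[match(gene_id, annotation$genes$gene_id)]
      letter <- toupper(substr(gene_name %||% "X", 1, 1))
      cl <- single_linkage_clusters(g$cleavage_site, cutoff = cutoff) |>
        arrange(.data$representative) |>
        mutate(cs_label = paste0(letter, row_number()))
      merged <- assign_to_representatives(
        g |> mutate(sample_id = .data$sample_id), cl
      ) |>
        left_join(cl |> select("cluster", "cs_label"), by = "cluster")
      list(
        clusters = cl |>
          mutate(
            gene_id = gene_id,
            n_calls = map_int(.data$members, length)
          ) |>
          select("gene_id", "cs_label", representative_pos = "representative",
                 "n_calls", "members"),
        calls = merged |>
          mutate(gene_id = gene_id) |>
          select("sample_id", "gene_id", "cs_label",
                 representative_pos = "representative",
                 any_of(c("n_merged", evidence_fields)))
      )
    }) |>
    purrr::transpose()
  list(
    clusters = list_rbind(per_gene$clusters),
    calls = list_rbind(per_gene$calls)
  )
}

#' Export predicted cleavage-site clusters as BED
#'
#' Writes representative positions as 0-based half-open single-base
#' intervals, named by gene and cluster label.
#'
#' @param clusters `clusters` tibble from [cluster_predicted_cs()].
#' @param genes An `apa_annotation` or its `genes` tibble (chromosome and
#'   strand lookup).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, genes, path) {
  if (inherits(genes, "apa_annotation")) genes <- genes$genes
  bed <- clusters |>
    left_join(genes, by = "gene_id") |>
    transmute(
      chrom = .data$chrom,
      start = as.integer(.data$representative_pos) - 1L,
      end = as.integer(.data$representative_pos),
      name = paste0(.data$gene_name, ":", .data$cs_label),
      score = .data$n_calls,
      strand = .data$strand
    ) |>
    arrange(.data$chrom, .data$start)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
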