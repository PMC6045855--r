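#' Build per-gene annotation models from an Ensembl-dialect GTF
#'
#' Extracts, for each target gene, the annotated cleavage sites (transcript
#' 3' ends), stop codons, and the mapping between them, from protein-coding
#' and nonsense-mediated-decay (NMD) transcripts whose CDS 3' end is
#' complete (no `cds_end_NF` tag). Transcript-level identity is discarded
#' after the cleavage-site-to-stop-codon map is extracted, and mapping pairs
#' made redundant by multiple transcripts sharing the same 3' end and stop
#' codon are collapsed. Annotated cleavage sites are then grouped by
#' [single_linkage_clusters()] with the given gap cutoff.
#'
#' Coordinates are 1-based and fully closed, as in the GTF. A transcript's
#' cleavage site is its 3'-most base (`max(end)` of its exons on the plus
#' strand, `min(start)` on the minus strand); a stop codon's position is its
#' transcript-3'-most genomic base. Transcripts of other biotypes, tagged
#' `cds_end_NF`, or lacking a `stop_codon` feature contribute nothing (the
#' last with a warning, since no 3' UTR can be anchored).
#'
#' @param gtf Path to a GTF file (Ensembl attribute dialect; both
#'   `transcript_biotype` and `gene_biotype` keys are understood, with the
#'   `source` column as a fallback used by older Ensembl releases).
#' @param target_genes Character vector of gene symbols or Ensembl gene IDs.
#'   Genes absent from the annotation are skipped with a warning.
#' @param cluster_cutoff Gap cutoff in bp for clustering annotated cleavage
#'   sites (default 20).
#' @return An `apa_annotation` object: a list of tibbles `genes` (gene_id,
#'   gene_name, chrom, strand), `cs` (per clustered annotated cleavage site:
#'   gene_id, cs_id, representative_pos, members list-column), `stops`
#'   (gene_id, stop_id, pos, biotypes, is_nmd), and `cs_stop_map` (gene_id,
#'   cs_id, stop_id), with the clustering cutoff recorded in `params`.
#' @export
parse_gene_annotation <- function(gtf, target_genes, cluster_cutoff = 20) {
  stopifnot(is.character(target_genes), length(target_genes) > 0)
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as_tibble(as.data.frame(gr, stringsAsFactors = FALSE))
  if (!all(c("type", "gene_id", "transcript_id") %in% names(df))) {
    abort("GTF lacks required gene_id/transcript_id attributes.")
  }
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  # rtracklayer keeps only one value of the repeated Ensembl `tag` attribute,
  # so the cds_end_NF flag can be masked by another tag; recover it from the
  # raw attribute text instead.
  nf_tx <- cds_end_nf_transcripts(gtf)

  biotype <- df$transcript_biotype %||% df$gene_biotype %||% as.character(df$source)
  df$biotype <- as.character(biotype)
  if (is.null(df$gene_name)) df$gene_name <- df$gene_id

  exons <- df |> filter(.data$type == "exon", !is.na(.data$transcript_id))
  if (nrow(exons) == 0) {
    # some dialects carry only transcript rows; fall back on their extent
    exons <- df |> filter(.data$type == "transcript", !is.na(.data$transcript_id))
  }
  tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      gene_name = .data$gene_name[1],
      chrom = .data$seqnames[1],
      strand = .data$strand[1],
      biotype = .data$biotype[1],
      cs_pos = if (.data$strand[1] == "-") min(.data$start) else max(.data$end),
      .groups = "drop"
    )

  stops <- df |>
    filter(.data$type == "stop_codon", !is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(
      stop_codon_pos = if (.data$strand[1] == "-") min(.data$start) else max(.data$end),
      .groups = "drop"
    )

  tx <- tx |>
    filter(.data$biotype %in% c("protein_coding", "nonsense_mediated_decay")) |>
    filter(!(.data$transcript_id %in% nf_tx)) |>
    left_join(stops, by = "transcript_id")

  n_no_stop <- sum(is.na(tx$stop_codon_pos))
  if (n_no_stop > 0) {
    warn(paste0(
      n_no_stop, " CDS-3'-complete transcript(s) lack a stop_codon feature ",
      "and were excluded (no 3' UTR can be anchored)."
    ))
    tx <- tx |> filter(!is.na(.data$stop_codon_pos))
  }

  hit <- tx$gene_name %in% target_genes | tx$gene_id %in% target_genes
  tx <- tx[hit, , drop = FALSE]
  found <- unique(c(tx$gene_name, tx$gene_id))
  missing <- setdiff(target_genes, found)
  if (length(missing) > 0) {
    warn(paste0(
      "Target gene(s) absent from annotation (skipped): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(tx) == 0) {
    abort("No target gene has an eligible transcript in the annotation.")
  }

  models <- tx |>
    arrange(.data$gene_id) |>
    group_by(.data$gene_id) |>
    group_map(~ build_gene_model(.x, .y$gene_id, cluster_cutoff)) |>
    purrr::transpose()

  new_apa_annotation(
    genes = list_rbind(models$gene),
    cs = list_rbind(models$cs),
    stops = list_rbind(models$stops),
    cs_stop_map = list_rbind(models$map),
    cluster_cutoff = cluster_cutoff
  )
}

# transcript_ids carrying the Ensembl cds_end_NF tag, from raw GTF text
cds_end_nf_transcripts <- function(gtf) {
  lines <- readr::read_lines(gtf)
  flagged <- lines[grepl('tag "cds_end_NF"', lines, fixed = TRUE)]
  if (length(flagged) == 0) {
    return(character())
  }
  ids <- stringr::str_match(flagged, 'transcript_id "([^"]+)"')[, 2]
  unique(ids[!is.na(ids)])
}

# one gene's model: cluster its annotated CSs, index stops, dedup the map
build_gene_model <- function(tx, gene_id, cluster_cutoff) {
  if (length(unique(tx$strand)) != 1 || length(unique(tx$chrom)) != 1) {
    abort(paste0("Gene ", gene_id, " has inconsistent strand or chromosome."))
  }
  strand <- tx$strand[1]
  bad <- if (strand == "+") {
    tx$stop_codon_pos > tx$cs_pos
  } else {
    tx$stop_codon_pos < tx$cs_pos
  }
  if (any(bad)) {
    abort(paste0(
      "Gene ", gene_id, ": stop codon transcript-downstream of the 3' end in ",
      sum(bad), " transcript(s); annotation is inconsistent."
    ))
  }
  gene_name <- tx$gene_name[1]
  letter <- toupper(substr(gene_name, 1, 1))
  if (is.na(letter) || letter == "") letter <- "X"

  clusters <- single_linkage_clusters(tx$cs_pos, cutoff = cluster_cutoff) |>
    arrange(.data$representative) |>
    mutate(cs_id = paste0(letter, row_number()))

  stop_tbl <- tx |>
    group_by(pos = .data$stop_codon_pos) |>
    summarise(
      biotypes = paste(sort(unique(.data$biotype)), collapse = ","),
      .groups = "drop"
    ) |>
    arrange(.data$pos) |>
    mutate(
      stop_id = paste0("s", row_number()),
      is_nmd = grepl("nonsense_mediated_decay", .data$biotypes, fixed = TRUE)
    )

  # cs cluster of each transcript, by membership of its 3' end
  member_lookup <- clusters |>
    select("cs_id", "members") |>
    unnest("members") |>
    distinct()
  map <- tx |>
    inner_join(member_lookup, by = c(cs_pos = "members"),
               relationship = "many-to-many") |>
    inner_join(stop_tbl |> select("pos", "stop_id"),
               by = c(stop_codon_pos = "pos")) |>
    distinct(.data$cs_id, .data$stop_id) |>
    arrange(.data$cs_id, .data$stop_id)

  list(
    gene = tibble(
      gene_id = gene_id, gene_name = gene_name,
      chrom = tx$chrom[1], strand = strand
    ),
    cs = clusters |>
      mutate(gene_id = gene_id) |>
      select("gene_id", "cs_id", representative_pos = "representative", "members"),
    stops = stop_tbl |>
      mutate(gene_id = gene_id) |>
      select("gene_id", "stop_id", "pos", "biotypes", "is_nmd"),
    map = map |> mutate(gene_id = gene_id) |> select("gene_id", "cs_id", "stop_id")
  )
}

new_apa_annotation <- function(genes, cs, stops, cs_stop_map, cluster_cutoff) {
  structure(
    list(
      genes = genes, cs = cs, stops = stops, cs_stop_map = cs_stop_map,
      params = list(cluster_cutoff = cluster_cutoff)
    ),
    class = "apa_annotation"
  )
}

#' @export
print.apa_annotation <- function(x, ...) {
  cat(
    "<apa_annotation> ", nrow(x$genes), " gene(s), ",
    nrow(x$cs), " clustered annotated CS(s), ",
    nrow(x$stops), " stop codon(s), ",
    nrow(x$cs_stop_map), " CS-stop map pair(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.apa_annotation <- function(x, ...) {
  x$cs |>
    left_join(x$genes, by = "gene_id") |>
    left_join(
      x$cs_stop_map |> group_by(.data$gene_id, .data$cs_id) |>
        summarise(n_stop_codons = n(), .groups = "drop"),
      by = c("gene_id", "cs_id")
    ) |>
    mutate(n_stop_codons = tidyr::replace_na(.data$n_stop_codons, 0L)) |>
    select(
      "gene_id", "gene_name", "chrom", "strand",
      "cs_id", "representative_pos", "n_stop_codons", "members"
    )
}

#' @export
glance.apa_annotation <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_annotated_cs = nrow(x$cs),
    n_stop_codons = nrow(x$stops),
    n_map_pairs = nrow(x$cs_stop_map),
    cluster_cutoff = x$params$cluster_cutoff
  )
}

#' 3' UTR length implied by a cleavage site and a stop codon
#'
#' The 3' UTR is counted in transcript orientation from the base immediately
#' after the stop codon's 3'-most base through the cleavage site, inclusive.
#' The result is therefore `cs_pos - stop_codon_pos` on the plus strand and
#' `stop_codon_pos - cs_pos` on the minus strand. A cleavage site
#' transcript-upstream of the stop codon is an invalid pairing and errors.
#'
#' @param cs_pos,stop_codon_pos 1-based genomic coordinates (vectorized).
#' @param strand `"+"` or `"-"` (vectorized, recycled).
#' @return Non-negative integer length(s) in nt.
#' @examples
#' utr_length(1500, 1000, "+") # 500
#' utr_length(1400, 2000, "-") # 600
#' @export
utr_length <- function(cs_pos, stop_codon_pos, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  len <- ifelse(strand == "+", cs_pos - stop_codon_pos, stop_codon_pos - cs_pos)
  if (any(len < 0)) {
    abort("Invalid (cleavage site, stop codon) pair: CS is transcript-upstream of the stop codon.")
  }
  as.integer(len)
}

#' Read a target-gene list
#'
#' One gene symbol or Ensembl gene ID per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path File path.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- stringr::str_trim(x)
  x[x != "" & !stringr::str_starts(x, "#")]
}

#' Serialize or restore per-gene annotation models as TSV
#'
#' The long format has one row per record: columns `gene_id`, `gene_name`,
#' `chrom`, `strand`, `record_type` (`cs`, `stop`, or `map`), `id`, `pos`,
#' `biotypes`, `member_positions` (comma-joined). Map rows store the pair as
#' `id = "<cs_id>-><stop_id>"`.
#'
#' @param annotation An `apa_annotation` object.
#' @param path Output (or input) TSV path.
#' @return `write_gene_models()` returns `path` invisibly;
#'   `read_gene_models()` returns an `apa_annotation`.
#' @export
write_gene_models <- function(annotation, path) {
  stopifnot(inherits(annotation, "apa_annotation"))
  g <- annotation$genes
  cs_rows <- annotation$cs |>
    left_join(g, by = "gene_id") |>
    mutate(
      record_type = "cs", id = .data$cs_id, pos = .data$representative_pos,
      biotypes = NA_character_,
      member_positions = map_chr(.data$members, ~ paste(.x, collapse = ","))
    )
  stop_rows <- annotation$stops |>
    left_join(g, by = "gene_id") |>
    mutate(
      record_type = "stop", id = .data$stop_id,
      member_positions = NA_character_
    )
  map_rows <- annotation$cs_stop_map |>
    left_join(g, by = "gene_id") |>
    mutate(
      record_type = "map", id = paste0(.data$cs_id, "->", .data$stop_id),
      pos = NA_real_, biotypes = NA_character_, member_positions = NA_character_
    )
  cols <- c(
    "gene_id", "gene_name", "chrom", "strand",
    "record_type", "id", "pos", "biotypes", "member_positions"
  )
  out <- bind_rows(
    cs_rows |> select(all_of(cols)),
    stop_rows |> select(all_of(cols)),
    map_rows |> select(all_of(cols))
  ) |>
    arrange(.data$gene_id, .data$record_type, .data$id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_gene_models
#' @param cluster_cutoff Cutoff recorded in the restored object (the models
#'   themselves are stored already clustered).
#' @export
read_gene_models <- function(path, cluster_cutoff = 20) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- x |> distinct(.data$gene_id, .data$gene_name, .data$chrom, .data$strand)
  cs <- x |>
    filter(.data$record_type == "cs") |>
    mutate(members = map(
      .data$member_positions,
      ~ as.numeric(strsplit(as.character(.x), ",", fixed = TRUE)[[1]])
    )) |>
    select("gene_id", cs_id = "id", representative_pos = "pos", "members")
  stops <- x |>
    filter(.data$record_type == "stop") |>
    mutate(is_nmd = grepl("nonsense_mediated_decay", .data$biotypes, fixed = TRUE)) |>
    select("gene_id", stop_id = "id", "pos", "biotypes", "is_nmd")
  map_tbl <- x |>
    filter(.data$record_type == "map") |>
    tidyr::separate_wider_delim("id", delim = "->", names = c("cs_id", "stop_id")) |>
    select("gene_id", "cs_id", "stop_id")
  new_apa_annotation(genes, cs, stops, map_tbl, cluster_cutoff)
}
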