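#' Map predicted cleavage-site clusters to annotated ones for trend calls
#'
#' Each predicted representative is mapped to the closest clustered
#' annotated cleavage site of its gene (ties toward the transcript-upstream
#' candidate). Representatives farther than `max_dist` bp from any annotated
#' site are flagged potentially novel and excluded from trend resolution,
#' because their stop codon — and hence 3' UTR length — is uncertain.
#'
#' @param clusters `clusters` tibble from [cluster_predicted_cs()]
#'   (`gene_id`, `cs_label`, `representative_pos`).
#' @param annotation An `apa_annotation`.
#' @param max_dist Maximum mapping distance in bp (default 25).
#' @return `clusters` with `annotated_cs` (NA when novel), `annot_distance`
#'   (signed, positive = transcript-downstream), and logical `novel` added.
#' @export
map_for_trend <- function(clusters, annotation, max_dist = 25) {
  mapped <- clusters |>
    select("gene_id", "cs_label", cleavage_site = "representative_pos") |>
    assign_nearest_annotated(annotation) |>
    mutate(
      novel = is.na(.data$signed_distance) | abs(.data$signed_distance) > max_dist,
      annotated_cs = ifelse(.data$novel, NA_character_, .data$nearest_annotated_cs)
    ) |>
    select("gene_id", "cs_label", annot_distance = "signed_distance",
           "annotated_cs", "novel")
  clusters |> left_join(mapped, by = c("gene_id", "cs_label"))
}

#' Resolve a 3' UTR length-change trend from per-site details
#'
#' Applies the deterministic trend rule to one event's significant cleavage
#' sites:
#' \enumerate{
#'   \item keep sites that mapped to an annotated cleavage site associated
#'     with exactly one stop codon (novel sites and multi-stop sites carry
#'     no unambiguous 3' UTR length and are ignored);
#'   \item restrict to the stop codon carrying the most such sites — a tie
#'     between stop codons is unresolvable and yields `complex`;
#'   \item if no up- or no down-shifted site remains, the event is `complex`;
#'   \item if every up site's 3' UTR is shorter than every down site's, the
#'     event is `shortening`; if every up site's is longer, `lengthening`;
#'     anything else is `complex`.
#' }
#'
#' @param detail Tibble with one row per significant cleavage site:
#'   `direction` (`"up"`/`"down"`), `stop_id` (NA when the site is novel or
#'   maps to zero or several stop codons), `utr_len` (nt, NA when
#'   ambiguous).
#' @return `"shortening"`, `"lengthening"`, or `"complex"`.
#' @export
resolve_trend <- function(detail) {
  usable <- detail |>
    filter(!is.na(.data$stop_id), !is.na(.data$utr_len),
           .data$direction %in% c("up", "down"))
  if (nrow(usable) == 0) {
    return("complex")
  }
  stop_counts <- usable |> count(.data$stop_id, sort = TRUE)
  top <- stop_counts$n[1]
  if (sum(stop_counts$n == top) > 1) {
    return("complex")
  }
  kept <- usable |> filter(.data$stop_id == stop_counts$stop_id[1])
  up <- kept$utr_len[kept$direction == "up"]
  down <- kept$utr_len[kept$direction == "down"]
  if (length(up) == 0 || length(down) == 0) {
    return("complex")
  }
  if (max(up) < min(down)) {
    return("shortening")
  }
  if (min(up) > max(down)) {
    return("lengthening")
  }
  "complex"
}

# per-significant-CS trend detail for one gene: mapping, stop codons, lengths
build_trend_detail <- function(sig_shifts, clusters, annotation, max_dist = 25) {
  mapped <- map_for_trend(clusters, annotation, max_dist = max_dist)
  stops_per_cs <- annotation$cs_stop_map |>
    left_join(
      annotation$stops |> select("gene_id", "stop_id", stop_pos = "pos", "is_nmd"),
      by = c("gene_id", "stop_id")
    )
  detail <- sig_shifts |>
    left_join(
      mapped |> select("gene_id", "cs_label", "annotated_cs", "annot_distance", "novel"),
      by = c("gene_id", "cs_label")
    ) |>
    left_join(
      stops_per_cs |> rename(annotated_cs = "cs_id"),
      by = c("gene_id", "annotated_cs"),
      relationship = "many-to-many"
    ) |>
    left_join(annotation$genes |> select("gene_id", "strand"), by = "gene_id") |>
    left_join(
      annotation$cs |> select("gene_id", annotated_cs = "cs_id",
                              annot_pos = "representative_pos"),
      by = c("gene_id", "annotated_cs")
    ) |>
    group_by(.data$gene_id, .data$cancer_type, .data$cs_label) |>
    mutate(n_stops = sum(!is.na(.data$stop_id))) |>
    ungroup()
  detail <- detail |>
    mutate(
      usable = !.data$novel & .data$n_stops == 1,
      exclusion = case_when(
        .data$novel ~ "novel",
        .data$n_stops == 0 ~ "unmapped_stop",
        .data$n_stops > 1 ~ "multi_stop",
        .default = NA_character_
      ),
      stop_id = ifelse(.data$usable, .data$stop_id, NA_character_),
      is_nmd = ifelse(.data$usable, .data$is_nmd, NA),
      utr_len = NA_integer_
    )
  ok <- detail$usable & !is.na(detail$stop_pos) & !is.na(detail$annot_pos)
  detail$utr_len[ok] <- utr_length(
    detail$annot_pos[ok], detail$stop_pos[ok], detail$strand[ok]
  )
  # a site mapped to several stop codons collapses to one ignored row
  detail |>
    distinct(
      .data$gene_id, .data$cancer_type, .data$cs_label, .data$direction,
      .data$p_value, .data$annotated_cs, .data$annot_distance,
      .data$stop_id, .data$is_nmd, .data$utr_len, .data$exclusion
    )
}

#' Classify each APA event's 3' UTR length trend
#'
#' For every detected event, maps its significantly shifted cleavage sites
#' to annotated ones ([map_for_trend()]), resolves the per-site 3' UTR
#' lengths through the cleavage-site-to-stop-codon map, and labels the event
#' `shortening`, `lengthening`, or `complex` ([resolve_trend()]). Stop
#' codons used by NMD transcripts are flagged in the detail table but do not
#' change the label.
#'
#' @param events Output of [detect_events()].
#' @param shifts Output of [cs_frequency_shifts()].
#' @param clusters `clusters` tibble from [cluster_predicted_cs()].
#' @param annotation An `apa_annotation`.
#' @param max_dist Mapping distance cutoff in bp (default 25).
#' @return A list: `events` (input plus `trend` column) and `detail` (one
#'   row per significant site per event: mapping, stop codon, NMD flag,
#'   3' UTR length, exclusion reason).
#' @export
classify_trends <- function(events, shifts, clusters, annotation, max_dist = 25) {
  if (nrow(events) == 0) {
    return(list(
      events = events |> mutate(trend = character()),
      detail = tibble()
    ))
  }
  sig <- shifts |>
    semi_join(events, by = c("gene_id", "cancer_type")) |>
    filter(.data$direction %in% c("up", "down"))
  detail <- build_trend_detail(sig, clusters, annotation, max_dist = max_dist)
  trends <- detail |>
    group_by(.data$gene_id, .data$cancer_type) |>
    group_modify(~ tibble(trend = resolve_trend(.x))) |>
    ungroup()
  list(
    events = events |> left_join(trends, by = c("gene_id", "cancer_type")),
    detail = detail
  )
}
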