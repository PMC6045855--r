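#' Single-linkage clustering of cleavage-site coordinates
#'
#' Groups 1-based genomic coordinates so that any two positions that are
#' `cutoff` bp or less apart — directly or through a chain of intermediate
#' members — end up in the same cluster. In one dimension this is exactly
#' single-linkage hierarchical clustering cut at the gap threshold: sort the
#' coordinates and split wherever the gap between consecutive positions
#' exceeds the cutoff. The same routine serves both annotated transcript 3'
#' ends and predicted cleavage sites.
#'
#' Repeated positions are meaningful: multiplicity counts as support when the
#' representative coordinate is chosen (see [cluster_representative()]).
#'
#' @param positions Numeric vector of 1-based coordinates on one chromosome
#'   and gene. May contain repeats; order is irrelevant.
#' @param cutoff Maximum gap in bp bridged within a cluster (default 20).
#' @return A tibble with one row per cluster, ordered by coordinate:
#'   `cluster` (integer id), `representative` (the mode coordinate, ties
#'   resolved as documented in [cluster_representative()]), and `members`
#'   (list-column of sorted member positions with multiplicity).
#' @examples
#' single_linkage_clusters(c(100, 115, 140), cutoff = 20)
#' @export
single_linkage_clusters <- function(positions, cutoff = 20) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  if (length(positions) == 0) {
    return(tibble(
      cluster = integer(), representative = double(), members = list()
    ))
  }
  if (!is.numeric(positions) || anyNA(positions)) {
    abort("`positions` must be numeric and free of NA.")
  }
  ord <- sort(positions)
  # gap > cutoff between consecutive sorted members starts a new cluster;
  # chaining means everything else is transitively merged
  grp <- cumsum(c(1, diff(ord) > cutoff))
  members <- unname(split(ord, grp))
  tibble(
    cluster = seq_along(members),
    representative = vapply(members, cluster_representative, double(1)),
    members = members
  )
}

#' Representative coordinate of a cleavage-site cluster
#'
#' The representative is the mode of the member coordinates (the position
#' supported by the most calls). When several positions tie for the mode, the
#' median of the tied modes is used. When that median falls between two
#' coordinates (an even number of tied modes with a half-integer midpoint),
#' it is rounded toward the multiplicity-weighted mean of the whole cluster;
#' an exact tie rounds down. The result always lies within the member range.
#'
#' @param members Numeric vector of member coordinates with multiplicity.
#' @return A single coordinate.
#' @examples
#' cluster_representative(c(100, 100, 100, 105)) # mode -> 100
#' cluster_representative(c(100, 100, 110, 110)) # median of modes -> 105
#' @export
cluster_representative <- function(members) {
  stopifnot(length(members) > 0)
  tab <- table(members)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  m <- median(modes)
  if (m == floor(m)) {
    return(m)
  }
  wm <- mean(members)
  if (wm > m) ceiling(m) else floor(m)
}

#' Map calls onto cluster representatives and merge within samples
#'
#' Re-coordinates each call to the representative of the cluster containing
#' its position, then collapses calls from the same sample that landed on the
#' same representative into a single call. Poly(A)-evidence fields
#' (`length_of_tail_in_contig`, `number_of_bridge_reads`,
#' `max_bridge_read_tail_length`) are combined by element-wise maximum so the
#' strongest support survives. Calls from different samples are never merged.
#'
#' @param calls A data frame with at least `sample_id` and `cleavage_site`
#'   columns; evidence columns are merged by max, any other constant columns
#'   (gene, chromosome, strand) are carried through.
#' @param clusters Output of [single_linkage_clusters()] covering every call
#'   position.
#' @return A tibble with one row per (sample, cluster): `sample_id`,
#'   `cluster`, `representative`, `n_merged` (calls collapsed), plus carried
#'   and evidence columns.
#' @export
assign_to_representatives <- function(calls, clusters) {
  stopifnot(is.data.frame(calls), all(c("sample_id", "cleavage_site") %in% names(calls)))
  if (nrow(calls) == 0) {
    return(tibble(
      sample_id = character(), cluster = integer(),
      representative = double(), n_merged = integer()
    ))
  }
  lookup <- clusters |>
    select("cluster", "representative", "members") |>
    unnest("members") |>
    rename(cleavage_site = "members") |>
    distinct()
  orphans <- setdiff(unique(calls$cleavage_site), lookup$cleavage_site)
  if (length(orphans) > 0) {
    abort(paste0(
      "Internal error: call positions not covered by any cluster: ",
      paste(head(orphans, 5), collapse = ", ")
    ))
  }
  evidence_cols <- intersect(
    c("length_of_tail_in_contig", "number_of_bridge_reads", "max_bridge_read_tail_length"),
    names(calls)
  )
  carry_cols <- setdiff(
    names(calls),
    c("sample_id", "cleavage_site", evidence_cols)
  )
  calls |>
    inner_join(lookup, by = "cleavage_site", relationship = "many-to-one") |>
    group_by(.data$sample_id, .data$cluster, .data$representative) |>
    summarise(
      n_merged = n(),
      across(all_of(carry_cols), ~ .x[1]),
      across(all_of(evidence_cols), max),
      .groups = "drop"
    )
}
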