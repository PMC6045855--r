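#' Validate a sample manifest
#'
#' A manifest assigns every sample to a cohort (cancer type) and a condition.
#' Conditions other than `normal`/`tumor` are rejected; the tumor condition
#' is expected to pool primary, metastatic, recurrent, and additional-primary
#' samples upstream of this package.
#'
#' @param manifest Data frame with columns `sample_id`, `cancer_type`,
#'   `condition`.
#' @return The manifest as a tibble, invisibly validated.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(all(c("sample_id", "cancer_type", "condition") %in% names(manifest)))
  bad <- setdiff(unique(manifest$condition), c("normal", "tumor"))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition(s) in manifest: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(manifest$sample_id)) {
    abort("Duplicate sample_id in manifest.")
  }
  as_tibble(manifest)
}

#' Cancer types with enough normal samples to compare
#'
#' Only cohorts with at least `min_normal` normal samples enter the
#' normal-versus-tumor comparison; the rest are reported but skipped.
#'
#' @param manifest Sample manifest (see [validate_manifest()]).
#' @param min_normal Minimum number of normal samples (default 15).
#' @return Character vector of eligible cancer types, sorted.
#' @export
eligible_cancer_types <- function(manifest, min_normal = 15) {
  manifest <- validate_manifest(manifest)
  manifest |>
    filter(.data$condition == "normal") |>
    count(.data$cancer_type) |>
    filter(.data$n >= min_normal) |>
    pull(.data$cancer_type) |>
    sort()
}

#' Cleavage-site usage frequencies per sample group
#'
#' For each clustered cleavage site, cancer type, and condition, the usage
#' frequency is `freq = s / g`: `s` counts the group's samples in which the
#' site was predicted, and `g` counts the group's samples with sufficient
#' expression of the gene — defined as having at least one predicted
#' cleavage site anywhere in the gene. Samples without any call in a gene
#' (including manifest samples with no calls at all) are excluded from `g`
#' for that gene. Groups with `g = 0` yield no rows: the frequency is
#' undefined there and the gene-group is excluded downstream.
#'
#' @param clustered_calls `calls` tibble from [cluster_predicted_cs()]
#'   (`sample_id`, `gene_id`, `cs_label`).
#' @param manifest Sample manifest.
#' @return Tibble with `gene_id`, `cs_label`, `cancer_type`, `condition`,
#'   `s`, `g`, `freq`; includes `s = 0` rows for sites unused in one group
#'   whenever `g > 0` there.
#' @export
cs_frequencies <- function(clustered_calls, manifest) {
  manifest <- validate_manifest(manifest)
  calls <- clustered_calls |>
    inner_join(
      manifest |> select("sample_id", "cancer_type", "condition"),
      by = "sample_id"
    )
  n_unknown <- length(setdiff(unique(clustered_calls$sample_id), manifest$sample_id))
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " sample(s) with calls are absent from the manifest and were ignored."))
  }
  if (nrow(calls) == 0) {
    return(tibble(
      gene_id = character(), cs_label = character(), cancer_type = character(),
      condition = character(), s = integer(), g = integer(), freq = double()
    ))
  }
  g_tbl <- calls |>
    distinct(.data$gene_id, .data$cancer_type, .data$condition, .data$sample_id) |>
    count(.data$gene_id, .data$cancer_type, .data$condition, name = "g")
  s_tbl <- calls |>
    distinct(.data$gene_id, .data$cs_label, .data$cancer_type, .data$condition,
             .data$sample_id) |>
    count(.data$gene_id, .data$cs_label, .data$cancer_type, .data$condition,
          name = "s")
  # s = 0 rows: every known site crossed with every group where g > 0
  sites <- calls |> distinct(.data$gene_id, .data$cs_label)
  sites |>
    inner_join(g_tbl, by = "gene_id", relationship = "many-to-many") |>
    left_join(
      s_tbl,
      by = c("gene_id", "cs_label", "cancer_type", "condition")
    ) |>
    mutate(
      s = tidyr::replace_na(.data$s, 0L),
      freq = .data$s / .data$g
    ) |>
    arrange(.data$gene_id, .data$cs_label, .data$cancer_type, .data$condition)
}

#' Fisher's exact test on cleavage-site presence counts
#'
#' Two-sided exact test on the 2x2 table of normal and tumor samples with
#' and without a predicted cleavage site, computed from the hypergeometric
#' density: the p-value sums the probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (with the conventional 1 + 1e-7 relative tolerance for floating-
#' point ties). Vectorized over the four counts.
#'
#' @param s_n,without_n Normal samples with / without the site.
#' @param s_t,without_t Tumor samples with / without the site.
#' @return p-value(s) in (0, 1]; `NA` when a group is empty (undefined test).
#' @examples
#' fisher_cs_test(5, 5, 5, 5) # 1
#' @export
fisher_cs_test <- function(s_n, without_n, s_t, without_t) {
  stopifnot(
    all(s_n >= 0), all(without_n >= 0), all(s_t >= 0), all(without_t >= 0)
  )
  mapply(function(a, b, c, d) {
    g_n <- a + b
    g_t <- c + d
    if (g_n == 0 || g_t == 0) {
      return(NA_real_)
    }
    k <- a + c
    support <- max(0, k - g_t):min(k, g_n)
    dens <- dhyper(support, g_n, g_t, k)
    p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
    min(p, 1)
  }, s_n, without_n, s_t, without_t)
}

#' Normal-versus-tumor frequency shifts per cleavage site
#'
#' Joins a site's normal and tumor frequencies within each cancer type,
#' tests the difference with [fisher_cs_test()], and labels the direction:
#' `up` when the shift is significant (`p < alpha`) with higher tumor
#' frequency, `down` when significant with lower, `none` otherwise.
#' Gene-cancer combinations lacking either group (undefined frequency) are
#' excluded.
#'
#' @param freqs Output of [cs_frequencies()].
#' @param alpha Per-site significance level (default 0.01).
#' @return Tibble with counts (`s_n`, `g_n`, `s_t`, `g_t`), frequencies
#'   (`freq_n`, `freq_t`, `delta = freq_t - freq_n`), `p_value`, and
#'   `direction` per gene x site x cancer type.
#' @export
cs_frequency_shifts <- function(freqs, alpha = 0.01) {
  if (nrow(freqs) == 0) {
    return(tibble(
      gene_id = character(), cs_label = character(), cancer_type = character(),
      s_n = integer(), g_n = integer(), s_t = integer(), g_t = integer(),
      freq_n = double(), freq_t = double(), delta = double(),
      p_value = double(), direction = character()
    ))
  }
  wide <- freqs |>
    pivot_wider(
      id_cols = c("gene_id", "cs_label", "cancer_type"),
      names_from = "condition",
      values_from = c("s", "g", "freq")
    )
  for (col in c("s_normal", "g_normal", "freq_normal", "s_tumor", "g_tumor", "freq_tumor")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  wide |>
    filter(!is.na(.data$g_normal), !is.na(.data$g_tumor)) |>
    mutate(
      delta = .data$freq_tumor - .data$freq_normal,
      p_value = fisher_cs_test(
        .data$s_normal, .data$g_normal - .data$s_normal,
        .data$s_tumor, .data$g_tumor - .data$s_tumor
      ),
      direction = case_when(
        .data$p_value < alpha & .data$delta > 0 ~ "up",
        .data$p_value < alpha & .data$delta < 0 ~ "down",
        .default = "none"
      )
    ) |>
    select(
      "gene_id", "cs_label", "cancer_type",
      s_n = "s_normal", g_n = "g_normal", s_t = "s_tumor", g_t = "g_tumor",
      freq_n = "freq_normal", freq_t = "freq_tumor",
      "delta", "p_value", "direction"
    ) |>
    arrange(.data$gene_id, .data$cancer_type, .data$cs_label)
}

#' Detect tumor-specific APA events via the co-occurrence rule
#'
#' A gene x cancer-type pair is an APA event when at least one of its
#' cleavage sites significantly gains frequency in tumor and at least one
#' other significantly loses it (both at `p < alpha`). Requiring both
#' directions guards against calling plain gene up- or down-regulation,
#' which moves all site frequencies the same way. The pair-level p-value is
#' the product of the smallest significant-up and smallest significant-down
#' p-values, hence always below `alpha^2`.
#'
#' @param shifts Output of [cs_frequency_shifts()].
#' @param alpha Per-site significance level used for the directions
#'   (default 0.01); must match the alpha used in the shifts.
#' @return Tibble of events: `gene_id`, `cancer_type`, `n_up`, `n_down`,
#'   `n_sites_tested`, `pair_p`.
#' @export
detect_events <- function(shifts, alpha = 0.01) {
  if (nrow(shifts) == 0) {
    return(tibble(
      gene_id = character(), cancer_type = character(),
      n_up = integer(), n_down = integer(), n_sites_tested = integer(),
      pair_p = double()
    ))
  }
  shifts |>
    group_by(.data$gene_id, .data$cancer_type) |>
    summarise(
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n_sites_tested = n(),
      pair_p = if (any(.data$direction == "up") && any(.data$direction == "down")) {
        min(.data$p_value[.data$direction == "up"]) *
          min(.data$p_value[.data$direction == "down"])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    filter(.data$n_up >= 1, .data$n_down >= 1) |>
    arrange(.data$pair_p)
}

#' Benjamini-Hochberg q-values over the full gene-by-cohort test grid
#'
#' The multiple-testing universe is every (target gene, eligible cancer
#' type) cell, of size `m`; gene-cancer pairs that produced no event carry
#' an assigned p-value of 1. Standard step-up BH with monotonicity
#' enforcement is applied over that grid and the q-values of the supplied
#' pair-level p-values are returned.
#'
#' @param pair_p Numeric vector of event pair-level p-values.
#' @param m Total grid size (>= `length(pair_p)`).
#' @return q-values, same length and order as `pair_p`.
#' @examples
#' bh_fdr(rep(1e-4, 77), m = 1596) # all ~2.073e-3
#' @export
bh_fdr <- function(pair_p, m) {
  stopifnot(m >= length(pair_p), all(pair_p >= 0 & pair_p <= 1, na.rm = TRUE))
  if (length(pair_p) == 0) {
    return(double())
  }
  full <- c(pair_p, rep(1, m - length(pair_p)))
  p.adjust(full, method = "BH")[seq_along(pair_p)]
}
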