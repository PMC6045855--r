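# Independent oracles used to check the package's own implementations.

# Transitive closure of the "<= cutoff apart" relation, by repeated sweeps
# over the full distance matrix. Only feasible for small instances.
brute_force_partition <- function(positions, cutoff) {
  n <- length(positions)
  comp <- seq_len(n)
  adj <- abs(outer(positions, positions, "-")) <= cutoff
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      new <- min(comp[linked])
      if (any(comp[linked] != new)) {
        comp[linked] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # canonical form: sorted list of sorted member vectors
  parts <- unname(split(positions, comp))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, using binomial coefficients directly.
enum_fisher <- function(a, b, c, d) {
  g1 <- a + b
  g2 <- c + d
  k <- a + c
  n <- g1 + g2
  xs <- max(0, k - g2):min(k, g1)
  probs <- choose(g1, xs) * choose(g2, k - xs) / choose(n, k)
  sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# Exhaustive window scan: best PAS hit by rank, then by closeness to the CS.
brute_force_pas <- function(window, motifs) {
  L <- nchar(window)
  best <- NULL
  for (i in seq_len(max(0, L - 5))) {
    hex <- substr(window, i, i + 5)
    r <- match(hex, motifs)
    if (is.na(r)) next
    d <- L - (i + 5) + 1
    if (is.null(best) || r < best$rank ||
        (r == best$rank && d < best$distance)) {
      best <- list(hexamer = hex, distance = d, rank = r)
    }
  }
  best
}

# Write an annotation GTF from a transcript table
# (gene_name, gene_id, strand, tx_start, cs_pos, stop_pos, biotype, tags).
write_archetype_gtf <- function(tx, path = withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())) {
  rows <- character()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    at <- paste0(
      'gene_id "', t$gene_id, '"; transcript_id "', t$gene_id, ".t", i,
      '"; gene_name "', t$gene_name,
      '"; gene_biotype "protein_coding"; transcript_biotype "', t$biotype, '";',
      if (!is.na(t$tags) && nzchar(t$tags)) {
        paste0(' tag "', strsplit(t$tags, ",")[[1]], '";', collapse = "")
      } else ""
    )
    if (t$strand == "+") {
      exon <- c(t$tx_start, t$cs_pos)
      stopc <- c(t$stop_pos - 2, t$stop_pos)
    } else {
      exon <- c(t$cs_pos, t$tx_start)
      stopc <- c(t$stop_pos, t$stop_pos + 2)
    }
    rows <- c(
      rows,
      paste("1", "test", "exon", exon[1], exon[2], ".", t$strand, ".", at, sep = "\t"),
      paste("1", "test", "stop_codon", stopc[1], stopc[2], ".", t$strand, ".", at, sep = "\t")
    )
  }
  writeLines(rows, path)
  path
}

archetype_tx <- function(gene_name, gene_id, strand, cs_pos, stop_pos,
                         biotype = "protein_coding", tags = NA_character_) {
  tx_start <- if (strand == "+") min(stop_pos) - 500 else max(stop_pos) + 500
  tibble::tibble(
    gene_name = gene_name, gene_id = gene_id, strand = strand,
    tx_start = tx_start, cs_pos = cs_pos, stop_pos = stop_pos,
    biotype = biotype, tags = tags
  )
}
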