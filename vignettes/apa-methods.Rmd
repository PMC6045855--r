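---
title: "Detecting tumor-specific APA regulation from cohort cleavage-site calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-specific APA regulation from cohort cleavage-site calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(apacohort)
library(dplyr)
```

## The problem

Most human genes carry more than one cleavage-and-polyadenylation site (CS),
so one gene can produce mRNA isoforms with different 3' UTRs. Alternative
polyadenylation (APA) is classically summarised as "3' UTR shortening or
lengthening" between a proximal and a distal site, but with more than two
CSs per gene — and with CSs that map to different stop codons, to several
stop codons at once, or to stop codons used by nonsense-mediated-decay (NMD)
transcripts — that two-site paradigm breaks down.

`apacohort` analyses APA at the cohort level. Its inputs are per-sample CS
call tables (the seven-column KLEAT-style format: gene, transcript strand,
chromosome, cleavage site, and three poly(A)-evidence fields), an
Ensembl-dialect GTF, a genome FASTA, a sample manifest assigning each sample
a cancer type and a normal/tumor condition, and a target-gene list. Its
output is a table of *tumor-specific APA events*: gene × cancer-type pairs
where the cleavage pattern differs between normal and tumor groups, each
labelled with a 3' UTR trend (`shortening`, `lengthening`, or `complex`).

## The model and procedure

### Annotation models

For each target gene we keep the 3' ends and stop codons of protein-coding
and NMD transcripts whose CDS 3' end is complete (transcripts tagged
`cds_end_NF` contribute nothing — their reading frame, and hence their stop
codon, is not trustworthy). Transcript identity is then discarded: what
remains per gene is a set of annotated CSs, a set of stop codons, and a
deduplicated CS-to-stop map. A transcript that is CDS-3'-complete but has no
`stop_codon` feature cannot anchor a 3' UTR and is excluded with a warning.

Coordinates are 1-based and closed, as in the GTF. A stop codon's position
is its transcript-3'-most genomic base, so the 3' UTR length for a (CS,
stop) pair is the count of bases strictly after the stop codon through the
CS in transcript orientation: `cs - stop` on the plus strand, `stop - cs`
on the minus strand. The anchoring convention (3'-most versus 5'-most stop
base) shifts every length by at most 3 nt and can never reorder two UTRs,
which is all the trend rule relies on.

### Clustering

Predicted CSs scatter around true cleavage points, so both annotated and
predicted CSs are grouped by single-linkage clustering with a 20 bp gap
cutoff. In one dimension this is exact and cheap: sort the coordinates and
cut where consecutive gaps exceed the cutoff; chains of small gaps merge
transitively, which is the fixed point of iterated merging. Each cluster is
represented by its mode coordinate (the position with most supporting
calls); ties take the median of the tied modes, and a half-integer median
is rounded toward the cluster's multiplicity-weighted mean (an exact tie
rounds down). Within each sample, calls landing on the same representative
are merged into one, combining evidence fields by maximum so the strongest
support survives; calls are never merged across samples. Consequences: two
true CSs closer than the cutoff cannot be distinguished, and on synthetic
cohorts with planted CSs at least 60 bp apart the event calls are unchanged
for cutoffs of 15, 20, or 25 bp.

### Call filtering

Raw calls pass four gates. (1) Off-target calls — genes outside the target
list — are dropped. (2) Calls whose `transcript_strand` disagrees with the
gene model's strand are dropped with a warning. (3) Each call is assigned to
the closest clustered annotated CS, with the signed distance positive when
the call is transcript-downstream; exact distance ties resolve to the
transcript-upstream candidate so the assignment is deterministic. (4) The
two-criterion confidence filter retains a call if **A** its absolute
distance to the nearest annotated CS is ≤ 25 bp (recovers annotated sites),
or **B** one of the two strongest polyadenylation-signal hexamers (AATAAA,
ATTAAA) lies within the 50 bp transcript-upstream window *and* at least one
evidence field passes (`length_of_tail_in_contig` ≥ 4,
`number_of_bridge_reads` ≥ 2, or `max_bridge_read_tail_length` ≥ 4).
Criterion B is annotation-independent and is what admits novel sites.

The hexamer scan uses a ranked 12-motif list (AATAAA and ATTAAA first); only
those two matter for criterion B, the rest are reported when found. A
hexamer must lie entirely within the window, overlapping occurrences count,
and the reported distance is anchored at the hexamer's transcript-3' end: a
hexamer at distance *d* occupies upstream positions *d*+5 through *d*, so
distances run from 1 to 45 in a 50 bp window. Whether the retention
criterion uses signed or absolute distance is not observable from the
thresholds alone; absolute distance is used. Windows are truncated at
chromosome boundaries and scan what exists.

### Usage frequencies and the co-occurrence rule

For each clustered CS, cancer type, and condition, the usage frequency is

$$\mathit{freq} = s/g,$$

where $s$ counts the group's samples in which the CS was predicted and $g$
counts the group's samples with *sufficient expression* of the gene —
operationally, at least one predicted CS anywhere in the gene. Samples
without any call in the gene are excluded from $g$; if $g = 0$ the frequency
is undefined and the gene-group drops out. This per-sample presence
frequency is deliberately a "horizontal" measure across a cohort, not an
expression-level quantification: it only says how often a site is used, not
how much.

Each CS's normal-versus-tumor difference is tested with a two-sided Fisher's
exact test on the 2×2 table of samples with and without the site. The test
is computed directly from the hypergeometric density (summing the
probabilities of all tables with the observed margins that are no more
likely than the observed one, with the conventional $1 + 10^{-7}$ relative
tolerance); the test suite checks it against both an explicit enumeration
oracle over all margins up to 30 and `stats::fisher.test()`. Direction
(`up`/`down`) comes from the sign of the frequency difference at
significance $p < \alpha$, with $\alpha = 0.01$; the test itself is
two-sided because the analysis has no a-priori direction per site.

A gene × cancer-type pair becomes an **APA event** only when at least one CS
significantly gains frequency *and* another significantly loses it. The
rationale is specificity: plain gene up- or down-regulation moves all of a
gene's CS frequencies the same way, so requiring opposite significant moves
guards against calling differential expression an APA event, at a known cost
in sensitivity. The event's pair-level p-value is the product of the
smallest significant-up and smallest significant-down p-values — an upper
bound below $\alpha^2 = 10^{-4}$ by construction.

Only cancer types with at least 15 normal samples are compared. The
multiple-testing universe is the *full* grid of target genes × eligible
cancer types ($m$ cells), with an assigned p-value of 1 for every cell that
produced no event; Benjamini-Hochberg is applied over that grid. Padding
with 1s is conservative and makes $m$ independent of how many events were
found. When several cancer types have no test at all for a gene the grid
still counts them — this is the one place where the procedure is defined by
convention rather than forced, and the convention is the published grid
arithmetic (e.g. 114 genes × 14 cohorts = 1596 tests).

### Trend resolution

For each event, the significantly shifted CS clusters are mapped back to
annotated CSs (≤ 25 bp, ties upstream; farther sites are *potentially
novel* and excluded — their stop codon is unknown, so they carry no length).
A mapped CS associated with exactly one stop codon has an unambiguous 3'
UTR length; CSs mapping to several stop codons are ignored. The label is
then resolved deterministically:

1. keep significant, mapped, single-stop CSs;
2. restrict to the stop codon carrying the most such CSs (a tie between
   stop codons is `complex`);
3. if no up or no down CS remains, the event is `complex`;
4. if every up CS's UTR is shorter than every down CS's → `shortening`;
   if every up CS's UTR is longer → `lengthening`; otherwise `complex`.

Step 2 is the package's generalisation of the worked many-stop-codon case
(ignore CSs on minority stop codons or with ambiguous mappings, then read
the direction off the dominant stop codon); it reproduces all the archetype
configurations exercised in the test suite — the single-stop shortening and
lengthening patterns on both strands, and the multi-stop / separate-stop
patterns that must come out `complex`. Stop codons used by NMD transcripts
are flagged in the per-event detail table but do not change the label; NMD
is interpretive context, not part of the rule. Reversing all significance
directions provably swaps `shortening` and `lengthening` and fixes
`complex`, which the suite checks property-style.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cluster_cutoff` | 20 | bp | single-linkage gap for CS clustering |
| `max_annot_dist` | 25 | bp | criterion A proximity; also trend mapping cutoff |
| `pas_window` | 50 | bp | upstream hexamer search window |
| `strong_motifs` | AATAAA, ATTAAA | — | criterion B motifs |
| `tail_min`, `bridge_min`, `bridge_tail_min` | 4, 2, 4 | nt / reads / nt | criterion B evidence bounds |
| `alpha` | 0.01 | — | per-site Fisher significance |
| `min_normal` | 15 | samples | cohort eligibility |
| `trend_map_dist` | 25 | bp | novel-site cutoff in trend stage |

All defaults live in `apa_params()` and flow through every stage; none is
recomputed from data.

## The synthetic universe

`sim_config()` / `build_toy_reference()` / `simulate_cohort()` generate a
complete toy study: a one-chromosome genome with an AATAAA planted at
distance 21 bp upstream of every CS (the canonical hexamer-to-CS spacing),
an Ensembl-dialect GTF realizing configurable CS-to-stop topologies
(`one_to_one`, `one_to_many`, `mixed`) with optional NMD stop codons and
`cds_end_NF` decoy transcripts (written with the NF tag *first* among the
tags, which traps parsers that keep only one repeated attribute), a sample
manifest, and per-sample call tables.

The generator's defaults are the package's reference study conditions: one
cohort of 100 normal and 100 tumor samples; a planted event in one gene
(usage 0.9→0.4 on one CS and 0.3→0.85 on another) and a null second gene;
3 bp positional jitter (well inside the 20 bp cutoff, so clustering is
exercised without being trivial); evidence fields drawn as 4 + geometric
tail lengths and Poisson(3) bridge reads so criterion B passes unless
`weak_evidence` deliberately disables it; 5% novel-site decoys planted
300 bp beyond the outermost annotated CS; 5% off-target decoy calls.

What the simulation does *not* model: read-level noise (assembly and
alignment artifacts), expression-level variation between samples,
correlated site usage within a sample, batch effects, or realistic genomic
sequence composition (upstream windows are scrubbed to C/G so the planted
hexamer is the only hit). Passing the round-trip tests therefore shows the
*statistical machinery* is correct under its own assumptions — it does not
certify performance on real tumor cohorts, where call quality, coverage,
and cohort composition dominate.

```{r example}
cfg <- sim_config(seed = 7)
ref <- build_toy_reference(cfg)
sim <- simulate_cohort(cfg, ref)
gtf <- tempfile(fileext = ".gtf"); writeLines(ref$gtf_lines, gtf)
ann <- parse_gene_annotation(gtf, cfg$genes$gene_name)
res <- run_apa_pipeline(sim$calls, ann, ref$genome, sim$manifest)
glance(res)
tidy(res) |> select(gene_name, cancer_type, n_up, n_down, pair_p, q_value, trend)
```

## Numerical and design choices

* **Fisher test**: computed from `dhyper()` rather than calling
  `stats::fisher.test()` per table, so the per-table cost stays small on
  large grids and `fisher.test()` remains available as an independent
  cross-check in the tests. Degenerate tables (an empty normal or tumor
  group) return `NA` rather than a p-value.
* **Tie-breaks** are all deterministic and documented: upstream candidate on
  equidistant annotated CSs, median-of-modes with weighted-mean rounding in
  clustering, closest hit among equal-rank hexamers.
* **Determinism**: stages are pure given inputs and parameters; output
  tables are sorted on stable keys, and file-based runs are byte-identical
  on reruns. Simulation uses `withr::local_seed()` so the caller's RNG
  state is untouched and the same seed is byte-reproducible.
* **Problem sizes in the test suite** were chosen as the smallest that
  exercise each property honestly: exhaustive Fisher agreement over all 2×2
  tables with margins ≤ 30; 1000 random clustering instances of ≤ 12
  positions against a transitive-closure oracle; 200 seeded replicates of
  the planted-event recovery study at 100+100 samples; one 200-gene null
  cohort at 50+50 for the false-positive bound; a 2000+2000-sample cohort
  for the law-of-large-numbers check on the generator.
* **Empty margins and empty inputs** degrade to empty tables or `NA`
  markers with warnings, never to errors, so a cohort with no usable calls
  is reportable.

## Known limitations

* CSs closer than the clustering cutoff are indistinguishable by design.
* Usage frequency is presence/absence per sample; it cannot weigh isoform
  abundance, and for CSs mapped to several stop codons it aggregates
  isoforms that share a cleavage point.
* The trend rule's dominant-stop-codon restriction is a reconstruction
  validated against archetypal configurations, not against an exhaustive
  published rule; events whose restricted set keeps only one direction are
  conservatively labelled `complex`.
* The co-occurrence requirement trades sensitivity for specificity: an APA
  shift in which only one direction reaches significance is not reported.
* Eligibility takes no account of tumor-sample counts, matched pairs, or
  covariates; the comparison is marginal by design.
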