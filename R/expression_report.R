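#' Normalize a junction count to the beta-actin control
#'
#' Expression relative to sequencing depth is the log10 ratio of the gene's
#' junction read count to the beta-actin (Actb) junction read count from the
#' same libraries. A zero Actb count means the library carries no control
#' signal and is unusable; a zero gene count has no finite log ratio and is
#' reported as `NA` (absent) rather than -Inf.
#'
#' @param raw_count,actb_count Non-negative integer read counts (vectorized).
#' @return `log10(raw_count / actb_count)`, `NA` where `raw_count` is 0.
#' @examples
#' normalized_expression(10, 1000)    # -2
#' normalized_expression(1000, 1000)  # 0
#' @export
normalized_expression <- function(raw_count, actb_count) {
  if (any(raw_count < 0) || any(actb_count < 0)) abort("counts must be non-negative")
  if (any(actb_count == 0)) abort("no control reads; library unusable")
  ifelse(raw_count == 0, NA_real_, log10(raw_count / actb_count))
}

#' Aggregate junction-query counts into long (L) and short (S) subtotals
#'
#' Species often carry several junction queries per isoform class (splice
#' length variants, paralog-specific junctions). Each query is mapped to
#' whether its junction implies the cassette exon is present; L subtotal =
#' sum of counts of cassette-containing junctions, S subtotal = sum of
#' counts of cassette-skipping junctions.
#'
#' @param per_query_counts Tibble with `query_id`, `count`, and (optionally)
#'   `species_id`, `gene_id` used as grouping keys.
#' @param containment Tibble `query_id`, `contains_cassette` (logical).
#'   Every counted query must be mapped.
#' @return Tibble with the grouping keys and columns `L`, `S`.
#' @export
aggregate_isoforms <- function(per_query_counts, containment) {
  if (inherits(per_query_counts, "junction_counts")) {
    per_query_counts <- per_query_counts$counts
  }
  unmapped <- setdiff(per_query_counts$query_id, containment$query_id)
  if (length(unmapped)) {
    abort(paste("query not in containment map:", unmapped[1]))
  }
  keys <- intersect(c("species_id", "gene_id"), names(per_query_counts))
  df <- left_join(per_query_counts,
                  containment[, c("query_id", "contains_cassette")],
                  by = "query_id")
  df |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(L = sum(.data$count[.data$contains_cassette]),
              S = sum(.data$count[!.data$contains_cassette]),
              .groups = "drop")
}

#' Per-species isoform expression table with presence calls
#'
#' @param subtotals Output of [aggregate_isoforms()] (columns `L`, `S` plus
#'   keys).
#' @param actb_counts Tibble with the same keys minus `gene_id` and a column
#'   `actb_count`, or a single count when `subtotals` has one row group.
#' @param min_reads Reads required to call an isoform present (default 1:
#'   a single perfect junction read is treated as detection; raw counts are
#'   retained so stricter thresholds can be applied downstream).
#' @return Tibble, two rows (isoform classes L and S) per input row:
#'   `isoform_class`, `raw_count`, `actb_count`, `log10_ratio`, `present`.
#' @export
isoform_expression <- function(subtotals, actb_counts, min_reads = 1L) {
  if (is.numeric(actb_counts)) {
    subtotals$actb_count <- as.integer(actb_counts)
  } else {
    keys <- intersect(c("species_id"), names(subtotals))
    subtotals <- left_join(subtotals, actb_counts, by = keys)
  }
  long <- tidyr::pivot_longer(subtotals, c("L", "S"),
                              names_to = "isoform_class",
                              values_to = "raw_count")
  long$log10_ratio <- normalized_expression(long$raw_count, long$actb_count)
  long$present <- long$raw_count >= min_reads
  long
}

#' Sequencing-depth adequacy report
#'
#' Orders species by total Actb junction reads (the depth gauge) and reports
#' the association between depth and apparent presence of the skipping
#' isoform. The association is the rank-biserial correlation between the
#' depth ranks of S-present and S-absent species: 0 when presence is
#' unrelated to depth, 1 when presence is confined to the deepest libraries.
#' Diagnostic only; no hypothesis test is attached.
#'
#' @param depth_table Tibble with `species_id`, `actb_total`, `s_present`
#'   (logical).
#' @return Object of class `depth_report`: list with the sorted `table` and
#'   `association`. `glance()` returns a one-row summary.
#' @export
depth_report <- function(depth_table) {
  stopifnot(all(c("species_id", "actb_total", "s_present") %in%
                  names(depth_table)))
  if (nrow(depth_table) < 2) abort("need at least 2 species")
  tab <- arrange(depth_table, .data$actb_total)
  tab$depth_rank <- rank(tab$actb_total)
  n1 <- sum(tab$s_present); n0 <- sum(!tab$s_present)
  assoc <- if (n1 == 0 || n0 == 0 || length(unique(tab$actb_total)) == 1) {
    0
  } else {
    2 * (mean(tab$depth_rank[tab$s_present]) -
           mean(tab$depth_rank[!tab$s_present])) / nrow(tab)
  }
  structure(list(table = tab, association = assoc), class = "depth_report")
}

#' @export
print.depth_report <- function(x, ...) {
  cat(sprintf("<depth_report> %d species; depth~presence rank association %.3f\n",
              nrow(x$table), x$association))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.depth_report <- function(x, ...) {
  tibble(n_species = nrow(x$table),
         n_s_present = sum(x$table$s_present),
         association = x$association)
}

#' @exportS3Method generics::tidy
tidy.depth_report <- function(x, ...) x$table

#' Length-normalized skipping-fraction estimate
#'
#' Junction-spanning read counts scale with the number of read start
#' positions on each transcript, so the raw count ratio S/(L+S) is biased by
#' the isoform length difference. Each count is normalized by the effective
#' number of start positions on its transcript (`len - read_length + 1`)
#' before forming the ratio (junctions interior to both isoforms contribute
#' `read_length - 2*flank + 1` spanning positions each, which cancels).
#'
#' @param inclusion_count,skipping_count Junction read counts.
#' @param inclusion_len,skipping_len Transcript lengths (nt).
#' @param read_length Mean read length (nt).
#' @return Estimated fraction of transcripts skipping the cassette exon.
#' @export
estimate_skipping_fraction <- function(inclusion_count, skipping_count,
                                       inclusion_len, skipping_len,
                                       read_length = 108) {
  wi <- max(inclusion_len - read_length + 1, 1)
  ws <- max(skipping_len - read_length + 1, 1)
  s <- skipping_count * ws
  i <- inclusion_count * wi
  if (s + i == 0) return(NA_real_)
  s / (s + i)
}
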