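#' Map a gene's coding introns onto a protein alignment
#'
#' Each coding intron is expressed as an alignment anchor: the alignment
#' column at/after which the intron falls, plus its splice phase. A phase-0
#' intron splices between codons, so its anchor sits between two residue
#' columns (reported as the column of the preceding residue); phase-1/2
#' introns fall inside a codon and anchor at the column holding that codon's
#' residue. Residue-to-column mapping skips gap columns, so anchors are
#' invariant under insertion of all-gap columns outside the anchored region.
#'
#' @param models Gene-model tibble.
#' @param gene_id Which gene.
#' @param alignment Protein alignment (character vector/matrix/AAStringSet).
#' @param row Alignment row (index or name) carrying this gene's protein.
#' @param translation Optional translated CDS to verify the row against; when
#'   supplied, the row's ungapped sequence (stops stripped) must equal it,
#'   and the first discordant residue is named otherwise.
#' @return Tibble of anchors: `intron_id`, `row`, `column`, `phase`.
#' @export
map_intron_to_alignment <- function(models, gene_id, alignment, row,
                                    translation = NULL) {
  m <- as_alignment_matrix(alignment)
  rowv <- m[row, ]
  res_cols <- which(rowv != "-" & rowv != ".")
  res_seq <- paste0(rowv[res_cols], collapse = "")
  if (!is.null(translation)) {
    translation <- sub("\\*$", "", toupper(translation))
    if (res_seq != translation) {
      a <- strsplit(res_seq, "")[[1]]; b <- strsplit(translation, "")[[1]]
      k <- min(length(a), length(b))
      d <- which(a[seq_len(k)] != b[seq_len(k)])[1]
      if (is.na(d)) d <- k + 1L
      abort(sprintf(
        "alignment row disagrees with translated CDS at residue %d ('%s' vs '%s')",
        d, a[d] %||% "", b[d] %||% ""))
    }
  }
  mrow <- model_row(models, gene_id)
  introns <- mrow$introns[[1]]
  exons <- mrow$exons[[1]]
  up_cds <- cumsum(exons$cds_len)[-nrow(exons)]
  coding <- !is.na(introns$phase)
  anchors <- lapply(which(coding), function(i) {
    cds_nt <- up_cds[i]
    phase <- introns$phase[i]
    res <- if (phase == 0L) cds_nt %/% 3L else cds_nt %/% 3L + 1L
    if (res > length(res_cols)) {
      abort(sprintf("intron %s anchors beyond the aligned protein", introns$intron_id[i]))
    }
    tibble(intron_id = introns$intron_id[i],
           row = if (is.character(row)) row else rownames(m)[row] %||% as.character(row),
           column = res_cols[res], phase = phase)
  })
  if (!length(anchors)) {
    return(tibble(intron_id = character(), row = character(),
                  column = integer(), phase = integer()))
  }
  bind_rows(anchors)
}

#' Pair introns conserved between two anchor sets
#'
#' Two introns are conserved homologs when their anchors sit at the identical
#' alignment column with the identical splice phase (strict conservation; no
#' intron-sliding allowance by default). A `slack` of k columns can be
#' allowed for ragged alignments but defaults to 0.
#'
#' @param anchors_a,anchors_b Anchor tibbles from the same alignment.
#' @param slack Maximum column difference still counted as the same position
#'   (default 0, i.e. exact).
#' @return Tibble of matched pairs: `intron_a`, `intron_b`, `column_a`,
#'   `column_b`, `phase`. Symmetric in its arguments (up to column naming).
#' @export
conserved_intron_pairs <- function(anchors_a, anchors_b, slack = 0L) {
  out <- list()
  for (i in seq_len(nrow(anchors_a))) {
    j <- which(abs(anchors_b$column - anchors_a$column[i]) <= slack &
                 anchors_b$phase == anchors_a$phase[i])
    for (jj in j) {
      out[[length(out) + 1L]] <- tibble(
        intron_a = anchors_a$intron_id[i], intron_b = anchors_b$intron_id[jj],
        column_a = anchors_a$column[i], column_b = anchors_b$column[jj],
        phase = anchors_a$phase[i])
    }
  }
  if (!length(out)) {
    return(tibble(intron_a = character(), intron_b = character(),
                  column_a = integer(), column_b = integer(),
                  phase = integer()))
  }
  bind_rows(out)
}

#' Detect the exon-deletion-by-intron-recombination signature
#'
#' Tests whether gene B lost the cassette exon that gene A retains, by
#' recombination between the exon's two flanking phase-0 introns. The
#' signature requires: gene A shows two phase-0 anchors flanking the cassette
#' exon; the exon's alignment columns are gapped in gene B's row (at least
#' `gap_fraction` of them); and gene B shows exactly one phase-0 anchor at
#' the fused position. `retained` is returned when the exon's columns are
#' non-gap in both rows and both flanking anchors pair; anything else is
#' `no_signature`.
#'
#' @param models Gene-model tibble containing both genes.
#' @param gene_a,gene_b Gene IDs (A retains the exon).
#' @param alignment Protein alignment containing a row per gene.
#' @param row_a,row_b Alignment rows (default: the gene IDs as row names).
#' @param cassette_exon_id The cassette exon of gene A.
#' @param gap_fraction Fraction of the exon's columns that must be gapped in
#'   gene B to call the exon absent (default 1, i.e. all; relax for ragged
#'   alignments).
#' @param slack Column slack forwarded to [conserved_intron_pairs()].
#' @return Object of class `exon_loss_call`: list with `verdict`
#'   (`retained` / `deleted_by_intron_recombination` / `no_signature`) and
#'   `evidence` (anchors, exon column span, gap fraction observed).
#' @export
detect_exon_loss_signature <- function(models, gene_a, gene_b, alignment,
                                       row_a = gene_a, row_b = gene_b,
                                       cassette_exon_id,
                                       gap_fraction = 1,
                                       slack = 0L) {
  m <- as_alignment_matrix(alignment)
  for (r in c(row_a, row_b)) {
    if (is.character(r) && !r %in% rownames(m)) {
      abort(sprintf("alignment lacks row '%s'", r))
    }
  }
  anchors_a <- map_intron_to_alignment(models, gene_a, m, row_a)
  anchors_b <- map_intron_to_alignment(models, gene_b, m, row_b)

  row_amod <- model_row(models, gene_a)
  exons <- row_amod$exons[[1]]
  k <- match(cassette_exon_id, exons$exon_id)
  if (is.na(k)) abort(sprintf("exon %s not in gene %s", cassette_exon_id, gene_a))
  if (k == 1L || k == nrow(exons)) abort("cassette exon must be internal")
  flank_up <- anchors_a[anchors_a$intron_id == paste0("i", k - 1L), ]
  flank_down <- anchors_a[anchors_a$intron_id == paste0("i", k), ]

  ## project the exon's coding residues to alignment columns of row A
  up_cds <- cumsum(exons$cds_len)
  res_from <- up_cds[k - 1L] %/% 3L + 1L
  res_to <- ceiling(up_cds[k] / 3)
  rowva <- m[row_a, ]
  res_cols_a <- which(rowva != "-" & rowva != ".")
  cols <- res_cols_a[res_from:res_to]

  rowvb <- m[row_b, ]
  gapped_b <- mean(rowvb[cols] %in% c("-", "."))
  gapped_a <- mean(rowva[cols] %in% c("-", "."))

  pairs <- conserved_intron_pairs(anchors_a, anchors_b, slack = slack)
  both_flanks_pair <- nrow(flank_up) == 1 && nrow(flank_down) == 1 &&
    flank_up$phase == 0L && flank_down$phase == 0L &&
    flank_up$intron_id %in% pairs$intron_a &&
    flank_down$intron_id %in% pairs$intron_a

  evidence <- list(anchors_a = anchors_a, anchors_b = anchors_b,
                   exon_columns = range(cols),
                   gap_fraction_b = gapped_b, pairs = pairs)
  verdict <- "no_signature"
  if (gapped_a == 0 && gapped_b == 0 && both_flanks_pair) {
    verdict <- "retained"
  } else if (gapped_b >= gap_fraction &&
             nrow(flank_up) == 1 && nrow(flank_down) == 1 &&
             flank_up$phase == 0L && flank_down$phase == 0L) {
    ## gene B must show exactly one phase-0 anchor at the fused position,
    ## where gene A shows two
    fused <- anchors_b[anchors_b$phase == 0L &
                         anchors_b$column >= flank_up$column &
                         anchors_b$column <= flank_down$column, ]
    if (nrow(fused) == 1L) verdict <- "deleted_by_intron_recombination"
  }
  structure(list(gene_a = gene_a, gene_b = gene_b, verdict = verdict,
                 evidence = evidence),
            class = "exon_loss_call")
}

#' @export
print.exon_loss_call <- function(x, ...) {
  cat(sprintf("<exon_loss_call> %s vs %s: %s\n", x$gene_a, x$gene_b, x$verdict))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.exon_loss_call <- function(x, ...) {
  tibble(gene_a = x$gene_a, gene_b = x$gene_b, verdict = x$verdict,
         gap_fraction_b = x$evidence$gap_fraction_b)
}

#' Write an anchor/call report as TSV
#' @param anchors Anchor tibble (or list of them, row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_tsv <- function(anchors, path) {
  if (!is.data.frame(anchors)) anchors <- bind_rows(anchors)
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
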