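#' Build a gene model from an exon table
#'
#' A gene model is one row of a tibble: identifiers, strand, and list-columns
#' holding the exon and intron tables. Exons are given in transcript (5'->3')
#' order with genomic 1-based inclusive coordinates and the number of coding
#' nucleotides each contributes (`cds_len`). Introns are derived as the gaps
#' between consecutive exons, and each coding intron is assigned its splice
#' phase: the cumulative coding length upstream of the intron modulo 3
#' (phase 0 splices between codons, phases 1 and 2 within a codon).
#'
#' @param gene_id,species_id Identifiers.
#' @param seqid Name of the genomic sequence the exons live on.
#' @param strand `"+"` or `"-"`. Minus-strand exons are still supplied in
#'   transcript order (descending genomic coordinates).
#' @param exons Data frame with columns `exon_id`, `start`, `end`, `cds_len`.
#' @param cds_offset Untranslated nucleotides preceding the CDS in the spliced
#'   transcript (0 when the transcript starts at the start codon).
#' @return A one-row tibble with list-columns `exons` and `introns`, and a
#'   `complete_orf` flag (FALSE, with a warning, when the total CDS length is
#'   not a multiple of 3 — a possible pseudogene or partial model).
#' @examples
#' ex <- tibble::tibble(exon_id = c("e1", "e2", "e3"),
#'                      start = c(1, 201, 401), end = c(120, 287, 499),
#'                      cds_len = c(120, 87, 99))
#' gm <- gene_model("g", "toy", "chr1", "+", ex)
#' gm$introns[[1]]$phase  # both phase 0
#' @export
gene_model <- function(gene_id, species_id, seqid, strand, exons,
                       cds_offset = 0L) {
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "start", "end", "cds_len") %in% names(exons)))
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  exons <- as_tibble(exons[, c("exon_id", "start", "end", "cds_len")])
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons$cds_len <- as.integer(exons$cds_len)
  if (any(exons$end < exons$start)) abort("exon end < start")
  if (any(exons$cds_len > exons$end - exons$start + 1L)) {
    abort("exon cds_len exceeds exon width")
  }
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(ord, seq_len(nrow(exons)))) {
    abort("exons must be supplied in transcript (5'->3') orientation")
  }
  ## non-overlap in genomic space
  g <- exons[order(exons$start), ]
  if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
    abort("exons overlap")
  }
  introns <- derive_introns(exons, strand)
  total_cds <- sum(exons$cds_len)
  complete_orf <- total_cds %% 3L == 0L
  if (!complete_orf) {
    warn(sprintf("gene %s: total CDS length %d not divisible by 3 (possible pseudogene/partial model)",
                 gene_id, total_cds))
  }
  tibble(gene_id = gene_id, species_id = species_id, seqid = seqid,
         strand = strand, cds_offset = as.integer(cds_offset),
         complete_orf = complete_orf,
         exons = list(exons), introns = list(introns))
}

derive_introns <- function(exons, strand) {
  n <- nrow(exons)
  if (n < 2) {
    return(tibble(intron_id = character(), start = integer(),
                  end = integer(), phase = integer()))
  }
  up_cds <- cumsum(exons$cds_len)[-n]
  total <- sum(exons$cds_len)
  ## coding intron: CDS on both sides; UTR-only introns get the NA sentinel
  phase <- ifelse(up_cds > 0L & up_cds < total, up_cds %% 3L, NA_integer_)
  if (strand == "+") {
    start <- exons$end[-n] + 1L
    end <- exons$start[-1] - 1L
  } else {
    start <- exons$end[-1] + 1L
    end <- exons$start[-n] - 1L
  }
  if (any(end < start)) abort("adjacent exons leave no room for an intron")
  tibble(intron_id = paste0("i", seq_len(n - 1L)),
         start = as.integer(start), end = as.integer(end),
         phase = as.integer(phase))
}

#' Splice phase of an intron
#'
#' Phase = (coding nucleotides upstream of the intron) mod 3. Introns lying
#' entirely in untranslated regions are non-coding and return the `NA`
#' sentinel rather than 0.
#'
#' @param models Gene-model tibble (from [gene_model()] or
#'   [read_gene_models()]).
#' @param gene_id Which gene.
#' @param intron_index 1-based intron index in transcript order.
#' @return Integer phase 0/1/2, or `NA` for a non-coding intron.
#' @export
intron_phase <- function(models, gene_id, intron_index) {
  row <- model_row(models, gene_id)
  introns <- row$introns[[1]]
  if (intron_index < 1 || intron_index > nrow(introns)) {
    abort(sprintf("gene %s has no intron %d", gene_id, intron_index))
  }
  introns$phase[[intron_index]]
}

model_row <- function(models, gene_id) {
  i <- which(models$gene_id == gene_id)
  if (length(i) != 1) abort(sprintf("gene '%s' not found (or ambiguous)", gene_id))
  models[i, ]
}

#' Define an isoform as an ordered subset of a gene's exons
#'
#' @param isoform_id,gene_id Identifiers.
#' @param exon_ids Exon IDs retained by the isoform, in gene order.
#' @param label One of `"inclusion"`, `"skipping"`, `"other"`.
#' @return One-row tibble with an `exon_ids` list-column.
#' @export
isoform_model <- function(isoform_id, gene_id, exon_ids,
                          label = c("inclusion", "skipping", "other")) {
  label <- match.arg(label)
  tibble(isoform_id = isoform_id, gene_id = gene_id,
         exon_ids = list(as.character(exon_ids)), label = label)
}

#' Splice an isoform's transcript sequence from genomic sequence
#'
#' Concatenates the isoform's exon sequences in transcript orientation
#' (reverse-complementing minus-strand exons).
#'
#' @param models Gene-model tibble.
#' @param isoform One row of an isoform tibble ([isoform_model()]), or a
#'   character vector of exon IDs.
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector)
#'   of genomic sequences.
#' @param gene_id Required when `isoform` is a bare exon-ID vector.
#' @return A single character string, the spliced transcript.
#' @export
splice_transcript <- function(models, isoform, genome, gene_id = NULL) {
  if (is.character(isoform)) {
    exon_ids <- isoform
    if (is.null(gene_id)) abort("gene_id required when isoform is an exon-ID vector")
  } else {
    exon_ids <- isoform$exon_ids[[1]]
    gene_id <- isoform$gene_id[[1]]
  }
  row <- model_row(models, gene_id)
  exons <- row$exons[[1]]
  missing <- setdiff(exon_ids, exons$exon_id)
  if (length(missing)) {
    abort(sprintf("isoform exons absent from gene %s: %s",
                  gene_id, paste(missing, collapse = ", ")))
  }
  idx <- match(exon_ids, exons$exon_id)
  if (is.unsorted(idx)) abort("isoform exon_ids must preserve gene order")
  genome <- as_dna_set(genome)
  if (!row$seqid %in% names(genome)) {
    abort(sprintf("sequence '%s' not found in genome", row$seqid))
  }
  chrom <- genome[[row$seqid]]
  if (max(exons$end[idx]) > length(chrom)) {
    abort(sprintf("exon coordinates exceed length of sequence '%s'", row$seqid))
  }
  pieces <- lapply(idx, function(i) {
    s <- Biostrings::subseq(chrom, exons$start[i], exons$end[i])
    if (row$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  paste0(unlist(pieces), collapse = "")
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(x)
}

#' Translate a coding sequence and flag premature stops
#'
#' Standard-code translation starting at `cds_offset`; trailing bases short of
#' a full codon are ignored. Ambiguity codes translate to `X`. The premature
#' stop flag is set when a stop codon occurs before the final codon (used to
#' flag candidate pseudogenes).
#'
#' @param sequence Nucleotide string.
#' @param cds_offset 0-based offset of the first codon.
#' @return List with `aa` (translation, stops as `*`) and `premature_stop`.
#' @examples
#' translate_cds("ATGAAATAA")   # MK*, no premature stop
#' translate_cds("ATGTAAAAATAA")  # premature stop after M
#' @export
translate_cds <- function(sequence, cds_offset = 0L) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence) - cds_offset
  if (n < 3) abort("fewer than 3 nt downstream of cds_offset")
  n_codons <- n %/% 3L
  cds <- substr(sequence, cds_offset + 1L, cds_offset + 3L * n_codons)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  list(aa = aa, premature_stop = grepl("*", internal, fixed = TRUE))
}

#' Transcript coordinates of a gene's junctions and exons
#'
#' Helper mapping each exon of an isoform to its interval on the spliced
#' transcript. Used by the simulator and the QC classifier.
#' @param models Gene-model tibble; `gene_id` which gene; `exon_ids` the
#'   isoform's exons in order.
#' @return Tibble with `exon_id`, `tx_start`, `tx_end` (1-based inclusive).
#' @export
exon_transcript_coords <- function(models, gene_id, exon_ids) {
  row <- model_row(models, gene_id)
  exons <- row$exons[[1]]
  idx <- match(exon_ids, exons$exon_id)
  if (anyNA(idx)) abort("unknown exon_id")
  w <- exons$end[idx] - exons$start[idx] + 1L
  ends <- cumsum(w)
  tibble(exon_id = exon_ids, tx_start = ends - w + 1L, tx_end = ends)
}
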