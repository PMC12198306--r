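#' Read gene models from GFF3 + sequence
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` features (1-based inclusive GFF3
#' coordinates) and returns a gene-model tibble with computed intron phases.
#' Minus-strand genes are reported in transcript orientation. One mRNA per
#' gene is used (the first by ID). Each exon's coding contribution is the
#' total overlap with that mRNA's CDS features; a gene whose CDS length is
#' not a multiple of 3 is flagged (`complete_orf = FALSE`) with a warning.
#'
#' @param gff_path Path to a GFF3 file.
#' @param genome Named [Biostrings::DNAStringSet], named character vector, or
#'   path to a FASTA file covering all referenced sequences.
#' @param species_id Species identifier to stamp on models; when `NULL`, the
#'   gene feature's `species` attribute is used (or `"unknown"`).
#' @return Tibble of gene models (see [gene_model()]).
#' @export
read_gene_models <- function(gff_path, genome, species_id = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  } else {
    genome <- as_dna_set(genome)
  }
  gr <- rtracklayer::import(gff_path)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  parent_of <- function(i) as.character(unlist(meta$Parent[i]))[1]

  genes <- which(type == "gene")
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    gi <- genes[[k]]
    gid <- as.character(meta$ID[gi])
    sp <- species_id %||%
      (if ("species" %in% names(meta)) as.character(meta$species[gi]) else NA) %||%
      "unknown"
    if (is.na(sp)) sp <- "unknown"
    mrnas <- which(type == "mRNA" &
                     vapply(seq_along(gr), parent_of, "") == gid)
    if (!length(mrnas)) abort(sprintf("gene %s has no mRNA feature", gid))
    mid <- as.character(meta$ID[mrnas[[1]]])
    kids <- vapply(seq_along(gr), parent_of, "") == mid
    ex <- which(type == "exon" & kids)
    cds <- which(type == "CDS" & kids)
    if (!length(ex)) abort(sprintf("mRNA %s has no exon features", mid))
    seqid <- as.character(GenomicRanges::seqnames(gr))[ex[1]]
    if (!seqid %in% names(genome)) {
      abort(sprintf("exon of gene %s references absent sequence '%s'", gid, seqid))
    }
    strand <- as.character(GenomicRanges::strand(gr))[ex[1]]
    if (!strand %in% c("+", "-")) abort(sprintf("gene %s lacks a strand", gid))
    et <- tibble(
      exon_id = as.character(meta$ID[ex]),
      start = GenomicRanges::start(gr)[ex],
      end = GenomicRanges::end(gr)[ex]
    )
    et <- et[order(if (strand == "+") et$start else -et$start), ]
    if (max(et$end) > length(genome[[seqid]])) {
      abort(sprintf("gene %s: exon coordinates exceed sequence '%s'", gid, seqid))
    }
    ## coding nt contributed by each exon = overlap with CDS intervals
    cs <- GenomicRanges::start(gr)[cds]; ce <- GenomicRanges::end(gr)[cds]
    et$cds_len <- vapply(seq_len(nrow(et)), function(i) {
      ov <- pmin(et$end[i], ce) - pmax(et$start[i], cs) + 1L
      sum(pmax(ov, 0L))
    }, integer(1))
    ## 5'-UTR nt preceding the CDS on the spliced transcript
    cds_offset <- 0L
    if (length(cds)) {
      first_cds <- if (strand == "+") min(cs) else max(ce)
      w <- et$end - et$start + 1L
      tx0 <- cumsum(w) - w  # transcript nt before each exon
      host <- which(et$start <= first_cds & et$end >= first_cds)[1]
      inside <- if (strand == "+") first_cds - et$start[host]
                else et$end[host] - first_cds
      cds_offset <- tx0[host] + inside
    }
    out[[k]] <- gene_model(gid, sp, seqid, strand, et, cds_offset)
  }
  bind_rows(out)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features for each model. CDS
#' features carry the GFF3 frame/phase column. The species identifier is
#' stored as a `species` attribute on the gene feature, so models survive a
#' write/read round trip.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    row <- models[i, ]
    exons <- row$exons[[1]]
    gstart <- min(exons$start); gend <- max(exons$end)
    mid <- paste0(row$gene_id, ".t1")
    lines <- c(lines,
      gff_line(row$seqid, "gene", gstart, gend, row$strand, ".",
               sprintf("ID=%s;species=%s", row$gene_id, row$species_id)),
      gff_line(row$seqid, "mRNA", gstart, gend, row$strand, ".",
               sprintf("ID=%s;Parent=%s", mid, row$gene_id)))
    for (j in seq_len(nrow(exons))) {
      lines <- c(lines, gff_line(row$seqid, "exon", exons$start[j],
                                 exons$end[j], row$strand, ".",
                                 sprintf("ID=%s;Parent=%s", exons$exon_id[j], mid)))
    }
    lines <- c(lines, cds_gff_lines(row, mid))
  }
  writeLines(lines, path)
  invisible(path)
}

gff_line <- function(seqid, type, start, end, strand, frame, attrs) {
  paste(seqid, "cassette", type, start, end, ".", strand, frame, attrs,
        sep = "\t")
}

## Genomic CDS intervals per exon, walking the transcript and consuming the
## 5'-UTR offset; assumes each exon's coding portion is contiguous.
cds_gff_lines <- function(row, mid) {
  exons <- row$exons[[1]]
  utr <- row$cds_offset
  cum_cds <- 0L
  out <- character()
  for (j in seq_len(nrow(exons))) {
    w <- exons$end[j] - exons$start[j] + 1L
    cl <- exons$cds_len[j]
    if (cl == 0L) { utr <- utr - w; next }
    skip <- max(utr, 0L)  # UTR nt at the 5' edge of this exon
    utr <- utr - w
    if (row$strand == "+") {
      cs <- exons$start[j] + skip
      ce <- cs + cl - 1L
    } else {
      ce <- exons$end[j] - skip
      cs <- ce - cl + 1L
    }
    frame <- (3L - cum_cds %% 3L) %% 3L
    out <- c(out, gff_line(row$seqid, "CDS", cs, ce, row$strand, frame,
                           sprintf("ID=%s.cds%d;Parent=%s", row$gene_id, j, mid)))
    cum_cds <- cum_cds + cl
  }
  out
}

#' Export gene models as JSON
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_json <- function(models, path) {
  x <- lapply(seq_len(nrow(models)), function(i) {
    row <- models[i, ]
    list(gene_id = row$gene_id, species_id = row$species_id,
         seqid = row$seqid, strand = row$strand,
         cds_offset = row$cds_offset, complete_orf = row$complete_orf,
         exons = row$exons[[1]], introns = row$introns[[1]])
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
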