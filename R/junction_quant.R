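#' Design an exon-junction query (ej-RNA)
#'
#' An ej-RNA is a 30-nt (2 x `flank`) query spanning a splice junction: the
#' last `flank` nucleotides of the upstream exon followed by the first
#' `flank` nucleotides of the downstream exon, in transcript orientation.
#' The junction type is inferred from exon adjacency in the gene model:
#' adjacent exons give an inclusion junction, exons separated by exactly one
#' (cassette) exon give a skipping junction; pass `type` to override (e.g.
#' `"control"` for the beta-actin exon 3|4 junction).
#'
#' @param models Gene-model tibble.
#' @param genome Named sequence set the model coordinates refer to.
#' @param gene_id Gene to design for.
#' @param upstream_exon_id,downstream_exon_id Exon IDs joined by the junction.
#' @param flank Nucleotides taken from each exon (default 15).
#' @param type Optional junction type override.
#' @param query_id Optional identifier; default
#'   `"<gene>:<up>|<down>"`.
#' @return One-row tibble: `query_id`, `gene_id`, `species_id`,
#'   `junction_type`, `upstream_exon_id`, `downstream_exon_id`, `sequence`.
#' @export
design_ejrna <- function(models, genome, gene_id, upstream_exon_id,
                         downstream_exon_id, flank = 15L, type = NULL,
                         query_id = NULL) {
  row <- model_row(models, gene_id)
  exons <- row$exons[[1]]
  iu <- match(upstream_exon_id, exons$exon_id)
  id <- match(downstream_exon_id, exons$exon_id)
  if (is.na(iu) || is.na(id)) {
    abort(sprintf("exon not in gene %s: %s", gene_id,
                  paste(setdiff(c(upstream_exon_id, downstream_exon_id),
                                exons$exon_id), collapse = ", ")))
  }
  if (id <= iu) abort("downstream exon must follow upstream exon in gene order")
  widths <- exons$end - exons$start + 1L
  if (widths[iu] < flank || widths[id] < flank) {
    abort(sprintf("exon shorter than flank (%d nt)", flank))
  }
  up_seq <- splice_transcript(models, exons$exon_id[iu], genome, gene_id)
  down_seq <- splice_transcript(models, exons$exon_id[id], genome, gene_id)
  seqc <- paste0(substr(up_seq, nchar(up_seq) - flank + 1L, nchar(up_seq)),
                 substr(down_seq, 1L, flank))
  jt <- type %||% if (id - iu == 1L) "inclusion"
        else if (id - iu == 2L) "skipping" else "other"
  tibble(query_id = query_id %||%
           sprintf("%s:%s|%s", gene_id, upstream_exon_id, downstream_exon_id),
         gene_id = gene_id, species_id = row$species_id,
         junction_type = jt,
         upstream_exon_id = upstream_exon_id,
         downstream_exon_id = downstream_exon_id,
         sequence = seqc)
}

#' Screen an ej-RNA set for uniqueness against a transcript collection
#'
#' Lists, for every query, the transcripts containing its 30-mer on either
#' strand. A query is unique when only its intended transcripts contain it.
#'
#' @param queries ej-RNA tibble ([design_ejrna()] rows).
#' @param transcripts Named sequence set to screen against.
#' @param intended Named list mapping `query_id` to the transcript names that
#'   are allowed to contain it. By default, transcripts whose name starts
#'   with the query's `gene_id` are considered intended.
#' @return Tibble: `query_id`, `hits` (list of transcript names), `n_hits`,
#'   `unique`, `unscreened` (TRUE when `transcripts` was empty: nothing was
#'   screened and `unique` is `NA`).
#' @export
check_uniqueness <- function(queries, transcripts, intended = NULL) {
  if (length(transcripts) == 0) {
    warn("empty transcript set; uniqueness unscreened")
    return(tibble(query_id = queries$query_id,
                  hits = rep(list(character()), nrow(queries)),
                  n_hits = 0L, unique = NA, unscreened = TRUE))
  }
  transcripts <- as_dna_set(transcripts)
  tx <- as.character(transcripts)
  tx_rc <- as.character(Biostrings::reverseComplement(transcripts))
  res <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries$sequence[i]
    hit <- names(tx)[stringr::str_detect(tx, stringr::fixed(q)) |
                       stringr::str_detect(tx_rc, stringr::fixed(q))]
    ok_set <- if (!is.null(intended)) intended[[queries$query_id[i]]] %||% character()
              else names(tx)[startsWith(names(tx), queries$gene_id[i])]
    tibble(query_id = queries$query_id[i], hits = list(hit),
           n_hits = length(hit),
           unique = all(hit %in% ok_set), unscreened = FALSE)
  })
  bind_rows(res)
}

#' Count reads containing ej-RNAs with perfect matches
#'
#' A read increments a query's count when the query's full sequence occurs in
#' the read with no mismatches and no gaps ("perfect 30/30"); each read
#' counts at most once per query, however many times the query occurs in it.
#' Under `strand_mode = "both"` (the default; library strandedness unknown)
#' the reverse complement is also searched. Reads shorter than the query
#' width silently contribute zero; reads with characters outside ACGTN are
#' skipped with a warning. Counts over disjoint read batches are additive.
#'
#' @param reads Named character vector, [Biostrings::DNAStringSet], or
#'   unnamed character vector (IDs are generated) of read sequences.
#' @param queries ej-RNA tibble with distinct `query_id`s and equal-width
#'   `sequence`s.
#' @param strand_mode `"both"` or `"forward"`.
#' @return Object of class `junction_counts`: list with `counts` (tibble
#'   `query_id`, `junction_type`, `count`), `matches` (tibble `read_id`,
#'   `query_id`, `offset` (0-based), `orientation`, `read_sequence`),
#'   `n_reads`, `strand_mode`. `tidy()` returns the count table.
#' @export
count_junction_reads <- function(reads, queries,
                                 strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (anyDuplicated(queries$query_id)) abort("duplicate query_id")
  if (length(unique(nchar(queries$sequence))) > 1) {
    abort("queries must share a single width")
  }
  if (any(grepl("[^ACGT]", queries$sequence))) {
    abort("query sequences must be plain ACGT")
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warn(sprintf("%d read(s) with non-ACGTN characters skipped", sum(bad)))
    reads <- reads[!bad]
  }
  w <- unique(nchar(queries$sequence))
  eligible <- reads[nchar(reads) >= w]
  hit_pairs <- scan_reads(eligible, queries$sequence, strand_mode)
  counts <- tibble(query_id = queries$query_id,
                   junction_type = queries$junction_type %||%
                     rep(NA_character_, nrow(queries)),
                   count = tabulate(hit_pairs$q, nbins = nrow(queries)))
  matches <- build_matches(hit_pairs, eligible, queries)
  multi <- unique(matches$read_id[duplicated(matches$read_id)])
  if (length(multi)) {
    warn(sprintf("%d read(s) matched more than one query; check query uniqueness",
                 length(multi)))
  }
  structure(list(counts = counts, matches = matches,
                 n_reads = length(reads), strand_mode = strand_mode),
            class = "junction_counts")
}

## Indexed multi-pattern scan: PDict over the (constant-width) queries,
## read-level hits via vwhichPDict, both strands by also scanning with the
## reverse-complemented dictionary.
scan_reads <- function(reads, query_seqs, strand_mode) {
  if (length(reads) == 0) {
    return(list(r = integer(), q = integer(), orient = character()))
  }
  subj <- Biostrings::DNAStringSet(reads)
  qset <- Biostrings::DNAStringSet(query_seqs)
  pd_f <- Biostrings::PDict(qset)
  hits_f <- Biostrings::vwhichPDict(pd_f, subj)
  r <- rep(seq_along(reads), lengths(hits_f))
  q <- unlist(hits_f, use.names = FALSE)
  orient <- rep("forward", length(q))
  if (strand_mode == "both") {
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(qset))
    hits_r <- Biostrings::vwhichPDict(pd_r, subj)
    r2 <- rep(seq_along(reads), lengths(hits_r))
    q2 <- unlist(hits_r, use.names = FALSE)
    ## read-level: drop rc hits already seen forward
    dup <- paste(r2, q2) %in% paste(r, q)
    r <- c(r, r2[!dup]); q <- c(q, q2[!dup])
    orient <- c(orient, rep("reverse_complement", sum(!dup)))
  }
  list(r = as.integer(r), q = as.integer(q), orient = orient)
}

build_matches <- function(hit_pairs, reads, queries) {
  if (!length(hit_pairs$r)) {
    return(tibble(read_id = character(), query_id = character(),
                  offset = integer(), orientation = character(),
                  read_sequence = character()))
  }
  offset <- integer(length(hit_pairs$r))
  for (k in seq_along(hit_pairs$r)) {
    rd <- reads[[hit_pairs$r[k]]]
    q <- queries$sequence[[hit_pairs$q[k]]]
    pat <- if (hit_pairs$orient[k] == "forward") q else revcomp(q)
    offset[k] <- regexpr(pat, rd, fixed = TRUE)[1] - 1L
  }
  tibble(read_id = names(reads)[hit_pairs$r],
         query_id = queries$query_id[hit_pairs$q],
         offset = offset,
         orientation = hit_pairs$orient,
         read_sequence = unname(reads[hit_pairs$r])) |>
    arrange(.data$read_id, .data$query_id)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("<junction_counts> %d queries over %d reads (strand_mode=%s)\n",
              nrow(x$counts), x$n_reads, x$strand_mode))
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.junction_counts <- function(x, ...) x$counts

#' @exportS3Method generics::glance
glance.junction_counts <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_queries = nrow(x$counts),
         n_matched_reads = length(unique(x$matches$read_id)),
         total_count = sum(x$counts$count))
}

#' Combine junction counts from disjoint read batches
#'
#' @param ... `junction_counts` objects over the same query set.
#' @return A `junction_counts` with summed counts and pooled matches.
#' @export
combine_junction_counts <- function(...) {
  xs <- list(...)
  ids <- xs[[1]]$counts$query_id
  for (x in xs) if (!identical(x$counts$query_id, ids)) {
    abort("junction_counts objects cover different query sets")
  }
  counts <- xs[[1]]$counts
  counts$count <- Reduce(`+`, lapply(xs, function(x) x$counts$count))
  structure(list(counts = counts,
                 matches = bind_rows(lapply(xs, `[[`, "matches")),
                 n_reads = sum(vapply(xs, `[[`, 0L, "n_reads")),
                 strand_mode = xs[[1]]$strand_mode),
            class = "junction_counts")
}
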