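#' QC parameters for matched-read classification
#'
#' @param max_subs Maximum scattered substitutions for a read to count as a
#'   legitimate (clean) transcript read (default 5, the bound observed on
#'   real clean junction reads).
#' @param min_leftover Minimum unexplained leftover length (nt) worth
#'   identifying against reference sets; shorter leftovers are
#'   `unidentified_short` (default 20, roughly the floor for confident
#'   sequence identification).
#' @param seed_len Exact-seed length used to identify leftovers (default 16).
#' @param stop_run Ungapped extension from the junction stops when this many
#'   consecutive mismatches are met (default 3).
#' @return List of parameters.
#' @export
qc_params <- function(max_subs = 5L, min_leftover = 20L, seed_len = 16L,
                      stop_run = 3L) {
  list(max_subs = as.integer(max_subs), min_leftover = as.integer(min_leftover),
       seed_len = as.integer(seed_len), stop_run = as.integer(stop_run))
}

qc_categories <- c("clean", "rearranged_same_gene", "chimeric_same_species",
                   "chimeric_foreign", "vector_or_barcode",
                   "unidentified_short")

## Precompute everything reusable across reads matching one query: the
## transcript byte vector, the junction position, and the reference sets
## (with reverse complements) in classification priority order.
prepare_qc_ctx <- function(query_sequence, expected_transcript,
                           same_gene = NULL, same_species_refs = NULL,
                           foreign_refs = NULL, vector_refs = NULL) {
  q <- toupper(as.character(query_sequence))
  tx <- toupper(as.character(expected_transcript))
  tpos <- regexpr(q, tx, fixed = TRUE)[1]
  if (tpos < 0) {
    abort("expected transcript lacks the junction 30-mer (configuration bug)")
  }
  prep <- function(refs) {
    if (is.null(refs) || !length(refs)) return(NULL)
    refs <- toupper(unname(as.character(refs)))
    c(refs, revcomp(refs))
  }
  list(q = q, qlen = nchar(q), tx = tx, tv = utf8ToInt(tx), tpos = tpos,
       sets = list(vector_or_barcode = prep(vector_refs),
                   rearranged_same_gene = prep(same_gene %||% tx),
                   chimeric_same_species = prep(same_species_refs),
                   chimeric_foreign = prep(foreign_refs)))
}

#' Classify one matched read into an identity/artifact category
#'
#' Verifies the read beyond its 30-mer junction match: the junction match is
#' extended without gaps in both directions against the expected isoform
#' transcript. If the entire read is explained with at most `max_subs`
#' scattered substitutions, the read is a legitimate transcript read
#' (`clean`). Otherwise the unexplained leftover is identified by exact
#' seed search (either strand) against, in priority order, vector/barcode
#' sequences, the same gene's transcripts (`rearranged_same_gene`: wrong
#' strand, wrong region, or separated by a gap), other transcripts of the
#' same species, then foreign references. Leftovers shorter than
#' `min_leftover`, or matching nothing, are `unidentified_short`.
#'
#' @param read_sequence Read (as stored in the FASTQ).
#' @param offset 0-based offset of the junction 30-mer in the read.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @param query_sequence The ej-RNA the read matched.
#' @param expected_transcript Transcript of the expected isoform; must
#'   contain the junction 30-mer (a configuration error otherwise).
#' @param same_gene Character vector/DNAStringSet of the same gene's
#'   transcripts (defaults to the expected transcript).
#' @param same_species_refs,foreign_refs,vector_refs Reference sets for
#'   leftover identification (may be `NULL`).
#' @param params [qc_params()].
#' @return One-row tibble: `category`, `substitutions`, `matched_span`,
#'   `leftover_len`, `hit_set`, `multi_hit`, `note`.
#' @export
classify_matched_read <- function(read_sequence, offset, orientation,
                                  query_sequence, expected_transcript,
                                  same_gene = NULL,
                                  same_species_refs = NULL,
                                  foreign_refs = NULL,
                                  vector_refs = NULL,
                                  params = qc_params()) {
  ctx <- prepare_qc_ctx(query_sequence, expected_transcript, same_gene,
                        same_species_refs, foreign_refs, vector_refs)
  as_tibble(classify_core(read_sequence, offset, orientation, ctx, params))
}

classify_core <- function(read_sequence, offset, orientation, ctx, params) {
  read <- toupper(as.character(read_sequence))
  if (orientation == "reverse_complement") {
    read <- revcomp(read)
    offset <- nchar(read) - offset - ctx$qlen
  }
  if (substr(read, offset + 1L, offset + ctx$qlen) != ctx$q) {
    abort("offset/orientation does not reproduce the query in the read")
  }
  rv <- utf8ToInt(read)
  tv <- ctx$tv
  len <- length(rv); lt <- length(tv)
  ## register: read position i <-> transcript position i + shift
  shift <- ctx$tpos - (offset + 1L)

  ## read lying entirely within the transcript at this register: compare
  ## base-by-base, so scattered substitutions at the read ends still count
  ## as substitutions rather than as unexplained leftover
  within <- (1L + shift) >= 1L && (len + shift) <= lt
  if (within) {
    m <- sum(rv != tv[seq_len(len) + shift])
    if (m <= params$max_subs) {
      return(qc_row("clean", m, len, 0L, character(), FALSE, ""))
    }
  }
  ext <- extend_match(rv, tv, shift, offset + 1L, offset + ctx$qlen, params)
  if (within && ext$left == 1L && ext$right == len) {
    ## whole read collinear with the expected transcript but too divergent
    return(qc_row("rearranged_same_gene", ext$subs, ext$span, 0L,
                  "same_gene", FALSE,
                  "excess divergence from expected transcript"))
  }
  ## leftover: the longer unexplained flank
  left_piece <- if (ext$left > 1L) substr(read, 1L, ext$left - 1L) else ""
  right_piece <- if (ext$right < len) substr(read, ext$right + 1L, len) else ""
  piece <- if (nchar(left_piece) >= nchar(right_piece)) left_piece else right_piece
  leftover_len <- nchar(left_piece) + nchar(right_piece)
  if (nchar(piece) < params$min_leftover) {
    return(qc_row("unidentified_short", ext$subs, ext$span, leftover_len,
                  character(), FALSE, "leftover too short to identify"))
  }
  hits <- names(ctx$sets)[vapply(ctx$sets, function(refs) {
    !is.null(refs) && seed_hit(piece, refs, params$seed_len)
  }, logical(1))]
  if (!length(hits)) {
    return(qc_row("unidentified_short", ext$subs, ext$span, leftover_len,
                  character(), FALSE, "leftover matched no reference set"))
  }
  qc_row(hits[[1]], ext$subs, ext$span, leftover_len, hits,
         length(hits) > 1L,
         if (length(hits) > 1L) "leftover matched multiple reference sets"
         else "")
}

## Maximal ungapped extension of [qs, qe] (read coords) against the
## transcript at fixed register `shift`; tolerates scattered substitutions up
## to max_subs total, stops at a run of stop_run consecutive mismatches or at
## either sequence's end. Returns explained read span and substitution count.
extend_match <- function(rv, tv, shift, qs, qe, params) {
  lt <- length(tv); len <- length(rv)
  subs <- 0L
  step <- function(from, dir) {
    pos <- from
    run <- 0L
    pending <- 0L  # trailing mismatches not yet confirmed by a later match
    repeat {
      nxt <- pos + dir
      tp <- nxt + shift
      if (nxt < 1L || nxt > len || tp < 1L || tp > lt) break
      if (rv[nxt] == tv[tp]) {
        subs <<- subs + pending
        pending <- 0L
        run <- 0L
        pos <- nxt
      } else {
        run <- run + 1L
        if (run >= params$stop_run) break
        if (subs + pending + 1L > params$max_subs) break
        pending <- pending + 1L
        pos <- nxt
      }
    }
    ## trailing unconfirmed mismatches are not part of the explained span
    pos - dir * pending
  }
  right <- step(qe, 1L)
  left <- step(qs, -1L)
  list(left = left, right = right, subs = subs, span = right - left + 1L)
}

## refs is a plain character vector that already contains both strands
seed_hit <- function(piece, refs, seed_len) {
  if (nchar(piece) < seed_len) return(FALSE)
  starts <- unique(c(seq(1L, nchar(piece) - seed_len + 1L, by = 8L),
                     nchar(piece) - seed_len + 1L))
  for (s in starts) {
    seed <- substr(piece, s, s + seed_len - 1L)
    if (any(grepl(seed, refs, fixed = TRUE))) return(TRUE)
  }
  FALSE
}

qc_row <- function(category, subs, span, leftover_len, hits, multi, note) {
  list(category = category, substitutions = as.integer(subs),
       matched_span = as.integer(span),
       leftover_len = as.integer(leftover_len),
       hit_set = paste(hits, collapse = ","), multi_hit = multi, note = note)
}

#' Classify all matched reads of a counting run
#'
#' Data-frame wrapper over [classify_matched_read()]: joins each matched read
#' to its query and expected transcript and returns one category per read
#' (reads matching several queries are classified against the first). The
#' reference preparation (junction location, both-strand reference sets) is
#' done once per query, so large matched-read sets classify quickly.
#'
#' @param matches `matches` tibble from [count_junction_reads()] (or a
#'   `junction_counts` object).
#' @param queries ej-RNA tibble.
#' @param expected Named list/character: `query_id` -> expected isoform
#'   transcript sequence.
#' @param same_gene Optional: character vector of the gene's transcripts, or
#'   a named list keyed by `query_id`.
#' @param same_species_refs,foreign_refs,vector_refs Reference sets; each
#'   may also be a named list keyed by `query_id`.
#' @param params [qc_params()].
#' @return Tibble: `read_id`, `query_id`, `read_length`, and the
#'   [classify_matched_read()] columns.
#' @export
classify_reads <- function(matches, queries, expected, same_gene = NULL,
                           same_species_refs = NULL, foreign_refs = NULL,
                           vector_refs = NULL, params = qc_params()) {
  if (inherits(matches, "junction_counts")) matches <- matches$matches
  matches <- matches[!duplicated(matches$read_id), ]
  template <- tibble(read_id = character(), query_id = character(),
                     read_length = integer(), category = character(),
                     substitutions = integer(), matched_span = integer(),
                     leftover_len = integer(), hit_set = character(),
                     multi_hit = logical(), note = character())
  if (!nrow(matches)) return(template)
  ## reference sets may be given once for all queries, or as named lists
  ## keyed by query_id
  pick <- function(x, qid) if (is.list(x)) x[[qid]] else x
  out <- vector("list", length(unique(matches$query_id)))
  k <- 0L
  for (qid in unique(matches$query_id)) {
    qrow <- queries[queries$query_id == qid, ]
    if (nrow(qrow) != 1) abort(sprintf("query '%s' not found", qid))
    ctx <- prepare_qc_ctx(qrow$sequence, expected[[qid]],
                          pick(same_gene, qid),
                          pick(same_species_refs, qid),
                          pick(foreign_refs, qid),
                          pick(vector_refs, qid))
    sub <- matches[matches$query_id == qid, ]
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      classify_core(sub$read_sequence[i], sub$offset[i], sub$orientation[i],
                    ctx, params)
    })
    k <- k + 1L
    out[[k]] <- tibble(
      read_id = sub$read_id, query_id = qid,
      read_length = nchar(sub$read_sequence),
      category = vapply(rows, `[[`, "", "category"),
      substitutions = vapply(rows, `[[`, 0L, "substitutions"),
      matched_span = vapply(rows, `[[`, 0L, "matched_span"),
      leftover_len = vapply(rows, `[[`, 0L, "leftover_len"),
      hit_set = vapply(rows, `[[`, "", "hit_set"),
      multi_hit = vapply(rows, `[[`, TRUE, "multi_hit"),
      note = vapply(rows, `[[`, "", "note"))
  }
  bind_rows(out)
}

#' Summarise QC categories
#'
#' @param categories Character vector of category labels, or a
#'   [classify_reads()] tibble (its `category`/`read_length` columns are
#'   used).
#' @param read_lengths Read lengths (nt), recycled against `categories`;
#'   optional when `categories` is a tibble.
#' @return One-row tibble: `n_reads`, `mean_read_length` (total nt / reads,
#'   rounded to the nearest integer; `NA` for empty input), one count and one
#'   rounded integer-percent column per category. Counts always sum to the
#'   input size.
#' @examples
#' qc_summary(rep(c("clean", "chimeric_foreign"), c(2134, 64)), 108)
#' @export
qc_summary <- function(categories, read_lengths = NULL) {
  if (is.data.frame(categories)) {
    read_lengths <- read_lengths %||% categories$read_length
    categories <- categories$category
  }
  n <- length(categories)
  counts <- vapply(qc_categories, function(k) sum(categories == k), integer(1))
  unknown <- setdiff(unique(categories), qc_categories)
  if (length(unknown)) abort(paste("unknown category:", unknown[1]))
  out <- tibble(n_reads = n,
                mean_read_length = if (n == 0 || is.null(read_lengths)) {
                  NA_integer_
                } else {
                  as.integer(round_half_up(sum(rep_len(read_lengths, n)) / n))
                })
  for (k in qc_categories) {
    out[[paste0(k, "_n")]] <- counts[[k]]
    out[[paste0(k, "_pct")]] <-
      if (n == 0) 0L else as.integer(round_half_up(100 * counts[[k]] / n))
  }
  out
}
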