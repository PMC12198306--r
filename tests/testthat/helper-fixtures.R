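# Deterministic hand-built fixtures and independent oracles shared by the
# test files. Everything here is constructed in code; nothing is read from
# disk.

# A tiny plus-strand gene: 3 exons fully coding (120, 87, 99 nt), introns of
# 80 nt, 40 nt genomic flanks. Sequence is a fixed arbitrary pattern so
# tests are byte-reproducible without touching the RNG.
toy_gene <- function(gene_id = "g1", species_id = "toy", strand = "+") {
  base <- paste(rep(c("ACGTTGCA"), 200), collapse = "")
  exl <- c(120L, 87L, 99L)
  intl <- 80L
  flank <- 40L
  starts <- integer(3); ends <- integer(3)
  pos <- flank + 1L
  for (i in 1:3) {
    starts[i] <- pos; ends[i] <- pos + exl[i] - 1L
    pos <- ends[i] + 1L + intl
  }
  contig <- substr(base, 1, ends[3] + flank)
  if (strand == "-") {
    L <- nchar(contig)
    contig <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(contig)))
    tmp <- starts
    starts <- L - ends + 1L
    ends <- L - tmp + 1L
  }
  exons <- tibble::tibble(exon_id = paste0("e", 1:3),
                          start = starts, end = ends, cds_len = exl)
  models <- gene_model(gene_id, species_id, "chrT", strand, exons)
  genome <- Biostrings::DNAStringSet(stats::setNames(contig, "chrT"))
  list(models = models, genome = genome)
}

# Naive per-read, per-query substring scan: the independent oracle for the
# indexed junction counter.
naive_count <- function(reads, queries, strand_mode = "both") {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  counts <- stats::setNames(integer(nrow(queries)), queries$query_id)
  pairs <- list()
  for (r in names(reads)) {
    for (k in seq_len(nrow(queries))) {
      q <- queries$sequence[k]
      hit_f <- grepl(q, reads[[r]], fixed = TRUE)
      hit_r <- strand_mode == "both" && grepl(rc(q), reads[[r]], fixed = TRUE)
      if (hit_f || hit_r) {
        counts[k] <- counts[k] + 1L
        pairs[[length(pairs) + 1L]] <-
          data.frame(read_id = r, query_id = queries$query_id[k],
                     orientation = if (hit_f) "forward"
                                   else "reverse_complement")
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(read_id = character(), query_id = character(),
               orientation = character())
  pairs <- pairs[order(pairs$read_id, pairs$query_id), ]
  rownames(pairs) <- NULL
  list(counts = counts, pairs = pairs)
}

# Brute-force recomputation of the column scores and window means, written
# directly from the scoring rules (independent of the package internals).
brute_profile <- function(aln, w, groups = default_substitution_groups()) {
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(m); W <- ncol(m)
  grp <- function(a) {
    for (gi in seq_along(groups)) if (a %in% groups[[gi]]) return(gi)
    0L
  }
  col_score <- function(j) {
    col <- m[, j]
    if (!any(col %in% c("-", ".")) && length(unique(col)) == 1) return(3)
    tot <- 0; np <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      np <- np + 1
      if (col[a] %in% c("-", ".") || col[b] %in% c("-", ".")) next
      if (col[a] == col[b]) tot <- tot + 2
      else if (grp(col[a]) != 0 && grp(col[a]) == grp(col[b])) tot <- tot + 1
    }
    tot / np
  }
  ns <- vapply(seq_len(W), col_score, numeric(1))
  starts <- seq_len(W - w + 1)
  data.frame(center = starts + (if (w %% 2 == 0) w %/% 2 else (w - 1) %/% 2),
             score = vapply(starts, function(s) mean(ns[s:(s + w - 1)]),
                            numeric(1)))
}

# Exhaustive small-parsimony minimum: enumerate every assignment of states
# to internal nodes and count changed edges (vectorized over assignments in
# chunks, so the 19-internal-node fixture enumerates in seconds).
enum_min_changes <- function(tree, tip_states) {
  states <- ifelse(tip_states[tree$tip.label] == "present", 1L, 0L)
  ntip <- ape::Ntip(tree)
  internal <- sort(unique(tree$edge[, 1]))
  m <- length(internal)
  edge <- tree$edge
  best <- Inf
  total <- 2^m
  chunk <- 65536L
  for (lo in seq(0, total - 1, by = chunk)) {
    masks <- lo:min(lo + chunk - 1, total - 1)
    B <- vapply(seq_len(m) - 1L,
                function(b) bitwAnd(bitwShiftR(masks, b), 1L),
                integer(length(masks)))
    cost <- integer(length(masks))
    for (e in seq_len(nrow(edge))) {
      p <- B[, match(edge[e, 1], internal)]
      k <- if (edge[e, 2] <= ntip) states[edge[e, 2]]
           else B[, match(edge[e, 2], internal)]
      cost <- cost + (p != k)
    }
    best <- min(best, min(cost))
  }
  as.integer(best)
}

# Random rooted binary tree with named tips, via ape.
random_tip_tree <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr
}
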