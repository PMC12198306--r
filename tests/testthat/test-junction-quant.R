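# A fixed two-gene fixture used throughout: target gene with cassette exon
# target.e6 and an actb-like control.
fx <- simulate_gene_fixture(seed = 42)

test_that("ej-RNA design joins 15 nt of each exon terminus", {
  # hand-built exons with known termini
  up <- "GATTACAGATTACAG"   # last 15 nt of the upstream exon
  down <- "CCCGGGTTTAAACCC" # first 15 nt of the downstream exon
  e1 <- paste0(strrep("A", 25), up)
  e2 <- paste0(down, strrep("T", 25))
  contig <- paste0(strrep("G", 10), e1, strrep("C", 50), e2, strrep("G", 10))
  ex <- tibble::tibble(exon_id = c("x1", "x2"),
                       start = c(11, 11 + 40 + 50),
                       end = c(10 + 40, 10 + 40 + 50 + 40),
                       cds_len = c(39, 39))
  suppressWarnings(gm <- gene_model("gx", "toy", "c", "+", ex))
  q <- design_ejrna(gm, c(c = contig), "gx", "x1", "x2")
  expect_equal(q$sequence, paste0(up, down))
  expect_equal(nchar(q$sequence), 30)
  expect_equal(q$junction_type, "inclusion")
})

test_that("inclusion and skipping queries share their first 15 nt", {
  q <- design_junction_queries(fx)
  incl <- q$sequence[q$junction_type == "inclusion"]
  skip <- q$sequence[q$junction_type == "skipping"]
  expect_identical(substr(incl, 1, 15), substr(skip, 1, 15))
  expect_false(substr(incl, 16, 30) == substr(skip, 16, 30))
  # control joins the control gene's exon 3 and exon 4
  ctl <- q[q$junction_type == "control", ]
  expect_equal(ctl$upstream_exon_id, "actb.e3")
  expect_equal(ctl$downstream_exon_id, "actb.e4")
  expect_true(all(nchar(q$sequence) == 30))
})

test_that("design rejects short exons and unknown exon IDs", {
  ex <- tibble::tibble(exon_id = c("a", "b"), start = c(1, 100),
                       end = c(10, 200), cds_len = c(9, 99))
  suppressWarnings(gm <- gene_model("g", "toy", "c", "+", ex))
  genome <- c(c = strrep("ACGT", 100))
  expect_error(design_ejrna(gm, genome, "g", "a", "b"), "shorter than flank")
  expect_error(design_ejrna(gm, genome, "g", "a", "zz"), "not in gene")
  expect_error(design_ejrna(gm, genome, "g", "b", "a"), "must follow")
})

test_that("uniqueness screen finds intended and planted occurrences", {
  q <- design_junction_queries(fx)
  rep_ <- check_uniqueness(q, fx$transcripts)
  # inclusion query occurs only in the inclusion transcript; the skipping
  # transcript lacks that junction entirely
  incl_row <- rep_[rep_$query_id == q$query_id[q$junction_type == "inclusion"], ]
  expect_identical(incl_row$hits[[1]], "target|inclusion")
  expect_true(incl_row$unique)
  skip_row <- rep_[rep_$query_id == q$query_id[q$junction_type == "skipping"], ]
  expect_identical(skip_row$hits[[1]], "target|skipping")
  # plant a query inside an unrelated transcript -> non-unique, named
  planted <- fx$transcripts
  planted[["actb|inclusion"]] <- paste0(
    planted[["actb|inclusion"]], q$sequence[q$junction_type == "inclusion"])
  rep2 <- check_uniqueness(q, planted)
  bad <- rep2[rep2$query_id == incl_row$query_id, ]
  expect_false(bad$unique)
  expect_true("actb|inclusion" %in% bad$hits[[1]])
  # empty transcript set -> unscreened flag
  expect_warning(rep3 <- check_uniqueness(q, character()), "unscreened")
  expect_true(all(rep3$unscreened))
})

test_that("counting requires a perfect, gap-free 30/30 match", {
  q <- design_junction_queries(fx)[1, ]
  tx <- fx$transcripts[["target|inclusion"]]
  pos <- regexpr(q$sequence, tx, fixed = TRUE)[1]
  read_ok <- substr(tx, pos - 20, pos + 50)
  read_sub <- read_ok
  # one substitution inside the 30-mer
  p <- 21 + 14
  substr(read_sub, p, p) <- if (substr(read_sub, p, p) == "A") "C" else "A"
  jc <- count_junction_reads(c(r1 = read_ok, r2 = read_sub), q)
  expect_equal(jc$counts$count, 1L)
  expect_equal(jc$matches$read_id, "r1")
  # the matched 30-mer at the reported offset reproduces the query
  expect_identical(substr(jc$matches$read_sequence,
                          jc$matches$offset + 1, jc$matches$offset + 30),
                   q$sequence)
})

test_that("strand_mode both finds reverse-complement reads; forward does not", {
  q <- design_junction_queries(fx)[1, ]
  tx <- fx$transcripts[["target|inclusion"]]
  pos <- regexpr(q$sequence, tx, fixed = TRUE)[1]
  frag <- substr(tx, pos - 25, pos + 55)
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  both <- count_junction_reads(c(r = rc_read), q, strand_mode = "both")
  fwd <- count_junction_reads(c(r = rc_read), q, strand_mode = "forward")
  expect_equal(both$counts$count, 1L)
  expect_equal(both$matches$orientation, "reverse_complement")
  expect_equal(fwd$counts$count, 0L)
  # offset/orientation re-verifies for rc matches too
  m <- both$matches
  got <- substr(m$read_sequence, m$offset + 1, m$offset + 30)
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(got))), q$sequence)
})

test_that("a read counts once per query even with repeated occurrences", {
  q <- tibble::tibble(query_id = "q1", gene_id = "g", species_id = "s",
                      junction_type = "inclusion",
                      sequence = strrep("ACGTTGCAAC", 3))
  read <- paste0(q$sequence, "TTTT", q$sequence)
  jc <- count_junction_reads(c(r = read), q)
  expect_equal(jc$counts$count, 1L)
  expect_equal(nrow(jc$matches), 1L)
})

test_that("degenerate reads are handled per contract", {
  q <- design_junction_queries(fx)[1, ]
  short <- substr(q$sequence, 1, 29)              # < query width: never counts
  expect_warning(
    jc <- count_junction_reads(c(a = short, b = "ACGTXX", c = q$sequence), q),
    "non-ACGTN")
  expect_equal(jc$counts$count, 1L)
  dup <- dplyr::bind_rows(q, q)
  expect_error(count_junction_reads(c(r = q$sequence), dup),
               "duplicate query_id")
})

test_that("counts over disjoint batches are additive", {
  q <- design_junction_queries(fx)
  tx <- fx$transcripts[["target|inclusion"]]
  pos <- regexpr(q$sequence[1], tx, fixed = TRUE)[1]
  read <- substr(tx, pos - 10, pos + 45)
  b1 <- count_junction_reads(c(r1 = read, r2 = strrep("A", 50)), q)
  b2 <- count_junction_reads(c(r3 = read), q)
  all_in_one <- count_junction_reads(
    c(r1 = read, r2 = strrep("A", 50), r3 = read), q)
  comb <- combine_junction_counts(b1, b2)
  expect_equal(comb$counts$count, all_in_one$counts$count)
  expect_equal(comb$n_reads, 3L)
  # monotonicity: adding reads never decreases any count
  expect_true(all(comb$counts$count >= b1$counts$count))
})

test_that("indexed scan equals the naive per-read per-query oracle", {
  set.seed(7)
  q <- design_junction_queries(fx)
  txs <- fx$transcripts
  reads <- character(400)
  for (i in seq_along(reads)) {
    t <- txs[[sample(length(txs), 1)]]
    len <- sample(30:120, 1)
    s <- sample(nchar(t) - len + 1, 1)
    r <- substr(t, s, s + len - 1)
    if (runif(1) < 0.5) {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    reads[i] <- r
  }
  names(reads) <- paste0("read", seq_along(reads))
  for (mode in c("both", "forward")) {
    jc <- count_junction_reads(reads, q, strand_mode = mode)
    oracle <- naive_count(reads, q, strand_mode = mode)
    expect_equal(jc$counts$count, unname(oracle$counts[jc$counts$query_id]))
    got <- jc$matches[order(jc$matches$read_id, jc$matches$query_id),
                      c("read_id", "query_id", "orientation")]
    expect_equal(as.data.frame(got), oracle$pairs)
  }
})

test_that("tidy and glance summarise a counting run", {
  q <- design_junction_queries(fx)
  jc <- count_junction_reads(c(r = fx$transcripts[[1]]), q)
  expect_identical(tidy(jc), jc$counts)
  g <- glance(jc)
  expect_equal(g$n_reads, 1L)
  expect_equal(g$total_count, sum(jc$counts$count))
})
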