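fx <- simulate_gene_fixture(seed = 42)
q_all <- design_junction_queries(fx)
q1 <- q_all[1, ]
tx <- fx$transcripts[["target|inclusion"]]
jpos <- regexpr(q1$sequence, tx, fixed = TRUE)[1]

read_at <- function(from, to) substr(tx, from, to)

test_that("reads explained by the expected transcript are clean", {
  read <- read_at(jpos - 40, jpos + 70)
  res <- classify_matched_read(read, 40, "forward", q1$sequence, tx)
  expect_equal(res$category, "clean")
  expect_equal(res$substitutions, 0L)

  # scattered substitutions up to the bound stay clean, even at read ends
  # (positions avoid the 30-mer at read positions 41..70, which must stay
  # perfect for the read to have been retrieved at all)
  sub <- read
  for (p in c(1, 20, 85, 111)) {
    substr(sub, p, p) <- if (substr(sub, p, p) == "A") "G" else "A"
  }
  res4 <- classify_matched_read(sub, 40, "forward", q1$sequence, tx)
  expect_equal(res4$category, "clean")
  expect_equal(res4$substitutions, 4L)
})

test_that("raising max_subs never moves a read out of clean", {
  read <- read_at(jpos - 30, jpos + 60)
  for (p in seq(3, 27, by = 6)) {
    substr(read, p, p) <- if (substr(read, p, p) == "C") "T" else "C"
  }
  for (ms in 5:10) {
    res <- classify_matched_read(read, 30, "forward", q1$sequence, tx,
                                 params = qc_params(max_subs = ms))
    if (ms >= 5) expect_equal(res$category, "clean")
  }
})

test_that("reverse-complement matches are verified after reorientation", {
  frag <- read_at(jpos - 35, jpos + 65)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  off <- nchar(rc) - 35 - 30  # 0-based offset of the rc 30-mer
  res <- classify_matched_read(rc, off, "reverse_complement",
                               q1$sequence, tx)
  expect_equal(res$category, "clean")
})

test_that("artifact categories are identified from the leftover", {
  frag <- read_at(jpos - 40, jpos + 44)
  vec <- strrep("TGCAGGTCCAGA", 10)
  sv <- classify_matched_read(paste0(frag, substr(vec, 1, 40)), 40, "forward",
                              q1$sequence, tx, vector_refs = vec)
  expect_equal(sv$category, "vector_or_barcode")

  # same-gene wrong-strand content -> rearranged
  other <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tx, 100, 160))))
  sr <- classify_matched_read(paste0(frag, other), 40, "forward",
                              q1$sequence, tx, vector_refs = vec)
  expect_equal(sr$category, "rearranged_same_gene")

  # foreign content; and priority flags when several sets hit
  foreign <- strrep("GATCCGTA", 30)
  sf <- classify_matched_read(paste0(frag, substr(foreign, 3, 60)), 40,
                              "forward", q1$sequence, tx,
                              foreign_refs = foreign)
  expect_equal(sf$category, "chimeric_foreign")

  # short unexplained leftover: complement of the transcript continuation,
  # so every appended base mismatches
  garbage <- chartr("ACGT", "TGCA", substr(tx, jpos + 45, jpos + 55))
  ss <- classify_matched_read(paste0(frag, garbage), 40, "forward",
                              q1$sequence, tx, vector_refs = vec)
  expect_equal(ss$category, "unidentified_short")
  expect_lt(ss$leftover_len, 20)
})

test_that("a transcript lacking the junction is a configuration error", {
  expect_error(
    classify_matched_read(read_at(jpos - 10, jpos + 40), 10, "forward",
                          q1$sequence, fx$transcripts[["actb|inclusion"]]),
    "configuration")
})

test_that("classification partitions matched reads and recovers truth", {
  scen <- simulation_scenario(
    tibble::tibble(species_id = "spA", pi_s = 0.4, n_reads = 4000),
    seed = 19, error_rate = 0, chimera_fraction = 0.15)
  sim <- simulate_reads(scen)
  res <- suppressWarnings(analyse_simulated(sim))
  truth <- sim$reads$truth_category[match(res$qc_reads$read_id,
                                          sim$reads$read_id)]
  # exact recovery on error-free constructs
  expect_identical(res$qc_reads$category, truth)
  # partition: category counts sum to the matched-read count
  s <- res$qc
  cats <- c("clean_n", "rearranged_same_gene_n", "chimeric_same_species_n",
            "chimeric_foreign_n", "vector_or_barcode_n",
            "unidentified_short_n")
  expect_equal(sum(unlist(s[cats])), nrow(res$qc_reads))
})

test_that("clean recall stays high at the default error rate", {
  scen <- simulation_scenario(
    tibble::tibble(species_id = "spB", pi_s = 0.3, n_reads = 6000),
    seed = 23)  # defaults: error 0.005, chimeras 0.03
  sim <- simulate_reads(scen)
  res <- suppressWarnings(analyse_simulated(sim))
  truth <- sim$reads$truth_category[match(res$qc_reads$read_id,
                                          sim$reads$read_id)]
  clean_truth <- truth == "clean"
  recall <- mean(res$qc_reads$category[clean_truth] == "clean")
  expect_gte(recall, 0.95)
})

test_that("qc_summary reproduces printed means and fractions", {
  # 2,198 reads totalling 236,984 nt -> mean read length 108
  lens <- rep(c(108L, 107L), c(1798L, 400L))
  expect_equal(sum(lens), 236984L)
  cats <- rep(c("clean", "chimeric_foreign"), c(2134L, 64L))
  s <- qc_summary(cats, lens)
  expect_equal(s$n_reads, 2198L)
  expect_equal(s$mean_read_length, 108L)
  expect_equal(s$clean_pct, 97L)
  expect_equal(s$clean_n + s$chimeric_foreign_n, 2198L)
  # 65 artifact reads of 2,198 -> 3%
  s2 <- qc_summary(rep(c("clean", "vector_or_barcode"), c(2133L, 65L)))
  expect_equal(s2$vector_or_barcode_pct, 3L)
  # single clean read
  s3 <- qc_summary("clean", 50)
  expect_equal(s3$mean_read_length, 50L)
  expect_equal(s3$clean_pct, 100L)
  # empty input: all-zero counts, absent mean
  s0 <- qc_summary(character())
  expect_equal(s0$n_reads, 0L)
  expect_true(is.na(s0$mean_read_length))
})
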