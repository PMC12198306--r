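# Gene models built directly from exon tables; protein rows are written by
# hand so anchor columns are known exactly.

# 6-exon gene: a 9-codon cassette exon (e3) flanked by phase-0 introns.
# Per-exon codons: 10, 8, 9, 7, 6 -> 40 codons + implicit stop handling
# is irrelevant here (anchors only need cds_len bookkeeping).
anchored_gene <- function(gene_id, cassette = TRUE) {
  codons <- if (cassette) c(10L, 8L, 9L, 7L, 6L) else c(10L, 8L, 7L, 6L)
  cds <- 3L * codons
  starts <- cumsum(c(1L, head(cds, -1) + 50L))
  ex <- tibble::tibble(exon_id = paste0("e", seq_along(cds)),
                       start = starts, end = starts + cds - 1L,
                       cds_len = cds)
  gene_model(gene_id, "toy", "c", "+", ex)
}

test_that("anchors land between codons for phase 0, inside for phase 1/2", {
  # gapless alignment: intron after codon 10, phase 0 -> anchor at column 10
  gm <- anchored_gene("ga")
  aln <- matrix(strsplit(strrep("M", 40), "")[[1]], nrow = 1)
  aln <- rbind(aln, aln)
  rownames(aln) <- c("ga", "other")
  a <- map_intron_to_alignment(gm, "ga", aln, "ga")
  expect_equal(a$column, c(10L, 18L, 27L, 34L))
  expect_equal(a$phase, rep(0L, 4))

  # three leading gap columns shift every anchor by 3
  gapped <- cbind(matrix(c("-", "M"), 2, 3), aln)
  rownames(gapped) <- c("ga", "other")
  a2 <- map_intron_to_alignment(gm, "ga", gapped, "ga")
  expect_equal(a2$column, a$column + 3L)

  # phase-1 intron inside codon 4 anchors at the column holding residue 4
  ex <- tibble::tibble(exon_id = c("p1", "p2"),
                       start = c(1, 100), end = c(10, 210),
                       cds_len = c(10L, 110L))
  gm1 <- gene_model("gp", "toy", "c", "+", ex)
  aln1 <- matrix(strsplit(strrep("M", 40), "")[[1]], nrow = 1)
  aln1 <- rbind(aln1, aln1); rownames(aln1) <- c("gp", "x")
  a3 <- map_intron_to_alignment(gm1, "gp", aln1, "gp")
  expect_equal(a3$phase, 1L)
  expect_equal(a3$column, 4L)
})

test_that("row/translation mismatch is a hard error naming the residue", {
  gm <- anchored_gene("ga")
  aln <- matrix(strsplit(strrep("M", 40), "")[[1]], nrow = 1)
  rownames(aln) <- "ga"
  aln2 <- rbind(aln, aln); rownames(aln2) <- c("ga", "b")
  good <- strrep("M", 40)
  expect_silent(map_intron_to_alignment(gm, "ga", aln2, "ga",
                                        translation = good))
  bad <- paste0(strrep("M", 19), "W", strrep("M", 20))
  expect_error(map_intron_to_alignment(gm, "ga", aln2, "ga",
                                       translation = bad),
               "residue 20")
})

test_that("conserved pairs need identical column and identical phase", {
  a <- tibble::tibble(intron_id = c("i1", "i2"), row = "a",
                      column = c(10L, 20L), phase = c(0L, 1L))
  b <- tibble::tibble(intron_id = c("j1", "j2"), row = "b",
                      column = c(10L, 20L), phase = c(0L, 0L))
  p <- conserved_intron_pairs(a, b)
  expect_equal(nrow(p), 1L)           # phases 1 vs 0 at column 20: no pair
  expect_equal(p$intron_a, "i1")
  # symmetric
  p2 <- conserved_intron_pairs(b, a)
  expect_equal(p2$intron_a, "j1")
  # one column apart: not paired at default slack 0, paired at slack 1
  b2 <- tibble::tibble(intron_id = "j1", row = "b", column = 11L, phase = 0L)
  expect_equal(nrow(conserved_intron_pairs(a, b2)), 0L)
  expect_equal(nrow(conserved_intron_pairs(a, b2, slack = 1)), 1L)
  # identical anchor sets pair completely
  expect_equal(nrow(conserved_intron_pairs(a, a)), 2L)
})

test_that("anchor mapping ignores all-gap columns outside the anchored span", {
  gm <- anchored_gene("ga")
  base <- matrix(strsplit(strrep("M", 40), "")[[1]], nrow = 1)
  base <- rbind(base, base); rownames(base) <- c("ga", "b")
  a0 <- map_intron_to_alignment(gm, "ga", base, "ga")
  # insert 5 all-gap columns at the far right: anchors unchanged
  wide <- cbind(base, matrix("-", 2, 5))
  rownames(wide) <- c("ga", "b")
  a1 <- map_intron_to_alignment(gm, "ga", wide, "ga")
  expect_equal(a1$column, a0$column)
})

exon_loss_alignment <- function() {
  # gene A: 40 residues, cassette e3 = residues 19..27
  # gene B: same protein minus those 9 residues, gapped in the alignment
  resA <- strsplit(paste0(strrep("A", 18), strrep("W", 9), strrep("K", 13)),
                   "")[[1]]
  resB <- resA
  resB[19:27] <- "-"
  m <- rbind(resA, resB)
  rownames(m) <- c("gA", "gB")
  m
}

test_that("the deletion-by-recombination signature is detected", {
  models <- dplyr::bind_rows(anchored_gene("gA"),
                             anchored_gene("gB", cassette = FALSE))
  m <- exon_loss_alignment()
  call <- detect_exon_loss_signature(models, "gA", "gB", m,
                                     cassette_exon_id = "e3")
  expect_equal(call$verdict, "deleted_by_intron_recombination")
  # gene B shows exactly one phase-0 anchor where gene A shows two
  ev <- call$evidence
  in_span <- ev$anchors_b$column >= 18 & ev$anchors_b$column <= 27 &
    ev$anchors_b$phase == 0
  expect_equal(sum(in_span), 1L)
  expect_equal(glance(call)$gap_fraction_b, 1)
})

test_that("an identical partner gene reads as retained", {
  models <- dplyr::bind_rows(anchored_gene("gA"), anchored_gene("gB"))
  res <- strsplit(strrep("M", 40), "")[[1]]
  m <- rbind(res, res); rownames(m) <- c("gA", "gB")
  call <- detect_exon_loss_signature(models, "gA", "gB", m,
                                     cassette_exon_id = "e3")
  expect_equal(call$verdict, "retained")
})

test_that("a fused intron of the wrong phase gives no signature", {
  # gene B misses the exon but its remaining intron is phase 1
  gB <- {
    codons <- c(10L, 8L, 7L, 6L)
    cds <- 3L * codons
    cds[2] <- cds[2] + 1L  # shift: the fused intron falls inside a codon
    cds[3] <- cds[3] - 1L
    starts <- cumsum(c(1L, head(cds, -1) + 50L))
    ex <- tibble::tibble(exon_id = paste0("e", seq_along(cds)),
                         start = starts, end = starts + cds - 1L,
                         cds_len = cds)
    gene_model("gB", "toy", "c", "+", ex)
  }
  models <- dplyr::bind_rows(anchored_gene("gA"), gB)
  m <- exon_loss_alignment()
  call <- detect_exon_loss_signature(models, "gA", "gB", m,
                                     cassette_exon_id = "e3")
  expect_equal(call$verdict, "no_signature")
})

test_that("a missing alignment row is a hard error", {
  models <- dplyr::bind_rows(anchored_gene("gA"),
                             anchored_gene("gB", cassette = FALSE))
  m <- exon_loss_alignment()
  rownames(m) <- c("gA", "gX")
  expect_error(detect_exon_loss_signature(models, "gA", "gB", m,
                                          cassette_exon_id = "e3"),
               "lacks row")
})
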