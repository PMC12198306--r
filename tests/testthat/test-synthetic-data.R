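test_that("fixture generation is byte-deterministic under a fixed seed", {
  f1 <- simulate_gene_fixture(seed = 77)
  f2 <- simulate_gene_fixture(seed = 77)
  expect_identical(as.character(f1$genome), as.character(f2$genome))
  expect_identical(f1$transcripts, f2$transcripts)
  f3 <- simulate_gene_fixture(seed = 78)
  expect_false(identical(as.character(f1$genome), as.character(f3$genome)))
})

test_that("default fixtures carry a phase-0 flanked cassette with an
           in-frame skipping transcript", {
  fx <- simulate_gene_fixture(seed = 13)
  tgt <- fx$models[fx$models$gene_id == "target", ]
  introns <- tgt$introns[[1]]
  k <- match(fx$meta$cassette_exon, tgt$exons[[1]]$exon_id)
  expect_equal(introns$phase[k - 1], 0L)
  expect_equal(introns$phase[k], 0L)
  cass_len <- tgt$exons[[1]]$cds_len[k]
  expect_true(cass_len / 3 >= 24 && cass_len / 3 <= 33)
  expect_false(translate_cds(fx$transcripts[["target|skipping"]])$premature_stop)
})

test_that("non-zero flank phases break the skipping reading frame", {
  fx <- simulate_gene_fixture(list(flank_phases = c(0L, 1L)), seed = 13)
  tgt <- fx$models[fx$models$gene_id == "target", ]
  k <- match(fx$meta$cassette_exon, tgt$exons[[1]]$exon_id)
  expect_equal(tgt$introns[[1]]$phase[k - 1], 0L)
  expect_equal(tgt$introns[[1]]$phase[k], 1L)
  skip <- fx$transcripts[["target|skipping"]]
  expect_true(nchar(skip) %% 3 != 0 ||
                translate_cds(skip)$premature_stop)
  expect_error(simulate_gene_fixture(list(cassette_codons = 0L)),
               "at least 1 codon")
})

test_that("read simulation is deterministic and respects pi_s = 0", {
  sp <- tibble::tibble(species_id = "s1", pi_s = 0, n_reads = 3000)
  scen <- simulation_scenario(sp, seed = 5)
  sim1 <- simulate_reads(scen)
  sim2 <- simulate_reads(scen)
  expect_identical(sim1$reads$sequence, sim2$reads$sequence)
  q <- design_junction_queries(sim1$fixtures$s1)
  jc <- count_junction_reads(
    setNames(sim1$reads$sequence, sim1$reads$read_id), q)
  expect_equal(jc$counts$count[jc$counts$junction_type == "skipping"], 0L)
  expect_gt(jc$counts$count[jc$counts$junction_type == "inclusion"], 0L)
  expect_error(simulation_scenario(
    tibble::tibble(species_id = "s", pi_s = 1.4, n_reads = 10), seed = 1),
    "pi_s")
})

test_that("junction counts match the spanning-position arithmetic", {
  # error-free, chimera-free: expected junction count =
  # sum over reads of (len - 29) / (L - len + 1) for reads on the
  # inclusion transcript; observed within 4 sigma binomial bounds
  sp <- tibble::tibble(species_id = "s1", pi_s = 0, n_reads = 30000)
  scen <- simulation_scenario(sp, seed = 9, error_rate = 0,
                              chimera_fraction = 0, control_weight = 0,
                              read_len_sd = 0)
  sim <- simulate_reads(scen)
  fx <- sim$fixtures$s1
  L <- nchar(fx$transcripts[["target|inclusion"]])
  len <- 108
  p <- (len - 29) / (L - len + 1)
  q <- design_junction_queries(fx)
  jc <- count_junction_reads(setNames(sim$reads$sequence,
                                      sim$reads$read_id), q)
  obs <- jc$counts$count[jc$counts$junction_type == "inclusion"]
  mu <- 30000 * p
  sigma <- sqrt(30000 * p * (1 - p))
  expect_lt(abs(obs - mu), 4 * sigma)
})

test_that("the chimera fraction reappears as the non-clean share of
           junction-spanning reads", {
  sp <- tibble::tibble(species_id = "s1", pi_s = 0.5, n_reads = 10000)
  scen <- simulation_scenario(sp, seed = 21, error_rate = 0,
                              chimera_fraction = 0.03)
  sim <- simulate_reads(scen)
  res <- suppressWarnings(analyse_simulated(sim))
  frac <- 1 - res$qc$clean_n / res$qc$n_reads
  n <- res$qc$n_reads
  sigma <- sqrt(0.03 * 0.97 / n)
  expect_lt(abs(frac - 0.03), 4 * sigma + 0.005)
})

test_that("scenario_from_table encodes the truth presence pattern", {
  tab <- species_status_fixture()
  expect_equal(nrow(tab), 29L)
  expect_equal(sum(tab$s_present), 12L)
  scen <- scenario_from_table(tab, seed = 2)
  expect_equal(nrow(scen$species), 29L)
  expect_equal(sum(scen$species$pi_s > 0), 12L)
  expect_equal(scen$species$pi_s[!tab$s_present], rep(0, 17))
  # depth tiers map to read counts
  expect_setequal(unique(scen$species$n_reads), c(5000L, 10000L, 20000L))
  # empty table -> empty scenario
  empty <- scenario_from_table(tab[0, ], seed = 2)
  expect_equal(nrow(empty$species), 0L)
  expect_error(scenario_from_table(
    tibble::tibble(species_id = "x", s_present = TRUE, depth_tier = "huge"),
    seed = 1), "unknown depth tier")
})

test_that("FASTQ output round-trips and honors gzip", {
  sp <- tibble::tibble(species_id = "s1", pi_s = 0.2, n_reads = 50)
  sim <- simulate_reads(simulation_scenario(sp, seed = 4))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(sim, fq)
  back <- read_reads(fq)
  expect_identical(unname(back), sim$reads$sequence)
  expect_identical(names(back), sim$reads$read_id)
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_reads_fastq(sim, gz)
  expect_identical(unname(read_reads(gz)), sim$reads$sequence)
})

test_that("truth labels round-trip through the pipeline at zero noise", {
  tab <- species_status_fixture()[c(1, 4, 6, 21), ]  # mixed presence
  scen <- scenario_from_table(tab, seed = 15,
                              reads_per_tier = c(low = 4000, mid = 4000,
                                                 high = 4000),
                              error_rate = 0, chimera_fraction = 0)
  sim <- simulate_reads(scen)
  res <- analyse_simulated(sim)
  got <- res$presence$both_detected[match(tab$species_id,
                                          res$presence$species_id)]
  expect_identical(got, tab$s_present)
})
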