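#' Simulate a gene fixture: cassette-exon gene plus control gene
#'
#' Generates, deterministically for a given seed, a target gene carrying a
#' short internal cassette exon (by default 24-33 codons, flanked by two
#' phase-0 introns, mirroring the structure of the D2-receptor exon 6) and a
#' beta-actin-like control gene, together with their genomic sequences,
#' inclusion/skipping isoform definitions and spliced transcripts.
#'
#' @param config Named list overriding defaults: `species_id`, `gene_id`,
#'   `control_id`, `n_exons` (8), `cassette_index` (6), `cassette_codons`
#'   (`NULL` = draw from `cassette_codon_range`), `cassette_codon_range`
#'   (24:33), `exon_codon_range` (40:80, non-cassette exons),
#'   `flank_phases` (c(0, 0): phases of the introns up/downstream of the
#'   cassette exon), `intron_len_range` (80:200), `control_n_exons` (6),
#'   `strand` ("+").
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List of class `gene_fixture`: `models` (gene-model tibble),
#'   `genome` (named DNAStringSet, one contig per gene), `isoforms`
#'   (isoform tibble), `transcripts` (named character vector
#'   `"<gene>|<isoform>"`), `meta` (cassette exon id, junction exon ids).
#' @export
simulate_gene_fixture <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    species_id = "sim", gene_id = "target", control_id = "actb",
    n_exons = 8L, cassette_index = 6L, cassette_codons = NULL,
    cassette_codon_range = 24:33, exon_codon_range = 40:80,
    flank_phases = c(0L, 0L), intron_len_range = 80:200,
    control_n_exons = 6L, strand = "+"), config)
  with_seed(seed, build_fixture(cfg))
}

build_fixture <- function(cfg) {
  cass <- cfg$cassette_codons %||%
    sample(cfg$cassette_codon_range, 1L)
  if (cass < 1) abort("cassette exon must be at least 1 codon")
  k <- cfg$cassette_index
  if (k <= 1L || k >= cfg$n_exons) abort("cassette exon must be internal")
  codons <- sample(cfg$exon_codon_range, cfg$n_exons, replace = TRUE)
  cds_len <- 3L * codons
  ## shift boundaries so the cassette's flanking introns have the requested
  ## phases while the total CDS stays a codon multiple
  p1 <- cfg$flank_phases[1]; p2 <- cfg$flank_phases[2]
  b <- (p2 - p1) %% 3L
  cds_len[k] <- 3L * cass + b
  cds_len[k - 1L] <- cds_len[k - 1L] + p1
  cds_len[k + 1L] <- cds_len[k + 1L] + (3L - (p1 + b) %% 3L) %% 3L

  target <- build_gene(cfg$gene_id, cfg$species_id, cds_len,
                       cfg$intron_len_range, cfg$strand)
  ctl_cds <- 3L * sample(cfg$exon_codon_range, cfg$control_n_exons,
                         replace = TRUE)
  control <- build_gene(cfg$control_id, cfg$species_id, ctl_cds,
                        cfg$intron_len_range, cfg$strand)

  models <- bind_rows(target$model, control$model)
  genome <- Biostrings::DNAStringSet(
    setNames(c(target$contig, control$contig),
             c(target$model$seqid, control$model$seqid)))
  exon_ids <- target$model$exons[[1]]$exon_id
  isoforms <- bind_rows(
    isoform_model(paste0(cfg$gene_id, "|inclusion"), cfg$gene_id, exon_ids,
                  "inclusion"),
    isoform_model(paste0(cfg$gene_id, "|skipping"), cfg$gene_id,
                  exon_ids[-k], "skipping"),
    isoform_model(paste0(cfg$control_id, "|inclusion"), cfg$control_id,
                  control$model$exons[[1]]$exon_id, "inclusion"))
  transcripts <- vapply(seq_len(nrow(isoforms)), function(i) {
    splice_transcript(models, isoforms[i, ], genome)
  }, "")
  names(transcripts) <- isoforms$isoform_id
  structure(list(models = models, genome = genome, isoforms = isoforms,
                 transcripts = transcripts,
                 meta = list(species_id = cfg$species_id,
                             gene_id = cfg$gene_id,
                             control_id = cfg$control_id,
                             cassette_exon = exon_ids[k],
                             upstream_exon = exon_ids[k - 1L],
                             downstream_exon = exon_ids[k + 1L],
                             control_up =
                               control$model$exons[[1]]$exon_id[
                                 min(3L, cfg$control_n_exons - 1L)],
                             control_down =
                               control$model$exons[[1]]$exon_id[
                                 min(4L, cfg$control_n_exons)])),
            class = "gene_fixture")
}

## Random ORF split across exons; exons are pure CDS (cds_offset 0).
build_gene <- function(gene_id, species_id, cds_len, intron_len_range,
                       strand) {
  total <- sum(cds_len)
  n_cod <- total %/% 3L
  pad <- total - 3L * n_cod  # only when flank phases leave a partial codon
  stops <- c("TAA", "TAG", "TGA")
  codons <- all_codons()[!all_codons() %in% stops]
  cds <- paste0(c("ATG", sample(codons, n_cod - 1L, replace = TRUE),
                  if (pad > 0) random_dna(pad)), collapse = "")
  exon_seqs <- split_seq(cds, cds_len)
  introns <- vapply(seq_along(cds_len)[-1], function(i) {
    paste0("GT", random_dna(sample(intron_len_range, 1L) - 4L), "AG")
  }, "")
  flank5 <- random_dna(40L); flank3 <- random_dna(40L)
  contig <- paste0(flank5,
                   paste0(exon_seqs,
                          c(introns, ""), collapse = ""),
                   flank3)
  ## exon genomic coordinates on the plus strand of the contig
  starts <- integer(length(cds_len)); ends <- integer(length(cds_len))
  pos <- nchar(flank5) + 1L
  for (i in seq_along(cds_len)) {
    starts[i] <- pos
    ends[i] <- pos + cds_len[i] - 1L
    pos <- ends[i] + 1L + if (i < length(cds_len)) nchar(introns[i]) else 0L
  }
  seqid <- paste0(species_id, "_", gene_id)
  if (strand == "-") {
    L <- nchar(contig)
    contig <- revcomp(contig)
    tmp <- starts
    starts <- L - ends + 1L
    ends <- L - tmp + 1L
  }
  exons <- tibble(exon_id = paste0(gene_id, ".e", seq_along(cds_len)),
                  start = starts, end = ends, cds_len = cds_len)
  model <- gene_model(gene_id, species_id, seqid, strand, exons,
                      cds_offset = 0L)
  list(model = model, contig = contig)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

split_seq <- function(s, lens) {
  ends <- cumsum(lens)
  substring(s, ends - lens + 1L, ends)
}

#' Build a simulation scenario
#'
#' The scenario fixes every study condition of the synthetic experiment: the
#' species and their isoform mixing proportions, library sizes, the read
#' length distribution (mean 108 nt), the per-base substitution error rate,
#' and the chimeric-read contamination fraction with its five artifact
#' categories.
#'
#' @param species Tibble with `species_id`, `pi_s` (fraction of target-gene
#'   transcripts skipping the cassette exon) and `n_reads` per species.
#' @param seed Integer master seed; all randomness flows from it.
#' @param read_len_mean,read_len_sd Read length distribution (normal,
#'   rounded, truncated to [30, transcript length]).
#' @param error_rate Per-base substitution probability.
#' @param chimera_fraction Fraction of reads replaced by chimeric/artifact
#'   constructs.
#' @param chimera_mix Named probabilities over the five artifact categories.
#' @param control_weight Fraction of reads drawn from the control gene.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(species, seed = 1L,
                                read_len_mean = 108, read_len_sd = 12,
                                error_rate = 0.005,
                                chimera_fraction = 0.03,
                                chimera_mix = c(rearranged_same_gene = 0.2,
                                                chimeric_same_species = 0.2,
                                                chimeric_foreign = 0.2,
                                                vector_or_barcode = 0.2,
                                                unidentified_short = 0.2),
                                control_weight = 0.5) {
  stopifnot(all(c("species_id", "pi_s", "n_reads") %in% names(species)))
  if (any(species$pi_s < 0 | species$pi_s > 1)) abort("pi_s must lie in [0, 1]")
  if (chimera_fraction < 0 || chimera_fraction > 1) {
    abort("chimera_fraction must lie in [0, 1]")
  }
  structure(list(species = as_tibble(species), seed = as.integer(seed),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 error_rate = error_rate,
                 chimera_fraction = chimera_fraction,
                 chimera_mix = chimera_mix / sum(chimera_mix),
                 control_weight = control_weight),
            class = "simulation_scenario")
}

#' Scenario from a species status table
#'
#' Translates a per-species presence/depth table (such as
#' [species_status_fixture()]) into a full [simulation_scenario()]: species
#' flagged `s_present` get a skipping proportion of `pi_s_present`, others
#' exactly 0; depth tiers map to library read counts.
#'
#' @param status_table Tibble `species_id`, `s_present`, `depth_tier`.
#' @param seed Master seed.
#' @param reads_per_tier Named vector mapping depth tiers to read counts.
#' @param pi_s_present Skipping proportion for S-positive species.
#' @param ... Further arguments to [simulation_scenario()].
#' @return A `simulation_scenario` whose truth presence pattern equals the
#'   table.
#' @export
scenario_from_table <- function(status_table, seed = 1L,
                                reads_per_tier = c(low = 5000, mid = 10000,
                                                   high = 20000),
                                pi_s_present = 0.3, ...) {
  stopifnot(all(c("species_id", "s_present", "depth_tier") %in%
                  names(status_table)))
  if (nrow(status_table) == 0) {
    return(simulation_scenario(tibble(species_id = character(),
                                      pi_s = numeric(), n_reads = integer()),
                               seed = seed, ...))
  }
  unknown <- setdiff(status_table$depth_tier, names(reads_per_tier))
  if (length(unknown)) abort(paste("unknown depth tier:", unknown[1]))
  if (anyDuplicated(status_table$species_id)) {
    abort("duplicate species in status table")
  }
  species <- tibble(
    species_id = status_table$species_id,
    pi_s = ifelse(status_table$s_present, pi_s_present, 0),
    n_reads = as.integer(reads_per_tier[status_table$depth_tier]))
  simulation_scenario(species, seed = seed, ...)
}

#' Simulate RNA-Seq reads with truth labels
#'
#' Draws reads per species from the inclusion/skipping/control transcript
#' mixture (uniform start positions, normal read lengths, iid base
#' substitutions) and replaces a `chimera_fraction` of them with constructed
#' artifacts that keep an intact junction 30-mer — so artifact reads are
#' still retrieved by perfect-match counting, as real chimeric reads are —
#' plus flanking matched sequence and a category-specific foreign portion.
#' Every read carries its truth labels.
#'
#' @param scenario A [simulation_scenario()].
#' @return List of class `simulated_reads`: `reads` (tibble `read_id`,
#'   `species_id`, `sequence`, `truth_isoform`, `truth_category`),
#'   `fixtures` (named list of per-species [simulate_gene_fixture()]
#'   output), `vector_refs`, `foreign_refs`, `scenario`.
#' @export
simulate_reads <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  pools <- with_seed(child_seed(scenario$seed, "pools"), {
    list(vector = setNames(vapply(1:2, function(i) random_dna(300L), ""),
                           paste0("vector", 1:2)),
         foreign = setNames(vapply(1:3, function(i) random_dna(500L), ""),
                            paste0("foreign", 1:3)))
  })
  fixtures <- list(); read_tabs <- list()
  for (i in seq_len(nrow(scenario$species))) {
    sp <- scenario$species$species_id[i]
    fx <- simulate_gene_fixture(list(species_id = sp),
                                seed = child_seed(scenario$seed,
                                                  paste0("gene:", sp)))
    if (scenario$species$pi_s[i] > 0 &&
        !any(fx$isoforms$label == "skipping")) {
      abort("pi_s > 0 but no skipping transcript in the gene set")
    }
    reads <- with_seed(child_seed(scenario$seed, paste0("reads:", sp)),
                       species_reads(fx, scenario,
                                     scenario$species$pi_s[i],
                                     scenario$species$n_reads[i], pools))
    reads$species_id <- sp
    reads$read_id <- paste0(sp, "_r", seq_len(nrow(reads)))
    fixtures[[sp]] <- fx
    read_tabs[[sp]] <- reads
  }
  reads <- bind_rows(read_tabs)
  structure(list(reads = reads[, c("read_id", "species_id", "sequence",
                                   "truth_isoform", "truth_category")],
                 fixtures = fixtures,
                 vector_refs = pools$vector, foreign_refs = pools$foreign,
                 scenario = scenario),
            class = "simulated_reads")
}

species_reads <- function(fx, scen, pi_s, n_reads, pools) {
  tx <- fx$transcripts
  incl <- paste0(fx$meta$gene_id, "|inclusion")
  skip <- paste0(fx$meta$gene_id, "|skipping")
  ctl <- paste0(fx$meta$control_id, "|inclusion")
  probs <- c(scen$control_weight,
             (1 - scen$control_weight) * (1 - pi_s),
             (1 - scen$control_weight) * pi_s)
  src <- sample(c(ctl, incl, skip), n_reads, replace = TRUE, prob = probs)
  tlen <- nchar(tx)[src]
  len <- pmin(pmax(round(rnorm(n_reads, scen$read_len_mean,
                               scen$read_len_sd)), 30L), tlen)
  start <- floor(runif(n_reads) * (tlen - len + 1)) + 1L
  seqs <- substr(tx[src], start, start + len - 1L)
  seqs <- add_substitutions(seqs, scen$error_rate)
  category <- rep("clean", n_reads)

  ## the chimera fraction is a fraction of the junction-spanning (hence
  ## retrievable) reads: artifact reads still carry an intact junction
  ## 30-mer, so enrichment by junction matching keeps their proportion
  jpos <- junction_positions(fx)
  j_src <- unlist(jpos[src], use.names = FALSE)
  spans <- start <= j_src - 14L & start + len - 1L >= j_src + 15L
  is_chim <- spans & runif(n_reads) < scen$chimera_fraction
  if (any(is_chim)) {
    cats <- sample(names(scen$chimera_mix), sum(is_chim), replace = TRUE,
                   prob = scen$chimera_mix)
    chim <- vapply(seq_along(cats), function(j) {
      make_chimera(tx, src[is_chim][j], jpos, cats[j], fx, pools)
    }, "")
    seqs[is_chim] <- chim
    category[is_chim] <- cats
  }
  tibble(sequence = unname(seqs), truth_isoform = unname(src),
         truth_category = category)
}

## 1-based transcript position of the last base before each assayed junction
junction_positions <- function(fx) {
  out <- list()
  for (i in seq_len(nrow(fx$isoforms))) {
    iso <- fx$isoforms[i, ]
    coords <- exon_transcript_coords(fx$models, iso$gene_id,
                                     iso$exon_ids[[1]])
    up <- if (iso$gene_id == fx$meta$control_id) fx$meta$control_up
          else fx$meta$upstream_exon
    j <- coords$tx_end[match(up, coords$exon_id)]
    out[[iso$isoform_id]] <- j
  }
  out
}

add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  ## byte-level edits; each erroneous base is replaced by one of the other
  ## three, chosen uniformly
  alt <- list()
  bases <- utf8ToInt("ACGT")
  for (b in bases) alt[[as.character(b)]] <- setdiff(bases, b)
  for (i in idx) {
    r <- utf8ToInt(seqs[i])
    pos <- sample.int(lens[i], nerr[i])
    pick <- ceiling(runif(nerr[i]) * 3)
    r[pos] <- vapply(seq_along(pos), function(j) {
      alt[[as.character(r[pos[j]])]][pick[j]]
    }, 0L)
    seqs[i] <- intToUtf8(r)
  }
  seqs
}

## Build one artifact read: junction-spanning fragment (30-mer intact, with
## extra matched flanks) plus a category-specific extra portion whose first
## bases are forced to differ from the transcript continuation, so the
## chimera breakpoint is always detectable.
make_chimera <- function(tx, src, jpos, cat, fx, pools) {
  t <- tx[[src]]
  j <- jpos[[src]]
  left <- 15L + sample(10:45, 1L)
  right <- 15L + sample(10:45, 1L)
  left <- min(left, j)
  right <- min(right, nchar(t) - j)
  frag <- substr(t, j - left + 1L, j + right)
  cont_at <- j + right + 1L
  continuation <- substr(t, cont_at, min(nchar(t), cont_at + 4L))
  extra <- switch(cat,
    rearranged_same_gene = {
      L <- sample(40:80, 1L)
      s0 <- sample.int(max(nchar(t) - L, 1L), 1L)
      revcomp(substr(t, s0, s0 + L - 1L))
    },
    chimeric_same_species = {
      other <- names(tx)[!startsWith(names(tx), sub("\\|.*", "", src))][1]
      o <- tx[[other]]
      L <- sample(40:80, 1L)
      s0 <- sample.int(max(nchar(o) - L, 1L), 1L)
      substr(o, s0, s0 + L - 1L)
    },
    chimeric_foreign = {
      o <- pools$foreign[[sample.int(length(pools$foreign), 1L)]]
      L <- sample(40:80, 1L)
      s0 <- sample.int(nchar(o) - L, 1L)
      substr(o, s0, s0 + L - 1L)
    },
    vector_or_barcode = {
      o <- pools$vector[[sample.int(length(pools$vector), 1L)]]
      L <- sample(40:80, 1L)
      s0 <- sample.int(nchar(o) - L, 1L)
      substr(o, s0, s0 + L - 1L)
    },
    unidentified_short = random_dna(sample(8:15, 1L)),
    abort(paste("unknown chimera category", cat)))
  extra <- force_break(extra, continuation)
  paste0(frag, extra)
}

## Mutate up to the first 3 bases of `extra` so each differs from the
## transcript continuation at the same register.
force_break <- function(extra, continuation) {
  bases <- c("A", "C", "G", "T")
  k <- min(3L, nchar(extra), nchar(continuation))
  for (p in seq_len(k)) {
    if (substr(extra, p, p) == substr(continuation, p, p)) {
      substr(extra, p, p) <- bases[(match(substr(extra, p, p), bases)) %% 4L + 1L]
    }
  }
  extra
}

#' Write simulated reads as FASTQ
#'
#' Constant qualities (`I`); gzip output when the path ends in `.gz`.
#' @param reads `simulated_reads` object or its `reads` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    strrep("I", nchar(reads$sequence))), con)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' @param path FASTQ/FASTA file (optionally gzipped). Qualities are ignored.
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path) {
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1)
  set <- if (startsWith(first, "@")) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*", "", names(set))
  out
}
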