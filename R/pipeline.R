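#' Design the standard junction query set for a simulated species fixture
#'
#' Three ej-RNAs per species: the inclusion junction (upstream exon |
#' cassette exon), the skipping junction (upstream exon | downstream exon)
#' and the control junction on the beta-actin-like gene (exon 3 | exon 4).
#'
#' @param fixture A [simulate_gene_fixture()] result.
#' @param flank Nucleotides per exon side (default 15).
#' @return ej-RNA tibble with a `contains_cassette` column (TRUE for the
#'   inclusion junction, FALSE for the skipping junction, NA for control).
#' @export
design_junction_queries <- function(fixture, flank = 15L) {
  m <- fixture$meta
  q <- bind_rows(
    design_ejrna(fixture$models, fixture$genome, m$gene_id,
                 m$upstream_exon, m$cassette_exon, flank = flank),
    design_ejrna(fixture$models, fixture$genome, m$gene_id,
                 m$upstream_exon, m$downstream_exon, flank = flank),
    design_ejrna(fixture$models, fixture$genome, m$control_id,
                 m$control_up, m$control_down, flank = flank,
                 type = "control"))
  q$contains_cassette <- c(TRUE, FALSE, NA)
  q
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> design -> count -> qc -> report over a species
#' status table, with optional parsimony and conservation-scan stages, and
#' records a manifest (stage log, config digest, content digests of any
#' files written). Reruns with the same config and seed reproduce the
#' digests.
#'
#' @param config Named list (or path to a YAML/JSON file): fields
#'   `seed` (integer), `species_table` (tibble or TSV path; see
#'   [species_status_fixture()]), optional `reads_per_tier`, `pi_s_present`,
#'   `error_rate`, `chimera_fraction`, `min_reads`, `out_dir`,
#'   `run_parsimony` (logical: also run the shipped presence fixture through
#'   [skipping_parsimony()]).
#' @return Object of class `cassette_run`: list with `presence` (per-species
#'   report), `qc` (summary), `counts`, `depth`, optional `parsimony`,
#'   `manifest`. `glance()` summarises; `tidy()` returns the presence table.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  seed <- as.integer(config$seed %||% 1L)
  tab <- config$species_table %||% species_status_fixture()
  if (is.character(tab)) {
    if (!file.exists(tab)) abort(sprintf("species table not found: %s", tab))
    tab <- as_tibble(utils::read.delim(tab))
    tab$s_present <- as.logical(tab$s_present)
  }
  stages <- list()
  t0 <- Sys.time()
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      stages[[length(stages) + 1L]] <<- tibble(stage = name, status = "failed",
                                               detail = conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            manifest = bind_rows(stages))
    })
    stages[[length(stages) + 1L]] <<- tibble(stage = name, status = "ok",
                                             detail = "")
    res
  }

  scenario <- run_stage("simulate", scenario_from_table(
    tab, seed = seed,
    reads_per_tier = config$reads_per_tier %||%
      c(low = 5000, mid = 10000, high = 20000),
    pi_s_present = config$pi_s_present %||% 0.3,
    error_rate = config$error_rate %||% 0.005,
    chimera_fraction = config$chimera_fraction %||% 0.03))
  sim <- run_stage("simulate", simulate_reads(scenario))
  res <- run_stage("analyse", analyse_simulated(
    sim, min_reads = config$min_reads %||% 1L))
  parsimony <- NULL
  if (isTRUE(config$run_parsimony)) {
    parsimony <- run_stage("parsimony", {
      fx <- d2s_presence_fixture()
      skipping_parsimony(fx$tree, fx$tip_states)
    })
  }
  out <- structure(c(res, list(parsimony = parsimony, scenario = scenario)),
                   class = "cassette_run")
  if (!is.null(config$out_dir)) {
    run_stage("write", write_run(out, config$out_dir))
  }
  out$manifest <- list(config_digest = config_digest(config),
                       seed = seed,
                       stages = bind_rows(stages),
                       files = if (!is.null(config$out_dir)) {
                         file_digests(config$out_dir)
                       } else tibble(file = character(), md5 = character()),
                       elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
  out
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("yaml package required to read YAML configs")
      }
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

## analysis inputs only: where the outputs land does not change the run
config_digest <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

file_digests <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE, recursive = TRUE))
  tibble(file = basename(files), md5 = unname(tools::md5sum(files)))
}

#' Analyse a simulated read set
#'
#' The measurement half of the pipeline, separated so it can be applied to
#' any `simulated_reads` object: per species, design the query set, count
#' perfect junction matches on both strands, QC-classify every matched read,
#' aggregate L/S subtotals, normalize to the control, and call presence.
#'
#' @param sim A [simulate_reads()] result.
#' @param min_reads Presence threshold (default 1 read).
#' @param qc Run the QC classifier (default TRUE).
#' @return List: `presence` (per-species tibble), `counts` (per-query),
#'   `qc_reads`, `qc` (summary row), `depth` (a [depth_report()]).
#' @export
analyse_simulated <- function(sim, min_reads = 1L, qc = TRUE) {
  per_species <- list(); count_tabs <- list(); qc_tabs <- list()
  for (sp in names(sim$fixtures)) {
    fx <- sim$fixtures[[sp]]
    queries <- design_junction_queries(fx)
    reads <- sim$reads[sim$reads$species_id == sp, ]
    jc <- count_junction_reads(setNames(reads$sequence, reads$read_id),
                               queries)
    counts <- jc$counts
    counts$species_id <- sp
    count_tabs[[sp]] <- counts

    if (qc && nrow(jc$matches)) {
      expected <- expected_transcripts(fx, queries)
      same_gene <- lapply(setNames(queries$query_id, queries$query_id),
                          function(qid) {
        g <- queries$gene_id[queries$query_id == qid]
        unname(fx$transcripts[startsWith(names(fx$transcripts), paste0(g, "|"))])
      })
      same_species <- lapply(setNames(queries$query_id, queries$query_id),
                             function(qid) {
        g <- queries$gene_id[queries$query_id == qid]
        unname(fx$transcripts[!startsWith(names(fx$transcripts),
                                          paste0(g, "|"))])
      })
      qcr <- classify_reads(jc, queries, expected, same_gene = same_gene,
                            same_species_refs = same_species,
                            foreign_refs = sim$foreign_refs,
                            vector_refs = sim$vector_refs)
      qcr$species_id <- sp
      qc_tabs[[sp]] <- qcr
    }

    gene_counts <- counts[counts$junction_type != "control", ]
    sub <- aggregate_isoforms(
      tibble(query_id = gene_counts$query_id, count = gene_counts$count,
             species_id = sp, gene_id = fx$meta$gene_id),
      queries[!is.na(queries$contains_cassette),
              c("query_id", "contains_cassette")])
    actb <- sum(counts$count[counts$junction_type == "control"])
    expr <- isoform_expression(sub, actb, min_reads = min_reads)
    expr$species_id <- sp
    per_species[[sp]] <- expr
  }
  expr <- bind_rows(per_species)
  presence <- expr |>
    select("species_id", "gene_id", "isoform_class", "raw_count",
           "actb_count", "log10_ratio", "present") |>
    tidyr::pivot_wider(id_cols = c("species_id", "gene_id", "actb_count"),
                       names_from = "isoform_class",
                       values_from = c("raw_count", "log10_ratio", "present"))
  presence$both_detected <- presence$present_L & presence$present_S
  qc_reads <- bind_rows(qc_tabs)
  depth <- if (nrow(presence) >= 2) {
    depth_report(tibble(species_id = presence$species_id,
                        actb_total = presence$actb_count,
                        s_present = presence$present_S))
  }
  list(presence = presence,
       counts = bind_rows(count_tabs),
       qc_reads = qc_reads,
       qc = if (nrow(qc_reads)) qc_summary(qc_reads) else NULL,
       depth = depth)
}

expected_transcripts <- function(fx, queries) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$query_id[i]
    g <- queries$gene_id[i]
    iso <- switch(queries$junction_type[i],
                  skipping = paste0(g, "|skipping"),
                  paste0(g, "|inclusion"))
    out[[qid]] <- unname(fx$transcripts[[iso]])
  }
  out
}

#' @export
print.cassette_run <- function(x, ...) {
  cat(sprintf("<cassette_run> %d species; %d detected both isoforms\n",
              nrow(x$presence), sum(x$presence$both_detected)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cassette_run <- function(x, ...) x$presence

#' @exportS3Method generics::glance
glance.cassette_run <- function(x, ...) {
  tibble(n_species = nrow(x$presence),
         n_both_detected = sum(x$presence$both_detected),
         n_l_only = sum(x$presence$present_L & !x$presence$present_S),
         depth_association = if (!is.null(x$depth)) x$depth$association
                             else NA_real_,
         clean_pct = if (!is.null(x$qc)) x$qc$clean_pct else NA_integer_)
}

write_run <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(x$presence, "presence.tsv")
  tsv(x$counts, "counts.tsv")
  if (nrow(x$qc_reads)) tsv(x$qc_reads, "qc_reads.tsv")
  if (!is.null(x$qc)) {
    jsonlite::write_json(as.list(x$qc), file.path(out_dir, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
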