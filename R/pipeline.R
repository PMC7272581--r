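# End-to-end orchestration: simulate (or load) reads, genotype, quantify,
# build the comparative locus-set datasets, and summarize. Every stage
# persists plain-text intermediates (FASTA/FASTQ/TSV/JSON) so it can be
# re-run or audited independently; all outputs are deterministic under the
# configured seed.

#' Pipeline configuration
#'
#' Either simulate a cohort (`simulate = list(...)`) or point at existing
#' inputs (`panel_fasta`/`panel_annotation` plus per-sample FASTQ pairs in
#' `reads`). A YAML file with the same fields can be loaded with
#' [load_pipeline_config()].
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed recorded in every output header.
#' @param sets Locus sets to build (subset of 1:4).
#' @param min_unique_support Genotyper threshold.
#' @param min_n Minimum per-group n for allele summaries.
#' @param simulate List of arguments for the simulator: `n_samples`,
#'   `alleles_per_locus`, `divergence`, `depth`, `error_rate`, plus any
#'   [sim_config()] field.
#' @param panel_fasta,panel_annotation Reference panel paths (used when not
#'   simulating; also written when simulating).
#' @param reads Named list: per sample, `c(r1 = path, r2 = path)`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sets = 1:4,
                            min_unique_support = 10, min_n = 3,
                            simulate = NULL, panel_fasta = NULL,
                            panel_annotation = NULL, reads = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, all(sets %in% 1:4))
  if (is.null(simulate) &&
      (is.null(panel_fasta) || is.null(panel_annotation) || is.null(reads))) {
    stop("config error: provide either `simulate` or panel paths plus reads",
         call. = FALSE)
  }
  if (!is.null(panel_fasta) && !file.exists(panel_fasta)) {
    stop("config error: panel FASTA not found: ", panel_fasta, call. = FALSE)
  }
  if (!is.null(panel_annotation) && !file.exists(panel_annotation)) {
    stop("config error: panel annotation not found: ", panel_annotation,
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sets = as.integer(sets),
                 min_unique_support = min_unique_support, min_n = min_n,
                 simulate = simulate, panel_fasta = panel_fasta,
                 panel_annotation = panel_annotation, reads = reads),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @param out_dir Optional override of the config's `out_dir`.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

log_event <- function(con, event, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full pipeline
#'
#' Stages: (1) obtain panel and reads (simulated with ground truth, or
#' loaded from disk); (2) genotype every sample per locus; (3) classify
#' phase and count in-phase reads; (4) build the requested normalized locus
#' set datasets; (5) per-set locus and allele summaries. Stage outputs are
#' written under `config$out_dir` as they complete; the run report records
#' read accounting (total, perfectly matched, in-phase) per sample.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log.jsonl")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  log_event(con, "start", seed = config$seed,
            config_hash = digest_config(config))

  # stage 1: panel + reads
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    panel <- synthesize_panel(
      loci = sim$loci %||% .LOCI,
      alleles_per_locus = sim$alleles_per_locus %||% 3,
      divergence = sim$divergence %||% 4,
      seed = config$seed)
    cfg_args <- sim[intersect(names(sim), names(formals(sim_config)))]
    cfg_args$seed <- config$seed
    scfg <- do.call(sim_config, cfg_args)
    genos <- simulate_genotypes(panel, scfg$n_samples,
                                seed = config$seed + 1L)
    truth <- simulate_expression(genos, scfg, panel)
    em <- emit_reads(truth, panel, scfg, out_dir = config$out_dir)
    reads <- lapply(em$reads, function(r) c(r$r1, r$r2))
    write_reference_set(panel, file.path(config$out_dir, "panel.fasta"),
                        file.path(config$out_dir, "panel_exons.tsv"))
    write_tsv(genos, file.path(config$out_dir, "genotypes_truth.tsv"))
  } else {
    panel <- load_reference_set(config$panel_fasta, config$panel_annotation)
    reads <- lapply(config$reads, function(p) c(read_fastq(p[["r1"]]),
                                                read_fastq(p[["r2"]])))
  }
  log_event(con, "panel_ready", n_alleles = length(panel$alleles),
            n_samples = length(reads))

  # stage 2-3: genotype + quantify
  calls <- list(); phase <- list(); counts <- list(); acct <- list()
  for (sid in names(reads)) {
    rr <- reads[[sid]]
    cl <- genotype_sample(rr, panel,
                          min_unique_support = config$min_unique_support)
    calls[[sid]] <- cl
    q <- quantify_sample(cl, panel, sample_id = sid)
    phase[[sid]] <- q$phase
    counts[[sid]] <- q$counts
    hits <- attr(cl, "hits")
    acct[[sid]] <- data.frame(
      sample_id = sid,
      reads_total = length(rr),
      reads_matched = length(unique(hits$read_id)),
      reads_in_phase = sum(q$counts$raw_reads),
      stringsAsFactors = FALSE)
    log_event(con, "sample_done", sample = sid,
              matched = length(unique(hits$read_id)))
  }
  gt <- genotype_table(calls)
  phase <- do.call(rbind, c(phase, list(make.row.names = FALSE)))
  counts <- do.call(rbind, c(counts, list(make.row.names = FALSE)))
  acct <- do.call(rbind, c(acct, list(make.row.names = FALSE)))
  write_tsv(gt, file.path(config$out_dir, "genotypes.tsv"))
  write_tsv(phase, file.path(config$out_dir, "phase.tsv"))
  write_tsv(counts, file.path(config$out_dir, "counts.tsv"))

  # stage 4-5: datasets + summaries
  exclusions <- list()
  for (k in config$sets) {
    ds <- build_dataset(counts, phase, k)
    write_tsv(ds, file.path(config$out_dir, sprintf("dataset_%d.tsv", k)))
    exclusions[[as.character(k)]] <- as.list(attr(ds, "excluded"))
    if (nrow(ds)) {
      write_tsv(locus_summary(ds),
                file.path(config$out_dir, sprintf("locus_summary_%d.tsv", k)))
      asum <- allele_summary(ds, min_n = config$min_n)
      if (!is.null(asum)) {
        write_tsv(asum,
                  file.path(config$out_dir,
                            sprintf("allele_summary_%d.tsv", k)))
      }
    }
    log_event(con, "dataset_done", set = k, rows = nrow(ds))
  }

  report <- list(
    seed = config$seed,
    config_hash = digest_config(config),
    package_version = as.character(utils::packageVersion("hlacapture")),
    n_samples = length(reads),
    n_alleles = length(panel$alleles),
    accounting = acct,
    excluded_samples = exclusions
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  log_event(con, "done")
  invisible(report)
}

digest_config <- function(config) {
  # stable short hash of the serialized config (no external digest dep)
  raw <- serialize(unclass(config)[order(names(unclass(config)))], NULL,
                   version = 2)
  sum <- 0
  for (b in as.integer(raw)) sum <- (sum * 31 + b) %% 2147483647
  sprintf("%08x", sum)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `genotype`, `quantify`, `stats`
#' and `run` over the package's exported functions. This is the function
#' behind the `inst/cli/hlacapture.R` wrapper script; it is exported so the
#' dispatch logic is unit-testable.
#'
#' @param args Character vector of command-line arguments (first element:
#'   subcommand).
#' @return Exit status, invisibly: 0 success, 2 usage/config error.
#' @export
hlacapture_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hlacapture <command> [options]",
    "commands:",
    "  run      --config <yaml> [--out <dir>] [--seed <int>]",
    "  simulate --out <dir> [--samples <n>] [--depth <n>] [--seed <int>]",
    "  genotype --reads1 <fq> --reads2 <fq> --panel <fa> --annotation <tsv>",
    "           --out <tsv> [--min-support <n>]",
    "  quantify --reads1 <fq> --reads2 <fq> --panel <fa> --annotation <tsv>",
    "           --sets <1,2,3,4> --out <dir>",
    "  stats    --counts <dataset tsv> --out <dir> [--min-n <n>]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  status <- tryCatch({
    switch(cmd,
      run = {
        cfg <- load_pipeline_config(opts[["config"]],
                                    out_dir = opts[["out"]])
        if (!is.null(opts[["seed"]])) cfg$seed <- as.integer(opts[["seed"]])
        run_pipeline(cfg)
        0L
      },
      simulate = {
        cfg <- pipeline_config(
          out_dir = opts[["out"]],
          seed = as.integer(opts[["seed"]] %||% 1),
          simulate = list(n_samples = as.integer(opts[["samples"]] %||% 6),
                          depth = as.integer(opts[["depth"]] %||% 2000)))
        sim <- cfg$simulate
        panel <- synthesize_panel(seed = cfg$seed)
        scfg <- sim_config(n_samples = sim$n_samples, depth = sim$depth,
                           seed = cfg$seed)
        genos <- simulate_genotypes(panel, scfg$n_samples,
                                    seed = cfg$seed + 1L)
        truth <- simulate_expression(genos, scfg, panel)
        emit_reads(truth, panel, scfg, out_dir = cfg$out_dir)
        write_reference_set(panel, file.path(cfg$out_dir, "panel.fasta"),
                            file.path(cfg$out_dir, "panel_exons.tsv"))
        0L
      },
      genotype = {
        panel <- load_reference_set(opts[["panel"]], opts[["annotation"]])
        rr <- c(read_fastq(opts[["reads1"]]), read_fastq(opts[["reads2"]]))
        cl <- genotype_sample(rr, panel,
          min_unique_support = as.integer(opts[["min-support"]] %||% 10))
        write_tsv(genotype_table(cl), opts[["out"]])
        0L
      },
      quantify = {
        panel <- load_reference_set(opts[["panel"]], opts[["annotation"]])
        rr <- c(read_fastq(opts[["reads1"]]), read_fastq(opts[["reads2"]]))
        cl <- genotype_sample(rr, panel)
        q <- quantify_sample(cl, panel,
                             sample_id = opts[["sample"]] %||% "S1")
        dir.create(opts[["out"]], showWarnings = FALSE, recursive = TRUE)
        write_tsv(q$phase, file.path(opts[["out"]], "phase.tsv"))
        write_tsv(q$counts, file.path(opts[["out"]], "counts.tsv"))
        sets <- as.integer(strsplit(opts[["sets"]] %||% "2", ",")[[1]])
        for (k in sets) {
          write_tsv(build_dataset(q$counts, q$phase, k),
                    file.path(opts[["out"]], sprintf("dataset_%d.tsv", k)))
        }
        0L
      },
      stats = {
        ds <- read_tsv(opts[["counts"]])
        dir.create(opts[["out"]], showWarnings = FALSE, recursive = TRUE)
        write_tsv(locus_summary(ds),
                  file.path(opts[["out"]], "locus_summary.tsv"))
        asum <- allele_summary(ds, min_n = as.integer(opts[["min-n"]] %||% 3))
        if (!is.null(asum)) {
          write_tsv(asum, file.path(opts[["out"]], "allele_summary.tsv"))
        }
        0L
      },
      { message(usage); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

# "--key value" pairs -> named list
parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opts[[substring(args[i], 3)]] <- args[i + 1]
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  opts
}
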