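#' Load a pipeline run configuration
#'
#' Reads a YAML configuration exposing the cascade thresholds and simulation
#' settings, merged over the package defaults. Recognised sections:
#' `quality` (min_total_reads, min_variant_reads, min_variant_fraction),
#' `rarity` (max_maf, require_inhouse_absent), `conservation` (min_phylop),
#' `association` (alpha, conf_level, min_expected), `simulate_families`
#' and `simulate_replication` (fields of the respective config
#' constructors, seeds excluded — the run seed governs).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested list of configuration values.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- list(
    quality = list(min_total_reads = 10L, min_variant_reads = 5L,
                   min_variant_fraction = 0.20),
    rarity = list(max_maf = 0.001, require_inhouse_absent = TRUE),
    conservation = list(min_phylop = 3.0),
    association = list(alpha = 0.05, conf_level = 0.95, min_expected = 5),
    simulate_families = list(n_families = 12L, members_per_family = 2L,
                             n_background_variants = 500L),
    simulate_replication = list(n_cases = 381L, n_controls = 381L,
                                control_carrier_freq = 2 / 381,
                                true_odds_ratio = 4.59, missing_rate = 0,
                                n_variants = 1L)
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  for (sec in intersect(names(user), names(defaults))) {
    for (key in intersect(names(user[[sec]]), names(defaults[[sec]]))) {
      defaults[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  defaults
}

log_kv <- function(stage, ...) {
  kv <- list(...)
  message(paste0("stage=", stage,
                 if (length(kv)) paste0(" ", paste(names(kv), unlist(kv),
                                                   sep = "=", collapse = " "))
                 else ""))
}

#' Run the full pipeline end to end
#'
#' Chains simulation, prioritization, association, and cohort summary:
#' simulates a family cohort and a replication cohort from the run seed,
#' writes them under `out_dir`, reads the cohort VCF back through the
#' standard readers, runs the cascade, associates the replication table, and
#' summarizes the packaged clinical table. With a fixed seed the run is
#' fully reproducible, byte for byte.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing both simulations.
#' @param config Configuration list from [load_run_config()].
#' @param clinical_path Clinical table to summarize; defaults to the
#'   packaged familial-cohort fixture.
#' @return Invisibly, list with `cascade` (a `cascade_report`),
#'   `association` (an `assoc_table`), `summary` (a `cohort_summary`), and
#'   `paths`.
#' @export
run_pipeline <- function(out_dir, seed, config = load_run_config(),
                         clinical_path = system.file("extdata",
                                                     "familial_cd_clinical.tsv",
                                                     package = "famrvar")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam_cfg <- do.call(family_sim_config,
                     c(config$simulate_families, list(seed = seed)))
  sim <- simulate_families(fam_cfg)
  sim_paths <- write_family_sim(sim, file.path(out_dir, "simulated"))
  log_kv("simulate", families = fam_cfg$n_families,
         variants = nrow(sim$variants))

  vcf <- read_vcf(sim_paths$vcf)
  pedigree <- read_pedigree(sim_paths$pedigree)
  panels <- read_gene_panels(sim_paths$gwas, sim_paths$pid, sim_paths$pathway)
  report <- run_cascade(vcf$variants, vcf$calls, pedigree, panels,
                        quality = do.call(quality_thresholds, config$quality),
                        rarity = do.call(rarity_thresholds, config$rarity),
                        conservation = do.call(conservation_threshold,
                                               config$conservation))
  cascade_tsv <- file.path(out_dir, "cascade_report.tsv")
  write_cascade_report(report, cascade_tsv,
                       file.path(out_dir, "cascade_detail.json"))
  for (i in seq_len(nrow(report$stages))) {
    log_kv("prioritize", stage = report$stages$stage[i],
           remaining = report$stages$n[i])
  }

  rep_cfg <- do.call(replication_sim_config,
                     c(config$simulate_replication, list(seed = seed + 1L)))
  rep_sim <- simulate_replication(rep_cfg)
  rep_tsv <- file.path(out_dir, "replication_tallies.tsv")
  write_tsv(rep_sim$tallies, rep_tsv)
  assoc <- associate_all(rep_sim$tallies,
                         alpha = config$association$alpha,
                         conf_level = config$association$conf_level,
                         min_expected = config$association$min_expected)
  assoc_tsv <- file.path(out_dir, "association.tsv")
  write_assoc_table(assoc, assoc_tsv)
  log_kv("associate", variants = nrow(assoc),
         significant = sum(assoc$significant))

  clin <- read_clinical_table(clinical_path)
  summ <- summarize_cohort(clin)
  summary_tsv <- file.path(out_dir, "cohort_summary.tsv")
  write_cohort_summary(summ, summary_tsv,
                       file.path(out_dir, "cohort_summary.json"))
  log_kv("summarize", n = summ$n)

  invisible(list(cascade = report, association = assoc, summary = summ,
                 paths = list(simulated = sim_paths, cascade = cascade_tsv,
                              replication = rep_tsv, association = assoc_tsv,
                              summary = summary_tsv)))
}

cli_usage <- function() {
  paste(
    "usage: famrvar <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate    --seed INT --out-dir DIR [--config FILE]",
    "  prioritize  --vcf FILE --pedigree FILE --gwas FILE --pid FILE",
    "              --pathway FILE --out-dir DIR [--config FILE]",
    "              [--pass-list FILE] [--cap-list FILE]",
    "  associate   --tallies FILE --out-dir DIR [--config FILE]",
    "  summarize   --clinical FILE --out-dir DIR",
    "  run-all     --seed INT --out-dir DIR [--config FILE]",
    "",
    "common options: --version",
    sep = "\n")
}

parse_cli <- function(args) {
  known_flags <- c("--seed", "--out-dir", "--config", "--vcf", "--pedigree",
                   "--gwas", "--pid", "--pathway", "--tallies", "--clinical",
                   "--pass-list", "--cap-list")
  out <- list(subcommand = NULL, opts = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--version") {
      out$opts$version <- TRUE
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (!a %in% known_flags) stop("unknown flag: ", a, call. = FALSE)
      if (i == length(args)) stop("flag needs a value: ", a, call. = FALSE)
      out$opts[[gsub("-", "_", sub("^--", "", a))]] <- args[[i + 1L]]
      i <- i + 2L
    } else if (is.null(out$subcommand)) {
      out$subcommand <- a
      i <- i + 1L
    } else {
      stop("unexpected argument: ", a, call. = FALSE)
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `prioritize`,
#' `associate`, `summarize`, `run-all`) from an argument vector and returns
#' a process exit status: 0 on success, 2 on a usage error (with usage text
#' on stderr), 1 on a data or validation error. The installed script
#' `inst/cli/famrvar` forwards `commandArgs()` here.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
famrvar_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli(args), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed))
    message(cli_usage())
    return(invisible(2L))
  }
  if (isTRUE(parsed$opts$version)) {
    message("famrvar ", as.character(utils::packageVersion("famrvar")))
    return(invisible(0L))
  }
  sub <- parsed$subcommand
  if (is.null(sub) ||
      !sub %in% c("simulate", "prioritize", "associate", "summarize",
                  "run-all")) {
    message(cli_usage())
    return(invisible(2L))
  }
  o <- parsed$opts
  need <- function(keys) {
    miss <- setdiff(keys, names(o))
    if (length(miss)) {
      stop("missing required option(s): ",
           paste0("--", gsub("_", "-", miss), collapse = ", "), call. = FALSE)
    }
  }
  status <- tryCatch({
    config <- load_run_config(o$config)
    switch(sub,
      "simulate" = {
        need(c("seed", "out_dir"))
        cfg <- do.call(family_sim_config,
                       c(config$simulate_families,
                         list(seed = as.integer(o$seed))))
        write_family_sim(simulate_families(cfg),
                         file.path(o$out_dir, "simulated"))
        log_kv("simulate", seed = o$seed, out = o$out_dir)
      },
      "prioritize" = {
        need(c("vcf", "pedigree", "gwas", "pid", "pathway", "out_dir"))
        dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
        vcf <- read_vcf(o$vcf)
        report <- run_cascade(
          vcf$variants, vcf$calls, read_pedigree(o$pedigree),
          read_gene_panels(o$gwas, o$pid, o$pathway),
          quality = do.call(quality_thresholds, config$quality),
          rarity = do.call(rarity_thresholds, config$rarity),
          conservation = do.call(conservation_threshold, config$conservation),
          pass_list = if (!is.null(o$pass_list)) readLines(o$pass_list),
          cap_list = if (!is.null(o$cap_list)) readLines(o$cap_list))
        write_cascade_report(report,
                             file.path(o$out_dir, "cascade_report.tsv"),
                             file.path(o$out_dir, "cascade_detail.json"))
        for (i in seq_len(nrow(report$stages))) {
          log_kv("prioritize", stage = report$stages$stage[i],
                 remaining = report$stages$n[i])
        }
      },
      "associate" = {
        need(c("tallies", "out_dir"))
        dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
        assoc <- associate_all(read_replication_table(o$tallies),
                               alpha = config$association$alpha,
                               conf_level = config$association$conf_level,
                               min_expected = config$association$min_expected)
        write_assoc_table(assoc, file.path(o$out_dir, "association.tsv"))
        log_kv("associate", variants = nrow(assoc),
               significant = sum(assoc$significant))
      },
      "summarize" = {
        need(c("clinical", "out_dir"))
        dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
        summ <- summarize_cohort(read_clinical_table(o$clinical))
        write_cohort_summary(summ, file.path(o$out_dir, "cohort_summary.tsv"),
                             file.path(o$out_dir, "cohort_summary.json"))
        log_kv("summarize", n = summ$n)
      },
      "run-all" = {
        need(c("seed", "out_dir"))
        run_pipeline(o$out_dir, as.integer(o$seed), config = config)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
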