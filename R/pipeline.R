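# End-to-end orchestration: simulate (or load) -> mutation matrix ->
# prevalence -> burden-adjusted differential -> candidate screen, with a
# JSON run manifest making outputs pure functions of (inputs, config,
# seed).

#' Default pipeline configuration
#'
#' @param seed Global seed routed to every stage.
#' @param n_iter Monte-Carlo iterations for the burden null.
#' @param alpha Significance level for direction calls and the screen.
#' @param min_prevalence Localized-prevalence candidate gate.
#' @param cna_segment_mbp Mean CNA segment length for the null.
#' @param synthetic Either `NULL` (inputs must be files) or a list of
#'   arguments passed to [synthetic_config()] /
#'   [synthetic_driver_catalog()] (`n_localized`, `n_mcrpc`, `n_genes`,
#'   `delta`, `log_hr` named lists, ...).
#' @param inputs Named list of file paths (`seg`, `snv`, `sv`, `clinical`,
#'   `outcomes`, `catalog`) when running on files.
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1L, n_iter = 10000L, alpha = 0.05,
                            min_prevalence = 0.05, cna_segment_mbp = 10,
                            synthetic = list(), inputs = NULL) {
  list(
    seed = as.integer(seed), n_iter = as.integer(n_iter), alpha = alpha,
    min_prevalence = min_prevalence, cna_segment_mbp = cna_segment_mbp,
    synthetic = synthetic, inputs = inputs
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#' @param path Path to the config file.
#' @return A config list merged over [pipeline_config()] defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modifyList(pipeline_config(), cfg)
}

#' Run the full pipeline
#'
#' Stages, in order: `simulate` (or `load`), `matrix`, `prevalence`,
#' `differential`, `screen`, `manifest`. Each stage writes a TSV under
#' `output_dir`; the manifest records the config hash, seed, per-stage row
#' counts and MD5 checksums of every output, so identical config + seed
#' yields identical checksums. A stage failure aborts with the failing
#' stage named.
#'
#' @param config A config list ([pipeline_config()] or
#'   [read_pipeline_config()]).
#' @param output_dir Directory for output tables and the manifest.
#' @return Invisibly, a list with the output tables and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("driverdelta")),
    seed = config$seed,
    config_hash = hash_object(config),
    stages = list()
  )
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      rows = if (is.data.frame(out)) nrow(out) else NA
    )
    message(sprintf("[driverdelta] stage %-12s done (%s rows)", name,
                    if (is.data.frame(out)) nrow(out) else "-"))
    out
  }

  null_cfg <- null_model_config(n_iter = config$n_iter, seed = config$seed,
                                cna_segment_mbp = config$cna_segment_mbp)

  if (is.null(config$inputs)) {
    syn_args <- config$synthetic %||% list()
    n_genes <- syn_args$n_genes %||% 12L
    catalog <- synthetic_driver_catalog(n_genes)
    cfg_args <- syn_args[setdiff(names(syn_args),
                                 c("n_genes", "delta", "log_hr"))]
    cfg_args$seed <- config$seed
    cfg_args$null <- null_cfg
    syn_cfg <- do.call(synthetic_config, cfg_args)
    truth <- synthetic_truth(
      catalog,
      delta = unlist(syn_args$delta),
      log_hr = unlist(syn_args$log_hr)
    )
    cohort <- stage("simulate", generate_cohort(syn_cfg, catalog, truth))
    samples <- cohort$samples
    outcomes <- cohort$outcomes
    matrix <- stage("matrix", cohort$matrix)
    write_synthetic_cohort(cohort, file.path(output_dir, "cohort"))
  } else {
    inp <- config$inputs
    catalog <- stage("load", read_driver_catalog(inp$catalog))
    samples <- read_samples(inp$clinical)
    outcomes <- if (!is.null(inp$outcomes)) {
      readr::read_tsv(inp$outcomes, show_col_types = FALSE, progress = FALSE)
    } else {
      NULL
    }
    calls <- list(
      cna = if (!is.null(inp$seg)) read_seg(inp$seg),
      snv = if (!is.null(inp$snv)) read_snv_calls(inp$snv),
      sv = if (!is.null(inp$sv)) read_sv_calls(inp$sv)
    )
    matrix <- stage("matrix", build_mutation_matrix(calls, catalog, samples))
  }
  write_mutation_matrix(matrix, file.path(output_dir, "mutation_matrix.tsv"))

  prevalence <- stage("prevalence", prevalence_table(matrix, samples))
  readr::write_tsv(prevalence, file.path(output_dir, "prevalence.tsv"),
                   progress = FALSE)

  differential <- stage("differential",
                        differential_table(matrix, samples, catalog,
                                           null_cfg, alpha = config$alpha))
  readr::write_tsv(as_tibble(differential),
                   file.path(output_dir, "differential.tsv"),
                   progress = FALSE)

  screen <- if (!is.null(outcomes)) {
    stage("screen",
          screen_candidates(differential, matrix, samples, outcomes,
                            alpha = config$alpha,
                            min_prevalence = config$min_prevalence))
  } else {
    NULL
  }
  if (!is.null(screen)) {
    readr::write_tsv(screen, file.path(output_dir, "candidates.tsv"),
                     progress = FALSE)
  }

  outputs <- list.files(output_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  manifest$total_seconds <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(matrix = matrix, prevalence = prevalence,
                 differential = differential, screen = screen,
                 manifest = manifest))
}

# md5 of the canonical JSON serialization of an R object
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
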