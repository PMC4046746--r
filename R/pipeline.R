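#' Assemble a pipeline run configuration
#'
#' A run configuration names either a simulation block (the bundled
#' tag-sequencing simulator provides reference, truth, reads and annotation)
#' or existing input files, plus the analysis parameters and a global seed.
#' Configurations round-trip through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param output_dir Directory receiving all stage outputs and the manifest.
#' @param seed Integer seed governing every stochastic stage.
#' @param control Label of the control sample; every other sample is compared
#'   against it.
#' @param simulate `NULL`, or a list of simulator settings (`n_genes`,
#'   `mean_length`, `catg_free_fraction`, `conditions`, `de_fraction`,
#'   `effect_log2`, `dispersion`, `depth`, `error_rate`, `adaptor_only_rate`,
#'   `n_read_rate`, `n_terms`, `annotated_fraction`); missing entries take
#'   the generator defaults.
#' @param inputs `NULL`, or a list with `reference_fasta`, named `samples`
#'   (condition -> FASTQ path or tag-count TSV path), and optionally
#'   `annotation` (gene/term TSV).
#' @param parameters Analysis parameters: `max_mismatch`, `fdr_max`,
#'   `min_abs_log2`, `q_max`, `bin_edges`, `saturation_fractions`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1, control = "control",
                            simulate = NULL, inputs = NULL,
                            parameters = list()) {
  if (is.null(simulate) && is.null(inputs)) {
    cli::cli_abort("Provide either a {.field simulate} block or {.field inputs}.")
  }
  defaults <- list(
    max_mismatch = 1, fdr_max = 0.001, min_abs_log2 = 1, q_max = 0.05,
    bin_edges = c(1, 2, 6, 11, 21, 51, 101),
    saturation_fractions = seq(0.1, 1, by = 0.1)
  )
  parameters <- utils::modifyList(defaults, as.list(parameters))
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), control = control,
         simulate = simulate, inputs = inputs, parameters = parameters),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(
    output_dir = cfg$output_dir %||% dirname(path),
    seed = cfg$seed %||% 1,
    control = cfg$control %||% "control",
    simulate = cfg$simulate,
    inputs = cfg$inputs,
    parameters = cfg$parameters %||% list()
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the tag-DGE pipeline end to end
#'
#' Executes the stages `simulate` (optional), `buildref`, `clean`, `map`,
#' `saturation`, `dge`, `enrich` and `report` in dependency order, writing
#' every stage result as TSV under `config$output_dir` together with a
#' `manifest.json` recording the package version, seed, parameters and input
#' checksums. A stage whose inputs and parameters are unchanged since the
#' recorded run is skipped as up to date unless `force = TRUE`. Two runs with
#' the same configuration and seed produce byte-identical stage tables.
#'
#' @param config A `pipeline_config` or path to its YAML file.
#' @param force Rerun every stage even if up to date.
#' @param stages Optional subset of stage names to run (dependencies must
#'   already have outputs on disk).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, force = FALSE, stages = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  par <- config$parameters

  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    list()
  }
  manifest$package <- "tagdge"
  manifest$version <- as.character(utils::packageVersion("tagdge"))
  manifest$seed <- config$seed
  manifest$control <- config$control
  manifest$parameters <- par
  old_stages <- manifest$stages %||% list()
  manifest$stages <- old_stages

  log_msg <- function(...) if (!quiet) message(sprintf(...))
  path_of <- function(...) file.path(out, sprintf(...))

  want <- function(stage) is.null(stages) || stage %in% stages

  # A stage runs unless its recorded signature (parameters + input-file
  # checksums) matches and all outputs still exist.
  run_stage <- function(name, inputs, outputs, params, fun) {
    if (!want(name)) return(invisible(NULL))
    sig_obj <- list(
      params = params,
      inputs = as.list(unname(tools::md5sum(inputs[file.exists(inputs)])))
    )
    sig <- substr(tools::md5sum(
      {f <- tempfile(); writeLines(jsonlite::toJSON(sig_obj, auto_unbox = TRUE, digits = NA), f); f}
    ), 1, 32)
    rec <- old_stages[[name]]
    if (!force && !is.null(rec) && identical(unname(rec$signature), unname(sig)) &&
        all(file.exists(outputs))) {
      log_msg("[%s] up to date, skipped", name)
      return(invisible(NULL))
    }
    missing <- inputs[!file.exists(inputs)]
    if (length(missing) > 0L) {
      cli::cli_abort("Stage {.val {name}}: missing input{?s} {.file {missing}}.")
    }
    t0 <- Sys.time()
    fun()
    log_msg("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    manifest$stages[[name]] <<- list(
      signature = unname(sig),
      inputs = as.list(tools::md5sum(inputs)),
      outputs = outputs
    )
    invisible(NULL)
  }

  # ---- resolve input layout -------------------------------------------------
  simulating <- !is.null(config$simulate)
  if (simulating) {
    sim <- config$simulate
    conditions <- as.character(sim$conditions %||%
                                 c("control", "cold_1h", "cold_5h", "cold_24h"))
    ref_fa <- path_of("reference.fasta")
    ann_tsv <- path_of("annotation.tsv")
    sample_files <- stats::setNames(path_of("reads_%s.fastq", conditions), conditions)
    run_stage(
      "simulate",
      inputs = character(0),
      outputs = c(ref_fa, path_of("truth.tsv"), ann_tsv, unname(sample_files)),
      params = list(sim = sim, seed = config$seed),
      fun = function() {
        tx <- simulate_transcriptome(
          n_genes = sim$n_genes %||% 1000,
          mean_length = sim$mean_length %||% 560,
          catg_free_fraction = sim$catg_free_fraction %||% 0.05,
          seed = config$seed
        )
        truth <- simulate_expression(
          tx, conditions = conditions,
          de_fraction = sim$de_fraction %||% 0.1,
          effect_log2 = sim$effect_log2 %||% 3,
          dispersion = sim$dispersion %||% 3,
          seed = config$seed + 1L
        )
        ann <- simulate_annotation(
          tx, n_terms = sim$n_terms %||% 20,
          annotated_fraction = sim$annotated_fraction %||% 0.6,
          seed = config$seed + 2L
        )
        write_transcripts_fasta(tx, ref_fa)
        readr::write_tsv(truth, path_of("truth.tsv"))
        readr::write_tsv(ann, ann_tsv)
        for (i in seq_along(conditions)) {
          reads <- simulate_tag_library(
            tx, truth, conditions[i],
            depth = sim$depth %||% 20000,
            error_rate = sim$error_rate %||% 0.01,
            adaptor_only_rate = sim$adaptor_only_rate %||% 0.05,
            n_read_rate = sim$n_read_rate %||% 0.03,
            seed = config$seed + 10L + i
          )
          write_reads_fastq(reads, sample_files[[i]])
        }
      }
    )
  } else {
    inp <- config$inputs
    ref_fa <- inp$reference_fasta
    ann_tsv <- inp$annotation
    sample_files <- unlist(inp$samples)
    conditions <- names(sample_files)
    if (is.null(conditions)) {
      cli::cli_abort("{.field inputs$samples} must be a named list (condition -> file).")
    }
  }
  if (!config$control %in% conditions) {
    cli::cli_abort("Control label {.val {config$control}} is not among the samples.")
  }
  treatments <- setdiff(conditions, config$control)

  # ---- buildref -------------------------------------------------------------
  run_stage(
    "buildref",
    inputs = ref_fa,
    outputs = c(path_of("tag_db.tsv"), path_of("tag_db_summary.tsv")),
    params = list(),
    fun = function() {
      idx <- build_tag_index(read_transcripts_fasta(ref_fa))
      write_tag_index(idx, path_of("tag_db.tsv"))
      readr::write_tsv(uniqueness_report(idx), path_of("tag_db_summary.tsv"))
    }
  )

  # ---- clean ----------------------------------------------------------------
  run_stage(
    "clean",
    inputs = unname(sample_files),
    outputs = c(path_of("tags_%s.tsv", conditions),
                path_of("abundance_%s.tsv", conditions),
                path_of("accounting.tsv")),
    params = list(bin_edges = par$bin_edges),
    fun = function() {
      acc <- purrr::map_dfr(conditions, function(cond) {
        f <- sample_files[[cond]]
        lib <- if (grepl("\\.(tsv|txt)$", f)) {
          read_tag_counts(f, sample_id = cond)
        } else {
          clean_reads(f, sample_id = cond)
        }
        write_tag_counts(lib, path_of("tags_%s.tsv", cond))
        readr::write_tsv(abundance_distribution(lib, par$bin_edges),
                         path_of("abundance_%s.tsv", cond))
        glance(lib)
      })
      readr::write_tsv(acc, path_of("accounting.tsv"))
    }
  )

  load_lib <- function(cond) {
    lib <- read_tag_counts(path_of("tags_%s.tsv", cond), sample_id = cond)
    acc <- readr::read_tsv(path_of("accounting.tsv"),
                           col_types = readr::cols(sample_id = readr::col_character(),
                                                   .default = readr::col_integer()))
    lib$accounting <- acc[acc$sample_id == cond,
                          setdiff(names(acc), "sample_id"), drop = FALSE]
    lib
  }

  # ---- map ------------------------------------------------------------------
  run_stage(
    "map",
    inputs = c(path_of("tag_db.tsv"), path_of("tags_%s.tsv", conditions),
               path_of("accounting.tsv")),
    outputs = c(path_of("gene_counts_%s.tsv", conditions),
                path_of("tag_status_%s.tsv", conditions),
                path_of("mapping_summary.tsv")),
    params = list(max_mismatch = par$max_mismatch),
    fun = function() {
      idx <- build_tag_index(read_transcripts_fasta(ref_fa))
      summ <- purrr::map_dfr(conditions, function(cond) {
        mp <- map_tags(load_lib(cond), idx, max_mismatch = par$max_mismatch)
        readr::write_tsv(tidy(mp), path_of("tag_status_%s.tsv", cond))
        gc <- gene_counts(mp)
        readr::write_tsv(gc, path_of("gene_counts_%s.tsv", cond))
        dplyr::mutate(glance(mp),
                      n_detected_genes = attr(gc, "n_detected"),
                      pct_of_ref_genes = pct(attr(gc, "n_detected"), length(idx$gene_ids)))
      })
      readr::write_tsv(summ, path_of("mapping_summary.tsv"))
    }
  )

  # ---- saturation -----------------------------------------------------------
  run_stage(
    "saturation",
    inputs = c(path_of("tag_db.tsv"), path_of("tags_%s.tsv", conditions),
               path_of("accounting.tsv")),
    outputs = path_of("saturation_%s.tsv", conditions),
    params = list(fractions = par$saturation_fractions,
                  max_mismatch = par$max_mismatch, seed = config$seed),
    fun = function() {
      idx <- build_tag_index(read_transcripts_fasta(ref_fa))
      for (cond in conditions) {
        lib <- load_lib(cond)
        grid <- unique(c(0L, as.integer(round(
          par$saturation_fractions * lib$accounting$total_clean
        ))))
        sc <- saturation_curve(lib, idx, grid = grid,
                               seed = config$seed + 100L,
                               max_mismatch = par$max_mismatch)
        readr::write_tsv(as_tibble(sc), path_of("saturation_%s.tsv", cond))
      }
    }
  )

  read_counts_file <- function(cond) {
    gc <- readr::read_tsv(path_of("gene_counts_%s.tsv", cond),
                          col_types = readr::cols(gene_id = readr::col_character(),
                                                  count = readr::col_integer(),
                                                  tpm = readr::col_double()))
    acc <- readr::read_tsv(path_of("accounting.tsv"), col_types = readr::cols())
    attr(gc, "total_clean") <- as.integer(acc$total_clean[acc$sample_id == cond])
    gc
  }

  # ---- dge ------------------------------------------------------------------
  run_stage(
    "dge",
    inputs = c(path_of("gene_counts_%s.tsv", conditions), path_of("accounting.tsv")),
    outputs = c(path_of("dge_%s.tsv", treatments), path_of("deg_counts.tsv")),
    params = list(fdr_max = par$fdr_max, min_abs_log2 = par$min_abs_log2),
    fun = function() {
      ctrl <- read_counts_file(config$control)
      counts <- purrr::map_dfr(treatments, function(cond) {
        dge <- dge_test(ctrl, read_counts_file(cond),
                        fdr_max = par$fdr_max, min_abs_log2 = par$min_abs_log2)
        readr::write_tsv(tidy(dge), path_of("dge_%s.tsv", cond))
        dplyr::bind_cols(tibble(comparison = paste(cond, "vs", config$control)),
                         glance(dge))
      })
      readr::write_tsv(counts, path_of("deg_counts.tsv"))
    }
  )

  # ---- enrich ---------------------------------------------------------------
  if (!is.null(ann_tsv)) {
    run_stage(
      "enrich",
      inputs = c(ann_tsv, path_of("dge_%s.tsv", treatments)),
      outputs = path_of("enrich_%s.tsv", treatments),
      params = list(q_max = par$q_max, fdr_max = par$fdr_max,
                    min_abs_log2 = par$min_abs_log2),
      fun = function() {
        ann <- read_annotation(ann_tsv)
        for (cond in treatments) {
          tab <- readr::read_tsv(path_of("dge_%s.tsv", cond),
                                 col_types = readr::cols())
          up <- call_degs(tab, fdr_max = par$fdr_max,
                          min_abs_log2 = par$min_abs_log2)$up
          readr::write_tsv(enrich_terms(up, ann, q_max = par$q_max),
                           path_of("enrich_%s.tsv", cond))
        }
      }
    )
  }

  # ---- report ---------------------------------------------------------------
  run_stage(
    "report",
    inputs = c(path_of("accounting.tsv"), path_of("mapping_summary.tsv"),
               path_of("deg_counts.tsv")),
    outputs = path_of("report.md"),
    params = list(),
    fun = function() render_report(out, quiet = quiet)
  )

  manifest$updated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
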