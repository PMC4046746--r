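#' Render a summary report of a pipeline run
#'
#' Collects the stage tables written by [run_pipeline()] into a single
#' markdown document: library accounting, tag copy-number distributions,
#' up/down DEG counts per comparison, significantly enriched terms, and a
#' top-regulator listing with per-comparison log2 ratios and a significance
#' flag column. Sections whose stage output is missing are omitted with a
#' warning. Every percentage in the report is recomputed from the underlying
#' tables.
#'
#' @param output_dir Directory of a pipeline run.
#' @param path Output file (default `report.md` inside `output_dir`).
#' @param top_n Rows in the top-regulator listing.
#' @param quiet Suppress messages.
#' @return Invisibly, a named list of the tibbles behind each section.
#' @export
render_report <- function(output_dir, path = file.path(output_dir, "report.md"),
                          top_n = 20, quiet = FALSE) {
  sections <- list()
  lines <- c("# Tag-DGE pipeline report", "")
  p <- function(...) file.path(output_dir, sprintf(...))
  read_if <- function(f) {
    if (file.exists(f)) {
      readr::read_tsv(f, col_types = readr::cols())
    } else {
      cli::cli_warn("Missing {.file {basename(f)}}; section omitted.")
      NULL
    }
  }
  md_table <- function(df) {
    fmt <- function(v) {
      if (is.numeric(v) && !all(v == as.integer(v) | is.na(v))) {
        formatC(v, format = "fg", digits = 6)
      } else {
        format(v)
      }
    }
    body <- vapply(seq_len(nrow(df)), function(i) {
      paste0("| ", paste(vapply(df[i, ], function(c) trimws(fmt(c[[1]])), ""),
                         collapse = " | "), " |")
    }, "")
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      body, "")
  }

  acc <- read_if(p("accounting.tsv"))
  if (!is.null(acc)) {
    sections$accounting <- acc
    lines <- c(lines, "## Library accounting", "", md_table(acc))
  }

  mapping <- read_if(p("mapping_summary.tsv"))
  if (!is.null(mapping)) {
    sections$mapping <- mapping
    keep <- intersect(
      c("sample_id", "total_clean", "all_mapped_total", "all_mapped_pct",
        "unambiguous_total", "unambiguous_pct", "unknown_total", "unknown_pct",
        "n_detected_genes", "pct_of_ref_genes"),
      names(mapping)
    )
    lines <- c(lines, "## Tag mapping", "", md_table(mapping[, keep]))
  }

  ab_files <- list.files(output_dir, pattern = "^abundance_.*\\.tsv$",
                         full.names = TRUE)
  if (length(ab_files) > 0L) {
    ab <- purrr::map_dfr(ab_files, function(f) {
      dplyr::mutate(readr::read_tsv(f, col_types = readr::cols()),
                    sample_id = sub("^abundance_(.*)\\.tsv$", "\\1", basename(f)),
                    .before = 1)
    })
    sections$abundance <- ab
    lines <- c(lines, "## Tag copy-number distribution", "", md_table(ab))
  }

  degc <- read_if(p("deg_counts.tsv"))
  if (!is.null(degc)) {
    sections$deg_counts <- degc
    keep <- intersect(c("comparison", "n_genes", "n_up", "n_down",
                        "fdr_max", "min_abs_log2"), names(degc))
    lines <- c(lines, "## Differentially expressed genes", "",
               md_table(degc[, keep]))
  }

  enr_files <- list.files(output_dir, pattern = "^enrich_.*\\.tsv$",
                          full.names = TRUE)
  if (length(enr_files) > 0L) {
    enr <- purrr::map_dfr(enr_files, function(f) {
      dplyr::mutate(readr::read_tsv(f, col_types = readr::cols()),
                    comparison = sub("^enrich_(.*)\\.tsv$", "\\1", basename(f)),
                    .before = 1)
    })
    sections$enrichment <- enr
    sig <- enr[enr$significant %in% TRUE, , drop = FALSE]
    lines <- c(lines, "## Significantly enriched terms", "",
               if (nrow(sig) > 0L) md_table(sig) else c("None.", ""))
  }

  dge_files <- list.files(output_dir, pattern = "^dge_.*\\.tsv$",
                          full.names = TRUE)
  if (length(dge_files) > 0L) {
    tops <- purrr::map(dge_files, function(f) {
      cond <- sub("^dge_(.*)\\.tsv$", "\\1", basename(f))
      tab <- readr::read_tsv(f, col_types = readr::cols())
      tibble(
        gene_id = tab$gene_id,
        log2_ratio = tab$log2_ratio,
        significant = tab$significant,
        comparison = cond
      )
    })
    top <- dplyr::bind_rows(tops)
    wide <- tidyr::pivot_wider(
      top, id_cols = "gene_id", names_from = "comparison",
      values_from = c("log2_ratio", "significant")
    )
    score <- apply(
      dplyr::select(wide, dplyr::starts_with("log2_ratio")), 1,
      function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE)
    )
    wide <- head(wide[order(-score), , drop = FALSE], top_n)
    sections$top_regulators <- wide
    lines <- c(lines,
               sprintf("## Top %d up-regulated genes (log2 ratio per comparison; `-` = undetected)", top_n),
               "", md_table(dplyr::mutate(wide, dplyr::across(
                 dplyr::starts_with("log2_ratio"),
                 ~ ifelse(is.na(.x), "-", formatC(.x, format = "f", digits = 2))
               ))))
  }

  writeLines(lines, path)
  if (!quiet) message(sprintf("report written to %s", path))
  invisible(sections)
}
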