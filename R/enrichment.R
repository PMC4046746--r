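#' Hypergeometric term enrichment of a DEG set
#'
#' Tests each annotation term for over-representation among differentially
#' expressed genes relative to the annotated background. With `N` background
#' genes carrying any term, `K` of them carrying the tested term, and `n`
#' DEGs inside the background of which `k` carry the term, the p-value is the
#' exact upper tail `P(X >= k)` of the hypergeometric distribution. Q-values
#' are Benjamini-Hochberg over all tested terms of one comparison, and a term
#' is significant when `q <= q_max`.
#'
#' The background defaults to every gene with at least one annotation (not
#' the whole reference), and the DEG set is intersected with it; both
#' conventions match how pathway-annotated denominators are reported.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotation Tibble with `gene_id`, `term_id`, optionally `term_name`.
#' @param background Optional character vector overriding the default
#'   annotated-gene background.
#' @param q_max Significance threshold on the q-value (default 0.05).
#' @return A tibble sorted by q then p with columns `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `pct_deg` (`100*k/n`, 2 dp), `pct_bg` (`100*K/N`),
#'   `p_value`, `q_value`, `significant`. Empty when no DEG is annotated.
#' @examples
#' ann <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3", "g4"),
#'   term_id = c("t1", "t1", "t2", "t2")
#' )
#' enrich_terms(c("g1", "g2"), ann)
#' @export
enrich_terms <- function(deg_genes, annotation, background = NULL, q_max = 0.05) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "term_id") %in% names(annotation))) {
    cli::cli_abort("{.arg annotation} must have columns {.field gene_id} and {.field term_id}.")
  }
  ann <- dplyr::distinct(annotation, .data$gene_id, .data$term_id,
                         .keep_all = TRUE)
  if (is.null(background)) background <- unique(ann$gene_id)
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  deg <- intersect(unique(deg_genes), background)

  N <- length(unique(background))
  n <- length(deg)
  empty <- tibble(
    term_id = character(), term_name = character(),
    k = integer(), n = integer(), K = integer(), N = integer(),
    pct_deg = numeric(), pct_bg = numeric(),
    p_value = numeric(), q_value = numeric(), significant = logical()
  )
  if (n == 0L || nrow(ann) == 0L) return(empty)

  per_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term_id),
    term_name = if ("term_name" %in% names(ann)) .data$term_name[1] else .data$term_id[1],
    K = dplyr::n_distinct(.data$gene_id),
    k = sum(unique(.data$gene_id) %in% deg),
    .groups = "drop"
  )
  drop <- per_term$K == 0L
  if (any(drop)) {
    cli::cli_warn("{sum(drop)} term{?s} with no background gene skipped.")
    per_term <- per_term[!drop, , drop = FALSE]
  }
  out <- dplyr::mutate(
    per_term,
    n = n, N = N,
    pct_deg = pct(.data$k, n),
    pct_bg = pct(.data$K, N),
    p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
    q_value = bh_adjust(.data$p_value),
    significant = .data$q_value <= q_max
  )
  out <- dplyr::select(
    out, "term_id", "term_name", "k", "n", "K", "N",
    "pct_deg", "pct_bg", "p_value", "q_value", "significant"
  )
  dplyr::arrange(out, .data$q_value, .data$p_value, .data$term_id)
}

#' Annotation coverage report
#'
#' Per annotation source, the number and percentage (2 dp) of reference
#' genes carrying an annotation — the arithmetic behind an "all-in-one"
#' annotation summary table.
#'
#' @param annotated_sets Named list: per source, either a character vector of
#'   annotated gene ids or a single count.
#' @param n_total Total number of reference genes (>= 1).
#' @return A tibble with `source`, `n_annotated`, `n_total`, `percentage`.
#' @examples
#' coverage_report(list(nr = 27396, kegg = 14105), 44382)
#' @export
coverage_report <- function(annotated_sets, n_total) {
  n_total <- check_count(n_total, "n_total")
  if (!is.list(annotated_sets) || is.null(names(annotated_sets)) ||
      any(!nzchar(names(annotated_sets)))) {
    cli::cli_abort("{.arg annotated_sets} must be a named list.")
  }
  n_ann <- vapply(annotated_sets, function(x) {
    if (is.character(x)) length(unique(x)) else as.integer(x)
  }, integer(1))
  tibble(
    source = names(annotated_sets),
    n_annotated = unname(n_ann),
    n_total = n_total,
    percentage = pct(unname(n_ann), n_total)
  )
}
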