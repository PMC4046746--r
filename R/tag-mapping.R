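#' Map clean tags to the virtual tag database
#'
#' Each distinct clean tag is resolved against the index: exact matches take
#' precedence; only tags with no exact match anywhere are queried against all
#' single-substitution neighbors of their 17 variable bases (the CATG anchor
#' must match exactly). A tag whose resolved gene set has exactly one gene is
#' `unambiguous`; tags hitting windows of multiple genes are `ambiguous` and
#' excluded from gene counting; tags matching nothing within the mismatch
#' budget are `unknown`. Multiple windows of the same gene count as one gene.
#'
#' @param lib A `tag_library`.
#' @param index A `tag_index` built from the reference the tags came from.
#' @param max_mismatch Either 0 (exact only) or 1 (the protocol's standard
#'   1 bp tolerance). Larger values are unsupported.
#' @return A `tag_mapping` object: `tidy()` gives the per-tag status table
#'   (`tag`, `count`, `status`, `gene_id`), `glance()` the mapping summary
#'   with totals, distinct counts and percentages of clean tags.
#' @export
map_tags <- function(lib, index, max_mismatch = 1) {
  stopifnot(inherits(lib, "tag_library"), inherits(index, "tag_index"))
  if (!max_mismatch %in% c(0, 1)) {
    cli::cli_abort("{.arg max_mismatch} must be 0 or 1; larger mismatch budgets are unsupported.")
  }
  q <- lib$counts
  ex <- exact_hits(index, q$tag)
  n_genes <- ex$n_genes
  gene <- ex$gene

  if (max_mismatch == 1 && any(n_genes == 0L)) {
    unres <- which(n_genes == 0L)
    mm <- resolve_one_mismatch(index, q$tag[unres])
    n_genes[unres] <- mm$n_genes
    gene[unres] <- mm$gene
  }

  status <- dplyr::case_when(
    n_genes == 1L ~ "unambiguous",
    n_genes > 1L ~ "ambiguous",
    TRUE ~ "unknown"
  )
  tags <- tibble(tag = q$tag, count = q$count, status = status, gene_id = gene)

  total_clean <- lib$accounting$total_clean
  stopifnot(sum(tags$count) == total_clean)

  structure(
    list(
      tags = tags,
      sample_id = lib$sample_id,
      total_clean = total_clean,
      distinct_clean = lib$accounting$distinct_clean,
      ref_genes = index$gene_ids
    ),
    class = "tag_mapping"
  )
}

# 1-mismatch resolution: for each query tag, the union of gene sets over all
# 51 single-substitution neighbors of the variable bases present in the index.
resolve_one_mismatch <- function(index, tags) {
  n <- length(tags)
  res_n <- integer(n)
  res_gene <- rep(NA_character_, n)
  orig_acc <- vector("list", 0L)
  key_acc <- vector("list", 0L)
  for (p in (nchar(TAG_ANCHOR) + 1L):TAG_LENGTH) {
    pre <- substr(tags, 1L, p - 1L)
    cur <- substr(tags, p, p)
    post <- substr(tags, p + 1L, TAG_LENGTH)
    for (b in DNA_BASES) {
      sel <- which(cur != b)
      if (length(sel) == 0L) next
      hit <- match(paste0(pre[sel], b, post[sel]), index$tag_keys)
      ok <- which(!is.na(hit))
      if (length(ok) > 0L) {
        orig_acc[[length(orig_acc) + 1L]] <- sel[ok]
        key_acc[[length(key_acc) + 1L]] <- hit[ok]
      }
    }
  }
  if (length(orig_acc) > 0L) {
    po <- unlist(orig_acc)
    genes <- index$gene_sets[unlist(key_acc)]
    df <- dplyr::distinct(tibble(orig = rep(po, lengths(genes)),
                                 gene = unlist(genes)))
    agg <- dplyr::summarise(dplyr::group_by(df, .data$orig),
                            n_genes = dplyr::n(), gene = .data$gene[1],
                            .groups = "drop")
    res_n[agg$orig] <- agg$n_genes
    one <- agg$n_genes == 1L
    res_gene[agg$orig[one]] <- agg$gene[one]
  }
  list(n_genes = res_n, gene = res_gene)
}

#' @export
print.tag_mapping <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<tag_mapping> %s: %s clean tags -> %s unambiguous (%.2f%%), %s ambiguous, %s unknown (%.2f%%)\n",
    x$sample_id, format(g$total_clean, big.mark = ","),
    format(g$unambiguous_total, big.mark = ","), g$unambiguous_pct,
    format(g$ambiguous_total, big.mark = ","),
    format(g$unknown_total, big.mark = ","), g$unknown_pct
  ))
  invisible(x)
}

#' @export
tidy.tag_mapping <- function(x, ...) x$tags

#' @export
glance.tag_mapping <- function(x, ...) {
  t <- x$tags
  tot <- function(s) sum(t$count[t$status %in% s])
  dis <- function(s) sum(t$status %in% s)
  N <- x$total_clean
  D <- x$distinct_clean
  tibble(
    sample_id = x$sample_id,
    total_clean = N,
    distinct_clean = D,
    all_mapped_total = tot(c("unambiguous", "ambiguous")),
    all_mapped_pct = pct(tot(c("unambiguous", "ambiguous")), N),
    all_mapped_distinct = dis(c("unambiguous", "ambiguous")),
    all_mapped_distinct_pct = pct(dis(c("unambiguous", "ambiguous")), D),
    unambiguous_total = tot("unambiguous"),
    unambiguous_pct = pct(tot("unambiguous"), N),
    unambiguous_distinct = dis("unambiguous"),
    unambiguous_distinct_pct = pct(dis("unambiguous"), D),
    ambiguous_total = tot("ambiguous"),
    ambiguous_distinct = dis("ambiguous"),
    unknown_total = tot("unknown"),
    unknown_pct = pct(tot("unknown"), N),
    unknown_distinct = dis("unknown"),
    unknown_distinct_pct = pct(dis("unknown"), D)
  )
}

#' Per-gene unambiguous tag counts and TPM
#'
#' Sums unambiguous tag counts per gene over the whole reference (genes with
#' no mapped tag get 0) and normalizes to TPM, transcripts per million clean
#' tags: `count / total_clean * 1e6`. The denominator is the library's total
#' clean tags, not only the mapped ones.
#'
#' @param mapping A `tag_mapping` from [map_tags()].
#' @return A tibble with `gene_id`, `count`, `tpm`, carrying attributes
#'   `total_clean`, `n_detected` (genes with count >= 1) and
#'   `fraction_of_reference` (`n_detected / n_reference_genes`).
#' @export
gene_counts <- function(mapping) {
  stopifnot(inherits(mapping, "tag_mapping"))
  un <- mapping$tags[mapping$tags$status == "unambiguous", , drop = FALSE]
  agg <- dplyr::summarise(dplyr::group_by(un, .data$gene_id),
                          count = sum(.data$count), .groups = "drop")
  out <- tibble(gene_id = mapping$ref_genes)
  out$count <- agg$count[match(out$gene_id, agg$gene_id)]
  out$count[is.na(out$count)] <- 0L
  out$tpm <- tpm_normalize(out$count, mapping$total_clean)
  stopifnot(sum(out$count) == sum(un$count))
  attr(out, "total_clean") <- mapping$total_clean
  attr(out, "n_detected") <- sum(out$count >= 1L)
  attr(out, "fraction_of_reference") <- sum(out$count >= 1L) / nrow(out)
  out
}

#' Gene-detection saturation curve
#'
#' Subsamples the clean-tag multiset without replacement at each grid size
#' and records how many genes are detected (>= 1 unambiguous tag). Internally
#' a single seeded permutation of the expanded tag multiset is drawn and each
#' grid size reads off a prefix, so subsamples are nested: the curve is
#' monotone by construction and its final point equals full-library
#' detection exactly. Each prefix is a uniform without-replacement subsample.
#'
#' @param lib A `tag_library`.
#' @param index A `tag_index`.
#' @param grid Integer subsample sizes (each between 0 and the library's
#'   total clean tags). Default: 5% steps of the clean total.
#' @param seed Optional integer seed.
#' @param max_mismatch Passed to [map_tags()].
#' @return A `saturation_curve` tibble with `subsample_size`, `n_detected`.
#' @export
saturation_curve <- function(lib, index, grid = NULL, seed = NULL,
                             max_mismatch = 1) {
  stopifnot(inherits(lib, "tag_library"))
  N <- lib$accounting$total_clean
  if (is.null(grid)) grid <- unique(c(0L, as.integer(round(seq(0.05, 1, by = 0.05) * N))))
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 0L) || any(grid > N)) {
    cli::cli_abort("Every grid size must lie between 0 and the library's total clean tags ({N}).")
  }
  mapping <- map_tags(lib, index, max_mismatch = max_mismatch)
  t <- mapping$tags
  gene_int <- match(t$gene_id, mapping$ref_genes) # NA unless unambiguous
  occ_gene <- rep(gene_int, t$count)
  with_seed_or_current(seed, {
    occ_gene <- occ_gene[sample.int(N)]
  })
  firsts <- which(!duplicated(occ_gene) & !is.na(occ_gene))
  n_det <- findInterval(grid, sort(firsts))
  out <- tibble(subsample_size = grid, n_detected = n_det)
  stopifnot(!is.unsorted(out$n_detected))
  if (N %in% grid) {
    stopifnot(out$n_detected[out$subsample_size == N] ==
                sum(!is.na(unique(occ_gene))))
  }
  class(out) <- c("saturation_curve", class(out))
  out
}
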