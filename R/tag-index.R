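#' Build the virtual tag database of a reference transcriptome
#'
#' Extracts every possible CATG+17 window (21 bp virtual tag) from the sense
#' strand of each reference sequence: one window per CATG occurrence that has
#' at least 17 following bases, including overlapping occurrences. The
#' resulting index is the mapping target for clean tags and records, per
#' window, the source gene, the 0-based offset of the CATG, and the window's
#' rank counted from the 3' end (1 = 3'-most).
#'
#' @param transcripts Tibble with `gene_id` and `sequence` (A/C/G/T only;
#'   any other character is an error naming the offending gene).
#' @param include_revcomp Also index windows of the reverse-complement strand
#'   (off by default: unigene orientation is fixed by the reference, and the
#'   protocol reads the sense strand).
#' @return A `tag_index` object. Use [tidy()] for the window table, [glance()]
#'   or [uniqueness_report()] for summary counts.
#' @examples
#' tx <- tibble::tibble(
#'   gene_id = "g1",
#'   sequence = "AACATGAAAAAAAAAAAAAAAAATT"
#' )
#' idx <- build_tag_index(tx)
#' tidy(idx)
#' @export
build_tag_index <- function(transcripts, include_revcomp = FALSE) {
  check_transcripts(transcripts)

  windows <- scan_windows(transcripts$gene_id, transcripts$sequence, strand = "+")
  if (isTRUE(include_revcomp)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(transcripts$sequence)
    ))
    windows <- dplyr::bind_rows(
      windows,
      scan_windows(transcripts$gene_id, rc, strand = "-")
    )
  }

  pairs <- dplyr::distinct(windows, .data$tag, .data$gene_id)
  tag_keys <- unique(pairs$tag)
  gene_sets <- unname(split(pairs$gene_id, factor(pairs$tag, levels = tag_keys)))
  n_genes_per_tag <- lengths(gene_sets)

  structure(
    list(
      windows = windows,
      tag_keys = tag_keys,
      gene_sets = gene_sets,
      n_genes_per_tag = n_genes_per_tag,
      first_gene = vapply(gene_sets, `[`, character(1), 1L),
      gene_ids = transcripts$gene_id,
      include_revcomp = isTRUE(include_revcomp)
    ),
    class = "tag_index"
  )
}

scan_windows <- function(gene_ids, seqs, strand) {
  hits <- gregexpr(TAG_ANCHOR, seqs, fixed = TRUE)
  starts <- lapply(hits, function(h) if (h[1] == -1L) integer(0) else as.integer(h))
  lens <- nchar(seqs)
  starts <- purrr::map2(starts, lens, function(s, l) s[s + TAG_LENGTH - 1L <= l])
  nwin <- lengths(starts)
  s <- unlist(starts, use.names = FALSE)
  if (is.null(s)) s <- integer(0)
  gid <- rep(gene_ids, nwin)
  tags <- substring(rep(seqs, nwin), s, s + TAG_LENGTH - 1L)
  out <- tibble(
    tag = tags,
    gene_id = gid,
    offset = s - 1L,
    strand = if (length(s)) strand else character(0)
  )
  dplyr::mutate(
    dplyr::group_by(out, .data$gene_id),
    rank_from_3prime = rank(-.data$offset, ties.method = "first"),
    .before = "strand"
  ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id, .data$offset)
}

#' Summarize tag-to-gene multiplicity of a virtual tag database
#'
#' @param index A `tag_index`.
#' @return A one-row tibble: number of distinct tags, tags belonging to a
#'   single gene, tags shared by multiple genes, genes with at least one
#'   window, and genes with none.
#' @export
uniqueness_report <- function(index) {
  stopifnot(inherits(index, "tag_index"))
  n_multi <- sum(index$n_genes_per_tag > 1L)
  tibble(
    n_distinct_tags = length(index$tag_keys),
    n_single_gene_tags = length(index$tag_keys) - n_multi,
    n_multi_gene_tags = n_multi,
    n_genes_with_windows = dplyr::n_distinct(index$windows$gene_id),
    n_genes_without_windows = length(index$gene_ids) -
      dplyr::n_distinct(index$windows$gene_id)
  )
}

#' Write a virtual tag database as TSV
#'
#' @param index A `tag_index`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tag_index <- function(index, path) {
  stopifnot(inherits(index, "tag_index"))
  readr::write_tsv(index$windows, path)
  invisible(path)
}

#' @export
print.tag_index <- function(x, ...) {
  rep <- uniqueness_report(x)
  cat(sprintf(
    "<tag_index> %d virtual tags (%d windows) over %d genes; %d multi-gene tags; %d genes without windows\n",
    rep$n_distinct_tags, nrow(x$windows), length(x$gene_ids),
    rep$n_multi_gene_tags, rep$n_genes_without_windows
  ))
  invisible(x)
}

#' @export
tidy.tag_index <- function(x, ...) x$windows

#' @export
glance.tag_index <- function(x, ...) uniqueness_report(x)

# For a character vector of query tags, return exact-hit classification
# against the index: integer number of distinct genes (0 if absent) and the
# unique gene for single-gene hits.
exact_hits <- function(index, tags) {
  i <- match(tags, index$tag_keys)
  n <- ifelse(is.na(i), 0L, index$n_genes_per_tag[i])
  gene <- ifelse(!is.na(i) & n == 1L, index$first_gene[i], NA_character_)
  list(n_genes = n, gene = gene, key_idx = i)
}
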