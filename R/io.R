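#' Read and write reference transcripts as FASTA
#'
#' Thin wrappers around Biostrings for the package's tabular transcript
#' representation (`gene_id`, `sequence`).
#'
#' @param transcripts Tibble with `gene_id` and `sequence`.
#' @param path File path.
#' @return `read_transcripts_fasta()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  check_transcripts(transcripts, require_acgt = FALSE)
  x <- Biostrings::DNAStringSet(transcripts$sequence)
  names(x) <- transcripts$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_transcripts_fasta
#' @export
read_transcripts_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    gene_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(unname(x))
  )
}

#' Read and write raw tag reads as FASTQ
#'
#' Simulated reads carry a constant dummy quality string of "I"s. Reading
#' returns only read ids and sequences; this protocol carries no per-base
#' quality information that downstream stages use.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path File path (optionally gz-compressed on read).
#' @return `read_reads_fastq()` returns a tibble with `read_id`, `sequence`;
#'   the writer returns `path` invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(unname(x))
  )
}

#' Read and write distinct-tag count tables
#'
#' The on-disk form is a two-column TSV (`tag`, `count`), the conventional
#' exchange format for pre-extracted tag lists.
#'
#' @param lib A `tag_library` or a tibble with `tag` and `count` columns.
#' @param path File path.
#' @param sample_id Sample label attached on read.
#' @return `read_tag_counts()` returns a [tag_library()]; the writer returns
#'   `path` invisibly.
#' @export
write_tag_counts <- function(lib, path) {
  counts <- if (inherits(lib, "tag_library")) lib$counts else lib
  readr::write_tsv(counts[, c("tag", "count")], path)
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path, sample_id = basename(path)) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    tag = readr::col_character(), count = readr::col_integer()
  ))
  tag_library(counts, sample_id = sample_id)
}

#' Read a gene-to-term annotation map
#'
#' Expects a TSV with columns `gene_id` and `term_id`, and optionally
#' `term_name`.
#'
#' @param path File path.
#' @return A tibble with `gene_id`, `term_id` (and `term_name` if present).
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
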