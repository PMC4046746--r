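#' Construct a tag library from pre-extracted tag counts
#'
#' A tag library holds one sample's distinct 21 bp tags with their counts,
#' plus read-accounting totals. [clean_reads()] builds one from raw reads;
#' this constructor wraps an already-clean tag count table (in which case the
#' raw totals equal the clean totals).
#'
#' @param counts Tibble with columns `tag` and `count` (positive integers).
#' @param sample_id Sample label.
#' @param accounting Optional one-row accounting tibble; computed from
#'   `counts` if omitted.
#' @return A `tag_library` object. `tidy()` returns the count table,
#'   `glance()` the accounting row.
#' @export
tag_library <- function(counts, sample_id = "sample", accounting = NULL) {
  if (!is.data.frame(counts) || !all(c("tag", "count") %in% names(counts))) {
    cli::cli_abort("{.arg counts} must have columns {.field tag} and {.field count}.")
  }
  counts <- as_tibble(counts[, c("tag", "count")])
  counts$count <- as.integer(counts$count)
  if (any(counts$count <= 0L)) cli::cli_abort("All tag counts must be positive.")
  if (anyDuplicated(counts$tag)) {
    counts <- dplyr::summarise(dplyr::group_by(counts, .data$tag),
                               count = sum(.data$count), .groups = "drop")
  }
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$tag)
  if (is.null(accounting)) {
    accounting <- tibble(
      total_raw = sum(counts$count),
      distinct_raw = nrow(counts),
      discarded_empty = 0L,
      discarded_n = 0L,
      total_clean = sum(counts$count),
      distinct_clean = nrow(counts)
    )
  }
  structure(
    list(sample_id = sample_id, counts = counts, accounting = accounting),
    class = "tag_library"
  )
}

#' Clean raw reads into a distinct-tag library
#'
#' Transforms raw 49 bp reads into clean 21 bp tags with full accounting.
#' The tag (CATG anchor + 17 variable bases) is extracted at `tag_start`;
#' a read is discarded as *empty* when it carries no CATG at the tag position
#' (adaptor-only reads) or is too short to contain a full tag, and as
#' *N-contaminated* when the 21 bp tag region contains an `N`. Counts are
#' aggregated over distinct surviving tags. The accounting identity
#' `discarded_empty + discarded_n + total_clean == total_raw` always holds,
#' and cleaning an already-clean tag list is a no-op.
#'
#' @param reads A tibble with a `sequence` column (e.g. from
#'   [simulate_tag_library()]), a character vector of read sequences, or a
#'   path to a FASTQ file.
#' @param sample_id Sample label.
#' @param tag_start 1-based position of the tag within the read (default 1;
#'   the protocol places the tag at the start of the read).
#' @return A `tag_library`.
#' @export
clean_reads <- function(reads, sample_id = "sample", tag_start = 1L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (missing(sample_id)) sample_id <- basename(reads)
    reads <- read_reads_fastq(reads)
  }
  seqs <- if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads)) {
      cli::cli_abort("{.arg reads} must have a {.field sequence} column.")
    }
    reads$sequence
  } else {
    as.character(reads)
  }
  tag_start <- check_count(tag_start, "tag_start")

  total_raw <- length(seqs)
  tag_end <- tag_start + TAG_LENGTH - 1L
  long_enough <- nchar(seqs) >= tag_end
  if (any(!long_enough)) {
    cli::cli_warn("{sum(!long_enough)} read{?s} shorter than the tag region; discarded as empty.")
  }
  region <- rep(NA_character_, total_raw)
  region[long_enough] <- substr(seqs[long_enough], tag_start, tag_end)

  has_anchor <- long_enough &
    substr(region, 1L, nchar(TAG_ANCHOR)) == TAG_ANCHOR
  has_anchor[is.na(has_anchor)] <- FALSE
  has_n <- has_anchor & grepl("N", region, fixed = TRUE)
  clean <- has_anchor & !has_n

  distinct_raw <- dplyr::n_distinct(region[long_enough])
  tab <- table(region[clean])
  counts <- tibble(tag = names(tab), count = as.integer(tab))
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$tag)

  accounting <- tibble(
    total_raw = total_raw,
    distinct_raw = as.integer(distinct_raw),
    discarded_empty = sum(!has_anchor),
    discarded_n = sum(has_n),
    total_clean = sum(counts$count),
    distinct_clean = nrow(counts)
  )
  stopifnot(accounting$discarded_empty + accounting$discarded_n +
              accounting$total_clean == accounting$total_raw)
  tag_library(counts, sample_id = sample_id, accounting = accounting)
}

#' Tag copy-number distribution of a library
#'
#' Assigns every distinct tag to one copy-number bin and reports per-bin
#' distinct-tag and total-tag counts, the accounting behind the classic
#' "distribution of total and distinct tags" library-quality display.
#'
#' @param lib A `tag_library`.
#' @param bin_edges Strictly increasing integer lower bin edges, starting at
#'   1. The default `c(1, 2, 6, 11, 21, 51, 101)` yields bins
#'   1, 2-5, 6-10, 11-20, 21-50, 51-100, >100.
#' @return A tibble with `bin`, `min_copies`, `max_copies`, `n_distinct`,
#'   `n_total`. Bin totals sum to the library's distinct and clean totals.
#' @export
abundance_distribution <- function(lib, bin_edges = c(1, 2, 6, 11, 21, 51, 101)) {
  stopifnot(inherits(lib, "tag_library"))
  if (length(bin_edges) < 1L || bin_edges[1] != 1 ||
      any(diff(bin_edges) <= 0) || any(bin_edges != as.integer(bin_edges))) {
    cli::cli_abort("{.arg bin_edges} must be strictly increasing integers starting at 1.")
  }
  lo <- as.integer(bin_edges)
  hi <- c(lo[-1] - 1L, NA_integer_) # NA = unbounded top bin
  lab <- ifelse(is.na(hi), paste0(">", lo - 1L),
                ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)))
  out <- tibble(bin = lab, min_copies = lo, max_copies = hi,
                n_distinct = 0L, n_total = 0L)
  if (nrow(lib$counts) > 0L) {
    idx <- findInterval(lib$counts$count, lo)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble(idx = idx, count = lib$counts$count), .data$idx),
      n_distinct = dplyr::n(), n_total = sum(.data$count), .groups = "drop"
    )
    out$n_distinct[agg$idx] <- agg$n_distinct
    out$n_total[agg$idx] <- agg$n_total
  }
  stopifnot(sum(out$n_distinct) == lib$accounting$distinct_clean,
            sum(out$n_total) == lib$accounting$total_clean)
  out
}

#' @export
print.tag_library <- function(x, ...) {
  a <- x$accounting
  cat(sprintf(
    "<tag_library> %s: %s clean tags (%s distinct) from %s raw reads (%s empty, %s with N discarded)\n",
    x$sample_id, format(a$total_clean, big.mark = ","),
    format(a$distinct_clean, big.mark = ","),
    format(a$total_raw, big.mark = ","),
    format(a$discarded_empty, big.mark = ","),
    format(a$discarded_n, big.mark = ",")
  ))
  invisible(x)
}

#' @export
tidy.tag_library <- function(x, ...) x$counts

#' @export
glance.tag_library <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$sample_id), x$accounting)
}
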