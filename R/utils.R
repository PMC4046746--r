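#' Percentage of a count pair, rounded to two decimals
#'
#' Helper used throughout the package's reports: `100 * k / n` rounded to two
#' decimal places, the convention used for every percentage the pipeline
#' prints (annotation coverage, mapping rates, enrichment columns).
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s); must be positive.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' pct(27396, 44382) # 61.73
#' @export
pct <- function(k, n, digits = 2) {
  if (any(n <= 0)) cli::cli_abort("{.arg n} must be positive.")
  round(100 * k / n, digits)
}

# Anchor recognized by NlaIII; every tag starts with it.
TAG_ANCHOR <- "CATG"
TAG_LENGTH <- 21L
VARIABLE_LENGTH <- 17L
READ_LENGTH <- 49L

# Fixed adaptor filler used to pad simulated reads to 49 bp and to emit
# adaptor-only contaminant reads. Its identity is irrelevant downstream; it
# just must not start with CATG.
ADAPTOR_SEQ <- paste0("TCGTATGCCGTCTTCTGCTTG", strrep("TA", 14))

DNA_BASES <- c("A", "C", "G", "T")

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    cli::cli_abort("{.arg {name}} must be a single integer >= {min}.")
  }
  as.integer(x)
}

check_rate <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    cli::cli_abort("{.arg {name}} must be a single number in [0, 1].")
  }
  as.numeric(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# with seed = NULL the current stream is used (still advancing it).
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

check_transcripts <- function(transcripts, require_acgt = TRUE) {
  if (!is.data.frame(transcripts) ||
      !all(c("gene_id", "sequence") %in% names(transcripts))) {
    cli::cli_abort(
      "{.arg transcripts} must be a data frame with columns {.field gene_id} and {.field sequence}."
    )
  }
  if (nrow(transcripts) == 0L) {
    cli::cli_abort("{.arg transcripts} must contain at least one gene.")
  }
  if (anyDuplicated(transcripts$gene_id)) {
    cli::cli_abort("{.field gene_id} values must be unique.")
  }
  if (any(!nzchar(transcripts$sequence))) {
    cli::cli_abort("All sequences must be non-empty.")
  }
  if (require_acgt) {
    bad <- grepl("[^ACGT]", transcripts$sequence)
    if (any(bad)) {
      cli::cli_abort(
        "Sequence of gene {.val {transcripts$gene_id[which(bad)[1]]}} contains characters outside A/C/G/T."
      )
    }
  }
  invisible(transcripts)
}
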