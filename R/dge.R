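#' Transcripts per million clean tags
#'
#' `TPM = count / total_clean * 1e6`, where the denominator is the library's
#' total number of clean tags (not only the mapped ones).
#'
#' @param counts Non-negative per-gene tag counts.
#' @param total_clean Total clean tags of the library (>= 1).
#' @return Numeric TPM vector.
#' @examples
#' tpm_normalize(100, 4362459) # 22.92...
#' @export
tpm_normalize <- function(counts, total_clean) {
  total_clean <- check_count(total_clean, "total_clean")
  if (any(counts < 0)) cli::cli_abort("{.arg counts} must be non-negative.")
  counts / total_clean * 1e6
}

#' Audic-Claverie exact test for one tag count in two libraries
#'
#' For a gene with `x` tags among `n1` clean tags in library 1 and `y` tags
#' among `n2` in library 2, the conditional law of `y` given `x` under equal
#' expression is
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},}
#' which is the negative binomial with size `x + 1` and success probability
#' `n1 / (n1 + n2)`; tails are therefore evaluated in a numerically stable
#' way for counts well beyond 1e5. The two-sided p-value doubles the smaller
#' tail, with the observed `y` included in both tails, capped at 1:
#' `p = min(1, 2 * min(P(Y <= y), P(Y >= y)))`.
#'
#' All four arguments are vectorized and recycled.
#'
#' @param x,y Observed tag counts (non-negative integers).
#' @param n1,n2 Library sizes in clean tags (>= 1).
#' @return Two-sided p-values in (0, 1].
#' @examples
#' ac_test(5, 25, 1e6, 1e6)
#' ac_test(10, 10, 1e6, 1e6) # exactly 1 for x == y with equal sizes
#' @export
ac_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) cli::cli_abort("Counts must be non-negative.")
  if (any(n1 < 1) || any(n2 < 1)) cli::cli_abort("Library sizes must be >= 1.")
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), k)
  y <- rep_len(as.numeric(y), k)
  p1 <- rep_len(n1, k) / (rep_len(n1, k) + rep_len(n2, k))
  lower <- pnbinom(y, size = x + 1, prob = p1)
  upper <- pnbinom(y - 1, size = x + 1, prob = p1, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a validated wrapper around
#' [stats::p.adjust()][stats::p.adjust] with `method = "BH"`).
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted values (monotone, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    cli::cli_abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Log2 expression ratio of two tag counts
#'
#' `log2((y / n_treat) / (x / n_ctrl))` on the TPM scale, with each zero
#' count floored at `zero_floor` tag-equivalents before conversion so that a
#' single-library detection still yields a finite ratio. Genes with zero in
#' both libraries have no defined ratio and return `NA` (rendered `"-"` in
#' reports).
#'
#' @param count_treat,count_ctrl Tag counts in treatment and control.
#' @param n_treat,n_ctrl Total clean tags in each library.
#' @param zero_floor Floor applied to zero counts for the ratio only
#'   (default 1 tag-equivalent; it plays no role in the significance test).
#' @return Numeric log2 ratios, `NA` where both counts are zero.
#' @export
log2_ratio <- function(count_treat, count_ctrl, n_treat, n_ctrl, zero_floor = 1) {
  if (any(count_treat < 0) || any(count_ctrl < 0)) {
    cli::cli_abort("Counts must be non-negative.")
  }
  yt <- pmax(count_treat, zero_floor)
  xc <- pmax(count_ctrl, zero_floor)
  out <- log2((yt / n_treat) / (xc / n_ctrl))
  out[count_treat == 0 & count_ctrl == 0] <- NA_real_
  out
}

#' Differential expression between two tag libraries
#'
#' Joins two per-gene count tables, computes TPMs, log2 ratios
#' (treatment/control), Audic-Claverie p-values, Benjamini-Hochberg FDR, and
#' significance calls at the standard thresholds `FDR <= 0.001` and
#' `|log2 ratio| >= 1`. Genes absent from one table get count 0; genes with
#' an undefined ratio (0 in both libraries) are never significant.
#'
#' @param control,treatment Per-gene count tibbles (`gene_id`, `count`),
#'   typically from [gene_counts()].
#' @param n_control,n_treatment Library sizes in total clean tags. Defaults
#'   to the `total_clean` attribute that [gene_counts()] attaches.
#' @param fdr_max Maximum FDR for a significant call.
#' @param min_abs_log2 Minimum absolute log2 ratio for a significant call.
#' @param zero_floor Passed to [log2_ratio()].
#' @return A `dge_result`. `tidy()` gives the per-gene table (`gene_id`, `x`,
#'   `y`, `tpm_control`, `tpm_treatment`, `log2_ratio`, `p_value`, `fdr`,
#'   `significant`, `direction`); `glance()` the call totals.
#' @export
dge_test <- function(control, treatment,
                     n_control = attr(control, "total_clean"),
                     n_treatment = attr(treatment, "total_clean"),
                     fdr_max = 0.001, min_abs_log2 = 1, zero_floor = 1) {
  for (nm in c("control", "treatment")) {
    tb <- get(nm)
    if (!is.data.frame(tb) || !all(c("gene_id", "count") %in% names(tb))) {
      cli::cli_abort("{.arg {nm}} must have columns {.field gene_id} and {.field count}.")
    }
  }
  if (is.null(n_control) || is.null(n_treatment)) {
    cli::cli_abort("Library sizes {.arg n_control} and {.arg n_treatment} are required (total clean tags).")
  }
  n_control <- check_count(n_control, "n_control")
  n_treatment <- check_count(n_treatment, "n_treatment")

  tab <- dplyr::full_join(
    dplyr::select(control, "gene_id", x = "count"),
    dplyr::select(treatment, "gene_id", y = "count"),
    by = "gene_id"
  )
  tab$x[is.na(tab$x)] <- 0L
  tab$y[is.na(tab$y)] <- 0L
  tab <- dplyr::mutate(
    tab,
    tpm_control = tpm_normalize(.data$x, n_control),
    tpm_treatment = tpm_normalize(.data$y, n_treatment),
    log2_ratio = log2_ratio(.data$y, .data$x, n_treatment, n_control,
                            zero_floor = zero_floor),
    p_value = ac_test(.data$x, .data$y, n_control, n_treatment),
    fdr = bh_adjust(.data$p_value),
    significant = !is.na(.data$log2_ratio) &
      .data$fdr <= fdr_max & abs(.data$log2_ratio) >= min_abs_log2,
    direction = dplyr::case_when(
      .data$significant & .data$log2_ratio >= min_abs_log2 ~ "up",
      .data$significant & .data$log2_ratio <= -min_abs_log2 ~ "down",
      TRUE ~ "none"
    )
  )
  structure(
    list(table = tab, n_control = n_control, n_treatment = n_treatment,
         fdr_max = fdr_max, min_abs_log2 = min_abs_log2),
    class = "dge_result"
  )
}

#' Up- and down-regulated gene calls
#'
#' Applies the significance rule `FDR <= fdr_max` and
#' `|log2 ratio| >= min_abs_log2` to a DE table and returns the two gene
#' lists. Undefined ratios are never significant.
#'
#' @param results A `dge_result` or its tidied table.
#' @param fdr_max,min_abs_log2 Call thresholds (defaults 0.001 and 1).
#' @return A list with character vectors `up` and `down`.
#' @export
call_degs <- function(results, fdr_max = 0.001, min_abs_log2 = 1) {
  tab <- if (inherits(results, "dge_result")) results$table else results
  sig <- !is.na(tab$log2_ratio) & tab$fdr <= fdr_max
  list(
    up = tab$gene_id[sig & tab$log2_ratio >= min_abs_log2],
    down = tab$gene_id[sig & tab$log2_ratio <= -min_abs_log2]
  )
}

#' @export
print.dge_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dge_result> %d genes tested (N1 = %s, N2 = %s): %d up, %d down at FDR <= %g & |log2| >= %g\n",
    g$n_genes, format(x$n_control, big.mark = ","),
    format(x$n_treatment, big.mark = ","), g$n_up, g$n_down,
    x$fdr_max, x$min_abs_log2
  ))
  invisible(x)
}

#' @export
tidy.dge_result <- function(x, ...) x$table

#' @export
glance.dge_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    n_control = x$n_control,
    n_treatment = x$n_treatment,
    fdr_max = x$fdr_max,
    min_abs_log2 = x$min_abs_log2
  )
}

#' Classify time-course response phase of up-regulated genes
#'
#' Assigns each gene its earliest significant up-regulation time point
#' against a common control: `phase1` if up at the first time point,
#' else `phase2` if first up at the second, else `phase3` if first up at the
#' third, else `none`.
#'
#' @param up_1h,up_5h,up_24h Character vectors of up-called gene ids at each
#'   time point (all called against the same control).
#' @param genes Gene universe for the output; defaults to the union of the
#'   three call sets.
#' @return A tibble with `gene_id`, logical `up_1h`, `up_5h`, `up_24h`, and
#'   `phase` in `c("phase1", "phase2", "phase3", "none")`.
#' @export
classify_phase <- function(up_1h, up_5h, up_24h,
                           genes = union(union(up_1h, up_5h), up_24h)) {
  out <- tibble(
    gene_id = genes,
    up_1h = genes %in% up_1h,
    up_5h = genes %in% up_5h,
    up_24h = genes %in% up_24h
  )
  out$phase <- dplyr::case_when(
    out$up_1h ~ "phase1",
    out$up_5h ~ "phase2",
    out$up_24h ~ "phase3",
    TRUE ~ "none"
  )
  out
}
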