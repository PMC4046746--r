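#' Simulate a reference transcriptome for tag profiling
#'
#' Generates random A/C/G/T unigene sequences with lengths drawn around
#' `mean_length` (log-normal, floored at `min_length`). A configurable
#' fraction of genes is guaranteed to carry no CATG site at all (protocol
#' dropouts: such genes can never produce a tag), and every remaining gene is
#' guaranteed that its 3'-most CATG has at least 17 downstream bases, i.e. it
#' is taggable both for the virtual tag database and for the simulated
#' NlaIII/MmeI protocol.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_length Mean sequence length in bp (>= 30). Default 560, the
#'   scale of a typical short-read de novo unigene set.
#' @param catg_free_fraction Fraction of genes guaranteed CATG-free.
#' @param length_sdlog Log-scale SD of the length distribution.
#' @param min_length Minimum sequence length (>= 30 so a CATG+17 window fits).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A tibble with columns `gene_id` and `sequence`.
#' @examples
#' tx <- simulate_transcriptome(50, mean_length = 200, seed = 1)
#' tx
#' @export
simulate_transcriptome <- function(n_genes, mean_length = 560,
                                   catg_free_fraction = 0.05,
                                   length_sdlog = 0.7, min_length = 30,
                                   seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes")
  mean_length <- check_count(mean_length, "mean_length", min = 30L)
  check_rate(catg_free_fraction, "catg_free_fraction")
  min_length <- check_count(min_length, "min_length", min = 30L)

  with_seed_or_current(seed, {
    lens <- pmax(
      min_length,
      as.integer(round(rlnorm(n_genes,
                              meanlog = log(mean_length) - length_sdlog^2 / 2,
                              sdlog = length_sdlog)))
    )
    bases <- sample(DNA_BASES, sum(lens), replace = TRUE)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- substring(paste(bases, collapse = ""), starts, ends)

    n_free <- as.integer(round(catg_free_fraction * n_genes))
    free <- logical(n_genes)
    if (n_free > 0L) free[sample.int(n_genes, n_free)] <- TRUE

    seqs[free] <- scrub_catg(seqs[free])
    seqs[!free] <- ensure_taggable(seqs[!free])

    tibble(
      gene_id = sprintf("gene_%05d", seq_len(n_genes)),
      sequence = seqs
    )
  })
}

# Remove every CATG occurrence. Replacing CATG -> CATT cannot create a new
# CATG (the replacement contains no G), so one gsub pass suffices.
scrub_catg <- function(seqs) {
  gsub(TAG_ANCHOR, "CATT", seqs, fixed = TRUE)
}

# Guarantee the 3'-most CATG has exactly >= 17 downstream bases: where the
# check fails, implant CATG at length-20 and scrub any CATG further 3'.
ensure_taggable <- function(seqs) {
  bad <- is.na(tag_at_3prime(seqs))
  if (any(bad)) {
    fix <- seqs[bad]
    len <- nchar(fix)
    substr(fix, len - 20L, len - 17L) <- TAG_ANCHOR
    tail17 <- scrub_catg(substr(fix, len - 16L, len))
    fix <- paste0(substr(fix, 1L, len - 17L), tail17)
    seqs[bad] <- fix
  }
  seqs
}

# 21 bp tag produced by the simulated protocol: the 3'-most CATG plus the 17
# following bases, or NA if the 3'-most CATG has fewer than 17 downstream
# bases (MmeI cannot cut) or the gene has no CATG.
tag_at_3prime <- function(seqs) {
  hits <- gregexpr(TAG_ANCHOR, seqs, fixed = TRUE)
  last <- vapply(hits, function(h) if (h[1] == -1L) NA_integer_ else max(h), integer(1))
  ok <- !is.na(last) & (nchar(seqs) - (last + 3L) >= VARIABLE_LENGTH)
  out <- rep(NA_character_, length(seqs))
  out[ok] <- substr(seqs[ok], last[ok], last[ok] + TAG_LENGTH - 1L)
  out
}

#' Simulate ground-truth expression with differential structure
#'
#' Draws heavy-tailed (log-normal) baseline transcript abundances and plants
#' differential expression: one subset of `de_fraction` genes, with up/down
#' signs split evenly, has its abundance multiplied by `2^(+-effect_log2)` in
#' every non-baseline condition; abundances are renormalized to sum to one
#' within each condition. The first element of `conditions` is the baseline.
#'
#' @param transcripts Tibble from [simulate_transcriptome()] (or any table
#'   with a `gene_id` column).
#' @param conditions Character vector of condition labels; first is baseline.
#' @param de_fraction Fraction of genes that are differentially expressed.
#' @param effect_log2 Planted absolute log2 effect size (> 0).
#' @param dispersion Log-scale SD of the baseline abundance law. The default
#'   3 reproduces the strongly skewed tag-abundance shape of real libraries,
#'   where most detected genes carry fewer than 10 tag copies at around one
#'   million tags of depth.
#' @param seed Optional integer seed.
#' @return A tibble with columns `gene_id`, `condition`, `abundance`
#'   (summing to 1 within condition), `de_flag`, `log2_effect`.
#' @export
simulate_expression <- function(transcripts,
                                conditions = c("control", "cold_1h", "cold_5h", "cold_24h"),
                                de_fraction = 0.1, effect_log2 = 3,
                                dispersion = 3, seed = NULL) {
  if (!is.data.frame(transcripts) || !"gene_id" %in% names(transcripts)) {
    cli::cli_abort("{.arg transcripts} must be a data frame with a {.field gene_id} column.")
  }
  if (length(conditions) < 1L) cli::cli_abort("At least one condition label is required.")
  if (!is.numeric(de_fraction) || length(de_fraction) != 1L ||
      is.na(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    cli::cli_abort("{.arg de_fraction} must be a single number in [0, 1].")
  }
  if (effect_log2 <= 0) cli::cli_abort("{.arg effect_log2} must be positive.")
  if (dispersion <= 0) cli::cli_abort("{.arg dispersion} must be positive.")

  genes <- transcripts$gene_id
  n <- length(genes)

  with_seed_or_current(seed, {
    base <- rlnorm(n, meanlog = 0, sdlog = dispersion)
    base <- base / sum(base)

    n_de <- as.integer(round(de_fraction * n))
    effect <- numeric(n)
    if (n_de > 0L) {
      de_idx <- sample.int(n, n_de)
      effect[de_idx] <- sample(rep(c(1, -1), length.out = n_de)) * effect_log2
    }

    purrr::map_dfr(seq_along(conditions), function(i) {
      if (i == 1L) {
        ab <- base
        eff <- numeric(n)
      } else {
        ab <- base * 2^effect
        ab <- ab / sum(ab)
        eff <- effect
      }
      tibble(
        gene_id = genes, condition = conditions[i],
        abundance = ab, de_flag = eff != 0, log2_effect = eff
      )
    })
  })
}

#' Simulate one raw tag-sequencing library
#'
#' Emulates the NlaIII/MmeI DGE protocol: each sequenced molecule yields the
#' 3'-most CATG of its transcript plus the 17 following bases (21 bp tag),
#' padded with adaptor sequence to a 49 bp read. Genes whose 3'-most CATG has
#' fewer than 17 downstream bases emit nothing (their draws are reassigned to
#' taggable genes by renormalizing abundances). Sequencing errors substitute
#' each of the 17 variable bases independently with probability `error_rate`
#' (the CATG anchor is enzymatically fixed and left intact). Adaptor-only and
#' N-contaminated reads are injected at their configured rates.
#'
#' @param transcripts Reference tibble (`gene_id`, `sequence`).
#' @param truth Expression truth from [simulate_expression()].
#' @param condition Which condition of `truth` to sample from.
#' @param depth Total number of raw reads to emit.
#' @param error_rate Per-base substitution probability on the 17 variable bases.
#' @param adaptor_only_rate Fraction of reads that are pure adaptor (no CATG).
#' @param n_read_rate Fraction of reads whose tag contains an 'N'.
#' @param seed Optional integer seed.
#' @return A tibble of raw reads: `read_id`, `sequence` (49 bp), `category`
#'   (one of `"tag"`, `"adaptor_only"`, `"n_contaminated"`), and provenance
#'   `gene_id` (NA for adaptor-only reads).
#' @export
simulate_tag_library <- function(transcripts, truth, condition, depth,
                                 error_rate = 0.01, adaptor_only_rate = 0.05,
                                 n_read_rate = 0.03, seed = NULL) {
  check_transcripts(transcripts)
  depth <- check_count(depth, "depth")
  check_rate(error_rate, "error_rate")
  check_rate(adaptor_only_rate, "adaptor_only_rate")
  check_rate(n_read_rate, "n_read_rate")
  if (adaptor_only_rate + n_read_rate >= 1) {
    cli::cli_abort("Contamination rates must sum to less than 1.")
  }
  tr <- truth[truth$condition == condition, , drop = FALSE]
  if (nrow(tr) == 0L) {
    cli::cli_abort("Condition {.val {condition}} not present in {.arg truth}.")
  }
  ab <- tr$abundance[match(transcripts$gene_id, tr$gene_id)]
  ab[is.na(ab)] <- 0

  tags3 <- tag_at_3prime(transcripts$sequence)
  taggable <- which(!is.na(tags3) & ab > 0)
  if (length(taggable) == 0L) {
    cli::cli_abort("No taggable transcripts: every gene with positive abundance lacks a CATG+17 window.")
  }
  prob <- ab[taggable] / sum(ab[taggable])

  with_seed_or_current(seed, {
    n_cat <- drop(rmultinom(1, depth,
                            c(tag = 1 - adaptor_only_rate - n_read_rate,
                              adaptor_only = adaptor_only_rate,
                              n_contaminated = n_read_rate)))
    n_tag <- n_cat[["tag"]]
    n_ad <- n_cat[["adaptor_only"]]
    n_n <- n_cat[["n_contaminated"]]

    m <- n_tag + n_n
    gene_idx <- if (m > 0L) taggable[sample.int(length(taggable), m, replace = TRUE, prob = prob)] else integer(0)
    tags <- tags3[gene_idx]
    if (error_rate > 0 && m > 0L) tags <- mutate_variable_bases(tags, error_rate)
    if (n_n > 0L) {
      npos <- sample.int(TAG_LENGTH, n_n, replace = TRUE)
      ntags <- tags[n_tag + seq_len(n_n)]
      substr(ntags, npos, npos) <- "N"
      tags[n_tag + seq_len(n_n)] <- ntags
    }

    pad <- substr(ADAPTOR_SEQ, 1L, READ_LENGTH - TAG_LENGTH)
    seqs <- c(paste0(tags, pad), rep(ADAPTOR_SEQ, n_ad))
    cats <- c(rep("tag", n_tag), rep("n_contaminated", n_n), rep("adaptor_only", n_ad))
    genes <- c(transcripts$gene_id[gene_idx], rep(NA_character_, n_ad))

    ord <- sample.int(depth)
    tibble(
      read_id = sprintf("%s_read_%07d", condition, seq_len(depth)),
      sequence = seqs[ord],
      category = cats[ord],
      gene_id = genes[ord]
    )
  })
}

# Independent per-base substitution on the 17 variable positions; a
# substituted base is drawn uniformly from the three other bases.
mutate_variable_bases <- function(tags, error_rate) {
  m <- length(tags)
  hit <- matrix(runif(m * VARIABLE_LENGTH) < error_rate, nrow = m)
  for (p in seq_len(VARIABLE_LENGTH)) {
    idx <- which(hit[, p])
    if (length(idx) == 0L) next
    at <- 4L + p
    cur <- match(substr(tags[idx], at, at), DNA_BASES)
    new <- DNA_BASES[(cur - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L + 1L]
    tg <- tags[idx]
    substr(tg, at, at) <- new
    tags[idx] <- tg
  }
  tags
}

#' Simulate a gene-to-term annotation map
#'
#' Assigns synthetic pathway-style terms to a fraction of genes, with
#' heterogeneous term sizes, for exercising the enrichment stage. Purely
#' artifact plumbing: real analyses supply their own annotation table.
#'
#' @param transcripts Reference tibble (`gene_id` column used).
#' @param n_terms Number of distinct terms.
#' @param annotated_fraction Fraction of genes receiving at least one term.
#' @param mean_terms_per_gene Mean number of terms per annotated gene.
#' @param seed Optional integer seed.
#' @return A tibble with columns `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotation <- function(transcripts, n_terms = 20,
                                annotated_fraction = 0.6,
                                mean_terms_per_gene = 1.5, seed = NULL) {
  n_terms <- check_count(n_terms, "n_terms")
  check_rate(annotated_fraction, "annotated_fraction")
  genes <- transcripts$gene_id
  with_seed_or_current(seed, {
    ann_genes <- genes[runif(length(genes)) < annotated_fraction]
    k <- pmax(1L, stats::rpois(length(ann_genes), mean_terms_per_gene))
    w <- rlnorm(n_terms, 0, 1)
    terms <- sprintf("term_%03d", seq_len(n_terms))
    out <- tibble(
      gene_id = rep(ann_genes, k),
      term_id = terms[sample.int(n_terms, sum(k), replace = TRUE, prob = w / sum(w))]
    )
    out <- dplyr::distinct(out)
    out$term_name <- paste("Pathway", sub("term_", "", out$term_id))
    out
  })
}
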