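test_that("transcriptome generator rejects invalid sizes", {
  expect_error(simulate_transcriptome(0), "n_genes")
  expect_error(simulate_transcriptome(10, mean_length = 10), "mean_length")
  expect_error(simulate_transcriptome(10, catg_free_fraction = 1.5), "catg_free_fraction")
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_transcriptome(100, mean_length = 200, seed = 42)
  b <- simulate_transcriptome(100, mean_length = 200, seed = 42)
  expect_identical(a, b)

  ta <- simulate_expression(a, seed = 7)
  tb <- simulate_expression(b, seed = 7)
  expect_identical(ta, tb)

  ra <- simulate_tag_library(a, ta, "control", depth = 2000, seed = 9)
  rb <- simulate_tag_library(b, tb, "control", depth = 2000, seed = 9)
  expect_identical(ra, rb)
})

test_that("catg_free_fraction yields exactly the requested number of window-free genes", {
  tx <- simulate_transcriptome(1000, mean_length = 150,
                               catg_free_fraction = 0.1, seed = 3)
  # count taggable windows with a direct string scan, not the package index
  n_windows <- vapply(tx$sequence, function(s) length(naive_windows(s)$tags),
                      integer(1), USE.NAMES = FALSE)
  expect_identical(sum(n_windows == 0L), 100L)
  expect_true(all(n_windows[n_windows != 0L] >= 1L))
  expect_true(all(grepl("^[ACGT]+$", tx$sequence)))
  expect_true(abs(mean(nchar(tx$sequence)) - 150) < 25)
})

test_that("expression truth honours de_fraction and normalization", {
  tx <- simulate_transcriptome(1000, mean_length = 100, seed = 5)

  null_truth <- simulate_expression(tx, de_fraction = 0, seed = 1)
  expect_false(any(null_truth$de_flag))
  base <- null_truth$abundance[null_truth$condition == "control"]
  for (cond in unique(null_truth$condition)) {
    expect_equal(null_truth$abundance[null_truth$condition == cond], base)
  }

  truth <- simulate_expression(tx, de_fraction = 0.1, effect_log2 = 2, seed = 1)
  per_cond <- split(truth, truth$condition)
  for (tt in per_cond) expect_equal(sum(tt$abundance), 1)
  cold <- per_cond[["cold_5h"]]
  expect_identical(sum(cold$de_flag), 100L)
  expect_true(all(cold$de_flag == (abs(cold$log2_effect) > 0)))
  # signs split evenly
  expect_equal(sum(cold$log2_effect > 0), 50)
  expect_error(simulate_expression(tx, de_fraction = -0.1), "de_fraction")
})

test_that("noiseless tag reads round-trip into the virtual tag database", {
  tx <- simulate_transcriptome(200, mean_length = 300, seed = 11)
  truth <- simulate_expression(tx, seed = 12)
  reads <- simulate_tag_library(tx, truth, "control", depth = 5000,
                                error_rate = 0, adaptor_only_rate = 0,
                                n_read_rate = 0, seed = 13)
  expect_true(all(reads$category == "tag"))
  expect_true(all(nchar(reads$sequence) == 49L))
  idx <- build_tag_index(tx)
  expect_true(all(substr(reads$sequence, 1, 21) %in% idx$tag_keys))
})

test_that("zero-abundance genes emit no reads", {
  tx <- simulate_transcriptome(50, mean_length = 200, seed = 21)
  truth <- simulate_expression(tx, conditions = "control", de_fraction = 0, seed = 22)
  truth$abundance[truth$gene_id == "gene_00001"] <- 0
  truth$abundance <- truth$abundance / sum(truth$abundance)
  reads <- simulate_tag_library(tx, truth, "control", depth = 20000,
                                error_rate = 0, seed = 23)
  expect_false("gene_00001" %in% reads$gene_id)
})

test_that("an all-untaggable reference is an explicit error", {
  tx <- tibble::tibble(gene_id = c("g1", "g2"),
                       sequence = c(strrep("A", 100), strrep("T", 80)))
  truth <- tibble::tibble(gene_id = c("g1", "g2"), condition = "control",
                          abundance = c(0.5, 0.5), de_flag = FALSE,
                          log2_effect = 0)
  expect_error(simulate_tag_library(tx, truth, "control", depth = 10),
               "taggable")
})

test_that("contaminant categories follow their configured rates", {
  tx <- simulate_transcriptome(100, mean_length = 200, seed = 31)
  truth <- simulate_expression(tx, seed = 32)
  reads <- simulate_tag_library(tx, truth, "control", depth = 100000,
                                adaptor_only_rate = 0.05, n_read_rate = 0.02,
                                seed = 33)
  n_ad <- sum(reads$category == "adaptor_only")
  # binomial oracle: within 3 SD of the expectation
  expect_lt(abs(n_ad - 5000), 3 * sqrt(100000 * 0.05 * 0.95))

  # multinomial goodness of fit over repeated seeds
  counts <- c(tag = 0, adaptor_only = 0, n_contaminated = 0)
  for (s in 1:15) {
    r <- simulate_tag_library(tx, truth, "control", depth = 3000,
                              adaptor_only_rate = 0.1, n_read_rate = 0.05,
                              seed = 100 + s)
    tab <- table(factor(r$category, levels = names(counts)))
    counts <- counts + as.integer(tab)
  }
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = c(0.85, 0.1, 0.05))
  )
  expect_gt(gof$p.value, 0.001)
})

test_that("sequencing errors stay inside the 17 variable bases", {
  tx <- simulate_transcriptome(100, mean_length = 200, seed = 41)
  truth <- simulate_expression(tx, seed = 42)
  reads <- simulate_tag_library(tx, truth, "control", depth = 20000,
                                error_rate = 0.2, adaptor_only_rate = 0,
                                n_read_rate = 0, seed = 43)
  expect_true(all(substr(reads$sequence, 1, 4) == "CATG"))
  # at 20% per-base error nearly every read should differ somewhere
  idx <- build_tag_index(tx)
  frac_exact <- mean(substr(reads$sequence, 1, 21) %in% idx$tag_keys)
  expect_lt(frac_exact, 0.2)
})

test_that("at a million tags most detected genes carry fewer than 10 copies", {
  # the default dispersion is calibrated to this property of real libraries
  tx <- simulate_transcriptome(10000, mean_length = 560, seed = 121)
  truth <- simulate_expression(tx, de_fraction = 0, seed = 122)
  reads <- simulate_tag_library(tx, truth, "control", depth = 1e6,
                                adaptor_only_rate = 0, n_read_rate = 0,
                                seed = 123)
  per_gene <- table(reads$gene_id)
  expect_gt(mean(per_gene < 10), 0.5)
})

test_that("fastq and fasta round-trips preserve the tables", {
  tx <- simulate_transcriptome(20, mean_length = 100, seed = 51)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts_fasta(tx, fa)
  expect_equal(read_transcripts_fasta(fa), tx)

  truth <- simulate_expression(tx, seed = 52)
  reads <- simulate_tag_library(tx, truth, "control", depth = 100, seed = 53)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq)
  back <- read_reads_fastq(fq)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
})
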