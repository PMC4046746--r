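# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: naive string scans, all-pairs Hamming distance,
# and exact rational arithmetic (python fractions) for tail probabilities.

# Naive scan for CATG+17 windows: direct position-by-position check.
naive_windows <- function(sequence) {
  n <- nchar(sequence)
  out <- character(0)
  offs <- integer(0)
  if (n >= 21) {
    for (i in seq_len(n - 20)) {
      if (substr(sequence, i, i + 3) == "CATG") {
        out <- c(out, substr(sequence, i, i + 20))
        offs <- c(offs, i - 1L)
      }
    }
  }
  list(tags = out, offsets = offs)
}

# Character matrix of fixed-length strings (rows = strings).
char_matrix <- function(x, width) {
  matrix(unlist(strsplit(x, "")), nrow = length(x), ncol = width, byrow = TRUE)
}

# All-pairs Hamming distances between equal-length string vectors.
hamming_all_pairs <- function(a, b, width = 21L) {
  A <- char_matrix(a, width)
  B <- char_matrix(b, width)
  D <- matrix(0L, nrow = length(a), ncol = length(b))
  for (p in seq_len(width)) {
    D <- D + outer(A[, p], B[, p], "!=")
  }
  D
}

# Brute-force reference for map_tags: exact hits take precedence; otherwise
# windows at Hamming distance 1 with the CATG anchor intact.
brute_force_map <- function(tags, window_tbl) {
  D <- hamming_all_pairs(tags, window_tbl$tag)
  anchor_ok <- outer(
    substr(tags, 1, 4),
    substr(window_tbl$tag, 1, 4),
    "=="
  )
  vapply(seq_along(tags), function(i) {
    exact <- window_tbl$gene_id[D[i, ] == 0L]
    hit <- if (length(exact) > 0L) {
      exact
    } else {
      window_tbl$gene_id[D[i, ] == 1L & anchor_ok[i, ]]
    }
    genes <- unique(hit)
    if (length(genes) == 0L) {
      "unknown"
    } else if (length(genes) == 1L) {
      paste0("unambiguous:", genes)
    } else {
      "ambiguous"
    }
  }, "")
}

# Random 21 bp tag starting with the CATG anchor.
random_tags <- function(n) {
  paste0("CATG", vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
  }, ""))
}

# Exact-rational oracle for Audic-Claverie two-sided p-values and
# hypergeometric upper tails, via python's fractions.Fraction.
PY_ORACLE <- '
import sys, csv
from fractions import Fraction as F
from math import comb

def ac_p(x, y, n1, n2):
    p1 = F(n1, n1 + n2); p2 = 1 - p1
    def pmf(t):
        return comb(x + t, t) * p1 ** (x + 1) * p2 ** t
    lower = sum(pmf(t) for t in range(0, y + 1))
    upper = 1 - sum(pmf(t) for t in range(0, y))
    return float(min(F(1), 2 * min(lower, upper)))

def hyper_upper(k, K, n, N):
    tot = comb(N, n)
    return float(sum(F(comb(K, t) * comb(N - K, n - t), tot)
                     for t in range(k, min(n, K) + 1)))

rows = list(csv.reader(sys.stdin))
for row in rows:
    kind, a, b, c, d = row[0], int(row[1]), int(row[2]), int(row[3]), int(row[4])
    if kind == "ac":
        print(repr(ac_p(a, b, c, d)))
    else:
        print(repr(hyper_upper(a, b, c, d)))
'

# cases: data.frame with columns kind ("ac" or "hyper") and a,b,c,d.
# For "ac": a=x, b=y, c=N1, d=N2. For "hyper": a=k, b=K, c=n, d=N.
exact_tail_oracle <- function(cases) {
  input <- apply(cases, 1, paste, collapse = ",")
  out <- system2("python", c("-c", shQuote(PY_ORACLE)),
                 input = input, stdout = TRUE)
  as.numeric(out)
}
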