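# Independent oracles used across tests.

# Exhaustive global-alignment optimum: recursively enumerate every gapped
# pairing of the two sequences, scoring complete alignments column by column.
# Exponential — only for short sequences.
brute_force_align_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  recurse <- function(i, j, sc) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1L, j + 1L, sc + if (av[i] == bv[j]) match else mismatch)
    }
    if (i <= length(av)) recurse(i + 1L, j, sc + gap)
    if (j <= length(bv)) recurse(i, j + 1L, sc + gap)
  }
  recurse(1L, 1L, 0)
  best
}

# Alignment-free identity between equal-length (indel-free) sequences.
hamming_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  100 * mean(av == bv)
}

# Central finite-difference derivative.
numeric_slope <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Random peptide of a given length.
random_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
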