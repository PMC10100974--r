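# Needleman-Wunsch global alignment and percent identity. The dynamic
# programme is row-vectorized: with a linear gap penalty g, the left-gap
# chain max_{k<=j} (pre[k] + g*(j-k)) collapses to g*j + cummax(pre - g*j),
# so each row is filled without an inner loop.

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment of two residue strings under simple
#' match/mismatch/linear-gap scoring. The defaults (+2 match, -1 mismatch,
#' -2 per gap position) are adequate for threshold-based homology calls; no
#' substitution matrix is applied.
#'
#' @param a,b sequences: single non-empty character strings (amino acids or
#'   any alphabet).
#' @param match score for an identical column.
#' @param mismatch score for a substituted column.
#' @param gap score per gap position (linear gap penalty, negative).
#' @return A list of class `pairwise_alignment`: `a_aln` and `b_aln` (gapped
#'   strings of equal length, gaps as `-`) and `score`.
#' @examples
#' global_align("ACDE", "ACE")
#' @export
global_align <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)

  M <- matrix(0, n + 1L, m + 1L)
  M[1L, ] <- gap * 0:m
  M[, 1L] <- gap * 0:n
  jg <- gap * (1:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    # best score entering column j from the diagonal or from above
    pre <- pmax(M[i, 1:m] + sub, M[i, 2:(m + 1L)] + gap)
    # left-gap chains, seeded by the first-column boundary at k = 0
    chain <- cummax(pmax(pre - jg, c(M[i + 1L, 1L], rep(-Inf, m - 1L))))
    M[i + 1L, 2:(m + 1L)] <- jg + chain
  }

  # traceback
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == M[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == M[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  structure(list(a_aln = paste(ra, collapse = ""),
                 b_aln = paste(rb, collapse = ""),
                 score = M[n + 1L, m + 1L]),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$a_aln, "\n", x$b_aln, "\n", sprintf("score: %g", x$score), "\n", sep = "")
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' Identical columns divided by the full alignment length; gap columns count
#' in the denominator, the conservative convention for homology thresholds.
#'
#' @param alignment a [global_align()] result.
#' @return Identity as a percentage in `[0, 100]`.
#' @examples
#' percent_identity(global_align("ACDE", "ACE"))  # 75
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  a <- strsplit(alignment$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$b_aln, "", fixed = TRUE)[[1]]
  if (!length(a)) stop("zero-length alignment")
  100 * sum(a == b & a != "-") / length(a)
}
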