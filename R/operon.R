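# hmu operon survey: homolog detection by percent identity, 0/1/2
# conservation-pattern strings, pattern tallies, and synteny checks.

#' Canonical gene order of the hmu heme-uptake operon
#' @export
HMU_GENES <- c("hmuY", "hmuR", "hmuS", "hmuT", "hmuU", "hmuV")

as_seq_vector <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a named character vector or an AAStringSet")
  }
  if (length(out) && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

#' Find homologs of a bait protein in a proteome
#'
#' Aligns the bait globally against every proteome member and reports those
#' whose percent identity (identical columns over full alignment length)
#' meets the threshold — the >= 30 % global-identity convention used for Hmu
#' protein homology calls.
#'
#' @param bait a single protein sequence (character string).
#' @param proteome named character vector of protein sequences, or an
#'   `AAStringSet`. May be empty.
#' @param threshold percent-identity cutoff in `(0, 100]`; default 30.
#' @param ... scoring parameters passed to [global_align()].
#' @return A data.frame with columns `id` and `identity`, sorted by identity
#'   descending (zero rows when nothing reaches the threshold).
#' @export
detect_homologs <- function(bait, proteome, threshold = 30, ...) {
  stopifnot(is.character(bait), length(bait) == 1L, nzchar(bait))
  if (threshold <= 0 || threshold > 100) stop("'threshold' must be in (0, 100]")
  proteome <- as_seq_vector(proteome)
  if (!length(proteome)) {
    return(data.frame(id = character(0), identity = numeric(0)))
  }
  idents <- vapply(proteome,
                   function(s) percent_identity(global_align(bait, s, ...)),
                   numeric(1))
  hits <- data.frame(id = names(proteome), identity = unname(idents))
  hits <- hits[hits$identity >= threshold, , drop = FALSE]
  hits <- hits[order(-hits$identity), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Score the conservation pattern of the hmu operon in one genome
#'
#' For each of the six bait proteins (HmuY, R, S, T, U, V in order), the
#' genome's proteome is searched for homologs and the gene scored 0 when
#' absent, 1 when present once, and 2 when two or more copies are found,
#' giving a 6-character pattern string such as `"111111"` (complete operon)
#' or `"010111"` (HmuY and HmuS not detected).
#'
#' @param baits list (or named character vector) of the six bait protein
#'   sequences in hmuYRSTUV order.
#' @param proteome the genome's predicted proteome (named character vector
#'   or `AAStringSet`).
#' @param genome_id label for the genome.
#' @param threshold percent-identity cutoff; default 30.
#' @param ... passed to [detect_homologs()].
#' @return A list of class `conservation_pattern`: `genome_id`, `pattern`
#'   (6-character string over `{0,1,2}`) and `hits` (per-bait hit tables).
#' @export
conservation_pattern <- function(baits, proteome, genome_id = "genome",
                                 threshold = 30, ...) {
  baits <- as.list(baits)
  if (length(baits) != 6L) stop("exactly six baits (hmuYRSTUV) are required")
  hits <- lapply(baits, detect_homologs, proteome = proteome,
                 threshold = threshold, ...)
  names(hits) <- HMU_GENES
  score <- vapply(hits, function(h) min(nrow(h), 2L), integer(1))
  structure(list(genome_id = genome_id,
                 pattern = paste(score, collapse = ""),
                 hits = hits),
            class = "conservation_pattern")
}

#' @export
print.conservation_pattern <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$genome_id, x$pattern))
  invisible(x)
}

#' Tally conservation patterns across genomes
#'
#' @param patterns a character vector of 6-character pattern strings, or a
#'   list of [conservation_pattern()] objects.
#' @return A data.frame with columns `pattern` and `count`, sorted by count
#'   descending (ties by pattern); counts sum to the number of genomes.
#' @export
tally_patterns <- function(patterns) {
  if (is.list(patterns)) {
    patterns <- vapply(patterns, function(p) {
      if (inherits(p, "conservation_pattern")) p$pattern else as.character(p)
    }, character(1))
  }
  if (!length(patterns)) {
    return(data.frame(pattern = character(0), count = integer(0)))
  }
  if (any(nchar(patterns) != 6L) || any(grepl("[^012]", patterns))) {
    stop("patterns must be 6-character strings over {0,1,2}")
  }
  tab <- table(patterns)
  out <- data.frame(pattern = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess colocalization and gene-order synteny of operon loci
#'
#' Loci are colocalized when they all lie on one contig with every adjacent
#' intergenic gap at most `max_gap_bp` (20 kb by default, the usual
#' gene-cluster window). Order is preserved when the genomic order of the
#' present genes equals the canonical hmuYRSTUV order or its exact reverse
#' (an operon read off the minus strand).
#'
#' @param loci a data.frame with columns `gene` (values among
#'   [HMU_GENES]), `contig`, `start`, `end` (1-based inclusive) and
#'   optionally `strand`.
#' @param max_gap_bp maximum allowed intergenic gap (bp).
#' @param genome_id label carried into the report.
#' @return A list of class `synteny_report`: `genome_id`, `colocalized`,
#'   `max_gap_bp` (largest observed adjacent gap), `order_preserved`,
#'   `observed_order`.
#' @export
check_synteny <- function(loci, max_gap_bp = 20000, genome_id = "genome") {
  need <- c("gene", "contig", "start", "end")
  if (!is.data.frame(loci) || !all(need %in% names(loci))) {
    stop("loci must be a data.frame with columns gene, contig, start, end")
  }
  if (nrow(loci) < 2L) stop("need at least 2 loci to assess synteny")
  if (any(loci$start > loci$end) || any(loci$start < 1)) {
    stop("malformed coordinates: need 1 <= start <= end")
  }
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  one_contig <- length(unique(loci$contig)) == 1L
  gaps <- if (one_contig) {
    loci$start[-1L] - loci$end[-nrow(loci)] - 1L
  } else {
    NA_integer_
  }
  max_gap_obs <- if (one_contig) max(gaps) else NA_integer_
  colocalized <- one_contig && all(gaps <= max_gap_bp)

  observed <- loci$gene
  canonical <- HMU_GENES[HMU_GENES %in% observed]
  # duplicate copies break a strict order comparison
  order_preserved <- !anyDuplicated(observed) &&
    (identical(observed, canonical) || identical(observed, rev(canonical)))
  structure(list(genome_id = genome_id,
                 colocalized = colocalized,
                 max_gap_bp = max_gap_obs,
                 order_preserved = order_preserved,
                 observed_order = observed),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("%s: colocalized = %s, order preserved = %s (%s)\n",
              x$genome_id, x$colocalized, x$order_preserved,
              paste(x$observed_order, collapse = " > ")))
  invisible(x)
}
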