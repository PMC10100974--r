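# File-format adapters and the end-to-end pipeline driver.
#
# On-disk schemas (CSV: comma-separated, UTF-8, mandatory header row):
#   plate reader   time_h, well, od600
#   calibration    level, signal
#   chromatogram   scan_time_min, mz, intensity
#   gene loci      GFF3-like TSV: seqid, source, type, start, end, score,
#                  strand, attributes (gene=<name>); 1-based inclusive
# FASTA goes through Biostrings.

read_checked_csv <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read and write plate-reader optical density tables
#'
#' @param path CSV file with columns `time_h`, `well`, `od600`.
#' @return `read_plate_csv()`: a data.frame with those columns, checked for
#'   non-negative OD and per-well strictly increasing times.
#' @export
read_plate_csv <- function(path) {
  df <- read_checked_csv(path, c("time_h", "well", "od600"))
  if (any(df$od600 < 0)) stop("negative od600 in ", path)
  bad <- vapply(split(df$time_h, df$well),
                function(t) any(diff(sort(t)) <= 0) || is.unsorted(t),
                logical(1))
  if (any(bad)) {
    stop("non-increasing times for well(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  df
}

#' @rdname read_plate_csv
#' @param curves a data.frame with columns `time_h`, `od` (or `od600`) and
#'   `replicate_id` (or `well`), e.g. a [sim_growth_curve()] result.
#' @export
write_plate_csv <- function(curves, path) {
  df <- data.frame(
    time_h = curves$time_h,
    well = if (!is.null(curves$well)) curves$well else curves$replicate_id,
    od600 = if (!is.null(curves$od600)) curves$od600 else curves$od)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write calibration-standard tables
#'
#' @param path CSV file with columns `level`, `signal`.
#' @return A data.frame with those columns.
#' @export
read_calibration_csv <- function(path) {
  df <- read_checked_csv(path, c("level", "signal"))
  if (any(df$level < 0)) stop("negative standard level in ", path)
  df
}

#' @rdname read_calibration_csv
#' @param series a data.frame with columns `level` and `signal`.
#' @export
write_calibration_csv <- function(series, path) {
  utils::write.csv(series[, c("level", "signal")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write chromatograms
#'
#' @param path CSV file with columns `scan_time_min`, `mz`, `intensity`.
#' @return `read_chromatogram_csv()`: a [chromatogram()] object.
#' @export
read_chromatogram_csv <- function(path) {
  df <- read_checked_csv(path, c("scan_time_min", "mz", "intensity"))
  chromatogram(df$scan_time_min, df$mz, df$intensity)
}

#' @rdname read_chromatogram_csv
#' @param chrom a [chromatogram()] object.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write protein FASTA files
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' the sequence representation used by the alignment functions.
#'
#' @param path FASTA file.
#' @return `read_protein_fasta()`: named character vector of residues.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_protein_fasta
#' @param seqs named character vector (or `AAStringSet`).
#' @export
write_protein_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(as_seq_vector(seqs))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read and write gene loci as GFF3-like TSV
#'
#' Nine GFF3 columns, 1-based inclusive coordinates, the gene name carried
#' in the attributes column as `gene=<name>`.
#'
#' @param path TSV file.
#' @return `read_gene_loci()`: a data.frame with columns `gene`, `contig`,
#'   `start`, `end`, `strand`, usable directly by [check_synteny()].
#' @export
read_gene_loci <- function(path) {
  cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "frame", "attributes")
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(df$end < df$start)
  if (length(bad)) {
    stop("end < start at line(s): ", paste(bad + 1L, collapse = ", "))
  }
  gene <- sub(".*gene=([^;]+).*", "\\1", df$attributes)
  data.frame(gene = gene, contig = df$seqid, start = df$start, end = df$end,
             strand = df$strand)
}

#' @rdname read_gene_loci
#' @param loci a data.frame with columns `gene`, `contig`, `start`, `end`
#'   and optionally `strand` (defaults to `+`).
#' @export
write_gene_loci <- function(loci, path) {
  strand <- if (!is.null(loci$strand)) loci$strand else "+"
  df <- data.frame(seqid = loci$contig, source = "ironbudget", type = "gene",
                   start = loci$start, end = loci$end, score = ".",
                   strand = strand, frame = ".",
                   attributes = paste0("gene=", loci$gene))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON report
#'
#' @param x a list (or data.frame) of results.
#' @param path output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for the recognized fields.
#' @return A named list.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the full culture-to-reservoir pipeline
#'
#' For each condition: simulate (or accept) a culture bundle, fit its growth
#' curve, quantify total iron, heme and PPIX, normalize to DNA, and finally
#' extrapolate all conditions to the whole-microbiome reservoir. The two
#' output tables mirror the per-culture measurement table (analyte loads per
#' ug DNA plus the heme share of total iron) and the reservoir table
#' (milligrams of iron and heme-bound iron across the microbiome).
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `conditions` — named list mapping condition labels to true value triples
#'   (`total_iron`, `heme`, `ppix` in pmol per ug DNA); `seed` — base RNG
#'   seed; optional `genome_bp`, `n_cells`, `cell_mass_pg`, `noise_sd_od`,
#'   `noise_rel_signal`, and `out_dir` to write CSV/JSON outputs.
#' @return A list with `measurements` (per-condition analyte table),
#'   `reservoir` (reservoir table), `growth_fits` (per-condition
#'   [fit_gompertz()] parameter summaries) and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(is.list(config), !is.null(config$conditions))
  seed <- as.integer(config$seed %||% 1L)
  cm <- cell_model(genome_bp = config$genome_bp %||% 6.26e6)
  mm <- microbiome_model(n_cells = config$n_cells %||% 3.8e13,
                         cell_mass_pg = config$cell_mass_pg %||% 5,
                         model = cm)

  conds <- config$conditions
  rows <- list()
  fits <- list()
  for (i in seq_along(conds)) {
    label <- names(conds)[i]
    tv <- unlist(conds[[i]])
    cfg <- sim_config(seed = seed + 10L * i,
                      noise_sd_od = config$noise_sd_od %||% 0.01,
                      noise_rel_signal = config$noise_rel_signal %||% 0.01)
    bundle <- sim_culture_dataset(condition = label, true_values = tv,
                                  config = cfg)
    fit <- fit_gompertz(bundle$growth_curve$time_h, bundle$growth_curve$od)
    fits[[label]] <- list(A = fit$params$A, mu_m = fit$params$mu_m,
                          lam = fit$params$lam, ssr = fit$ssr)
    q <- quantify_culture(bundle)
    loads <- stats::setNames(q$pmol_per_ug_dna, q$analyte)
    rows[[label]] <- data.frame(
      condition = label,
      total_fe_pmol_per_ug = loads[["total_iron"]],
      heme_pmol_per_ug = loads[["heme"]],
      ppix_pmol_per_ug = loads[["ppix"]],
      heme_fraction_pct = heme_fraction(min(loads[["heme"]],
                                            loads[["total_iron"]]),
                                        loads[["total_iron"]]))
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  reservoir <- reservoir_table(measurements, mm)

  provenance <- list(seed = seed,
                     genome_bp = cm$genome_bp,
                     n_cells = mm$n_cells,
                     conditions = names(conds),
                     package_version = as.character(
                       utils::packageVersion("ironbudget")),
                     timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(measurements = measurements, reservoir = reservoir,
              growth_fits = fits, provenance = provenance)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measurements,
                     file.path(config$out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(reservoir, file.path(config$out_dir, "reservoir.csv"),
                     row.names = FALSE)
    write_report_json(list(growth_fits = fits, provenance = provenance),
                      file.path(config$out_dir, "run_log.json"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
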