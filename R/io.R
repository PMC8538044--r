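# Readers and writers for the plain-text formats the pipeline consumes:
# long-format count tables, compound metadata, gene models, plate-reader
# exports with a plate layout, and TSV output helpers.

#' Convert doses with explicit units to mol/L
#'
#' @param value Numeric dose values.
#' @param unit Character units, one of `"M"`, `"mM"`, `"uM"`, `"nM"`
#'   (recycled).
#' @return Doses in mol/L.
#' @examples
#' dose_to_molar(c(5, 10), "mM")
#' @export
dose_to_molar <- function(value, unit) {
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  unit <- rep_len(as.character(unit), length(value))
  bad <- !unit %in% names(fac)
  if (any(bad))
    stop("unknown dose unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         call. = FALSE)
  value * unname(fac[unit])
}

#' Write and read tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout the pipeline (tab
#' separated, header, no quoting or row names), so that every writer
#' round-trips through the matching reader.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return `read_tsv_file` returns a data frame; `write_tsv_file` its input,
#'   invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a long-format growth count table
#'
#' Expects tab-separated columns `well_id`, `time_h`, `count`.
#'
#' @param path File path.
#' @return Data frame suitable for [fit_doubling_time()].
#' @export
read_growth_counts <- function(path) {
  df <- read_tsv_file(path)
  .require_columns(df, c("well_id", "time_h", "count"), path)
  df
}

#' Read a compound metadata table
#'
#' Comma-separated with at least `name`, `mw_g_per_mol`, `solvent`,
#' `teratogen_truth`; optional reference-dose columns (e.g.
#' `rat_ld50_mg_per_kg`) are kept as-is.
#'
#' @param path File path.
#' @return Data frame of compound records.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("name", "mw_g_per_mol", "solvent", "teratogen_truth"),
                   path)
  if (any(!is.na(df$mw_g_per_mol) & df$mw_g_per_mol <= 0))
    stop("molecular weights must be > 0 in ", path, call. = FALSE)
  df
}

#' Read a long-format screen count table
#'
#' Tab-separated columns `insertion_id`, `screen`, `replicate`, `round`,
#' `count` (optional `tag`, `unique_mapping`), ready for
#' [normalize_counts()].
#'
#' @param path File path.
#' @return Data frame of raw counts.
#' @export
read_screen_counts <- function(path) {
  df <- read_tsv_file(path)
  .require_columns(df, c("insertion_id", "screen", "replicate", "round",
                         "count"), path)
  df
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read gene models from GFF3 or an equivalent TSV
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `type` with 1-based inclusive coordinates.  Files ending in `.gff`/`.gff3`
#' are parsed with rtracklayer (if installed); gene-level features (types
#' `gene`, `tRNA`, `pseudogene`, `transposable_element`) are kept and the
#' `ID` attribute becomes `gene_id`.  Records without a strand are rejected
#' with a warning; malformed coordinates are an error naming the offending
#' line.
#'
#' @param path File path.
#' @return Data frame of gene models for [annotate_insertions()].
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package; ",
           "alternatively supply the TSV dialect", call. = FALSE)
    gr <- rtracklayer::import(path)
    keep <- as.character(gr$type) %in%
      c("gene", "tRNA", "pseudogene", "transposable_element")
    gr <- gr[keep]
    df <- data.frame(gene_id = as.character(gr$ID),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     type = as.character(gr$type), stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_file(path)
    .require_columns(df, c("gene_id", "chrom", "start", "end", "strand",
                           "type"), path)
    start_n <- suppressWarnings(as.numeric(df$start))
    end_n <- suppressWarnings(as.numeric(df$end))
    bad <- which(is.na(start_n) | is.na(end_n))
    if (length(bad))
      stop("malformed coordinate in ", path, " at data line(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    df$start <- start_n; df$end <- end_n
  }
  no_strand <- is.na(df$strand) | !df$strand %in% c("+", "-")
  if (any(no_strand)) {
    warning(sum(no_strand), " gene record(s) without a strand rejected",
            call. = FALSE)
    df <- df[!no_strand, , drop = FALSE]
  }
  if (any(df$start > df$end))
    stop("gene model with start > end in ", path, call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Read a plate-reader export with a plate layout
#'
#' The export is a wide CSV whose first column is `time_h` and remaining
#' columns are wells.  The layout maps each well to `(compound, dose, unit,
#' reporter, replicate)` and may be a CSV (columns `well, compound, dose,
#' unit, reporter, replicate`, optional `channel`) or a YAML file with one
#' entry per well carrying the same fields.
#'
#' @param path Plate-reader CSV export.
#' @param layout_path Plate-layout CSV or YAML.
#' @return Long data frame `well, compound, dose_molar, reporter,
#'   replicate_id, time_h, fluorescence` ready for [normalize_course()]
#'   after splitting by (compound, dose, reporter).
#' @export
read_plate_reader <- function(path, layout_path) {
  wide <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(wide)[1] != "time_h")
    stop("plate-reader export must have 'time_h' as its first column",
         call. = FALSE)
  if (grepl("\\.ya?ml$", layout_path, ignore.case = TRUE)) {
    lay <- yaml::read_yaml(layout_path)
    layout <- do.call(rbind, lapply(names(lay), function(w) {
      e <- lay[[w]]
      data.frame(well = w, compound = e$compound, dose = e$dose,
                 unit = e$unit, reporter = e$reporter,
                 replicate = e$replicate, stringsAsFactors = FALSE)
    }))
  } else {
    layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
    .require_columns(layout, c("well", "compound", "dose", "unit", "reporter",
                               "replicate"), layout_path)
  }
  wells <- setdiff(names(wide), "time_h")
  miss <- setdiff(wells, layout$well)
  if (length(miss))
    stop("layout does not describe well(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(wells, function(w) {
    L <- layout[layout$well == w, ][1, ]
    data.frame(well = w, compound = L$compound,
               dose_molar = dose_to_molar(L$dose, L$unit),
               reporter = L$reporter,
               replicate_id = sprintf("rep%s", L$replicate),
               time_h = wide$time_h, fluorescence = wide[[w]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
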