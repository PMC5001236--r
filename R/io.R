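FLOWGRAM_COLUMNS <- c("read_id", "flow_index", "nucleotide", "read_position",
                      "voltage")

#' Read and write flowgram TSV
#'
#' The flowgram dialect is the package's plain-text stand-in for binary SFF:
#' a header line `read_id  flow_index  nucleotide  read_position  voltage`,
#' UTF-8, tab-separated, `.` decimal separator, one row per flow.
#' `read_position` is the 1-based base offset of the flow's homopolymer start
#' within the read. Voltages are serialized at 6-decimal fixed precision
#' (far below the smallest modelled stdev of 0.14, so nothing relevant to
#' calling is lost), which keeps writes byte-deterministic.
#'
#' @param path File path.
#' @param rows Tibble with the flowgram columns (extra columns are dropped on
#'   write).
#' @return `read_flowgram_tsv()`: tibble of flows; `write_flowgram_tsv()`:
#'   `path`, invisibly.
#' @export
read_flowgram_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("flowgram file not found: %s", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, FLOWGRAM_COLUMNS)) {
    abort(sprintf(
      "flowgram header mismatch: expected '%s', found '%s'",
      paste(FLOWGRAM_COLUMNS, collapse = "\t"),
      paste(header, collapse = "\t")
    ))
  }
  rows <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      flow_index = readr::col_integer(),
      nucleotide = readr::col_character(),
      read_position = readr::col_integer(),
      voltage = readr::col_double()
    ),
    progress = FALSE
  )
  bad <- which(
    !rows$nucleotide %in% NUCLEOTIDES |
      is.na(rows$read_position) | rows$read_position < 1 |
      is.na(rows$voltage) | rows$voltage < 0
  )
  if (length(bad) > 0) {
    abort(sprintf("malformed flowgram row(s) at line(s) %s of %s",
                  paste(head(bad + 1L, 5), collapse = ", "), path))
  }
  rows
}

#' @rdname read_flowgram_tsv
#' @export
write_flowgram_tsv <- function(rows, path) {
  rows <- as_tibble(rows)
  assert_columns(rows, FLOWGRAM_COLUMNS, "flowgram")
  out <- rows[, FLOWGRAM_COLUMNS]
  out$voltage <- sprintf("%.6f", out$voltage)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write ground-truth / calls TSV
#'
#' Plain TSV companions to the flowgram dialect. The calls layout has the
#' fixed column order `read_id`, `flow_index`, `nucleotide`, `zone`,
#' `voltage`, `ref_length`, `method`, `called_length`, `posterior_max`,
#' `score_max`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_calls_tsv <- function(x, path) {
  cols <- c("read_id", "flow_index", "nucleotide", "zone", "voltage",
            "ref_length", "method", "called_length", "posterior_max",
            "score_max")
  x <- as_tibble(x)
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  out <- x[, cols]
  out$voltage <- sprintf("%.6f", out$voltage)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname write_calls_tsv
#' @export
write_truth_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings with the package's conventions: sequences
#' are uppercased on read, validated to the A/C/G/T/N alphabet, and written
#' wrapped at 80 columns.
#'
#' @param path File path.
#' @param records Tibble with `read_id` (or `name`) and `sequence`, or a
#'   named character vector.
#' @return `read_fasta()`: tibble (`read_id`, `sequence`);
#'   `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() requires the Biostrings package")
  }
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  out <- tibble(
    read_id = names(seqs),
    sequence = unname(toupper(as.character(seqs)))
  )
  bad <- stringr::str_locate(out$sequence, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "non-ACGTN character in record '%s' at position %d",
      out$read_id[i], bad[i]
    ))
  }
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("write_fasta() requires the Biostrings package")
  }
  if (is.character(records)) {
    records <- tibble(read_id = names(records), sequence = unname(records))
  }
  records <- as_tibble(records)
  if (!"read_id" %in% names(records) && "name" %in% names(records)) {
    records <- dplyr::rename(records, read_id = "name")
  }
  assert_columns(records, c("read_id", "sequence"), "`records`")
  seqs <- Biostrings::DNAStringSet(toupper(records$sequence))
  names(seqs) <- records$read_id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Run configurations drive the command-line pipeline: zone `profile`
#' (torrent/proton/custom), `length_range`, `penalties`
#' (match/substitution/indel), `weight` or a `grid` specification, `seed`,
#' and a `paths` map. YAML (`.yaml`/`.yml`) and JSON are accepted. The
#' configuration is validated before any stage runs.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return Validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs require the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$profile <- cfg$profile %||% "torrent"
  if (!cfg$profile %in% c("torrent", "proton", "custom")) {
    abort("config `profile` must be torrent, proton or custom")
  }
  cfg$length_range <- as.integer(cfg$length_range %||% c(2L, 6L))
  if (length(cfg$length_range) != 2 ||
      cfg$length_range[1] > cfg$length_range[2]) {
    abort("config `length_range` must be an inclusive [min, max] pair")
  }
  if (!is.null(cfg$weight) && (cfg$weight < 0 || cfg$weight > 1)) {
    abort("config `weight` must lie in [0, 1]")
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  pen <- cfg$penalties %||% list(match = 0, substitution = -1, indel = -2)
  cfg$penalties <- penalty_scheme(pen$match, pen$substitution, pen$indel)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
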