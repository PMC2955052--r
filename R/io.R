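# Readers and writers for the formats the pipeline consumes and emits:
# protein/nucleotide FASTA, aligned FASTA / Clustal, probe tables,
# expanded-probe FASTA, array feature tables (plain TSV or a
# NimbleGen-style .pair layout) and flat key=value configuration files.

#' Read a protein FASTA file
#'
#' @param path FASTA path.
#' @return Tibble with `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) abort(sprintf("no records in '%s'", path))
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Read a nucleotide FASTA file
#'
#' @param path FASTA path.
#' @return Tibble with `id`, `seq`.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) abort(sprintf("no records in '%s'", path))
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Read a protein multiple alignment
#'
#' @param path Alignment path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return Tibble with `id`, `seq` (gapped, equal lengths).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  x <- as.character(aln)
  if (length(x) == 0L) abort(sprintf("no records in alignment '%s'", path))
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(x))
}

#' Write sequences as FASTA
#'
#' Sequences may contain inosine and IUPAC codes, so records are written
#' over the unrestricted string alphabet.
#'
#' @param tbl Tibble with an id column and a sequence column.
#' @param path Output path.
#' @param id_col,seq_col Column names (defaults `id`, `seq`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, id_col = "id", seq_col = "seq") {
  stopifnot(is.data.frame(tbl), all(c(id_col, seq_col) %in% names(tbl)))
  x <- Biostrings::BStringSet(tbl[[seq_col]])
  names(x) <- tbl[[id_col]]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a probe candidate table as TSV
#'
#' @param candidates Candidate tibble (see [enumerate_probes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(candidates, path) {
  readr::write_tsv(candidates, path)
  invisible(path)
}

#' Read an array feature table
#'
#' Expects the tab-separated layout `probe_id, x, y, intensity,
#' probe_class, replicate`; `probe_class` must be `target` or `random`.
#'
#' @param path TSV path.
#' @return Feature tibble.
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           probe_id = readr::col_character(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           intensity = readr::col_double(),
                           probe_class = readr::col_character(),
                           replicate = readr::col_integer()))
  bad <- which(!out$probe_class %in% c("target", "random"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown probe_class '%s' at row %d of '%s'",
                  out$probe_class[[bad[[1]]]], bad[[1]], path))
  }
  out
}

#' Read a NimbleGen-style .pair feature report
#'
#' Accepts the documented tab-separated .pair column layout (comment
#' lines starting with `#`; columns including `PROBE_ID`, `X`, `Y` and
#' `PM`). Intensity is taken from `PM`; probes whose id matches
#' `random_pattern` are classed `random`, the rest `target`; replicate
#' indices are assigned per probe in file order.
#'
#' @param path .pair path.
#' @param random_pattern Regular expression identifying random control
#'   probes (default `"^RAND"`).
#' @return Feature tibble as in [read_feature_table()].
#' @export
read_pair <- function(path, random_pattern = "^RAND") {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("PROBE_ID", "X", "Y", "PM")
  if (!all(need %in% names(out))) {
    abort(sprintf("'%s' lacks .pair columns: %s", path,
                  paste(setdiff(need, names(out)), collapse = ", ")))
  }
  out |>
    dplyr::transmute(
      probe_id = .data$PROBE_ID,
      x = as.numeric(.data$X), y = as.numeric(.data$Y),
      intensity = as.numeric(.data$PM),
      probe_class = ifelse(grepl(random_pattern, .data$PROBE_ID),
                           "random", "target")) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values parseable as numbers become numeric, `true`/`false`
#' become logical.
#'
#' @param path Config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([^=]+)=(.*)$")
  if (anyNA(kv[, 1])) {
    abort(sprintf("malformed config line: '%s'",
                  lines[which(is.na(kv[, 1]))[[1]]]))
  }
  keys <- trimws(kv[, 2])
  vals <- lapply(trimws(kv[, 3]), function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, keys)
}

#' Write a flat key=value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v)) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}
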