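#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings handling multi-record, line-wrapped
#' FASTA.
#'
#' @param path File path.
#' @param proteins Named character vector of sequences.
#' @param width Line width when writing.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  x <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a site annotation table (TSV)
#'
#' Expects a header with at least `protein_id`, `position`, `residue`;
#' extra columns (e.g. `family`, `cluster`) are preserved.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_site_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("protein_id", "position", "residue")
  if (!all(required %in% names(out))) {
    abort("site table needs columns protein_id, position, residue.")
  }
  out$position <- as.integer(out$position)
  out
}

#' Read / write a benchmark as TSV
#'
#' The TSV carries the five benchmark columns plus a `# key: value`
#' comment header recording the window geometry and central classes, so a
#' round trip restores the `pbs_benchmark` attributes.
#'
#' @param benchmark A `pbs_benchmark`.
#' @param path File path.
#' @return `read_benchmark()` returns a `pbs_benchmark`;
#'   `write_benchmark()` returns `path` invisibly.
#' @export
write_benchmark <- function(benchmark, path) {
  at <- benchmark_attrs(benchmark)
  hdr <- c(sprintf("# m: %d", at$m), sprintf("# n: %d", at$n),
           sprintf("# center_classes: %s",
                   paste(at$center_classes, collapse = ",")))
  writeLines(hdr, path)
  suppressWarnings(
    readr::write_tsv(as_tibble(benchmark), path, append = TRUE,
                     col_names = TRUE))
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  new_pbs_benchmark(tbl, node = NULL,
                    m = as.integer(get("m")), n = as.integer(get("n")),
                    center_classes = strsplit(get("center_classes"),
                                              ",")[[1]])
}

#' Write optimized position weights as TSV
#'
#' Columns: `position` (1-based index in the window), `offset` (from the
#' central residue) and `weight`.
#'
#' @param fit A `pwd_fit` (or bare weight vector named by offsets).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_position_weights <- function(fit, path) {
  tbl <- if (inherits(fit, "pwd_fit")) tidy(fit) else {
    tibble(position = seq_along(fit),
           offset = as.integer(names(fit)), weight = unname(fit))
  }
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read / write a threshold table as JSON
#'
#' @param table A `threshold_table`.
#' @param path File path.
#' @return `read_threshold_table()` returns a `threshold_table`;
#'   the writer returns `path` invisibly.
#' @export
write_threshold_table <- function(table, path) {
  payload <- list(
    group = attr(table, "group"),
    background_size = attr(table, "background_size"),
    repeats = attr(table, "repeats"),
    seed = attr(table, "seed"),
    levels = as_tibble(table))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(payload$levels)
  attr(out, "group") <- payload$group
  attr(out, "background_size") <- as.integer(payload$background_size)
  attr(out, "repeats") <- as.integer(payload$repeats)
  attr(out, "seed") <- as.integer(payload$seed)
  class(out) <- c("threshold_table", class(out))
  out
}

#' Write scan predictions as TSV
#'
#' @param predictions Tibble from [scan_fasta()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path, progress = FALSE)
  invisible(path)
}
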