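# 21-letter pseudo-amino-acid alphabet: the 20 standard residues in
# alphabetical order followed by the terminal padding symbol "*".
PBP_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*"
)
PBP_PAD <- 21L
PBP_STANDARD <- PBP_ALPHABET[1:20]

#' The 21-letter peptide alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order, followed by
#' `"*"`, the padding symbol used where a peptide window overruns a protein
#' terminus. All scoring machinery in the package operates over this alphabet.
#'
#' @return A character vector of length 21.
#' @export
#' @examples
#' pbp_alphabet()
pbp_alphabet <- function() PBP_ALPHABET

#' BLOSUM62 over the 21-letter peptide alphabet
#'
#' The standard BLOSUM62 substitution matrix restricted and reordered to the
#' 21 symbols of [pbp_alphabet()]. The `"*"` row/column follows the
#' conventional extension: +1 on the diagonal and -4 against every residue.
#' Any symmetric 21x21 matrix with this alphabet can be supplied wherever a
#' `matrix` argument is accepted, e.g. one read with
#' [read_substitution_matrix()].
#'
#' @return A symmetric 21x21 integer matrix with dimnames equal to
#'   [pbp_alphabet()].
#' @export
#' @examples
#' m <- blosum62_21()
#' m["S", "T"]
blosum62_21 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[PBP_ALPHABET, PBP_ALPHABET]
  storage.mode(m) <- "double"
  m
}

check_substitution_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(21L, 21L))) {
    abort("`matrix` must be a 21 x 21 substitution matrix.")
  }
  if (!identical(rownames(matrix), PBP_ALPHABET) ||
      !identical(colnames(matrix), PBP_ALPHABET)) {
    abort("`matrix` dimnames must equal pbp_alphabet() in order.")
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    abort("substitution matrix must be symmetric.")
  }
  invisible(matrix)
}

#' Read / write a substitution matrix in NCBI text format
#'
#' The NCBI matrix format is whitespace-separated: an optional run of `#`
#' comment lines, a header row of symbols, then one row per symbol beginning
#' with the symbol itself. Symbols outside the 21-letter alphabet (B, Z, X,
#' J) are dropped on read; the matrix is reordered to [pbp_alphabet()].
#'
#' @param path File path.
#' @param matrix A 21x21 substitution matrix as from [blosum62_21()].
#' @return `read_substitution_matrix()` returns a 21x21 numeric matrix;
#'   `write_substitution_matrix()` returns `path` invisibly.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  body <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  syms <- vapply(body, `[`, character(1), 1L)
  vals <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  dimnames(vals) <- list(syms, header)
  missing <- setdiff(PBP_ALPHABET, intersect(syms, header))
  if (length(missing)) {
    abort(paste0("matrix file lacks required symbols: ",
                 paste(missing, collapse = ", ")))
  }
  m <- vals[PBP_ALPHABET, PBP_ALPHABET]
  check_substitution_matrix(m)
  m
}

#' @rdname read_substitution_matrix
#' @export
write_substitution_matrix <- function(matrix, path) {
  check_substitution_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(" ", PBP_ALPHABET), collapse = " "), con)
  for (i in seq_len(21)) {
    writeLines(paste(c(PBP_ALPHABET[i], format(matrix[i, ], trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

# Encode peptides (equal-length character vector) as an n x K integer matrix
# of alphabet indices. Non-standard residue letters (U, B, Z, X, J, O) map to
# the padding index so the alphabet stays at 21 symbols.
peptide_codes <- function(peptides) {
  k <- unique(nchar(peptides))
  if (length(k) != 1L) {
    abort("all peptides must have the same length.")
  }
  chars <- strsplit(peptides, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  codes <- match(flat, PBP_ALPHABET)
  bad <- is.na(codes)
  if (any(bad)) {
    nonletter <- !grepl("^[A-Za-z]$", flat[bad])
    if (any(nonletter)) {
      abort(paste0("invalid peptide character(s): ",
                   paste(unique(flat[bad][nonletter]), collapse = ", ")))
    }
    codes[bad] <- PBP_PAD
  }
  matrix(codes, nrow = length(peptides), ncol = k, byrow = TRUE)
}
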