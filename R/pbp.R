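#' Extract a padded peptide window around a candidate site
#'
#' A PBP(m, n) window is the central S/T/Y residue flanked by `m` residues
#' upstream and `n` downstream; where the window overruns a protein terminus
#' it is padded with `"*"`. Non-standard residue letters (U, B, Z, X, ...)
#' in the source sequence are mapped to `"*"` so that the window stays on the
#' 21-letter alphabet. Positions are 1-based, following UniProt convention.
#'
#' @param sequence A single protein sequence string.
#' @param position 1-based position of the central residue.
#' @param m,n Number of upstream / downstream flanking residues
#'   (default 10 and 10, giving a 21-mer).
#' @param center_classes Optional character vector of allowed central
#'   residues (subset of S, T, Y); if supplied, a central residue outside
#'   this set is an error.
#' @param protein_id Optional identifier carried into the output.
#' @return A one-row tibble with columns `protein_id`, `position`,
#'   `residue`, `peptide`.
#' @export
#' @examples
#' extract_pbp("MSK", 2, m = 2, n = 2)$peptide  # "*MSK*"
extract_pbp <- function(sequence, position, m = 10, n = 10,
                        center_classes = NULL, protein_id = NA_character_) {
  stopifnot(length(sequence) == 1L, length(position) == 1L)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (position < 1 || position > len) {
    abort(sprintf("position %d is outside sequence of length %d.",
                  as.integer(position), len))
  }
  residue <- substr(sequence, position, position)
  if (!is.null(center_classes) && !(residue %in% toupper(center_classes))) {
    abort(sprintf(
      "central residue '%s' at position %d is not one of {%s}.",
      residue, as.integer(position),
      paste(toupper(center_classes), collapse = ", ")))
  }
  tibble(
    protein_id = protein_id,
    position = as.integer(position),
    residue = residue,
    peptide = pbp_window_strings(sequence, position, m, n)
  )
}

# Vectorized window extraction over positions of one sequence.
pbp_window_strings <- function(sequence, positions, m, n) {
  stopifnot(m >= 0, n >= 0)
  padded <- paste0(strrep("*", m), sequence, strrep("*", n))
  win <- substring(padded, positions, positions + m + n)
  # non-standard letters collapse onto the padding symbol
  gsub("[^ACDEFGHIKLMNPQRSTVWY*]", "*", win)
}

#' All candidate site windows of a protein
#'
#' Enumerates every position whose residue belongs to `center_classes` and
#' extracts its PBP(m, n) window.
#'
#' @inheritParams extract_pbp
#' @return A tibble with one row per candidate site (possibly zero rows).
#' @export
pbp_windows <- function(sequence, m = 10, n = 10,
                        center_classes = c("S", "T", "Y"),
                        protein_id = NA_character_) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars %in% toupper(center_classes))
  tibble(
    protein_id = protein_id,
    position = as.integer(pos),
    residue = chars[pos],
    peptide = if (length(pos)) pbp_window_strings(sequence, pos, m, n)
              else character(0)
  )
}

#' Nodes of the binding-domain hierarchy
#'
#' Predictors are organised in a three-level hierarchy: two groups (pS/pT
#' and pY, by the phosphoresidue the domain reads), families within a group,
#' and single-domain clusters within a family. A group node fixes the
#' central residue classes (S and T for pS/pT; Y for pY); families and
#' clusters inherit them from their parent.
#'
#' @param name Node name, e.g. `"pS/pT"`, `"14-3-3"`, `"YWHAZ"`.
#' @param level One of `"group"`, `"family"`, `"cluster"`.
#' @param parent Parent `hierarchy_node` (required for families and
#'   clusters).
#' @param center_classes For group nodes without a recognisable name, the
#'   allowed central residues (subset of S, T, Y).
#' @return An object of class `hierarchy_node`.
#' @export
#' @examples
#' fam <- hierarchy_node("14-3-3", "family", parent = hierarchy_node("pS/pT", "group"))
#' fam$center_classes
hierarchy_node <- function(name, level = c("group", "family", "cluster"),
                           parent = NULL, center_classes = NULL) {
  level <- match.arg(level)
  if (level == "group") {
    if (is.null(center_classes)) {
      center_classes <- switch(name,
        "pS/pT" = c("S", "T"),
        "pY" = "Y",
        abort("supply `center_classes` for a group node with a custom name."))
    }
  } else {
    if (is.null(parent) || !inherits(parent, "hierarchy_node")) {
      abort(sprintf("a %s node requires a `parent` hierarchy_node.", level))
    }
    expected_parent <- if (level == "family") "group" else "family"
    if (parent$level != expected_parent) {
      abort(sprintf("parent of a %s node must be a %s node.",
                    level, expected_parent))
    }
    center_classes <- parent$center_classes
  }
  center_classes <- toupper(center_classes)
  if (!all(center_classes %in% c("S", "T", "Y"))) {
    abort("center_classes must be a subset of S, T, Y.")
  }
  structure(
    list(name = name, level = level, parent = parent,
         center_classes = center_classes),
    class = "hierarchy_node"
  )
}

#' @export
print.hierarchy_node <- function(x, ...) {
  chain <- x$name
  p <- x$parent
  while (!is.null(p)) {
    chain <- c(p$name, chain)
    p <- p$parent
  }
  cat(sprintf("<hierarchy_node> %s (%s; centers %s)\n",
              paste(chain, collapse = " > "), x$level,
              paste(x$center_classes, collapse = "/")))
  invisible(x)
}

#' Group of a hierarchy node
#'
#' @param node A `hierarchy_node`.
#' @return `"pS/pT"`-style group decision as `"ST"` or `"Y"` based on the
#'   node's central residue classes.
#' @keywords internal
node_group <- function(node) {
  if (identical(node$center_classes, "Y")) "pY" else "pS/pT"
}

as_protein_set <- function(proteins) {
  if (inherits(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  if (is.character(proteins) && length(proteins) == 1L &&
      is.null(names(proteins)) && file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  if (!is.character(proteins) || is.null(names(proteins)) ||
      any(!nzchar(names(proteins)))) {
    abort("`proteins` must be a named character vector, AAStringSet, or FASTA path.")
  }
  toupper(proteins)
}

#' Build a labeled benchmark of positive and negative site windows
#'
#' Positive windows are extracted around each annotated site; negative
#' windows are taken from every other residue of the allowed central classes
#' in the same proteins. Both sets are de-duplicated at the peptide-string
#' level (first occurrence in input order wins) and any negative peptide
#' identical to a positive peptide is removed, so the two classes are
#' disjoint by construction.
#'
#' @param proteins Named character vector of sequences, an `AAStringSet`,
#'   or a FASTA file path.
#' @param sites Data frame of positive sites with columns `protein_id`,
#'   `position` (1-based) and `residue`; each must match the sequence.
#' @param node Optional [hierarchy_node()] the benchmark belongs to; its
#'   central residue classes define the negative universe.
#' @param m,n Window flanks (default 10/10).
#' @param center_classes Allowed central residues; defaults to the node's
#'   classes, or to the residues present in `sites`.
#' @param negative_proteins Optional alternative protein set from which
#'   negatives are drawn; defaults to the proteins carrying positives.
#' @return A `pbs_benchmark`: a tibble with columns `protein_id`,
#'   `position`, `residue`, `peptide`, `label` and attributes `node`, `m`,
#'   `n`, `center_classes`.
#' @export
build_benchmark <- function(proteins, sites, node = NULL, m = 10, n = 10,
                            center_classes = NULL,
                            negative_proteins = NULL) {
  proteins <- as_protein_set(proteins)
  sites <- as_tibble(sites)
  required <- c("protein_id", "position", "residue")
  if (!all(required %in% names(sites))) {
    abort("`sites` needs columns protein_id, position, residue.")
  }
  if (nrow(sites) == 0L) abort("no positive sites supplied.")
  center_classes <- toupper(
    center_classes %||% (if (!is.null(node)) node$center_classes
                         else sort(unique(toupper(sites$residue)))))

  # validate every site against its sequence
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    if (!pid %in% names(proteins)) {
      abort(sprintf("site %s:%d refers to an unknown protein.", pid, pos))
    }
    seq_i <- proteins[[pid]]
    if (pos < 1 || pos > nchar(seq_i)) {
      abort(sprintf("site %s:%d is outside the sequence (length %d).",
                    pid, pos, nchar(seq_i)))
    }
    found <- substr(seq_i, pos, pos)
    if (found != toupper(sites$residue[i])) {
      abort(sprintf("site %s:%d expects residue %s but sequence has %s.",
                    pid, pos, toupper(sites$residue[i]), found))
    }
  }

  positives <- purrr::pmap_dfr(
    list(sites$protein_id, sites$position),
    function(pid, pos) extract_pbp(proteins[[pid]], pos, m = m, n = n,
                                   protein_id = pid)
  )
  positives <- distinct(positives, .data$peptide, .keep_all = TRUE)

  neg_prot <- if (is.null(negative_proteins)) {
    proteins[unique(sites$protein_id)]
  } else {
    as_protein_set(negative_proteins)
  }
  pos_keys <- paste(sites$protein_id, sites$position)
  negatives <- purrr::imap_dfr(neg_prot, function(seq_i, pid) {
    pbp_windows(seq_i, m = m, n = n, center_classes = center_classes,
                protein_id = pid)
  })
  negatives <- filter(negatives,
                      !paste(.data$protein_id, .data$position) %in% pos_keys)
  negatives <- distinct(negatives, .data$peptide, .keep_all = TRUE)
  negatives <- filter(negatives, !.data$peptide %in% positives$peptide)

  new_pbs_benchmark(
    bind_rows(mutate(positives, label = "positive"),
              mutate(negatives, label = "negative")),
    node = node, m = m, n = n, center_classes = center_classes
  )
}

new_pbs_benchmark <- function(tbl, node, m, n, center_classes) {
  out <- as_tibble(tbl)
  attr(out, "node") <- node
  attr(out, "m") <- as.integer(m)
  attr(out, "n") <- as.integer(n)
  attr(out, "center_classes") <- center_classes
  class(out) <- c("pbs_benchmark", class(out))
  out
}

#' Positive / negative peptides of a benchmark
#'
#' @param benchmark A `pbs_benchmark`.
#' @return Character vector of peptide strings.
#' @export
benchmark_positives <- function(benchmark) {
  benchmark$peptide[benchmark$label == "positive"]
}

#' @rdname benchmark_positives
#' @export
benchmark_negatives <- function(benchmark) {
  benchmark$peptide[benchmark$label == "negative"]
}

benchmark_labels <- function(benchmark) {
  as.integer(benchmark$label == "positive")
}

benchmark_attrs <- function(benchmark) {
  list(node = attr(benchmark, "node"), m = attr(benchmark, "m"),
       n = attr(benchmark, "n"),
       center_classes = attr(benchmark, "center_classes"))
}

#' @export
print.pbs_benchmark <- function(x, ...) {
  at <- benchmark_attrs(x)
  cat(sprintf(
    "<pbs_benchmark> %d positives, %d negatives; PBP(%d, %d); centers %s\n",
    sum(x$label == "positive"), sum(x$label == "negative"),
    at$m, at$n, paste(at$center_classes, collapse = "/")))
  NextMethod()
}
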