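#' Specify a position-specific binding motif
#'
#' A motif is a central phosphoacceptor class plus a set of position
#' constraints: at offset `o` from the central residue, a positive peptide
#' carries a residue from `residues` with probability `q` (the adherence)
#' and a background draw otherwise. Unconstrained positions and all
#' negative peptides draw from `background`. This mirrors the structure of
#' real binding motifs such as the 14-3-3 family's RxRSxpSxP-like pattern
#' or the SH2-family YxN / YxxM patterns.
#'
#' @param name Motif name.
#' @param center_class Central residue, one of `"S"`, `"T"`, `"Y"`.
#' @param constraints Data frame with columns `offset` (integer, nonzero),
#'   `residues` (string of allowed one-letter residues), `q` (adherence
#'   probability in \[0, 1\]).
#' @param background Length-20 probability vector over the standard
#'   residues (alphabetical order); default uniform, which keeps analytic
#'   expectations exact in tests. A proteome-like preset is available via
#'   `background = "proteome"`.
#' @return An object of class `motif_spec`.
#' @export
#' @examples
#' motif_spec("toy", "S", data.frame(offset = -3, residues = "R", q = 0.9))
motif_spec <- function(name, center_class, constraints = NULL,
                       background = NULL) {
  center_class <- toupper(center_class)
  if (!center_class %in% c("S", "T", "Y")) {
    abort("center_class must be S, T or Y.")
  }
  if (is.null(constraints)) {
    constraints <- tibble(offset = integer(), residues = character(),
                          q = double())
  }
  constraints <- as_tibble(constraints)
  stopifnot(all(c("offset", "residues", "q") %in% names(constraints)))
  if (any(constraints$offset == 0L)) {
    abort("constraint offsets must be nonzero (the center is fixed).")
  }
  if (any(constraints$q < 0 | constraints$q > 1)) {
    abort("adherence q must lie in [0, 1].")
  }
  bad <- constraints$q > 0 &
    (!nzchar(constraints$residues) |
       !vapply(strsplit(toupper(constraints$residues), ""),
               function(ch) all(ch %in% PBP_STANDARD), logical(1)))
  if (any(bad)) {
    abort("each constraint with q > 0 needs a nonempty set of standard residues.")
  }
  if (identical(background, "proteome")) {
    background <- proteome_frequencies()
  }
  background <- background %||% rep(1 / 20, 20)
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-8) {
    abort("background must be 20 probabilities summing to 1.")
  }
  structure(list(name = name, center_class = center_class,
                 constraints = constraints,
                 background = setNames(as.numeric(background),
                                       PBP_STANDARD)),
            class = "motif_spec")
}

# Approximate vertebrate proteome residue frequencies (alphabetical).
proteome_frequencies <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f / sum(f)
}

#' Preset motif specifications
#'
#' Ready-made motifs used throughout the tests and examples:
#' `"14-3-3"`, an RxRSxpSxP-like pS motif (R at -5/-3, S at -2, P at +2);
#' `"sh2-yxn"` and `"sh2-yxxm"`, pY motifs with N at +2 or M at +3;
#' `"separable-family"`, a five-constraint pS motif at 0.95 adherence —
#' the well-separated family benchmark used for end-to-end pipeline and
#' calibration experiments; and `"null-st"` / `"null-y"`, unconstrained
#' backgrounds for null experiments.
#'
#' @param name Preset name.
#' @return A [motif_spec()].
#' @export
motif_preset <- function(name = c("14-3-3", "sh2-yxn", "sh2-yxxm",
                                  "separable-family", "null-st",
                                  "null-y")) {
  name <- match.arg(name)
  switch(name,
    "separable-family" = motif_spec("separable-family", "S", tibble(
      offset = c(-5L, -3L, -2L, 2L, 4L),
      residues = c("R", "R", "S", "P", "L"),
      q = 0.95)),
    "14-3-3" = motif_spec("14-3-3-like", "S", tibble(
      offset = c(-5L, -3L, -2L, 2L),
      residues = c("R", "R", "S", "P"),
      q = c(0.7, 0.9, 0.6, 0.8))),
    "sh2-yxn" = motif_spec("SH2-YxN-like", "Y", tibble(
      offset = c(2L, 3L),
      residues = c("N", "ILVPM"),
      q = c(0.9, 0.7))),
    "sh2-yxxm" = motif_spec("SH2-YxxM-like", "Y", tibble(
      offset = 3L, residues = "M", q = 0.9)),
    "null-st" = motif_spec("null-ST", "S"),
    "null-y" = motif_spec("null-Y", "Y"))
}

#' Derive a child motif by adding constraints
#'
#' Emulates the group/family/cluster hierarchy: a child motif keeps every
#' parental constraint and adds its own, so child constraint sets are
#' supersets of the parent's.
#'
#' @param spec Parent [motif_spec()].
#' @param constraints Additional constraint rows.
#' @param name Child name (default parent name + "+").
#' @return A [motif_spec()].
#' @export
motif_extend <- function(spec, constraints, name = NULL) {
  stopifnot(inherits(spec, "motif_spec"))
  motif_spec(name %||% paste0(spec$name, "+"), spec$center_class,
             bind_rows(spec$constraints, as_tibble(constraints)),
             background = spec$background)
}

# Sample n motif-governed peptide windows (positives) or pure background
# windows (negatives) as residue matrices collapsed to strings.
sample_windows <- function(spec, n, m, win_n, positive = TRUE) {
  k <- m + 1L + win_n
  if (n == 0L) return(character(0))
  mat <- matrix(sample(PBP_STANDARD, n * k, replace = TRUE,
                       prob = spec$background),
                nrow = n, ncol = k)
  mat[, m + 1L] <- spec$center_class
  if (positive && nrow(spec$constraints)) {
    for (i in seq_len(nrow(spec$constraints))) {
      off <- spec$constraints$offset[i]
      col <- off + m + 1L
      if (col < 1L || col > k) next
      set <- strsplit(toupper(spec$constraints$residues[i]), "")[[1]]
      adhere <- runif(n) < spec$constraints$q[i]
      if (any(adhere)) {
        mat[adhere, col] <- sample(set, sum(adhere), replace = TRUE)
      }
    }
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Generate a seeded motif-structured benchmark
#'
#' Positives follow the motif's constraints; negatives are pure background
#' windows with the same central residue. Both sets are de-duplicated and
#' negatives identical to a positive are dropped, so the generator may
#' return slightly fewer peptides than requested; actual counts are what
#' the benchmark reports (no resampling, so seeds stay meaningful).
#' `neg_ratio` controls the class imbalance, covering the 4.3-204.3 range
#' seen in real binding-site benchmarks.
#'
#' @param spec A [motif_spec()].
#' @param n_pos Positives to draw (>= 1).
#' @param neg_ratio Negative:positive ratio (> 0).
#' @param m,n Window flanks (default 10/10).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A `pbs_benchmark` tibble.
#' @export
generate_benchmark <- function(spec, n_pos, neg_ratio = 10, m = 10,
                               n = 10, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"), n_pos >= 1, neg_ratio > 0)
  n_neg <- round(n_pos * neg_ratio)
  withr::with_seed(seed, {
    pos <- sample_windows(spec, n_pos, m, n, positive = TRUE)
    neg <- sample_windows(spec, n_neg, m, n, positive = FALSE)
  })
  pos <- pos[!duplicated(pos)]
  neg <- neg[!duplicated(neg)]
  neg <- neg[!neg %in% pos]
  classes <- if (spec$center_class %in% c("S", "T")) c("S", "T") else "Y"
  tbl <- tibble(
    protein_id = sprintf("syn%05d", seq_len(length(pos) + length(neg))),
    position = m + 1L,
    residue = spec$center_class,
    peptide = c(pos, neg),
    label = rep(c("positive", "negative"), c(length(pos), length(neg)))
  )
  new_pbs_benchmark(tbl, node = NULL, m = m, n = n,
                    center_classes = classes)
}

#' Generate a synthetic proteome with planted motif sites
#'
#' Proteins are drawn residue-by-residue from the background composition;
#' motif instances are planted at recorded positions (whole windows
#' overwrite the background, away from the termini so no padding is
#' involved) and returned in a truth table for recovery scoring.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of protein lengths (uniform).
#' @param planted List of `list(spec = motif_spec, count = integer)`
#'   entries.
#' @param m,n Window flanks used when planting.
#' @param seed Integer seed; same seed, same FASTA bytes.
#' @param background Length-20 residue probability vector (default
#'   uniform).
#' @return A list with `proteins` (named character vector) and `truth`
#'   (tibble `protein_id`, `position`, `residue`, `motif`).
#' @export
generate_proteome <- function(n_proteins = 50,
                              length_range = c(300L, 600L),
                              planted = list(), m = 10, n = 10,
                              seed = 1L, background = NULL) {
  background <- background %||% rep(1 / 20, 20)
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    proteins <- vapply(lens, function(len) {
      paste(sample(PBP_STANDARD, len, replace = TRUE, prob = background),
            collapse = "")
    }, character(1))
    names(proteins) <- sprintf("SYNPROT%04d", seq_len(n_proteins))

    truth <- list()
    used <- list()
    for (pl in planted) {
      spec <- pl$spec
      count <- pl$count
      total_slots <- sum(pmax(lens - (m + n), 0L))
      if (count > total_slots) abort("not enough room to plant all sites.")
      placed <- 0L
      guard <- 0L
      while (placed < count) {
        guard <- guard + 1L
        if (guard > 50L * count) abort("failed to place motif sites without collision.")
        p <- sample.int(n_proteins, 1L)
        if (lens[p] < m + n + 1L) next
        pos <- sample((m + 1L):(lens[p] - n), 1L)
        key <- names(proteins)[p]
        span <- (pos - m):(pos + n)
        if (any(span %in% used[[key]])) next
        win <- sample_windows(spec, 1L, m, n, positive = TRUE)
        substr(proteins[p], pos - m, pos + n) <- win
        used[[key]] <- c(used[[key]], span)
        placed <- placed + 1L
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = key, position = as.integer(pos),
          residue = spec$center_class, motif = spec$name)
      }
    }
  })
  truth <- if (length(truth)) arrange(bind_rows(truth), .data$protein_id,
                                      .data$position)
           else tibble(protein_id = character(), position = integer(),
                       residue = character(), motif = character())
  list(proteins = proteins, truth = truth)
}
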