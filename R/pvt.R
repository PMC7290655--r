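#' The 231 unordered residue-pair labels
#'
#' Over the alphabetically ordered 21-letter alphabet (padding symbol last)
#' there are 21 * 22 / 2 = 231 unordered symbol pairs; `(a, b)` and
#' `(b, a)` share one slot. The ordering is lexicographic on the sorted
#' pair: AA, AC, AD, ..., AY, A*, CC, CD, ..., YY, Y*, **.
#'
#' @return A character vector of length 231 of two-symbol labels.
#' @export
#' @examples
#' length(pvt_pairs())  # 231
pvt_pairs <- function() {
  unlist(lapply(seq_len(21), function(i) {
    paste0(PBP_ALPHABET[i], PBP_ALPHABET[i:21])
  }), use.names = FALSE)
}

# 21 x 21 lookup: symbol-code pair -> index into pvt_pairs().
pair_index_matrix <- function() {
  idx <- matrix(0L, 21, 21)
  p <- 0L
  for (i in seq_len(21)) {
    for (j in i:21) {
      p <- p + 1L
      idx[i, j] <- p
      idx[j, i] <- p
    }
  }
  idx
}
PAIR_INDEX <- pair_index_matrix()

#' Encode peptides as 231-dimensional pair-similarity vectors
#'
#' For a query window `A` and positive windows `P_1..P_N`, every aligned
#' residue pairing `(A_j, P_ij)` is binned by its unordered symbol pair
#' `{a, b}`. With `D_j` the number of such `ab` pairings at position `j`,
#' the pair score is the position-weight-weighted average
#' `S_ab = sum_j D_j * M(a, b) * W_j / sum_j D_j`,
#' and 0 for pairs never realized between the query and the positive set.
#' The 231 scores, ordered as in [pvt_pairs()], form the vector consumed by
#' the neural classifier. Only query-versus-positive pairings enter the
#' counts (never positive-versus-positive).
#'
#' `pvt_encode()` encodes a whole peptide vector at once (one row each);
#' `encode_pvt()` is the single-peptide convenience form.
#'
#' @param peptides Character vector of query windows (common length K).
#' @param query A single query window.
#' @param positives Character vector of positive windows, same length.
#' @param weights Numeric position weights of length K.
#' @param matrix Substitution matrix (default [blosum62_21()]).
#' @return `pvt_encode()`: a numeric `length(peptides)` x 231 matrix with
#'   column names [pvt_pairs()]; `encode_pvt()`: a named numeric vector of
#'   length 231.
#' @export
pvt_encode <- function(peptides, positives, weights,
                       matrix = blosum62_21()) {
  check_substitution_matrix(matrix)
  submat <- matrix
  if (length(positives) == 0L) abort("positive peptide set is empty.")
  codes <- peptide_codes(peptides)
  k <- ncol(codes)
  if (length(weights) != k) {
    abort(sprintf("`weights` must have length %d (window length).", k))
  }
  prof <- positive_profile(positives)  # 21 x K counts
  if (ncol(prof) != k) {
    abort("query and positive peptides must have the same length.")
  }
  w <- as.numeric(weights)

  # Per (query symbol a, position j) the contribution to the numerator and
  # denominator is fixed: D over b is the positive count column. Lay these
  # 21*K contribution rows out densely, then one sparse indicator product
  # accumulates each query's K contributions.
  num <- matrix(0, 21L * k, 231L)
  den <- matrix(0, 21L * k, 231L)
  for (j in seq_len(k)) {
    cnt <- prof[, j]
    for (a in seq_len(21L)) {
      r <- (j - 1L) * 21L + a
      cols <- PAIR_INDEX[a, ]
      den[r, cols] <- cnt
      num[r, cols] <- cnt * submat[a, ] * w[j]
    }
  }
  n <- nrow(codes)
  cell <- sweep(codes, 2L, (seq_len(k) - 1L) * 21L, "+")
  ind <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                              j = as.vector(cell), x = 1,
                              dims = c(n, 21L * k))
  num_q <- as.matrix(ind %*% num)
  den_q <- as.matrix(ind %*% den)
  out <- ifelse(den_q > 0, num_q / ifelse(den_q > 0, den_q, 1), 0)
  dimnames(out) <- list(NULL, pvt_pairs())
  out
}

#' @rdname pvt_encode
#' @export
encode_pvt <- function(query, positives, weights, matrix = blosum62_21()) {
  stopifnot(length(query) == 1L)
  drop(pvt_encode(query, positives, weights, matrix))
}
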