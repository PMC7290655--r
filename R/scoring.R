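# Residue-count profile of a positive peptide set: a 21 x K matrix whose
# (b, j) entry counts positives carrying symbol b at position j.
positive_profile <- function(positives) {
  if (length(positives) == 0L) abort("positive peptide set is empty.")
  codes <- peptide_codes(positives)
  k <- ncol(codes)
  counts <- vapply(seq_len(k), function(j) tabulate(codes[, j], nbins = 21L),
                   integer(21))
  structure(counts, n_pos = nrow(codes))
}

# n x K matrix of mean substitution scores between each query and the
# positive set, position by position: s_j = (1/N) sum_i M(A_j, P_ij).
# Computed as one 21x21 by 21xK product, then indexed by the query codes.
per_position_score_matrix <- function(peptides, positives, submat) {
  codes <- peptide_codes(peptides)
  prof <- positive_profile(positives)
  if (ncol(prof) != ncol(codes)) {
    abort("query and positive peptides must have the same length.")
  }
  score_by_symbol <- (submat %*% prof) / attr(prof, "n_pos")  # 21 x K
  k <- ncol(codes)
  n <- nrow(codes)
  out <- matrix(score_by_symbol[cbind(as.vector(codes),
                                      rep(seq_len(k), each = n))],
                nrow = n, ncol = k)
  colnames(out) <- position_offsets(k)
  out
}

position_offsets <- function(k) {
  center <- (k + 1L) / 2L
  if (k %% 2L == 1L) as.character(seq_len(k) - center)
  else as.character(seq_len(k))
}

#' Mean per-position substitution scores against a positive set
#'
#' For a query window `A` and positive windows `P_1..P_N` of common length
#' `K`, position `j` gets `s_j = (1/N) * sum_i M(A_j, P_ij)`: the mean
#' substitution-matrix score between the query residue and the residues the
#' positives carry at that position. The group-based similarity score is the
#' weight-weighted sum of this vector (see [similarity_score()]).
#'
#' @param query A single peptide string.
#' @param positives Character vector of positive peptides, same length as
#'   `query`.
#' @param matrix Substitution matrix over the 21-letter alphabet
#'   (default [blosum62_21()]).
#' @return A named numeric vector of length `K`; names are position offsets
#'   from the central residue.
#' @export
per_position_scores <- function(query, positives, matrix = blosum62_21()) {
  stopifnot(length(query) == 1L)
  check_substitution_matrix(matrix)
  drop(per_position_score_matrix(query, positives, matrix))
}

#' Group-based peptide similarity score
#'
#' The average similarity `S` between a query window and the whole positive
#' set, weighted per position:
#' `S = (1/N) * sum_j (sum_i M(A_j, P_ij)) * W_j`.
#' When the query is itself a member of the positive set it is *not*
#' excluded; leave-one-out handling belongs to cross-validation.
#'
#' @param query A peptide string, or a character vector of peptides to score
#'   in one call.
#' @param positives Character vector of positive peptides (common length K).
#' @param weights Numeric vector of position weights, length K.
#' @param matrix Substitution matrix (default [blosum62_21()]).
#' @return A numeric vector of scores, one per query.
#' @export
#' @examples
#' pos <- c("ARKSAPSTPAR", "GRKSSPSTPKR")
#' similarity_score("ARKSAPSTPAR", pos, weights = rep(1, 11))
similarity_score <- function(query, positives, weights,
                             matrix = blosum62_21()) {
  check_substitution_matrix(matrix)
  s <- per_position_score_matrix(query, positives, matrix)
  if (length(weights) != ncol(s)) {
    abort(sprintf("`weights` must have length %d (window length).", ncol(s)))
  }
  drop(s %*% as.numeric(weights))
}
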