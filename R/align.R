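# Local alignment scoring. The package scores protein queries against
# reference seeds with Smith-Waterman local alignment under an affine gap
# model in which a gap of length L costs gap_open + L * gap_extend. The
# heavy lifting is delegated to Biostrings::pairwiseAlignment, which
# implements exactly this convention; the test suite holds an independent
# full-DP oracle against which the scores are checked cell-exactly.

known_matrices <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                    "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                    "PAM250")

get_sub_matrix <- function(matrix_name) {
  if (!matrix_name %in% known_matrices)
    abort_config("unknown substitution matrix '%s'", matrix_name)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  get(matrix_name, envir = env)
}

check_amino <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    abort_empty_input("%s sequence is empty", what)
}

#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment score of two amino-acid sequences; a gap of
#' length L costs `gap_open + L * gap_extend`. The score is symmetric in
#' its sequence arguments.
#'
#' @param query,target Amino-acid strings (non-empty).
#' @param matrix_name Substitution matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @return Numeric alignment score.
#' @export
local_align_score <- function(query, target, matrix_name = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  check_amino(query, "query")
  check_amino(target, "target")
  mat <- get_sub_matrix(matrix_name)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

# scores of one query against many targets in a single vectorized call
score_against <- function(query, targets, matrix_name = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  check_amino(query, "query")
  if (length(targets) == 0L) abort_empty_input("no target sequences")
  mat <- get_sub_matrix(matrix_name)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(targets), Biostrings::AAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

#' Self-alignment score of sequences
#'
#' The score of a sequence aligned to itself, i.e. the sum of diagonal
#' substitution-matrix values over its residues; used to normalize query
#' scores to the `[0, 1 + eps]` range.
#'
#' @param residues Character vector of amino-acid sequences.
#' @param matrix_name Substitution matrix name.
#' @return Numeric vector of self scores.
#' @export
self_score <- function(residues, matrix_name = "BLOSUM62") {
  mat <- get_sub_matrix(matrix_name)
  d <- diag(mat)
  vapply(residues, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(d[chars])
  }, 0, USE.NAMES = FALSE)
}
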