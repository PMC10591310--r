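# Independent brute-force oracles. These deliberately share no code with
# the implementation: full-matrix DP for local alignment, character-set
# IUPAC matching, and naive double loops for binding-site and amplicon
# search.

oracle_blosum <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# full Smith-Waterman DP with affine gaps (gap of length L costs
# open + L * ext), all cells materialized
oracle_sw_score <- function(a, b, mat = oracle_blosum, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_base_match <- function(p, t) {
  length(intersect(oracle_iupac_sets[[p]], oracle_iupac_sets[[t]])) > 0
}

oracle_count_mm <- function(primer, window) {
  p <- strsplit(primer, "")[[1]]; w <- strsplit(window, "")[[1]]
  sum(!mapply(oracle_base_match, p, w))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive scan: every window, smallest position wins ties; REVERSE primers
# scanned on the reverse complement, positions mapped to the input strand
oracle_best_binding <- function(iupac, sequence, orientation = "FORWARD") {
  k <- nchar(iupac)
  target <- if (orientation == "FORWARD") sequence
            else oracle_revcomp(sequence)
  n <- nchar(target)
  best_mm <- Inf; best_pos <- NA_integer_
  positions <- if (orientation == "FORWARD") seq_len(n - k + 1)
               else rev(seq_len(n - k + 1))  # ascending input-strand order
  for (p in positions) {
    mm <- oracle_count_mm(iupac, substr(target, p, p + k - 1))
    input_pos <- if (orientation == "FORWARD") p else n - p - k + 2
    if (mm < best_mm) { best_mm <- mm; best_pos <- input_pos }
  }
  list(position = best_pos, mismatches = best_mm)
}

oracle_sites <- function(mix_variants, orientation, sequence, max_mm) {
  out <- NULL
  n <- nchar(sequence)
  for (iupac in mix_variants) {
    k <- nchar(iupac)
    target <- if (orientation == "FORWARD") sequence
              else oracle_revcomp(sequence)
    for (p in seq_len(n - k + 1)) {
      mm <- oracle_count_mm(iupac, substr(target, p, p + k - 1))
      if (mm <= max_mm) {
        s <- if (orientation == "FORWARD") p else n - p - k + 2
        out <- rbind(out, data.frame(start = s, end = s + k - 1,
                                     mismatches = mm))
      }
    }
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      mismatches = integer()))
  out <- out[order(out$start, out$end, out$mismatches), ]
  out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
}

oracle_amplicons <- function(fwd_variants, rev_variants, sequence, max_mm,
                             min_len, max_len) {
  fw <- oracle_sites(fwd_variants, "FORWARD", sequence, max_mm)
  rv <- oracle_sites(rev_variants, "REVERSE", sequence, max_mm)
  out <- NULL
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    if (rv$start[j] > fw$end[i]) {
      len <- rv$end[j] - fw$start[i] + 1
      if (len >= min_len && len <= max_len)
        out <- rbind(out, data.frame(start = fw$start[i], end = rv$end[j],
                                     fwd_mm = fw$mismatches[i],
                                     rev_mm = rv$mismatches[j]))
    }
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      fwd_mm = integer(),
                                      rev_mm = integer()))
  out[order(out$start, out$end), , drop = FALSE]
}

random_aa <- function(len) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL),
               len, replace = TRUE), collapse = "")
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_iupac <- function(len, n_degenerate = 2) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0) {
    at <- sample(len, n_degenerate)
    x[at] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), n_degenerate,
                    replace = TRUE)
  }
  paste(x, collapse = "")
}
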