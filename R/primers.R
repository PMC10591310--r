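# In-silico evaluation of degenerate PCR primers. Matching is indel-free:
# a primer is slid along the target and compared position-wise under IUPAC
# set-intersection semantics.

iupac_masks <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

encode_iupac <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "")[[1]]
  m <- iupac_masks[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    abort_alphabet("%s: invalid IUPAC character '%s' at position %d",
                   what, chars[bad], bad)
  }
  unname(m)
}

#' Do two IUPAC nucleotide codes match?
#'
#' True iff the expansion sets of the codes intersect, so primer R matches
#' target A or G, and a target N matches everything. With
#' `target_ambiguity_is_mismatch = TRUE` any ambiguity code on the target
#' side is counted as a mismatch instead (set-intersection semantics
#' inflate coverage on N-rich targets).
#'
#' @param primer_base,target_base Single IUPAC codes.
#' @param target_ambiguity_is_mismatch See above. Default FALSE.
#' @return Logical.
#' @export
iupac_match <- function(primer_base, target_base,
                        target_ambiguity_is_mismatch = FALSE) {
  pm <- encode_iupac(primer_base, "primer base")
  tm <- encode_iupac(target_base, "target base")
  if (target_ambiguity_is_mismatch && !target_base %in% c("A", "C", "G", "T"))
    return(FALSE)
  bitwAnd(pm, tm) > 0L
}

#' Count mismatches between a primer and an equal-length target window
#'
#' Indel-free positionwise comparison under [iupac_match()] semantics.
#'
#' @param primer_iupac Primer string (IUPAC, 5'->3').
#' @param target_window Target string of identical length.
#' @param target_ambiguity_is_mismatch See [iupac_match()].
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(primer_iupac, target_window,
                             target_ambiguity_is_mismatch = FALSE) {
  pm <- encode_iupac(primer_iupac, "primer")
  tm <- encode_iupac(target_window, "target")
  if (length(pm) != length(tm))
    abort_length("primer length %d != window length %d",
                 length(pm), length(tm))
  if (target_ambiguity_is_mismatch) {
    ambiguous <- !(tm %in% c(1L, 2L, 4L, 8L))
    sum(bitwAnd(pm, tm) == 0L | ambiguous)
  } else {
    sum(bitwAnd(pm, tm) == 0L)
  }
}

revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# mismatch counts of a primer against every window of a sequence
# (positions are starts on the given strand); vectorized over windows
window_mismatches <- function(primer, sequence,
                              target_ambiguity_is_mismatch = FALSE) {
  pm <- encode_iupac(primer, "primer")
  tm <- encode_iupac(sequence, "sequence")
  k <- length(pm); n <- length(tm)
  if (n < k)
    abort_length("sequence (%d nt) shorter than primer (%d nt)", n, k)
  nw <- n - k + 1L
  counts <- integer(nw)
  amb <- if (target_ambiguity_is_mismatch) !(tm %in% c(1L, 2L, 4L, 8L))
         else rep(FALSE, n)
  for (j in seq_len(k)) {
    idx <- j:(j + nw - 1L)
    counts <- counts + as.integer(bitwAnd(pm[j], tm[idx]) == 0L | amb[idx])
  }
  counts
}

#' Best binding site of a primer on a sequence
#'
#' FORWARD primers are scanned 5'->3' along the given strand; REVERSE
#' primers are scanned against the reverse complement, with the reported
#' position mapped back to the input strand (the 1-based start of the
#' matched window). The minimum-mismatch window wins; ties break to the
#' smallest input-strand position.
#'
#' @param primer A one-row variant from a primer mix (list/data.frame
#'   with `iupac`, `orientation`, optionally `primer_name`), or a bare
#'   IUPAC string (then `orientation` applies).
#' @param sequence Nucleotide string (length >= primer length).
#' @param orientation Used when `primer` is a bare string. Default
#'   "FORWARD".
#' @param target_ambiguity_is_mismatch See [iupac_match()].
#' @return data.frame: `primer_name`, `position`, `strand`, `mismatches`.
#' @export
best_binding <- function(primer, sequence, orientation = "FORWARD",
                         target_ambiguity_is_mismatch = FALSE) {
  if (is.character(primer)) {
    primer <- list(primer_name = "primer", iupac = primer,
                   orientation = orientation)
  }
  k <- nchar(primer$iupac)
  if (primer$orientation == "FORWARD") {
    counts <- window_mismatches(primer$iupac, sequence,
                                target_ambiguity_is_mismatch)
    pos <- which.min(counts)   # first minimum = smallest position
    data.frame(primer_name = primer$primer_name, position = pos,
               strand = "+", mismatches = counts[pos],
               stringsAsFactors = FALSE)
  } else {
    rc <- revcomp_iupac(sequence)
    counts <- window_mismatches(primer$iupac, rc,
                                target_ambiguity_is_mismatch)
    n <- nchar(sequence)
    # window starting at p on the revcomp covers input-strand positions
    # [n - p - k + 2, n - p + 1]
    starts <- n - seq_along(counts) - k + 2L
    ord <- order(counts, starts)
    best <- ord[1]
    data.frame(primer_name = primer$primer_name, position = starts[best],
               strand = "-", mismatches = counts[best],
               stringsAsFactors = FALSE)
  }
}

# all windows of a mix at or under a mismatch budget, input-strand starts
mix_sites <- function(mix, sequence, max_mm,
                      target_ambiguity_is_mismatch = FALSE) {
  out <- list()
  n <- nchar(sequence)
  for (v in seq_len(nrow(mix$variants))) {
    iupac <- mix$variants$iupac[v]
    k <- nchar(iupac)
    if (n < k)
      abort_length("sequence (%d nt) shorter than primer (%d nt)", n, k)
    if (mix$orientation == "FORWARD") {
      counts <- window_mismatches(iupac, sequence,
                                  target_ambiguity_is_mismatch)
      starts <- seq_along(counts)
    } else {
      counts <- window_mismatches(iupac, revcomp_iupac(sequence),
                                  target_ambiguity_is_mismatch)
      starts <- n - seq_along(counts) - k + 2L
    }
    hit <- counts <= max_mm
    if (any(hit))
      out[[length(out) + 1L]] <-
        data.frame(start = starts[hit], end = starts[hit] + k - 1L,
                   mismatches = counts[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  sites <- do.call(rbind, out)
  # best (fewest-mismatch) variant represents the mix at each window
  sites <- sites[order(sites$start, sites$end, sites$mismatches), ]
  sites[!duplicated(sites[, c("start", "end")]), , drop = FALSE]
}

#' Is a sequence covered by a primer mix?
#'
#' A mix covers a sequence iff any of its variants binds with at most
#' `max_mm` mismatches (logical OR over the mixture, matching wet-lab
#' behavior of degenerate primer mixes).
#'
#' @param sequence Nucleotide string.
#' @param mix `dsr_primer_mix`.
#' @param max_mm Mismatch budget.
#' @param target_ambiguity_is_mismatch See [iupac_match()].
#' @return Logical.
#' @export
is_covered <- function(sequence, mix, max_mm = 1L,
                       target_ambiguity_is_mismatch = FALSE) {
  for (v in seq_len(nrow(mix$variants))) {
    b <- best_binding(as.list(mix$variants[v, ]), sequence,
                      target_ambiguity_is_mismatch =
                        target_ambiguity_is_mismatch)
    if (b$mismatches <= max_mm) return(TRUE)
  }
  FALSE
}

#' Per-clade coverage of a primer mix
#'
#' Fraction of each clade's sequences covered by the mix within the
#' mismatch budget; a clade passes iff its fraction is at least
#' `clade_pass_frac` (inclusive, the ">= 75% of sequences in a clade, 1
#' mismatch allowed" rule).
#'
#' @param sequences Nucleotide record table.
#' @param clades data.frame with `sequence_id`, `clade_id` covering every
#'   sequence.
#' @param mix `dsr_primer_mix`.
#' @param config `dsr_config` (`max_primer_mismatches`,
#'   `clade_pass_frac`, `target_ambiguity_is_mismatch`).
#' @return data.frame: `clade_id`, `n_sequences`, `n_covered`, `fraction`,
#'   `passed`.
#' @export
clade_coverage <- function(sequences, clades, mix,
                           config = analysis_config()) {
  if (!all(sequences$id %in% clades$sequence_id))
    abort_value("sequence(s) without clade assignment: %s",
                paste(setdiff(sequences$id, clades$sequence_id),
                      collapse = ", "))
  cl <- clades$clade_id[match(sequences$id, clades$sequence_id)]
  empty <- setdiff(unique(clades$clade_id), cl)
  if (length(empty))
    abort_empty_clade("clade(s) with no sequences: %s",
                      paste(empty, collapse = ", "))
  out <- list()
  for (c_id in sort(unique(cl))) {
    seqs <- sequences$residues[cl == c_id]
    cov <- vapply(seqs, is_covered, TRUE, mix = mix,
                  max_mm = config$max_primer_mismatches,
                  target_ambiguity_is_mismatch =
                    config$target_ambiguity_is_mismatch,
                  USE.NAMES = FALSE)
    out[[c_id]] <- data.frame(clade_id = c_id, n_sequences = length(seqs),
                              n_covered = sum(cov),
                              fraction = mean(cov),
                              passed = mean(cov) >= config$clade_pass_frac,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Find amplicons of a forward/reverse mix pair on a sequence
#'
#' Enumerates all pairs of a forward-mix site and a downstream
#' reverse-mix site, both within the mismatch budget, whose product
#' length (1-based inclusive span of the primer outer ends) lies in
#' `[min_len, max_len]`.
#'
#' @param fwd_mix,rev_mix `dsr_primer_mix` of opposite orientations.
#' @param sequence Nucleotide string.
#' @param max_mm Mismatch budget per primer.
#' @param min_len,max_len Product length bounds.
#' @param target_ambiguity_is_mismatch See [iupac_match()].
#' @return data.frame: `start`, `end`, `fwd_mm`, `rev_mm`.
#' @export
find_amplicons <- function(fwd_mix, rev_mix, sequence, max_mm = 1L,
                           min_len = 1L, max_len = .Machine$integer.max,
                           target_ambiguity_is_mismatch = FALSE) {
  if (fwd_mix$orientation != "FORWARD" || rev_mix$orientation != "REVERSE")
    abort_orientation("need a FORWARD mix and a REVERSE mix (got %s / %s)",
                      fwd_mix$orientation, rev_mix$orientation)
  fw <- mix_sites(fwd_mix, sequence, max_mm, target_ambiguity_is_mismatch)
  rv <- mix_sites(rev_mix, sequence, max_mm, target_ambiguity_is_mismatch)
  out <- data.frame(start = integer(), end = integer(),
                    fwd_mm = integer(), rev_mm = integer())
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    if (rv$start[j] > fw$end[i]) {
      len <- rv$end[j] - fw$start[i] + 1L
      if (len >= min_len && len <= max_len)
        out <- rbind(out, data.frame(start = fw$start[i], end = rv$end[j],
                                     fwd_mm = fw$mismatches[i],
                                     rev_mm = rv$mismatches[j]))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}
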