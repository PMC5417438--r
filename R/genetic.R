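#' Levenshtein edit distance between nucleotide sequences
#'
#' The minimal number of single-character insertions, deletions or
#' substitutions transforming one sequence into the other. Comparison is
#' case-insensitive, and an N is treated as matching nothing, not even
#' another N: an ambiguous base never supplies evidence that two reads came
#' from the same template.
#'
#' Vectorised elementwise with recycling.
#'
#' @param a,b Character vectors of non-empty nucleotide sequences.
#' @return Integer vector of edit distances.
#' @export
edit_distance <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("sequences must be non-empty")
  }
  # Remap N to different sentinels on the two sides so that N mismatches
  # everything, including N, under plain Levenshtein comparison.
  a2 <- chartr("N", "1", toupper(a))
  b2 <- chartr("N", "2", toupper(b))
  n <- max(length(a2), length(b2))
  a2 <- rep_len(a2, n)
  b2 <- rep_len(b2, n)
  d <- utils::adist(a2, b2)
  as.integer(d[cbind(seq_len(n), seq_len(n))])
}

#' Length-normalised genetic dissimilarity
#'
#' The genetic criterion's metric: `2 * E / (l1 + l2)`, where `E` is the
#' Levenshtein edit distance and `l1`, `l2` the two sequence lengths. It is
#' 0 exactly for identical sequences and always below 2; for sequences that
#' approximate an alignment without indels it approximates the proportion of
#' mismatched sites.
#'
#' @inheritParams edit_distance
#' @return Numeric vector of dissimilarities in `[0, 2)`.
#' @export
genetic_dissimilarity <- function(a, b) {
  e <- edit_distance(a, b)
  n <- length(e)
  la <- rep_len(nchar(a), n)
  lb <- rep_len(nchar(b), n)
  2 * e / (la + lb)
}

#' Genetic criterion
#'
#' A candidate may be merged into an OTU only if the normalised edit
#' dissimilarity does not exceed the threshold. The comparison is inclusive:
#' merging is blocked only when the dissimilarity is strictly greater than
#' the threshold.
#'
#' @inheritParams edit_distance
#' @param threshold Dissimilarity threshold in (0, 2); default 0.1.
#' @return Logical vector.
#' @export
passes_genetic_criterion <- function(a, b, threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 2)
  genetic_dissimilarity(a, b) <= threshold
}

#' Alignment-based genetic dissimilarity (gold standard)
#'
#' Global (Needleman-Wunsch) pairwise alignment with match-favouring scores,
#' returning the proportion of mismatched sites: aligned columns where the
#' two residues differ, divided by the number of aligned columns where
#' neither sequence has a gap. Used as the reference against which the fast
#' Levenshtein metric is evaluated.
#'
#' @inheritParams edit_distance
#' @param match,mismatch,gap_opening,gap_extension Alignment scores.
#' @return Numeric vector of mismatch proportions in `[0, 1]`.
#' @export
alignment_dissimilarity <- function(a, b, match = 1, mismatch = -1,
                                    gap_opening = 2, gap_extension = 1) {
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("sequences must be non-empty")
  }
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n)
  b <- rep_len(toupper(b), n)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  vapply(seq_len(n), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      a[i], b[i], type = "global", substitutionMatrix = sub_mat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    both <- p != "-" & s != "-"
    sum(p[both] != s[both]) / sum(both)
  }, numeric(1))
}
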