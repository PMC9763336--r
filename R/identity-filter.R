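## Sequence-identity redundancy filtering of a test set against a training
## set. This is a documented stand-in for CD-HIT-2D, not bit-compatible with
## it: identity is computed from an optimal global alignment instead of
## CD-HIT's greedy word-filtered clustering.

identity_sub_matrix <- function() {
  m <- diag(1, 20L)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' Pairwise sequence identity
#'
#' Identity between two peptide sequences, defined as the number of identical
#' aligned positions in an optimal global alignment (match = 1, mismatch = 0,
#' gap = -1) divided by the length of the shorter sequence — the denominator
#' convention CD-HIT uses.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Identity in `[0, 1]`.
#' @export
#' @examples
#' sequence_identity("GLFDIVKKVVGTLAGL", "GLFDIVKKVVGTIAGL") # 15/16
sequence_identity <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = identity_sub_matrix(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

## Maximum identity of each test sequence against any training sequence.
max_identity_to_train <- function(test_seqs, train_seqs) {
  train_set <- Biostrings::AAStringSet(train_seqs)
  sub <- identity_sub_matrix()
  vapply(test_seqs, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = train_set, subject = s, type = "global",
      substitutionMatrix = sub, gapOpening = 0, gapExtension = 1
    )
    max(Biostrings::nmatch(aln) / pmin(nchar(s), nchar(train_seqs)))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Filter redundant test peptides against a training set
#'
#' Keeps the test peptides whose maximum identity to *any* training peptide
#' is strictly below `threshold`. Used to build non-redundant test sets at
#' the usual 0.4 / 0.8 / 0.9 identity thresholds before independent testing.
#'
#' @param test,train Peptide tibbles.
#' @param threshold Identity threshold in `(0, 1]`; a test peptide is removed
#'   when its best identity to the training set is `>= threshold`.
#' @return The filtered test tibble with an extra column `max_identity`. An
#'   empty result is allowed.
#' @export
#' @examples
#' train <- peptide_tbl("t1", "GLFDIVKKVVGTIAGL")
#' test <- peptide_tbl(c("s1", "s2"), c("GLFDIVKKVVGTLAGL", "WWWWW"))
#' identity_filter(test, train, threshold = 0.9)
identity_filter <- function(test, train, threshold = 0.9) {
  test <- validate_peptides(test)
  train <- validate_peptides(train)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort_validation("threshold must be in (0, 1]")
  }
  if (nrow(test) == 0L) {
    test$max_identity <- numeric(0L)
    return(test)
  }
  test$max_identity <- max_identity_to_train(test$sequence, train$sequence)
  test[test$max_identity < threshold, ]
}
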