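## Feature schemes: turn peptide sequences into fixed-size numeric matrices.
##
## Per-residue feature blocks:
##   * bpf   -- 20-d one-hot binary profile over the alphabetical amino-acid
##              order (every scheme starts with this block);
##   * quanc -- 6 z-scored quantitative properties (see aa_quant_table());
##   * qualc -- 10 one-hot qualitative category indicators (see
##              aa_qual_table()).
## Scheme dimensions: bpf 20, quanc 26, qualc 30, mix 36; the learnable
## "embedding" scheme is 36-wide but its rows are trainable network
## parameters, so encode_sequence() refuses it.
##
## A peptide of length l becomes an Lmax x d matrix: rows 1..l encode the
## residues, rows l+1..Lmax hold the pad value 0 (the least informative value
## after z-scoring).

SCHEME_NAMES <- c("bpf", "quanc", "qualc", "mix", "embedding")
LMAX_DEFAULT <- 50L
PAD_VALUE <- 0

#' Feature scheme descriptor
#'
#' Resolves a scheme name to its per-residue dimension and ordered channel
#' labels. `"quanl"` is accepted as an alias of `"qualc"`.
#'
#' @param name One of `"bpf"`, `"quanc"`, `"qualc"` (alias `"quanl"`),
#'   `"mix"`, `"embedding"`.
#' @return An object of class `acp_scheme`: list with `name`, `d` and
#'   `channel_names` (length `d`; for `"embedding"` the channels are the 36
#'   anonymous embedding dimensions).
#' @export
#' @examples
#' feature_scheme("mix")$d
feature_scheme <- function(name) {
  name <- match.arg(tolower(name), c(SCHEME_NAMES, "quanl"))
  if (name == "quanl") name <- "qualc"
  bpf_names <- paste0("bpf_", AA_ALPHABET)
  quanc_names <- paste0("quanc_", setdiff(names(aa_quant_table()), "amino_acid"))
  qualc_names <- colnames(qual_onehot_matrix())
  channels <- switch(name,
    bpf = bpf_names,
    quanc = c(bpf_names, quanc_names),
    qualc = c(bpf_names, qualc_names),
    mix = c(bpf_names, quanc_names, qualc_names),
    embedding = sprintf("emb_%02d", 1:36)
  )
  structure(
    list(name = name, d = length(channels), channel_names = channels),
    class = "acp_scheme"
  )
}

#' Channel labels of a feature scheme
#'
#' @param scheme A scheme name or an `acp_scheme` object.
#' @return Character vector of `d` channel labels, in the exact column order
#'   produced by [encode_sequence()].
#' @export
#' @examples
#' channel_names("qualc")
channel_names <- function(scheme) {
  if (!inherits(scheme, "acp_scheme")) scheme <- feature_scheme(scheme)
  scheme$channel_names
}

#' One-hot binary profile of a residue
#'
#' @param residue Single amino-acid symbols (vectorized).
#' @return For one residue, a named 20-vector with a single 1 at the
#'   residue's alphabetical index; for several, a matrix with one row each.
#' @export
#' @examples
#' bpf_encode("A")
bpf_encode <- function(residue) {
  idx <- match(toupper(residue), AA_ALPHABET)
  if (anyNA(idx)) {
    abort_validation(paste0(
      "unknown residue: ", paste(residue[is.na(idx)], collapse = ", ")
    ))
  }
  m <- matrix(0, length(idx), 20L, dimnames = list(NULL, paste0("bpf_", AA_ALPHABET)))
  m[cbind(seq_along(idx), idx)] <- 1
  if (length(idx) == 1L) m[1L, ] else m
}

#' Qualitative one-hot encoding of a residue
#'
#' Concatenation of four one-hot blocks: hydrophobicity (Y, N), polarity
#' (Y, N), charge (negative, positive, N) and aromatic-or-aliphatic
#' (aromatic, aliphatic, N). Each block sums to exactly 1.
#'
#' @inheritParams bpf_encode
#' @return A named 10-vector (or matrix for several residues).
#' @export
#' @examples
#' qualc_encode("D")[c("charge_negative", "charge_positive", "charge_N")]
qualc_encode <- function(residue) {
  idx <- match(toupper(residue), AA_ALPHABET)
  if (anyNA(idx)) {
    abort_validation(paste0(
      "unknown residue: ", paste(residue[is.na(idx)], collapse = ", ")
    ))
  }
  m <- qual_onehot_matrix()[idx, , drop = FALSE]
  rownames(m) <- NULL
  if (length(idx) == 1L) m[1L, ] else m
}

## Per-residue feature matrix (20 x d) for a fixed scheme, rows in
## alphabetical amino-acid order. Encoding a sequence is then a row lookup.
residue_feature_matrix <- function(scheme) {
  if (!inherits(scheme, "acp_scheme")) scheme <- feature_scheme(scheme)
  if (scheme$name == "embedding") {
    abort_validation(
      "the embedding scheme has no fixed residue features; its rows are trained inside the network"
    )
  }
  bpf <- diag(20L)
  blocks <- list(bpf)
  if (scheme$name %in% c("quanc", "mix")) {
    z <- std_quant_matrix()$z
    blocks <- c(blocks, list(z[AA_ALPHABET, , drop = FALSE]))
  }
  if (scheme$name %in% c("qualc", "mix")) {
    blocks <- c(blocks, list(qual_onehot_matrix()))
  }
  m <- do.call(cbind, blocks)
  dimnames(m) <- list(AA_ALPHABET, scheme$channel_names)
  m
}

#' Encode one peptide as an Lmax x d matrix
#'
#' Row i is the feature vector of residue i (binary profile, plus z-scored
#' quantitative properties and/or qualitative one-hots depending on the
#' scheme); rows beyond the true length are padded with 0.
#'
#' @param sequence A single amino-acid sequence (or a one-row peptide tibble).
#' @param scheme Scheme name or `acp_scheme` (not `"embedding"`).
#' @param lmax Padded length (default 50).
#' @return Numeric `lmax x d` matrix with the channel labels as colnames and
#'   attributes `true_length` and `scheme`.
#' @export
#' @examples
#' m <- encode_sequence("GLFDIVKKVVGTIAGL", "mix")
#' dim(m)
encode_sequence <- function(sequence, scheme = "mix", lmax = LMAX_DEFAULT) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stopifnot(length(sequence) == 1L)
  if (!inherits(scheme, "acp_scheme")) scheme <- feature_scheme(scheme)
  tbl <- peptide_tbl("x", sequence, lmax = lmax)
  residues <- strsplit(tbl$sequence, "")[[1L]]
  l <- length(residues)
  feats <- residue_feature_matrix(scheme)
  m <- matrix(PAD_VALUE, lmax, scheme$d, dimnames = list(NULL, scheme$channel_names))
  m[seq_len(l), ] <- feats[residues, , drop = FALSE]
  attr(m, "true_length") <- l
  attr(m, "scheme") <- scheme$name
  m
}

#' Encode a peptide dataset as a 3-d array
#'
#' @param peptides A peptide tibble.
#' @param scheme Scheme name or `acp_scheme`. For the `"embedding"` scheme
#'   the result is an integer index matrix (`n x lmax`, 0 = padding) that the
#'   network resolves through its trainable lookup table.
#' @param lmax Padded length (default 50).
#' @return For fixed schemes, an `n x lmax x d` array with attributes `ids`,
#'   `lengths`, `scheme`, `channel_names`; for `"embedding"`, an integer
#'   matrix with the same attributes.
#' @export
encode_dataset <- function(peptides, scheme = "mix", lmax = LMAX_DEFAULT) {
  peptides <- validate_peptides(peptides, lmax = lmax)
  if (!inherits(scheme, "acp_scheme")) scheme <- feature_scheme(scheme)
  n <- nrow(peptides)
  lengths <- nchar(peptides$sequence)
  if (scheme$name == "embedding") {
    idx <- matrix(0L, n, lmax)
    for (i in seq_len(n)) {
      r <- match(strsplit(peptides$sequence[i], "")[[1L]], AA_ALPHABET)
      idx[i, seq_along(r)] <- r
    }
    out <- idx
  } else {
    feats <- residue_feature_matrix(scheme)
    out <- array(PAD_VALUE, dim = c(n, lmax, scheme$d))
    for (i in seq_len(n)) {
      residues <- strsplit(peptides$sequence[i], "")[[1L]]
      out[i, seq_along(residues), ] <- feats[residues, , drop = FALSE]
    }
  }
  attr(out, "ids") <- peptides$id
  attr(out, "lengths") <- lengths
  attr(out, "scheme") <- scheme$name
  attr(out, "channel_names") <- scheme$channel_names
  out
}

#' Decode the binary-profile block of an encoded peptide
#'
#' Inverse of the BPF block of [encode_sequence()]: recovers the original
#' sequence from the first `true_length` rows.
#'
#' @param encoded A matrix from [encode_sequence()].
#' @return The decoded amino-acid sequence string.
#' @export
decode_bpf <- function(encoded) {
  l <- attr(encoded, "true_length") %||% nrow(encoded)
  rows <- encoded[seq_len(l), seq_len(20L), drop = FALSE]
  paste(AA_ALPHABET[max.col(rows)], collapse = "")
}

#' Export an encoded dataset as a wide CSV
#'
#' Long-by-position layout: one row per (peptide, position) with the channel
#' labels as columns.
#'
#' @param encoded Array from [encode_dataset()] (fixed schemes only).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoded_csv <- function(encoded, path) {
  if (!is.array(encoded) || length(dim(encoded)) != 3L) {
    abort_validation("expected a 3-d encoded array from encode_dataset()")
  }
  d <- dim(encoded)
  ids <- attr(encoded, "ids")
  flat <- matrix(aperm(encoded, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
  colnames(flat) <- attr(encoded, "channel_names")
  tbl <- tibble::as_tibble(as.data.frame(flat))
  tbl <- dplyr::bind_cols(
    tibble::tibble(
      id = rep(ids, each = d[2L]),
      position = rep(seq_len(d[2L]), times = d[1L])
    ),
    tbl
  )
  readr::write_csv(tbl, path)
  invisible(path)
}
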