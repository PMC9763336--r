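## Peptide datasets: tibbles with columns `id`, `sequence` and optionally
## `label` (1 = ACP, 0 = non-ACP) plus a free-form `description`.

#' Construct and validate a peptide dataset
#'
#' Builds the canonical peptide tibble used throughout the package.
#' Sequences are uppercased on ingest; any character outside the 20-letter
#' amino-acid alphabet is a fatal validation error (silent data loss is worse
#' than failure), as is any sequence shorter than `min_length` or longer than
#' `lmax`.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param label Optional numeric/integer vector of binary labels
#'   (1 = ACP, 0 = non-ACP); `NA` allowed for unlabeled records.
#' @param description Optional character vector of FASTA description text.
#' @param min_length,lmax Accepted sequence length range (defaults 3 and 50,
#'   the range the classifiers are defined on).
#' @return A tibble with columns `id`, `sequence` and, when given, `label`
#'   and `description`.
#' @export
#' @examples
#' peptide_tbl(c("p1", "p2"), c("glfdivkkvvgtiagl", "KWKLFKKI"), label = c(1, 0))
peptide_tbl <- function(id, sequence, label = NULL, description = NULL,
                        min_length = 3L, lmax = 50L) {
  tbl <- tibble::tibble(id = as.character(id), sequence = toupper(sequence))
  if (!is.null(description)) tbl$description <- as.character(description)
  if (!is.null(label)) tbl$label <- as.integer(label)
  validate_peptides(tbl, min_length = min_length, lmax = lmax)
}

#' Validate a peptide tibble
#'
#' Checks id uniqueness, the amino-acid alphabet, the length range and (when
#' present) that labels are binary. Returns the tibble invisibly unchanged so
#' it can sit inside a pipe.
#'
#' @param peptides A tibble with columns `id` and `sequence` (and optionally
#'   `label`).
#' @inheritParams peptide_tbl
#' @return The validated tibble (sequences uppercased).
#' @export
validate_peptides <- function(peptides, min_length = 3L, lmax = 50L) {
  if (!is.data.frame(peptides) || !all(c("id", "sequence") %in% names(peptides))) {
    abort_validation("a peptide dataset needs `id` and `sequence` columns")
  }
  peptides <- tibble::as_tibble(peptides)
  peptides$sequence <- toupper(peptides$sequence)
  if (anyDuplicated(peptides$id)) {
    dup <- unique(peptides$id[duplicated(peptides$id)])
    abort_validation(paste0(
      "duplicate peptide id(s): ", paste(head(dup, 5L), collapse = ", ")
    ))
  }
  bad_chr <- stringr::str_remove_all(
    peptides$sequence, paste0("[", paste(AA_ALPHABET, collapse = ""), "]")
  )
  offending <- which(nchar(bad_chr) > 0L)
  if (length(offending) > 0L) {
    first <- offending[1L]
    abort_validation(paste0(
      "illegal residue character(s) \"",
      paste(unique(strsplit(bad_chr[first], "")[[1L]]), collapse = ""),
      "\" in record \"", peptides$id[first], "\"",
      if (length(offending) > 1L) {
        paste0(" (and ", length(offending) - 1L, " more record(s))")
      } else ""
    ))
  }
  len <- nchar(peptides$sequence)
  bad_len <- which(len < min_length | len > lmax)
  if (length(bad_len) > 0L) {
    first <- bad_len[1L]
    abort_validation(paste0(
      "sequence length out of range [", min_length, ", ", lmax, "] for record \"",
      peptides$id[first], "\" (length ", len[first], ")",
      if (length(bad_len) > 1L) {
        paste0(" (and ", length(bad_len) - 1L, " more record(s))")
      } else ""
    ))
  }
  if ("label" %in% names(peptides)) {
    lab <- peptides$label
    if (!all(is.na(lab) | lab %in% c(0L, 1L))) {
      abort_validation("labels must be binary (1 = ACP, 0 = non-ACP) or NA")
    }
    peptides$label <- as.integer(lab)
  }
  peptides
}

require_labels <- function(peptides, caller) {
  if (!"label" %in% names(peptides) || anyNA(peptides$label)) {
    abort_validation(paste0(caller, " requires every peptide to be labeled"))
  }
  invisible(peptides)
}

#' Read peptides from a FASTA file
#'
#' One peptide per record. The record id is the header text up to the first
#' whitespace; any remaining text is kept in a `description` column but is
#' ignored by the models. A label can be encoded as an id suffix `"|1"` /
#' `"|0"`, or supplied separately through `labels` (a two-column id/label
#' data frame or the path of such a TSV).
#'
#' @param path Path to a FASTA file.
#' @param labels Optional labels: a data frame with columns `id` and `label`,
#'   or the path to a two-column TSV.
#' @inheritParams peptide_tbl
#' @return A validated peptide tibble. An empty file yields an empty tibble
#'   with a warning.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|1 example", "GLFDIVKKVVGTIAGL"), fa)
#' read_fasta_peptides(fa)
read_fasta_peptides <- function(path, labels = NULL, min_length = 3L, lmax = 50L) {
  if (!file.exists(path)) {
    abort_io(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort_io(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble::tibble(id = character(), sequence = character()))
  }
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  sequence <- unname(as.character(set))
  label <- NULL
  has_suffix <- grepl("\\|[01]$", id)
  if (any(has_suffix)) {
    label <- ifelse(has_suffix, as.integer(stringr::str_sub(id, -1L)), NA_integer_)
    id <- ifelse(has_suffix, stringr::str_sub(id, 1L, -3L), id)
  }
  tbl <- peptide_tbl(id, sequence,
    label = label,
    description = if (any(nzchar(description))) description else NULL,
    min_length = min_length, lmax = lmax
  )
  if (!is.null(labels)) {
    tbl <- join_labels(tbl, labels)
  }
  tbl
}

#' Write peptides to a FASTA file
#'
#' @param peptides A peptide tibble.
#' @param path Output path.
#' @param with_labels If `TRUE` and a `label` column exists, labels are
#'   appended to the record ids as `"|1"` / `"|0"`.
#' @return `path`, invisibly.
#' @export
write_fasta_peptides <- function(peptides, path, with_labels = FALSE) {
  peptides <- validate_peptides(peptides)
  ids <- peptides$id
  if (with_labels && "label" %in% names(peptides)) {
    ids <- paste0(ids, "|", peptides$label)
  }
  if ("description" %in% names(peptides)) {
    has_desc <- !is.na(peptides$description) & nzchar(peptides$description)
    ids[has_desc] <- paste(ids[has_desc], peptides$description[has_desc])
  }
  set <- Biostrings::BStringSet(peptides$sequence)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column label TSV (id, label)
#'
#' @param path Path to a TSV with columns `id` and `label`.
#' @return A tibble with columns `id` (character) and `label` (integer).
#' @export
read_label_tsv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("label file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "label") %in% names(tbl))) {
    abort_validation("label TSV must have columns `id` and `label`")
  }
  tibble::tibble(id = as.character(tbl$id), label = as.integer(tbl$label))
}

join_labels <- function(peptides, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- read_label_tsv(labels)
  }
  labels <- tibble::as_tibble(labels)
  missing <- setdiff(peptides$id, labels$id)
  if (length(missing) > 0L) {
    abort_validation(paste0(
      "no label for peptide id(s): ", paste(head(missing, 5L), collapse = ", ")
    ))
  }
  peptides$label <- as.integer(labels$label[match(peptides$id, labels$id)])
  validate_peptides(peptides)
}

#' Stratified K-fold assignment
#'
#' Assigns every labeled peptide to one of `k` folds so that, per class, fold
#' sizes differ by at most one; with balanced classes each fold then holds an
#' (almost) equal number of positives and negatives. Deterministic given
#' `seed`.
#'
#' @param peptides A fully labeled peptide tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the shuffle.
#' @return A tibble with columns `id` and `fold` (integer in `0:(k-1)`), with
#'   attributes `k` and `seed`.
#' @export
#' @examples
#' bench <- make_benchmark(n_pos = 10, n_neg = 10, seed = 1)
#' table(dplyr::left_join(bench, stratified_kfold(bench, 5, 1), by = "id")[
#'   c("fold", "label")])
stratified_kfold <- function(peptides, k = 5L, seed = 1L) {
  peptides <- validate_peptides(peptides)
  require_labels(peptides, "stratified_kfold()")
  k <- as.integer(k)
  if (k < 2L) abort_validation("k must be >= 2")
  counts <- table(peptides$label)
  if (length(counts) < 2L || any(counts < k)) {
    abort_validation(paste0(
      "each class needs at least k = ", k, " members (have ",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")"
    ))
  }
  assignment <- with_seed(seed, {
    dplyr::bind_rows(lapply(split(peptides$id, peptides$label), function(ids) {
      ids <- sample(ids)
      tibble::tibble(id = ids, fold = (seq_along(ids) - 1L) %% k)
    }))
  })
  out <- assignment[match(peptides$id, assignment$id), ]
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Stratified holdout split
#'
#' Splits a labeled dataset into train and test parts, drawing
#' `round(test_fraction * n)` peptides per class into the test set.
#' Deterministic given `seed`.
#'
#' @inheritParams stratified_kfold
#' @param test_fraction Fraction of each class placed in the test set,
#'   strictly between 0 and 1.
#' @return A named list with peptide tibbles `train` and `test`.
#' @export
#' @examples
#' bench <- make_benchmark(n_pos = 50, n_neg = 50, seed = 1)
#' sp <- holdout_split(bench, 0.2, seed = 1)
#' nrow(sp$test)
holdout_split <- function(peptides, test_fraction = 0.2, seed = 1L) {
  peptides <- validate_peptides(peptides)
  require_labels(peptides, "holdout_split()")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort_validation("test_fraction must be strictly between 0 and 1")
  }
  if (any(table(peptides$label) == 0L)) {
    abort_validation("both classes must be present")
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(split(peptides$id, peptides$label), function(ids) {
      n_test <- round(test_fraction * length(ids))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  list(
    train = peptides[!peptides$id %in% test_ids, ],
    test  = peptides[peptides$id %in% test_ids, ]
  )
}

#' Export a fold assignment as TSV
#'
#' @param split A tibble from [stratified_kfold()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_tsv <- function(split, path) {
  readr::write_tsv(split[c("id", "fold")], path)
  invisible(path)
}
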