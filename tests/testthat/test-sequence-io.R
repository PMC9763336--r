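test_that("FASTA round-trip preserves ids, sequences and labels", {
  tbl <- peptide_tbl(
    c("pep1", "pep2"), c("glfdivkkvvgtiagl", "KWKLFKKI"), label = c(1L, 0L)
  )
  expect_equal(tbl$sequence[1L], "GLFDIVKKVVGTIAGL") # uppercased on ingest
  path <- write_temp_fasta(tbl, with_labels = TRUE)
  back <- read_fasta_peptides(path)
  expect_equal(back$id, tbl$id)
  expect_equal(back$sequence, tbl$sequence)
  expect_equal(back$label, tbl$label)
})

test_that("FASTA descriptions are kept as metadata and labels joinable via TSV", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description text", "GLFDIVKKVVGTIAGL"), fa)
  tbl <- read_fasta_peptides(fa)
  expect_equal(nrow(tbl), 1L)
  expect_equal(nchar(tbl$sequence), 16L)
  expect_equal(tbl$description, "some description text")

  labs <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = "p1", label = 1L), labs)
  expect_equal(read_fasta_peptides(fa, labels = labs)$label, 1L)
})

test_that("empty FASTA warns and returns an empty dataset", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  file.create(fa)
  expect_warning(tbl <- read_fasta_peptides(fa), "empty")
  expect_equal(nrow(tbl), 0L)
})

test_that("illegal residues and out-of-range lengths are fatal and name the record", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">good", "ACDEF", ">bad", "ACXDE"), fa)
  err <- expect_error(read_fasta_peptides(fa), class = "acplearn_validation_error")
  expect_match(conditionMessage(err), "bad")
  expect_match(conditionMessage(err), "X")

  expect_error(peptide_tbl("short", "AD"), class = "acplearn_validation_error")
  expect_error(
    peptide_tbl("long", strrep("A", 51L)),
    class = "acplearn_validation_error"
  )
  expect_silent(peptide_tbl("min", "ADK"))
  expect_error(
    peptide_tbl(c("a", "a"), c("AAA", "CCC")),
    class = "acplearn_validation_error"
  )
})

test_that("stratified K folds balance both classes and are deterministic", {
  bench <- make_benchmark(n_pos = 10, n_neg = 10, seed = 1)
  split <- stratified_kfold(bench, k = 5, seed = 11)
  counts <- table(split$fold, bench$label[match(split$id, bench$id)])
  expect_true(all(counts == 2L))
  expect_identical(split$fold, stratified_kfold(bench, k = 5, seed = 11)$fold)
  expect_setequal(split$id, bench$id)
})

test_that("fold sizes differ by at most one per class at benchmark scale", {
  # 861 = 5 * 172 + 1, so per-fold class counts must be 172 or 173
  big <- tibble::tibble(
    id = sprintf("x%04d", 1:1722),
    sequence = strrep("A", 10L),
    label = rep(c(1L, 0L), each = 861L)
  )
  # bypass duplicate-sequence concerns: ids unique, sequences may repeat
  split <- stratified_kfold(big, k = 5, seed = 2)
  counts <- table(split$fold, big$label[match(split$id, big$id)])
  expect_true(all(counts %in% c(172L, 173L)))
  expect_equal(sum(counts), 1722L)
  expect_true(all(apply(counts, 2L, function(x) diff(range(x))) <= 1L))
})

test_that("holdout split draws round(fraction * class size) per class", {
  bench <- make_benchmark(n_pos = 100, n_neg = 100, seed = 1)
  sp <- holdout_split(bench, 0.2, seed = 5)
  expect_equal(as.vector(table(sp$test$label)), c(20L, 20L))
  expect_equal(nrow(sp$train) + nrow(sp$test), 200L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  # same seed, same split
  sp2 <- holdout_split(bench, 0.2, seed = 5)
  expect_identical(sort(sp$test$id), sort(sp2$test$id))

  big <- tibble::tibble(
    id = sprintf("x%04d", 1:1722), sequence = strrep("A", 10L),
    label = rep(c(1L, 0L), each = 861L)
  )
  expect_equal(as.vector(table(holdout_split(big, 0.2, seed = 1)$test$label)),
               c(172L, 172L))
  expect_error(holdout_split(bench, 0), class = "acplearn_validation_error")
})

test_that("unlabeled or too-small datasets are rejected by the splitters", {
  unl <- peptide_tbl(c("a", "b"), c("AAA", "CCC"))
  expect_error(stratified_kfold(unl, 2, 1), class = "acplearn_validation_error")
  small <- make_benchmark(n_pos = 3, n_neg = 3, seed = 1)
  expect_error(stratified_kfold(small, 5, 1), class = "acplearn_validation_error")
})

test_that("sequence identity matches the position-count oracle", {
  # single substitution in a 16-mer: 15 identical positions / 16
  expect_equal(
    sequence_identity("GLFDIVKKVVGTLAGL", "GLFDIVKKVVGTIAGL"), 15 / 16
  )
  expect_equal(sequence_identity("AAAA", "AAAA"), 1)
  expect_equal(sequence_identity("WWWW", "AAAA"), 0)
  # denominator is the shorter sequence
  expect_equal(sequence_identity("AAA", "AAAAAA"), 1)
})

test_that("identity_filter removes redundant sequences, strictly-below rule", {
  train <- peptide_tbl(c("t1", "t2"), c("AAAA", "GLFDIVKKVVGTIAGL"))
  test <- peptide_tbl(
    c("s1", "s2", "s3"), c("AAAA", "GLFDIVKKVVGTLAGL", "WWWW")
  )
  kept09 <- identity_filter(test, train, threshold = 0.9)
  expect_setequal(kept09$id, "s3") # exact dup and 93.75%-identical both removed
  kept04 <- identity_filter(test, train, threshold = 0.4)
  expect_setequal(kept04$id, "s3") # zero identity to either training sequence
  # exact duplicates fail even a threshold of 1.0
  expect_false("s1" %in% identity_filter(test, train, threshold = 1)$id)
})

test_that("lowering the identity threshold never adds sequences back", {
  train <- random_peptides(15, length_range = c(5L, 20L), seed = 31)
  test <- dplyr::bind_rows(
    random_peptides(15, length_range = c(5L, 20L), seed = 32, prefix = "t"),
    peptide_tbl("dup", train$sequence[1L])
  )
  kept <- lapply(c(1, 0.9, 0.6, 0.4), function(th) {
    identity_filter(test, train, threshold = th)$id
  })
  for (i in seq_len(length(kept) - 1L)) {
    expect_true(all(kept[[i + 1L]] %in% kept[[i]]))
  }
})

test_that("fold assignments export as TSV", {
  bench <- make_benchmark(n_pos = 5, n_neg = 5, seed = 1)
  split <- stratified_kfold(bench, k = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_tsv(split, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 10L)
  expect_named(back, c("id", "fold"))
})
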