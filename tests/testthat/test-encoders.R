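test_that("scheme dimensions and channel labels are fixed by construction", {
  expect_equal(feature_scheme("bpf")$d, 20L)
  expect_equal(feature_scheme("quanc")$d, 26L)
  expect_equal(feature_scheme("qualc")$d, 30L)
  expect_equal(feature_scheme("mix")$d, 36L)
  expect_equal(feature_scheme("embedding")$d, 36L)
  # "quanl" is an accepted alias of the BPF + qualitative combination
  expect_equal(feature_scheme("quanl")$name, "qualc")

  expect_equal(channel_names("bpf"), paste0("bpf_", aa_alphabet()))
  expect_equal(
    channel_names("mix")[21:26],
    paste0("quanc_", c(
      "molecular_mass", "isoelectric_point", "pk1", "pk2", "pKa", "vdw_volume"
    ))
  )
  expect_true("charge_N" %in% channel_names("qualc"))
  # channel order must equal the encoded column order
  m <- encode_sequence("ACD", "mix")
  expect_equal(colnames(m), channel_names("mix"))
})

test_that("binary profile is one-hot at the alphabetical index", {
  a <- bpf_encode("A")
  expect_equal(unname(a), c(1, rep(0, 19)))
  c_ <- bpf_encode("C")
  expect_equal(unname(c_), c(0, 1, rep(0, 18)))
  y <- bpf_encode("Y")
  expect_equal(unname(y), c(rep(0, 19), 1))
  expect_error(bpf_encode("X"), class = "acplearn_validation_error")
})

test_that("qualitative one-hot blocks match the category table and partition", {
  d <- qualc_encode("D")
  expect_equal(unname(d[c("charge_negative", "charge_positive", "charge_N")]),
               c(1, 0, 0))
  k <- qualc_encode("K")
  expect_equal(unname(k[c("charge_negative", "charge_positive", "charge_N")]),
               c(0, 1, 0))
  g <- qualc_encode("G")
  expect_equal(unname(g[c("charge_negative", "charge_positive", "charge_N")]),
               c(0, 0, 1))
  expect_equal(unname(g[c("aromatic", "aliphatic", "aroali_N")]), c(0, 0, 1))
  # every block sums to exactly 1 for all 20 amino acids
  enc <- qualc_encode(aa_alphabet())
  blocks <- list(1:2, 3:4, 5:7, 8:10)
  for (b in blocks) expect_equal(unname(rowSums(enc[, b])), rep(1, 20))
})

test_that("property table matches its source values at spot-check cells", {
  tbl <- aa_quant_table()
  expect_equal(tbl$molecular_mass[tbl$amino_acid == "G"], 75.07)
  expect_equal(tbl$isoelectric_point[tbl$amino_acid == "R"], 10.76)
  expect_equal(tbl$pKa[tbl$amino_acid == "K"], 10.53)
  # the no-side-chain-pKa rows carry a literal 0
  expect_equal(tbl$pKa[tbl$amino_acid == "G"], 0)
  # provisional proline parse, isolated in the shipped CSV
  p <- tbl[tbl$amino_acid == "P", ]
  expect_equal(unlist(p[-1], use.names = FALSE),
               c(115.13, 6.30, 1.99, 10.60, 0, 88))
})

test_that("standardization gives population z-scores, mean 0 / sd 1", {
  std <- standardize_table(aa_quant_table())
  expect_lt(max(abs(colMeans(std$z))), 1e-9)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(max(abs(apply(std$z, 2L, pop_sd) - 1)), 1e-9)

  # direct-summation oracle for glycine's molecular mass, from the printed
  # 20 masses
  masses <- c(
    75.07, 89.09, 117.15, 131.17, 131.17, 165.19, 204.23, 181.19, 133.10,
    155.16, 132.12, 147.13, 146.19, 146.15, 149.21, 174.20, 105.09, 119.12,
    121.16, 115.13
  )
  mu1 <- sum(masses) / 20
  sigma1 <- sqrt(sum((masses - mu1)^2) / 20)
  expect_equal(std$z["G", "molecular_mass"], (75.07 - mu1) / sigma1,
               tolerance = 1e-12)

  # shift invariance of the z-score
  shifted <- aa_quant_table()
  shifted$pk1 <- shifted$pk1 + 5
  expect_equal(standardize_table(shifted)$z[, "pk1"], std$z[, "pk1"])

  # zero-variance columns are rejected
  flat <- aa_quant_table()
  flat$pk1 <- 1
  expect_error(standardize_table(flat), class = "acplearn_validation_error")
})

test_that("encoded matrices have the padded shape and zero pad rows", {
  m <- encode_sequence("GLFDIVKKVVGTIAGL", "mix")
  expect_equal(dim(m), c(50L, 36L))
  expect_equal(attr(m, "true_length"), 16L)
  expect_true(all(m[17:50, ] == 0))
  # first 20 entries of every real row are one-hot
  expect_equal(unname(rowSums(m[1:16, 1:20])), rep(1, 16))
  expect_true(all(m[1:16, 1:20] %in% c(0, 1)))

  m3 <- encode_sequence("KDY", "bpf")
  expect_equal(sum(rowSums(m3 != 0) > 0), 3L)
  expect_error(encode_sequence("AD", "bpf"), class = "acplearn_validation_error")
  expect_error(encode_sequence(strrep("A", 51), "mix"),
               class = "acplearn_validation_error")
  expect_error(encode_sequence("ACD", "embedding"),
               class = "acplearn_validation_error")
})

test_that("decoding the BPF block recovers the sequence (round trip)", {
  peps <- random_peptides(20, seed = 5)
  for (s in peps$sequence) {
    for (scheme in c("bpf", "mix")) {
      expect_equal(decode_bpf(encode_sequence(s, scheme)), s)
    }
  }
})

test_that("encoding is deterministic and position-local", {
  a <- encode_sequence("ACDEFGHIK", "mix")
  b <- encode_sequence("ACDEFGHIK", "mix")
  expect_identical(a, b)
  c_ <- encode_sequence("ACDWFGHIK", "mix") # position 4 changed: E -> W
  diff_rows <- which(rowSums(a != c_) > 0)
  expect_equal(diff_rows, 4L)
})

test_that("dataset encoding stacks per-peptide matrices and exports to CSV", {
  peps <- peptide_tbl(c("a", "b"), c("ACD", "KKKK"))
  enc <- encode_dataset(peps, "qualc")
  expect_equal(dim(enc), c(2L, 50L, 30L))
  expect_equal(attr(enc, "ids"), c("a", "b"))
  expect_equal(matrix(enc[1L, , ], 50L, 30L),
               unname(encode_sequence("ACD", "qualc")[, ]),
               ignore_attr = TRUE)
  # embedding scheme encodes to residue indices with 0 padding
  idx <- encode_dataset(peps, "embedding")
  expect_true(is.matrix(idx))
  expect_equal(idx[1L, 1:4], c(1L, 2L, 3L, 0L))

  path <- withr::local_tempfile(fileext = ".csv")
  write_encoded_csv(enc, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 100L)
  expect_equal(names(back)[3:5], channel_names("qualc")[1:3])
  expect_equal(back$charge_N[1:3], c(1, 1, 0)) # A, C neutral; D negative
})
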