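## Amino-acid property tables and their standardization.
##
## Two small CSV resources ship with the package:
##   * aa_quant_properties.csv -- six quantitative properties per amino acid
##     (molecular mass, isoelectric point, pk1, pk2, pKa, van der Waals
##     volume). Amino acids without a measurable side-chain pKa carry a
##     literal 0 in the pKa column; that 0 enters the z-score as printed.
##     The proline row is provisional: the primary source renders it
##     ambiguously and the values here follow a column-count reading
##     (pk1 = 1.99, pk2 = 10.60, pKa = 0, volume = 88).
##   * aa_qual_properties.csv -- four categorical properties per amino acid
##     (hydrophobicity Y/N, polarity Y/N, charge negative/positive/N,
##     aromatic/aliphatic/N).

.acplearn_cache <- new.env(parent = emptyenv())

read_extdata_csv <- function(file) {
  path <- system.file("extdata", file, package = "acplearn", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Quantitative amino-acid property table
#'
#' Six quantitative physicochemical properties for the 20 standard amino
#' acids: molecular mass, isoelectric point, pk1 (alpha-carboxyl pKa), pk2
#' (alpha-amino pKa), side-chain pKa (0 where the side chain has none), and
#' van der Waals volume. Read once from the CSV resource shipped with the
#' package and cached.
#'
#' @return A tibble with 20 rows and columns `amino_acid`,
#'   `molecular_mass`, `isoelectric_point`, `pk1`, `pk2`, `pKa`,
#'   `vdw_volume`.
#' @seealso [standardize_table()], [aa_qual_table()]
#' @export
#' @examples
#' aa_quant_table()
aa_quant_table <- function() {
  if (is.null(.acplearn_cache$quant)) {
    tbl <- read_extdata_csv("aa_quant_properties.csv")
    stopifnot(nrow(tbl) == 20L, ncol(tbl) == 7L)
    .acplearn_cache$quant <- tbl
  }
  .acplearn_cache$quant
}

#' Qualitative amino-acid property table
#'
#' Category assignments for the 20 standard amino acids under four
#' qualitative properties: hydrophobicity (Y/N), polarity (Y/N), charge
#' (negative/positive/N) and aromatic-or-aliphatic (aromatic/aliphatic/N).
#'
#' @return A tibble with 20 rows and columns `amino_acid`,
#'   `hydrophobicity`, `polarity`, `charge`, `aromatic_or_aliphatic`.
#' @export
#' @examples
#' aa_qual_table()
aa_qual_table <- function() {
  if (is.null(.acplearn_cache$qual)) {
    tbl <- read_extdata_csv("aa_qual_properties.csv")
    stopifnot(nrow(tbl) == 20L, ncol(tbl) == 5L)
    .acplearn_cache$qual <- tbl
  }
  .acplearn_cache$qual
}

#' Z-score standardization of the quantitative property table
#'
#' Standardizes each property column to mean 0 and *population* standard
#' deviation 1 over the 20 amino acids (the divisor is 20, not 19). The
#' column means and standard deviations are retained so the transformation
#' is reproducible and can be serialized with trained models.
#'
#' @param raw A quantitative property table as returned by
#'   [aa_quant_table()]: 20 rows, an `amino_acid` column plus 6 numeric
#'   property columns.
#' @return An object of class `acp_std_table`: a list with
#'   * `z` -- 20 x 6 numeric matrix of z-scores, rownames = amino acids;
#'   * `mu` -- named 6-vector of column means;
#'   * `sigma` -- named 6-vector of column population standard deviations.
#' @export
#' @examples
#' std <- standardize_table(aa_quant_table())
#' colMeans(std$z)   # ~0
#' std$z["G", "molecular_mass"]
standardize_table <- function(raw = aa_quant_table()) {
  stopifnot(is.data.frame(raw), "amino_acid" %in% names(raw))
  x <- as.matrix(raw[setdiff(names(raw), "amino_acid")])
  rownames(x) <- raw$amino_acid
  if (nrow(x) != 20L) {
    abort_validation("expected a complete 20-row property table")
  }
  mu <- colMeans(x)
  sigma <- apply(x, 2L, pop_sd)
  if (any(sigma == 0)) {
    abort_validation(paste0(
      "zero variance in property column(s): ",
      paste(colnames(x)[sigma == 0], collapse = ", ")
    ))
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sigma, "/")
  structure(list(z = z, mu = mu, sigma = sigma), class = "acp_std_table")
}

## Cached standardized table in the fixed BPF (alphabetical) row order used
## by the encoders. Standardization statistics come from the fixed 20-row
## table, never from training data, so encoding is dataset-independent.
std_quant_matrix <- function() {
  if (is.null(.acplearn_cache$std)) {
    std <- standardize_table(aa_quant_table())
    .acplearn_cache$std <- std
  }
  .acplearn_cache$std
}

## 20 x 10 qualitative one-hot matrix in alphabetical row order. Column
## blocks: hydrophobicity {Y,N} | polarity {Y,N} |
## charge {negative, positive, N} | aromatic-or-aliphatic
## {aromatic, aliphatic, N}. Every block sums to 1 for every amino acid.
qual_onehot_matrix <- function() {
  if (!is.null(.acplearn_cache$qual_mat)) {
    return(.acplearn_cache$qual_mat)
  }
  tbl <- aa_qual_table()
  tbl <- tbl[match(AA_ALPHABET, tbl$amino_acid), ]
  m <- cbind(
    hydrophobicity_Y = as.numeric(tbl$hydrophobicity == "Y"),
    hydrophobicity_N = as.numeric(tbl$hydrophobicity == "N"),
    polarity_Y       = as.numeric(tbl$polarity == "Y"),
    polarity_N       = as.numeric(tbl$polarity == "N"),
    charge_negative  = as.numeric(tbl$charge == "negative"),
    charge_positive  = as.numeric(tbl$charge == "positive"),
    charge_N         = as.numeric(tbl$charge == "N"),
    aromatic         = as.numeric(tbl$aromatic_or_aliphatic == "aromatic"),
    aliphatic        = as.numeric(tbl$aromatic_or_aliphatic == "aliphatic"),
    aroali_N         = as.numeric(tbl$aromatic_or_aliphatic == "N")
  )
  rownames(m) <- AA_ALPHABET
  .acplearn_cache$qual_mat <- m
  m
}
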