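# Shared fixtures, all built in code.

# Trivially separable toy dataset: homopolymer lysine positives vs aspartate
# negatives; class is determined by a single residue identity.
make_separable <- function(n_per_class = 10L, len = 8L) {
  peptide_tbl(
    sprintf("p%02d", seq_len(2L * n_per_class)),
    c(
      replicate(n_per_class, strrep("K", len)),
      replicate(n_per_class, strrep("D", len))
    ),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

# Small config that trains in well under a second.
tiny_config <- function(scheme = "bpf", architecture = "basic", n_units = 8L,
                        dense_units = 8L, epochs = 10L, batch_size = 8L,
                        learning_rate = 0.02, seed = 3L, ...) {
  model_config(
    scheme = scheme, architecture = architecture, n_units = n_units,
    dense_units = dense_units, epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, seed = seed, ...
  )
}

write_temp_fasta <- function(peptides, with_labels = FALSE) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  write_fasta_peptides(peptides, path, with_labels = with_labels)
  path
}
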