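# Small fixture builders shared across test files.

# A toy 2-mer table over a 2-dim space with hand-chosen vectors, used for
# hand-assembled encoding checks.
toy_table_2mer <- function() {
  kmers <- c("AA", "AC", "CA", "GG", "GU")
  mat <- matrix(seq_len(length(kmers) * 2), ncol = 2, byrow = TRUE)
  rownames(mat) <- kmers
  embedding_table(mat)
}

# Complete k-mer table where every k-mer maps to a distinct one-hot-style
# basis vector (dim = 4^k).
one_hot_table <- function(k = 2) {
  kmers <- sort(do.call(paste0,
                        rev(expand.grid(rep(list(c("A", "C", "G", "U")), k),
                                        stringsAsFactors = FALSE))))
  mat <- diag(length(kmers))
  rownames(mat) <- kmers
  embedding_table(mat)
}

# Minimal feature-matrix-shaped list for classifier/mRMR tests that do not
# need real sequence provenance.
toy_feature_matrix <- function(values, labels) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  list(values = values,
       labels = factor(as.character(labels), levels = c("negative", "positive")))
}

# Write a FASTA file from named sequences; returns the path.
write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]), seqs[[i]])
  }
  writeLines(lines, path)
  path
}
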