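#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("position", "count"))

# Canonical RNA normalization: uppercase and DNA->RNA transliteration.
# Datasets for modification sites frequently ship in the DNA alphabet.
normalize_rna <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

RNA_ALPHABET <- c("A", "C", "G", "U")

# Check that every character of every string is in {A,C,G,U} (after
# normalization).  Returns invisibly or stops with the offending string.
check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("alphabet error: %s %d contains characters outside {A,C,G,U}: '%s'",
                 what, i, x[i]), call. = FALSE)
  }
  invisible(x)
}

# Derive a child seed from a master seed and a stream index, staying well
# inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587)
}

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used to stamp outputs so artifacts from different configurations are
# distinguishable without a heavyweight digest dependency.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits, so stay in numeric space
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
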