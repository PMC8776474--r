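#' Construct a k-mer embedding table
#'
#' An embedding table maps every k-mer (over the RNA alphabet A, C, G, U) to
#' a fixed-length real vector, typically learned by a word-embedding method
#' on a genome corpus and consumed here as data.  The default geometry used
#' throughout the package is `k = 4`, `dim = 30`: each 4-mer carries a
#' 30-dimensional vector.
#'
#' @param vectors Numeric matrix with one row per k-mer; row names are the
#'   k-mer tokens (DNA-alphabet tokens are transliterated to RNA).
#' @return An object of class `embedding_table` with fields `k`, `dim` and
#'   `vectors` (the row-named matrix).
#' @examples
#' tab <- embedding_table(matrix(0, 1, 30, dimnames = list("AAAA")))
#' tab$k   # 4
#' tab$dim # 30
#' @export
embedding_table <- function(vectors) {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("argument error: 'vectors' must be a numeric matrix with k-mer row names",
         call. = FALSE)
  }
  tokens <- rownames(vectors)
  if (is.null(tokens) || anyNA(tokens) || any(tokens == "")) {
    stop("argument error: every row of 'vectors' must be named by its k-mer",
         call. = FALSE)
  }
  tokens <- normalize_rna(tokens)
  check_rna_alphabet(tokens, what = "k-mer token")
  if (anyDuplicated(tokens)) {
    dup <- tokens[duplicated(tokens)][1]
    stop(sprintf("duplicate-key error: k-mer '%s' appears more than once", dup),
         call. = FALSE)
  }
  k <- unique(nchar(tokens))
  if (length(k) != 1L) {
    stop("format error: k-mer tokens have inconsistent lengths", call. = FALSE)
  }
  rownames(vectors) <- tokens
  structure(list(k = as.integer(k), dim = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d %d-mers x %d dimensions\n",
              nrow(x$vectors), x$k, x$dim))
  invisible(x)
}

#' Read a k-mer embedding table from whitespace-separated text
#'
#' Each line holds a token followed by its vector components:
#' `TOKEN w1 w2 ... wd`.  An optional first line consisting of exactly two
#' numbers (`count dim`, the word2vec-style header) is detected and skipped.
#' Tokens in the DNA alphabet are transliterated to RNA (T to U).
#'
#' @param path Path to the text file.
#' @param expected_k If given, the token length must equal this value.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path, expected_k = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("format error: empty embedding file: %s", path), call. = FALSE)
  }
  line_no <- seq_along(lines)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]
    line_no <- line_no[-1]
    if (length(lines) == 0L) {
      stop("format error: embedding file contains only a header line", call. = FALSE)
    }
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  d <- nf[1] - 1L
  if (d < 1L) {
    stop(sprintf("format error at line %d: no vector components", line_no[1]),
         call. = FALSE)
  }
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop(sprintf("format error at line %d: expected %d vector components, found %d",
                 line_no[bad[1]], d, nf[bad[1]] - 1L), call. = FALSE)
  }
  tokens <- normalize_rna(vapply(fields, `[`, "", 1L))
  klen <- nchar(tokens[1])
  wrong <- which(nchar(tokens) != klen)
  if (length(wrong)) {
    stop(sprintf("format error at line %d: token '%s' has length %d, expected %d",
                 line_no[wrong[1]], tokens[wrong[1]], nchar(tokens[wrong[1]]), klen),
         call. = FALSE)
  }
  if (!is.null(expected_k) && klen != expected_k) {
    stop(sprintf("format error: token length %d does not match expected k = %d",
                 klen, expected_k), call. = FALSE)
  }
  values <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1]), numeric(d))
  )
  if (anyNA(values)) {
    bad_line <- which(apply(is.na(rbind(values)), 2, any))[1]
    stop(sprintf("format error at line %d: non-numeric vector component",
                 line_no[bad_line]), call. = FALSE)
  }
  mat <- t(rbind(values))
  rownames(mat) <- tokens
  embedding_table(mat)
}

#' Write an embedding table as whitespace-separated text
#'
#' The written dialect is the one [read_embeddings()] consumes: one line per
#' k-mer, token first, then the components at full precision (17 significant
#' digits), space-separated, no header.
#'
#' @param table An [embedding_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  rows <- vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[i],
            sprintf("%.17g", table$vectors[i, ])), collapse = " ")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Look up the embedding vector of a k-mer
#'
#' @param table An [embedding_table()].
#' @param kmer k-mer string (DNA alphabet accepted; transliterated to RNA).
#' @param missing What to do for a k-mer absent from the table: `"error"`
#'   (default) raises a lookup error; `"zero"` substitutes a zero vector.
#' @return Numeric vector of length `table$dim`.
#' @export
lookup_kmer <- function(table, kmer, missing = c("error", "zero")) {
  stopifnot(inherits(table, "embedding_table"))
  missing <- match.arg(missing)
  kmer <- normalize_rna(kmer)
  if (nchar(kmer) != table$k) {
    stop(sprintf("argument error: query '%s' has length %d, table k = %d",
                 kmer, nchar(kmer), table$k), call. = FALSE)
  }
  idx <- match(kmer, rownames(table$vectors))
  if (is.na(idx)) {
    if (missing == "zero") return(numeric(table$dim))
    stop(sprintf("lookup error: k-mer '%s' not present in embedding table", kmer),
         call. = FALSE)
  }
  table$vectors[idx, ]
}
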