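#' Valid k-mer start positions in a centred window
#'
#' Every window shares the same nucleotide (C) at its centre, so k-mers
#' covering the centre carry no discriminative information and are dropped.
#' The remaining start positions — the "slots" — are all `s` in
#' `[1, window_len - k + 1]` whose k-mer `[s, s + k - 1]` does not contain
#' the centre.  For the default 41-nt window with `k = 4` and centre 21
#' this is starts 1..17 and 22..38: 34 slots.
#'
#' @param window_len Window length (default 41).
#' @param k k-mer length (default 4).
#' @param center 1-based centre position (default 21).
#' @return Ascending integer vector of valid 1-based starts.
#' @export
valid_kmer_starts <- function(window_len = 41L, k = 4L, center = 21L) {
  window_len <- as.integer(window_len); k <- as.integer(k); center <- as.integer(center)
  if (center < 1L || center > window_len) {
    stop("argument error: center must lie inside the window", call. = FALSE)
  }
  if (k < 1L || k > window_len) {
    stop("argument error: k must be between 1 and window_len", call. = FALSE)
  }
  starts <- seq_len(window_len - k + 1L)
  starts[!(starts <= center & center <= starts + k - 1L)]
}

#' Describe the full feature space for a window geometry
#'
#' Feature ordering is slot-major: feature indices `(j-1)*dim + 1` ..
#' `j*dim` belong to slot `j` (the j-th valid start, ascending), components
#' 1..dim of its k-mer embedding.  Provenance formulas:
#' `slot = ceiling(index / dim)`, `emb_dim = (index - 1) %% dim + 1`.
#'
#' @param dim Embedding dimensionality.
#' @param starts Ordered valid starts, as from [valid_kmer_starts()].
#' @param k k-mer length.
#' @return A `data.frame` with one row per feature: `index`, `feature_id`
#'   (the `s{slot}d{dim}` label), `slot`, `start`, `emb_dim`, and list
#'   column `covered_positions`.
#' @export
feature_descriptors <- function(dim = 30L, starts = valid_kmer_starts(), k = 4L) {
  n <- length(starts) * dim
  index <- seq_len(n)
  slot <- ceiling(index / dim)
  emb_dim <- (index - 1L) %% dim + 1L
  start <- starts[slot]
  data.frame(index = index,
             feature_id = sprintf("s%dd%d", slot, emb_dim),
             slot = as.integer(slot), start = as.integer(start),
             emb_dim = as.integer(emb_dim),
             covered_positions = I(lapply(start, function(s) seq.int(s, s + k - 1L))),
             stringsAsFactors = FALSE)
}

#' Provenance of a single feature index
#'
#' @param index 1-based feature index in `[1, dim * length(starts)]`.
#' @inheritParams feature_descriptors
#' @return One-row `data.frame` as in [feature_descriptors()].
#' @export
descriptor_for <- function(index, dim = 30L, starts = valid_kmer_starts(), k = 4L) {
  n <- length(starts) * dim
  if (index < 1L || index > n) {
    stop(sprintf("argument error: feature index %d outside [1, %d]", index, n),
         call. = FALSE)
  }
  feature_descriptors(dim = dim, starts = starts, k = k)[index, , drop = FALSE]
}

#' Encode windows into the k-mer embedding feature matrix
#'
#' Each window contributes, for every valid k-mer slot, the full embedding
#' vector of the k-mer starting there.  With 41-nt windows, `k = 4` and a
#' 30-dimensional table this yields the canonical 1020-column
#' (34 slots x 30 dims) matrix.  Column order is slot-major.
#'
#' @param records A [site_records()] table (or any data.frame with columns
#'   `id`, `window`, `label`).
#' @param table An [embedding_table()].
#' @param center 1-based centre position; defaults to the middle of the
#'   window.
#' @param missing Missing-k-mer policy passed to the lookup (`"error"` or
#'   `"zero"`).
#' @return An object of class `feature_matrix`: a list with `values`
#'   (n x p numeric matrix, columns named by feature id), `descriptors`
#'   (see [feature_descriptors()]), `labels` (factor) and the geometry
#'   (`window_len`, `center`, `k`, `dim`, `starts`).
#' @export
encode_windows <- function(records, table, center = NULL,
                           missing = c("error", "zero")) {
  stopifnot(inherits(table, "embedding_table"))
  missing <- match.arg(missing)
  windows <- normalize_rna(records$window)
  n <- length(windows)
  if (n == 0L) stop("argument error: no records to encode", call. = FALSE)
  lens <- unique(nchar(windows))
  if (length(lens) != 1L) {
    stop("argument error: windows have inconsistent lengths", call. = FALSE)
  }
  window_len <- lens
  if (is.null(center)) center <- (window_len + 1L) %/% 2L
  k <- table$k
  starts <- valid_kmer_starts(window_len, k, center)
  desc <- feature_descriptors(dim = table$dim, starts = starts, k = k)

  # gather the k-mer at every (window, slot) pair, then map through the
  # table in one indexed lookup
  kmers <- vapply(starts, function(s) substr(windows, s, s + k - 1L),
                  character(n))
  kmers <- matrix(kmers, nrow = n)   # n x n_slots
  row_idx <- match(kmers, rownames(table$vectors))
  if (anyNA(row_idx)) {
    miss <- which(is.na(row_idx))[1]
    i <- (miss - 1L) %% n + 1L
    j <- (miss - 1L) %/% n + 1L
    if (missing == "error") {
      stop(sprintf("lookup error: record '%s', slot %d (start %d): k-mer '%s' not in embedding table",
                   records$id[i], j, starts[j], kmers[miss]), call. = FALSE)
    }
  }
  n_slots <- length(starts)
  values <- matrix(0, nrow = n, ncol = n_slots * table$dim)
  for (j in seq_len(n_slots)) {
    rows <- row_idx[(j - 1L) * n + seq_len(n)]
    block <- matrix(0, n, table$dim)
    ok <- !is.na(rows)
    block[ok, ] <- table$vectors[rows[ok], , drop = FALSE]
    values[, (j - 1L) * table$dim + seq_len(table$dim)] <- block
  }
  colnames(values) <- desc$feature_id
  rownames(values) <- records$id
  structure(list(values = values, descriptors = desc,
                 labels = factor(as.character(records$label),
                                 levels = c("negative", "positive")),
                 window_len = as.integer(window_len), center = as.integer(center),
                 k = as.integer(k), dim = table$dim, starts = starts),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%d slots x %d dims), centre %d of %d nt\n",
              nrow(x$values), ncol(x$values), length(x$starts), x$dim,
              x$center, x$window_len))
  cat(sprintf("labels: %d positive / %d negative\n",
              sum(x$labels == "positive"), sum(x$labels == "negative")))
  invisible(x)
}

#' Export a feature matrix as TSV with a descriptor sidecar
#'
#' Writes `<prefix>.features.tsv` (header of feature ids, one row per
#' sample, first columns `id` and `label`) and `<prefix>.descriptors.tsv`
#' (index, slot, start, emb_dim, covered positions).
#'
#' @param fm A `feature_matrix`.
#' @param path_prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_feature_matrix <- function(fm, path_prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  fpath <- paste0(path_prefix, ".features.tsv")
  dpath <- paste0(path_prefix, ".descriptors.tsv")
  df <- data.frame(id = rownames(fm$values), label = as.character(fm$labels),
                   fm$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  desc <- fm$descriptors
  desc$covered_positions <- vapply(desc$covered_positions, paste, "",
                                   collapse = ",")
  utils::write.table(desc, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fpath, dpath))
}
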