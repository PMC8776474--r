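#' Specify a plantable motif
#'
#' A motif is a fixed RNA pattern planted at a fixed window position with
#' class-dependent probability: `presence_prob` in positive windows,
#' `background_prob` in negative windows.  The defaults used elsewhere in
#' the package emulate the sequence structure reported downstream of
#' methylated cytosines — a UCCA tetramer immediately 3' of the site and
#' G-rich runs further downstream.
#'
#' @param pattern RNA string (DNA alphabet accepted).
#' @param start 1-based window position of the first pattern base.
#' @param presence_prob Probability the motif is planted in a positive
#'   window.
#' @param background_prob Probability the motif is planted in a negative
#'   window.
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(pattern, start, presence_prob = 1.0,
                       background_prob = 0.05) {
  pattern <- normalize_rna(pattern)
  check_rna_alphabet(pattern, what = "motif pattern")
  if (presence_prob < 0 || presence_prob > 1 ||
      background_prob < 0 || background_prob > 1) {
    stop("argument error: motif probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pattern = pattern, start = as.integer(start),
                 presence_prob = presence_prob,
                 background_prob = background_prob),
            class = "motif_spec")
}

#' Configuration of the synthetic window generator
#'
#' Defaults mirror the benchmark layout the pipeline targets: balanced
#' positive/negative 41-nt windows with the candidate cytosine fixed at
#' position 21, uniform background base composition, and a UCCA motif
#' planted immediately downstream of the site (positions 22-25) in
#' positives.
#'
#' @param n_pos,n_neg Positive / negative sample counts (default 120 each).
#' @param window_len Window length (default 41).
#' @param center Centre position, fixed to C (default 21).
#' @param motifs List of [motif_spec()]s (default: one UCCA at 22).
#' @param base_composition Named probabilities over A, C, G, U (default
#'   uniform); must sum to 1.
#' @param seed Master seed (default 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pos = 120L, n_neg = 120L, window_len = 41L,
                         center = 21L,
                         motifs = list(motif_spec("UCCA", 22L)),
                         base_composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, U = 0.25),
                         seed = 1L) {
  if (n_pos < 0 || n_neg < 0) {
    stop("argument error: sample counts must be nonnegative", call. = FALSE)
  }
  if (abs(sum(base_composition) - 1) > 1e-8) {
    stop("argument error: base_composition must sum to 1", call. = FALSE)
  }
  if (!setequal(names(base_composition), RNA_ALPHABET)) {
    stop("argument error: base_composition must name A, C, G, U", call. = FALSE)
  }
  # validate motif placement and mutual overlap
  spans <- lapply(motifs, function(m) seq.int(m$start, m$start + nchar(m$pattern) - 1L))
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    if (m$start < 1L || m$start + nchar(m$pattern) - 1L > window_len) {
      stop(sprintf("validation error: motif '%s' at %d extends outside the %d-nt window",
                   m$pattern, m$start, window_len), call. = FALSE)
    }
    if (center %in% spans[[i]] &&
        substr(m$pattern, center - m$start + 1L, center - m$start + 1L) != "C") {
      stop(sprintf("validation error: motif '%s' at %d would overwrite the centre C",
                   m$pattern, m$start), call. = FALSE)
    }
  }
  if (length(motifs) > 1L) {
    for (i in seq_len(length(motifs) - 1L)) {
      for (j in seq.int(i + 1L, length(motifs))) {
        if (length(intersect(spans[[i]], spans[[j]]))) {
          stop("validation error: overlapping motifs in the same configuration",
               call. = FALSE)
        }
      }
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_len = as.integer(window_len), center = as.integer(center),
                 motifs = motifs, base_composition = base_composition,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One window under the per-record seed stream: background from the base
# composition, centre forced to C, then motifs planted by their
# class-dependent probabilities.
generate_one_window <- function(config, positive, record_index) {
  set.seed(derive_seed(config$seed, record_index))
  bases <- sample(RNA_ALPHABET, config$window_len, replace = TRUE,
                  prob = config$base_composition[RNA_ALPHABET])
  bases[config$center] <- "C"
  for (m in config$motifs) {
    prob <- if (positive) m$presence_prob else m$background_prob
    if (stats::runif(1) < prob) {
      span <- seq.int(m$start, m$start + nchar(m$pattern) - 1L)
      bases[span] <- strsplit(m$pattern, "")[[1]]
    }
  }
  paste(bases, collapse = "")
}

#' Generate a labelled synthetic window dataset
#'
#' Windows are drawn independently from the background base composition,
#' the centre is fixed to C, and each configured motif is planted with its
#' class-dependent probability.  Negatives come from the same background
#' as positives, so any class signal is fully attributable to the planted
#' motifs.  Generation is seeded per record from the master seed, so a
#' record's sequence is stable under changes to the sample counts before
#' it.
#'
#' @param config A [synth_config()].
#' @return A [site_records()] table with `n_pos + n_neg` rows.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_pos + config$n_neg
  positive <- rep(c(TRUE, FALSE), c(config$n_pos, config$n_neg))
  windows <- vapply(seq_len(n), function(i) {
    generate_one_window(config, positive[i], i)
  }, "")
  if (n == 0L) windows <- character(0)
  ids <- sprintf("%s_%04d", ifelse(positive, "pos", "neg"),
                 c(seq_len(config$n_pos), seq_len(config$n_neg)))
  flank <- (config$window_len - 1L) %/% 2L
  site_records(id = ids, window = windows,
               label = ifelse(positive, "positive", "negative"),
               flank = flank,
               center_check = (config$center == flank + 1L))
}

#' Generate a deterministic synthetic embedding table
#'
#' Two schemes are available.  `"gaussian"` draws every component i.i.d.
#' standard normal.  `"near_orthogonal"` draws unit vectors by seeded
#' rejection sampling so that every pair of distinct k-mer vectors has
#' absolute cosine similarity below `max_cosine` — distinct k-mers are
#' guaranteed to be geometrically separable.
#'
#' @param k k-mer length (all `4^k` k-mers are generated).
#' @param dim Embedding dimensionality.
#' @param scheme `"gaussian"` or `"near_orthogonal"`.
#' @param seed Integer seed.
#' @param max_cosine Bound on pairwise `|cos|` for `"near_orthogonal"`
#'   (default 0.5).
#' @return An [embedding_table()] with `4^k` entries.
#' @export
generate_embeddings <- function(k = 4L, dim = 30L,
                                scheme = c("near_orthogonal", "gaussian"),
                                seed = 1L, max_cosine = 0.5) {
  scheme <- match.arg(scheme)
  if (dim < 1L) stop("argument error: dim must be >= 1", call. = FALSE)
  kmers <- do.call(paste0, rev(expand.grid(rep(list(RNA_ALPHABET), k),
                                           stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  n <- length(kmers)
  set.seed(derive_seed(seed, 0L))
  if (scheme == "gaussian") {
    mat <- matrix(stats::rnorm(n * dim), nrow = n)
  } else {
    mat <- matrix(0, nrow = n, ncol = dim)
    for (i in seq_len(n)) {
      for (attempt in seq_len(2000L)) {
        v <- stats::rnorm(dim)
        v <- v / sqrt(sum(v^2))
        if (i == 1L) break
        cosines <- abs(mat[seq_len(i - 1L), , drop = FALSE] %*% v)
        if (max(cosines) < max_cosine) break
        if (attempt == 2000L) {
          stop(sprintf("unable to place %d near-orthogonal vectors in %d dimensions with |cos| < %g",
                       n, dim, max_cosine), call. = FALSE)
        }
      }
      mat[i, ] <- v
    }
  }
  rownames(mat) <- kmers
  embedding_table(mat)
}

#' Write synthetic inputs in the formats the real pipeline consumes
#'
#' Produces the positive/negative FASTA pair plus the embedding text file,
#' so synthetic and real inputs are interchangeable end to end.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if absent).
#' @param dim Embedding dimensionality.
#' @param scheme Embedding scheme, see [generate_embeddings()].
#' @param k k-mer length for the embedding table.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Named character vector with paths `positive`, `negative`,
#'   `embeddings`.
#' @export
write_synth_inputs <- function(config, dir, dim = 30L,
                               scheme = "near_orthogonal", k = 4L,
                               overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(positive = file.path(dir, "positive.fasta"),
             negative = file.path(dir, "negative.fasta"),
             embeddings = file.path(dir, "embeddings.txt"))
  if (!overwrite && any(file.exists(paths))) {
    stop(sprintf("refusing to overwrite existing file(s) in %s (use overwrite = TRUE)",
                 dir), call. = FALSE)
  }
  records <- generate_dataset(config)
  write_site_fasta(records, paths[["positive"]], paths[["negative"]])
  table <- generate_embeddings(k = k, dim = dim, scheme = scheme,
                               seed = config$seed)
  write_embeddings(table, paths[["embeddings"]])
  paths
}
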