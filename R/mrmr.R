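#' Three-state discretization of a continuous feature
#'
#' Maps each value to one of three states using the feature's own mean and
#' population standard deviation: state -1 below `mu - alpha * sigma`,
#' state +1 above `mu + alpha * sigma`, state 0 inside the closed band
#' (boundary values inclusive).  A constant feature (`sigma = 0`)
#' discretizes to all zeros.  This is the classic preprocessing used by
#' mutual-information feature ranking on continuous data.
#'
#' @param values Numeric vector over samples.
#' @param alpha Band half-width in standard deviations (default 1.0).
#' @return Integer vector of states in {-1, 0, +1}.
#' @export
discretize3 <- function(values, alpha = 1.0) {
  if (length(values) == 0L) {
    stop("argument error: cannot discretize an empty vector", call. = FALSE)
  }
  if (anyNA(values)) stop("argument error: NA in values", call. = FALSE)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))   # population sd
  if (sigma == 0) return(integer(length(values)))
  lo <- mu - alpha * sigma
  hi <- mu + alpha * sigma
  s <- integer(length(values))
  s[values < lo] <- -1L
  s[values > hi] <- 1L
  s
}

# MI (bits) from a joint count table given as a vector of cell counts plus
# the two marginal layouts.  Zero cells contribute zero.
mi_from_counts <- function(counts, n_a, n_b) {
  n <- sum(counts)
  joint <- matrix(counts, nrow = n_a, ncol = n_b)
  pa <- rowSums(joint) / n
  pb <- colSums(joint) / n
  p <- joint / n
  pos <- p > 0
  outer_ab <- outer(pa, pb)
  sum(p[pos] * log2(p[pos] / outer_ab[pos]))
}

# Fast path used by the greedy loop: x, y are integer vectors already coded
# 1..n_a and 1..n_b.
mi_coded <- function(x, y, n_a, n_b) {
  counts <- tabulate((y - 1L) * n_a + x, nbins = n_a * n_b)
  mi_from_counts(counts, n_a, n_b)
}

#' Mutual information of two discrete state vectors
#'
#' Plug-in estimate in bits over the empirical joint distribution:
#' `sum p(a,b) * log2(p(a,b) / (p(a) p(b)))`, with zero-probability cells
#' contributing zero.  `MI(x, x)` equals the empirical entropy of `x`.
#'
#' @param x,y Equal-length vectors of discrete states (any values coercible
#'   to factor levels).
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("argument error: x and y must have equal length", call. = FALSE)
  }
  if (length(x) == 0L) stop("argument error: empty vectors", call. = FALSE)
  xf <- as.integer(factor(x))
  yf <- as.integer(factor(y))
  max(0, mi_coded(xf, yf, max(xf), max(yf)))
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy forward ranking under the difference (MID) criterion.  All
#' features are discretized once up front ([discretize3()]); class labels
#' enter as a two-state discrete variable and are never discretized.  The
#' first pick maximizes relevance `MI(f, c)`; every later pick maximizes
#' `MI(f, c) - mean_g MI(f, g)` over features `g` already in the list.
#' Score ties (within `1e-12` bits) break to the lowest feature index.
#'
#' @param fm A `feature_matrix` from [encode_windows()], or any list with
#'   numeric matrix `values` and factor `labels`.
#' @param n_select Number of features to rank (default: all).
#' @param alpha Discretization band half-width, passed to [discretize3()].
#' @return An object of class `mrmr_ranking`: a `data.frame` with columns
#'   `rank`, `feature`, `feature_id`, `relevance_bits`, `redundancy_bits`,
#'   `difference`.
#' @export
mrmr_rank <- function(fm, n_select = NULL, alpha = 1.0) {
  values <- fm$values
  labels <- fm$labels
  p <- ncol(values)
  n <- nrow(values)
  if (p < 1L) stop("argument error: no features", call. = FALSE)
  if (n < 2L) stop("argument error: need at least 2 samples", call. = FALSE)
  cls <- as.integer(labels)
  if (length(unique(cls)) < 2L) {
    stop("validation error: both classes must be present", call. = FALSE)
  }
  if (is.null(n_select)) n_select <- p
  if (n_select > p) {
    stop(sprintf("argument error: n_select (%d) exceeds number of features (%d)",
                 n_select, p), call. = FALSE)
  }
  tol <- 1e-12

  # discretize every feature once; recode states -1/0/+1 to 1..3
  D <- matrix(0L, n, p)
  for (j in seq_len(p)) D[, j] <- discretize3(values[, j], alpha) + 2L

  relevance <- vapply(seq_len(p), function(j) mi_coded(D[, j], cls, 3L, 2L),
                      numeric(1))

  order_out <- integer(n_select)
  rel_out <- numeric(n_select)
  red_out <- numeric(n_select)
  redsum <- numeric(p)            # cumulative MI to already-ranked features
  in_list <- logical(p)

  pick <- function(score, candidates) {
    best <- max(score)
    candidates[score >= best - tol][1]
  }

  first <- pick(relevance, seq_len(p))
  order_out[1] <- first; rel_out[1] <- relevance[first]; red_out[1] <- 0
  in_list[first] <- TRUE

  for (step in seq_len(n_select)[-1]) {
    last <- order_out[step - 1L]
    remaining <- which(!in_list)
    dl <- D[, last]
    for (j in remaining) {
      redsum[j] <- redsum[j] + mi_coded(D[, j], dl, 3L, 3L)
    }
    meanred <- redsum[remaining] / (step - 1L)
    chosen <- pick(relevance[remaining] - meanred, remaining)
    order_out[step] <- chosen
    rel_out[step] <- relevance[chosen]
    red_out[step] <- redsum[chosen] / (step - 1L)
    in_list[chosen] <- TRUE
  }

  ids <- colnames(values)
  if (is.null(ids)) ids <- as.character(order_out) else ids <- ids[order_out]
  out <- data.frame(rank = seq_len(n_select), feature = order_out,
                    feature_id = ids, relevance_bits = rel_out,
                    redundancy_bits = red_out,
                    difference = rel_out - red_out,
                    stringsAsFactors = FALSE)
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' Write an mRMR ranking as TSV
#'
#' @param ranking An `mrmr_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
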