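# Independent oracles used to cross-check the mRMR implementation.
# These deliberately take a different computational route from the package:
# MI via the entropy decomposition H(x) + H(y) - H(x, y), and the greedy
# ranking recomputed naively (no caching, full redundancy recomputation at
# every step).

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  H(rowSums(tab) / n) + H(colSums(tab) / n) - H(as.vector(tab) / n)
}

oracle_discretize <- function(v, alpha = 1) {
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) return(rep(0L, length(v)))
  ifelse(v < mu - alpha * s, -1L, ifelse(v > mu + alpha * s, 1L, 0L))
}

# Naive O(p^2 * steps) greedy difference-criterion ranking; ties within
# 1e-12 bits break to the lowest feature index.
oracle_mrmr <- function(values, labels, alpha = 1) {
  disc <- apply(values, 2, oracle_discretize, alpha = alpha)
  cls <- ifelse(as.character(labels) == "positive", 1L, -1L)
  p <- ncol(values)
  rel <- vapply(seq_len(p), function(j) oracle_mi(disc[, j], cls), numeric(1))
  picked <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    scores <- vapply(remaining, function(j) {
      red <- if (length(picked)) {
        mean(vapply(picked, function(g) oracle_mi(disc[, j], disc[, g]),
                    numeric(1)))
      } else 0
      rel[j] - red
    }, numeric(1))
    cand <- remaining[scores >= max(scores) - 1e-12]
    choice <- min(cand)
    picked <- c(picked, choice)
    remaining <- setdiff(remaining, choice)
  }
  picked
}
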