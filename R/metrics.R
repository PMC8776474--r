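#' Confusion counts
#'
#' Counts are real-valued, not integer, so rate-scaled counts (e.g. a row
#' reported as SN/SP on a balanced benchmark: TP = SN, FN = 1 - SN,
#' TN = SP, FP = 1 - SP) are admissible — every derived metric is invariant
#' to a positive rescaling of the whole table.
#'
#' @param TP,TN,FP,FN Nonnegative true/false positive/negative counts.
#' @return A named list of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("argument error: negative confusion counts", call. = FALSE)
  if (sum(v) == 0) stop("argument error: all-zero confusion counts", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

# Pool predicted/true factor vectors into counts.
pool_confusion <- function(truth, predicted, positive = "positive") {
  confusion_counts(TP = sum(truth == positive & predicted == positive),
                   TN = sum(truth != positive & predicted != positive),
                   FP = sum(truth != positive & predicted == positive),
                   FN = sum(truth == positive & predicted != positive))
}

#' The six performance measures from a confusion table
#'
#' Sensitivity `SN = TP/(TP+FN)` (recall), specificity `SP = TN/(TN+FP)`,
#' accuracy `ACC = (TP+TN)/total`, Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, precision
#' `TP/(TP+FP)` and `F1 = 2 * recall * precision / (recall + precision)`.
#' Any measure whose denominator is zero is defined as 0 (MCC included).
#'
#' @param counts A [confusion_counts()] (or list with TP, TN, FP, FN).
#' @return Named numeric vector of class `metric_set` with elements
#'   `SN`, `SP`, `ACC`, `MCC`, `precision`, `F1`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) {
    stop("argument error: negative confusion counts", call. = FALSE)
  }
  total <- TP + TN + FP + FN
  if (total == 0) stop("argument error: all-zero confusion counts", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  SN <- safe_div(TP, TP + FN)
  SP <- safe_div(TN, TN + FP)
  ACC <- (TP + TN) / total
  precision <- safe_div(TP, TP + FP)
  F1 <- safe_div(2 * SN * precision, SN + precision)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- safe_div(TP * TN - FP * FN, mcc_den)
  structure(c(SN = SN, SP = SP, ACC = ACC, MCC = MCC,
              precision = precision, F1 = F1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}
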