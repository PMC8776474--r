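#' Build a validated table of labelled candidate-site windows
#'
#' A site record is one fixed-width RNA window with the candidate cytosine
#' at its centre: with the default flank of 20 nt the window is 41 nt long
#' and the site sits at position 21 (1-based).  Both positive (modified)
#' and negative (unmodified) candidate sites are cytosines, so the centre
#' check applies to both labels by default.
#'
#' @param id Character vector of record identifiers.
#' @param window Character vector of RNA windows (DNA alphabet accepted).
#' @param label Character/factor vector with values `"positive"` /
#'   `"negative"`.
#' @param flank Number of nucleotides on each side of the centre site
#'   (window length is `2 * flank + 1`).
#' @param center_check If `TRUE` (default), require the centre character of
#'   every window to be C.
#' @param source_position Optional 1-based coordinate of the centre site in
#'   its source sequence.
#' @return A `data.frame` of class `site_records` with columns `id`,
#'   `window`, `label` (factor, levels `negative`/`positive`) and
#'   `source_position`; attribute `flank` records the half-width.
#' @export
site_records <- function(id, window, label, flank = 20L, center_check = TRUE,
                         source_position = NA_integer_) {
  window <- normalize_rna(window)
  n <- length(window)
  stopifnot(length(id) == n)
  width <- 2L * as.integer(flank) + 1L
  wrong <- which(nchar(window) != width)
  if (length(wrong)) {
    stop(sprintf("format error: record '%s' has window length %d, expected %d",
                 id[wrong[1]], nchar(window[wrong[1]]), width), call. = FALSE)
  }
  if (n > 0) check_rna_alphabet(window, what = "window")
  label <- as.character(label)
  if (n > 0 && !all(label %in% c("positive", "negative"))) {
    stop("argument error: labels must be 'positive' or 'negative'", call. = FALSE)
  }
  if (center_check && n > 0) {
    centre <- substr(window, flank + 1L, flank + 1L)
    bad <- which(centre != "C")
    if (length(bad)) {
      stop(sprintf("validation error: record '%s' has '%s' at the centre position %d; expected C",
                   id[bad[1]], centre[bad[1]], flank + 1L), call. = FALSE)
    }
  }
  out <- data.frame(id = as.character(id), window = window,
                    label = factor(label, levels = c("negative", "positive")),
                    source_position = rep_len(as.integer(source_position), n),
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("site_records", "data.frame")
  out
}

#' Extract a fixed-flank window around a site
#'
#' Cuts the subsequence running from `position - flank` to
#' `position + flank` (1-based, inclusive) so the site of interest sits at
#' the centre of a `2 * flank + 1` nt window.
#'
#' @param sequence RNA (or DNA) string.
#' @param position 1-based coordinate of the site.
#' @param flank Nucleotides to keep on each side (default 20, for 41-nt
#'   windows).
#' @return The window string (normalized to RNA alphabet).
#' @export
extract_window <- function(sequence, position, flank = 20L) {
  sequence <- normalize_rna(sequence)
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    stop(sprintf("argument error: position %d outside sequence of length %d",
                 position, len), call. = FALSE)
  }
  up_deficit <- flank - (position - 1L)
  down_deficit <- flank - (len - position)
  if (up_deficit > 0L || down_deficit > 0L) {
    stop(sprintf(paste0("boundary error: position %d needs %d nt on each side ",
                        "(short by %d upstream, %d downstream)"),
                 position, flank, max(up_deficit, 0L), max(down_deficit, 0L)),
         call. = FALSE)
  }
  substr(sequence, position - flank, position + flank)
}

# Read one FASTA file into a character vector of sequences named by record
# id.  A missing, empty, or whitespace-only file yields zero records.
read_fasta_windows <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  info <- file.info(path)
  raw <- readLines(path, warn = FALSE)
  if (info$size == 0 || !any(nzchar(trimws(raw)))) {
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read positive/negative candidate-site FASTA files
#'
#' The conventional layout for candidate-site benchmarks is a pair of FASTA
#' files, one of experimentally supported (positive) sites and one of
#' unmodified (negative) sites, each record a pre-cut window of
#' `2 * flank + 1` nt with the candidate cytosine at the centre.
#'
#' @param positive_path,negative_path FASTA paths for the two classes.
#' @inheritParams site_records
#' @return A [site_records()] table with one row per input record, labelled
#'   by source file.
#' @export
read_site_fasta <- function(positive_path, negative_path, flank = 20L,
                            center_check = TRUE) {
  pos <- read_fasta_windows(positive_path)
  neg <- read_fasta_windows(negative_path)
  site_records(id = c(names(pos), names(neg)),
               window = c(unname(pos), unname(neg)),
               label = rep(c("positive", "negative"), c(length(pos), length(neg))),
               flank = flank, center_check = center_check)
}

#' Read a single labelled FASTA with labels in the headers
#'
#' Plumbing for the single-file convention where each header carries a
#' `label=1` (positive) or `label=0` (negative) field.
#'
#' @param path FASTA path.
#' @inheritParams site_records
#' @return A [site_records()] table.
#' @export
read_labeled_fasta <- function(path, flank = 20L, center_check = TRUE) {
  info <- file.info(path)
  if (is.na(info$size)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (info$size == 0 || !any(nzchar(trimws(raw)))) {
    return(site_records(character(0), character(0), character(0), flank = flank))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  m <- regmatches(headers, regexpr("label=[01]", headers))
  if (length(m) != length(set)) {
    missing_lab <- which(!grepl("label=[01]", headers))[1]
    stop(sprintf("format error: record '%s' has no label=1|0 field in its header",
                 sub("\\s.*$", "", headers[missing_lab])), call. = FALSE)
  }
  site_records(id = sub("\\s.*$", "", headers),
               window = as.character(set),
               label = ifelse(m == "label=1", "positive", "negative"),
               flank = flank, center_check = center_check)
}

#' Write site records as a positive/negative FASTA pair
#'
#' @param records A [site_records()] table.
#' @param positive_path,negative_path Output FASTA paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_site_fasta <- function(records, positive_path, negative_path) {
  stopifnot(inherits(records, "site_records"))
  for (side in c("positive", "negative")) {
    sub <- records[records$label == side, , drop = FALSE]
    path <- if (side == "positive") positive_path else negative_path
    set <- Biostrings::RNAStringSet(sub$window)
    names(set) <- sub$id
    Biostrings::writeXStringSet(set, path, width = 80L)
  }
  invisible(c(positive_path, negative_path))
}
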