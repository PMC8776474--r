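#' Run the full site-analysis pipeline
#'
#' End-to-end orchestration of the analysis: read the positive/negative
#' window FASTA pair and the k-mer embedding table, encode windows into the
#' slot-major feature matrix, rank features by mRMR, run incremental
#' feature selection for each requested classifier family under stratified
#' cross-validation, and map each optimum model's features back to window
#' positions.  All artifacts are written under `out_dir` together with a
#' machine-readable JSON manifest (inputs, configuration, seed, package
#' version, configuration hash); every TSV carries the configuration hash
#' in a leading comment line so artifacts from different runs are
#' distinguishable.
#'
#' @param positive_path,negative_path FASTA paths of the two classes.
#' @param embeddings_path Whitespace-separated embedding table path.
#' @param out_dir Output directory (created if absent).
#' @param families Character vector of classifier families to evaluate
#'   (default all four).
#' @param flank Window half-width (default 20).
#' @param alpha mRMR discretization band half-width.
#' @param n_folds Cross-validation folds (default 10).
#' @param max_size Largest ranked prefix to evaluate (default 50; raise to
#'   `NULL` to evaluate every prefix of the ranking).
#' @param n_rank How many features to rank with mRMR (default:
#'   `max_size`, or all features when `max_size` is `NULL`).
#' @param seed Seed for fold construction and classifier randomness.
#' @param center_check Require C at the window centre (default `TRUE`).
#' @param plot_ext Bar-chart format (default `"png"`).
#' @return Invisibly, a list with the feature matrix, the ranking, the
#'   per-family `ifs_result`s, the per-family `position_frequency` tables,
#'   and the manifest.
#' @export
run_m5c_pipeline <- function(positive_path, negative_path, embeddings_path,
                             out_dir,
                             families = c("decision_tree", "knn",
                                          "random_forest", "svm"),
                             flank = 20L, alpha = 1.0, n_folds = 10L,
                             max_size = 50L, n_rank = NULL, seed = 1L,
                             center_check = TRUE, plot_ext = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_site_fasta(positive_path, negative_path, flank = flank,
                             center_check = center_check)
  table <- read_embeddings(embeddings_path)
  fm <- encode_windows(records, table)

  if (is.null(n_rank)) {
    n_rank <- if (is.null(max_size)) ncol(fm$values) else max_size
  }
  ranking <- mrmr_rank(fm, n_select = n_rank, alpha = alpha)

  config <- list(positive = positive_path, negative = negative_path,
                 embeddings = embeddings_path, families = families,
                 flank = flank, alpha = alpha, n_folds = n_folds,
                 max_size = max_size, n_rank = n_rank, seed = seed,
                 center_check = center_check)
  hash <- fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE))
  stamp <- function(path) {
    content <- readLines(path)
    writeLines(c(sprintf("# config_hash=%s seed=%d", hash, seed), content), path)
  }

  write_ranked_list(ranking, file.path(out_dir, "mrmr_ranking.tsv"))
  stamp(file.path(out_dir, "mrmr_ranking.tsv"))

  cv <- cv_config(n_folds = n_folds, seed = seed)
  ifs_results <- list()
  freqs <- list()
  for (family in families) {
    spec <- classifier_spec(family)
    res <- run_ifs(fm, ranking, spec = spec, cv = cv, max_size = max_size)
    ifs_results[[family]] <- res
    ifs_path <- file.path(out_dir, sprintf("ifs_%s.tsv", family))
    write_ifs_table(res, ifs_path,
                    optimum_path = file.path(out_dir,
                                             sprintf("optimum_%s.tsv", family)))
    stamp(ifs_path)
    selected <- fm$descriptors[ranking$feature[seq_len(attr(res, "optimum_size"))], ]
    freq <- position_frequencies(selected, window_len = fm$window_len)
    freqs[[family]] <- freq
    write_frequency_outputs(freq,
                            file.path(out_dir, sprintf("sitefreq_%s", family)),
                            ext = plot_ext)
    stamp(file.path(out_dir, sprintf("sitefreq_%s.tsv", family)))
  }

  manifest <- list(config = config, config_hash = hash,
                   n_samples = nrow(fm$values), n_features = ncol(fm$values),
                   package_version = as.character(utils::packageVersion("m5Cselect")),
                   optimum_sizes = lapply(ifs_results,
                                          function(r) attr(r, "optimum_size")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(feature_matrix = fm, ranking = ranking, ifs = ifs_results,
                 frequencies = freqs, manifest = manifest))
}
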