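#' Run the full cleavage-site prediction pipeline on a scenario bundle
#'
#' Encodes training and test windows, ranks features by mRMR, scans
#' nested prefixes by cross-validated incremental feature selection,
#' picks the optimal feature set, and evaluates it on the held-out
#' proteins.  The position-specific frequency table is built once from
#' all training positives before cross-validation (the classical scheme);
#' set \code{fold_safe_freq = TRUE} to rebuild it inside each CV training
#' fold instead, removing that mild leakage at the cost of a different
#' (slightly pessimistic) CV estimate.
#'
#' @param bundle a scenario bundle as returned by
#'   \code{\link{default_scenario}} (window lists plus providers), or any
#'   list with the same components.
#' @param k cross-validation folds (default 5).
#' @param seed integer seed for fold assignment and forest training.
#' @param max_prefix largest IFS prefix to scan (default 60).
#' @param step IFS scan step after the first \code{dense_until} prefixes.
#' @param dense_until scan every prefix size up to this value, then every
#'   \code{step} (keeps the scan cheap without missing the early rise of
#'   the MCC curve).
#' @param config a \code{\link{forest_config}}.
#' @param fold_safe_freq rebuild the frequency table within each CV fold.
#' @return List with \code{freq_table}, \code{train_fm}, \code{test_fm},
#'   \code{ranked}, \code{ifs}, \code{optimal}, \code{holdout}
#'   (a \code{metric_set}) and \code{summary} (family/site tallies).
#' @export
run_pipeline <- function(bundle, k = 5L, seed = 1L,
                         max_prefix = 60L, step = 4L, dense_until = 12L,
                         config = forest_config(seed = seed),
                         fold_safe_freq = FALSE) {
  freq <- build_frequency_table(bundle$train_positives)
  train_windows <- c(bundle$train_positives, bundle$train_negatives)
  test_windows <- c(bundle$test_positives, bundle$test_negatives)
  train_fm <- encode_windows(train_windows, bundle$providers, freq)
  test_fm <- encode_windows(test_windows, bundle$providers, freq)
  D <- discretize(train_fm)
  ranked <- mrmr_ranking(D, train_fm$meta$label, n_select = max_prefix)
  sizes_step <- max(1L, as.integer(step))
  ifs <- run_ifs_scan(train_fm, ranked, k = k, seed = seed,
                      max_prefix = max_prefix, step = sizes_step,
                      dense_until = dense_until, config = config,
                      fold_safe_freq = fold_safe_freq,
                      bundle = bundle)
  optimal <- select_optimal(ifs)
  holdout <- evaluate_holdout(train_fm, test_fm, optimal, config)
  list(freq_table = freq,
       train_fm = train_fm,
       test_fm = test_fm,
       ranked = ranked,
       ifs = ifs,
       optimal = optimal,
       holdout = holdout,
       summary = summarize_optimal_features(optimal,
                                            W = train_fm$window_size))
}

# Two-phase IFS scan: every prefix up to dense_until, then strided.
run_ifs_scan <- function(train_fm, ranked, k, seed, max_prefix, step,
                         dense_until, config, fold_safe_freq = FALSE,
                         bundle = NULL) {
  if (fold_safe_freq) {
    return(run_ifs_fold_safe(bundle, ranked, k = k, seed = seed,
                             max_prefix = max_prefix, step = step,
                             dense_until = dense_until, config = config))
  }
  feats <- ranked$mrmr$feature
  max_prefix <- min(max_prefix, length(feats))
  sizes <- unique(c(seq_len(min(dense_until, max_prefix)),
                    seq(min(dense_until, max_prefix), max_prefix, by = step),
                    max_prefix))
  rows <- lapply(sizes, function(i) {
    m <- compute_metrics(crossval_confusion(train_fm, feats[seq_len(i)],
                                            k = k, seed = seed,
                                            config = config))
    data.frame(i = i, Sn = m$Sn, Sp = m$Sp, Ac = m$Ac, MCC = m$MCC)
  })
  out <- do.call(rbind, rows)
  attr(out, "features") <- feats
  class(out) <- c("ifs_table", "data.frame")
  out
}

# Leakage-free variant: the frequency table (the only feature family that
# depends on the training labels) is rebuilt from the positives of the CV
# training folds, and the fold's held-out windows are re-encoded with it.
run_ifs_fold_safe <- function(bundle, ranked, k, seed, max_prefix, step,
                              dense_until, config) {
  feats <- ranked$mrmr$feature
  max_prefix <- min(max_prefix, length(feats))
  sizes <- unique(c(seq_len(min(dense_until, max_prefix)),
                    seq(min(dense_until, max_prefix), max_prefix, by = step),
                    max_prefix))
  windows <- c(bundle$train_positives, bundle$train_negatives)
  labels <- factor(vapply(windows, `[[`, character(1L), "label"),
                   levels = c("negative", "positive"))
  fold <- stratified_folds(labels, k, seed)
  fold_fms <- lapply(seq_len(k), function(f) {
    pos_tr <- windows[fold != f &
                        vapply(windows, `[[`, character(1L),
                               "label") == "positive"]
    freq_f <- build_frequency_table(pos_tr)
    list(train = encode_windows(windows[fold != f], bundle$providers, freq_f),
         test = encode_windows(windows[fold == f], bundle$providers, freq_f))
  })
  rows <- lapply(sizes, function(i) {
    sel <- feats[seq_len(i)]
    tp <- tn <- fp <- fn <- 0L
    for (f in seq_len(k)) {
      cfg <- config
      cfg$seed <- config$seed + f
      fm <- fold_fms[[f]]
      model <- train_forest(subset_features(fm$train, sel)$features,
                            fm$train$meta$label, cfg)
      pred <- predict(model, subset_features(fm$test, sel)$features)
      truth <- factor(fm$test$meta$label, levels = c("negative", "positive"))
      tp <- tp + sum(pred == "positive" & truth == "positive")
      tn <- tn + sum(pred == "negative" & truth == "negative")
      fp <- fp + sum(pred == "positive" & truth == "negative")
      fn <- fn + sum(pred == "negative" & truth == "positive")
    }
    m <- compute_metrics(confusion_counts(tp, tn, fp, fn))
    data.frame(i = i, Sn = m$Sn, Sp = m$Sp, Ac = m$Ac, MCC = m$MCC)
  })
  out <- do.call(rbind, rows)
  attr(out, "features") <- feats
  class(out) <- c("ifs_table", "data.frame")
  out
}
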