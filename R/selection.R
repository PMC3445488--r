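#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts (sum > 0).
#' @return An object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || sum(v) == 0) {
    stop("confusion counts must be non-negative with positive total",
         call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Classification metrics from a confusion table
#'
#' Sensitivity Sn = TP / (TP + FN), specificity Sp = TN / (TN + FP),
#' accuracy Ac = (TP + TN) / total, and the Matthews correlation
#' coefficient
#' \code{MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}.
#' When any MCC denominator factor is zero, MCC is defined as 0 with a
#' warning (the standard convention); Sn or Sp with a zero denominator is
#' reported as \code{NA}.
#'
#' @param counts a \code{confusion_counts} (or list with TP, TN, FP, FN).
#' @return A \code{metric_set}: list with Sn, Sp, Ac (proportions in
#'   [0, 1]) and MCC in [-1, 1]; the source counts are kept in attribute
#'   \code{"counts"}.
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  Ac <- (TP + TN) / (TP + TN + FP + FN)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom == 0) {
    warning("an MCC denominator factor is zero; defining MCC = 0")
    MCC <- 0
  } else {
    MCC <- (TP * TN - FP * FN) / sqrt(denom)
  }
  structure(list(Sn = Sn, Sp = Sp, Ac = Ac, MCC = MCC),
            counts = counts, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn %.2f%%  Sp %.2f%%  Ac %.2f%%  MCC %.4f\n",
              100 * x$Sn, 100 * x$Sp, 100 * x$Ac, x$MCC))
  invisible(x)
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into k folds, so every fold keeps the class balance.
stratified_folds <- function(labels, k, seed) {
  f <- as.factor(labels)
  if (any(table(f) < k)) {
    stop("each class needs at least k members for stratified k-fold CV",
         call. = FALSE)
  }
  fold <- integer(length(f))
  with_seed(seed, {
    for (lev in levels(f)) {
      idx <- which(f == lev)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated confusion counts for a feature subset
#'
#' Stratified k-fold cross-validation: each window is predicted exactly
#' once by a random forest trained on the other folds, restricted to the
#' given features; counts are pooled over folds.  Deterministic under
#' \code{seed} (fold assignment and per-fold forest seeds both derive
#' from it).
#'
#' @param fm a \code{feature_matrix}.
#' @param feature_subset character vector of feature names to use.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param config a \code{\link{forest_config}}.
#' @return A \code{confusion_counts} with \code{TP + TN + FP + FN} equal
#'   to the number of windows.
#' @export
crossval_confusion <- function(fm, feature_subset, k = 5L, seed = 1L,
                               config = forest_config()) {
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  labels <- factor(fm$meta$label, levels = c("negative", "positive"))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  x <- subset_features(fm, feature_subset)$features
  fold <- stratified_folds(labels, k, seed)
  tp <- tn <- fp <- fn <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_forest(x[tr, , drop = FALSE], labels[tr], cfg)
    pred <- predict(model, x[!tr, , drop = FALSE])
    truth <- labels[!tr]
    tp <- tp + sum(pred == "positive" & truth == "positive")
    tn <- tn + sum(pred == "negative" & truth == "negative")
    fp <- fp + sum(pred == "positive" & truth == "negative")
    fn <- fn + sum(pred == "negative" & truth == "positive")
  }
  confusion_counts(tp, tn, fp, fn)
}

#' Incremental feature selection (IFS)
#'
#' Evaluates nested prefixes of the mRMR-ranked feature list: the i-th
#' candidate set consists of the first i ranked features, so consecutive
#' sets are nested.  Each prefix is scored by cross-validated random
#' forests and its Sn/Sp/Ac/MCC recorded.  Fold assignment is shared
#' across prefixes (same seed), so rows are directly comparable and a
#' capped run equals the matching rows of an uncapped run.
#'
#' @param fm a \code{feature_matrix}.
#' @param ranked a \code{ranked_features} (its mRMR order is used) or a
#'   character vector of ranked feature names.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param max_prefix largest prefix size to evaluate (default: all ranked
#'   features; values beyond the ranking length are clipped with a
#'   warning).
#' @param step evaluate prefix sizes 1, 1 + step, ... (default 1,
#'   the exhaustive one-by-one scan; larger steps give a coarse scan).
#'   \code{max_prefix} is always included as the final row.
#' @param config a \code{\link{forest_config}}.
#' @return An \code{ifs_table}: data.frame (i, Sn, Sp, Ac, MCC) with the
#'   ranked feature names in attribute \code{"features"}.
#' @export
run_ifs <- function(fm, ranked, k = 5L, seed = 1L, max_prefix = NULL,
                    step = 1L, config = forest_config()) {
  feats <- if (inherits(ranked, "ranked_features")) ranked$mrmr$feature
           else as.character(ranked)
  N <- length(feats)
  max_prefix <- as.integer(max_prefix %||% N)
  if (max_prefix > N) {
    warning(sprintf("max_prefix %d exceeds the %d ranked features; clipping",
                    max_prefix, N))
    max_prefix <- N
  }
  sizes <- unique(c(seq(1L, max_prefix, by = as.integer(step)), max_prefix))
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    i <- sizes[si]
    m <- compute_metrics(crossval_confusion(fm, feats[seq_len(i)],
                                            k = k, seed = seed,
                                            config = config))
    rows[[si]] <- data.frame(i = i, Sn = m$Sn, Sp = m$Sp, Ac = m$Ac,
                             MCC = m$MCC)
  }
  out <- do.call(rbind, rows)
  attr(out, "features") <- feats
  class(out) <- c("ifs_table", "data.frame")
  out
}

#' Choose the optimal feature set from an IFS table
#'
#' The optimal prefix maximizes cross-validated MCC; ties go to the
#' smallest prefix (parsimony).
#'
#' @param table an \code{ifs_table}.
#' @return An \code{optimal_feature_set}: list with \code{features}
#'   (names, in ranked order), \code{size} and the achieved \code{metrics}.
#' @export
select_optimal <- function(table) {
  if (nrow(table) == 0L) stop("empty IFS table", call. = FALSE)
  feats <- attr(table, "features")
  best <- which(table$MCC == max(table$MCC))
  best <- best[which.min(table$i[best])]
  size <- table$i[best]
  structure(list(features = feats[seq_len(size)],
                 size = size,
                 metrics = structure(list(Sn = table$Sn[best],
                                          Sp = table$Sp[best],
                                          Ac = table$Ac[best],
                                          MCC = table$MCC[best]),
                                     class = "metric_set")),
            class = "optimal_feature_set")
}

#' @export
print.optimal_feature_set <- function(x, ...) {
  cat(sprintf("<optimal_feature_set> %d features; CV ", x$size))
  print(x$metrics)
  invisible(x)
}

#' Tally an optimal feature set by family, window site and PSSM column
#'
#' Decomposes the selected feature names into (a) counts per feature
#' family, (b) counts per window site, and (c), for PSSM features, counts
#' per target amino acid of the conservation column.
#'
#' @param optimal an \code{optimal_feature_set}, a \code{ranked_features}
#'   prefix, or a character vector of feature names.
#' @param W window size for the site tally (default: largest site seen).
#' @return List with \code{family} (named counts over the 6 families),
#'   \code{site} (named counts over sites 1..W) and \code{pssm_aa} (named
#'   counts over the 20 amino acids).
#' @export
summarize_optimal_features <- function(optimal, W = NULL) {
  feats <- if (inherits(optimal, "optimal_feature_set")) optimal$features
           else as.character(optimal)
  parsed <- parse_feature_name(feats)
  W <- as.integer(W %||% max(parsed$site))
  tally <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(as.integer(tab), names(tab))
  }
  list(family = tally(parsed$family, FEATURE_FAMILIES),
       site = tally(parsed$site, seq_len(W)),
       pssm_aa = tally(PSSM_COLUMNS[parsed$k[parsed$family == "pssm"]],
                       PSSM_COLUMNS))
}
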