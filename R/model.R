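#' Random-forest configuration
#'
#' Each tree is grown on a with-replacement bootstrap resample of the
#' training windows, considering \code{m_try} randomly chosen variables
#' per split, fully grown and not pruned.  By default
#' \code{m_try = floor(log2(M)) + 1} for M candidate features, a value
#' much smaller than M.
#'
#' @param n_trees number of trees (default 100; set 10 for the leaner
#'   behaviour of older toolkits).
#' @param m_try variables tried per split; \code{NULL} (default) uses
#'   \code{floor(log2(M)) + 1} at training time.
#' @param seed integer seed for the forest's randomness.
#' @return An object of class \code{forest_config}.
#' @export
forest_config <- function(n_trees = 100L, m_try = NULL, seed = 1L) {
  if (n_trees < 1L) stop("'n_trees' must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 m_try = if (is.null(m_try)) NULL else as.integer(m_try),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a random forest on a feature subset
#'
#' Deterministic under \code{config$seed}; the fitted model stores the
#' feature names it was trained on and refuses prediction inputs whose
#' columns do not match.
#'
#' @param x numeric matrix (windows x features) with column names.
#' @param labels factor/character labels with classes \code{negative} and
#'   \code{positive}.
#' @param config a \code{\link{forest_config}}.
#' @return A \code{cleave_model}.
#' @export
train_forest <- function(x, labels, config = forest_config()) {
  labels <- factor(labels, levels = c("negative", "positive"))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  if (is.null(colnames(x))) stop("'x' must have column names", call. = FALSE)
  M <- ncol(x)
  m_try <- min(M, config$m_try %||% (floor(log2(M)) + 1L))
  forest <- with_seed(config$seed,
    randomForest::randomForest(x = x, y = labels,
                               ntree = config$n_trees,
                               mtry = m_try,
                               replace = TRUE))
  structure(list(forest = forest,
                 features = colnames(x),
                 config = config,
                 m_try = m_try,
                 class_prior = as.numeric(table(labels) / length(labels))),
            class = "cleave_model")
}

#' @export
print.cleave_model <- function(x, ...) {
  cat(sprintf("<cleave_model> %d trees, m_try = %d, %d features\n",
              x$config$n_trees, x$m_try, length(x$features)))
  invisible(x)
}

#' Predict cleavage labels by majority vote
#'
#' Each tree votes; the class with most votes wins, and an exact vote tie
#' (possible with an even number of trees) resolves to the positive
#' class.  Columns are matched by name, so reordering the input columns
#' does not change predictions; missing or extra columns raise a schema
#' error naming them.
#'
#' @param object a \code{cleave_model}.
#' @param newdata numeric matrix with named columns.
#' @param ... unused.
#' @return Factor of predicted labels (\code{negative}/\code{positive}).
#' @export
predict.cleave_model <- function(object, newdata, ...) {
  lv <- c("negative", "positive")
  if (nrow(newdata) == 0L) return(factor(character(0), levels = lv))
  missing <- setdiff(object$features, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$features)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop(sprintf("feature schema mismatch; missing: [%s] extra: [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  votes <- stats::predict(object$forest,
                          newdata[, object$features, drop = FALSE],
                          type = "vote", norm.votes = TRUE)
  factor(ifelse(votes[, "positive"] >= votes[, "negative"],
                "positive", "negative"),
         levels = lv)
}

#' Final train-on-train / evaluate-on-test report
#'
#' Trains one forest on all training windows restricted to the optimal
#' feature set and reports Sn/Sp/Ac/MCC on the held-out windows.  The
#' training and test windows must come from disjoint protein sets; any
#' overlap raises a leakage error.
#'
#' @param train_fm,test_fm \code{feature_matrix} objects for the training
#'   and held-out windows.
#' @param optimal an \code{optimal_feature_set} (or character vector of
#'   feature names).
#' @param config a \code{\link{forest_config}}.
#' @return A \code{metric_set} with the holdout confusion counts in
#'   attribute \code{"counts"} and the trained model in attribute
#'   \code{"model"}.
#' @export
evaluate_holdout <- function(train_fm, test_fm, optimal,
                             config = forest_config()) {
  overlap <- intersect(unique(train_fm$meta$accession),
                       unique(test_fm$meta$accession))
  if (length(overlap) > 0L) {
    stop("protein leakage between train and test splits: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  feats <- if (inherits(optimal, "optimal_feature_set")) optimal$features
           else as.character(optimal)
  model <- train_forest(subset_features(train_fm, feats)$features,
                        train_fm$meta$label, config)
  pred <- predict(model, subset_features(test_fm, feats)$features)
  truth <- factor(test_fm$meta$label, levels = c("negative", "positive"))
  counts <- confusion_counts(
    TP = sum(pred == "positive" & truth == "positive"),
    TN = sum(pred == "negative" & truth == "negative"),
    FP = sum(pred == "positive" & truth == "negative"),
    FN = sum(pred == "negative" & truth == "positive"))
  out <- compute_metrics(counts)
  attr(out, "model") <- model
  out
}
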