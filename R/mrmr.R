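#' Discretize a feature matrix for mutual-information estimation
#'
#' Continuous columns are binned into 3 states by the thresholds
#' \code{mean - alpha * sd} and \code{mean + alpha * sd} (plug-in mutual
#' information needs discrete states).  Columns already taking values in
#' \{0, 1\} (the one-hot accessibility / secondary-structure indicators)
#' pass through unchanged as 2 states; constant columns collapse to the
#' single state 0 and carry zero relevance by definition.
#'
#' @param x numeric matrix or \code{feature_matrix}.
#' @param alpha positive multiplier of the per-column standard deviation
#'   (default 1).
#' @return A \code{discretized_matrix}: list with \code{states} (integer
#'   matrix, states \code{0 .. n_states - 1}), \code{n_states} and
#'   per-column \code{thresholds}.
#' @export
discretize <- function(x, alpha = 1) {
  if (inherits(x, "feature_matrix")) x <- x$features
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be a single positive number", call. = FALSE)
  }
  n <- ncol(x)
  states <- matrix(0L, nrow = nrow(x), ncol = n,
                   dimnames = dimnames(x))
  n_states <- integer(n)
  thresholds <- vector("list", n)
  for (j in seq_len(n)) {
    v <- x[, j]
    u <- unique(v)
    if (length(u) == 1L) {
      n_states[j] <- 1L
      thresholds[[j]] <- numeric(0)
    } else if (all(u %in% c(0, 1))) {
      states[, j] <- as.integer(v)
      n_states[j] <- 2L
      thresholds[[j]] <- 0.5
    } else {
      m <- mean(v)
      s <- stats::sd(v)
      th <- c(m - alpha * s, m + alpha * s)
      states[, j] <- as.integer(findInterval(v, th))
      n_states[j] <- 3L
      thresholds[[j]] <- th
    }
  }
  structure(list(states = states, n_states = n_states,
                 thresholds = thresholds),
            class = "discretized_matrix")
}

#' Mutual information between two discrete state vectors
#'
#' Plug-in estimate over observed joint states, in bits:
#' \code{MI = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )}.  Non-negative
#' and symmetric.
#'
#' @param x,y equal-length vectors of discrete states.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(x) == 0L) stop("empty vectors", call. = FALSE)
  joint <- table(x, y)
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# MI (bits) of every column of an integer state matrix against one state
# vector, computed through indicator cross-products so a full ranking pass
# stays vectorized.  States must be 0-based small integers.
mi_vector <- function(states, y) {
  n <- nrow(states)
  ys <- sort(unique(y))
  xs <- 0L:max(states)
  Y <- matrix(0, n, length(ys))
  for (b in seq_along(ys)) Y[, b] <- as.numeric(y == ys[b])
  py <- colSums(Y) / n
  mi <- numeric(ncol(states))
  pxs <- matrix(0, ncol(states), length(xs))
  counts <- vector("list", length(xs))
  for (a in seq_along(xs)) {
    Xa <- states == xs[a]
    storage.mode(Xa) <- "numeric"
    counts[[a]] <- crossprod(Xa, Y) / n      # features x y-states
    pxs[, a] <- colSums(Xa) / n
  }
  for (a in seq_along(xs)) {
    pj <- counts[[a]]
    for (b in seq_along(ys)) {
      pab <- pj[, b]
      expct <- pxs[, a] * py[b]
      term <- pab * log2(pab / expct)
      term[pab == 0] <- 0
      mi <- mi + term
    }
  }
  pmax(mi, 0)
}

#' Rank features by relevance to the class label (MaxRel)
#'
#' Relevance of a feature is its mutual information with the label.
#' Features are sorted by decreasing relevance; exact ties keep the
#' original column order.  Zero-variance features have relevance 0.
#'
#' @param D a \code{discretized_matrix}.
#' @param labels binary class labels (factor, character or 0/1).
#' @return A data.frame (feature, relevance, rank) sorted by rank.
#' @export
maxrel_ranking <- function(D, labels) {
  y <- as_binary_states(labels, nrow(D$states))
  rel <- mi_vector(D$states, y)
  ord <- order(-rel, seq_along(rel))
  data.frame(feature = colnames(D$states)[ord],
             relevance = rel[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

as_binary_states <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels length must match sample count", call. = FALSE)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  as.integer(f) - 1L
}

#' Rank features by maximum relevance / minimum redundancy (mRMR)
#'
#' Greedy forward ranking: round 1 selects the most relevant feature; each
#' later round selects the unselected feature maximizing
#' \code{MI(feature, label) - mean( MI(feature, selected) )} (the
#' difference form of the mRMR criterion).  Exact ties resolve to the
#' lower original column index, so rankings are reproducible.  A smaller
#' selection round h means a better relevance/redundancy trade-off.
#'
#' @param D a \code{discretized_matrix}.
#' @param labels binary class labels.
#' @param n_select number of rounds to run (default: all features, giving
#'   a full permutation; a smaller value yields the leading prefix, which
#'   is all incremental feature selection needs).
#' @return A \code{ranked_features} object: list with \code{maxrel} (from
#'   \code{\link{maxrel_ranking}}) and \code{mrmr} (data.frame feature,
#'   round, score).
#' @export
mrmr_ranking <- function(D, labels, n_select = NULL) {
  y <- as_binary_states(labels, nrow(D$states))
  N <- ncol(D$states)
  n_select <- min(as.integer(n_select %||% N), N)
  rel <- mi_vector(D$states, y)
  maxrel <- {
    ord <- order(-rel, seq_along(rel))
    data.frame(feature = colnames(D$states)[ord], relevance = rel[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  selected <- integer(0)
  red_sum <- numeric(N)           # running sum of MI(j, selected)
  scores <- numeric(n_select)
  remaining <- rep(TRUE, N)
  for (h in seq_len(n_select)) {
    crit <- if (h == 1L) rel else rel - red_sum / length(selected)
    crit[!remaining] <- -Inf
    pick <- which.max(crit)       # which.max takes the first (lowest index) tie
    scores[h] <- crit[pick]
    selected <- c(selected, pick)
    remaining[pick] <- FALSE
    if (h < n_select) {
      red_sum <- red_sum + mi_vector(D$states, D$states[, pick])
    }
  }
  structure(list(
    maxrel = maxrel,
    mrmr = data.frame(feature = colnames(D$states)[selected],
                      round = seq_len(n_select),
                      score = scores,
                      stringsAsFactors = FALSE),
    n_features = N),
    class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features; mRMR rounds run: %d\n",
              x$n_features, nrow(x$mrmr)))
  cat("top mRMR features:\n")
  print(utils::head(x$mrmr, 5L))
  invisible(x)
}
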