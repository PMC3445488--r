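#' Read protein sequences and cleavage annotations
#'
#' Builds one \code{protein_record} per FASTA entry, attaching the 1-based
#' P1 positions of annotated cleavage sites.  A cleavage site is the bond
#' between residues \code{p} and \code{p + 1}, so every position must
#' satisfy \code{1 <= p < length(sequence)}.  Duplicate annotation rows are
#' collapsed and sites are stored sorted.
#'
#' @param fasta_source path to a multi-record FASTA file of amino-acid
#'   sequences (20 standard letters; see \code{map_nonstandard}).
#' @param table_source path to a tab- or comma-separated annotation table
#'   with header columns \code{accession}, \code{position} and optionally
#'   \code{label}; when a label column is present only rows labelled
#'   \code{"positive"} are taken as cleavage sites.
#' @param map_nonstandard if \code{TRUE}, non-standard letters (B, J, O, U,
#'   Z, X) in input sequences are mapped to the padding symbol X instead of
#'   being rejected.  Off by default because X is reserved for terminal
#'   padding and silent coercion would distort the frequency feature.
#' @return A named list of \code{protein_record} objects (accession,
#'   sequence, sites).
#' @export
read_annotations <- function(fasta_source, table_source,
                             map_nonstandard = FALSE) {
  seqs <- read_protein_fasta(fasta_source, map_nonstandard = map_nonstandard)
  tab <- read_site_table(table_source)
  records <- lapply(names(seqs), function(acc) {
    protein_record(acc, seqs[[acc]], sites = integer(0),
                   allow_x = map_nonstandard)
  })
  names(records) <- names(seqs)
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    p <- tab$position[i]
    if (!acc %in% names(records)) {
      stop(sprintf("annotation references unknown accession '%s'", acc),
           call. = FALSE)
    }
    len <- nchar(records[[acc]]$sequence)
    if (is.na(p) || p < 1L || p >= len) {
      stop(sprintf(
        "cleavage position %s out of bounds for '%s' (length %d; need 1 <= p < length)",
        p, acc, len), call. = FALSE)
    }
    records[[acc]]$sites <- c(records[[acc]]$sites, as.integer(p))
  }
  for (acc in names(records)) {
    records[[acc]]$sites <- sort(unique(records[[acc]]$sites))
  }
  records
}

#' Construct a protein record
#'
#' @param accession accession string.
#' @param sequence amino-acid sequence over the 20 standard letters.
#' @param sites integer vector of 1-based P1 cleavage positions (each
#'   annotated pair is residues \code{p}, \code{p + 1}).
#' @param allow_x if \code{TRUE}, the padding symbol X is tolerated inside
#'   the sequence (used when non-standard input letters are mapped to X;
#'   such residues encode to all-zero features).
#' @return An object of class \code{protein_record}.
#' @export
protein_record <- function(accession, sequence, sites = integer(0),
                           allow_x = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) {
    stop("sequence must have length >= 1", call. = FALSE)
  }
  alphabet <- if (allow_x) c(AA_STANDARD, PAD_SYMBOL) else AA_STANDARD
  bad <- setdiff(strsplit(sequence, "")[[1L]], alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("sequence for '%s' contains non-standard letters: %s",
                 accession, paste(sort(unique(bad)), collapse = ", ")),
         call. = FALSE)
  }
  sites <- sort(unique(as.integer(sites)))
  if (any(sites < 1L | sites >= nchar(sequence))) {
    stop(sprintf("cleavage positions out of bounds for '%s'", accession),
         call. = FALSE)
  }
  structure(list(accession = as.character(accession),
                 sequence = sequence,
                 sites = sites),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, %d cleavage site(s)\n",
              x$accession, nchar(x$sequence), length(x$sites)))
  invisible(x)
}

read_protein_fasta <- function(path, map_nonstandard = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  accs <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(accs)) {
    stop("duplicated accessions in FASTA: ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (map_nonstandard) {
    seqs <- vapply(seqs, function(s) {
      gsub(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), PAD_SYMBOL, s)
    }, character(1L), USE.NAMES = FALSE)
  }
  names(seqs) <- accs
  seqs
}

read_site_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("accession", "position") %in% names(tab))) {
    stop("annotation table must have columns 'accession' and 'position'",
         call. = FALSE)
  }
  if ("label" %in% names(tab)) {
    tab <- tab[tolower(tab$label) == "positive", , drop = FALSE]
  }
  tab$position <- as.integer(tab$position)
  tab
}

#' Extract a peptide window around a candidate scissile bond
#'
#' The window of size \code{W = 2k} covers protein positions
#' \code{p - k + 1 .. p + k}, so window sites \code{k} and \code{k + 1}
#' hold the annotated residue pair \code{p}, \code{p + 1} (for W = 22 the
#' bond lies between sites 11 and 12).  Positions outside the protein are
#' padded with the symbol X.
#'
#' @param record a \code{protein_record}.
#' @param p 1-based position of the P1 residue (\code{1 <= p < length}).
#' @param W window size, one of 16, 18, 20, 22.
#' @param label window label, \code{"positive"} or \code{"negative"}.
#' @return A \code{peptide_window}: residues string, window size, label,
#'   source \code{(accession, p)} and logical \code{pad_mask} (TRUE at X).
#' @export
extract_window <- function(record, p, W, label = "positive") {
  if (!(W %in% WINDOW_SIZES)) {
    stop("window size W must be one of ", paste(WINDOW_SIZES, collapse = ", "),
         call. = FALSE)
  }
  len <- nchar(record$sequence)
  p <- as.integer(p)
  if (p < 1L || p >= len) {
    stop(sprintf("position %d out of range for '%s' (length %d)",
                 p, record$accession, len), call. = FALSE)
  }
  k <- W %/% 2L
  pos <- (p - k + 1L):(p + k)
  inside <- pos >= 1L & pos <= len
  chars <- rep(PAD_SYMBOL, W)
  chars[inside] <- strsplit(record$sequence, "")[[1L]][pos[inside]]
  structure(list(residues = paste(chars, collapse = ""),
                 W = as.integer(W),
                 label = match.arg(label, c("positive", "negative")),
                 accession = record$accession,
                 p = p,
                 pad_mask = !inside),
            class = "peptide_window")
}

#' @export
print.peptide_window <- function(x, ...) {
  cat(sprintf("<peptide_window> %s @%d [%s] %s\n",
              x$accession, x$p, x$label, x$residues))
  invisible(x)
}

#' Extract all positive windows of a protein set
#'
#' @param records list of \code{protein_record}.
#' @param W window size.
#' @return List of positive \code{peptide_window} objects, one per
#'   annotated cleavage site.
#' @export
positive_windows <- function(records, W) {
  out <- list()
  for (rec in records) {
    for (p in rec$sites) {
      out[[length(out) + 1L]] <- extract_window(rec, p, W, "positive")
    }
  }
  out
}

#' Sample negative windows centred on non-cleavage bonds
#'
#' Pools every bond \code{(q, q + 1)} with \code{q} not annotated as a
#' cleavage position across the whole protein set, then samples uniformly
#' without replacement so the total negative count is \code{ratio} times
#' the number of annotated sites (global allocation, matching a fixed
#' overall negative:positive ratio rather than a per-protein quota).
#'
#' @param records a \code{protein_record} or list of them.
#' @param W window size.
#' @param ratio negatives per positive (>= 1).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @param n_negatives optional explicit number of negatives, overriding
#'   \code{ratio * positives}.
#' @return List of negative \code{peptide_window} objects.  If the request
#'   exceeds the available non-cleavage bonds, all available bonds are
#'   returned with a warning.
#' @export
sample_negatives <- function(records, W, ratio = 3L, seed = 1L,
                             n_negatives = NULL) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (is.null(n_negatives) && (!is.numeric(ratio) || ratio < 1)) {
    stop("'ratio' must be a positive integer >= 1", call. = FALSE)
  }
  pool_acc <- character(0)
  pool_q <- integer(0)
  n_pos <- 0L
  for (rec in records) {
    len <- nchar(rec$sequence)
    q <- setdiff(seq_len(len - 1L), rec$sites)
    pool_acc <- c(pool_acc, rep(rec$accession, length(q)))
    pool_q <- c(pool_q, q)
    n_pos <- n_pos + length(rec$sites)
  }
  if (length(pool_q) == 0L) {
    stop("no non-cleavage bonds available in the protein set", call. = FALSE)
  }
  want <- if (!is.null(n_negatives)) as.integer(n_negatives)
          else as.integer(round(ratio * n_pos))
  if (want > length(pool_q)) {
    warning(sprintf(
      "requested %d negatives but only %d non-cleavage bonds available; using all",
      want, length(pool_q)))
    idx <- seq_along(pool_q)
  } else {
    idx <- with_seed(seed, sample.int(length(pool_q), want))
  }
  by_acc <- split(pool_q[idx], pool_acc[idx])
  recs <- records
  names(recs) <- vapply(records, `[[`, character(1L), "accession")
  out <- vector("list", length(idx))
  j <- 0L
  for (acc in names(by_acc)) {
    for (q in by_acc[[acc]]) {
      j <- j + 1L
      out[[j]] <- extract_window(recs[[acc]], q, W, "negative")
    }
  }
  out
}

#' Split proteins into training and testing sets
#'
#' The split is protein-level (all windows of a protein stay on one side)
#' so held-out evaluation never sees training proteins.
#'
#' @param records list of \code{protein_record}.
#' @param test_fraction proportion of proteins held out (0 < f < 1).
#' @param seed integer seed.
#' @return A list with components \code{train} and \code{test}, each a
#'   named list of records; accession sets are disjoint and their union is
#'   the input set.
#' @export
split_train_test <- function(records, test_fraction, seed = 1L) {
  n <- length(records)
  if (n < 2L) stop("need at least 2 proteins to split", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("'test_fraction' must be strictly between 0 and 1", call. = FALSE)
  }
  n_test <- max(1L, min(n - 1L, as.integer(round(test_fraction * n))))
  idx <- with_seed(seed, sample.int(n, n_test))
  accs <- vapply(records, `[[`, character(1L), "accession")
  test <- records[idx]
  train <- records[-idx]
  names(test) <- accs[idx]
  names(train) <- accs[-idx]
  structure(list(train = train, test = test), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train: %d proteins, test: %d proteins\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Tabulate peptide windows
#'
#' @param windows list of \code{peptide_window}.
#' @return A data.frame with columns accession, p, label, residues.
#' @export
windows_to_df <- function(windows) {
  data.frame(
    accession = vapply(windows, `[[`, character(1L), "accession"),
    p = vapply(windows, `[[`, integer(1L), "p"),
    label = vapply(windows, `[[`, character(1L), "label"),
    residues = vapply(windows, `[[`, character(1L), "residues"),
    stringsAsFactors = FALSE)
}

#' Rebuild peptide windows from a window table
#'
#' Inverse of \code{\link{windows_to_df}} up to object identity; used by
#' the command-line interface to pass window sets between stages as TSV.
#'
#' @param df data.frame with columns accession, p, label, residues.
#' @return List of \code{peptide_window} objects.
#' @export
df_to_windows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    res <- df$residues[i]
    structure(list(residues = res,
                   W = nchar(res),
                   label = df$label[i],
                   accession = df$accession[i],
                   p = as.integer(df$p[i]),
                   pad_mask = strsplit(res, "")[[1L]] == PAD_SYMBOL),
              class = "peptide_window")
  })
}
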