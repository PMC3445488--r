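#' Canonical feature names for a window size
#'
#' Features are named \code{AA\{site\}_\{family\}_\{k\}} with site 1..W,
#' family one of \code{pssm, disorder, aafactor, sa, ss, freq} and k the
#' index within the family.  Per residue the fixed family order is
#' pssm (20), disorder (1), aafactor (5), sa (2), ss (3), freq (1) = 32
#' features, so a window of size W yields W x 32 named columns (704 for
#' W = 22).  \code{AA11_pssm_20} is the conservation score against valine
#' (PSSM column 20) of the P1 residue in a size-22 window.
#'
#' @param W window size.
#' @return Character vector of length \code{W * 32}.
#' @export
feature_names <- function(W) {
  per_site <- unlist(lapply(FEATURE_FAMILIES, function(fam) {
    paste0(fam, "_", seq_len(FAMILY_WIDTHS[[fam]]))
  }))
  as.vector(t(outer(paste0("AA", seq_len(W), "_"), per_site, paste0)))
}

#' Parse a canonical feature name
#'
#' @param name one or more feature names of the form
#'   \code{AA\{site\}_\{family\}_\{k\}}.
#' @return A data.frame with columns \code{site}, \code{family}, \code{k}.
#' @export
parse_feature_name <- function(name) {
  pat <- sprintf("^AA([0-9]+)_(%s)_([0-9]+)$",
                 paste(FEATURE_FAMILIES, collapse = "|"))
  ok <- grepl(pat, name)
  if (!all(ok)) {
    stop("unparseable feature name(s): ",
         paste(utils::head(name[!ok], 5L), collapse = ", "), call. = FALSE)
  }
  site <- as.integer(sub(pat, "\\1", name))
  family <- sub(pat, "\\2", name)
  k <- as.integer(sub(pat, "\\3", name))
  bad <- k < 1L | k > FAMILY_WIDTHS[family]
  if (any(bad)) {
    stop("feature index out of range in: ",
         paste(name[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(site = site, family = family, k = k, stringsAsFactors = FALSE)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII matrix written by PSI-BLAST (`-out_ascii_pssm`):
#' header lines, then one row per residue starting with the position index
#' and the residue letter followed by at least 20 integer log-odds scores
#' in the fixed column order A R N D C Q E G H I L K M F P S T W Y V.
#' Only the first 20 score columns are used; trailing percentage columns
#' are ignored.  Scores are kept as raw log-odds (no rescaling).
#'
#' @param source path to the ASCII PSSM file.
#' @param sequence optional protein sequence; when given, the profile
#'   length must match.
#' @return A numeric n x 20 matrix (class \code{pssm_profile}) with
#'   colnames in PSSM column order and the residue string in attribute
#'   \code{"residues"}.
#' @export
load_pssm <- function(source, sequence = NULL) {
  lines <- readLines(source)
  rows <- list()
  res <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) < 2L || is.na(suppressWarnings(as.integer(tok[1L])))) next
    if (!tok[2L] %in% c(AA_STANDARD, PAD_SYMBOL)) next
    scores <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(scores) < 20L || anyNA(scores[1:20])) {
      stop(sprintf("malformed PSSM row at line %d of '%s' (need 20 numeric scores)",
                   i, source), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- scores[1:20]
    res <- c(res, tok[2L])
  }
  if (length(rows) == 0L) {
    stop("no PSSM rows found in '", source, "'", call. = FALSE)
  }
  prof <- do.call(rbind, rows)
  colnames(prof) <- PSSM_COLUMNS
  if (!is.null(sequence) && nrow(prof) != nchar(sequence)) {
    stop(sprintf("PSSM length %d does not match sequence length %d in '%s'",
                 nrow(prof), nchar(sequence), source), call. = FALSE)
  }
  attr(prof, "residues") <- paste(res, collapse = "")
  class(prof) <- c("pssm_profile", class(prof))
  prof
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Round-trips through \code{\link{load_pssm}}; used by the synthetic-data
#' writer so fixtures exercise the same reader as real PSI-BLAST output.
#'
#' @param profile n x 20 numeric matrix in PSSM column order.
#' @param path output file path.
#' @param sequence protein sequence (residue letters for the row labels).
#' @export
write_pssm <- function(profile, path, sequence) {
  if (ncol(profile) != 20L) stop("profile must have 20 columns", call. = FALSE)
  if (nrow(profile) != nchar(sequence)) {
    stop("profile rows must match sequence length", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", PSSM_COLUMNS),
                                            collapse = " "))), con)
  for (i in seq_len(nrow(profile))) {
    writeLines(sprintf("%5d %s %s", i, chars[i],
                       paste(sprintf("%3d", as.integer(round(profile[i, ]))),
                             collapse = " ")), con)
  }
}

#' Read a per-residue disorder profile
#'
#' Two-column tab-separated file (position, score); scores in [0, 1].
#'
#' @param source path.
#' @return Numeric vector of per-residue disorder scores.
#' @export
load_disorder <- function(source) {
  tab <- utils::read.table(source, header = FALSE, sep = "\t")
  if (ncol(tab) < 2L) {
    stop("disorder file must have two columns (position, score): ", source,
         call. = FALSE)
  }
  ord <- order(as.integer(tab[[1L]]))
  scores <- as.numeric(tab[[2L]][ord])
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("disorder scores must lie in [0, 1]: ", source, call. = FALSE)
  }
  scores
}

#' Read secondary-structure / accessibility strings
#'
#' FASTA-like files holding one class character per residue: secondary
#' structure over \{H, E, O\} (helix, strand, other) and solvent
#' accessibility over \{b, e\} (buried, exposed).
#'
#' @param source path to the FASTA-like file.
#' @param alphabet allowed class characters.
#' @return Named character vector (accession -> class string).
#' @export
load_structure <- function(source, alphabet = c("H", "E", "O")) {
  set <- Biostrings::readBStringSet(source)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  bad <- vapply(out, function(s) {
    any(!strsplit(s, "")[[1L]] %in% alphabet)
  }, logical(1L))
  if (any(bad)) {
    stop("structure strings contain characters outside {",
         paste(alphabet, collapse = ","), "}: ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Bundle per-residue annotation providers
#'
#' A provider set supplies, per accession, the PSSM profile, disorder
#' scores, secondary-structure classes and accessibility classes that the
#' encoder consumes.  Profiles come either from files written by external
#' predictors (PSI-BLAST, a disorder predictor, a secondary-structure /
#' accessibility predictor) or from \code{\link{synthetic_providers}}.
#'
#' @param pssm named list of n x 20 matrices.
#' @param disorder named list of numeric vectors in [0, 1].
#' @param ss named list of character vectors over \{helix, strand, other\}
#'   (or strings over \{H, E, O\}).
#' @param sa named list over \{buried, exposed\} (or strings over
#'   \{b, e\}).
#' @return An object of class \code{providers}.
#' @export
providers <- function(pssm, disorder, ss, sa) {
  ss <- lapply(ss, normalize_classes,
               map = c(H = "helix", E = "strand", O = "other"),
               full = SS_CLASSES)
  sa <- lapply(sa, normalize_classes,
               map = c(b = "buried", e = "exposed"),
               full = SA_CLASSES)
  structure(list(pssm = pssm, disorder = disorder, ss = ss, sa = sa),
            class = "providers")
}

normalize_classes <- function(x, map, full) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  if (all(x %in% names(map))) x <- unname(map[x])
  if (!all(x %in% full)) {
    stop("unknown structure class in profile: ",
         paste(setdiff(x, full), collapse = ", "), call. = FALSE)
  }
  x
}

#' Load providers from annotation directories
#'
#' Expects, per accession, \code{<acc>.pssm} (PSI-BLAST ASCII),
#' \code{<acc>.disorder} (position/score TSV), and shared FASTA-like
#' \code{ss.txt} / \code{sa.txt} files in the respective directories.
#'
#' @param pssm_dir,disorder_dir,ss_file,sa_file locations of the profile
#'   files.
#' @param records named list of \code{protein_record} (lengths validated).
#' @return A \code{providers} object.
#' @export
load_providers <- function(pssm_dir, disorder_dir, ss_file, sa_file, records) {
  accs <- names(records)
  pssm <- lapply(accs, function(a) {
    load_pssm(file.path(pssm_dir, paste0(a, ".pssm")),
              sequence = records[[a]]$sequence)
  })
  disorder <- lapply(accs, function(a) {
    d <- load_disorder(file.path(disorder_dir, paste0(a, ".disorder")))
    if (length(d) != nchar(records[[a]]$sequence)) {
      stop("disorder profile length mismatch for ", a, call. = FALSE)
    }
    d
  })
  names(pssm) <- names(disorder) <- accs
  ss <- load_structure(ss_file, alphabet = c("H", "E", "O"))[accs]
  sa <- load_structure(sa_file, alphabet = c("b", "e"))[accs]
  providers(pssm, disorder, as.list(ss), as.list(sa))
}

#' Position-specific amino-acid frequency table
#'
#' Empirical occurrence frequency of each of the 21 symbols (20 amino
#' acids plus the padding symbol X) at each window site among training
#' positive windows.  Each row is a probability distribution over the 21
#' symbols.
#'
#' @param positives list of positive \code{peptide_window}, all of the
#'   same size W.
#' @return A W x 21 matrix (class \code{frequency_table}); rows sum to 1.
#' @export
build_frequency_table <- function(positives) {
  if (length(positives) == 0L) {
    stop("cannot build a frequency table from zero windows", call. = FALSE)
  }
  Ws <- vapply(positives, `[[`, integer(1L), "W")
  if (length(unique(Ws)) != 1L) {
    stop("all windows must share the same window size", call. = FALSE)
  }
  labs <- vapply(positives, `[[`, character(1L), "label")
  if (any(labs != "positive")) {
    stop("frequency table is built from positive windows only", call. = FALSE)
  }
  W <- Ws[1L]
  symbols <- c(AA_STANDARD, PAD_SYMBOL)
  counts <- matrix(0L, nrow = W, ncol = 21L,
                   dimnames = list(paste0("site", seq_len(W)), symbols))
  for (w in positives) {
    chars <- strsplit(w$residues, "")[[1L]]
    for (s in seq_len(W)) counts[s, chars[s]] <- counts[s, chars[s]] + 1L
  }
  freq <- counts / length(positives)
  class(freq) <- c("frequency_table", class(freq))
  freq
}

#' Encode one residue as its 32-feature vector
#'
#' Concatenates, in fixed order: 20 PSSM conservation scores, 1 disorder
#' score, 5 Atchley amino-acid factors, 2 solvent-accessibility indicators
#' (buried = 10, exposed = 01), 3 secondary-structure indicators
#' (helix = 100, strand = 010, other = 001) and 1 position-specific
#' amino-acid frequency.  The padding symbol X encodes as 32 zeros,
#' overriding every family including the frequency lookup.
#'
#' @param symbol residue letter or \code{"X"}.
#' @param site window site (1..W), used for the frequency lookup.
#' @param pssm_row numeric 20-vector in PSSM column order.
#' @param disorder_value disorder score in [0, 1].
#' @param structure list with elements \code{ss} (helix/strand/other) and
#'   \code{sa} (buried/exposed).
#' @param freq_table a \code{frequency_table} for the window size.
#' @return Numeric vector of length 32.
#' @export
encode_residue <- function(symbol, site, pssm_row, disorder_value,
                           structure, freq_table) {
  if (symbol == PAD_SYMBOL) return(numeric(FEATURES_PER_RESIDUE))
  if (!symbol %in% AA_STANDARD) {
    stop("unknown residue symbol: ", symbol, call. = FALSE)
  }
  sa <- as.numeric(SA_CLASSES == structure$sa)
  ss <- as.numeric(SS_CLASSES == structure$ss)
  unname(c(as.numeric(pssm_row),
           disorder_value,
           ATCHLEY_FACTORS[symbol, ],
           sa,
           ss,
           freq_table[site, symbol]))
}

#' Encode peptide windows into a feature matrix
#'
#' Produces one row per window and \code{W * 32} named columns ordered by
#' window site, then by the fixed per-residue family order.  Per-residue
#' profiles are looked up in the provider set at the protein position each
#' window site covers; X-padded sites contribute zero columns.
#'
#' @param windows list of \code{peptide_window}, all the same size.
#' @param prov a \code{providers} object covering every source protein.
#' @param freq_table a \code{frequency_table} built from training
#'   positives (see \code{\link{build_frequency_table}}).
#' @return A \code{feature_matrix}: list with \code{features} (numeric
#'   matrix), \code{meta} (data.frame accession, p, label) and
#'   \code{window_size}.
#' @export
encode_windows <- function(windows, prov, freq_table) {
  if (length(windows) == 0L) stop("no windows to encode", call. = FALSE)
  W <- windows[[1L]]$W
  if (any(vapply(windows, `[[`, integer(1L), "W") != W)) {
    stop("all windows must share one window size", call. = FALSE)
  }
  k <- W %/% 2L
  cn <- feature_names(W)
  X <- matrix(0, nrow = length(windows), ncol = length(cn),
              dimnames = list(NULL, cn))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    acc <- w$accession
    pssm <- prov$pssm[[acc]]
    dis <- prov$disorder[[acc]]
    ss <- prov$ss[[acc]]
    sa <- prov$sa[[acc]]
    if (is.null(pssm) || is.null(dis) || is.null(ss) || is.null(sa)) {
      stop("missing provider profiles for accession '", acc, "'",
           call. = FALSE)
    }
    chars <- strsplit(w$residues, "")[[1L]]
    row <- numeric(length(cn))
    for (s in seq_len(W)) {
      if (chars[s] == PAD_SYMBOL) next
      pos <- w$p - k + s
      row[((s - 1L) * FEATURES_PER_RESIDUE + 1L):(s * FEATURES_PER_RESIDUE)] <-
        encode_residue(chars[s], s, pssm[pos, ], dis[pos],
                       list(ss = ss[pos], sa = sa[pos]), freq_table)
    }
    X[i, ] <- row
  }
  structure(list(features = X,
                 meta = windows_to_df(windows)[, c("accession", "p", "label")],
                 window_size = W),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (W = %d; %d positive)\n",
              nrow(x$features), ncol(x$features), x$window_size,
              sum(x$meta$label == "positive")))
  invisible(x)
}

#' Subset a feature matrix to named features
#'
#' @param fm a \code{feature_matrix}.
#' @param features character vector of feature names.
#' @return A \code{feature_matrix} restricted to those columns, in the
#'   given order.
#' @export
subset_features <- function(fm, features) {
  missing <- setdiff(features, colnames(fm$features))
  if (length(missing) > 0L) {
    stop("unknown features: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(list(features = fm$features[, features, drop = FALSE],
                 meta = fm$meta, window_size = fm$window_size),
            class = "feature_matrix")
}

#' Generate synthetic per-residue annotation providers
#'
#' Stand-in for the outputs of external per-residue predictors, used by
#' the synthetic-data module.  PSSM rows are integer noise with an
#' elevated score in the column of the residue actually present (so
#' conservation tracks the sequence, as in a real profile); disorder is
#' uniform noise; secondary-structure and accessibility classes are drawn
#' from categorical distributions, with strand enriched within
#' \code{site_halo} residues of each annotated bond and buried enriched at
#' the bond residues themselves.  Deterministic under \code{seed}.
#'
#' @param records named list of \code{protein_record}.
#' @param seed integer seed.
#' @param pssm_elevation score added to the own-residue PSSM column.
#' @param pssm_noise_sd standard deviation of the integer noise scores.
#' @param ss_probs baseline P(helix, strand, other).
#' @param ss_probs_near_site same, within the halo of an annotated bond.
#' @param sa_probs baseline P(buried, exposed).
#' @param sa_probs_at_site same, at the two bond residues.
#' @param site_halo half-width (in residues) of the structural enrichment
#'   around each annotated bond.
#' @return A \code{providers} object.
#' @export
synthetic_providers <- function(records, seed = 1L,
                                pssm_elevation = 8,
                                pssm_noise_sd = 2,
                                ss_probs = c(helix = 0.35, strand = 0.25,
                                             other = 0.40),
                                ss_probs_near_site = c(helix = 0.15,
                                                       strand = 0.60,
                                                       other = 0.25),
                                sa_probs = c(buried = 0.45, exposed = 0.55),
                                sa_probs_at_site = c(buried = 0.85,
                                                     exposed = 0.15),
                                site_halo = 2L) {
  if (is.null(names(records))) {
    names(records) <- vapply(records, `[[`, character(1L), "accession")
  }
  with_seed(seed, {
    pssm <- list(); disorder <- list(); ss <- list(); sa <- list()
    for (acc in names(records)) {
      rec <- records[[acc]]
      n <- nchar(rec$sequence)
      chars <- strsplit(rec$sequence, "")[[1L]]
      m <- matrix(round(stats::rnorm(n * 20L, 0, pssm_noise_sd)),
                  nrow = n, dimnames = list(NULL, PSSM_COLUMNS))
      known <- chars %in% PSSM_COLUMNS
      m[cbind(which(known), match(chars[known], PSSM_COLUMNS))] <-
        m[cbind(which(known), match(chars[known], PSSM_COLUMNS))] +
        round(pssm_elevation)
      pssm[[acc]] <- m
      disorder[[acc]] <- stats::runif(n)
      near <- rep(FALSE, n)
      at_bond <- rep(FALSE, n)
      for (p in rec$sites) {
        lo <- max(1L, p - site_halo); hi <- min(n, p + 1L + site_halo)
        near[lo:hi] <- TRUE
        at_bond[p] <- TRUE
        at_bond[p + 1L] <- TRUE
      }
      ssv <- character(n)
      nn <- sum(!near)
      if (nn > 0L) ssv[!near] <- sample(SS_CLASSES, nn, TRUE, ss_probs)
      if (any(near)) {
        ssv[near] <- sample(SS_CLASSES, sum(near), TRUE, ss_probs_near_site)
      }
      sav <- character(n)
      if (any(!at_bond)) {
        sav[!at_bond] <- sample(SA_CLASSES, sum(!at_bond), TRUE, sa_probs)
      }
      if (any(at_bond)) {
        sav[at_bond] <- sample(SA_CLASSES, sum(at_bond), TRUE, sa_probs_at_site)
      }
      ss[[acc]] <- ssv
      sa[[acc]] <- sav
    }
    providers(pssm, disorder, ss, sa)
  })
}
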