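# Independent oracles, deliberately naive: direct loops / closed forms
# that share no code with the implementation they check.

# Plug-in mutual information (bits) by explicit loop over state pairs.
mi_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (ux in unique(x)) {
    for (uy in unique(y)) {
      pxy <- sum(x == ux & y == uy) / n
      if (pxy > 0) {
        s <- s + pxy * log2(pxy / ((sum(x == ux) / n) * (sum(y == uy) / n)))
      }
    }
  }
  s
}

# Exhaustive greedy mRMR (difference criterion) using the oracle MI.
mrmr_oracle <- function(states, labels) {
  N <- ncol(states)
  y <- as.integer(as.factor(labels)) - 1L
  rel <- vapply(seq_len(N), function(j) mi_oracle(states[, j], y), numeric(1))
  selected <- integer(0)
  for (h in seq_len(N)) {
    best <- -Inf; pick <- NA_integer_
    for (j in setdiff(seq_len(N), selected)) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(sj) {
          mi_oracle(states[, j], states[, sj])
        }, numeric(1)))
      }
      crit <- rel[j] - red
      if (crit > best + 1e-12) { best <- crit; pick <- j }
    }
    selected <- c(selected, pick)
  }
  selected
}

# MCC via Pearson correlation of the expanded binary truth/prediction
# vectors (an algebraically equivalent but independently computed route).
mcc_oracle <- function(TP, TN, FP, FN) {
  truth <- c(rep(1, TP), rep(0, TN), rep(0, FP), rep(1, FN))
  pred <- c(rep(1, TP), rep(0, TN), rep(1, FP), rep(0, FN))
  suppressWarnings(stats::cor(truth, pred))
}

# A deterministic toy protein set with hand-placed cleavage sites.
toy_records <- function() {
  list(
    A1 = protein_record("A1", "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL", sites = c(12L)),
    B2 = protein_record("B2", "MKLVRDSAGTYWFHQENCIPMKLVRDSAGT", sites = c(5L, 20L)),
    C3 = protein_record("C3", strrep("ACDEFGHIKL", 4L), sites = c(15L))
  )
}

# Flat providers with recognisable constants so encodings are predictable:
# PSSM row r for position i = i repeated over 20 columns.
toy_providers <- function(records) {
  mk <- function(rec) {
    n <- nchar(rec$sequence)
    list(
      pssm = matrix(rep(seq_len(n), 20L), nrow = n,
                    dimnames = list(NULL, c("A","R","N","D","C","Q","E","G","H",
                                            "I","L","K","M","F","P","S","T",
                                            "W","Y","V"))),
      disorder = rep(0.25, n),
      ss = rep("helix", n),
      sa = rep("buried", n)
    )
  }
  parts <- lapply(records, mk)
  providers(pssm = lapply(parts, `[[`, "pssm"),
            disorder = lapply(parts, `[[`, "disorder"),
            ss = lapply(parts, `[[`, "ss"),
            sa = lapply(parts, `[[`, "sa"))
}

# Write a records list as FASTA + CSV annotation files in a temp dir.
# (Created under the session tempdir; cleaned up when the session ends.)
write_toy_inputs <- function(records, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "prot.fasta")
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$accession), r$sequence)
  }))
  writeLines(lines, fasta)
  rows <- do.call(rbind, lapply(records, function(r) {
    if (length(r$sites) == 0) return(NULL)
    data.frame(accession = r$accession, position = r$sites)
  }))
  sites <- file.path(dir, "sites.csv")
  write.csv(rows, sites, row.names = FALSE, quote = FALSE)
  list(fasta = fasta, sites = sites, dir = dir)
}

# Small planted-signal numeric matrix: first n_inf columns shift with the
# label, the rest are independent noise.
planted_matrix <- function(n = 400, n_feat = 20, n_inf = 5, delta = 1.5,
                           seed = 42) {
  set.seed(seed)
  y <- rep(c("negative", "positive"), length.out = n)
  x <- matrix(rnorm(n * n_feat), n, n_feat)
  shift <- as.numeric(y == "positive") * delta
  for (j in seq_len(n_inf)) x[, j] <- x[, j] + shift
  colnames(x) <- sprintf("F%02d", seq_len(n_feat))
  list(x = x, labels = y)
}

# Wrap a numeric matrix + labels as a feature_matrix so the CV machinery
# can consume synthetic fixtures that never came from peptide windows.
as_feature_matrix <- function(x, labels) {
  structure(list(features = x,
                 meta = data.frame(accession = sprintf("S%04d", seq_len(nrow(x))),
                                   p = seq_len(nrow(x)),
                                   label = labels,
                                   stringsAsFactors = FALSE),
                 window_size = NA_integer_),
            class = "feature_matrix")
}
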