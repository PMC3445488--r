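#' Planted cleavage-motif specification
#'
#' Describes the emission distributions used when planting cleavage sites
#' in synthetic proteins.  Window sites without an entry emit from the
#' background distribution.  The defaults mirror the sequence preferences
#' commonly seen around protease cleavage sites — arginine/aspartate
#' enriched at P1 (window site 11 of a size-22 window) and small residues
#' (serine, alanine, glycine) at P1' (site 12) — together with strand
#' enrichment near the bond and a buried bond, so the planted signal
#' touches every feature family.
#'
#' The effective emission at a motif site is
#' \code{strength * motif + (1 - strength) * background}: strength 0 makes
#' positives indistinguishable from background, strength 1 emits the motif
#' distribution exactly.
#'
#' @param site_emissions named list (window site -> named probability
#'   vector over the 20 amino acids).
#' @param background background amino-acid distribution (default uniform,
#'   which keeps null calibration analytic).
#' @param strength motif strength in [0, 1] (default 0.8).
#' @param W window size the site indices refer to (default 22).
#' @return An object of class \code{motif_spec}.
#' @export
motif_spec <- function(site_emissions = NULL,
                       background = NULL,
                       strength = 0.8,
                       W = 22L) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
  }
  if (is.null(site_emissions)) {
    k <- W %/% 2L
    p1 <- motif_dist(c(R = 0.50, D = 0.30))
    p1p <- motif_dist(c(S = 0.30, A = 0.25, G = 0.25))
    site_emissions <- stats::setNames(list(p1, p1p),
                                      as.character(c(k, k + 1L)))
  }
  # canonicalize to the fixed amino-acid order so sampling probabilities
  # line up regardless of how the caller ordered the named vectors
  canon <- function(d) {
    if (is.null(names(d)) || !setequal(names(d), AA_STANDARD)) {
      stop("emission distributions must be named over the 20 amino acids",
           call. = FALSE)
    }
    d <- d[AA_STANDARD]
    stopifnot(abs(sum(d) - 1) < 1e-9, all(d >= 0))
    d
  }
  background <- canon(background)
  site_emissions <- lapply(site_emissions, canon)
  if (!is.numeric(strength) || strength < 0 || strength > 1) {
    stop("'strength' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(site_emissions = site_emissions,
                 background = background,
                 strength = strength,
                 W = as.integer(W)),
            class = "motif_spec")
}

# Build a 20-AA distribution with the named masses fixed and the rest of
# the probability spread uniformly over the remaining residues.
motif_dist <- function(masses) {
  d <- stats::setNames(rep(0, 20L), AA_STANDARD)
  d[names(masses)] <- masses
  rest <- setdiff(AA_STANDARD, names(masses))
  d[rest] <- (1 - sum(masses)) / length(rest)
  d
}

# Effective per-site emission under the strength mix.
effective_emission <- function(motif, site) {
  em <- motif$site_emissions[[as.character(site)]]
  if (is.null(em)) return(motif$background)
  motif$strength * em + (1 - motif$strength) * motif$background
}

#' Generate a synthetic protein set with planted cleavage sites
#'
#' Protein sequences are drawn i.i.d. from the background distribution;
#' at each planted site p, window sites carrying a motif emission
#' (positions \code{p - k + s} for emission site s) are overwritten with
#' draws from the strength-mixed emission.  Per-residue annotation
#' profiles are produced by \code{\link{synthetic_providers}}.  Everything
#' is reproducible under \code{seed}.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of protein lengths (uniform).
#' @param sites_per_protein range of planted sites per protein, or use
#'   \code{n_sites} for an exact total.
#' @param n_sites optional exact total number of planted sites; each
#'   protein gets at least one, the remainder are spread at random.
#' @param motif a \code{\link{motif_spec}}.
#' @param seed integer seed.
#' @param provider_args list of extra arguments to
#'   \code{\link{synthetic_providers}}.
#' @return List with \code{records} (named list of \code{protein_record})
#'   and \code{providers}.
#' @export
generate_dataset <- function(n_proteins,
                             length_range = c(60L, 600L),
                             sites_per_protein = c(1L, 3L),
                             n_sites = NULL,
                             motif = motif_spec(),
                             seed = 1L,
                             provider_args = list()) {
  if (n_proteins < 1L) stop("'n_proteins' must be positive", call. = FALSE)
  W <- motif$W
  k <- W %/% 2L
  if (min(length_range) < W) {
    stop("'length_range' must admit the largest window (min length >= W)",
         call. = FALSE)
  }
  records <- with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    n_per <- if (!is.null(n_sites)) {
      if (n_sites < n_proteins) {
        stop("'n_sites' must be >= n_proteins (each protein gets one site)",
             call. = FALSE)
      }
      extra <- stats::rmultinom(1L, n_sites - n_proteins,
                                rep(1 / n_proteins, n_proteins))[, 1L]
      1L + extra
    } else {
      sample(sites_per_protein[1L]:sites_per_protein[2L], n_proteins,
             replace = TRUE)
    }
    recs <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      len <- lens[i]
      # keep planted bonds clear of the termini so motif positions exist
      lo <- k; hi <- len - k
      avail <- hi - lo + 1L
      if (avail < n_per[i]) {
        stop(sprintf(
          "cannot place %d sites in a length-%d protein (interior span %d)",
          n_per[i], len, max(0L, avail)), call. = FALSE)
      }
      sites <- sort(sample(lo:hi, n_per[i]))
      chars <- sample(AA_STANDARD, len, replace = TRUE,
                      prob = motif$background)
      for (p in sites) {
        for (s in as.integer(names(motif$site_emissions))) {
          pos <- p - k + s
          if (pos >= 1L && pos <= len) {
            chars[pos] <- sample(AA_STANDARD, 1L,
                                 prob = effective_emission(motif, s))
          }
        }
      }
      recs[[i]] <- protein_record(sprintf("SYN%04d", i),
                                  paste(chars, collapse = ""),
                                  sites = sites)
    }
    names(recs) <- vapply(recs, `[[`, character(1L), "accession")
    recs
  })
  prov <- do.call(synthetic_providers,
                  c(list(records = records, seed = seed + 1L), provider_args))
  list(records = records, providers = prov)
}

#' Default synthetic study scenario
#'
#' One call reproducing the study-scale dataset geometry with the planted
#' motif at its defaults: 459 proteins carrying 712 cleavage sites,
#' split protein-wise into 371 training and 88 testing proteins, with
#' negatives sampled at 3:1 within each split (about 578/1734 training
#' and 134/402 testing windows).
#'
#' @param seed master integer seed; all sub-seeds derive from it.
#' @param W window size (default 22).
#' @param neg_ratio negatives per positive (default 3).
#' @param motif a \code{\link{motif_spec}}.
#' @return A list with \code{records}, \code{providers}, \code{split}
#'   (train/test records), and the four window sets
#'   \code{train_positives}, \code{train_negatives},
#'   \code{test_positives}, \code{test_negatives}.
#' @export
default_scenario <- function(seed = 1L, W = 22L, neg_ratio = 3L,
                             motif = motif_spec(W = W)) {
  gen <- generate_dataset(n_proteins = 459L, n_sites = 712L,
                          motif = motif, seed = seed)
  split <- split_train_test(gen$records, test_fraction = 88 / 459,
                            seed = seed + 10L)
  train_pos <- positive_windows(split$train, W)
  test_pos <- positive_windows(split$test, W)
  train_neg <- sample_negatives(split$train, W, ratio = neg_ratio,
                                seed = seed + 20L)
  test_neg <- sample_negatives(split$test, W, ratio = neg_ratio,
                               seed = seed + 21L)
  list(records = gen$records,
       providers = gen$providers,
       split = split,
       train_positives = train_pos,
       train_negatives = train_neg,
       test_positives = test_pos,
       test_negatives = test_neg,
       W = as.integer(W),
       seed = as.integer(seed))
}

#' Write a synthetic scenario to disk in the pipeline's file dialects
#'
#' Emits exactly the formats the readers consume: a multi-record FASTA, a
#' CSV annotation table (accession, position, label), per-protein
#' PSI-BLAST-style \code{.pssm} files, per-protein \code{.disorder} TSVs
#' and FASTA-like \code{ss.txt} / \code{sa.txt} class-string files, so
#' fixtures double as format-conformance tests.
#'
#' @param bundle output of \code{\link{default_scenario}} or a list with
#'   \code{records} and \code{providers}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  dis_dir <- file.path(dir, "disorder")
  dir.create(pssm_dir, showWarnings = FALSE)
  dir.create(dis_dir, showWarnings = FALSE)
  records <- bundle$records
  prov <- bundle$providers
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1L),
                                        "sequence"))
  names(seqs) <- names(records)
  fasta <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- do.call(rbind, lapply(records, function(r) {
    if (length(r$sites) == 0L) return(NULL)
    data.frame(accession = r$accession, position = r$sites,
               label = "positive", stringsAsFactors = FALSE)
  }))
  ann_path <- file.path(dir, "sites.csv")
  utils::write.table(ann, ann_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  ss_map <- c(helix = "H", strand = "E", other = "O")
  sa_map <- c(buried = "b", exposed = "e")
  ss_set <- Biostrings::BStringSet(vapply(names(records), function(a) {
    paste(ss_map[prov$ss[[a]]], collapse = "")
  }, character(1L)))
  sa_set <- Biostrings::BStringSet(vapply(names(records), function(a) {
    paste(sa_map[prov$sa[[a]]], collapse = "")
  }, character(1L)))
  ss_path <- file.path(dir, "ss.txt")
  sa_path <- file.path(dir, "sa.txt")
  Biostrings::writeXStringSet(ss_set, ss_path)
  Biostrings::writeXStringSet(sa_set, sa_path)
  for (a in names(records)) {
    write_pssm(prov$pssm[[a]], file.path(pssm_dir, paste0(a, ".pssm")),
               records[[a]]$sequence)
    utils::write.table(
      data.frame(pos = seq_along(prov$disorder[[a]]),
                 score = round(prov$disorder[[a]], 6)),
      file.path(dis_dir, paste0(a, ".disorder")),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(list(fasta = fasta, sites = ann_path, pssm_dir = pssm_dir,
                 disorder_dir = dis_dir, ss = ss_path, sa = sa_path))
}
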