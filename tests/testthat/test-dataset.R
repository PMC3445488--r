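test_that("read_annotations builds validated records and deduplicates sites", {
  recs <- toy_records()
  paths <- write_toy_inputs(recs)
  got <- read_annotations(paths$fasta, paths$sites)
  expect_named(got, c("A1", "B2", "C3"))
  expect_equal(got$A1$sites, 12L)
  expect_equal(got$B2$sites, c(5L, 20L))

  # duplicate rows collapse: 3 proteins, 5 rows, one duplicate -> 4 sites
  tab <- read.csv(paths$sites)
  tab <- rbind(tab, tab[1L, ])
  dup_path <- file.path(paths$dir, "dup.csv")
  write.csv(tab, dup_path, row.names = FALSE, quote = FALSE)
  got2 <- read_annotations(paths$fasta, dup_path)
  expect_equal(sum(lengths(lapply(got2, `[[`, "sites"))), 4L)

  # position p = length is invalid (the pair would need residue length+1)
  bad <- data.frame(accession = "A1", position = nchar(recs$A1$sequence))
  bad_path <- file.path(paths$dir, "bad.csv")
  write.csv(bad, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(paths$fasta, bad_path), "out of bounds")

  unk <- data.frame(accession = "ZZ9", position = 3L)
  unk_path <- file.path(paths$dir, "unk.csv")
  write.csv(unk, unk_path, row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(paths$fasta, unk_path), "unknown accession")
})

test_that("sequences with non-standard letters are rejected unless mapped", {
  expect_error(protein_record("U1", "ACDEFGHIKB"), "non-standard")
  rec <- protein_record("U1", "ACDEFGHIKX", allow_x = TRUE)
  expect_equal(nchar(rec$sequence), 10L)
})

test_that("extract_window pads with X exactly at out-of-range positions", {
  rec <- protein_record("P", "ACDEFGHIKLMNPQRSTVWY")  # length 20
  w <- extract_window(rec, 10L, 22L)
  expect_equal(w$residues, "XACDEFGHIKLMNPQRSTVWYX")
  expect_equal(which(w$pad_mask), c(1L, 22L))
  # the bond residues sit at window sites k and k+1
  expect_equal(substr(w$residues, 11L, 12L),
               substr(rec$sequence, 10L, 11L))

  # interior window: no padding at all
  long <- protein_record("L", strrep("ACDEFGHIKL", 5L), sites = 25L)
  wi <- extract_window(long, 25L, 22L)
  expect_false(any(wi$pad_mask))

  # N-terminal window: coverage p-k+1 .. p+k, so p=1, W=16 gives 7 X
  w3 <- extract_window(rec, 1L, 16L)
  expect_equal(w3$residues, paste0(strrep("X", 7L), "ACDEFGHIK"))

  expect_error(extract_window(rec, 10L, 17L), "window size")
  expect_error(extract_window(rec, 20L, 16L), "out of range")
})

test_that("window round trip and X-count match brute-force enumeration", {
  set.seed(7)
  for (i in 1:25) {
    len <- sample(16:80, 1L)
    seqc <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"),
                         len, replace = TRUE), collapse = "")
    rec <- protein_record(sprintf("R%02d", i), seqc)
    W <- sample(c(16L, 18L, 20L, 22L), 1L)
    k <- W %/% 2L
    p <- sample(seq_len(len - 1L), 1L)
    w <- extract_window(rec, p, W)
    # brute force: enumerate covered positions and count those off-protein
    covered <- (p - k + 1L):(p + k)
    expect_equal(sum(w$pad_mask), sum(covered < 1L | covered > len))
    expect_equal(sum(w$pad_mask), max(0L, k - p) + max(0L, p + k - len))
    # sites k, k+1 always hold residues p, p+1
    expect_equal(substr(w$residues, k, k + 1L),
                 substr(rec$sequence, p, p + 1L))
  }
})

test_that("negative sampling avoids annotated bonds and hits the ratio", {
  tiny <- protein_record("T", "ACDEF", sites = 2L)  # bonds q in 1..4
  negs <- sample_negatives(tiny, 16L, n_negatives = 3L, seed = 1L)
  expect_setequal(vapply(negs, `[[`, integer(1L), "p"), c(1L, 3L, 4L))

  recs <- toy_records()  # 4 positives in total
  negs3 <- sample_negatives(recs, 22L, ratio = 3L, seed = 5L)
  expect_length(negs3, 12L)
  expect_true(all(vapply(negs3, `[[`, character(1L), "label") == "negative"))
  pos_keys <- unlist(lapply(recs, function(r) paste(r$accession, r$sites)))
  neg_keys <- vapply(negs3, function(w) paste(w$accession, w$p), character(1L))
  expect_length(intersect(pos_keys, neg_keys), 0L)

  # determinism: same seed identical, different seed differs
  again <- sample_negatives(recs, 22L, ratio = 3L, seed = 5L)
  expect_identical(vapply(again, `[[`, integer(1L), "p"),
                   vapply(negs3, `[[`, integer(1L), "p"))
  other <- sample_negatives(recs, 22L, ratio = 3L, seed = 6L)
  expect_false(identical(
    sort(vapply(other, function(w) paste(w$accession, w$p), character(1L))),
    sort(neg_keys)))

  # over-request drains the pool with a warning
  expect_warning(all_of_them <- sample_negatives(tiny, 16L,
                                                 n_negatives = 99L, seed = 1L),
                 "available")
  expect_length(all_of_them, 3L)
})

test_that("train/test split is a reproducible protein-level partition", {
  recs <- lapply(seq_len(459L), function(i) {
    protein_record(sprintf("P%03d", i), strrep("ACDEFGHIKL", 3L), sites = 10L)
  })
  sp <- split_train_test(recs, test_fraction = 88 / 459, seed = 3L)
  expect_length(sp$test, 88L)
  expect_length(sp$train, 371L)
  expect_length(intersect(names(sp$train), names(sp$test)), 0L)
  expect_setequal(c(names(sp$train), names(sp$test)),
                  vapply(recs, `[[`, character(1L), "accession"))

  sp2 <- split_train_test(recs, test_fraction = 88 / 459, seed = 3L)
  expect_identical(names(sp2$test), names(sp$test))

  ten <- recs[1:10]
  tiny_split <- split_train_test(ten, test_fraction = 0.01, seed = 1L)
  expect_gte(length(tiny_split$test), 1L)
  expect_error(split_train_test(recs[1L], 0.5), "at least 2")
  expect_error(split_train_test(ten, 1.2), "between 0 and 1")
})
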