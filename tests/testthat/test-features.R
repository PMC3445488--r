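test_that("feature naming is complete and the grammar round-trips", {
  expect_length(feature_names(22L), 704L)
  expect_length(feature_names(20L), 640L)
  expect_length(feature_names(18L), 576L)
  expect_length(feature_names(16L), 512L)

  nms <- feature_names(22L)
  expect_false(anyDuplicated(nms) > 0L)
  parsed <- parse_feature_name(nms)
  rebuilt <- sprintf("AA%d_%s_%d", parsed$site, parsed$family, parsed$k)
  expect_identical(rebuilt, nms)
  # 32 features per site in the fixed family order
  per_site <- parsed$family[parsed$site == 1L]
  expect_identical(per_site, rep(c("pssm", "disorder", "aafactor",
                                   "sa", "ss", "freq"),
                                 times = c(20L, 1L, 5L, 2L, 3L, 1L)))
  expect_error(parse_feature_name("AA3_bogus_1"), "unparseable")
  expect_error(parse_feature_name("AA3_pssm_21"), "out of range")
})

test_that("PSI-BLAST PSSM files round-trip through write and load", {
  d <- withr::local_tempdir()
  seqc <- "MKLVR"
  m <- matrix(1:100, nrow = 5L)
  write_pssm(m, file.path(d, "toy.pssm"), seqc)
  prof <- load_pssm(file.path(d, "toy.pssm"), sequence = seqc)
  expect_equal(dim(prof), c(5L, 20L))
  expect_equal(colnames(prof),
               c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"))
  expect_equal(unclass(prof)[, ], m, ignore_attr = TRUE)
  expect_equal(attr(prof, "residues"), seqc)

  # property: random integer matrices survive the round trip exactly
  set.seed(11)
  for (i in 1:5) {
    n <- sample(3:30, 1L)
    mm <- matrix(sample(-12:12, n * 20L, replace = TRUE), nrow = n)
    sq <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"),
                       n, replace = TRUE), collapse = "")
    write_pssm(mm, file.path(d, "rt.pssm"), sq)
    back <- load_pssm(file.path(d, "rt.pssm"), sequence = sq)
    expect_equal(unclass(back)[, ], mm, ignore_attr = TRUE)
  }

  # a row with only 19 scores is malformed, and the error names the line
  lines <- readLines(file.path(d, "toy.pssm"))
  row_idx <- grep("^\\s*3\\s", lines)[1L]
  toks <- strsplit(trimws(lines[row_idx]), "\\s+")[[1L]]
  lines[row_idx] <- paste(toks[-length(toks)], collapse = " ")
  writeLines(lines, file.path(d, "bad.pssm"))
  expect_error(load_pssm(file.path(d, "bad.pssm")), "line")
  # length mismatch against the declared sequence
  expect_error(load_pssm(file.path(d, "toy.pssm"), sequence = "MKLV"),
               "does not match")
})

test_that("disorder and structure readers validate their alphabets", {
  d <- withr::local_tempdir()
  writeLines(c("1\t0.2", "2\t0.9", "3\t0.5"), file.path(d, "a.disorder"))
  expect_equal(load_disorder(file.path(d, "a.disorder")), c(0.2, 0.9, 0.5))
  writeLines(c("1\t1.7"), file.path(d, "bad.disorder"))
  expect_error(load_disorder(file.path(d, "bad.disorder")), "\\[0, 1\\]")

  writeLines(c(">A1", "HHEOO"), file.path(d, "ss.txt"))
  ss <- load_structure(file.path(d, "ss.txt"), alphabet = c("H", "E", "O"))
  expect_equal(unname(ss["A1"]), "HHEOO")
  writeLines(c(">A1", "HHXOO"), file.path(d, "bad_ss.txt"))
  expect_error(load_structure(file.path(d, "bad_ss.txt"),
                              alphabet = c("H", "E", "O")), "outside")
})

test_that("frequency table rows are site distributions over 21 symbols", {
  rec <- protein_record("F", strrep("ACDEFGHIKLMNPQRSTVWY", 2L),
                        sites = c(15L, 20L, 25L))
  pos <- positive_windows(list(rec), 22L)
  ft <- build_frequency_table(pos)
  expect_equal(dim(ft), c(22L, 21L))
  expect_true(all(abs(rowSums(ft) - 1) < 1e-9))
  expect_true(all(ft >= 0))

  # degenerate: every window has R at site 11 -> frequency 1.0
  rrec <- protein_record("R", strrep("RA", 20L), sites = c(11L, 13L, 15L))
  rf <- build_frequency_table(positive_windows(list(rrec), 22L))
  expect_equal(unname(rf[11L, "R"]), 1.0)

  # hand count at site 1 over four windows (p = 3 pads to X there)
  h <- protein_record("H", "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                      sites = c(3L, 8L, 12L, 20L))
  hw <- positive_windows(list(h), 16L)
  s1 <- vapply(hw, function(w) substr(w$residues, 1L, 1L), character(1L))
  hf <- build_frequency_table(hw)
  for (sym in unique(s1)) {
    expect_equal(unname(hf[1L, sym]), mean(s1 == sym))
  }

  expect_error(build_frequency_table(list()), "zero windows")
  neg <- extract_window(rec, 10L, 22L, label = "negative")
  expect_error(build_frequency_table(list(neg)), "positive windows only")
})

test_that("encode_residue concatenates the six families in fixed order", {
  ft <- matrix(0, nrow = 16L, ncol = 21L,
               dimnames = list(NULL, c("A","C","D","E","F","G","H","I","K","L",
                                       "M","N","P","Q","R","S","T","V","W","Y",
                                       "X")))
  ft[1L, "A"] <- 0.5
  v <- encode_residue("A", 1L, pssm_row = 1:20, disorder_value = 0.2,
                      structure = list(ss = "helix", sa = "buried"),
                      freq_table = ft)
  expect_length(v, 32L)
  expect_equal(v, c(1:20, 0.2, unname(atchley_table()["A", ]),
                    1, 0, 1, 0, 0, 0.5))
  # strand/exposed flip only the one-hot blocks
  v2 <- encode_residue("A", 1L, 1:20, 0.2,
                       list(ss = "strand", sa = "exposed"), ft)
  expect_equal(v2[22:26], v[22:26])
  expect_equal(v2[27:31], c(0, 1, 0, 1, 0))

  expect_equal(encode_residue("X", 5L, 1:20, 0.9,
                              list(ss = "other", sa = "exposed"), ft),
               rep(0, 32L))
  expect_error(encode_residue("B", 1L, 1:20, 0.2,
                              list(ss = "helix", sa = "buried"), ft),
               "unknown residue")
})

test_that("encode_windows yields named W x 32 columns with zero X blocks", {
  recs <- toy_records()
  prov <- toy_providers(recs)
  pos <- positive_windows(recs, 22L)
  ft <- build_frequency_table(pos)
  fm <- encode_windows(pos, prov, ft)
  expect_equal(ncol(fm$features), 704L)
  expect_equal(nrow(fm$features), length(pos))
  expect_equal(colnames(fm$features)[(10L * 32L) + 20L], "AA11_pssm_20")

  # windows from B2 p=5 with W=22 have 6 leading X sites -> zero blocks
  w <- pos[[which(fm$meta$accession == "B2" & fm$meta$p == 5L)]]
  expect_true(any(w$pad_mask))
  row <- fm$features[which(fm$meta$accession == "B2" & fm$meta$p == 5L), ]
  for (s in which(w$pad_mask)) {
    block <- ((s - 1L) * 32L + 1L):(s * 32L)
    expect_equal(unname(row[block]), rep(0, 32L))
  }
  # non-padded sites carry the toy PSSM constant = protein position
  s <- which(!w$pad_mask)[1L]
  expect_equal(unname(row[(s - 1L) * 32L + 1L]), w$p - 11L + s)

  # encoding is pure: identical inputs give identical matrices
  fm2 <- encode_windows(pos, prov, ft)
  expect_identical(fm$features, fm2$features)

  # changing only the frequency table can move only the W freq columns
  ft2 <- ft
  ft2[] <- pmax(ft - 0.01, 0)
  ft2 <- ft2 / rowSums(ft2)
  fm3 <- encode_windows(pos, prov, ft2)
  changed <- colnames(fm$features)[colSums(fm$features != fm3$features) > 0L]
  expect_true(all(grepl("_freq_", changed)))
  expect_lte(length(changed), 22L)

  # missing provider data names the accession
  prov_bad <- prov
  prov_bad$pssm$B2 <- NULL
  expect_error(encode_windows(pos, prov_bad, ft), "B2")
})

test_that("synthetic providers are seed-stable and track the sequence", {
  recs <- generate_dataset(12L, c(60L, 150L), n_sites = 20L,
                           seed = 9L)$records
  p1 <- synthetic_providers(recs, seed = 4L)
  p2 <- synthetic_providers(recs, seed = 4L)
  expect_identical(p1, p2)
  p3 <- synthetic_providers(recs, seed = 5L)
  expect_false(identical(p1$pssm, p3$pssm))

  # profile lengths match sequences; PSSM argmax hits the own column >= 80%
  hits <- 0L; total <- 0L
  for (acc in names(recs)) {
    n <- nchar(recs[[acc]]$sequence)
    expect_equal(nrow(p1$pssm[[acc]]), n)
    expect_length(p1$disorder[[acc]], n)
    expect_length(p1$ss[[acc]], n)
    expect_length(p1$sa[[acc]], n)
    chars <- strsplit(recs[[acc]]$sequence, "")[[1L]]
    am <- apply(p1$pssm[[acc]], 1L, which.max)
    hits <- hits + sum(colnames(p1$pssm[[acc]])[am] == chars)
    total <- total + n
  }
  expect_gte(hits / total, 0.80)
})
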