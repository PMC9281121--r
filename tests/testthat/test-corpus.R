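test_that("degron tables load, collapse isoform duplicates, and reject mismatches", {
  proteome <- toy_proteome(list(
    GEN1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    GEN2 = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL"))
  degrons <- data.frame(
    protein_accession = c("GEN1", "GEN1-2", "GEN2", "GEN2"),
    start = c(5L, 8L, 3L, 10L),
    end = c(10L, 13L, 8L, 14L),
    sequence = c("YIAKQR", "YIAKQR", "DEFGHI", "WRONGX"),
    source = c("ELM", "study1", "ELM", "ELM"),
    e3 = c("E3A", "E3A", "", ""))
  fix <- write_degron_fixture(degrons, proteome)

  expect_message(tab <- load_degron_table(fix$tsv, proteome), "rejected")
  # isoform duplicate collapsed, mismatch rejected
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$protein_accession, c("GEN1", "GEN2"))
  expect_equal(nrow(attr(tab, "rejected")), 1L)
  expect_equal(attr(tab, "rejected")$sequence, "WRONGX")

  # empty table -> empty result
  empty <- degrons[0, ]
  fix2 <- write_degron_fixture(empty, proteome)
  expect_equal(nrow(load_degron_table(fix2$tsv, proteome)), 0L)

  # missing column -> format error; unresolvable accession -> lookup error
  bad <- degrons[1, ]; bad$start <- NULL
  tsv <- tempfile(); write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_degron_table(tsv, proteome), "missing columns")
  orphan <- degrons[1, ]; orphan$protein_accession <- "NOPE"
  fix3 <- write_degron_fixture(orphan, proteome)
  expect_error(load_degron_table(fix3$tsv, proteome), "no canonical sequence")
})

test_that("short degrons expand symmetrically and one-sidedly at termini", {
  p <- protein_record("P", paste(rep("ACDEFGHIKL", 5), collapse = ""))
  d3 <- data.frame(protein_accession = "P", start = 10L, end = 12L,
                   sequence = substr(p$sequence, 10, 12), source = "ELM", e3 = "")
  e3 <- expand_short_degron(d3, p)
  expect_equal(c(e3$start, e3$end), c(9L, 13L))
  expect_equal(e3$sequence, substr(p$sequence, 9, 13))

  dN <- data.frame(protein_accession = "P", start = 1L, end = 3L,
                   sequence = substr(p$sequence, 1, 3), source = "ELM", e3 = "")
  eN <- expand_short_degron(dN, p)
  expect_equal(c(eN$start, eN$end), c(1L, 5L))

  dC <- data.frame(protein_accession = "P", start = 48L, end = 50L,
                   sequence = substr(p$sequence, 48, 50), source = "ELM", e3 = "")
  eC <- expand_short_degron(dC, p)
  expect_equal(c(eC$start, eC$end), c(46L, 50L))

  d4 <- data.frame(protein_accession = "P", start = 20L, end = 23L,
                   sequence = substr(p$sequence, 20, 23), source = "ELM", e3 = "")
  e4 <- expand_short_degron(d4, p)
  expect_equal(c(e4$start, e4$end), c(19L, 24L))
  expect_equal(e4$end - e4$start + 1L, 6L)

  d5 <- data.frame(protein_accession = "P", start = 10L, end = 14L,
                   sequence = substr(p$sequence, 10, 14), source = "ELM", e3 = "")
  expect_identical(expand_short_degron(d5, p), d5)

  tiny <- protein_record("T", "ACDE")
  dt <- data.frame(protein_accession = "T", start = 1L, end = 3L,
                   sequence = "ACD", source = "ELM", e3 = "")
  expect_error(expand_short_degron(dt, tiny), "too short")
})

test_that("window sampling always contains the degron, pads termini, and round-trips", {
  p <- protein_record("P", random_sequence(300, seed = 11))
  d <- data.frame(protein_accession = "P", start = 140L, end = 147L,
                  sequence = substr(p$sequence, 140, 147), source = "ELM", e3 = "")
  ws <- sample_windows(d, p, k = 10L, w = 128L, seed = 3L)
  expect_length(ws, 10L)
  for (wi in ws) {
    expect_equal(nchar(wi$residues), 128L)
    # degron present at the labelled positions; label count == degron length
    expect_equal(sum(wi$y), 8L)
    span <- range(which(wi$y == 1L))
    expect_equal(substr(wi$residues, span[1], span[2]), d$sequence)
    # round-trip: residues equal the padded protein subsequence at the origin
    pos <- wi$window_start:(wi$window_start + 127L)
    expected <- vapply(pos, function(q)
      if (q >= 1 && q <= p$length) substr(p$sequence, q, q) else "X", character(1))
    expect_equal(wi$residues, paste(expected, collapse = ""))
  }

  # short protein: every window padded with X to full width
  ps <- protein_record("S", random_sequence(50, seed = 12))
  ds <- data.frame(protein_accession = "S", start = 20L, end = 25L,
                   sequence = substr(ps$sequence, 20, 25), source = "ELM", e3 = "")
  wss <- sample_windows(ds, ps, k = 5L, w = 128L, seed = 4L)
  expect_true(all(vapply(wss, function(wi) grepl("X", wi$residues), logical(1))))
  expect_true(all(vapply(wss, function(wi) sum(wi$y) == 6L, logical(1))))

  expect_length(sample_windows(d, p, k = 0L), 0L)
  expect_error(sample_windows(d, p, k = 1L, w = 5L), "smaller than degron")

  # determinism and full-containment under arbitrary seeds
  expect_identical(sample_windows(d, p, 6L, seed = 42L),
                   sample_windows(d, p, 6L, seed = 42L))
  for (seed in c(1L, 77L, 1234L)) {
    for (wi in sample_windows(d, p, 4L, w = 16L, seed = seed)) {
      expect_equal(sum(wi$y), 8L)
    }
  }
})

test_that("degron placement within the window is uniform over legal offsets", {
  p <- protein_record("P", random_sequence(200, seed = 21))
  d <- data.frame(protein_accession = "P", start = 100L, end = 103L,
                  sequence = substr(p$sequence, 100, 103), source = "ELM", e3 = "")
  w <- 16L  # 13 legal offsets
  ws <- sample_windows(d, p, k = 10000L, w = w, seed = 9L)
  offsets <- vapply(ws, function(wi) which.max(wi$y), integer(1))
  tab <- table(factor(offsets, levels = seq_len(w - 4L + 1L)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("labels mark degron spans and masks cover clipped 3-residue flanks", {
  lab <- make_labels(128L, list(c(60L, 65L)))
  expect_equal(which(lab$y == 1L), 60:65)
  expect_equal(which(lab$mask), c(57:59, 66:68))

  lab0 <- make_labels(128L, list())
  expect_equal(sum(lab0$y), 0L)
  expect_false(any(lab0$mask))

  labL <- make_labels(128L, list(c(1L, 5L)))
  expect_equal(which(labL$mask), 6:8)
  labR <- make_labels(10L, list(c(6L, 10L)))
  expect_equal(which(labR$mask), 3:5)
})

test_that("negative windows are match-centred, all-zero, and honour the ratio", {
  proteome <- toy_proteome(stats::setNames(
    lapply(1:20, function(i) random_sequence(200, seed = 100 + i)),
    paste0("NEG", 1:20)))
  matches <- do.call(rbind, lapply(names(proteome), function(a) {
    data.frame(protein_accession = a, start = seq(20L, 160L, by = 5L),
               end = seq(25L, 165L, by = 5L))
  }))
  neg <- sample_negative_windows(proteome, matches, n_pos = 100L, ratio = 5,
                                 w = 128L, seed = 8L)
  expect_length(neg, 500L)
  expect_true(all(vapply(neg, function(wi) sum(wi$y) == 0L, logical(1))))
  # match centre sits at the window midpoint
  wi <- neg[[1]]
  row <- matches[matches$protein_accession == wi$accession &
                   (matches$start + matches$end) %/% 2L ==
                   wi$window_start + 63L, ]
  expect_gte(nrow(row), 1L)

  expect_length(sample_negative_windows(proteome, matches, 100L, ratio = 0), 0L)
  expect_error(sample_negative_windows(proteome, matches[1:10, ], 100L, ratio = 20),
               "insufficient")
})

test_that("window TSV serialization round-trips", {
  p <- protein_record("P", random_sequence(200, seed = 31))
  d <- data.frame(protein_accession = "P", start = 90L, end = 96L,
                  sequence = substr(p$sequence, 90, 96), source = "ELM", e3 = "")
  ws <- sample_windows(d, p, k = 4L, seed = 5L)
  path <- tempfile(fileext = ".tsv")
  write_windows(ws, path)
  expect_identical(read_windows(path), ws)
})
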