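test_that("a database sequence matches itself exactly with identity scoring", {
  set.seed(51)
  seqs <- data.frame(id = c("a", "b"), label = c("F1", "F2"),
                     residues = vapply(1:2, function(i)
                       paste(sample(AA_STANDARD, 60, TRUE), collapse = ""),
                       character(1)), stringsAsFactors = FALSE)
  db <- identity_db_from_seqs(seqs)
  q <- seqs$residues[1]
  m <- classify_words(q, db)
  fwd_own <- m[m$direction == "forward" & m$family == "F1", ]
  # every window yields an exact forward match scoring 12
  expect_equal(sort(fwd_own$start), 0:(60 - 18))
  expect_true(all(rowSums(fwd_own$scores) == 12))
  # per-residue maxima of 1 across the whole sequence sum to its length
  ms <- mosaic_score(m, nchar(q))
  expect_equal(ms$total_score[ms$family == "F1"], 60)
  expect_equal(ms$covered_residues[ms$family == "F1"], 60)
})

test_that("same-family neighbours combine by per-position maximum, differing ones stay separate", {
  set.seed(52)
  a <- aa_ordering()
  base <- strsplit(random_word(), "")[[1]]
  base[c(10, 15)] <- "K"       # mid-rank letters keep room on both sides
  mk <- function(pos, letter) {
    w <- base; w[pos] <- letter; paste(w, collapse = "")
  }
  # stored words flank the query: w1 < q < w2 in evolutionary order, each
  # differing from it at one distinct suffix position
  q <- paste(base, collapse = "")
  w1 <- mk(10, "A")            # rank 0 < rank(K)
  w2 <- mk(15, "C")            # rank 19 > rank(K)
  for (labs in list(c("F1", "F1"), c("F1", "F2"))) {
    fwd <- dict_from_words(c(w1, w2), labs)
    db <- manual_db(fwd, dict_from_words(character(0), character(0),
                                         family_names = fwd$family_names),
                    identity_pssm(), identity_pssm(direction = "reverse"),
                    use_reverse = FALSE)
    m <- classify_words(q, db)
    if (labs[2] == "F1") {
      # one combined match: mismatch positions rescued by the other word
      expect_equal(nrow(m), 1L)
      expect_equal(rowSums(m$scores), 12)
    } else {
      expect_equal(nrow(m), 2L)
      expect_equal(sort(rowSums(m$scores)), c(11, 11))
    }
  }
})

test_that("word classification agrees with the brute-force oracle", {
  fx <- tiny_fixture()
  db <- fx$db
  set.seed(53)
  for (i in 1:25) {
    q <- paste(sample(AA_STANDARD, sample(18:40, 1), TRUE), collapse = "")
    got <- flatten_matches(classify_words(q, db))
    want <- oracle_classify(q, db)
    if (is.null(want)) {
      expect_true(is.null(got) || nrow(got) == 0L)
    } else {
      expect_equal(sort_matches(got), sort_matches(want), tolerance = 1e-12)
    }
  }
})

test_that("mosaic totals equal the per-residue enumeration oracle and the fast path", {
  fx <- tiny_fixture()
  db <- fx$db
  set.seed(54)
  for (i in 1:10) {
    q <- paste(sample(AA_STANDARD, 50, TRUE), collapse = "")
    m <- classify_words(q, db)
    ms <- mosaic_score(m, nchar(q))
    want <- oracle_mosaic(m, nchar(q))
    expect_equal(setNames(ms$total_score, ms$family),
                 want[ms$family], tolerance = 1e-9)
    fast <- mosaicmatch:::mosaic_totals(q, db)
    expect_equal(ms$total_score[order(ms$family)],
                 fast$total_score[order(fast$family)], tolerance = 1e-12)
  }
})

test_that("adding a same-family match never lowers that family's total", {
  fx <- tiny_fixture()
  db <- fx$db
  set.seed(55)
  q <- paste(sample(AA_STANDARD, 60, TRUE), collapse = "")
  m <- classify_words(q, db)
  expect_gte(nrow(m), 2L)
  for (drop in sample(nrow(m), min(5, nrow(m)))) {
    fam <- m$family[drop]
    with_all <- mosaic_score(m, 60)
    without <- mosaic_score(m[-drop, , drop = FALSE], 60)
    t1 <- with_all$total_score[with_all$family == fam]
    t0 <- without$total_score[without$family == fam]
    if (length(t0) == 0L) t0 <- -Inf
    expect_gte(t1, t0)
  }
})

test_that("classification is deterministic", {
  fx <- tiny_fixture()
  q <- fx$fam$holdout$residues[1]
  expect_identical(classify_words(q, fx$db), classify_words(q, fx$db))
  expect_identical(mosaicmatch:::mosaic_totals(q, fx$db),
                   mosaicmatch:::mosaic_totals(q, fx$db))
})

test_that("prediction applies thresholds, best-mode and tie-breaks", {
  set.seed(56)
  seqs <- data.frame(id = c("a", "b"), label = c("F1", "F2"),
                     residues = vapply(1:2, function(i)
                       paste(sample(AA_STANDARD, 40, TRUE), collapse = ""),
                       character(1)), stringsAsFactors = FALSE)
  mk_thr <- function(v) {
    structure(list(thresholds = matrix(v, 1, 3,
                     dimnames = list("default", c("32", "64", "128"))),
                   levels = c(default = 0.001), lengths = c(32L, 64L, 128L),
                   n_random = 0, seed = 1L), class = "threshold_table")
  }
  db <- identity_db_from_seqs(seqs)
  db$thresholds <- mk_thr(rep(1e6, 3))
  expect_equal(nrow(predict_protein(seqs$residues[1], db)), 0L)
  db$thresholds <- mk_thr(rep(-1e9, 3))
  all_hits <- predict_protein(seqs$residues[1], db, mode = "all")
  expect_gte(nrow(all_hits), 1L)
  best <- predict_protein(seqs$residues[1], db, mode = "best")
  expect_equal(nrow(best), 1L)
  expect_equal(best$family, "F1")
  expect_error(predict_protein(seqs$residues[1], db, level = "nope"), "level")

  # equal best scores resolve to the smaller family index
  m <- data.frame(family = c("F2", "F1"), direction = "forward",
                  start = 0L, stringsAsFactors = FALSE)
  m$positions <- rbind(6:17, 6:17)
  m$scores <- rbind(rep(1, 12), rep(1, 12))
  ms <- mosaic_score(m, 18)
  expect_equal(ms$family[1], "F1")
})

test_that("the reverse path mirrors the forward path on reversed inputs", {
  set.seed(57)
  seqs <- data.frame(id = sprintf("s%d", 1:4),
                     label = c("F1", "F1", "F2", "F2"),
                     residues = vapply(1:4, function(i)
                       paste(sample(AA_STANDARD, 50, TRUE), collapse = ""),
                       character(1)), stringsAsFactors = FALSE)
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  seqs_rev <- transform(seqs, residues = vapply(residues, rev_str,
                                                character(1)))
  # reverse-only classification of q against seqs
  db_rev_only <- identity_db_from_seqs(seqs)
  db_rev_only$forward <- dict_from_words(character(0), character(0),
                                         family_names = db_rev_only$family_names)
  # forward-only classification of reversed q against reversed seqs
  db_fwd_rev <- identity_db_from_seqs(seqs_rev, use_reverse = FALSE)
  q <- paste(sample(AA_STANDARD, 45, TRUE), collapse = "")
  t1 <- mosaicmatch:::mosaic_totals(q, db_rev_only)
  t2 <- mosaicmatch:::mosaic_totals(rev_str(q), db_fwd_rev)
  t1 <- t1[order(t1$family), ]; t2 <- t2[order(t2$family), ]
  expect_equal(t1$family, t2$family)
  expect_equal(t1$total_score, t2$total_score, tolerance = 1e-12)
})
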