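make_seq_df <- function(residues, label = "F1", id = NULL) {
  data.frame(id = if (is.null(id)) sprintf("s%d", seq_along(residues)) else id,
             label = label, residues = residues, stringsAsFactors = FALSE)
}

test_that("word extraction enumerates valid windows only", {
  set.seed(31)
  w18 <- random_word()
  expect_equal(nrow(extract_words(make_seq_df(w18))), 1L)
  expect_equal(nrow(extract_words(make_seq_df(substr(w18, 1, 17)))), 0L)
  # X at position 10 of a 20-residue sequence: every 18-window covers it
  s20 <- paste0(substr(random_word(), 1, 9), "X",
                paste(sample(aa_ordering()$letters, 10, TRUE), collapse = ""))
  expect_equal(nchar(s20), 20L)
  ew <- extract_words(make_seq_df(s20))
  expect_equal(nrow(ew), 0L)
  expect_equal(attr(ew, "n_skipped"), 3L)
  # a 20-residue clean sequence gives 3 windows
  s20b <- paste(sample(aa_ordering()$letters, 20, TRUE), collapse = "")
  expect_equal(nrow(extract_words(make_seq_df(s20b))), 3L)
  # lowercase means pre-masked
  expect_equal(nrow(extract_words(make_seq_df(tolower(w18)))), 0L)
})

test_that("entropy masking suppresses low-complexity tracts", {
  poly <- strrep("A", 40)
  expect_true(all(mask_low_complexity(poly)))
  set.seed(8)
  diverse <- paste(sample(AA_STANDARD, 40, TRUE), collapse = "")
  expect_false(any(mask_low_complexity(diverse)))
  mixed <- paste0(diverse, strrep("S", 30), diverse)
  m <- mask_low_complexity(mixed)
  expect_true(any(m[41:70]))
  expect_false(any(m[1:29]))
  expect_lt(nrow(extract_words(make_seq_df(mixed), masker = "entropy")),
            nrow(extract_words(make_seq_df(mixed), masker = "none")))
})

test_that("dictionary construction applies dedup, ambiguity and singleton rules", {
  empty <- build_dictionary(data.frame(prefix = numeric(0),
                                       suffix = numeric(0),
                                       label = character(0)))
  expect_equal(length(empty$suffixes), 0L)

  # identical word under two families is removed entirely
  set.seed(32)
  w <- random_word()
  d <- dict_from_words(c(w, w), c("F1", "F2"))
  expect_equal(length(d$suffixes), 0L)
  expect_equal(unname(d$stats["ambiguous"]), 2L)

  # duplicates of the same (word, label) collapse to one entry
  d2 <- dict_from_words(c(w, w, w), c("F1", "F1", "F1"))
  expect_equal(length(d2$suffixes), 1L)
  expect_equal(unname(d2$stats["deduplicated"]), 2L)

  # singleton flagging on a sorted 6-word toy: labels F1 F1 F2 F1 F1 F2
  # -> words 3 and 6 are flagged (word 3's neighbours are F1/F1, word 6's
  # single neighbour is F1)
  words <- vapply(1:6, function(i) random_word(), character(1))
  enc <- lapply(words, encode_word)
  words <- words[order(vapply(enc, `[[`, numeric(1), "prefix_code"),
                       vapply(enc, `[[`, numeric(1), "suffix_code"))]
  labs <- c("F1", "F1", "F2", "F1", "F1", "F2")  # in dictionary sort order
  d3 <- dict_from_words(words, labs)
  l <- d3$labels
  exp_sing <- vapply(seq_along(l), function(i) {
    nb <- l[setdiff(c(i - 1L, i + 1L), c(0L, length(l) + 1L))]
    all(nb != l[i])
  }, logical(1))
  expect_equal(d3$singleton, exp_sing)
  expect_equal(sum(d3$singleton), 2L)
})

test_that("prefix blocks partition the sorted dictionary", {
  set.seed(33)
  words <- unique(vapply(1:100, function(i) random_word(), character(1)))
  labs <- sample(c("F1", "F2", "F3"), length(words), TRUE)
  d <- dict_from_words(words, labs)
  expect_equal(d$block_start[1], 0L)
  expect_equal(d$block_end[length(d$block_end)], length(d$suffixes))
  expect_true(all(d$block_start[-1] == d$block_end[-length(d$block_end)]))
  expect_false(is.unsorted(d$prefix_keys, strictly = TRUE))
  # within blocks suffixes strictly increase
  for (b in seq_along(d$prefix_keys)) {
    idx <- (d$block_start[b] + 1L):d$block_end[b]
    expect_false(is.unsorted(d$suffixes[idx], strictly = TRUE))
  }
})

test_that("binary-search lookup agrees with a linear-scan oracle", {
  set.seed(34)
  words <- unique(vapply(1:100, function(i) random_word(), character(1)))
  d <- dict_from_words(words, sample(c("F1", "F2"), length(words), TRUE))

  # exact query
  wq <- decode_word(d$prefixes[5], d$suffixes[5], d$shape, d$alphabet)
  r <- dict_lookup(d, wq)
  expect_equal(r$kind, "exact")
  expect_equal(r$distance, 0)

  # neighbours sharing 17 leading residues are at LCP distance 1
  base <- strsplit(random_word(), "")[[1]]
  a <- aa_ordering()
  w1 <- paste(c(base[1:17], a$inverse[1]), collapse = "")
  w2 <- paste(c(base[1:17], a$inverse[5]), collapse = "")
  q  <- paste(c(base[1:17], a$inverse[3]), collapse = "")
  d2 <- dict_from_words(c(w1, w2), c("F1", "F1"))
  r2 <- dict_lookup(d2, q)
  expect_equal(r2$kind, "insert")
  expect_equal(r2$distance, c(1L, 1L))
  expect_setequal(r2$word, c(w1, w2))

  # 200 random queries against the oracle
  for (i in 1:200) {
    q <- random_word()
    enc <- encode_word(q, d$shape, d$alphabet)
    got <- mosaicmatch:::cpp_lookup(mosaicmatch:::dict_view(d),
                      as.integer(enc$prefix_code),
                      enc$suffix_code, 6L, 12L, TRUE)
    want <- oracle_lookup(d$prefixes, d$suffixes, d$labels,
                          enc$prefix_code, enc$suffix_code)
    expect_equal(got$kind, want$kind)
    expect_equal(sort(got$index), sort(want$index))
  }

  expect_equal(dict_lookup(dict_from_words(character(0), character(0)),
                           random_word())$kind, "none")
})

test_that("the reverse dictionary equals the forward pipeline on reversed words", {
  set.seed(35)
  seqs <- make_seq_df(vapply(1:10, function(i)
    paste(sample(AA_STANDARD, 40, TRUE), collapse = ""), character(1)),
    label = rep(c("F1", "F2"), 5))
  rev_d <- reverse_dictionary(seqs, family_names = c("F1", "F2"))
  # independent construction: reverse every 18-mer window by hand
  manual <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
    ch <- strsplit(seqs$residues[i], "")[[1]]
    do.call(rbind, lapply(0:(length(ch) - 18L), function(s) {
      w <- paste(rev(ch[(s + 1):(s + 18)]), collapse = "")
      e <- encode_word(w)
      data.frame(prefix = e$prefix_code, suffix = e$suffix_code,
                 label = seqs$label[i], stringsAsFactors = FALSE)
    }))
  }))
  fwd_on_rev <- build_dictionary(manual, family_names = c("F1", "F2"))
  expect_identical(rev_d$suffixes, fwd_on_rev$suffixes)
  expect_identical(rev_d$labels, fwd_on_rev$labels)
  expect_identical(rev_d$prefix_keys, fwd_on_rev$prefix_keys)
})

test_that("after singleton removal every word keeps a same-label neighbour", {
  set.seed(36)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    words <- unique(vapply(seq_len(n * 2), function(i) random_word(),
                           character(1)))[1:n]
    labs <- sample(sprintf("F%d", 1:4), n, TRUE)
    d <- remove_singletons(dict_from_words(words, labs))
    l <- d$labels
    m <- length(l)
    if (m < 2) next
    ok <- vapply(seq_len(m), function(i) {
      nb <- l[setdiff(c(i - 1L, i + 1L), c(0L, m + 1L))]
      any(nb == l[i]) || i %in% c(1L, m)
    }, logical(1))
    expect_true(all(ok))
  }
})
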