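# dictionary stub with given sorted labels (suffix codes are arbitrary but
# distinct and increasing; prefix constant)
label_dict <- function(labels, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  fam <- sort(unique(labels))
  structure(list(shape = word_shape(), alphabet = aa_ordering(),
                 direction = "forward",
                 suffixes = as.numeric(sort(sample.int(20^6, n))),
                 prefixes = rep(0, n),
                 labels = match(labels, fam), singleton = logical(n),
                 family_names = fam,
                 prefix_keys = 0L, block_start = 0L, block_end = n,
                 stats = c(input = n)),
            class = "word_dictionary")
}

# training split constructed by hand (pair i joins words i and i+1)
manual_split <- function(train, validation, y) {
  structure(list(train = train, validation = validation, y = y,
                 n_words = length(y) + 1L), class = "training_split")
}

test_that("mixed-location rule routes pairs into train and validation", {
  s1 <- make_training_split(label_dict(c("F1", "F1", "F1")))
  expect_length(s1$train, 0)
  expect_length(s1$validation, 2)
  expect_equal(s1$y, c(1L, 1L))

  s2 <- make_training_split(label_dict(c("F1", "F1", "F2")))
  expect_equal(sort(s2$train), c(1L, 2L))  # location 2 is mixed
  expect_length(s2$validation, 0)

  s3 <- make_training_split(label_dict(c("F1", "F2", "F1", "F1")))
  expect_equal(sort(s3$train), c(2L, 3L))  # location 3 is mixed
  expect_equal(s3$validation, 1L)
  expect_equal(s3$y, c(-1L, -1L, 1L))

  expect_length(make_training_split(label_dict("F1"))$train, 0)
})

# words chained so that consecutive pairs alternate: odd pairs substitute
# within a conservative set at `inf_pos`, even pairs substitute uniformly;
# suffix positions outside inf_pos are uniform for both classes
chain_words <- function(n_words, inf_pos, cons_set = c("L", "I", "V", "M")) {
  a <- aa_ordering()
  slen <- 12L
  w <- matrix("", n_words, 18L)
  w[1, ] <- sample(a$letters, 18L, TRUE)
  for (i in 2:n_words) {
    prev <- w[i - 1L, ]
    cur <- prev
    if (i %% 2 == 0) {            # conservative move (positive pair)
      for (j in inf_pos)
        cur[6L + j] <- sample(cons_set, 1L)
      for (j in setdiff(seq_len(slen), inf_pos))
        cur[6L + j] <- sample(a$letters, 1L)
    } else {                      # uniform move (negative pair)
      for (j in seq_len(slen))
        cur[6L + j] <- sample(a$letters, 1L)
    }
    w[i, ] <- cur
  }
  apply(w, 1L, paste, collapse = "")
}

# also force the "positive" words to carry conservative letters at inf_pos
seed_conservative <- function(words, inf_pos, cons_set = c("L", "I", "V", "M")) {
  vapply(words, function(w) {
    ch <- strsplit(w, "")[[1]]
    for (j in inf_pos) ch[6L + j] <- sample(cons_set, 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

test_that("ridge fit matches the dense normal-equations oracle", {
  set.seed(41)
  words <- vapply(1:21, function(i) random_word(), character(1))
  d <- dict_from_words(words, rep("F1", 21))
  stopifnot(length(d$suffixes) == 21)
  y <- sample(c(-1L, 1L), 20L, TRUE)
  split <- manual_split(train = 1:20, validation = integer(0), y = y)
  fit <- fit_pssm(d, split, lambda_grid = 1)
  digits <- mosaicmatch:::cpp_code_digits(d$suffixes, 12L)
  w_oracle <- oracle_ridge(digits, 1:20, y, lambda = 1)
  w_fit <- numeric(4800)
  for (j in 1:12)
    w_fit[(j - 1) * 400 + seq_len(400)] <- as.numeric(t(fit$matrices[, , j]))
  expect_lt(max(abs(w_fit - w_oracle)), 1e-6)
})

test_that("extreme regularization shrinks all scores to zero", {
  set.seed(42)
  words <- vapply(1:40, function(i) random_word(), character(1))
  d <- dict_from_words(words, rep("F1", 40))
  n <- length(d$suffixes)
  y <- rep_len(c(1L, -1L), n - 1L)
  split <- manual_split(train = seq_len(20), validation = seq(21L, n - 1L),
                        y = y)
  fit <- fit_pssm(d, split, lambda_grid = 1e9)
  expect_lt(max(abs(fit$matrices)), 1e-5)
  # all predictions ~0 count as negative: accuracy = share of -1 targets
  expect_equal(fit$validation_accuracy,
               mean(y[split$validation] == -1L))
})

test_that("training error is non-decreasing in lambda and informative positions dominate the SSW profile", {
  set.seed(43)
  inf_pos <- 1:4
  words <- chain_words(400, inf_pos)
  words <- ifelse(seq_along(words) %% 2 == 0,
                  seed_conservative(words, inf_pos), words)
  d <- structure(list(shape = word_shape(), alphabet = aa_ordering(),
                      direction = "forward",
                      suffixes = vapply(words, function(w)
                        encode_word(w)$suffix_code, numeric(1),
                        USE.NAMES = FALSE),
                      prefixes = numeric(400), labels = rep(1L, 400),
                      singleton = logical(400), family_names = "F1",
                      prefix_keys = 0L, block_start = 0L, block_end = 400L,
                      stats = c(input = 400L)),
                 class = "word_dictionary")
  np <- 399L
  y <- ifelse(seq_len(np) %% 2 == 1L, 1L, -1L)  # pair (2i-1, 2i) is positive
  train <- seq_len(240L)
  split <- manual_split(train, setdiff(seq_len(np), train), y)
  fit <- fit_pssm(d, split)
  expect_true(all(diff(fit$train_rss) >= -1e-6))
  expect_gt(max(fit$validation_accuracy), 0.9)
  ssw <- ssw_profile(fit)
  expect_gt(min(ssw[inf_pos]), max(ssw[setdiff(1:12, inf_pos)]))
})

test_that("fit rejects degenerate training sets", {
  d <- label_dict(c("F1", "F1", "F1", "F1"))
  split <- make_training_split(d)
  expect_error(fit_pssm(d, split), "empty")
  split2 <- manual_split(1:2, 3L, c(1L, 1L, -1L))
  expect_error(fit_pssm(d, split2), "one class")
})

test_that("SSW profile is the per-position squared Frobenius norm", {
  arr <- array(0, dim = c(20, 20, 12))
  p0 <- manual_pssm(arr)
  expect_equal(ssw_profile(p0), rep(0, 12))
  arr[3, 7, 1] <- 2
  expect_equal(ssw_profile(manual_pssm(arr)), c(4, rep(0, 11)))
  set.seed(44)
  arr[] <- rnorm(4800)
  expect_lt(max(abs(ssw_profile(manual_pssm(arr)) -
                    apply(arr, 3, function(m) sum(m^2)))), 1e-12)
})

test_that("word-pair scoring indexes the PSSM by query row and reference column", {
  set.seed(45)
  arr <- array(rnorm(4800), dim = c(20, 20, 12))
  ps <- manual_pssm(arr)
  a <- aa_ordering()
  q <- random_word()
  r <- random_word()
  sc <- score_word_pair(ps, q, r)
  qd <- a$rank[strsplit(substr(q, 7, 18), "")[[1]]]
  rd <- a$rank[strsplit(substr(r, 7, 18), "")[[1]]]
  for (j in 1:12)
    expect_identical(sc[j], arr[qd[j] + 1, rd[j] + 1, j])
  # identical words hit the diagonal; identity matrices give 12 in total
  expect_equal(sum(score_word_pair(identity_pssm(), q, q)), 12)
  sc_diag <- score_word_pair(ps, q, q)
  expect_equal(sc_diag, arr[cbind(qd + 1, qd + 1, 1:12)],
               ignore_attr = TRUE)
})
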