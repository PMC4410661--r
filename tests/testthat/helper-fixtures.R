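# Shared small fixtures, built once per test run.

# small synthetic database: 4 families x 10 members x 120 aa, 5%
# substitutions; calibrated with a reduced random sample (tests that need
# the full-scale calibration build their own)
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- family_spec(n_families = 4, members = 10, length = 120,
                          rate = 0.05, n_holdout = 3, seed = 42)
      fam <- generate_families(spec)
      db <- build_database(fam$reference, n_random = 2000,
                           lengths = c(32L, 64L, 128L), seed = 11)
      cache <<- list(spec = spec, fam = fam, db = db)
    }
    cache
  }
})

# hand-sized dictionary from explicit words (no sequences involved)
dict_from_words <- function(words, labels, shape = word_shape(),
                            alph = aa_ordering(), family_names = NULL) {
  enc <- lapply(words, encode_word, shape = shape, alph = alph)
  build_dictionary(
    data.frame(prefix = vapply(enc, `[[`, numeric(1), "prefix_code"),
               suffix = vapply(enc, `[[`, numeric(1), "suffix_code"),
               label = labels, stringsAsFactors = FALSE),
    shape, alph, family_names = family_names)
}

# a bare pssm_set whose matrices are given explicitly (for controlled
# scoring in classify tests)
manual_pssm <- function(matrices, direction = "forward") {
  structure(list(matrices = matrices, lambda = 1,
                 lambda_grid = 1, validation_accuracy = NA_real_,
                 train_rss = NA_real_, n_train = NA_integer_,
                 n_validation = NA_integer_, orientation = "query-is-row",
                 direction = direction, alphabet = aa_ordering()$order),
            class = "pssm_set")
}

identity_pssm <- function(slen = 12L, direction = "forward") {
  arr <- array(0, dim = c(20L, 20L, slen))
  for (j in seq_len(slen)) arr[, , j] <- diag(20)
  manual_pssm(arr, direction)
}

# assemble a mosaic_db from parts (thresholds optional)
manual_db <- function(fwd, rev, pssm_fwd, pssm_rev, thresholds = NULL,
                      empty_block = "global", use_reverse = TRUE) {
  structure(list(shape = fwd$shape, alphabet = fwd$alphabet,
                 family_names = fwd$family_names,
                 forward = fwd, reverse = rev,
                 pssm_fwd = pssm_fwd, pssm_rev = pssm_rev,
                 thresholds = thresholds, background = read_background(),
                 options = list(empty_block = empty_block,
                                use_reverse = use_reverse),
                 meta = list(format_version = 1L, seed = 1L,
                             masker = "none", n_sequences = NA_integer_)),
            class = "mosaic_db")
}

random_word <- function(alph = aa_ordering(), n = 18L) {
  paste(sample(alph$letters, n, replace = TRUE), collapse = "")
}

# db of random same-length sequences, identity PSSMs (deterministic scores)
identity_db_from_seqs <- function(seqs, use_reverse = TRUE,
                                  empty_block = "global") {
  fn <- sort(unique(seqs$label))
  fwd <- build_dictionary(extract_words(seqs), family_names = fn)
  rev <- reverse_dictionary(seqs, family_names = fn)
  manual_db(fwd, rev, identity_pssm(), identity_pssm(direction = "reverse"),
            empty_block = empty_block, use_reverse = use_reverse)
}
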