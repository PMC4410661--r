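#' Mask low-complexity regions by sliding-window entropy
#'
#' Marks residues lying in any length-`window` window whose Shannon entropy
#' (base 2, over the residues present) falls below `threshold` bits.
#' Low-complexity tracts (poly-X runs, simple repeats) generate huge
#' numbers of spurious identical words across unrelated families; masking
#' them before word extraction keeps the dictionary informative. This is a
#' simple entropy masker with documented defaults (window 12, threshold
#' 2.2 bits); pre-masked input (lowercase residues) is also honoured by
#' [extract_words()].
#'
#' @param seq Amino-acid string.
#' @param window Window width in residues.
#' @param threshold Entropy threshold in bits; windows strictly below it
#'   are masked.
#' @return Logical vector, `TRUE` where the residue is masked.
#' @export
mask_low_complexity <- function(seq, window = 12L, threshold = 2.2) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  mask <- logical(n)
  if (n < window) return(mask)
  code <- match(chars, AA_STANDARD)      # NA for non-standard; they don't
  for (s in seq_len(n - window + 1L)) {  # contribute to entropy
    win <- code[s:(s + window - 1L)]
    win <- win[!is.na(win)]
    if (!length(win)) next
    p <- tabulate(win, nbins = 20L)
    p <- p[p > 0] / length(win)
    if (-sum(p * log2(p)) < threshold)
      mask[s:(s + window - 1L)] <- TRUE
  }
  mask
}

#' Extract encoded oligopeptide words from labelled sequences
#'
#' Slides a window of `shape$word_length` residues (stride 1) over each
#' sequence and encodes every valid window. Windows overlapping a masked
#' residue (lowercase input, or entropy-masked when `masker = "entropy"`)
#' or any non-standard character are skipped, never substituted: a wrong
#' residue would place the word at an arbitrary dictionary position.
#' Sequences shorter than the word length emit nothing.
#'
#' @param seqs A data frame with columns `id`, `label` and `residues`
#'   (amino-acid strings; lowercase letters are treated as pre-masked).
#' @param shape A [word_shape()].
#' @param alph An [aa_ordering()].
#' @param masker `"none"` or `"entropy"` (see [mask_low_complexity()]).
#' @return A data frame with columns `prefix`, `suffix` (numeric codes)
#'   and `label`; attribute `n_skipped` counts invalid windows.
#' @export
extract_words <- function(seqs, shape = word_shape(), alph = aa_ordering(),
                          masker = c("none", "entropy")) {
  masker <- match.arg(masker)
  stopifnot(is.data.frame(seqs), all(c("label", "residues") %in% names(seqs)))
  out_p <- vector("list", nrow(seqs))
  out_s <- vector("list", nrow(seqs))
  n_skipped <- 0L
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$residues[i]
    ranks <- residue_ranks(s, alph)      # NA for invalid and lowercase
    if (masker == "entropy") {
      m <- mask_low_complexity(toupper(s))
      ranks[m] <- NA_integer_
    }
    ranks[is.na(ranks)] <- -1L
    w <- cpp_window_codes(ranks, shape$prefix_length, shape$suffix_length,
                          reverse = FALSE)
    n_total <- max(0L, length(ranks) - shape$word_length + 1L)
    n_skipped <- n_skipped + n_total - length(w$start)
    out_p[[i]] <- w$prefix
    out_s[[i]] <- w$suffix
  }
  counts <- lengths(out_p)
  res <- data.frame(prefix = unlist(out_p), suffix = unlist(out_s),
                    label = rep(seqs$label, counts),
                    stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- n_skipped
  res
}

# prefix table (sorted occupied keys + half-open block offsets, 0-based)
# from the per-word prefix codes of an already-sorted dictionary
make_prefix_table <- function(prefixes) {
  if (!length(prefixes))
    return(list(prefix_keys = integer(0), block_start = integer(0),
                block_end = integer(0)))
  r <- rle(prefixes)
  ends <- cumsum(r$lengths)
  list(prefix_keys = as.integer(r$values),
       block_start = as.integer(ends - r$lengths),
       block_end = as.integer(ends))
}

# singleton flag: label differs from both sorted neighbours (boundary words
# compare only against their single neighbour); computed on the original
# sorted order, single pass
flag_singletons <- function(labels) {
  n <- length(labels)
  if (n <= 1L) return(logical(n))
  prev_diff <- c(TRUE, labels[-1] != labels[-n])
  next_diff <- c(labels[-n] != labels[-1], TRUE)
  sing <- prev_diff & next_diff
  sing[1] <- labels[1] != labels[2]
  sing[n] <- labels[n] != labels[n - 1L]
  sing
}

#' Build a sorted oligopeptide word dictionary
#'
#' Deduplicates identical (word, label) pairs, removes ambiguous words
#' (identical 18-mers submitted under two or more distinct families — the
#' word carries no unambiguous evidence), sorts by (prefix, suffix) code
#' under the evolutionary ordering, flags singleton words (label differing
#' from both sorted neighbours), and builds the hexamer prefix table.
#' Singletons are only flagged here: they are valuable negative examples
#' for PSSM training and are removed afterwards with
#' [remove_singletons()].
#'
#' @param words Data frame from [extract_words()] (columns `prefix`,
#'   `suffix`, `label`).
#' @param shape,alph Word shape and alphabet used for encoding.
#' @param family_names Optional fixed family universe (character); defaults
#'   to the sorted unique labels present. Supplying it keeps family indices
#'   aligned between the forward and reverse dictionaries.
#' @param direction `"forward"` or `"reverse"`.
#' @return A `word_dictionary` object.
#' @export
build_dictionary <- function(words, shape = word_shape(),
                             alph = aa_ordering(), family_names = NULL,
                             direction = "forward") {
  if (is.null(family_names))
    family_names <- sort(unique(words$label))
  lab <- match(words$label, family_names)
  if (anyNA(lab))
    stop("labels not in `family_names`: ",
         paste(unique(words$label[is.na(lab)]), collapse = ", "))
  n_input <- nrow(words)
  if (n_input == 0L) {
    d <- list(shape = shape, alphabet = alph, direction = direction,
              suffixes = numeric(0), prefixes = numeric(0),
              labels = integer(0), singleton = logical(0),
              family_names = family_names,
              prefix_keys = integer(0), block_start = integer(0),
              block_end = integer(0),
              stats = c(input = 0L, deduplicated = 0L, ambiguous = 0L,
                        singleton_flagged = 0L))
    class(d) <- "word_dictionary"
    return(d)
  }
  o <- order(words$prefix, words$suffix, lab)
  p <- words$prefix[o]; s <- words$suffix[o]; l <- lab[o]
  # collapse duplicate (word, label) pairs
  dup <- c(FALSE, p[-1] == p[-length(p)] & s[-1] == s[-length(s)] &
                  l[-1] == l[-length(l)])
  n_dedup <- sum(dup)
  p <- p[!dup]; s <- s[!dup]; l <- l[!dup]
  # ambiguous words: same (prefix, suffix) still present under >1 label
  same_next <- c(p[-1] == p[-length(p)] & s[-1] == s[-length(s)], FALSE)
  ambig <- same_next | c(FALSE, same_next[-length(same_next)])
  n_ambig <- sum(ambig)
  p <- p[!ambig]; s <- s[!ambig]; l <- l[!ambig]
  sing <- flag_singletons(l)
  d <- list(shape = shape, alphabet = alph, direction = direction,
            suffixes = s, prefixes = p, labels = l, singleton = sing,
            family_names = family_names,
            stats = c(input = n_input, deduplicated = n_dedup,
                      ambiguous = n_ambig, singleton_flagged = sum(sing)))
  d <- c(d, make_prefix_table(p))
  class(d) <- "word_dictionary"
  d
}

#' Build the reverse-word dictionary
#'
#' Applies the identical extract/build pipeline with every 18-mer reversed
#' (residue order flipped) before encoding. Reverse matching gives a query
#' word a second chance when its suffix is better conserved than its
#' prefix: the reversed word's leading hexamer is the original word's
#' (reversed) tail.
#'
#' @inheritParams extract_words
#' @inheritParams build_dictionary
#' @return A `word_dictionary` with `direction = "reverse"`.
#' @export
reverse_dictionary <- function(seqs, shape = word_shape(),
                               alph = aa_ordering(),
                               masker = c("none", "entropy"),
                               family_names = NULL) {
  masker <- match.arg(masker)
  out_p <- vector("list", nrow(seqs)); out_s <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$residues[i]
    ranks <- residue_ranks(s, alph)
    if (masker == "entropy") {
      m <- mask_low_complexity(toupper(s))
      ranks[m] <- NA_integer_
    }
    ranks[is.na(ranks)] <- -1L
    w <- cpp_window_codes(ranks, shape$prefix_length, shape$suffix_length,
                          reverse = TRUE)
    out_p[[i]] <- w$prefix; out_s[[i]] <- w$suffix
  }
  counts <- lengths(out_p)
  words <- data.frame(prefix = unlist(out_p), suffix = unlist(out_s),
                      label = rep(seqs$label, counts),
                      stringsAsFactors = FALSE)
  build_dictionary(words, shape, alph, family_names, direction = "reverse")
}

#' Remove flagged singleton words from a dictionary
#'
#' Drops the words whose label differed from both sorted neighbours at
#' build time and rebuilds the prefix table. Removal is a single pass on
#' the original neighbourhood (no cascade): a retained word's
#' label-sharing neighbour is by construction never a singleton, so no new
#' singletons can arise.
#'
#' @param dict A `word_dictionary`.
#' @return The pruned `word_dictionary`.
#' @export
remove_singletons <- function(dict) {
  keep <- !dict$singleton
  dict$suffixes <- dict$suffixes[keep]
  dict$prefixes <- dict$prefixes[keep]
  dict$labels <- dict$labels[keep]
  dict$singleton <- logical(sum(keep))
  dict[c("prefix_keys", "block_start", "block_end")] <-
    make_prefix_table(dict$prefixes)
  dict$stats["singleton_removed"] <- sum(!keep)
  dict
}

#' @export
print.word_dictionary <- function(x, ...) {
  cat(sprintf("word_dictionary (%s): %d words, %d families, %d prefix blocks\n",
              x$direction, length(x$suffixes), length(x$family_names),
              length(x$prefix_keys)))
  if (any(x$singleton))
    cat(sprintf("  %d singleton-flagged words pending removal\n",
                sum(x$singleton)))
  invisible(x)
}

# C++-facing view (plain list, 0-based offsets)
dict_view <- function(dict) {
  list(prefix_keys = dict$prefix_keys, block_start = dict$block_start,
       block_end = dict$block_end, suffixes = dict$suffixes,
       labels = dict$labels)
}

#' Nearest-neighbour lookup of a word in the dictionary
#'
#' Binary search in the block of words sharing the query's hexamer prefix.
#' An exact match returns the stored word and its family; otherwise the
#' insertion position in the dictionary is returned with the (up to) two
#' adjacent reference words and their LCP distances (word length minus the
#' longest common prefix, computed over all 18 positions). When the
#' query's prefix block is empty, behaviour depends on `empty_block`:
#' `"global"` (default) consults the flanking words across the global
#' sorted order; `"skip"` reports no match.
#'
#' @param dict A `word_dictionary`.
#' @param word Query word (string of `word_length` residues), or `NULL` if
#'   `prefix_code`/`suffix_code` are given directly.
#' @param prefix_code,suffix_code Encoded query (used when `word` is NULL).
#' @param empty_block `"global"` or `"skip"`.
#' @return A list with `kind` (`"exact"`, `"insert"` or `"none"`) and, for
#'   matches, parallel vectors `index`, `word` (decoded), `label` (family
#'   name) and `distance`.
#' @export
dict_lookup <- function(dict, word = NULL, prefix_code = NULL,
                        suffix_code = NULL,
                        empty_block = c("global", "skip")) {
  empty_block <- match.arg(empty_block)
  if (!is.null(word)) {
    enc <- encode_word(word, dict$shape, dict$alphabet)
    if (is.null(enc)) stop("query word contains non-standard residues")
    prefix_code <- enc$prefix_code; suffix_code <- enc$suffix_code
  }
  res <- cpp_lookup(dict_view(dict), as.integer(prefix_code), suffix_code,
                    dict$shape$prefix_length, dict$shape$suffix_length,
                    empty_block == "global")
  if (res$kind == "none") return(res)
  res$word <- vapply(res$index, function(i)
    decode_word(dict$prefixes[i], dict$suffixes[i], dict$shape,
                dict$alphabet), character(1))
  res$label <- dict$family_names[res$label]
  res
}
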