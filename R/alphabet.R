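#' @useDynLib mosaicmatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head tail read.table capture.output
NULL

#' The 20 standard amino acids in conventional (alphabetical) order
#' @format Character vector of 20 one-letter codes.
#' @export
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","W","Y","V")

# Evolutionary ordering used by default throughout: amino acids arranged so
# that lexicographically adjacent oligopeptide words tend to share a family
# label. Shipped as a fixed constant so databases are bit-stable across
# builds; alphabet_distance()/shortest_cyclic_order() recompute orderings
# for user-supplied scoring matrices.
EVOLUTIONARY_ORDER <- "ATSPGNDEQKRHYWFMLIVC"

#' Create an amino-acid alphabet ordering
#'
#' An `aa_ordering` fixes a permutation of the 20 standard amino acids and
#' the induced rank encoding (rank 0 for the first letter, 19 for the last).
#' All dictionary sorting, word encoding and PSSM indexing is performed in
#' this ordering. The default is an evolutionary ordering chosen (via the
#' shortest cyclic path through cosine distances between scoring-matrix
#' columns) so that adjacent words in a sorted dictionary tend to belong to
#' the same protein family.
#'
#' @param order A string of 20 distinct amino-acid letters, or a character
#'   vector of 20 single letters. Defaults to the evolutionary ordering
#'   `"ATSPGNDEQKRHYWFMLIVC"`.
#' @return An object of class `aa_ordering` with elements `order` (string),
#'   `letters` (character vector), `rank` (named integer vector, 0-based)
#'   and `inverse` (character vector indexed by rank + 1).
#' @examples
#' alph <- aa_ordering()
#' alph$rank[["A"]]  # 0
#' alph$rank[["T"]]  # 1
#' @export
aa_ordering <- function(order = EVOLUTIONARY_ORDER) {
  if (length(order) == 1L && nchar(order) == 20L)
    letters20 <- strsplit(order, "")[[1]]
  else
    letters20 <- as.character(order)
  if (length(letters20) != 20L || !setequal(letters20, AA_STANDARD) ||
      anyDuplicated(letters20))
    stop("`order` must be a permutation of the 20 standard amino acids")
  rank <- setNames(seq_along(letters20) - 1L, letters20)
  structure(
    list(order = paste(letters20, collapse = ""),
         letters = letters20,
         rank = rank,
         inverse = letters20),
    class = "aa_ordering")
}

#' @export
print.aa_ordering <- function(x, ...) {
  cat("Amino-acid alphabet ordering:", x$order, "\n")
  invisible(x)
}

#' Word shape: total length and prefix/suffix split
#'
#' Oligopeptide words have a fixed length (default 18 residues) split into a
#' hexamer prefix, which indexes dictionary blocks, and a 12-residue suffix,
#' which is stored explicitly and scored by the PSSMs. The suffix code must
#' fit 64-bit integer semantics; with base-20 digits this bounds the suffix
#' at 14 residues (20^14 < 2^64), and exact double representation used
#' internally bounds it at 12 (20^12 < 2^53).
#'
#' @param word_length Total word length in residues (default 18).
#' @param prefix_length Prefix length in residues (default 6).
#' @return An object of class `word_shape`.
#' @export
word_shape <- function(word_length = 18L, prefix_length = 6L) {
  word_length <- as.integer(word_length)
  prefix_length <- as.integer(prefix_length)
  suffix_length <- word_length - prefix_length
  if (prefix_length < 1L || suffix_length < 1L)
    stop("prefix and suffix lengths must be positive")
  if (suffix_length * log2(20) > 53)
    stop("suffix of ", suffix_length,
         " residues does not fit exact 64-bit/double integer encoding")
  if (prefix_length * log2(20) > 31)
    stop("prefix of ", prefix_length, " residues does not fit a 32-bit code")
  structure(list(word_length = word_length,
                 prefix_length = prefix_length,
                 suffix_length = suffix_length),
            class = "word_shape")
}

#' @export
print.word_shape <- function(x, ...) {
  cat(sprintf("word shape: %d residues = %d (prefix) + %d (suffix)\n",
              x$word_length, x$prefix_length, x$suffix_length))
  invisible(x)
}

#' Cosine distances between scoring-matrix columns
#'
#' Computes the pairwise dissimilarity d_ij = 1 - s_i's_j / (|s_i| |s_j|)
#' between the column vectors s_i of a 20 x 20 amino-acid scoring matrix.
#' These distances drive the evolutionary re-ordering of the alphabet: amino
#' acids whose substitution profiles are similar end up adjacent, so words
#' differing by a conservative substitution stay close in the sorted
#' dictionary.
#'
#' @param S A 20 x 20 numeric matrix with amino-acid letters as row and
#'   column names (a substitution scoring matrix).
#' @return A symmetric 20 x 20 distance matrix with zero diagonal; entries
#'   lie in \[0, 2\].
#' @seealso [shortest_cyclic_order()], [read_scoring_matrix()]
#' @export
alphabet_distance <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S))
    stop("S must be square")
  if (is.null(colnames(S)))
    stop("S must carry amino-acid letters as dimnames")
  nrm <- sqrt(colSums(S^2))
  if (any(nrm == 0))
    stop("zero-norm column for amino acid(s): ",
         paste(colnames(S)[nrm == 0], collapse = ", "))
  C <- crossprod(S) / tcrossprod(nrm)
  D <- 1 - C
  D <- (D + t(D)) / 2          # enforce exact symmetry
  diag(D) <- 0
  dimnames(D) <- dimnames(S)
  D
}

# total length of the cyclic tour visiting D's elements in order `perm`
tour_length <- function(D, perm) {
  nxt <- c(perm[-1], perm[1])
  sum(D[cbind(perm, nxt)])
}

# Held-Karp dynamic program over subsets; exact minimum cyclic tour.
# Feasible up to n ~ 12 (the documented limit for method = "exact").
held_karp <- function(D) {
  n <- nrow(D)
  m <- n - 1L                       # cities 2..n relative to fixed start 1
  full <- bitwShiftL(1L, m) - 1L
  cost <- matrix(Inf, nrow = full + 1L, ncol = m)
  parent <- matrix(NA_integer_, nrow = full + 1L, ncol = m)
  for (j in seq_len(m))
    cost[bitwShiftL(1L, j - 1L) + 1L, j] <- D[1L, j + 1L]
  for (mask in seq_len(full)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(members) < 2L) next
    for (j in members) {
      sub <- mask - bitwShiftL(1L, j - 1L)
      prev <- which(bitwAnd(sub, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
      cands <- cost[sub + 1L, prev] + D[prev + 1L, j + 1L]
      b <- which.min(cands)
      cost[mask + 1L, j] <- cands[b]
      parent[mask + 1L, j] <- prev[b]
    }
  }
  ends <- cost[full + 1L, ] + D[seq_len(m) + 1L, 1L]
  j <- which.min(ends)
  tour <- integer(m)
  mask <- full
  for (k in m:1) {
    tour[k] <- j + 1L
    pj <- parent[mask + 1L, j]
    mask <- mask - bitwShiftL(1L, j - 1L)
    j <- pj
    if (k == 1L) break
  }
  c(1L, tour)
}

# nearest-neighbour construction followed by 2-opt refinement
tsp_heuristic <- function(D, max_sweeps = 50L) {
  n <- nrow(D)
  # nearest-neighbour start
  perm <- integer(n); used <- logical(n)
  perm[1] <- 1L; used[1] <- TRUE
  for (k in 2:n) {
    d <- D[perm[k - 1L], ]
    d[used] <- Inf
    perm[k] <- which.min(d)
    used[perm[k]] <- TRUE
  }
  # 2-opt: reverse segments while any improvement is found
  improved <- TRUE; sweeps <- 0L
  while (improved && sweeps < max_sweeps) {
    improved <- FALSE; sweeps <- sweeps + 1L
    for (i in 1:(n - 1L)) {
      for (k in (i + 1L):n) {
        a <- perm[i]; b <- perm[if (i == 1L) n else i - 1L]
        c_ <- perm[k]; d_ <- perm[if (k == n) 1L else k + 1L]
        if (b == c_ || a == d_) next
        delta <- (D[b, c_] + D[a, d_]) - (D[b, a] + D[c_, d_])
        if (delta < -1e-12) {
          perm[i:k] <- rev(perm[i:k])
          improved <- TRUE
        }
      }
    }
  }
  perm
}

# canonical representative of a cyclic tour: rotate so the smallest label
# comes first, then pick the direction with the smaller second label
canonical_tour <- function(perm) {
  n <- length(perm)
  s <- which(perm == min(perm))
  perm <- perm[c(s:n, seq_len(s - 1L))]
  if (perm[2] > perm[n])
    perm <- c(perm[1], rev(perm[-1]))
  perm
}

#' Order an alphabet along the shortest cyclic path
#'
#' Finds a cyclic tour through all alphabet elements minimizing the summed
#' pairwise distance, and returns the visiting order as an alphabet
#' ordering. `method = "exact"` uses a Held-Karp dynamic program and is
#' limited to 12 or fewer elements (it is intended for validation on small
#' alphabets); `method = "heuristic"` uses a nearest-neighbour start with
#' 2-opt refinement and never returns a tour longer than the identity
#' ordering's.
#'
#' The returned tour is canonicalized: rotated so the lexicographically
#' smallest letter starts it and reflected so its successor is the smaller
#' of the two possible neighbours, making the result deterministic among
#' the 2n equivalent representations of a cyclic tour.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal and
#'   letters as dimnames (for a 20-letter input, a permutation of the
#'   standard amino acids).
#' @param method `"exact"` or `"heuristic"`.
#' @return For a 20-letter standard alphabet, an [aa_ordering()]. For toy
#'   alphabets, a list with elements `letters` (visit order) and `length`
#'   (tour length). The tour length is attached as attribute
#'   `tour_length` in both cases.
#' @export
shortest_cyclic_order <- function(D, method = c("heuristic", "exact")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be a symmetric square matrix")
  if (is.null(colnames(D))) colnames(D) <- rownames(D) <- as.character(seq_len(n))
  if (method == "exact") {
    if (n > 12L)
      stop("method = \"exact\" supports at most 12 elements; use \"heuristic\"")
    perm <- held_karp(D)
  } else {
    perm <- tsp_heuristic(D)
    if (tour_length(D, perm) > tour_length(D, seq_len(n)))
      perm <- seq_len(n)           # guaranteed no worse than identity
  }
  perm <- canonical_tour(perm)
  letters_out <- colnames(D)[perm]
  len <- tour_length(D, perm)
  if (n == 20L && setequal(letters_out, AA_STANDARD)) {
    out <- aa_ordering(letters_out)
    attr(out, "tour_length") <- len
    return(out)
  }
  structure(list(letters = letters_out, length = len), tour_length = len)
}

#' Read a substitution scoring matrix from a text table
#'
#' Parses the common whitespace-delimited substitution-matrix dialect: an
#' optional comment block (`#` lines), one header row of amino-acid
#' letters, then one row per amino acid beginning with its letter. Rows and
#' columns beyond the 20 standard amino acids (B, Z, X, *) are dropped.
#'
#' @param path Path to the matrix file.
#' @return A 20 x 20 numeric matrix with amino-acid dimnames.
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rn <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(rn, header)
  keep_r <- rn %in% AA_STANDARD
  keep_c <- header %in% AA_STANDARD
  M <- vals[keep_r, keep_c, drop = FALSE]
  if (nrow(M) != 20L || ncol(M) != 20L)
    stop("scoring matrix must cover all 20 standard amino acids")
  M[AA_STANDARD, AA_STANDARD]
}

#' Encode an oligopeptide word as prefix and suffix integer codes
#'
#' A word of `shape$word_length` residues is mapped to a pair of base-20
#' integers (prefix code, suffix code), with the first residue most
#' significant, so that numeric order of the pair equals lexicographic
#' order of the word under the alphabet's evolutionary ranks. Words
#' containing any non-standard character (X, B, Z, U, *, gaps, lowercase
#' masking) are rejected with `NULL`: a corrupted residue would place the
#' word at an arbitrary dictionary position, so callers skip such windows.
#'
#' @param word Character string of exactly `shape$word_length` residues.
#' @param shape A [word_shape()].
#' @param alph An [aa_ordering()].
#' @return A list with `prefix_code` and `suffix_code` (numeric, exact
#'   integers), or `NULL` if the word contains an unrepresentable symbol.
#' @export
encode_word <- function(word, shape = word_shape(), alph = aa_ordering()) {
  if (nchar(word) != shape$word_length)
    stop("word must have exactly ", shape$word_length, " residues")
  ranks <- alph$rank[strsplit(word, "")[[1]]]
  if (anyNA(ranks)) return(NULL)
  p <- shape$prefix_length
  pw <- 20^((p - 1L):0)
  sw <- 20^((shape$suffix_length - 1L):0)
  list(prefix_code = sum(ranks[seq_len(p)] * pw),
       suffix_code = sum(ranks[(p + 1L):shape$word_length] * sw))
}

#' Decode prefix/suffix integer codes back to the amino-acid word
#'
#' @param prefix_code,suffix_code Numeric integer codes as produced by
#'   [encode_word()].
#' @inheritParams encode_word
#' @return The decoded word as a character string.
#' @export
decode_word <- function(prefix_code, suffix_code, shape = word_shape(),
                        alph = aa_ordering()) {
  digits <- function(code, len) {
    out <- integer(len)
    for (i in len:1) {
      out[i] <- code %% 20
      code <- (code - out[i]) / 20
    }
    out
  }
  d <- c(digits(prefix_code, shape$prefix_length),
         digits(suffix_code, shape$suffix_length))
  paste(alph$inverse[d + 1L], collapse = "")
}

# integer rank vector (0..19, NA for invalid) for a residue string
residue_ranks <- function(seq, alph) {
  chars <- strsplit(seq, "")[[1]]
  r <- alph$rank[chars]
  unname(r)
}
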