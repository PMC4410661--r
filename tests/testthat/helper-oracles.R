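# Independent reference implementations used to cross-check the package's
# fast paths. Deliberately naive: linear scans, dense solves, exhaustive
# enumeration.

# word string under the evolutionary ordering for a (prefix, suffix) pair
oracle_decode <- function(p, s, shape = word_shape(), alph = aa_ordering()) {
  decode_word(p, s, shape, alph)
}

# nearest neighbours of a query by sorting all stored words and scanning
# linearly for the insertion index
oracle_lookup <- function(prefixes, suffixes, labels, qp, qs) {
  stopifnot(!is.unsorted(order(prefixes, suffixes)))
  n <- length(prefixes)
  exact <- which(prefixes == qp & suffixes == qs)
  if (length(exact)) return(list(kind = "exact", index = exact))
  after <- which(prefixes > qp | (prefixes == qp & suffixes > qs))
  ins <- if (length(after)) min(after) else n + 1L
  idx <- c(if (ins > 1L) ins - 1L, if (ins <= n) ins)
  list(kind = "insert", index = idx)
}

# per-residue max-sum mosaic total from a match data frame (family,
# positions matrix, scores matrix), brute-force per-residue table
oracle_mosaic <- function(matches, query_length) {
  fams <- unique(matches$family)
  sapply(fams, function(f) {
    tab <- matrix(-Inf, nrow = 0, ncol = query_length)
    rows <- which(matches$family == f)
    best <- rep(-Inf, query_length)
    for (i in rows)
      for (j in seq_len(ncol(matches$positions))) {
        p <- matches$positions[i, j] + 1L
        best[p] <- max(best[p], matches$scores[i, j])
      }
    sum(best[is.finite(best)])
  })
}

# dense ridge regression by explicit normal equations on the full
# 4800-column one-hot design
oracle_ridge <- function(digits, pairs, y, lambda, slen = 12L) {
  n <- length(pairs)
  X <- matrix(0, nrow = n, ncol = 400L * slen)
  for (t in seq_len(n)) {
    i <- pairs[t]
    for (j in seq_len(slen)) {
      f <- (j - 1L) * 400L + digits[i, j] * 20L + digits[i + 1L, j] + 1L
      X[t, f] <- X[t, f] + 1
    }
  }
  w <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y))
  as.numeric(w)
}

# exhaustive six-frame ORF enumeration via per-frame translation
oracle_orfs <- function(dna, min_len = 60L) {
  dna <- toupper(dna)
  L <- nchar(dna)
  gc <- Biostrings::GENETIC_CODE
  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) dna else reverse_complement(dna)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (!ncod) next
      aa <- character(ncod)
      for (c0 in seq_len(ncod)) {
        cod <- substr(s, f + 3L * (c0 - 1L) + 1L, f + 3L * c0)
        aa[c0] <- if (grepl("[^ACGT]", cod)) "X" else unname(gc[cod])
      }
      run_start <- NULL
      for (c0 in seq_len(ncod + 1L)) {
        stop_here <- c0 > ncod || aa[c0] == "*"
        if (!stop_here && is.null(run_start)) run_start <- c0
        if (stop_here && !is.null(run_start)) {
          c1 <- run_start; c2 <- c0 - 1L
          if (3L * (c2 - c1 + 1L) >= min_len) {
            s0 <- f + 3L * (c1 - 1L); s1 <- f + 3L * c2
            res[[length(res) + 1L]] <- data.frame(
              frame = strand * (f + 1L),
              nt_start = if (strand == 1L) s0 else L - s1,
              nt_end = if (strand == 1L) s1 else L - s0,
              protein = paste(aa[c1:c2], collapse = ""),
              stringsAsFactors = FALSE)
          }
          run_start <- NULL
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), protein = character(0)))
  do.call(rbind, res)
}

sort_orfs <- function(df) {
  df <- df[c("frame", "nt_start", "nt_end", "protein")]
  df <- df[do.call(order, df[c("frame", "nt_start")]), ]
  rownames(df) <- NULL
  df
}

# brute-force word classification: for every valid window and direction,
# find neighbours by linear scan and apply the exact/insert scoring rules
oracle_classify <- function(query, db) {
  shape <- db$shape; alph <- db$alphabet
  plen <- shape$prefix_length; slen <- shape$suffix_length
  k <- shape$word_length
  L <- nchar(query)
  chars <- strsplit(query, "")[[1]]
  out <- list()
  score_vs <- function(qd, dict, i, pssm) {
    rd <- as.integer(cpp_digits(dict$suffixes[i], slen))
    pssm$matrices[cbind(qd + 1L, rd + 1L, seq_len(slen))]
  }
  cpp_digits <- function(code, len) {
    out <- integer(len)
    for (i in len:1) { out[i] <- code %% 20; code <- (code - out[i]) / 20 }
    out
  }
  for (s in 0:(L - k)) {
    win <- paste(chars[(s + 1):(s + k)], collapse = "")
    for (dir in c("forward", "reverse")) {
      w <- if (dir == "forward") win else
        paste(rev(strsplit(win, "")[[1]]), collapse = "")
      enc <- encode_word(w, shape, alph)
      if (is.null(enc)) next
      dict <- if (dir == "forward") db$forward else db$reverse
      pssm <- if (dir == "forward") db$pssm_fwd else db$pssm_rev
      if (!length(dict$suffixes)) next
      lk <- oracle_lookup(dict$prefixes, dict$suffixes, dict$labels,
                          enc$prefix_code, enc$suffix_code)
      qd <- as.integer(cpp_digits(enc$suffix_code, slen))
      emit <- function(fam, sc) {
        pos <- if (dir == "forward") s + plen + 0:(slen - 1) else
          s + 0:(slen - 1)
        sc_ord <- if (dir == "forward") sc else rev(sc)
        data.frame(family = db$family_names[fam], direction = dir,
                   start = s, t(pos), t(sc_ord), stringsAsFactors = FALSE)
      }
      if (lk$kind == "exact") {
        out[[length(out) + 1L]] <-
          emit(dict$labels[lk$index], score_vs(qd, dict, lk$index, pssm))
      } else {
        idx <- lk$index
        if (length(idx) == 2L && dict$labels[idx[1]] == dict$labels[idx[2]]) {
          sc <- pmax(score_vs(qd, dict, idx[1], pssm),
                     score_vs(qd, dict, idx[2], pssm))
          out[[length(out) + 1L]] <- emit(dict$labels[idx[1]], sc)
        } else {
          for (i in idx)
            out[[length(out) + 1L]] <-
              emit(dict$labels[i], score_vs(qd, dict, i, pssm))
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# flatten the package's classify_words() output to a comparable plain frame
flatten_matches <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  data.frame(family = m$family, direction = m$direction, start = m$start,
             as.data.frame(m$positions), as.data.frame(m$scores),
             stringsAsFactors = FALSE)
}

sort_matches <- function(df) {
  df <- df[do.call(order, df[c("direction", "start", "family")]), ]
  rownames(df) <- NULL
  names(df) <- c("family", "direction", "start",
                 paste0("p", 1:12), paste0("s", 1:12))
  df
}
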