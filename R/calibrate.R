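#' Amino-acid background frequencies
#'
#' Loads a 20-line text table (letter, frequency) and normalizes it to sum
#' exactly one. The bundled default is the average amino-acid composition
#' of UniProtKB/Swiss-Prot, the standard i.i.d. background for protein
#' null models.
#'
#' @param path Path to the table; default: the bundled table.
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1, class `aa_background`.
#' @export
read_background <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_background.txt",
                        package = "mosaicmatch", mustWork = TRUE)
  tab <- read.table(path, header = FALSE, col.names = c("aa", "freq"),
                    stringsAsFactors = FALSE)
  f <- setNames(tab$freq, tab$aa)
  if (!setequal(names(f), AA_STANDARD))
    stop("background table must cover exactly the 20 standard amino acids")
  if (any(f <= 0)) stop("background frequencies must be positive")
  f <- f[AA_STANDARD] / sum(f)
  structure(f, class = "aa_background")
}

#' Generate a random protein sequence
#'
#' Residues are drawn i.i.d. from the background frequencies — the null
#' model against which noise thresholds are calibrated.
#'
#' @param length Sequence length in residues (>= 1).
#' @param bg An `aa_background` (default: bundled table).
#' @return Amino-acid string. Reproducible under a fixed RNG seed.
#' @export
random_protein <- function(length, bg = read_background()) {
  stopifnot(length >= 1)
  paste(sample(names(bg), length, replace = TRUE, prob = bg), collapse = "")
}

# n x L matrix of alphabet ranks drawn i.i.d. from bg (fast path used by
# calibration; one sequence per row)
random_rank_matrix <- function(n, L, bg, alph) {
  p <- as.numeric(bg)[match(alph$letters, names(bg))]
  matrix(sample.int(20L, n * L, replace = TRUE, prob = p) - 1L,
         nrow = n, ncol = L)
}

#' Calibrate length-dependent noise thresholds at fixed FPR levels
#'
#' For each calibration length, `n_random` random i.i.d. sequences are
#' classified and the maximum per-family mosaic score of each sequence
#' recorded (0 when no word matches at all). The threshold for FPR level f
#' is the empirical (1-f)-quantile of that max-score distribution, taken
#' as the upper (conservative) order statistic: sorted ascending, the
#' value at index n - floor(f n), so that at most floor(f n) calibration
#' sequences strictly exceed it. The FPR is per-sequence: one random
#' sequence counts as one false positive if any family exceeds the
#' threshold.
#'
#' @param db A `mosaic_db` with dictionaries and PSSMs built.
#' @param bg Background frequencies (default: bundled table).
#' @param n_random Random sequences per length (default 1e5; must be at
#'   least 1/f for every level f).
#' @param lengths Calibration lengths in residues; default
#'   c(32, 64, 128, 256, 512, 1024).
#' @param levels Named FPR levels; default c(default = 0.001,
#'   sensitive = 0.01).
#' @param seed Integer seed for the random-sequence draw.
#' @return A `threshold_table`: thresholds matrix (levels x lengths),
#'   levels, lengths, n_random, seed.
#' @export
calibrate_thresholds <- function(db, bg = read_background(),
                                 n_random = 1e5,
                                 lengths = c(32L, 64L, 128L, 256L, 512L, 1024L),
                                 levels = c(default = 0.001, sensitive = 0.01),
                                 seed = 1L) {
  if (is.null(names(levels)) || any(!nzchar(names(levels))))
    stop("`levels` must be a named vector of FPR values")
  if (any(n_random < 1 / levels))
    stop("n_random = ", n_random, " cannot resolve an FPR of ",
         min(levels), "; need at least ", ceiling(1 / min(levels)),
         " random sequences")
  lengths <- as.integer(sort(lengths))
  thr <- matrix(NA_real_, nrow = length(levels), ncol = length(lengths),
                dimnames = list(names(levels), as.character(lengths)))
  set.seed(seed)
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    if (L < db$shape$word_length) {
      # no window fits: every score is 0, any positive threshold silences it
      thr[, li] <- 0
      next
    }
    ranks <- random_rank_matrix(n_random, L, bg, db$alphabet)
    sc <- sort(cpp_batch_max_scores(ranks, dict_view(db$forward),
                                    dict_view(db$reverse),
                                    db$pssm_fwd$matrices,
                                    db$pssm_rev$matrices,
                                    length(db$family_names),
                                    db$shape$prefix_length,
                                    db$shape$suffix_length,
                                    db$options$empty_block == "global",
                                    db$options$use_reverse))
    for (lv in seq_along(levels))
      thr[lv, li] <- sc[max(1, n_random - floor(levels[lv] * n_random + 1e-9))]
  }
  structure(list(thresholds = thr, levels = levels, lengths = lengths,
                 n_random = n_random, seed = seed),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("threshold_table: %d levels x %d lengths (n_random = %g, seed = %d)\n",
              length(x$levels), length(x$lengths), x$n_random, x$seed))
  print(round(x$thresholds, 3))
  invisible(x)
}

#' Interpolated noise threshold for an arbitrary sequence length
#'
#' Exact table value at the calibrated lengths; between them, piecewise
#' linear in log2(length) (the calibration grid is geometric); clamped
#' flat below the smallest and above the largest calibrated length.
#'
#' @param table A `threshold_table`.
#' @param L Query length in residues (>= 1).
#' @param level Level name present in the table.
#' @return The threshold (scalar).
#' @export
threshold_for_length <- function(table, L, level = "default") {
  if (!level %in% rownames(table$thresholds))
    stop("unknown threshold level: ", level)
  v <- table$thresholds[level, ]
  g <- table$lengths
  if (L <= g[1]) return(unname(v[1]))
  if (L >= g[length(g)]) return(unname(v[length(v)]))
  hi <- findInterval(L, g, rightmost.closed = TRUE) + 1L
  if (L == g[hi - 1L]) return(unname(v[hi - 1L]))
  w <- (log2(L) - log2(g[hi - 1L])) / (log2(g[hi]) - log2(g[hi - 1L]))
  unname(v[hi - 1L] + w * (v[hi] - v[hi - 1L]))
}

# per-sequence FPR of a calibrated db on a fresh random sample
measure_fpr <- function(db, level, L, n, bg = read_background()) {
  thr <- threshold_for_length(db$thresholds, L, level)
  ranks <- random_rank_matrix(n, L, bg, db$alphabet)
  sc <- cpp_batch_max_scores(ranks, dict_view(db$forward),
                             dict_view(db$reverse),
                             db$pssm_fwd$matrices, db$pssm_rev$matrices,
                             length(db$family_names),
                             db$shape$prefix_length, db$shape$suffix_length,
                             db$options$empty_block == "global",
                             db$options$use_reverse)
  mean(sc > thr)
}
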