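#' Reverse complement of a DNA string
#' @param dna DNA string over A, C, G, T, N (case-insensitive).
#' @return Reverse-complemented uppercase string.
#' @export
reverse_complement <- function(dna) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(dna), "")[[1]]), collapse = ""))
}

# translate a codon character vector with the standard genetic code;
# codons containing N (or any non-ACGT) become "X" — unknown, not a stop —
# and are rejected downstream at the word-window level
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Find open reading frames in all six frames
#'
#' An ORF here is a maximal stop-codon-free codon run of at least
#' `min_len` nucleotides in any of the six frames. No start codon is
#' required and read ends count as open boundaries: short sequencing
#' fragments rarely contain a gene start, so requiring ATG would discard
#' most genuine coding windows. Stop codons are TAA, TAG and TGA
#' (standard code); codons containing N translate to X and do not
#' terminate a run.
#'
#' @param dna DNA string over A, C, G, T, N.
#' @param min_len Minimum ORF length in nucleotides (default 60,
#'   inclusive).
#' @param id Optional source identifier recorded in the output.
#' @return Data frame with columns `source_id`, `frame` (+1, +2, +3, -1,
#'   -2, -3), `nt_start`, `nt_end` (0-based half-open on the forward
#'   strand) and `protein`. Negative frames refer to the reverse
#'   complement; their proteins read along the reverse strand.
#' @export
find_orfs <- function(dna, min_len = 60L, id = NA_character_) {
  dna <- toupper(dna)
  L <- nchar(dna)
  empty <- data.frame(source_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (L < min_len) return(empty)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) dna else reverse_complement(dna)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod == 0L) next
      starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      aa <- translate_codons(codons)
      is_stop <- aa == "*"
      # maximal runs of non-stop codons
      r <- rle(!is_stop)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        c1 <- begs[k]; c2 <- ends[k]
        nt <- 3L * (c2 - c1 + 1L)
        if (nt < min_len) next
        s_start <- f + 3L * (c1 - 1L)       # 0-based on this strand
        s_end <- f + 3L * c2
        if (strand == 1L) {
          nt_start <- s_start; nt_end <- s_end
        } else {
          nt_start <- L - s_end; nt_end <- L - s_start
        }
        out[[length(out) + 1L]] <- data.frame(
          source_id = id, frame = strand * (f + 1L),
          nt_start = nt_start, nt_end = nt_end,
          protein = paste(aa[c1:c2], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Codon-usage log-odds score of an ORF
#'
#' Mean per-codon log-odds of a coding codon-frequency table against the
#' uniform distribution. Used by the optional ORF pre-filter of the
#' normal DNA mode; with `table = NULL` the filter is a no-op (every ORF
#' passes), which is the default behaviour.
#'
#' @param orf_dna The ORF's in-frame DNA string.
#' @param table Named codon frequency vector (64 codons) estimated from
#'   coding sequence, or `NULL`.
#' @return Mean log-odds per codon (0 when `table` is NULL).
#' @export
codon_logodds <- function(orf_dna, table = NULL) {
  if (is.null(table)) return(0)
  orf_dna <- toupper(orf_dna)
  starts <- seq(1L, nchar(orf_dna) - 2L, by = 3L)
  codons <- substring(orf_dna, starts, starts + 2L)
  f <- table[codons]
  f[is.na(f) | f <= 0] <- 1 / 64   # unseen or N-containing codons: uniform
  mean(log(f / (1 / 64)))
}

# extract an ORF's in-frame DNA from the forward-strand read
orf_dna <- function(read, orf_row) {
  seg <- substr(toupper(read), orf_row$nt_start + 1L, orf_row$nt_end)
  if (orf_row$frame < 0) seg <- reverse_complement(seg)
  seg
}

#' Classify a DNA read against the database
#'
#' Extracts ORFs (six frames, >= 60 nt by default) and classifies each
#' translated protein. In `"short"` mode — intended for reads below
#' ~200 bp — no ORF pre-selection is performed and only the single
#' highest-scoring significant family across all ORFs is reported. In
#' `"normal"` mode, ORFs may first be filtered by the codon-usage
#' log-odds score (disabled unless a codon table is supplied), and all
#' significant families of every surviving ORF are reported, which
#' matters for multidomain proteins.
#'
#' @param read DNA string.
#' @param db Calibrated `mosaic_db`.
#' @param mode `"short"` or `"normal"`.
#' @param level Threshold level (`"default"` or `"sensitive"`).
#' @param min_orf Minimum ORF length in nt.
#' @param codon_table Optional codon frequency table for the normal-mode
#'   pre-filter; `NULL` disables the filter.
#' @param codon_cutoff Log-odds cutoff when the filter is active.
#' @param id Read identifier carried into the output.
#' @return Data frame with columns `id`, `family`, `score`, `frame`,
#'   `nt_start`, `nt_end` (one row per reported family; empty when
#'   nothing is significant).
#' @export
classify_dna <- function(read, db, mode = c("short", "normal"),
                         level = "default", min_orf = 60L,
                         codon_table = NULL, codon_cutoff = 0,
                         id = NA_character_) {
  mode <- match.arg(mode)
  empty <- data.frame(id = character(0), family = character(0),
                      score = numeric(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      stringsAsFactors = FALSE)
  orfs <- find_orfs(read, min_len = min_orf, id = id)
  if (nrow(orfs) == 0L) return(empty)
  if (mode == "normal" && !is.null(codon_table)) {
    lo <- vapply(seq_len(nrow(orfs)), function(i)
      codon_logodds(orf_dna(read, orfs[i, ]), codon_table), numeric(1))
    orfs <- orfs[lo >= codon_cutoff, , drop = FALSE]
    if (nrow(orfs) == 0L) return(empty)
  }
  hits <- list()
  for (i in seq_len(nrow(orfs))) {
    prot <- orfs$protein[i]
    if (nchar(prot) < db$shape$word_length) next
    pr <- predict_protein(prot, db, level = level, mode = "all")
    if (nrow(pr) == 0L) next
    hits[[length(hits) + 1L]] <- data.frame(
      id = id, family = pr$family, score = pr$score,
      frame = orfs$frame[i], nt_start = orfs$nt_start[i],
      nt_end = orfs$nt_end[i], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  if (mode == "short") {
    res$fam_idx <- match(res$family, db$family_names)
    res <- res[order(-res$score, res$fam_idx, res$nt_start), , drop = FALSE]
    res <- res[1L, c("id", "family", "score", "frame", "nt_start", "nt_end"),
               drop = FALSE]
  }
  rownames(res) <- NULL
  res[, c("id", "family", "score", "frame", "nt_start", "nt_end"),
      drop = FALSE]
}
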