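#' Classify every oligopeptide window of a protein query
#'
#' Runs the nearest-neighbour word classification in both directions. For
#' each valid 18-mer window: the forward dictionary is searched; an exact
#' match yields one scored match against the stored word; otherwise the
#' two words flanking the insertion position label the query word — if
#' they share a family, one match takes the per-position maximum of the
#' two substitution scores, if they differ each contributes its own match.
#' The reversed window is searched in the reverse dictionary the same way
#' and scored with the reverse PSSMs; its suffix positions map back onto
#' the first 12 residues of the original window. Windows containing
#' non-standard residues are skipped.
#'
#' @param query Amino-acid string (length at least the word length).
#' @param db A `mosaic_db` (see [build_database()]).
#' @return A data frame of word matches: `family` (name), `direction`,
#'   `start` (0-based window start), and matrix columns `positions`
#'   (0-based query residue indices, increasing) and `scores` (the
#'   positional substitution scores at those residues).
#' @export
classify_words <- function(query, db) {
  ranks <- residue_ranks(query, db$alphabet)
  ranks[is.na(ranks)] <- -1L
  res <- cpp_classify_query(ranks, dict_view(db$forward),
                            dict_view(db$reverse),
                            db$pssm_fwd$matrices, db$pssm_rev$matrices,
                            length(db$family_names),
                            db$shape$prefix_length, db$shape$suffix_length,
                            db$options$empty_block == "global",
                            db$options$use_reverse, TRUE)
  m <- res$matches
  out <- data.frame(family = db$family_names[m$family],
                    direction = c("forward", "reverse")[m$direction],
                    start = m$start, stringsAsFactors = FALSE)
  out$positions <- m$positions
  out$scores <- m$scores
  out
}

#' Combine word matches into per-family mosaic scores
#'
#' Matching words overlap, so a residue can receive several positional
#' scores from the same family (from either direction). Per family and
#' residue the maximum is kept, and the maxima are summed over the whole
#' sequence to give the family's total score. Residues not covered by any
#' match contribute zero; negative positional scores on covered residues
#' are kept and can lower the total. Families appear only if they achieved
#' at least one word match.
#'
#' @param matches Data frame from [classify_words()].
#' @param query_length Query length in residues.
#' @return A data frame with columns `family`, `total_score`, `n_matches`
#'   and `covered_residues`, sorted by decreasing score.
#' @export
mosaic_score <- function(matches, query_length) {
  if (is.null(matches) || nrow(matches) == 0L)
    return(data.frame(family = character(0), total_score = numeric(0),
                      n_matches = integer(0), covered_residues = integer(0),
                      stringsAsFactors = FALSE))
  fams <- unique(matches$family)
  out <- lapply(fams, function(f) {
    rows <- which(matches$family == f)
    best <- rep(-Inf, query_length)
    for (i in rows) {
      pos <- matches$positions[i, ] + 1L
      sc <- matches$scores[i, ]
      upd <- sc > best[pos]
      best[pos[upd]] <- sc[upd]
    }
    cov <- is.finite(best)
    data.frame(family = f, total_score = sum(best[cov]),
               n_matches = length(rows), covered_residues = sum(cov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$total_score, out$family), , drop = FALSE]
}

# fast path: totals straight from the C++ engine (identical result to
# classify_words() + mosaic_score(); asserted in the test suite)
mosaic_totals <- function(query, db) {
  ranks <- residue_ranks(query, db$alphabet)
  ranks[is.na(ranks)] <- -1L
  res <- cpp_classify_query(ranks, dict_view(db$forward),
                            dict_view(db$reverse),
                            db$pssm_fwd$matrices, db$pssm_rev$matrices,
                            length(db$family_names),
                            db$shape$prefix_length, db$shape$suffix_length,
                            db$options$empty_block == "global",
                            db$options$use_reverse, FALSE)
  data.frame(family = db$family_names[res$family],
             total_score = res$total_score,
             n_matches = res$n_matches,
             covered_residues = res$covered_residues,
             stringsAsFactors = FALSE)
}

#' Predict protein families for a protein query
#'
#' Computes mosaic scores and reports the families whose total exceeds the
#' length-dependent noise threshold at the requested calibration level.
#'
#' @param query Amino-acid string.
#' @param db A calibrated `mosaic_db`.
#' @param level Threshold level name: `"default"` (0.1% FPR) or
#'   `"sensitive"` (1% FPR).
#' @param mode `"all"` reports every significant family; `"best"` at most
#'   the top-scoring one (ties broken by the smaller family index).
#' @return Data frame with columns `family`, `score`, sorted by
#'   decreasing score.
#' @export
predict_protein <- function(query, db, level = "default",
                            mode = c("all", "best")) {
  mode <- match.arg(mode)
  if (is.null(db$thresholds))
    stop("database is not calibrated; run calibrate_thresholds() first")
  tot <- mosaic_totals(query, db)
  thr <- threshold_for_length(db$thresholds, nchar(query), level)
  sig <- tot[tot$total_score > thr, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(family = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  sig$fam_idx <- match(sig$family, db$family_names)
  sig <- sig[order(-sig$total_score, sig$fam_idx), , drop = FALSE]
  if (mode == "best") sig <- sig[1L, , drop = FALSE]
  data.frame(family = sig$family, score = sig$total_score,
             stringsAsFactors = FALSE)
}
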