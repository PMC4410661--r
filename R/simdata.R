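#' Specification for a synthetic protein-family fixture
#'
#' Defines the study conditions for the synthetic generator: per family an
#' ancestor sequence is drawn i.i.d. from the background frequencies and
#' members are derived by i.i.d. substitutions at a fixed per-residue
#' rate (a substituted residue is replaced by a uniform draw from the 19
#' other amino acids, so the realized substitution fraction matches the
#' nominal rate). Defaults — 10 families, 50 members of 300 residues at a
#' 5% substitution rate — emulate a reference collection with moderate
#' within-family variation.
#'
#' @param n_families Number of families.
#' @param members Database members per family.
#' @param length Member length in residues.
#' @param rate Per-residue substitution rate in \[0, 1).
#' @param n_holdout Held-out members per family (generated identically,
#'   disjoint from the database members).
#' @param bg Background frequencies.
#' @param seed RNG seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_families = 10L, members = 50L, length = 300L,
                        rate = 0.05, n_holdout = 10L,
                        bg = read_background(), seed = 1L) {
  stopifnot(rate >= 0, rate < 1, length >= 18L)
  structure(list(n_families = as.integer(n_families),
                 members = as.integer(members),
                 length = as.integer(length), rate = rate,
                 n_holdout = as.integer(n_holdout), bg = bg,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# substitute each residue independently with prob `rate`, replacement
# uniform over the 19 other letters
mutate_protein <- function(chars, rate) {
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    idx <- which(hit)
    for (i in idx) {
      alt <- AA_STANDARD[AA_STANDARD != chars[i]]
      chars[i] <- alt[sample.int(19L, 1L)]
    }
  }
  chars
}

#' Generate a synthetic labelled protein-family fixture
#'
#' @param spec A [family_spec()].
#' @return List with data frames `reference` and `holdout`, each with
#'   columns `id`, `label`, `residues`, plus `ancestors` (one string per
#'   family). Reproducible from `spec$seed`.
#' @export
generate_families <- function(spec) {
  set.seed(spec$seed)
  bg <- spec$bg
  fam_labels <- sprintf("FAM%03d", seq_len(spec$n_families))
  ancestors <- character(spec$n_families)
  ref <- list(); hold <- list()
  for (f in seq_len(spec$n_families)) {
    anc <- sample(names(bg), spec$length, replace = TRUE, prob = bg)
    ancestors[f] <- paste(anc, collapse = "")
    for (m in seq_len(spec$members)) {
      ref[[length(ref) + 1L]] <- data.frame(
        id = sprintf("%s_m%03d", fam_labels[f], m), label = fam_labels[f],
        residues = paste(mutate_protein(anc, spec$rate), collapse = ""),
        stringsAsFactors = FALSE)
    }
    for (m in seq_len(spec$n_holdout)) {
      hold[[length(hold) + 1L]] <- data.frame(
        id = sprintf("%s_h%03d", fam_labels[f], m), label = fam_labels[f],
        residues = paste(mutate_protein(anc, spec$rate), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  list(reference = do.call(rbind, ref),
       holdout = do.call(rbind, hold),
       ancestors = setNames(ancestors, fam_labels))
}

# amino acid -> synonymous codon list (standard code, stops excluded)
aa_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Back-translate a protein into DNA with uniform synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' codons — the classifier path under test carries no codon-usage
#' assumption, so none is injected.
#'
#' @param protein Amino-acid string (standard residues only).
#' @return In-frame DNA string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  tab <- aa_codons()
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot back-translate residue: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Simulate unassembled reads from labelled genes
#'
#' Draws uniform random fragment start positions from each gene until the
#' requested fold-coverage is reached; fragments inherit the gene's
#' label. No sequencing errors or length variation are simulated.
#'
#' @param genes Data frame with columns `id`, `label`, `dna` (in-frame
#'   coding DNA).
#' @param read_length Fragment length in nt.
#' @param coverage Target fold-coverage per gene.
#' @return Data frame with columns `id`, `label`, `source`, `dna`,
#'   `gene_start` (0-based fragment start within the gene).
#' @export
simulate_reads <- function(genes, read_length, coverage = 2) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    L <- nchar(genes$dna[g])
    if (L < read_length) next
    n_reads <- max(1L, round(coverage * L / read_length))
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
    for (k in seq_len(n_reads)) {
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_r%04d", genes$id[g], k),
        label = genes$label[g], source = genes$id[g],
        dna = substr(genes$dna[g], starts[k] + 1L, starts[k] + read_length),
        gene_start = starts[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Confusion counts and TPR/PPV for family predictions
#'
#' A read with a prediction equal to its annotated family is a true
#' positive. An annotated read with no prediction, or with a differing
#' prediction, counts as a false negative; predictions on unannotated
#' reads or differing from the annotation count as false positives.
#' TPR = TP / (TP + FN); PPV = TP / (TP + FP) (NA when undefined).
#'
#' @param predictions Data frame with columns `id`, `family` (one row per
#'   predicted read; at most one prediction per read).
#' @param truth Data frame with columns `id`, `family`; `NA` family marks
#'   a negative (unannotated) read.
#' @return List with `TP`, `FP`, `FN`, `TPR`, `PPV`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (anyDuplicated(truth$id))
    stop("duplicate ids in truth")
  unknown <- setdiff(predictions$id, truth$id)
  if (length(unknown))
    stop("predictions for ids absent from truth: ",
         paste(head(unknown, 5), collapse = ", "))
  pred <- setNames(predictions$family, predictions$id)
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    ann <- truth$family[i]
    p <- unname(pred[truth$id[i]])
    has_pred <- !is.na(p)
    if (!is.na(ann)) {
      if (has_pred && p == ann) tp <- tp + 1L
      else {
        fn <- fn + 1L
        if (has_pred) fp <- fp + 1L
      }
    } else if (has_pred) fp <- fp + 1L
  }
  list(TP = tp, FP = fp, FN = fn,
       TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}
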