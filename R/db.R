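#' Build a complete mosaic-matching database
#'
#' Runs the full construction pipeline: word extraction (optionally
#' entropy-masked), forward and reverse dictionary construction
#' (deduplication, ambiguity removal, singleton flagging), PSSM training
#' on the adjacent-pair examples of each dictionary while singletons are
#' still present, singleton removal, and finally noise-threshold
#' calibration on random sequences.
#'
#' @param seqs Data frame of labelled reference proteins: columns `id`,
#'   `label`, `residues`.
#' @param shape,alph Word geometry and alphabet ordering.
#' @param masker `"none"` or `"entropy"`.
#' @param lambda_grid Ridge grid for PSSM training.
#' @param calibrate Calibrate thresholds after building (default TRUE).
#' @param n_random,lengths,levels Calibration parameters, see
#'   [calibrate_thresholds()].
#' @param bg Background frequencies for calibration.
#' @param seed Seed driving the calibration draw (stored in the result;
#'   the same seed reproduces the database byte-for-byte).
#' @param empty_block Lookup behaviour for queries whose hexamer prefix
#'   block is empty: `"global"` (use the flanking words of the global
#'   sorted order; default) or `"skip"`.
#' @param use_reverse Enable reverse matching (default TRUE).
#' @return A `mosaic_db` object.
#' @export
build_database <- function(seqs, shape = word_shape(), alph = aa_ordering(),
                           masker = c("none", "entropy"),
                           lambda_grid = 10^seq(-2, 4, length.out = 10),
                           calibrate = TRUE, n_random = 1e5,
                           lengths = c(32L, 64L, 128L, 256L, 512L, 1024L),
                           levels = c(default = 0.001, sensitive = 0.01),
                           bg = read_background(), seed = 1L,
                           empty_block = c("global", "skip"),
                           use_reverse = TRUE) {
  masker <- match.arg(masker)
  empty_block <- match.arg(empty_block)
  if (nrow(seqs) == 0L) stop("no reference sequences supplied")
  family_names <- sort(unique(seqs$label))
  words <- extract_words(seqs, shape, alph, masker)
  fwd <- build_dictionary(words, shape, alph, family_names, "forward")
  rev <- reverse_dictionary(seqs, shape, alph, masker, family_names)
  split_f <- make_training_split(fwd)
  split_r <- make_training_split(rev)
  pssm_fwd <- fit_pssm(fwd, split_f, lambda_grid)
  pssm_rev <- fit_pssm(rev, split_r, lambda_grid)
  fwd <- remove_singletons(fwd)
  rev <- remove_singletons(rev)
  db <- structure(list(shape = shape, alphabet = alph,
                       family_names = family_names,
                       forward = fwd, reverse = rev,
                       pssm_fwd = pssm_fwd, pssm_rev = pssm_rev,
                       thresholds = NULL, background = bg,
                       options = list(empty_block = empty_block,
                                      use_reverse = use_reverse),
                       meta = list(format_version = 1L, seed = seed,
                                   masker = masker,
                                   n_sequences = nrow(seqs))),
                  class = "mosaic_db")
  if (calibrate)
    db$thresholds <- calibrate_thresholds(db, bg, n_random, lengths,
                                          levels, seed)
  db
}

#' @export
print.mosaic_db <- function(x, ...) {
  cat("mosaic_db:", length(x$family_names), "families\n")
  cat(sprintf("  forward dictionary: %d words | reverse: %d words\n",
              length(x$forward$suffixes), length(x$reverse$suffixes)))
  cat(sprintf("  pssm lambda: fwd %.4g / rev %.4g\n",
              x$pssm_fwd$lambda, x$pssm_rev$lambda))
  if (!is.null(x$thresholds))
    cat(sprintf("  calibrated at %s (n_random = %g, seed = %d)\n",
                paste(names(x$thresholds$levels), collapse = "/"),
                x$thresholds$n_random, x$thresholds$seed))
  else cat("  not calibrated\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------
# All files are plain text written with fixed formats, so identical content
# yields identical bytes and save -> load round-trips exactly ("%.17g"
# round-trips doubles).

fmt_num <- function(x) sprintf("%.17g", x)

write_lines <- function(lines, path) {
  con <- file(path, open = "wb")           # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

save_dictionary <- function(dict, dir, tag) {
  write_lines(fmt_num(dict$suffixes), file.path(dir, paste0(tag, "_suffixes.txt")))
  write_lines(as.character(dict$labels), file.path(dir, paste0(tag, "_labels.txt")))
  write_lines(sprintf("%d\t%d\t%d", dict$prefix_keys, dict$block_start,
                      dict$block_end),
              file.path(dir, paste0(tag, "_prefix_table.txt")))
}

load_dictionary <- function(dir, tag, shape, alph, family_names, direction) {
  suf <- as.numeric(readLines(file.path(dir, paste0(tag, "_suffixes.txt"))))
  lab <- as.integer(readLines(file.path(dir, paste0(tag, "_labels.txt"))))
  pt_path <- file.path(dir, paste0(tag, "_prefix_table.txt"))
  pt_lines <- readLines(pt_path)
  if (length(pt_lines)) {
    pt <- do.call(rbind, lapply(strsplit(pt_lines, "\t"), as.integer))
  } else pt <- matrix(integer(0), ncol = 3)
  prefixes <- rep(as.numeric(pt[, 1]), pt[, 3] - pt[, 2])
  d <- list(shape = shape, alphabet = alph, direction = direction,
            suffixes = suf, prefixes = prefixes, labels = lab,
            singleton = logical(length(suf)), family_names = family_names,
            prefix_keys = as.integer(pt[, 1]),
            block_start = as.integer(pt[, 2]),
            block_end = as.integer(pt[, 3]),
            stats = c(input = NA_integer_))
  class(d) <- "word_dictionary"
  d
}

save_pssm <- function(pssm, dir, tag) {
  write_lines(fmt_num(as.numeric(pssm$matrices)),
              file.path(dir, paste0(tag, "_pssm.txt")))
}

#' Save a database to a directory of plain-text files
#'
#' The directory holds a JSON metadata file, the family table, per-
#' direction suffix/label/prefix-table arrays, the PSSM weights, the
#' threshold table and the background frequencies. The format is
#' deterministic: identical database content produces byte-identical
#' files.
#'
#' @param db A `mosaic_db`.
#' @param dir Output directory (created; must not already contain a
#'   database unless `overwrite = TRUE`).
#' @param overwrite Replace an existing database directory.
#' @return `dir`, invisibly.
#' @export
save_database <- function(db, dir, overwrite = FALSE) {
  if (file.exists(file.path(dir, "meta.json")) && !overwrite)
    stop("database already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = db$meta$format_version,
               word_length = db$shape$word_length,
               prefix_length = db$shape$prefix_length,
               alphabet = db$alphabet$order,
               options = db$options,
               lambda_fwd = db$pssm_fwd$lambda,
               lambda_rev = db$pssm_rev$lambda,
               seed = db$meta$seed,
               masker = db$meta$masker,
               n_sequences = db$meta$n_sequences,
               calibrated = !is.null(db$thresholds))
  write_lines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE),
              file.path(dir, "meta.json"))
  write_lines(db$family_names, file.path(dir, "families.txt"))
  save_dictionary(db$forward, dir, "fwd")
  save_dictionary(db$reverse, dir, "rev")
  save_pssm(db$pssm_fwd, dir, "fwd")
  save_pssm(db$pssm_rev, dir, "rev")
  write_lines(sprintf("%s %s", names(db$background),
                      fmt_num(as.numeric(db$background))),
              file.path(dir, "background.txt"))
  if (!is.null(db$thresholds)) {
    tt <- db$thresholds
    hdr <- paste(c("level", "fpr", tt$lengths), collapse = "\t")
    rows <- vapply(seq_along(tt$levels), function(i)
      paste(c(names(tt$levels)[i], fmt_num(tt$levels[i]),
              fmt_num(tt$thresholds[i, ])), collapse = "\t"), character(1))
    write_lines(c(hdr, rows,
                  sprintf("#n_random\t%s", fmt_num(tt$n_random)),
                  sprintf("#seed\t%d", tt$seed)),
                file.path(dir, "thresholds.txt"))
  }
  invisible(dir)
}

#' Load a database saved by [save_database()]
#' @param dir Database directory.
#' @return A `mosaic_db`.
#' @export
load_database <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("no database found at ", dir)
  meta <- jsonlite::fromJSON(readLines(meta_path))
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("database format version ", meta$format_version,
         " is not supported by this build (expected 1)")
  shape <- word_shape(meta$word_length, meta$prefix_length)
  alph <- aa_ordering(meta$alphabet)
  family_names <- readLines(file.path(dir, "families.txt"))
  fwd <- load_dictionary(dir, "fwd", shape, alph, family_names, "forward")
  rev <- load_dictionary(dir, "rev", shape, alph, family_names, "reverse")
  load_pssm <- function(tag, lambda, direction) {
    v <- as.numeric(readLines(file.path(dir, paste0(tag, "_pssm.txt"))))
    structure(list(matrices = array(v, dim = c(20L, 20L, shape$suffix_length)),
                   lambda = lambda, lambda_grid = lambda,
                   validation_accuracy = NA_real_, train_rss = NA_real_,
                   n_train = NA_integer_, n_validation = NA_integer_,
                   orientation = "query-is-row", direction = direction,
                   alphabet = alph$order),
              class = "pssm_set")
  }
  bg_tab <- read.table(file.path(dir, "background.txt"), header = FALSE,
                       col.names = c("aa", "freq"), stringsAsFactors = FALSE)
  bg <- structure(setNames(bg_tab$freq, bg_tab$aa)[AA_STANDARD],
                  class = "aa_background")
  thresholds <- NULL
  thr_path <- file.path(dir, "thresholds.txt")
  if (file.exists(thr_path)) {
    lines <- readLines(thr_path)
    extra <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    hdr <- strsplit(body[1], "\t")[[1]]
    lengths <- as.integer(hdr[-(1:2)])
    rows <- strsplit(body[-1], "\t")
    lv_names <- vapply(rows, `[`, character(1), 1L)
    lv <- setNames(vapply(rows, function(r) as.numeric(r[2]), numeric(1)),
                   lv_names)
    thr <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-(1:2)])))
    dimnames(thr) <- list(lv_names, as.character(lengths))
    get_extra <- function(key) {
      ln <- extra[startsWith(extra, paste0("#", key))]
      if (length(ln)) as.numeric(strsplit(ln, "\t")[[1]][2]) else NA_real_
    }
    thresholds <- structure(list(thresholds = thr, levels = lv,
                                 lengths = lengths,
                                 n_random = get_extra("n_random"),
                                 seed = as.integer(get_extra("seed"))),
                            class = "threshold_table")
  }
  structure(list(shape = shape, alphabet = alph,
                 family_names = family_names,
                 forward = fwd, reverse = rev,
                 pssm_fwd = load_pssm("fwd", meta$lambda_fwd, "forward"),
                 pssm_rev = load_pssm("rev", meta$lambda_rev, "reverse"),
                 thresholds = thresholds, background = bg,
                 options = meta$options,
                 meta = list(format_version = meta$format_version,
                             seed = meta$seed, masker = meta$masker,
                             n_sequences = meta$n_sequences)),
            class = "mosaic_db")
}

#' Export a database directory to a single portable text archive
#'
#' Concatenates the database files into one file with explicit section
#' markers. [import_database()] restores the directory bit-exactly.
#'
#' @param dir Database directory.
#' @param file Output archive path.
#' @return `file`, invisibly.
#' @export
export_database <- function(dir, file) {
  files <- sort(list.files(dir))
  con <- base::file(file, open = "wb")
  on.exit(close(con))
  for (f in files) {
    writeLines(paste0(">>> ", f), con, sep = "\n")
    writeLines(readLines(file.path(dir, f)), con, sep = "\n")
    writeLines("<<<", con, sep = "\n")
  }
  invisible(file)
}

#' Import a portable archive back into a database directory
#' @param file Archive from [export_database()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
import_database <- function(file, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- readLines(file)
  starts <- which(startsWith(lines, ">>> "))
  ends <- which(lines == "<<<")
  if (length(starts) != length(ends))
    stop("malformed database archive")
  for (k in seq_along(starts)) {
    fname <- sub("^>>> ", "", lines[starts[k]])
    body <- if (ends[k] > starts[k] + 1L)
      lines[(starts[k] + 1L):(ends[k] - 1L)] else character(0)
    write_lines(body, file.path(dir, fname))
  }
  invisible(dir)
}
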