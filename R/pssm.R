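#' Split adjacent dictionary pairs into training and validation sets
#'
#' Every adjacent pair (i, i+1) of the sorted, ambiguity-pruned dictionary
#' (singletons still present — they supply the valuable negative examples)
#' is a word-match example with target y = +1 when the two labels agree
#' and -1 otherwise. A dictionary location is "mixed" when its two
#' incident pairs carry opposite signs; a pair trains iff either endpoint
#' is mixed. All remaining pairs validate the regularization parameter.
#' Mixed locations concentrate the family boundaries where discrimination
#' matters, and guarantee the training set holds both classes.
#'
#' @param dict A `word_dictionary` before singleton removal.
#' @return A `training_split`: list with integer pair indices `train` and
#'   `validation` (pair i joins words i and i+1), targets `y` for all
#'   pairs, and the source dictionary size.
#' @export
make_training_split <- function(dict) {
  n <- length(dict$suffixes)
  if (n < 2L)
    return(structure(list(train = integer(0), validation = integer(0),
                          y = integer(0), n_words = n),
                     class = "training_split"))
  l <- dict$labels
  y <- ifelse(l[-n] == l[-1], 1L, -1L)        # pair i = (i, i+1)
  np <- n - 1L
  mixed <- logical(n)
  if (n >= 3L)
    mixed[2:(n - 1L)] <- y[1:(np - 1L)] != y[2:np]
  train <- which(mixed[1:np] | mixed[2:(np + 1L)])
  structure(list(train = train,
                 validation = setdiff(seq_len(np), train),
                 y = y, n_words = n),
            class = "training_split")
}

#' @export
print.training_split <- function(x, ...) {
  cat(sprintf("training_split: %d train / %d validation pairs (%d words)\n",
              length(x$train), length(x$validation), x$n_words))
  invisible(x)
}

# sparse one-hot design matrix over substitution features for the given
# pair indices; feature (j, q, r) sits at column (j-1)*400 + q*20 + r + 1
pair_design <- function(digits, pairs, slen) {
  QR <- digits[pairs, , drop = FALSE] * 20L + digits[pairs + 1L, , drop = FALSE]
  cols <- sweep(QR, 2L, (seq_len(slen) - 1L) * 400L, `+`) + 1L
  Matrix::sparseMatrix(i = rep(seq_along(pairs), times = slen),
                       j = as.vector(cols), x = 1,
                       dims = c(length(pairs), 400L * slen))
}

#' Fit position-specific scoring matrices by regularized least squares
#'
#' Learns one 20 x 20 substitution-score matrix W_j per suffix position by
#' minimizing the ridge objective
#' \deqn{E(W) = \sum_{i \in train} (y_i - \sum_j W_j[a_i(j), a_{i+1}(j)])^2
#'   + \lambda \sum_j \|W_j\|_F^2}
#' over the suffix_length x 20 x 20 free parameters (one-hot substitution
#' indicators, no intercept). The prediction for a pair is the sum of the
#' indexed entries over the suffix positions. For each grid value of
#' lambda the normal equations are solved on the observed (active)
#' features — unobserved substitution pairs receive weight exactly 0 under
#' ridge — via one symmetric eigendecomposition of the Gram matrix shared
#' across the grid. The selected lambda maximizes sign-agreement accuracy
#' on the validation pairs (a prediction of exactly 0 counts as negative);
#' ties prefer the larger, more regularized lambda.
#'
#' @param dict A `word_dictionary` (pre-singleton-removal).
#' @param split A `training_split` from [make_training_split()].
#' @param lambda_grid Positive reals; default 10 points log-spaced in
#'   \[1e-2, 1e4\].
#' @return A `pssm_set`: list with `matrices` (20 x 20 x suffix_length
#'   array, query rank indexes rows, reference rank columns), `lambda`,
#'   `lambda_grid`, `validation_accuracy` and `train_rss` per grid point,
#'   `orientation` and `direction`.
#' @export
fit_pssm <- function(dict, split, lambda_grid = 10^seq(-2, 4, length.out = 10)) {
  slen <- dict$shape$suffix_length
  if (!length(split$train))
    stop("no mixed dictionary locations: training set is empty; ",
         "use a larger or more diverse reference set")
  if (!length(lambda_grid) || any(lambda_grid <= 0))
    stop("lambda_grid must be non-empty and positive")
  y_tr <- as.numeric(split$y[split$train])
  if (length(unique(y_tr)) < 2L)
    stop("training targets are all one class; ",
         "use a larger or more diverse reference set")
  digits <- cpp_code_digits(dict$suffixes, slen)
  X_tr <- pair_design(digits, split$train, slen)
  act <- which(Matrix::colSums(X_tr) > 0)
  Xa <- X_tr[, act, drop = FALSE]
  G <- as.matrix(Matrix::crossprod(Xa))
  b <- as.numeric(Matrix::crossprod(Xa, y_tr))
  eg <- eigen(G, symmetric = TRUE)
  Vtb <- as.numeric(crossprod(eg$vectors, b))
  has_val <- length(split$validation) > 0
  if (has_val) {
    Xv <- pair_design(digits, split$validation, slen)[, act, drop = FALSE]
    y_val <- split$y[split$validation]
  }
  lambda_grid <- sort(lambda_grid)
  acc <- rss <- numeric(length(lambda_grid))
  W <- vector("list", length(lambda_grid))
  for (k in seq_along(lambda_grid)) {
    w <- as.numeric(eg$vectors %*% (Vtb / (pmax(eg$values, 0) + lambda_grid[k])))
    W[[k]] <- w
    rss[k] <- sum((y_tr - as.numeric(Xa %*% w))^2)
    if (has_val) {
      pred <- as.numeric(Xv %*% w)
      acc[k] <- mean(ifelse(pred > 0, 1L, -1L) == y_val)
    } else {
      acc[k] <- NA_real_
    }
  }
  best <- if (has_val) max(which(acc == max(acc))) else 1L
  arr <- array(0, dim = c(20L, 20L, slen))
  f0 <- act - 1L
  j <- f0 %/% 400L
  q <- (f0 %% 400L) %/% 20L
  r <- f0 %% 20L
  arr[cbind(q + 1L, r + 1L, j + 1L)] <- W[[best]]
  structure(list(matrices = arr,
                 lambda = lambda_grid[best],
                 lambda_grid = lambda_grid,
                 validation_accuracy = acc,
                 train_rss = rss,
                 n_train = length(split$train),
                 n_validation = length(split$validation),
                 orientation = "query-is-row",
                 direction = dict$direction,
                 alphabet = dict$alphabet$order),
            class = "pssm_set")
}

#' @export
print.pssm_set <- function(x, ...) {
  cat(sprintf("pssm_set (%s): %d matrices 20x20, lambda = %.4g\n",
              x$direction, dim(x$matrices)[3], x$lambda))
  cat(sprintf("  trained on %d pairs, validated on %d (accuracy %.3f)\n",
              x$n_train, x$n_validation,
              x$validation_accuracy[match(x$lambda, x$lambda_grid)]))
  invisible(x)
}

#' Per-position sum of squared weights
#'
#' The contribution of each suffix position to the fitted classifier,
#' measured as the squared Frobenius norm of its scoring matrix. Positions
#' that discriminate correct from false nearest-neighbour matches carry
#' visibly more weight; in large natural dictionaries the profile decays
#' along the suffix because early positions, adjacent to the shared
#' hexamer, are the most informative.
#'
#' @param pssm A `pssm_set`.
#' @return Numeric vector of length suffix_length, non-negative.
#' @export
ssw_profile <- function(pssm) {
  apply(pssm$matrices^2, 3L, sum)
}

#' Positional substitution scores for a query/reference word pair
#'
#' Looks up the fitted score W_j\[rank(query_j), rank(ref_j)\] at each of
#' the suffix positions. Only suffix positions are scored: the hexamer
#' prefix is mostly identical between dictionary neighbours and carries
#' little discriminative signal.
#'
#' @param pssm A `pssm_set`.
#' @param query,ref Words of the full word length (strings), or encoded
#'   lists as returned by [encode_word()].
#' @param shape,alph Word geometry and alphabet (defaults match the
#'   package defaults used to train `pssm`).
#' @return Numeric vector of suffix_length positional scores.
#' @export
score_word_pair <- function(pssm, query, ref, shape = word_shape(),
                            alph = aa_ordering()) {
  slen <- shape$suffix_length
  get_digits <- function(w) {
    if (is.character(w)) {
      enc <- encode_word(w, shape, alph)
      if (is.null(enc)) stop("word contains non-standard residues")
      w <- enc
    }
    as.integer(cpp_code_digits(w$suffix_code, slen))
  }
  qd <- get_digits(query)
  rd <- get_digits(ref)
  pssm$matrices[cbind(qd + 1L, rd + 1L, seq_len(slen))]
}
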