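#' Alignment-free sequence transformations
#'
#' Map a variable-length protein sequence to a fixed-length numeric
#' feature vector. Four transformations are provided:
#'
#' * `aac()`: relative frequencies of the 20 amino acids (1-grams);
#'   20 features in canonical alphabetical order.
#' * `digram()`: relative frequencies of the 400 possible adjacent
#'   amino-acid pairs (overlapping 2-grams); 400 features in lexicographic
#'   pair order.
#' * `acc()`: auto-cross covariance of physicochemical descriptor
#'   trajectories. Each of the P descriptor scales (the five z-scales by
#'   default) is evaluated along the sequence and centered by its
#'   per-sequence mean; for lag d and scale pair (j, k) the feature is
#'   \deqn{acc(j,k,d) = \frac{1}{n-d}\sum_{i=1}^{n-d} \tilde z_j(i)\,\tilde z_k(i+d)}
#'   (j = k terms are auto covariances, j != k cross covariances).
#'   Concatenation is lag-major, then (j, k) row-major: P^2 * l features.
#' * `pdbt()`: physicochemical distance-based transformation. Each
#'   property scale is first standardized across the 20 amino acids
#'   (mean 0, sd 1 over the table column); the feature for property p and
#'   lag d is the mean squared difference
#'   \deqn{pdbt(p,d) = \frac{1}{L-d}\sum_{i=1}^{L-d} (\tilde P_p(a_i)-\tilde P_p(a_{i+d}))^2.}
#'   Concatenation is property-major, then lag: P * l features (531 * 8 =
#'   4248 with the full AAindex-derived table and the default lag).
#'
#' @param sequence Character scalar over the 20 standard one-letter codes.
#' @param table Descriptor table (20 x P numeric matrix, see [zscales()]
#'   and [aaindex_properties()]).
#' @param max_lag Maximum lag l (sequence must be longer than `max_lag`).
#' @return A named numeric feature vector.
#' @seealso [transform_dataset()] to apply a transform to a whole dataset.
#' @examples
#' aac("ACDC")
#' sum(digram("ACAC"))
#' acc("MKVLH", zscales(), max_lag = 2)[1:5]
#' @export
aac <- function(sequence) {
  chars <- seq_chars(sequence, min_len = 1L)
  counts <- tabulate(match(chars, AA_ALPHABET), nbins = 20L)
  setNames(counts / length(chars), AA_ALPHABET)
}

#' @rdname aac
#' @export
digram <- function(sequence) {
  chars <- seq_chars(sequence, min_len = 2L)
  n <- length(chars)
  pair_names <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  idx1 <- match(chars[-n], AA_ALPHABET)
  idx2 <- match(chars[-1], AA_ALPHABET)
  counts <- tabulate((idx1 - 1L) * 20L + idx2, nbins = 400L)
  setNames(counts / (n - 1L), pair_names)
}

#' @rdname aac
#' @export
acc <- function(sequence, table = zscales(), max_lag = 13L) {
  chars <- seq_chars(sequence, min_len = max_lag + 1L)
  n <- length(chars)
  P <- ncol(table)
  scales <- colnames(table) %||% paste0("d", seq_len(P))
  Z <- table[chars, , drop = FALSE]
  Z <- sweep(Z, 2L, colMeans(Z)) # center each descriptor trajectory
  out <- numeric(P * P * max_lag)
  nm <- character(P * P * max_lag)
  for (d in seq_len(max_lag)) {
    m <- crossprod(Z[seq_len(n - d), , drop = FALSE],
                   Z[(1L + d):n, , drop = FALSE]) / (n - d)
    block <- (d - 1L) * P * P
    out[block + seq_len(P * P)] <- as.vector(t(m)) # (j,k) row-major
    nm[block + seq_len(P * P)] <-
      paste0("lag", d, ".", as.vector(t(outer(scales, scales, paste, sep = "_"))))
  }
  setNames(out, nm)
}

#' @rdname aac
#' @export
pdbt <- function(sequence, table = aaindex_properties(), max_lag = 8L) {
  chars <- seq_chars(sequence, min_len = max_lag + 1L)
  n <- length(chars)
  P <- ncol(table)
  scales <- colnames(table) %||% paste0("p", seq_len(P))
  S <- scale(table)[chars, , drop = FALSE] # standardize over the 20 AAs
  out <- matrix(0, nrow = max_lag, ncol = P)
  for (d in seq_len(max_lag)) {
    diffs <- S[seq_len(n - d), , drop = FALSE] - S[(1L + d):n, , drop = FALSE]
    out[d, ] <- colSums(diffs^2) / (n - d)
  }
  # property-major then lag: column-major flattening of the lag x P matrix
  setNames(as.vector(out),
           paste0(rep(scales, each = max_lag), ".lag", rep(seq_len(max_lag), P)))
}

seq_chars <- function(sequence, min_len) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("sequence must be a character scalar")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < min_len) {
    abort(sprintf("sequence of length %d is too short (minimum %d)",
                  length(chars), min_len))
  }
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("non-standard residue code(s): %s; sanitize first",
                  paste(bad, collapse = ", ")))
  }
  chars
}

#' Transform every sequence of a dataset to a feature matrix
#'
#' Applies one of the four alignment-free transformations row-wise,
#' producing an N x D feature matrix aligned with the dataset's records.
#'
#' @param dataset A `labeled_dataset` (or any tibble with `id` and
#'   `sequence` columns).
#' @param method One of `"aac"`, `"digram"`, `"acc"`, `"pdbt"`.
#' @param table Descriptor table for `"acc"`/`"pdbt"`; defaults to
#'   [zscales()] for ACC and [aaindex_properties()] for PDBT.
#' @param max_lag Maximum lag for `"acc"` (default 13) and `"pdbt"`
#'   (default 8).
#' @return A `feature_matrix`: a numeric matrix with rownames = record
#'   ids, plus `method` attribute.
#' @examples
#' ds <- tibble::tibble(id = c("a", "b"), sequence = c("MKVLHEE", "GGAPWRD"))
#' dim(transform_dataset(ds, "aac"))
#' @export
transform_dataset <- function(dataset,
                              method = c("aac", "digram", "acc", "pdbt"),
                              table = NULL, max_lag = NULL) {
  method <- match.arg(method)
  fn <- switch(method,
    aac = function(s) aac(s),
    digram = function(s) digram(s),
    acc = {
      table <- table %||% zscales()
      max_lag <- max_lag %||% 13L
      function(s) acc(s, table, max_lag)
    },
    pdbt = {
      table <- table %||% aaindex_properties()
      max_lag <- max_lag %||% 8L
      function(s) pdbt(s, table, max_lag)
    })
  rows <- map2(dataset$sequence, dataset$id, function(s, id) {
    tryCatch(fn(s), error = function(e) {
      abort(sprintf("transform '%s' failed for record '%s': %s",
                    method, id, conditionMessage(e)))
    })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- dataset$id
  attr(X, "method") <- method
  class(X) <- c("feature_matrix", class(X))
  X
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("# feature_matrix: %d sequences x %d features (%s)\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

#' @describeIn transform_dataset Tidy a feature matrix into a long tibble
#'   (`id`, `feature`, `value`).
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.feature_matrix <- function(x, ...) {
  tibble(id = rep(rownames(x), ncol(x)),
         feature = rep(colnames(x), each = nrow(x)),
         value = as.vector(unclass(x)))
}
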