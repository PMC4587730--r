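#' SVM configuration
#'
#' Settings for the one-vs-one RBF-kernel SVM: the soft-margin penalty C,
#' the RBF width gamma, the grid-search candidate lists, the number of
#' cross-validation folds, whether features are standardized with
#' training-fold statistics, and the seed controlling fold shuffling.
#'
#' Default grids are the standard libsvm-style coarse grid in powers of 4:
#' C in 2^(-5), 2^(-3), ..., 2^15 and gamma in 2^(-15), ..., 2^3.
#'
#' @param C,gamma Positive reals; `gamma = NULL` means 1/D at fit time.
#' @param C_grid,gamma_grid Non-empty candidate vectors for [tune_hyperparameters()].
#' @param n_folds Cross-validation folds (>= 2).
#' @param standardize Standardize features per training fold (default TRUE).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL,
                       C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       n_folds = 5L, standardize = TRUE, seed = 1L) {
  stopifnot(C > 0, length(C_grid) > 0, length(gamma_grid) > 0, n_folds >= 2)
  structure(list(C = C, gamma = gamma, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid), n_folds = as.integer(n_folds),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "svm_config")
}

# Stratified fold assignment: within each class, shuffle members and deal
# them round-robin into folds, so every fold has close to n/k per class.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1 # constant features pass through
  list(mean = mu, sd = sigma)
}

apply_standardizer <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mean), 2L, sc$sd, "/")
}

#' Grid search for the SVM hyperparameters C and gamma
#'
#' Evaluates every (C, gamma) grid point by stratified cross-validation of
#' the full one-vs-one multi-class classifier and returns the point with
#' the highest mean CV accuracy. Ties are broken toward smaller C, then
#' smaller gamma. Deterministic given `config$seed`.
#'
#' @param X Feature matrix (rows = sequences).
#' @param y Label vector.
#' @param config An [svm_config()].
#' @return A list with `C_opt`, `gamma_opt`, `cv_accuracy` and the full
#'   `grid` tibble (one row per grid point).
#' @export
tune_hyperparameters <- function(X, y, config = svm_config()) {
  X <- unclass(as.matrix(X))
  y <- as.character(y)
  small <- table(y)[table(y) < config$n_folds]
  if (length(small) > 0) {
    abort(sprintf("class(es) with fewer members than n_folds: %s",
                  paste(names(small), collapse = ", ")))
  }
  fold <- withr::with_seed(config$seed, stratified_folds(y, config$n_folds))
  grid <- tidyr::expand_grid(C = sort(config$C_grid),
                             gamma = sort(config$gamma_grid))
  classes <- unique(y)
  acc <- map_dbl(seq_len(nrow(grid)), function(g) {
    fold_acc <- map_dbl(seq_len(config$n_folds), function(f) {
      tr <- fold != f
      fit <- fit_ovo(X[tr, , drop = FALSE], y[tr],
                     C = grid$C[g], gamma = grid$gamma[g],
                     classes = classes, standardize = config$standardize)
      pred <- predict_votes_dv(fit, X[!tr, , drop = FALSE])
      mean(pred$predicted == y[!tr])
    })
    mean(fold_acc)
  })
  grid$cv_accuracy <- acc
  # ties toward smaller C, then smaller gamma: grid is sorted C-major asc
  best <- order(-acc, grid$C, grid$gamma)[1]
  list(C_opt = grid$C[best], gamma_opt = grid$gamma[best],
       cv_accuracy = acc[best], grid = grid)
}

#' Fit a one-vs-one RBF-kernel SVM
#'
#' Trains the K(K-1)/2 pairwise soft-margin binary classifiers via libsvm
#' (through \pkg{e1071}). Features are optionally standardized with
#' statistics of this training set; the standardizer is stored with the
#' model and re-applied at prediction time, so no test-set statistics ever
#' enter the model.
#'
#' @param X Training feature matrix.
#' @param y Training labels (>= 2 distinct classes).
#' @param C Soft-margin penalty.
#' @param gamma RBF width; `NULL` means 1/ncol(X).
#' @param classes Ordered class vocabulary fixing the pair indexing;
#'   defaults to order of first appearance in `y`.
#' @param standardize Standardize features (default TRUE).
#' @return An object of class `ovo_svm` with elements `model`, `scaler`,
#'   `classes`, `n_pairs`.
#' @export
fit_ovo <- function(X, y, C = 1, gamma = NULL, classes = NULL,
                    standardize = TRUE) {
  X <- unclass(as.matrix(X))
  y <- as.character(y)
  classes <- classes %||% unique(y)
  present <- intersect(classes, unique(y))
  if (length(present) < 2L) abort("training set must contain at least 2 classes")
  gamma <- gamma %||% (1 / ncol(X))
  scaler <- if (standardize) standardizer(X) else NULL
  Xs <- if (standardize) apply_standardizer(X, scaler) else X
  fy <- factor(y, levels = classes)
  fy <- droplevels(fy)
  model <- e1071::svm(Xs, fy, type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
  k <- nlevels(fy)
  structure(list(model = model, scaler = scaler, classes = classes,
                 trained_classes = levels(fy),
                 n_pairs = k * (k - 1L) / 2L, C = C, gamma = gamma),
            class = "ovo_svm")
}

#' Predict with one-vs-one votes and pairwise decision values
#'
#' For each test item, every pairwise binary classifier casts one vote
#' (libsvm's rule: a positive decision value votes for the lower-indexed
#' class of the pair); votes are tallied and the predicted class is the
#' vote argmax, ties broken toward the lowest class index. The signed
#' decision value of every pair is returned, oriented so that a positive
#' value favors the lower-indexed class.
#'
#' @param object An `ovo_svm` fit.
#' @param X Test feature matrix (same feature dimension as training).
#' @return A tibble with one row per test item: `id`, `predicted`,
#'   `votes` (list of named integer vectors over all classes) and `dv`
#'   (list of named numeric vectors, names `"i/j"` with class indices
#'   i < j into the fit's class vocabulary).
#' @export
predict_votes_dv <- function(object, X) {
  X <- unclass(as.matrix(X))
  model <- object$model
  if (!is.null(object$scaler)) X <- apply_standardizer(X, object$scaler)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  pred <- predict(model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  classes <- object$classes
  K <- length(classes)
  # map e1071 pair columns "A/B" (A, B are level labels) to canonical
  # index pairs i<j with sign "positive favors lower index"
  pair_labels <- strsplit(colnames(dv), "/", fixed = TRUE)
  i_raw <- match(vapply(pair_labels, `[`, "", 1), classes)
  j_raw <- match(vapply(pair_labels, `[`, "", 2), classes)
  flip <- i_raw > j_raw
  i_idx <- ifelse(flip, j_raw, i_raw)
  j_idx <- ifelse(flip, i_raw, j_raw)
  dv_canon <- dv
  dv_canon[, flip] <- -dv[, flip, drop = FALSE]
  canon_names <- paste0(i_idx, "/", j_idx)
  colnames(dv_canon) <- canon_names
  votes_mat <- matrix(0L, nrow = nrow(X), ncol = K,
                      dimnames = list(NULL, classes))
  for (p in seq_along(canon_names)) {
    lo_wins <- dv_canon[, p] > 0
    votes_mat[, i_idx[p]] <- votes_mat[, i_idx[p]] + as.integer(lo_wins)
    votes_mat[, j_idx[p]] <- votes_mat[, j_idx[p]] + as.integer(!lo_wins)
  }
  predicted <- classes[apply(votes_mat, 1L, which.max)] # ties -> lowest index
  tibble(
    id = ids,
    predicted = predicted,
    votes = lapply(seq_len(nrow(X)), function(r) votes_mat[r, ]),
    dv = lapply(seq_len(nrow(X)), function(r) setNames(dv_canon[r, ], canon_names))
  )
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf(
    "# one-vs-one RBF SVM: %d classes, %d pairwise classifiers (C = %g, gamma = %g)\n",
    length(x$trained_classes), x$n_pairs, x$C, x$gamma))
  invisible(x)
}

#' @describeIn fit_ovo One-row model summary.
#' @param x An `ovo_svm` fit.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ovo_svm <- function(x, ...) {
  tibble(n_classes = length(x$trained_classes), n_pairs = x$n_pairs,
         C = x$C, gamma = x$gamma,
         n_support_vectors = nrow(x$model$SV),
         standardized = !is.null(x$scaler))
}
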