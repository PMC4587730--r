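#' Ensemble noise-rank filter configuration
#'
#' An independent, ensemble-based mislabeling detector used to
#' cross-validate the SVM-based candidate shortlist. Four base classifiers
#' — naive Bayes (NB), random forest (RF), RBF-kernel SVM and a one-hidden-
#' layer multi-layer perceptron (MLP) — are each evaluated by stratified
#' cross-validation over one shared fold assignment; a sequence "fails" a
#' classifier when that classifier misclassifies it as a test item. The
#' noise rank weights the failing classifiers (defaults MLP 3, SVM 2,
#' NB 1, RF 1) and the candidate set keeps sequences failed by at least
#' `min_failures` classifiers.
#'
#' @param roster Base classifiers to run (subset of `"NB"`, `"RF"`,
#'   `"SVM"`, `"MLP"`).
#' @param weights Named integer weights, one per roster member.
#' @param n_folds Shared stratified CV folds.
#' @param min_failures Minimum failing classifiers for candidacy.
#' @param svm_C,svm_gamma SVM hyperparameters (gamma `NULL` = 1/D).
#' @param rf_trees Random-forest size.
#' @param mlp_size Hidden-layer width; `NULL` = min(100, 2 D).
#' @param mlp_maxit MLP training iterations.
#' @param seed Integer seed.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(roster = c("NB", "RF", "SVM", "MLP"),
                            weights = c(MLP = 3, SVM = 2, NB = 1, RF = 1),
                            n_folds = 5L, min_failures = 3L,
                            svm_C = 1, svm_gamma = NULL,
                            rf_trees = 500L, mlp_size = NULL,
                            mlp_maxit = 150L, seed = 1L) {
  roster <- match.arg(roster, several.ok = TRUE)
  stopifnot(all(roster %in% names(weights)), all(weights > 0),
            min_failures <= length(roster), n_folds >= 2)
  structure(list(roster = roster, weights = weights[roster],
                 n_folds = as.integer(n_folds),
                 min_failures = as.integer(min_failures),
                 svm_C = svm_C, svm_gamma = svm_gamma,
                 rf_trees = as.integer(rf_trees), mlp_size = mlp_size,
                 mlp_maxit = as.integer(mlp_maxit),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Run the ensemble of base classifiers
#'
#' Evaluates every roster classifier by stratified cross-validation with a
#' single shared fold assignment, so per-sequence failures are comparable
#' across classifiers. Features are standardized with training-fold
#' statistics for NB, SVM and MLP.
#'
#' @param X Feature matrix (rownames = ids).
#' @param y Labels aligned with `X`.
#' @param config An [ensemble_config()].
#' @return A tibble: `id`, `true_class`, one logical failure column per
#'   roster classifier.
#' @export
run_ensemble <- function(X, y, config = ensemble_config()) {
  X <- unclass(as.matrix(X))
  y <- as.character(y)
  N <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(N))
  classes <- unique(y)
  small <- table(y)[table(y) < config$n_folds]
  if (length(small) > 0) {
    abort(sprintf("class(es) smaller than n_folds: %s",
                  paste(names(small), collapse = ", ")))
  }
  D <- ncol(X)
  gamma <- config$svm_gamma %||% (1 / D)
  mlp_size <- config$mlp_size %||% min(100L, 2L * D)
  flags <- matrix(NA, N, length(config$roster),
                  dimnames = list(ids, config$roster))
  withr::with_seed(config$seed, {
    fold <- stratified_folds(y, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      te <- which(!tr)
      sc <- standardizer(X[tr, , drop = FALSE])
      Xtr <- apply_standardizer(X[tr, , drop = FALSE], sc)
      Xte <- apply_standardizer(X[te, , drop = FALSE], sc)
      ytr <- factor(y[tr], levels = classes)
      for (clf in config$roster) {
        pred <- switch(clf,
          NB = {
            m <- e1071::naiveBayes(Xtr, ytr)
            as.character(predict(m, Xte))
          },
          RF = {
            m <- randomForest::randomForest(X[tr, , drop = FALSE], ytr,
                                            ntree = config$rf_trees)
            as.character(predict(m, X[te, , drop = FALSE]))
          },
          SVM = {
            m <- e1071::svm(Xtr, ytr, type = "C-classification",
                            kernel = "radial", cost = config$svm_C,
                            gamma = gamma, scale = FALSE)
            as.character(predict(m, Xte))
          },
          MLP = {
            m <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = mlp_size,
                            softmax = TRUE, maxit = config$mlp_maxit,
                            MaxNWts = 200000L, trace = FALSE)
            p <- predict(m, Xte)
            levels(ytr)[apply(p, 1L, which.max)]
          })
        flags[te, clf] <- pred != y[te]
      }
    }
  })
  out <- tibble(id = ids, true_class = y)
  for (clf in config$roster) out[[clf]] <- as.logical(flags[, clf])
  out
}

#' Noise rank from per-classifier failure flags
#'
#' Scores each sequence by the number of base classifiers that failed on
#' it and by the weighted sum of the failing classifiers' weights, and
#' returns the ranking (weighted score descending, ties by failure count
#' then id).
#'
#' @param flags Output of [run_ensemble()].
#' @param weights Named weights per classifier (defaults MLP 3, SVM 2,
#'   NB 1, RF 1).
#' @return A tibble `id`, `true_class`, `failure_count`, `weighted_score`,
#'   sorted as described.
#' @examples
#' fl <- tibble::tibble(id = "s1", true_class = "a",
#'                      NB = TRUE, RF = TRUE, SVM = TRUE, MLP = TRUE)
#' noise_rank(fl) # weighted_score 7
#' @export
noise_rank <- function(flags, weights = c(MLP = 3, SVM = 2, NB = 1, RF = 1)) {
  clf_cols <- intersect(names(weights), names(flags))
  if (length(clf_cols) == 0) abort("no classifier flag columns found")
  fm <- as.matrix(flags[, clf_cols, drop = FALSE])
  fc <- rowSums(fm)
  ws <- as.vector(fm %*% weights[clf_cols])
  out <- tibble(id = flags$id, true_class = flags$true_class,
                failure_count = as.integer(fc), weighted_score = ws)
  arrange(out, desc(.data$weighted_score), desc(.data$failure_count), .data$id)
}

#' Ensemble candidate set
#'
#' Sequences failed by at least `min_failures` classifiers ("majority")
#' and, reported alongside, by all of them ("consensus").
#'
#' @param ranked Output of [noise_rank()].
#' @param min_failures Minimum failing classifiers (default 3).
#' @param n_classifiers Roster size (default 4).
#' @return `ranked` filtered to the majority set, with a `consensus`
#'   logical column marking the all-fail subset.
#' @export
ensemble_candidates <- function(ranked, min_failures = 3L, n_classifiers = 4L) {
  out <- ranked[ranked$failure_count >= min_failures, , drop = FALSE]
  mutate(out, consensus = .data$failure_count >= n_classifiers)
}

#' Overlap between two candidate id sets
#'
#' @param set_a,set_b Character vectors of ids.
#' @return A one-row tibble: sizes, common count, and the integer
#'   percentage of each set found in the other.
#' @examples
#' overlap_report(c("a", "b", "c", "d"), c("a", "b", "c"))$pct_of_a # 75
#' @export
overlap_report <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  common <- length(intersect(a, b))
  tibble(n_a = length(a), n_b = length(b), n_common = common,
         pct_of_a = if (length(a) > 0) as.integer(round(100 * common / length(a))) else NA_integer_,
         pct_of_b = if (length(b) > 0) as.integer(round(100 * common / length(b))) else NA_integer_)
}
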