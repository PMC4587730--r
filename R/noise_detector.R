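#' Detector configuration
#'
#' Settings for the three-step systematic misclassification analysis:
#'
#' 1. `n_iterations` repetitions of a shuffled, stratified `n_folds`-fold
#'    cross-validation build per-sequence error rates ER (in percent); only
#'    sequences with ER at or above `e_threshold` percent are kept as
#'    frequent misclassifications.
#' 2. The voting ratio R = VT/VP (total one-vs-one votes of the true class
#'    over those of the most frequently predicted class, summed over all
#'    test occasions) flags a consistent ("large") error when R <= `theta_R`.
#' 3. The cumulative decision value CDV (sum over test occasions of the
#'    pairwise decision value confronting true and most-predicted class)
#'    flags a confident ("large") error when |CDV| >= `theta_CDV`.
#'
#' The final candidate shortlist is the union of the step-2 and step-3
#' large-error sets among the frequent misclassifications.
#'
#' `theta_CDV` is calibrated to 100 iterations; since the CDV is an
#' un-normalized sum, the effective threshold scales linearly as
#' `theta_CDV * n_iterations / 100` when `n_iterations` differs.
#'
#' The soft-margin penalty is jittered across folds: fold f uses
#' `C_opt * C_jitter[((f-1) mod length(C_jitter)) + 1]`, so each iteration
#' mixes slightly different SVM models near the tuned optimum.
#'
#' @param n_iterations Outer repetitions (default 100).
#' @param n_folds Cross-validation folds (default 5).
#' @param e_threshold Error-rate threshold in percent (default 75,
#'   inclusive).
#' @param theta_R Voting-ratio threshold (default 0.5).
#' @param theta_CDV Cumulative decision-value threshold (default 60).
#' @param C_jitter Multipliers applied to C across folds.
#' @param standardize Standardize features per training fold.
#' @param seed Integer seed.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(n_iterations = 100L, n_folds = 5L,
                            e_threshold = 75, theta_R = 0.5, theta_CDV = 60,
                            C_jitter = c(0.5, 0.75, 1, 1.25, 1.5),
                            standardize = TRUE, seed = 1L) {
  stopifnot(n_iterations >= 1, n_folds >= 2,
            e_threshold > 0, e_threshold <= 100,
            theta_R > 0, theta_CDV >= 0, length(C_jitter) >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds),
                 e_threshold = e_threshold, theta_R = theta_R,
                 theta_CDV = theta_CDV, C_jitter = C_jitter,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "detector_config")
}

#' Per-sequence error profiles from repeated cross-validated classification
#'
#' Repeats `n_iterations` times: reshuffle the data (seeded), run a
#' stratified `n_folds`-fold cross-validation of the one-vs-one RBF SVM
#' (gamma fixed at `gamma_opt`, C jittered around `C_opt` across folds),
#' and record for every sequence — which is a test item exactly once per
#' iteration — whether it was misclassified, which class it was assigned
#' to, the one-vs-one votes of every class, and the pairwise decision
#' values of all pairs involving its true class. Also records the
#' per-iteration overall accuracy and multi-class MCC.
#'
#' @param X Feature matrix (rownames = sequence ids).
#' @param y Label vector aligned with rows of `X`.
#' @param C_opt,gamma_opt Tuned SVM hyperparameters (see
#'   [tune_hyperparameters()]).
#' @param config A [detector_config()].
#' @param classes Ordered class vocabulary; defaults to order of first
#'   appearance in `y`.
#' @return An object of class `error_profiles`: list with
#'   * `profiles`: tibble (`id`, `true_class`, `ER`, `n_misclassified`,
#'     `assigned_counts`, `votes_total` — the last two are list-columns of
#'     named per-class vectors);
#'   * `votes_log`: integer array `[sequence, class, iteration]` of the
#'     one-vs-one votes each class received on that sequence's test
#'     occasion (an audit trail for recounting VT/VP);
#'   * `dv`: numeric array `[sequence, other class, iteration]` of the
#'     canonical pairwise decision value between the true class and every
#'     other class (sign: positive favors the lower class index);
#'   * `iteration_metrics`: tibble (`iteration`, `accuracy`, `mcc`);
#'   * `classes`, `config`, `C_opt`, `gamma_opt`.
#' @export
profile_errors <- function(X, y, C_opt, gamma_opt, config = detector_config(),
                           classes = NULL) {
  X <- unclass(as.matrix(X))
  y <- as.character(y)
  classes <- classes %||% unique(y)
  K <- length(classes)
  N <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(N))
  y_idx <- match(y, classes)
  if (anyNA(y_idx)) abort("labels outside the class vocabulary")
  small <- table(y)[table(y) < config$n_folds]
  if (length(small) > 0) {
    abort(sprintf("class(es) smaller than n_folds: %s",
                  paste(names(small), collapse = ", ")))
  }
  J <- length(config$C_jitter)

  miscls <- integer(N)
  assigned <- matrix(0L, N, K, dimnames = list(ids, classes))
  votes_total <- matrix(0L, N, K, dimnames = list(ids, classes))
  votes_log <- array(0L, dim = c(N, K, config$n_iterations),
                     dimnames = list(ids, classes, NULL))
  dv_arr <- array(NA_real_, dim = c(N, K, config$n_iterations),
                  dimnames = list(ids, classes, NULL))
  it_acc <- numeric(config$n_iterations)
  it_mcc <- numeric(config$n_iterations)

  withr::with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      fold <- stratified_folds(y, config$n_folds)
      pred_all <- character(N)
      for (f in seq_len(config$n_folds)) {
        tr <- fold != f
        te <- which(!tr)
        C_f <- C_opt * config$C_jitter[((f - 1L) %% J) + 1L]
        fit <- fit_ovo(X[tr, , drop = FALSE], y[tr], C = C_f,
                       gamma = gamma_opt, classes = classes,
                       standardize = config$standardize)
        pred <- predict_votes_dv(fit, X[te, , drop = FALSE])
        pred_all[te] <- pred$predicted
        for (r in seq_along(te)) {
          s <- te[r]
          i <- y_idx[s]
          v <- pred$votes[[r]]
          votes_total[s, ] <- votes_total[s, ] + v
          votes_log[s, , it] <- v
          dvs <- pred$dv[[r]]
          others <- setdiff(seq_len(K), i)
          key <- paste0(pmin(i, others), "/", pmax(i, others))
          dv_arr[s, others, it] <- dvs[key]
          if (pred$predicted[r] != y[s]) {
            miscls[s] <- miscls[s] + 1L
            j <- match(pred$predicted[r], classes)
            assigned[s, j] <- assigned[s, j] + 1L
          }
        }
      }
      Cm <- confusion(y, pred_all, classes)
      mm <- multiclass_metrics(Cm)
      it_acc[it] <- mm$accuracy_overall
      it_mcc[it] <- mm$mcc_multiclass
    }
  })

  profiles <- tibble(
    id = ids,
    true_class = y,
    ER = 100 * miscls / config$n_iterations,
    n_misclassified = miscls,
    assigned_counts = lapply(seq_len(N), function(s) assigned[s, ]),
    votes_total = lapply(seq_len(N), function(s) votes_total[s, ])
  )
  structure(list(profiles = profiles, dv = dv_arr, votes_log = votes_log,
                 iteration_metrics = tibble(iteration = seq_len(config$n_iterations),
                                            accuracy = it_acc, mcc = it_mcc),
                 classes = classes, config = config,
                 C_opt = C_opt, gamma_opt = gamma_opt),
            class = "error_profiles")
}

#' Select frequently misclassified sequences
#'
#' Keeps the profiles whose error rate is at least `e_threshold` percent
#' (inclusive boundary), preserving order.
#'
#' @param profiles The `profiles` tibble of an [profile_errors()] result
#'   (or the `error_profiles` object itself).
#' @param e_threshold Percent threshold (default 75).
#' @return The filtered profiles tibble.
#' @export
select_frequent <- function(profiles, e_threshold = 75) {
  if (inherits(profiles, "error_profiles")) profiles <- profiles$profiles
  profiles[profiles$ER >= e_threshold, , drop = FALSE]
}

#' Voting ratio of true vs most-predicted class
#'
#' For each sequence, the most-predicted class is the class receiving the
#' most misclassified assignments (ties toward the lowest class index);
#' VT is the total number of one-vs-one votes obtained by the true class
#' over all test occasions, VP the total obtained by the most-predicted
#' class, and the voting ratio is R = VT / VP. Small R (at or below
#' `theta_R`) marks a consistent, "large" classification error.
#'
#' @param profiles Profiles tibble (rows must have at least one
#'   misclassified occasion for the most-predicted class to be defined) or
#'   an `error_profiles` object.
#' @param classes Ordered class vocabulary (taken from the object if one
#'   is given).
#' @return The profiles tibble with added columns `predicted_class`,
#'   `VT`, `VP`, `R`.
#' @export
voting_ratio <- function(profiles, classes = NULL) {
  if (inherits(profiles, "error_profiles")) {
    classes <- profiles$classes
    profiles <- profiles$profiles
  }
  if (nrow(profiles) == 0) {
    return(mutate(profiles, predicted_class = character(0),
                  VT = numeric(0), VP = numeric(0), R = numeric(0)))
  }
  classes <- classes %||% names(profiles$assigned_counts[[1]])
  res <- pmap(list(profiles$true_class, profiles$assigned_counts,
                   profiles$votes_total),
              function(tc, ac, vt) {
    if (sum(ac) == 0) {
      return(tibble(predicted_class = NA_character_,
                    VT = NA_real_, VP = NA_real_, R = NA_real_))
    }
    j <- which.max(ac) # ties -> lowest class index
    VT <- unname(vt[match(tc, classes)])
    VP <- unname(vt[j])
    if (VP == 0) abort("most-predicted class received zero votes; corrupt profile")
    tibble(predicted_class = classes[j], VT = as.numeric(VT),
           VP = as.numeric(VP), R = VT / VP)
  })
  dplyr::bind_cols(profiles, dplyr::bind_rows(res))
}

#' Cumulative decision value of the true vs most-predicted pair
#'
#' For each sequence with true class index i and most-predicted class
#' index j, sums over all test occasions the decision value of the single
#' pairwise classifier confronting classes i and j, in the canonical
#' orientation (positive favors the lower class index). Under consistent
#' misclassification toward class j, the CDV is large positive when
#' i > j and large negative when i < j; an absolute value at or above the
#' (iteration-scaled) `theta_CDV` marks a confident, "large" error.
#'
#' @param ep An `error_profiles` object.
#' @param profiles Profiles tibble with a `predicted_class` column (from
#'   [voting_ratio()]); defaults to computing it.
#' @return The profiles tibble with an added `CDV` column.
#' @export
cumulative_dv <- function(ep, profiles = NULL) {
  stopifnot(inherits(ep, "error_profiles"))
  profiles <- profiles %||% voting_ratio(ep)
  if (nrow(profiles) == 0) return(mutate(profiles, CDV = numeric(0)))
  cdv <- map_dbl(seq_len(nrow(profiles)), function(r) {
    id <- profiles$id[r]
    j <- profiles$predicted_class[r]
    if (is.na(j)) return(NA_real_)
    vals <- ep$dv[id, j, ]
    if (anyNA(vals)) abort(sprintf("missing decision-value log for '%s'", id))
    sum(vals)
  })
  mutate(profiles, CDV = cdv)
}

#' Classify the magnitude of a misclassification
#'
#' A sequence's error is "large" when the voting ratio is at or below
#' `theta_R`, or when the absolute cumulative decision value is at or
#' above the effective CDV threshold (`theta_CDV` scaled by
#' `n_iterations/100`); otherwise "small".
#'
#' @param R Voting ratio(s).
#' @param CDV Cumulative decision value(s).
#' @param config A [detector_config()].
#' @return A tibble with `large_R`, `large_CDV`, `magnitude`.
#' @examples
#' classify_magnitude(R = 0.15, CDV = -46)
#' classify_magnitude(R = 0.67, CDV = 45) # small
#' @export
classify_magnitude <- function(R, CDV, config = detector_config()) {
  theta_cdv_eff <- config$theta_CDV * config$n_iterations / 100
  large_R <- !is.na(R) & R <= config$theta_R
  large_CDV <- !is.na(CDV) & abs(CDV) >= theta_cdv_eff
  tibble(large_R = large_R, large_CDV = large_CDV,
         magnitude = ifelse(large_R | large_CDV, "large", "small"))
}

#' End-to-end label-noise candidate detection
#'
#' Runs the full three-step analysis: repeated cross-validated error
#' profiling, voting-ratio analysis and cumulative decision-value analysis
#' of the frequently misclassified sequences. The candidate shortlist is
#' the union of the sequences flagged large by either criterion.
#'
#' @param X Feature matrix (rownames = ids).
#' @param y Labels aligned with `X`.
#' @param config A [detector_config()].
#' @param C_opt,gamma_opt Tuned hyperparameters; if either is `NULL`, a
#'   grid search with `tune_config` is run first.
#' @param tune_config An [svm_config()] for the grid search.
#' @param classes Ordered class vocabulary.
#' @return An object of class `noise_report`: list with `candidates`
#'   (shortlist tibble: id, true/predicted class, ER, VT, VP, R, CDV,
#'   flags, magnitude), `frequent` (all frequently misclassified
#'   sequences with the same columns), `profiles` (the full
#'   `error_profiles` object), `config`, `C_opt`, `gamma_opt`.
#' @export
detect_candidates <- function(X, y, config = detector_config(),
                              C_opt = NULL, gamma_opt = NULL,
                              tune_config = svm_config(), classes = NULL) {
  if (is.null(C_opt) || is.null(gamma_opt)) {
    tuned <- tune_hyperparameters(X, y, tune_config)
    C_opt <- C_opt %||% tuned$C_opt
    gamma_opt <- gamma_opt %||% tuned$gamma_opt
  }
  ep <- profile_errors(X, y, C_opt, gamma_opt, config, classes = classes)
  freq <- select_frequent(ep$profiles, config$e_threshold)
  freq <- voting_ratio(freq, classes = ep$classes)
  freq <- cumulative_dv(ep, freq)
  freq <- dplyr::bind_cols(freq,
                           classify_magnitude(freq$R, freq$CDV, config))
  cols <- c("id", "true_class", "predicted_class", "ER", "VT", "VP",
            "R", "CDV", "large_R", "large_CDV", "magnitude")
  freq_tab <- freq[, cols]
  candidates <- freq_tab[freq_tab$magnitude == "large", , drop = FALSE]
  structure(list(candidates = candidates, frequent = freq_tab,
                 profiles = ep, config = config,
                 C_opt = C_opt, gamma_opt = gamma_opt),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf(
    "# noise_report: %d frequently misclassified, %d label-noise candidates\n",
    nrow(x$frequent), nrow(x$candidates)))
  print(x$candidates, ...)
  invisible(x)
}

#' @describeIn detect_candidates Candidate shortlist as a tibble.
#' @param x A `noise_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.noise_report <- function(x, ...) as_tibble(x$candidates)

#' @describeIn detect_candidates One-row run summary (counts, mean
#'   iteration accuracy and MCC).
#' @exportS3Method generics::glance
glance.noise_report <- function(x, ...) {
  im <- x$profiles$iteration_metrics
  tibble(n_sequences = nrow(x$profiles$profiles),
         n_frequent = nrow(x$frequent),
         n_candidates = nrow(x$candidates),
         mean_accuracy = mean(im$accuracy),
         mean_mcc = mean(im$mcc),
         C_opt = x$C_opt, gamma_opt = x$gamma_opt)
}

#' @describeIn profile_errors Per-sequence profile tibble.
#' @param x An `error_profiles` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.error_profiles <- function(x, ...) as_tibble(x$profiles)

#' @describeIn profile_errors One-row summary of the repeated-CV run.
#' @exportS3Method generics::glance
glance.error_profiles <- function(x, ...) {
  tibble(n_sequences = nrow(x$profiles),
         n_iterations = x$config$n_iterations,
         mean_accuracy = mean(x$iteration_metrics$accuracy),
         sd_accuracy = sd(x$iteration_metrics$accuracy),
         mean_mcc = mean(x$iteration_metrics$mcc),
         sd_mcc = sd(x$iteration_metrics$mcc))
}
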