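# A small real profiling run shared across several tests (memoised).
profiled_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim(K = 4, n_per = 10, noise_rate = 0.05, seed = 23)
      X <- transform_dataset(sim$dataset, "aac")
      cfg <- detector_config(n_iterations = 20, seed = 31)
      ep <- profile_errors(X, sim$dataset$label, C_opt = 10, gamma_opt = 0.05,
                           config = cfg, classes = dataset_classes(sim$dataset))
      cache <<- list(sim = sim, X = X, cfg = cfg, ep = ep)
    }
    cache
  }
})

test_that("every sequence is a test item exactly once per iteration", {
  run <- profiled_run()
  ep <- run$ep
  K <- length(ep$classes)
  n_iter <- ep$config$n_iterations
  # each test occasion casts K(K-1)/2 votes, so totals must be exact
  total_votes <- vapply(ep$profiles$votes_total, sum, 1)
  expect_true(all(total_votes == n_iter * K * (K - 1) / 2))
  # the vote log holds one occasion per iteration
  per_iter <- apply(ep$votes_log, c(1, 3), sum)
  expect_true(all(per_iter == K * (K - 1) / 2))
  # ER consistent with the misclassification count
  expect_equal(ep$profiles$ER,
               100 * ep$profiles$n_misclassified / n_iter)
})

test_that("clean separable classes yield zero error rates everywhere", {
  sim <- small_sim(K = 3, n_per = 8, noise_rate = 0, seed = 40)
  X <- transform_dataset(sim$dataset, "aac")
  ep <- profile_errors(X, sim$dataset$label, C_opt = 10, gamma_opt = 0.05,
                       config = detector_config(n_iterations = 5, seed = 7),
                       classes = dataset_classes(sim$dataset))
  expect_true(all(ep$profiles$ER == 0))
  expect_true(all(ep$iteration_metrics$accuracy == 1))
  expect_equal(ep$iteration_metrics$mcc, rep(1, 5))
})

test_that("frequent-misclassification selection is inclusive and monotone", {
  profs <- tibble::tibble(id = letters[1:5], ER = c(74, 75, 76, 0, 100))
  expect_equal(select_frequent(profs, 75)$id, c("b", "c", "e"))
  expect_equal(select_frequent(profs, 0)$id, letters[1:5])
  # raising the threshold never grows the subset
  for (e in c(10, 50, 75, 90, 100)) {
    expect_true(all(select_frequent(profs, e)$id %in%
                      select_frequent(profs, e - 5)$id))
  }
})

test_that("voting ratio follows VT/VP with the most-assigned class", {
  classes <- c("mG", "CS", "GB", "VN", "Ph", "Od", "Ta")
  mk <- function(true, assigned, votes) {
    tibble::tibble(id = "s", true_class = true,
                   ER = 100, n_misclassified = sum(assigned),
                   assigned_counts = list(setNames(assigned, classes)),
                   votes_total = list(setNames(votes, classes)))
  }
  # worked example: true CS misclassified to mG; VT 91, VP 600 -> R 0.15
  votes <- c(600, 91, 100, 100, 100, 100, 100)
  vr <- voting_ratio(mk("CS", c(100, 0, 0, 0, 0, 0, 0), votes), classes)
  expect_equal(vr$predicted_class, "mG")
  expect_equal(c(vr$VT, vr$VP), c(91, 600))
  expect_equal(round(vr$R, 2), 0.15)
  # worked example: VT 300, VP 600 -> R 0.5
  vr2 <- voting_ratio(mk("VN", c(100, 0, 0, 0, 0, 0, 0),
                         c(600, 50, 50, 300, 50, 50, 50)), classes)
  expect_equal(vr2$R, 0.5)
  # VT = VP -> 1; tie in assignments -> lowest class index
  vr3 <- voting_ratio(mk("Ta", c(40, 0, 40, 0, 0, 0, 0),
                         c(500, 1, 500, 1, 1, 1, 500)), classes)
  expect_equal(vr3$predicted_class, "mG")
  expect_equal(vr3$R, 1)
  # no misclassification -> most-predicted class undefined
  vr4 <- voting_ratio(mk("mG", rep(0, 7), votes), classes)
  expect_true(is.na(vr4$predicted_class))
})

test_that("VT and VP survive an independent recount of the vote log", {
  ep <- profiled_run()$ep
  vr <- voting_ratio(ep)
  recount <- apply(ep$votes_log, c(1, 2), sum) # id x class
  for (r in which(!is.na(vr$predicted_class))) {
    expect_equal(vr$VT[r], unname(recount[vr$id[r], vr$true_class[r]]))
    expect_equal(vr$VP[r], unname(recount[vr$id[r], vr$predicted_class[r]]))
  }
})

test_that("cumulative decision value equals the re-summed pair log", {
  ep <- profiled_run()$ep
  freq <- cumulative_dv(ep, voting_ratio(ep))
  for (r in which(!is.na(freq$predicted_class))) {
    expect_equal(freq$CDV[r],
                 sum(ep$dv[freq$id[r], freq$predicted_class[r], ]))
  }
  # all-zero logged values sum to zero CDV
  ep0 <- ep
  ep0$dv[] <- 0
  z <- cumulative_dv(ep0, voting_ratio(ep))
  expect_true(all(z$CDV[!is.na(z$predicted_class)] == 0))
})

test_that("error magnitude thresholds follow the R and CDV rules", {
  m <- classify_magnitude(R = 0.15, CDV = 50)
  expect_true(m$large_R)
  expect_equal(m$magnitude, "large")
  m2 <- classify_magnitude(R = 0.8, CDV = -96)
  expect_true(m2$large_CDV)
  expect_equal(m2$magnitude, "large")
  m3 <- classify_magnitude(R = 0.67, CDV = 45)
  expect_equal(m3$magnitude, "small")
  # boundary cases are inclusive
  expect_true(classify_magnitude(0.5, 0)$large_R)
  expect_true(classify_magnitude(1, 60)$large_CDV)
  # theta_CDV scales with the number of iterations
  cfg20 <- detector_config(n_iterations = 20)
  expect_true(classify_magnitude(1, 12, cfg20)$large_CDV)
  expect_false(classify_magnitude(1, 11.9, cfg20)$large_CDV)
  # lowering theta_R never shrinks the large_R set
  rs <- seq(0, 1, by = 0.05)
  for (th in c(0.3, 0.5, 0.7)) {
    lo <- classify_magnitude(rs, 0, detector_config(theta_R = th - 0.2))$large_R
    hi <- classify_magnitude(rs, 0, detector_config(theta_R = th))$large_R
    expect_true(all(hi[lo]))
  }
})

test_that("CDV sign tracks the class-index order under consistent errors", {
  run <- profiled_run()
  ep <- run$ep
  freq <- cumulative_dv(ep, voting_ratio(select_frequent(ep, 75), ep$classes))
  checked <- 0
  for (r in seq_len(nrow(freq))) {
    i <- match(freq$true_class[r], ep$classes)
    j <- match(freq$predicted_class[r], ep$classes)
    dvs <- ep$dv[freq$id[r], freq$predicted_class[r], ]
    favored_j <- if (i < j) mean(dvs < 0) else mean(dvs > 0)
    if (favored_j >= 0.9) {
      expect_equal(sign(freq$CDV[r]), if (i > j) 1 else -1)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("end-to-end detection recovers flipped labels deterministically", {
  sim <- small_sim(K = 4, n_per = 10, noise_rate = 0.05, seed = 23)
  X <- transform_dataset(sim$dataset, "aac")
  cfg <- detector_config(n_iterations = 20, seed = 31)
  rep1 <- detect_candidates(X, sim$dataset$label, cfg, C_opt = 10,
                            gamma_opt = 0.05,
                            classes = dataset_classes(sim$dataset))
  flipped <- sim$truth[sim$truth$flipped, ]
  expect_true(all(flipped$id %in% rep1$candidates$id))
  # flipped sequences are predicted back into their original class
  hits <- rep1$candidates[rep1$candidates$id %in% flipped$id, ]
  expect_equal(hits$predicted_class,
               flipped$original_class[match(hits$id, flipped$id)])
  # identical rerun
  rep2 <- detect_candidates(X, sim$dataset$label, cfg, C_opt = 10,
                            gamma_opt = 0.05,
                            classes = dataset_classes(sim$dataset))
  expect_identical(rep1$candidates, rep2$candidates)
  expect_identical(rep1$profiles$iteration_metrics,
                   rep2$profiles$iteration_metrics)
  # clean data produce no candidates
  clean <- small_sim(K = 3, n_per = 8, noise_rate = 0, seed = 40)
  Xc <- transform_dataset(clean$dataset, "aac")
  rep0 <- detect_candidates(Xc, clean$dataset$label,
                            detector_config(n_iterations = 5, seed = 3),
                            C_opt = 10, gamma_opt = 0.05,
                            classes = dataset_classes(clean$dataset))
  expect_equal(nrow(rep0$candidates), 0)
  # tidiers
  expect_identical(tidy(rep1), tibble::as_tibble(rep1$candidates))
  expect_equal(glance(rep1)$n_candidates, nrow(rep1$candidates))
})
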