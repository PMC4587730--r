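test_that("binary metrics hit the analytic anchors", {
  perfect <- binary_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "mcc")]),
               c(accuracy = 1, precision = 1, recall = 1, mcc = 1))
  total_miss <- binary_metrics(tp = 0, tn = 0, fp = 5, fn = 5)
  expect_equal(total_miss$mcc, -1)
})

test_that("binary metrics equal direct evaluation of the defining formulas", {
  cases <- list(c(7, 3, 2, 1), c(1, 1, 1, 1), c(10, 0, 3, 2), c(2, 9, 4, 4))
  for (cs in cases) {
    tp <- cs[1]; tn <- cs[2]; fp <- cs[3]; fn <- cs[4]
    m <- binary_metrics(tp, tn, fp, fn)
    expect_equal(m$accuracy, (tp + tn) / (tp + fn + fp + tn))
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall, tp / (tp + fn))
    expect_equal(m$mcc, (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  }
  expect_error(binary_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("degenerate denominators yield NA metrics and a flagged 0 MCC", {
  m <- binary_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(m$precision))
  expect_equal(m$mcc, 0)
  expect_true(m$degenerate)
})

test_that("confusion counts true class in rows, predicted in columns", {
  cls <- c("a", "b", "c")
  C <- confusion(c("a", "b", "c"), c("a", "b", "c"), cls)
  expect_equal(unname(diag(C)), c(1L, 1L, 1L))
  expect_equal(sum(C) - sum(diag(C)), 0L)

  C2 <- confusion(c("a", "b", "c", "c"), rep("a", 4), cls)
  expect_equal(unname(colSums(C2)), c(4L, 0L, 0L))

  # hand tally of a shuffled case
  yt <- c("b", "a", "c", "b", "a")
  yp <- c("a", "a", "b", "b", "c")
  C3 <- confusion(yt, yp, cls)
  expect_equal(unname(C3["b", "a"]), 1L)
  expect_equal(unname(C3["a", "a"]), 1L)
  expect_equal(unname(C3["c", "b"]), 1L)
  expect_equal(unname(C3["b", "b"]), 1L)
  expect_equal(unname(C3["a", "c"]), 1L)
  expect_equal(sum(C3), 5L)
  expect_equal(unname(rowSums(C3)), c(2L, 2L, 1L)) # class supports

  expect_error(confusion("a", "z", cls), "z")
})

# Independent oracle: the generalized MCC as explicit sums over all matrix
# entries, written term by term.
mcc_sum_oracle <- function(C) {
  K <- nrow(C)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (m in 1:K) {
    num <- num + C[k, k] * C[m, l] - C[l, k] * C[k, m]
  }
  d1 <- 0
  d2 <- 0
  for (k in 1:K) {
    colk <- sum(C[, k])
    rowk <- sum(C[k, ])
    rest_col <- sum(C[, -k])
    rest_row <- sum(C[-k, ])
    d1 <- d1 + colk * rest_col
    d2 <- d2 + rowk * rest_row
  }
  num / (sqrt(d1) * sqrt(d2))
}

test_that("multi-class MCC matches the term-by-term summation oracle", {
  withr::with_seed(17, {
    for (rep in 1:6) {
      K <- sample(3:5, 1)
      C <- matrix(sample(0:9, K * K, replace = TRUE), K)
      if (sum(C) == 0 || any(rowSums(C) == 0)) next
      got <- multiclass_metrics(C)
      if (!got$degenerate) {
        expect_equal(got$mcc_multiclass, mcc_sum_oracle(C), tolerance = 1e-12)
      }
      expect_equal(got$accuracy_overall, sum(diag(C)) / sum(C))
    }
  })
})

test_that("multi-class anchors: perfect = 1, K=2 reduces to binary MCC", {
  expect_equal(multiclass_metrics(diag(10L, 7L))$mcc_multiclass, 1)
  C2 <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  bm <- binary_metrics(tp = 8, tn = 7, fp = 3, fn = 2)
  expect_equal(multiclass_metrics(C2)$mcc_multiclass, bm$mcc)
})

test_that("multi-class MCC is 0 for proportional rows and within [-1, 1]", {
  C <- rbind(c(10, 20, 30), c(5, 10, 15), c(1, 2, 3)) # rows proportional
  expect_equal(multiclass_metrics(C)$mcc_multiclass, 0, tolerance = 1e-12)
  withr::with_seed(31, {
    for (rep in 1:10) {
      C <- matrix(sample(0:20, 16, replace = TRUE), 4)
      m <- multiclass_metrics(C)$mcc_multiclass
      expect_gte(m, -1 - 1e-12)
      expect_lte(m, 1 + 1e-12)
    }
  })
})

test_that("accuracy is invariant under simultaneous class permutation", {
  withr::with_seed(8, {
    C <- matrix(sample(0:9, 16, replace = TRUE), 4)
    p <- sample(4)
    m1 <- multiclass_metrics(C)
    m2 <- multiclass_metrics(C[p, p])
    expect_equal(m1$accuracy_overall, m2$accuracy_overall)
    expect_equal(m1$mcc_multiclass, m2$mcc_multiclass)
  })
})

test_that("per-class recall is the diagonal over the row sum", {
  C <- rbind(c(6, 2, 2), c(1, 8, 1), c(0, 3, 7))
  rownames(C) <- colnames(C) <- c("a", "b", "c")
  pc <- multiclass_metrics(C)$per_class
  expect_equal(pc$recall, diag(C) / rowSums(C), ignore_attr = TRUE)
  # macro-binary accuracy is the mean of one-vs-rest accuracies
  expect_equal(multiclass_metrics(C)$accuracy_macro_binary, mean(pc$accuracy))
})
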