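# Shared fixture builders. Everything is generated in code at test time.

# Well-separated Gaussian feature blobs: K classes, n_per per class, d dims.
# Class centers sit on scaled unit axes so separation is controlled by `spread`.
make_blobs <- function(K = 3, n_per = 10, d = 4, spread = 6, sd = 0.5,
                       seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(0, K, d)
    for (k in seq_len(K)) centers[k, ((k - 1) %% d) + 1] <- spread * k
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
        matrix(centers[k, ], n_per, d, byrow = TRUE)
    }))
    rownames(X) <- sprintf("b%03d", seq_len(K * n_per))
    list(X = X, y = rep(paste0("c", seq_len(K)), each = n_per),
         classes = paste0("c", seq_len(K)))
  })
}

# A tiny two-descriptor toy table over the full alphabet (values arbitrary
# but fixed), for brute-force ACC/PDBT oracle checks.
toy_table <- function() {
  withr::with_seed(99, {
    m <- matrix(round(stats::runif(40, -2, 2), 2), nrow = 20,
                dimnames = list(protnoise:::AA_ALPHABET, c("t1", "t2")))
    m
  })
}

random_aa_seq <- function(len) {
  paste(sample(protnoise:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Independent brute-force ACC oracle: explicit double loop, per-sequence
# mean-centered trajectories, lag-major then (j,k) row-major concatenation.
acc_oracle <- function(sequence, table, max_lag) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  P <- ncol(table)
  traj <- sapply(seq_len(P), function(p) table[chars, p])
  means <- colMeans(traj)
  out <- c()
  for (d in seq_len(max_lag)) {
    for (j in seq_len(P)) {
      for (k in seq_len(P)) {
        s <- 0
        for (i in seq_len(n - d)) {
          s <- s + (traj[i, j] - means[j]) * (traj[i + d, k] - means[k])
        }
        out <- c(out, unname(s / (n - d)))
      }
    }
  }
  out
}

# Independent brute-force PDBT oracle: table standardized over the 20 AAs
# (sd with n-1 denominator), squared differences, property-major then lag.
pdbt_oracle <- function(sequence, table, max_lag) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  std <- apply(table, 2, function(col) (col - mean(col)) / stats::sd(col))
  rownames(std) <- rownames(table)
  out <- c()
  for (p in seq_len(ncol(table))) {
    for (d in seq_len(max_lag)) {
      s <- 0
      for (i in seq_len(n - d)) {
        s <- s + (std[chars[i], p] - std[chars[i + d], p])^2
      }
      out <- c(out, unname(s / (n - d)))
    }
  }
  out
}

# Small labeled synthetic dataset for end-to-end detector tests.
small_sim <- function(K = 4, n_per = 10, noise_rate = 0, seed = 5,
                      separation = 0.9, lengths = c(50, 90)) {
  generate_dataset(K = K, class_sizes = n_per, length_range = lengths,
                   separation = separation, noise_rate = noise_rate,
                   seed = seed)
}
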