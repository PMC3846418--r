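# Build an fp_counts object directly from its sufficient statistics, for
# estimator tests that start from counts rather than raw fingerprints.
make_counts <- function(N_present, N_class) {
  C <- length(N_class)
  N_present <- matrix(as.integer(N_present), nrow = C)
  colnames(N_present) <- paste0("f", seq_len(ncol(N_present)))
  structure(
    list(
      N = sum(N_class), N_class = as.integer(N_class),
      N_present = N_present, N_feat = colSums(N_present),
      C = C, L = ncol(N_present), levels = paste0("class", seq_len(C))
    ),
    class = "fp_counts"
  )
}

# Multiply every count by an integer factor (Remark-2 style scaling).
scale_counts <- function(counts, s) {
  make_counts(counts$N_present * s, counts$N_class * s)
}

# Random non-degenerate counts: feature-presence counts kept at least
# `margin` below the class size so the simplified absent-feature estimator
# stays defined for alpha up to ~margin - 1.
random_counts <- function(C = 2, L = 6, margin = 4L) {
  sizes <- sample(15:60, C, replace = TRUE)
  np <- sapply(seq_len(L), function(j) {
    pmin(stats::rbinom(C, sizes, stats::runif(1, 0.1, 0.7)), sizes - margin)
  })
  make_counts(np, sizes)
}

# The worked two-class toy used across estimator tests:
# class sizes (12, 8), one feature with presence counts (5, 3).
toy_counts <- function() make_counts(c(5, 3), c(12, 8))

# A small labelled dataset with a feature present in every compound of
# class 1 (the degenerate regime for the simplified absent estimator).
degenerate_data <- function() {
  x <- rbind(
    matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1), nrow = 4), # class 1: f1 all ones
    matrix(c(0, 1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1), nrow = 4) # class 2
  )
  fp_data(x, labels = rep(c("a", "b"), each = 4))
}

expect_cols_sum_to_one <- function(m, tol = 1e-10) {
  expect_lt(max(abs(colSums(m) - 1)), tol)
}
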