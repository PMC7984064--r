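# Brute-force oracles, deliberately written by a different route than the
# implementation they check.

# Exhaustive scan of every interior 3x3 neighbourhood.
bf_local_maxima <- function(m) {
  out <- NULL
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (all(m[i, j] > nb[-5])) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# Closed-form growing-window size: the Chebyshev distance from the peak to
# the nearest strictly brighter pixel bounds the largest clean window.
bf_window_size <- function(m, i, j, n_cap = 6L) {
  brighter <- which(m > m[i, j], arr.ind = TRUE)
  d <- if (nrow(brighter) == 0) Inf else
    min(pmax(abs(brighter[, 1] - i), abs(brighter[, 2] - j)))
  border <- min(i - 1, nrow(m) - i, j - 1, ncol(m) - j)
  n_max <- min(d - 1, n_cap, border)
  # capped: growth stopped by the cap or border without a brighter pixel in
  # the last probed (possibly clipped) window
  list(n_max = as.integer(n_max),
       capped = n_max == n_cap || (d - 1) > n_max)
}

# Single-linkage partition through hclust, an entirely separate code path.
bf_linkage <- function(coords, dmax) {
  n <- nrow(coords)
  if (n == 0) return(integer())
  if (n == 1) return(1L)
  cutree(hclust(dist(coords), method = "single"), h = dmax)
}

# Canonical form of a partition label vector so two partitions can be
# compared regardless of label values.
canon_partition <- function(labels) match(labels, unique(labels))

expect_same_partition <- function(a, b) {
  expect_identical(canon_partition(a), canon_partition(b))
}

# Small random plane with structure at several scales.
random_plane <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc), nr, nc)
}
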