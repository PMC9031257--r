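# Shared fixtures: small phantoms and hand-built datasets.

small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(width = 48L, height = 48L, background_n = 40L, seed = seed, ...)
}

# tiny raw dataset built by hand: 2x2 grid, two features
tiny_dataset <- function() {
  msi_dataset(list(
    pixel_spectrum(0, 0, c(400.0, 800.0), c(10, 1)),
    pixel_spectrum(1, 0, c(400.0005, 800.0), c(20, 2)),
    pixel_spectrum(0, 1, c(400.0, 800.0016), c(30, 3)),
    pixel_spectrum(1, 1, c(400.0005, 800.0016), c(40, 4))
  ), width = 2, height = 2)
}

# brute-force O(n^2) single-linkage binning oracle: link every pair of peaks
# within tolerance (ppm relative to the lighter peak) and take connected
# components via union-find — equivalent to single linkage cut at the
# tolerance, with no reliance on the peaks being sorted.
oracle_single_linkage <- function(mz, tolerance_ppm) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      lo <- min(mz[i], mz[j]); hi <- max(mz[i], mz[j])
      if ((hi - lo) / lo * 1e6 <= tolerance_ppm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# random peak pool with clusters straddling the linkage tolerance
random_peak_pool <- function(n = 50L, tolerance_ppm = 2.5) {
  centers <- runif(ceiling(n / 3), 200, 1200)
  mz <- sample(centers, n, replace = TRUE) *
    (1 + runif(n, -1.5 * tolerance_ppm, 1.5 * tolerance_ppm) * 1e-6)
  sort(mz)
}

# exhaustive minimum-SSE bipartition of a small point set; per-subset sums
# built by bit-DP over all 2^(n-1) bipartitions
oracle_best_bipartition <- function(x) {
  n <- nrow(x); d <- ncol(x)
  ncode <- 2^n
  sums <- matrix(0, ncode, d)
  cnt <- integer(ncode)
  for (code in 1:(ncode - 1)) {
    low <- bitwAnd(code, -code)
    bit <- round(log2(low)) + 1L
    prev <- code - low
    sums[code + 1, ] <- sums[prev + 1, ] + x[bit, ]
    cnt[code + 1] <- cnt[prev + 1] + 1L
  }
  tot_sq <- sum(x^2)
  tot_sum <- sums[ncode, ]
  best <- NULL; best_sse <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    cA <- cnt[code + 1]; cB <- n - cA
    if (cA == 0 || cB == 0) next
    sA <- sums[code + 1, ]; sB <- tot_sum - sA
    s <- tot_sq - sum(sA^2) / cA - sum(sB^2) / cB
    if (s < best_sse) { best_sse <- s; best <- code }
  }
  list(split = as.logical(bitwAnd(best, 2^(0:(n - 1)))), sse = best_sse)
}

# direct-formula Pearson correlation (independent of stats::cor)
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
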