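# Straight-line reference implementations, independent of the package's
# code paths: naive per-base tally, loop binning, textbook natural cubic
# spline (tridiagonal second-derivative solve), and the textbook Pearson
# formula. Used to cross-check the production pipeline.

oracle_coverage <- function(reads, chrom_sizes, mode = "span") {
  vals <- lapply(chrom_sizes, function(L) numeric(L))
  for (i in seq_len(nrow(reads))) {
    chr <- reads$chrom[i]
    if (!(chr %in% names(chrom_sizes))) next
    s <- max(0, reads$start[i]); e <- min(chrom_sizes[[chr]], reads$end[i])
    if (s >= e) next
    if (mode == "midpoint") {
      m <- floor((reads$start[i] + reads$end[i]) / 2)
      if (m >= 0 && m < chrom_sizes[[chr]])
        vals[[chr]][m + 1] <- vals[[chr]][m + 1] + 1
    } else {
      for (p in s:(e - 1)) vals[[chr]][p + 1] <- vals[[chr]][p + 1] + 1
    }
  }
  vals
}

oracle_bin <- function(values, w) {
  n <- ceiling(length(values) / w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- (i - 1) * w + 1
    hi <- min(i * w, length(values))
    out[i] <- sum(values[lo:hi])
  }
  out
}

# natural cubic spline: knots (x, y), evaluated at xout; second
# derivatives M solved from the standard tridiagonal system with
# M[1] = M[n] = 0
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    b <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      j <- i - 1
      A[j, j] <- 2 * (h[i - 1] + h[i])
      if (j > 1) A[j, j - 1] <- h[i - 1]
      if (j < n - 2) A[j, j + 1] <- h[i]
      b[j] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
    M[2:(n - 1)] <- solve(A, b)
  }
  vapply(xout, function(t) {
    i <- findInterval(t, x, rightmost.closed = TRUE)
    i <- max(1, min(i, n - 1))
    hi <- h[i]
    M[i] * (x[i + 1] - t)^3 / (6 * hi) +
      M[i + 1] * (t - x[i])^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - t) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (t - x[i])
  }, numeric(1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# full per-gene reference pipeline: per-base slice, loop binning,
# natural-spline smoothing on the expanded grid, textbook Pearson
oracle_shapediff_gene <- function(values_a, values_b, gene, bin_width = 10,
                                  expansion = 3) {
  slice <- function(v) {
    out <- v[(gene$start + 1):gene$end]
    if (gene$strand == "-") out <- rev(out)
    out
  }
  ba <- oracle_bin(slice(values_a), bin_width)
  bb <- oracle_bin(slice(values_b), bin_width)
  nb <- length(ba)
  xout <- seq(0, nb - 1, length.out = expansion * nb)
  sa <- oracle_natural_spline(0:(nb - 1), ba, xout)
  sb <- oracle_natural_spline(0:(nb - 1), bb, xout)
  oracle_pearson(sa, sb)
}

# Mann-Whitney AUC: probability that a value from `hi` exceeds one from
# `lo` (ties count half)
oracle_auc <- function(hi, lo) {
  cmp <- outer(hi, lo, ">") + 0.5 * outer(hi, lo, "==")
  mean(cmp)
}
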