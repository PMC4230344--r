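# Small in-code fixtures shared across test files.

# single-chromosome track from an explicit value vector
toy_track <- function(values, chrom = "chrI", total_reads = 100,
                      normalized = "raw") {
  coverage_track(stats::setNames(list(as.numeric(values)), chrom),
                 total_reads = total_reads, normalized = normalized)
}

# scale every per-base value of a track by k (depth change surrogate)
scale_track <- function(track, k) {
  track$values <- lapply(track$values, function(v) v * k)
  track
}

toy_chrom_sizes <- function(len = 1000, chrom = "chrI") {
  stats::setNames(len, chrom)
}

random_reads <- function(n, chrom_sizes, max_len = 200) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample(20:max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_sizes[[chrom[i]]] - len[i], 1) - 1, numeric(1))
  data.frame(chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             mapq = sample(0:60, n, replace = TRUE))
}
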