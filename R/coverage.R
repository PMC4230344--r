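#' Coverage track: per-base signal over the genome
#'
#' @param values Named list of numeric vectors, one per chromosome, one
#'   value per base.
#' @param total_reads Read count used for depth normalization.
#' @param normalized `"raw"`, `"rpm"` (reads per million) or `"ratio"`.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(values, total_reads, normalized = "raw",
                           chrom_sizes = lengths(values)) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (!all(lengths(values) == chrom_sizes[names(values)]))
    stop("coverage array lengths disagree with chrom_sizes", call. = FALSE)
  structure(list(values = values, total_reads = total_reads,
                 normalized = normalized,
                 chrom_sizes = chrom_sizes[names(values)]),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %s bp, %s, %s reads\n",
              length(x$values),
              format(sum(x$chrom_sizes), big.mark = ","),
              x$normalized,
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Read aligned reads from SAM, BAM or BED
#'
#' Returns a plain data frame of alignments in the internal 0-based
#' half-open convention. SAM input is converted to BAM on the fly; BED6
#' files use the score column as the mapping quality.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bam"`, `"sam"`, or `"bed"`.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `mapq`.
#' @export
read_alignments <- function(path, format = c("auto", "bam", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "bam", sam = "sam", bed = "bed",
                     stop("cannot infer alignment format of ", path,
                          call. = FALSE))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    mapq <- if (!is.null(gr$score)) as.integer(gr$score)
            else rep(0L, length(gr))
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      mapq = mapq))
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    path <- bam
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "mapq"))
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             mapq = S4Vectors::mcols(ga)$mapq)
}

#' Build a coverage track from aligned reads
#'
#' In `span` mode every retained read adds 1 to each base it covers; in
#' `midpoint` mode it adds 1 at its fragment midpoint only (the natural
#' choice for dyad-centric nucleosome analyses). Reads below `min_mapq`
#' are dropped; reads on chromosomes absent from `chrom_sizes` are skipped
#' with a warning, and reads running past a chromosome end are clipped.
#'
#' @param reads Data frame as from [read_alignments()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param mode `"span"` (default) or `"midpoint"`.
#' @param min_mapq Minimum mapping quality to retain (default 0).
#' @return A raw-count [coverage_track()] whose `total_reads` is the number
#'   of retained reads.
#' @export
coverage_from_alignments <- function(reads, chrom_sizes,
                                     mode = c("span", "midpoint"),
                                     min_mapq = 0L) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (is.null(reads$mapq)) reads$mapq <- 0L
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  unknown <- !(reads$chrom %in% names(chrom_sizes))
  if (any(unknown)) {
    warning(sum(unknown), " read(s) on unknown chromosome(s) skipped: ",
            paste(unique(reads$chrom[unknown]), collapse = ", "),
            call. = FALSE)
    reads <- reads[!unknown, , drop = FALSE]
  }
  clip <- reads$end > chrom_sizes[reads$chrom] | reads$start < 0
  if (any(clip)) {
    warning(sum(clip), " read(s) clipped to chromosome bounds",
            call. = FALSE)
    reads$start <- pmax(reads$start, 0)
    reads$end <- pmin(reads$end, chrom_sizes[reads$chrom])
    reads <- reads[reads$start < reads$end, , drop = FALSE]
  }
  values <- lapply(names(chrom_sizes), function(chr) {
    L <- as.integer(chrom_sizes[[chr]])
    r <- reads[reads$chrom == chr, , drop = FALSE]
    if (nrow(r) == 0L) return(numeric(L))
    if (mode == "midpoint") {
      mids <- floor((r$start + r$end) / 2)
      as.numeric(tabulate(mids + 1L, nbins = L))
    } else {
      # difference-array accumulation: O(reads + L)
      d <- numeric(L + 1L)
      s <- as.integer(r$start) + 1L
      e <- as.integer(r$end) + 1L
      add <- tabulate(s, nbins = L + 1L) - tabulate(e, nbins = L + 1L)
      cumsum(add)[seq_len(L)]
    }
  })
  names(values) <- names(chrom_sizes)
  coverage_track(values, total_reads = nrow(reads), normalized = "raw",
                 chrom_sizes = chrom_sizes)
}

#' Normalize a coverage track to reads per million
#'
#' @param track A raw-count [coverage_track()].
#' @return The track with every value scaled by `1e6 / total_reads` and the
#'   normalization flag set to `"rpm"`.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized != "raw")
    stop("track is already ", track$normalized, call. = FALSE)
  if (is.na(track$total_reads) || track$total_reads <= 0)
    stop("cannot RPM-normalize an empty library (total_reads = 0)",
         call. = FALSE)
  k <- 1e6 / track$total_reads
  track$values <- lapply(track$values, function(v) v * k)
  track$normalized <- "rpm"
  track
}

#' Extract a strand-oriented per-gene profile
#'
#' Slices the track over an interval and, for minus-strand genes, reverses
#' the slice so index 1 is always the TSS side.
#'
#' @param track A [coverage_track()].
#' @param chrom,start,end 0-based half-open interval (alternatively pass a
#'   list with those fields as `chrom`).
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of length `end - start` in transcript
#'   orientation.
#' @export
extract_profile <- function(track, chrom, start = NULL, end = NULL,
                            strand = "+") {
  if (is.list(chrom)) {
    iv <- chrom
    chrom <- iv$chrom; start <- iv$start; end <- iv$end
    if (!is.null(iv$strand)) strand <- iv$strand
  }
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom, call. = FALSE)
  if (start < 0 || end > length(v) || start >= end)
    stop(sprintf("interval [%s,%s) out of bounds on %s (length %d)",
                 format_bp(start), format_bp(end), chrom, length(v)),
         call. = FALSE)
  p <- v[(start + 1L):end]
  if (strand == "-") p <- rev(p)
  p
}

#' Bin a profile by summing fixed-width windows
#'
#' The transcribed region is divided into consecutive `bin_width`-bp bins
#' and values are summed within each; a short terminal bin is kept, so
#' binning conserves the profile total.
#'
#' @param profile Numeric vector (transcript orientation).
#' @param bin_width Bin width in bp (default 10).
#' @return Numeric vector of `ceiling(length(profile) / bin_width)` bin
#'   sums.
#' @export
bin_profile <- function(profile, bin_width = 10L) {
  stopifnot(bin_width >= 1L)
  L <- length(profile)
  if (L == 0L) stop("empty profile", call. = FALSE)
  idx <- (seq_len(L) - 1L) %/% bin_width
  as.numeric(tapply(profile, idx, sum))
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    nz <- r$values != 0
    if (!any(nz)) next
    writeLines(paste(chr, format_bp(s[nz]), format_bp(e[nz]),
                     format(r$values[nz], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a coverage track as fixed-step wiggle
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param step Step/span in bp (default 1).
#' @export
write_wiggle <- function(track, path, step = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (step > 1L) {
      idx <- (seq_along(v) - 1L) %/% step
      v <- as.numeric(tapply(v, idx, mean))
    }
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chr, step, step), con)
    writeLines(format(v, scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}
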