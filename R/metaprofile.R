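#' Anchor sets for metagene aggregation
#'
#' An anchor set is a data frame of `(chrom, position, strand)` points
#' around which per-gene windows are aligned: TSSs for classic metagene
#' plots, or intron junction ends for splice-site-aligned profiles.
#'
#' @param annotation A [genome_annotation()].
#' @return Data frame with columns `chrom`, `position`, `strand`.
#' @examples
#' sim <- simulate_annotation(sim_config(seed = 1, n_genes = 10))
#' head(tss_anchors(sim$annotation))
#' @export
tss_anchors <- function(annotation) {
  rows <- lapply(annotation$genes, function(g)
    data.frame(chrom = g$chrom,
               position = if (g$strand == "+") g$start else g$end - 1,
               strand = g$strand))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname tss_anchors
#' @param which Intron end to anchor on: `"five_prime_end"` or
#'   `"three_prime_end"`.
#' @param policy `"first_intron"` (default) or `"all_introns"` (see
#'   [intron_anchor_points()]).
#' @export
intron_anchors <- function(annotation,
                           which = c("five_prime_end", "three_prime_end"),
                           policy = c("first_intron", "all_introns")) {
  which <- match.arg(which)
  policy <- match.arg(policy)
  rows <- lapply(annotation$genes, intron_anchor_points,
                 which = which, policy = policy)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L)
    stop("no intron-containing genes in the annotation", call. = FALSE)
  out
}

#' Per-anchor signal matrix around a set of anchor points
#'
#' For each anchor the window `-upstream .. +downstream-1` (in transcript
#' orientation) is extracted from the track; minus-strand rows are
#' orientation-flipped before insertion so column 1 is always the
#' upstream-most position. Positions falling off the chromosome are
#' missing (`NA`), not zero, so edge anchors do not drag averages down.
#'
#' @param track A [coverage_track()].
#' @param anchors Data frame with `chrom`, `position`, `strand` (see
#'   [tss_anchors()]).
#' @param upstream,downstream Window extent in bp on each side of the
#'   anchor (the anchor base itself is column `upstream + 1`).
#' @return Numeric matrix, anchors in rows, `upstream + downstream`
#'   columns named by offset.
#' @export
anchor_profiles <- function(track, anchors, upstream, downstream) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0,
            nrow(anchors) > 0L)
  width <- upstream + downstream
  known <- anchors$chrom %in% names(track$values)
  if (!all(known)) {
    warning(sum(!known), " anchor(s) on unknown chromosome(s) skipped",
            call. = FALSE)
    anchors <- anchors[known, , drop = FALSE]
    if (nrow(anchors) == 0L) stop("no usable anchors", call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = width,
                dimnames = list(NULL,
                                as.character(seq(-upstream,
                                                 downstream - 1L))))
  for (i in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[i]
    pos <- anchors$position[i]
    v <- track$values[[chr]]
    L <- length(v)
    if (anchors$strand[i] == "-") {
      # transcript offset c maps to genomic position pos - c
      gpos <- pos - seq(-upstream, downstream - 1L)
    } else {
      gpos <- pos + seq(-upstream, downstream - 1L)
    }
    inb <- gpos >= 0 & gpos < L
    mat[i, inb] <- v[gpos[inb] + 1L]
  }
  mat
}

#' Average an anchor matrix into a metaprofile with confidence bands
#'
#' Per position (column): the mean over non-missing rows and a
#' normal-approximation confidence interval of that mean,
#' `mean +/- z * sd / sqrt(n)`. A bootstrap percentile interval is
#' available as an alternative. Columns with a single observation get a
#' zero-width band; columns with none are `NA` with `n = 0`.
#'
#' @param mat Matrix from [anchor_profiles()].
#' @param level Confidence level (default 0.95).
#' @param method `"normal"` (deterministic default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @return Object of class `metaprofile`: data frame with `position`,
#'   `mean`, `ci_low`, `ci_high`, `n`.
#' @export
aggregate_mean_ci <- function(mat, level = 0.95,
                              method = c("normal", "bootstrap"),
                              n_boot = 1000L) {
  method <- match.arg(method)
  if (all(is.na(mat))) stop("all-missing profile matrix", call. = FALSE)
  n <- colSums(!is.na(mat))
  m <- colMeans(mat, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  if (method == "normal") {
    z <- stats::qnorm((1 + level) / 2)
    s <- apply(mat, 2L, stats::sd, na.rm = TRUE)
    s[n < 2L] <- 0
    half <- ifelse(n > 0L, z * s / sqrt(pmax(n, 1L)), NA_real_)
    lo <- m - half; hi <- m + half
  } else {
    lo <- hi <- rep(NA_real_, ncol(mat))
    for (j in seq_len(ncol(mat))) {
      v <- mat[, j][!is.na(mat[, j])]
      if (length(v) == 0L) next
      if (length(v) == 1L) { lo[j] <- hi[j] <- v; next }
      bm <- vapply(seq_len(n_boot), function(b)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1L))
      q <- stats::quantile(bm, c((1 - level) / 2, (1 + level) / 2),
                           names = FALSE)
      lo[j] <- q[1L]; hi[j] <- q[2L]
    }
  }
  pos <- suppressWarnings(as.numeric(colnames(mat)))
  if (length(pos) != ncol(mat) || anyNA(pos)) pos <- seq_len(ncol(mat))
  structure(data.frame(position = pos, mean = m, ci_low = lo,
                       ci_high = hi, n = as.integer(n),
                       row.names = NULL),
            class = c("metaprofile", "data.frame"),
            level = level, ci_method = method)
}

#' Anchor-aligned metagene profile of a coverage track
#'
#' Convenience wrapper: [anchor_profiles()] followed by
#' [aggregate_mean_ci()]. For figure-style metagene plots the track should
#' be RPM-normalized so the y axis reads "average read counts per million
#' reads".
#'
#' @inheritParams anchor_profiles
#' @inheritParams aggregate_mean_ci
#' @return A `metaprofile` (see [aggregate_mean_ci()]).
#' @export
metaprofile <- function(track, anchors, upstream = 500L,
                        downstream = 2000L, level = 0.95,
                        method = "normal") {
  aggregate_mean_ci(anchor_profiles(track, anchors, upstream, downstream),
                    level = level, method = method)
}

#' @export
plot.metaprofile <- function(x, col = "steelblue", band_col = NULL,
                             xlab = "Position relative to anchor (bp)",
                             ylab = "Mean occupancy", add = FALSE, ...) {
  if (is.null(band_col))
    band_col <- grDevices::adjustcolor(col, alpha.f = 0.3)
  ok <- x$n > 0L
  if (!add)
    plot(x$position[ok], x$mean[ok], type = "n", xlab = xlab, ylab = ylab,
         ylim = range(c(x$ci_low[ok], x$ci_high[ok]), finite = TRUE), ...)
  graphics::polygon(c(x$position[ok], rev(x$position[ok])),
                    c(x$ci_low[ok], rev(x$ci_high[ok])),
                    col = band_col, border = NA)
  graphics::lines(x$position[ok], x$mean[ok], col = col, lwd = 2)
  invisible(x)
}

#' Write a metaprofile as TSV
#' @param mp A `metaprofile`.
#' @param path Output path.
#' @export
write_metaprofile <- function(mp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#position\tmean\tci_low\tci_high\tn", con)
  utils::write.table(as.data.frame(mp), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select the top transcription-rate genes and split by intron content
#'
#' Ranks genes by a transcription-rate (TR) score — in the motivating
#' analyses, RNA polymerase II Ser5-P occupancy — takes the top `n`, and
#' partitions them into intron-less and intron-containing subsets. Ties at
#' the selection boundary are broken by gene id (lexicographic), making
#' the selection deterministic.
#'
#' @param scores Data frame with columns `gene_id` and `tr_score`
#'   (non-negative, finite).
#' @param annotation A [genome_annotation()]; only genes present in it are
#'   considered.
#' @param n Number of genes to select (default 500).
#' @return List with character vectors `top`, `intronless`,
#'   `introncontaining` (the latter two partition `top`).
#' @export
select_top_tr_genes <- function(scores, annotation, n = 500L) {
  stopifnot(all(c("gene_id", "tr_score") %in% names(scores)))
  if (any(!is.finite(scores$tr_score)) || any(scores$tr_score < 0))
    stop("tr_score must be finite and non-negative", call. = FALSE)
  scores <- scores[scores$gene_id %in% names(annotation$genes), ,
                   drop = FALSE]
  if (nrow(scores) < n)
    stop("only ", nrow(scores), " scored genes in the annotation; ",
         "cannot select top ", n, call. = FALSE)
  ord <- order(-scores$tr_score, scores$gene_id)
  top <- scores$gene_id[ord][seq_len(n)]
  hi <- vapply(annotation$genes[top], has_intron, logical(1L))
  list(top = top, intronless = top[!hi], introncontaining = top[hi])
}

#' Histone-exchange ratio track (Flag-H3 relative to Myc-H3)
#'
#' The exchange rate at a base is the occupancy of newly deposited
#' (inducible Flag-tagged) H3 relative to pre-existing (constitutive
#' Myc-tagged) H3. Both tracks must be depth-normalized (RPM) so the ratio
#' is not confounded by library size; a pseudocount regularizes
#' low-coverage bases.
#'
#' @param flag_track,myc_track RPM-normalized [coverage_track()]s over the
#'   same chromosomes.
#' @param pseudocount Added to numerator and denominator (RPM units,
#'   default 0.5).
#' @param log2_output If `TRUE`, return `log2` of the ratio.
#' @return A [coverage_track()] flagged `"ratio"` (not further
#'   RPM-normalizable).
#' @export
exchange_ratio <- function(flag_track, myc_track, pseudocount = 0.5,
                           log2_output = FALSE) {
  stopifnot(inherits(flag_track, "coverage_track"),
            inherits(myc_track, "coverage_track"), pseudocount > 0)
  if (flag_track$normalized != "rpm" || myc_track$normalized != "rpm")
    stop("exchange_ratio requires RPM-normalized tracks ",
         "(ratios of raw counts confound sequencing depth)",
         call. = FALSE)
  if (!identical(flag_track$chrom_sizes, myc_track$chrom_sizes))
    stop("tracks have mismatched chromosomes/sizes", call. = FALSE)
  values <- mapply(function(f, m) {
    r <- (f + pseudocount) / (m + pseudocount)
    if (log2_output) log2(r) else r
  }, flag_track$values, myc_track$values, SIMPLIFY = FALSE)
  coverage_track(values, total_reads = NA_real_, normalized = "ratio",
                 chrom_sizes = flag_track$chrom_sizes)
}
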