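#' Spline-smooth a binned occupancy profile
#'
#' Smooths the binned read counts of a gene before the shape comparison.
#' The default reproduces R's built-in interpolating cubic spline with its
#' default parameters: knots at the bin indices `0 .. n_bins - 1`, "fmm"
#' end conditions, evaluated at `expansion * n_bins` points evenly spaced
#' over the knot range. A natural-end interpolating spline and a
#' cross-validated penalized smoothing spline are available as
#' alternatives.
#'
#' @param bins Numeric vector of bin values (see [bin_profile()]).
#' @param method `"interpolating"` (default) or `"smoothing"` (penalized
#'   cubic smoothing spline, generalized cross-validation).
#' @param expansion Evaluation density: number of output points per input
#'   bin (default 3, matching the built-in spline default).
#' @param ends End condition for the interpolating spline: `"fmm"`
#'   (default) or `"natural"`.
#' @return List with `values` (smoothed signal), `eval_points` (positions
#'   in bin-index units) and `method`.
#' @examples
#' smooth_profile(c(0, 5, 1, 8, 2, 9))$values
#' @export
smooth_profile <- function(bins, method = c("interpolating", "smoothing"),
                           expansion = 3L, ends = c("fmm", "natural")) {
  method <- match.arg(method)
  ends <- match.arg(ends)
  nb <- length(bins)
  if (nb < 4L)
    stop("need at least 4 bins for cubic spline smoothing (got ", nb, ")",
         call. = FALSE)
  x <- seq_len(nb) - 1
  n_out <- expansion * nb
  if (method == "interpolating") {
    sp <- stats::spline(x, bins, n = n_out, method = ends)
    out <- list(values = sp$y, eval_points = sp$x, method = method)
  } else {
    xout <- seq(0, nb - 1, length.out = n_out)
    fit <- stats::smooth.spline(x, bins)
    out <- list(values = stats::predict(fit, xout)$y, eval_points = xout,
                method = method)
  }
  if (!all(is.finite(out$values)))
    stop("non-finite smoothed values from finite input", call. = FALSE)
  out
}

#' Pearson correlation between two smoothed profiles
#'
#' The shape statistic for one gene: the Pearson correlation coefficient
#' over the paired smoothed values of the two samples. Zero-variance
#' (degenerate) inputs yield an undefined result with an explanatory
#' status rather than a silent number.
#'
#' @param a,b Numeric vectors or [smooth_profile()] results of equal
#'   length.
#' @param min_points Minimum number of paired points (default 4).
#' @return List of class `correlation_result` with `r` (in `[-1, 1]` or
#'   `NA`), `n_points`, and `status` (`"ok"`, `"degenerate_a"`,
#'   `"degenerate_b"`, `"too_short"`).
#' @export
profile_correlation <- function(a, b, min_points = 4L) {
  if (is.list(a)) a <- a$values
  if (is.list(b)) b <- b$values
  if (length(a) != length(b))
    stop("profiles have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  n <- length(a)
  res <- function(r, status)
    structure(list(r = r, n_points = n, status = status),
              class = "correlation_result")
  if (n < min_points) return(res(NA_real_, "too_short"))
  if (stats::var(a) == 0) return(res(NA_real_, "degenerate_a"))
  if (stats::var(b) == 0) return(res(NA_real_, "degenerate_b"))
  res(stats::cor(a, b), "ok")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %s (%s, n = %d)\n",
              ifelse(is.na(x$r), "NA", format(x$r, digits = 4)),
              x$status, x$n_points))
  invisible(x)
}

#' Shape correlation of one gene between two tracks
#'
#' Runs the full per-gene pipeline: extract the strand-oriented occupancy
#' profile over the transcribed region from each track, bin at `bin_width`
#' bp, spline-smooth, and correlate. Because the Pearson correlation is
#' invariant to positive scaling, the result is identical for raw and
#' RPM-normalized tracks.
#'
#' @param track_a,track_b [coverage_track()] objects over the same genome.
#' @param gene A [gene_model()].
#' @param bin_width Bin width in bp (default 10).
#' @param method,expansion,ends Passed to [smooth_profile()].
#' @param min_bins Genes with fewer bins are reported as `too_short`
#'   (default 4, the cubic-spline minimum).
#' @return A `correlation_result`.
#' @export
shape_diff_gene <- function(track_a, track_b, gene, bin_width = 10L,
                            method = "interpolating", expansion = 3L,
                            ends = "fmm", min_bins = 4L) {
  iv <- transcribed_region(gene)
  pa <- extract_profile(track_a, iv)
  pb <- extract_profile(track_b, iv)
  ba <- bin_profile(pa, bin_width)
  bb <- bin_profile(pb, bin_width)
  n <- length(ba)
  if (n < min_bins)
    return(structure(list(r = NA_real_, n_points = n,
                          status = "too_short"),
                     class = "correlation_result"))
  if (stats::var(ba) == 0)
    return(structure(list(r = NA_real_, n_points = n,
                          status = "degenerate_a"),
                     class = "correlation_result"))
  if (stats::var(bb) == 0)
    return(structure(list(r = NA_real_, n_points = n,
                          status = "degenerate_b"),
                     class = "correlation_result"))
  sa <- smooth_profile(ba, method, expansion, ends)
  sb <- smooth_profile(bb, method, expansion, ends)
  profile_correlation(sa, sb, min_points = min_bins)
}

#' Genome-wide shape comparison of two occupancy tracks
#'
#' The central estimator: for every gene with TSS and PAS coordinates, the
#' occupancy signal over the transcribed region is binned (10 bp), spline
#' smoothed, and the per-gene Pearson correlation between the two samples
#' is computed. The result is a classed object holding the per-gene
#' correlation table; use [summary()] for gene-set medians and threshold
#' counts, [plot()] for the correlation histogram, and
#' [as.data.frame()] for the raw table.
#'
#' Genes whose smoothed signal is constant in either sample are reported
#' with an explanatory status and an undefined coefficient; they are
#' excluded from summaries rather than contributing a spurious 0 or 1.
#'
#' @inheritParams shape_diff_gene
#' @param annotation A [genome_annotation()].
#' @return Object of class `shapediff`: list with `table` (data frame with
#'   one row per gene: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_bins`, `r`, `status`, `has_intron`), `params`, and `call`.
#' @examples
#' sim <- build_scenario("null", sim_config(seed = 1, n_genes = 12,
#'                                          depth = 20000))
#' sd_fit <- shape_diff(sim$tracks[[1]], sim$tracks[[2]], sim$annotation)
#' summary(sd_fit)
#' @export
shape_diff <- function(track_a, track_b, annotation, bin_width = 10L,
                       method = "interpolating", expansion = 3L,
                       ends = "fmm", min_bins = 4L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (length(annotation$genes) == 0L)
    stop("empty annotation", call. = FALSE)
  rows <- lapply(annotation$genes, function(g) {
    cr <- shape_diff_gene(track_a, track_b, g, bin_width, method,
                          expansion, ends, min_bins)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, strand = g$strand,
               n_bins = as.integer(ceiling((g$end - g$start) / bin_width)),
               r = cr$r, status = cr$status, has_intron = has_intron(g))
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(table = tab,
                 params = list(bin_width = bin_width, method = method,
                               expansion = expansion, ends = ends,
                               min_bins = min_bins),
                 call = match.call()),
            class = "shapediff")
}

#' @export
print.shapediff <- function(x, ...) {
  ok <- x$table$status == "ok"
  cat("Genome-wide occupancy shape comparison (shapeDiff)\n")
  cat(sprintf("  genes: %d (%d ok, %d skipped/degenerate)\n",
              nrow(x$table), sum(ok), sum(!ok)))
  if (any(ok))
    cat(sprintf("  median r = %.3f  [IQR %.3f, %.3f]\n",
                stats::median(x$table$r[ok]),
                stats::quantile(x$table$r[ok], 0.25),
                stats::quantile(x$table$r[ok], 0.75)))
  cat(sprintf("  params: bin %d bp, %s spline (%s ends), expansion %d\n",
              x$params$bin_width, x$params$method, x$params$ends,
              x$params$expansion))
  invisible(x)
}

#' @export
as.data.frame.shapediff <- function(x, ...) x$table

#' Summarize a shape comparison, optionally by gene set
#'
#' @param object A [shape_diff()] fit.
#' @param gene_sets Optional named list of gene-id vectors.
#' @param threshold Count genes with `r` above this value (default 0.6).
#' @param ... Unused.
#' @return Object of class `summary.shapediff`: the per-set summary table
#'   from [summarize_gene_sets()] (the set `"all"` always included).
#' @export
summary.shapediff <- function(object, gene_sets = NULL, threshold = 0.6,
                              ...) {
  sets <- c(list(all = object$table$gene_id), gene_sets)
  out <- summarize_gene_sets(object, sets, threshold)
  structure(list(summary = out, threshold = threshold,
                 n_genes = nrow(object$table)),
            class = "summary.shapediff")
}

#' @export
print.summary.shapediff <- function(x, ...) {
  cat("shapeDiff summary (", x$n_genes, " genes; threshold r > ",
      x$threshold, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.shapediff <- function(x, breaks = seq(-1, 1, by = 0.05),
                           main = "Per-gene shape correlation",
                           xlab = "Pearson r (smoothed profiles)", ...) {
  r <- x$table$r[x$table$status == "ok"]
  graphics::hist(r, breaks = breaks, main = main, xlab = xlab, ...)
  graphics::abline(v = stats::median(r), lty = 2)
  invisible(x)
}

#' Per-gene-set summary of shape correlations
#'
#' Computes, for each named gene set, the number of genes with a defined
#' coefficient, the median and quartiles of `r`, and the count of genes
#' exceeding a threshold (the figure-of-merit used to call two occupancy
#' patterns co-localized). Unknown gene ids are warned about and skipped;
#' degenerate/skipped genes never enter the summaries.
#'
#' @param x A [shape_diff()] fit or its correlation table.
#' @param gene_sets Named list of character vectors of gene ids.
#' @param threshold Threshold for the exceedance count (default 0.6).
#' @return Data frame with one row per set: `set`, `n`, `median_r`, `q1`,
#'   `q3`, `n_above_threshold`.
#' @export
summarize_gene_sets <- function(x, gene_sets, threshold = 0.6) {
  tab <- if (inherits(x, "shapediff")) x$table else x
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm) {
    ids <- gene_sets[[nm]]
    unknown <- setdiff(ids, tab$gene_id)
    if (length(unknown) > 0L)
      warning("set '", nm, "': ", length(unknown),
              " unknown gene id(s) skipped", call. = FALSE)
    sub <- tab[tab$gene_id %in% ids & tab$status == "ok", , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(set = nm, n = 0L, median_r = NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        n_above_threshold = 0L))
    q <- stats::quantile(sub$r, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(set = nm, n = nrow(sub), median_r = q[2L], q1 = q[1L],
               q3 = q[3L],
               n_above_threshold = sum(sub$r > threshold))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a correlation table as TSV
#'
#' Single `#`-prefixed header line followed by one row per gene.
#'
#' @param x A [shape_diff()] fit or its table.
#' @param path Output path.
#' @export
write_correlation_table <- function(x, path) {
  tab <- if (inherits(x, "shapediff")) x$table else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tab), collapse = "\t")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a correlation table written by [write_correlation_table()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_correlation_table <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  utils::read.table(path, sep = "\t", skip = 1L,
                    col.names = strsplit(hdr, "\t")[[1L]],
                    stringsAsFactors = FALSE)
}
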