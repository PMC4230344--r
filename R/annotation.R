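#' Gene model: transcribed region plus intron intervals
#'
#' A gene model records the coordinate scaffold every downstream analysis
#' uses: the transcribed region from the transcription start site (TSS) to
#' the polyadenylation site (PAS), and any intron intervals inside it. All
#' internal coordinates are 0-based, half-open. The body is stored as
#' (min, max) on the genome with the strand recorded, so for minus-strand
#' genes the TSS is at `end` and the PAS at `start`.
#'
#' @param gene_id Unique gene identifier.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open body interval (TSS to PAS extent).
#' @param strand `"+"` or `"-"`.
#' @param introns Two-column matrix of 0-based half-open intron intervals
#'   (columns `start`, `end`), or `NULL`/zero-row for intron-less genes.
#'   Stored 5'-to-3' in transcript orientation.
#' @return An object of class `gene_model`.
#' @examples
#' g <- gene_model("YAL001C", "chrI", 100, 400, "+",
#'                 introns = cbind(200, 300))
#' transcribed_region(g)
#' @export
gene_model <- function(gene_id, chrom, start, end, strand, introns = NULL) {
  if (is.null(introns) || NROW(introns) == 0L) {
    introns <- matrix(numeric(0), ncol = 2L)
  } else {
    introns <- matrix(as.numeric(unlist(introns)), ncol = 2L,
                      dimnames = NULL,
                      byrow = FALSE)
  }
  colnames(introns) <- c("start", "end")
  g <- structure(list(gene_id = as.character(gene_id),
                      chrom = as.character(chrom),
                      start = as.numeric(start), end = as.numeric(end),
                      strand = as.character(strand),
                      introns = introns),
                 class = "gene_model")
  # transcript orientation: ascending start for "+", descending for "-"
  if (nrow(g$introns) > 1L) {
    ord <- order(g$introns[, 1L], decreasing = (g$strand == "-"))
    g$introns <- g$introns[ord, , drop = FALSE]
  }
  validate_gene_model(g)
  g
}

validate_gene_model <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  if (!(g$strand %in% c("+", "-")))
    stop("gene ", g$gene_id, ": strand must be '+' or '-'", call. = FALSE)
  if (!(g$start >= 0 && g$start < g$end))
    stop("gene ", g$gene_id, ": invalid body interval [", g$start, ",",
         g$end, ")", call. = FALSE)
  if (nrow(g$introns) > 0L) {
    s <- g$introns[, 1L]; e <- g$introns[, 2L]
    if (any(s >= e))
      stop("gene ", g$gene_id, ": empty or inverted intron", call. = FALSE)
    if (any(s <= g$start) || any(e >= g$end))
      stop("gene ", g$gene_id, ": intron not strictly within body",
           call. = FALSE)
    gs <- sort(s)
    ge <- e[order(s)]
    if (nrow(g$introns) > 1L && any(gs[-1L] < ge[-length(ge)]))
      stop("gene ", g$gene_id, ": overlapping introns", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d intron(s)\n", x$gene_id,
              x$chrom, x$start, x$end, x$strand, nrow(x$introns)))
  invisible(x)
}

#' Does the gene contain at least one intron?
#' @param gene A `gene_model`.
#' @return Logical scalar.
#' @export
has_intron <- function(gene) nrow(gene$introns) > 0L

#' Genome annotation: a keyed collection of gene models
#'
#' @param genes List of [gene_model()] objects.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return An object of class `genome_annotation` with elements `genes`
#'   (named list) and `chrom_sizes`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a non-empty named vector", call. = FALSE)
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(genes) <- ids
  for (g in genes) {
    validate_gene_model(g)
    if (!(g$chrom %in% names(chrom_sizes)))
      stop("gene ", g$gene_id, ": unknown chromosome ", g$chrom,
           call. = FALSE)
    if (g$end > chrom_sizes[[g$chrom]])
      stop("gene ", g$gene_id, ": extends past end of ", g$chrom,
           call. = FALSE)
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  n_int <- sum(vapply(x$genes, has_intron, logical(1L)))
  cat(sprintf(paste0("<genome_annotation> %d genes (%d intron-containing) ",
                     "on %d chromosome(s)\n"),
              length(x$genes), n_int, length(x$chrom_sizes)))
  invisible(x)
}

#' @export
length.genome_annotation <- function(x) length(x$genes)

#' Read a chromosome-sizes table
#'
#' Two-column whitespace-separated table: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop("empty chromosome-sizes file: ", path,
                            call. = FALSE)
  stats::setNames(tab$length, tab$chrom)
}

#' Write a chromosome-sizes table
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes),
                                as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a gene annotation (GFF3 or BED12)
#'
#' Builds one [gene_model()] per transcript. GFF3 1-based closed
#' coordinates are converted to the internal 0-based half-open convention;
#' BED12 blocks become exons and the gaps between blocks become introns.
#' For GFF3 files carrying multiple transcripts per gene, the longest
#' transcript is kept. Records of type `gene` with no child transcripts are
#' imported as intron-less bodies.
#'
#' @param path Path to the annotation file, or a character vector of lines.
#' @param dialect `"gff3"` or `"bed12"`.
#' @param chrom_sizes Named numeric vector (see [read_chrom_sizes()]).
#' @return A [genome_annotation()].
#' @export
parse_gene_annotation <- function(path, dialect = c("gff3", "bed12"),
                                  chrom_sizes) {
  dialect <- match.arg(dialect)
  if (length(path) > 1L || !file.exists(path[1L])) {
    tmp <- tempfile(fileext = if (dialect == "gff3") ".gff3" else ".bed")
    writeLines(path, tmp)
    on.exit(unlink(tmp), add = TRUE)
    path <- tmp
  }
  prevalidate_annotation(path, dialect)
  genes <- switch(dialect,
                  bed12 = parse_bed12_models(path),
                  gff3  = parse_gff3_models(path))
  if (length(genes) == 0L)
    stop("no gene records found in ", path, call. = FALSE)
  genome_annotation(genes, chrom_sizes)
}

# Light structural scan so malformed lines are reported by number;
# content-level parsing is delegated to rtracklayer.
prevalidate_annotation <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") ||
        (dialect == "bed12" && grepl("^(track|browser)", ln))) next
    nf <- length(strsplit(ln, "\t|[ ]+")[[1L]])
    min_f <- if (dialect == "gff3") 9L else 12L
    if (nf < min_f)
      stop(sprintf("malformed %s line %d: expected >= %d fields, got %d",
                   dialect, i, min_f, nf), call. = FALSE)
  }
  invisible(TRUE)
}

parse_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  exons <- rtracklayer::blocks(gr)  # 1-based exon GRanges per record
  lapply(seq_along(gr), function(i) {
    ex <- exons[[i]]
    introns <- intron_gaps_from_exons(GenomicRanges::start(ex) - 1L,
                                      GenomicRanges::end(ex))
    gene_model(gene_id = gr$name[i],
               chrom = as.character(GenomicRanges::seqnames(gr)[i]),
               start = GenomicRanges::start(gr)[i] - 1L,
               end = GenomicRanges::end(gr)[i],
               strand = as.character(GenomicRanges::strand(gr)[i]),
               introns = introns)
  })
}

# exon coords 0-based half-open, genomic order; returns intron matrix
intron_gaps_from_exons <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  n <- length(starts)
  if (n < 2L) return(NULL)
  cbind(ends[-n], starts[-1L])
}

parse_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  tx_types <- c("mRNA", "transcript")
  is_tx <- type %in% tx_types
  if (!any(is_tx)) {
    # flat file: every `gene` record is an intron-less body
    gg <- gr[type == "gene"]
    ids <- gff3_record_id(gg)
    return(lapply(seq_along(gg), function(i)
      gene_model(ids[i], as.character(GenomicRanges::seqnames(gg)[i]),
                 GenomicRanges::start(gg)[i] - 1L,
                 GenomicRanges::end(gg)[i],
                 as.character(GenomicRanges::strand(gg)[i]))))
  }
  tx <- gr[is_tx]
  tx_id <- gff3_record_id(tx)
  tx_parent <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1L))
  gene_of_tx <- ifelse(is.na(tx_parent), tx_id, tx_parent)
  exn <- gr[type == "exon"]
  exn_parent <- vapply(as.list(exn$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1L))
  # longest transcript per gene
  w <- GenomicRanges::width(tx)
  keep <- vapply(split(seq_along(tx), gene_of_tx), function(ix)
    ix[which.max(w[ix])], integer(1L))
  lapply(names(keep), function(gid) {
    i <- keep[[gid]]
    ex <- exn[!is.na(exn_parent) & exn_parent == tx_id[i]]
    introns <- if (length(ex) >= 2L)
      intron_gaps_from_exons(GenomicRanges::start(ex) - 1L,
                             GenomicRanges::end(ex)) else NULL
    gene_model(gid, as.character(GenomicRanges::seqnames(tx)[i]),
               GenomicRanges::start(tx)[i] - 1L, GenomicRanges::end(tx)[i],
               as.character(GenomicRanges::strand(tx)[i]), introns)
  })
}

gff3_record_id <- function(gr) {
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  if (is.null(id)) stop("GFF3 records lack ID/Name attributes",
                        call. = FALSE)
  as.character(id)
}

#' Write an annotation as BED12
#'
#' Exons are the body minus the introns; one BED12 record per gene.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  lines <- vapply(annotation$genes, function(g) {
    intr <- g$introns[order(g$introns[, 1L]), , drop = FALSE]
    ex_start <- c(g$start, intr[, 2L])
    ex_end <- c(intr[, 1L], g$end)
    sizes <- ex_end - ex_start
    offs <- ex_start - g$start
    paste(g$chrom, format_bp(g$start), format_bp(g$end), g$gene_id, 0L,
          g$strand, format_bp(g$start), format_bp(g$end), 0L,
          length(sizes),
          paste0(paste(format_bp(sizes), collapse = ","), ","),
          paste0(paste(format_bp(offs), collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Transcribed region of a gene
#'
#' The TSS-to-PAS interval that the shape comparison operates on.
#'
#' @param gene A [gene_model()].
#' @return List with `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
transcribed_region <- function(gene) {
  list(chrom = gene$chrom, start = gene$start, end = gene$end,
       strand = gene$strand)
}

#' Intron anchor points for junction-aligned metaprofiles
#'
#' Returns the genomic positions of intron ends in transcript orientation:
#' for a plus-strand intron `[s, e)` the 5' end is `s` and the 3' end `e`;
#' on the minus strand the roles swap.
#'
#' @param gene A [gene_model()].
#' @param which `"five_prime_end"` or `"three_prime_end"`.
#' @param policy `"first_intron"` (the transcript's 5'-most intron only,
#'   the default) or `"all_introns"`.
#' @return Data frame with columns `chrom`, `position`, `strand`; zero rows
#'   for intron-less genes.
#' @export
intron_anchor_points <- function(gene,
                                 which = c("five_prime_end",
                                           "three_prime_end"),
                                 policy = c("first_intron", "all_introns")) {
  which <- match.arg(which)
  policy <- match.arg(policy)
  intr <- gene$introns  # already transcript-ordered
  if (nrow(intr) == 0L)
    return(data.frame(chrom = character(0), position = numeric(0),
                      strand = character(0)))
  if (policy == "first_intron") intr <- intr[1L, , drop = FALSE]
  pos <- if (gene$strand == "+") {
    if (which == "five_prime_end") intr[, 1L] else intr[, 2L]
  } else {
    if (which == "five_prime_end") intr[, 2L] else intr[, 1L]
  }
  data.frame(chrom = gene$chrom, position = as.numeric(pos),
             strand = gene$strand, row.names = NULL)
}
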