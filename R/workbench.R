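#' Run configuration for the pipeline commands
#'
#' Plain-text (YAML) configuration shared by the pipeline runners
#' ([run_simulate()], [run_shapediff()], [run_metaprofile()]). Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @name run_config
NULL

run_config_keys <- c(
  # inputs
  "reads_a", "reads_b", "reads_format", "annotation", "annotation_dialect",
  "chrom_sizes", "scores", "gene_sets",
  # stage parameters
  "bin_width", "spline_method", "spline_ends", "expansion", "min_bins",
  "coverage_mode", "min_mapq", "threshold",
  "anchor", "upstream", "downstream", "ci_level", "ci_method",
  "pseudocount", "log2_ratio", "top_n",
  # simulation
  "scenario", "seed", "n_genes", "depth", "intron_fraction",
  # output
  "out_dir", "log_level")

#' Read a run configuration file
#'
#' @param path YAML file of `key: value` pairs.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#' @param cfg A `run_config` (or plain named list).
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(as_run_config(cfg)), path)
  invisible(path)
}

cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

open_run_log <- function(out_dir, name, cfg, inputs = character(0)) {
  path <- file.path(out_dir, paste0(name, ".log"))
  con <- file(path, "w")
  stamp <- function(...) writeLines(paste0("[", name, "] ", ...), con)
  stamp("chromshape version ",
        as.character(utils::packageVersion("chromshape")))
  stamp("resolved config: ",
        paste(names(cfg), vapply(cfg, function(v)
          paste(format(v), collapse = ","), character(1L)),
          sep = "=", collapse = " "))
  for (f in inputs[file.exists(inputs)])
    stamp("input ", f, " md5=", unname(tools::md5sum(f)))
  list(con = con, stamp = stamp, path = path)
}

#' Generate a simulation scenario bundle on disk
#'
#' Builds the named scenario and writes its annotation (BED12),
#' chromosome sizes, transcription-rate scores, truth labels, and the
#' per-condition reads (BED6 and SAM) plus RPM coverage (bedGraph) to
#' `out_dir`. Byte-identical across runs with the same configuration.
#'
#' @param cfg A `run_config` (or named list / path to a YAML file) with at
#'   least `scenario`; honours `seed`, `n_genes`, `depth`,
#'   `intron_fraction`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [build_scenario()] bundle.
#' @export
run_simulate <- function(cfg, out_dir) {
  cfg <- resolve_cfg(cfg)
  if (is.null(cfg$scenario))
    stop("config key 'scenario' is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc_config <- sim_config(
    seed = as.integer(cfg_get(cfg, "seed", 1L)),
    n_genes = as.integer(cfg_get(cfg, "n_genes", 200L)),
    depth = as.numeric(cfg_get(cfg, "depth", 2e5)),
    intron_fraction = as.numeric(cfg_get(cfg, "intron_fraction", 0.3)))
  log <- open_run_log(out_dir, "simulate", cfg)
  on.exit(close(log$con))
  sc <- build_scenario(cfg$scenario, sc_config)
  write_annotation_bed12(sc$annotation,
                         file.path(out_dir, "annotation.bed12"))
  write_chrom_sizes(sc$annotation$chrom_sizes,
                    file.path(out_dir, "chrom.sizes"))
  write_tsv_hash(sc$scores, file.path(out_dir, "scores.tsv"))
  write_tsv_hash(sc$truth, file.path(out_dir, "truth.tsv"))
  for (cond in names(sc$reads)) {
    write_bed6(sc$reads[[cond]],
               file.path(out_dir, paste0("reads_", cond, ".bed")))
    write_sam(sc$reads[[cond]], sc$annotation$chrom_sizes,
              file.path(out_dir, paste0("reads_", cond, ".sam")))
    write_bedgraph(sc$tracks[[cond]],
                   file.path(out_dir, paste0("track_", cond,
                                             ".bedgraph")))
  }
  log$stamp("scenario '", sc$name, "': ", length(sc$annotation$genes),
            " genes, ", format(sc_config$depth, big.mark = ","),
            " reads/condition, conditions: ",
            paste(names(sc$reads), collapse = ", "))
  invisible(sc)
}

# header line starting '#', greppable TSV
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_hash <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  utils::read.table(path, sep = "\t", skip = 1L,
                    col.names = strsplit(hdr, "\t")[[1L]],
                    stringsAsFactors = FALSE)
}

#' Read a per-gene score table (gene_id, tr_score)
#' @param path TSV path, `#` header optional.
#' @return Data frame with `gene_id` and `tr_score`.
#' @export
read_gene_scores <- function(path) {
  first <- readLines(path, n = 1L)
  tab <- if (startsWith(first, "#")) read_tsv_hash(path)
         else utils::read.table(path, sep = "\t", header = FALSE,
                                col.names = c("gene_id", "tr_score"),
                                stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "tr_score") %in% names(tab)))
  tab[, c("gene_id", "tr_score")]
}

#' Read gene-set files (one gene id per line) into a named list
#' @param paths Named character vector of file paths; names become set
#'   names (file base names when unnamed).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  out <- lapply(paths, function(p) {
    ids <- readLines(p, warn = FALSE)
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    if (length(ids) == 0L)
      stop("empty gene-set file: ", p, call. = FALSE)
    ids
  })
  out
}

resolve_cfg <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_run_config(cfg)
  as_run_config(cfg)
}

load_annotation_cfg <- function(cfg) {
  for (k in c("annotation", "chrom_sizes"))
    if (is.null(cfg[[k]]))
      stop("config key '", k, "' is required", call. = FALSE)
  cs <- read_chrom_sizes(cfg$chrom_sizes)
  parse_gene_annotation(cfg$annotation,
                        dialect = cfg_get(cfg, "annotation_dialect",
                                          "bed12"),
                        chrom_sizes = cs)
}

load_track_cfg <- function(cfg, key, chrom_sizes) {
  path <- cfg[[key]]
  if (is.null(path)) stop("config key '", key, "' is required",
                          call. = FALSE)
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  reads <- read_alignments(path, cfg_get(cfg, "reads_format", "auto"))
  normalize_rpm(coverage_from_alignments(
    reads, chrom_sizes,
    mode = cfg_get(cfg, "coverage_mode", "span"),
    min_mapq = as.integer(cfg_get(cfg, "min_mapq", 0L))))
}

#' Run the genome-wide shape comparison end to end
#'
#' Reads two alignment files and an annotation, computes the per-gene
#' shape correlations, and writes the correlation table (TSV), a summary
#' JSON (per-set medians and threshold counts) and a provenance log to
#' `out_dir`. Deterministic: rerunning on the same inputs reproduces the
#' artifacts byte for byte.
#'
#' @param cfg `run_config`, named list, or YAML path. Required keys:
#'   `reads_a`, `reads_b`, `annotation`, `chrom_sizes`. Optional:
#'   `bin_width`, `spline_method`, `spline_ends`, `expansion`, `min_bins`,
#'   `coverage_mode`, `min_mapq`, `threshold`, `gene_sets`.
#' @param out_dir Output directory.
#' @return Invisibly, the [shape_diff()] fit.
#' @export
run_shapediff <- function(cfg, out_dir) {
  cfg <- resolve_cfg(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- open_run_log(out_dir, "shapediff", cfg,
                      inputs = unlist(cfg[c("reads_a", "reads_b",
                                            "annotation",
                                            "chrom_sizes")]))
  on.exit(close(log$con))
  ann <- load_annotation_cfg(cfg)
  track_a <- load_track_cfg(cfg, "reads_a", ann$chrom_sizes)
  track_b <- load_track_cfg(cfg, "reads_b", ann$chrom_sizes)
  fit <- shape_diff(track_a, track_b, ann,
                    bin_width = as.integer(cfg_get(cfg, "bin_width",
                                                   10L)),
                    method = cfg_get(cfg, "spline_method",
                                     "interpolating"),
                    expansion = as.integer(cfg_get(cfg, "expansion", 3L)),
                    ends = cfg_get(cfg, "spline_ends", "fmm"),
                    min_bins = as.integer(cfg_get(cfg, "min_bins", 4L)))
  skipped <- fit$table[fit$table$status != "ok", , drop = FALSE]
  for (i in seq_len(nrow(skipped)))
    log$stamp("gene ", skipped$gene_id[i], " skipped: ",
              skipped$status[i])
  sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets)
  s <- summary(fit, gene_sets = sets,
               threshold = as.numeric(cfg_get(cfg, "threshold", 0.6)))
  write_correlation_table(fit, file.path(out_dir, "correlations.tsv"))
  jsonlite::write_json(
    list(n_genes = nrow(fit$table),
         n_ok = sum(fit$table$status == "ok"),
         threshold = s$threshold,
         sets = s$summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  log$stamp("wrote correlations.tsv (", nrow(fit$table),
            " genes) and summary.json")
  invisible(fit)
}

#' Run an anchor-aligned metaprofile end to end
#'
#' Reads one alignment file and an annotation, builds the requested
#' anchor set (`tss`, `intron5` or `intron3`), optionally restricted to
#' gene sets, and writes one metaprofile TSV per set to `out_dir`.
#'
#' @param cfg `run_config`, named list, or YAML path. Required keys:
#'   `reads_a`, `annotation`, `chrom_sizes`. Optional: `anchor`,
#'   `upstream`, `downstream`, `ci_level`, `ci_method`, `gene_sets`.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of `metaprofile` objects.
#' @export
run_metaprofile <- function(cfg, out_dir) {
  cfg <- resolve_cfg(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- open_run_log(out_dir, "metaprofile", cfg,
                      inputs = unlist(cfg[c("reads_a", "annotation",
                                            "chrom_sizes")]))
  on.exit(close(log$con))
  ann <- load_annotation_cfg(cfg)
  track <- load_track_cfg(cfg, "reads_a", ann$chrom_sizes)
  anchor <- cfg_get(cfg, "anchor", "tss")
  defaults <- if (anchor == "tss") c(500L, 2000L) else c(500L, 500L)
  up <- as.integer(cfg_get(cfg, "upstream", defaults[1L]))
  down <- as.integer(cfg_get(cfg, "downstream", defaults[2L]))
  sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets)
          else list(all = names(ann$genes))
  anchors_of <- function(ids) {
    sub <- genome_annotation(ann$genes[intersect(ids,
                                                 names(ann$genes))],
                             ann$chrom_sizes)
    switch(anchor,
           tss = tss_anchors(sub),
           intron5 = intron_anchors(sub, "five_prime_end"),
           intron3 = intron_anchors(sub, "three_prime_end"),
           stop("unknown anchor '", anchor,
                "'; valid: tss, intron5, intron3", call. = FALSE))
  }
  out <- list()
  for (nm in names(sets)) {
    mp <- metaprofile(track, anchors_of(sets[[nm]]), up, down,
                      level = as.numeric(cfg_get(cfg, "ci_level", 0.95)),
                      method = cfg_get(cfg, "ci_method", "normal"))
    f <- file.path(out_dir, paste0("metaprofile_", nm, ".tsv"))
    write_metaprofile(mp, f)
    log$stamp("wrote ", f, " (", anchor, " anchor, window -", up, "..+",
              down - 1L, ")")
    out[[nm]] <- mp
  }
  invisible(out)
}
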