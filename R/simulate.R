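#' Configuration for the synthetic chromatin data generator
#'
#' Bundles every parameter of the generator: the gene layout, the
#' nucleosome-array geometry (NDR width, spacing, phasing decay), the
#' MNase fragment-size model (~147 bp mononucleosome fragments), the
#' sequencing depth, and the perturbation magnitudes used by the named
#' scenarios. Defaults emulate the statistical structure of budding-yeast
#' MNase-seq/ChIP-seq data: phased nucleosome arrays downstream of a
#' nucleosome-depleted region, polymerase density 5'-biased (Ser5-P-like)
#' or 3'-biased (Ser2-P-like), occupancy scaling with transcription rate,
#' and pausing at intron 3' ends.
#'
#' @param seed Integer seed; every generator output is byte-identical
#'   given the same seed and config.
#' @param n_genes Number of genes to place.
#' @param chrom Chromosome name of the synthetic genome.
#' @param chrom_length Length in bp, or `NULL` to size the chromosome to
#'   fit the genes.
#' @param gene_length_range Uniform range of gene (TSS-PAS) lengths, bp.
#' @param intron_fraction Probability a gene carries one intron, placed in
#'   the 5' half of the body.
#' @param intron_length_range Uniform range of intron lengths, bp (clamped
#'   so the intron fits the 5' half).
#' @param ndr_width Width of the promoter nucleosome-depleted region, bp.
#' @param nucleosome_spacing Dyad-to-dyad repeat length of the gene-body
#'   array, bp.
#' @param phasing_decay Per-nucleosome geometric factor in `(0, 1]`; peak
#'   standard deviation grows as `sd0 / phasing_decay^i`, so positioning
#'   blurs into the gene body.
#' @param fragment_length_mean,fragment_length_sd Normal fragment-length
#'   model, truncated to `[100, 250]` bp.
#' @param depth Sequenced reads per condition.
#' @param background_fraction Fraction of reads uniform over the
#'   chromosome (MNase/ChIP background).
#' @param gene_gap Minimum intergenic gap, bp.
#' @param flank Flanking region included in each gene's density support,
#'   bp.
#' @param tr_meanlog,tr_sdlog Log-normal transcription-rate score model.
#' @param disruption_severity Range of the body-disruption severity drawn
#'   for perturbed genes in the `chd1_like` scenario.
#' @param stall_severity Weight factor of the extra intron-3'-end stall
#'   component in the `ser5_shift` scenario mutant.
#' @param shift_bp Upstream (5'-ward) translation of the mutant Ser5-P
#'   density in the `ser5_shift` scenario, bp.
#' @param exchange_dip Fractional reduction of mutant Flag-H3 density at
#'   intron 3' ends in the `exchange` scenario.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, chrom = "chrSim",
                       chrom_length = NULL,
                       gene_length_range = c(600L, 2500L),
                       intron_fraction = 0.3,
                       intron_length_range = c(100L, 400L),
                       ndr_width = 140L, nucleosome_spacing = 165L,
                       phasing_decay = 0.9,
                       fragment_length_mean = 147, fragment_length_sd = 10,
                       depth = 2e5, background_fraction = 0.05,
                       gene_gap = 500L, flank = 300L,
                       tr_meanlog = 0, tr_sdlog = 1,
                       disruption_severity = c(0.6, 1.0),
                       stall_severity = 0.8, shift_bp = 100L,
                       exchange_dip = 0.6) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  with(cfg, {
    stopifnot(n_genes >= 1, gene_length_range[1L] >= 200,
              gene_length_range[1L] <= gene_length_range[2L],
              intron_fraction >= 0, intron_fraction <= 1,
              intron_length_range[1L] >= 20,
              ndr_width > 0, nucleosome_spacing > 0,
              phasing_decay > 0, phasing_decay <= 1,
              fragment_length_mean > 0, fragment_length_sd >= 0,
              nucleosome_spacing > fragment_length_sd,
              depth >= 0, background_fraction >= 0,
              background_fraction <= 1, gene_gap >= 0, flank >= 0,
              stall_severity >= 0, stall_severity <= 1,
              shift_bp >= 0, exchange_dip >= 0, exchange_dip <= 1,
              all(disruption_severity >= 0), all(disruption_severity <= 1))
  })
  cfg
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a gene annotation and transcription-rate scores
#'
#' Places `n_genes` non-overlapping genes with at least `gene_gap` bp
#' between them on alternating strands; each gene independently carries a
#' single intron (probability `intron_fraction`) located in the 5' half of
#' the body. Transcription-rate scores are drawn log-normally.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (a [genome_annotation()]) and `scores`
#'   (data frame `gene_id`, `tr_score`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    glr <- config$gene_length_range
    ilr <- config$intron_length_range
    lens <- sample(glr[1L]:glr[2L], n, replace = TRUE)
    gaps <- config$gene_gap + sample(0:200, n, replace = TRUE)
    starts <- config$flank + 300 + cumsum(c(0, lens[-n] + gaps[-n]))
    ends <- starts + lens
    needed <- ends[n] + config$flank + 300
    chrom_len <- config$chrom_length
    if (is.null(chrom_len)) {
      chrom_len <- needed
    } else if (chrom_len < needed) {
      stop("chrom_length ", format_bp(chrom_len), " too small to place ",
           n, " genes; need at least ", format_bp(needed), call. = FALSE)
    }
    strands <- rep(c("+", "-"), length.out = n)
    has_int <- stats::runif(n) < config$intron_fraction
    genes <- vector("list", n)
    for (i in seq_len(n)) {
      introns <- NULL
      if (has_int[i]) {
        max_len <- min(ilr[2L], floor(lens[i] / 2) - 60)
        ilen <- sample(min(ilr[1L], max_len):max_len, 1L)
        # transcript-coordinate start, within the 5' half
        t_max <- floor(lens[i] / 2) - ilen
        t0 <- sample(50:max(50L, t_max), 1L)
        introns <- if (strands[i] == "+")
          cbind(starts[i] + t0, starts[i] + t0 + ilen)
        else
          cbind(ends[i] - t0 - ilen, ends[i] - t0)
      }
      genes[[i]] <- gene_model(sprintf("g%04d", i), config$chrom,
                               starts[i], ends[i], strands[i], introns)
    }
    scores <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                         tr_score = stats::rlnorm(n, config$tr_meanlog,
                                                  config$tr_sdlog))
    ann <- genome_annotation(genes,
                             stats::setNames(chrom_len, config$chrom))
    list(annotation = ann, scores = scores)
  })
}

# ---- occupancy densities ------------------------------------------------

new_density <- function(chrom, start, values) {
  s <- sum(values)
  if (s <= 0) stop("degenerate density (zero total mass)", call. = FALSE)
  structure(list(chrom = chrom, start = start,
                 end = start + length(values), values = values / s),
            class = "occupancy_density")
}

#' @export
print.occupancy_density <- function(x, ...) {
  cat(sprintf("<occupancy_density> %s:%s-%s (%d bp, sums to 1)\n",
              x$chrom, format_bp(x$start), format_bp(x$end),
              x$end - x$start))
  invisible(x)
}

#' Perturbation applied to a synthetic occupancy density
#'
#' @param kind One of `"none"`, `"chd1_body_disruption"` (interpolate the
#'   +2-and-downstream nucleosome array toward uniform),
#'   `"ser5p_upstream_shift"` (translate the polymerase density 5'-ward),
#'   `"intron3_stall_release"` (add a stall component at the intron 3'
#'   end).
#' @param severity In `[0, 1]`.
#' @param shift_bp Translation in bp, for shift kinds.
#' @return List of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("none", "chd1_body_disruption",
                                       "ser5p_upstream_shift",
                                       "intron3_stall_release"),
                              severity = 0, shift_bp = 0L) {
  kind <- match.arg(kind)
  stopifnot(severity >= 0, severity <= 1, shift_bp >= 0)
  structure(list(kind = kind, severity = severity, shift_bp = shift_bp),
            class = "perturbation_spec")
}

# support of a gene's density + transcript coordinate of every base
gene_support <- function(gene, config, chrom_len) {
  s0 <- max(0, gene$start - config$flank)
  e0 <- min(chrom_len, gene$end + config$flank)
  gpos <- s0:(e0 - 1)
  tpos <- if (gene$strand == "+") gpos - gene$start
          else (gene$end - 1) - gpos
  list(s0 = s0, e0 = e0, tpos = tpos)
}

# transcript coordinate of the first intron's 3' end (junction), or NA
intron3_tpos <- function(gene) {
  ap <- intron_anchor_points(gene, "three_prime_end", "first_intron")
  if (nrow(ap) == 0L) return(NA_real_)
  if (gene$strand == "+") ap$position[1L] - gene$start
  else (gene$end - 1) - ap$position[1L]
}

as_perturbation_list <- function(perturbation) {
  if (is.null(perturbation)) return(list())
  if (inherits(perturbation, "perturbation_spec"))
    return(list(perturbation))
  stopifnot(all(vapply(perturbation, inherits, logical(1L),
                       "perturbation_spec")))
  perturbation
}

#' Synthetic nucleosome occupancy density for one gene
#'
#' A Gaussian-mixture dyad model: a -1 nucleosome upstream of the TSS, a
#' nucleosome-depleted region of `ndr_width`, then +1, +2, ... at
#' `nucleosome_spacing` intervals down to the PAS, with peak standard
#' deviation growing geometrically (`phasing_decay`) so positioning
#' blurs into the body. The `chd1_body_disruption` perturbation
#' interpolates the density from midway between +1 and +2 onward toward a
#' uniform density by its severity, leaving -1 and +1 untouched.
#'
#' @param gene A [gene_model()].
#' @param config A [sim_config()].
#' @param perturbation A [perturbation_spec()], a list of them, or `NULL`.
#' @param chrom_len Chromosome length (defaults to gene end + flank).
#' @return An `occupancy_density` (non-negative, sums to 1).
#' @export
nucleosome_density <- function(gene, config, perturbation = NULL,
                               chrom_len = gene$end + config$flank) {
  sup <- gene_support(gene, config, chrom_len)
  L <- gene$end - gene$start
  sd0 <- 20
  plus1 <- 75
  dyads <- seq(plus1, L - 40, by = config$nucleosome_spacing)
  sds <- sd0 / config$phasing_decay^(seq_along(dyads) - 1)
  dyads <- c(plus1 - (config$ndr_width + 147), dyads)  # prepend -1
  sds <- c(sd0, sds)
  d <- rowSums(vapply(seq_along(dyads), function(k)
    stats::dnorm(sup$tpos, dyads[k], sds[k]), numeric(length(sup$tpos))))
  for (p in as_perturbation_list(perturbation)) {
    if (p$kind == "chd1_body_disruption" && p$severity > 0) {
      region <- sup$tpos >= plus1 + config$nucleosome_spacing / 2 &
        sup$tpos < L
      mass <- sum(d[region])
      d[region] <- (1 - p$severity) * d[region] +
        p$severity * mass / sum(region)
    }
  }
  dens <- new_density(gene$chrom, sup$s0, d)
  dens
}

#' Synthetic RNA polymerase II occupancy density for one gene
#'
#' `ser5_like` concentrates density over the 5' half of the body
#' (exponential decay from the TSS), modelling early-elongation Ser5-P;
#' intron-containing genes additionally carry a pause component at the
#' intron 3' end, where the polymerase dwells at the junction.
#' `ser2_like` mirrors the decay toward the 3' end (late elongation).
#' Perturbations: `intron3_stall_release` adds a further stall component
#' of weight proportional to its severity at the intron 3' end (a no-op
#' on intron-less genes); `ser5p_upstream_shift` translates the final
#' density 5'-ward by `shift_bp`.
#'
#' @inheritParams nucleosome_density
#' @param mode `"ser5_like"` or `"ser2_like"`.
#' @return An `occupancy_density`.
#' @export
polymerase_density <- function(gene, mode = c("ser5_like", "ser2_like"),
                               config, perturbation = NULL,
                               chrom_len = gene$end + config$flank) {
  mode <- match.arg(mode)
  sup <- gene_support(gene, config, chrom_len)
  L <- gene$end - gene$start
  body <- sup$tpos >= 0 & sup$tpos < L
  base <- numeric(length(sup$tpos))
  base[body] <- if (mode == "ser5_like")
    exp(-3 * sup$tpos[body] / L) else exp(-3 * (L - 1 - sup$tpos[body]) / L)
  base <- base / sum(base)
  t3 <- intron3_tpos(gene)
  pause_sd <- 60
  w_extra <- 0
  extra <- numeric(length(sup$tpos))
  if (mode == "ser5_like" && !is.na(t3)) {
    # constitutive junction pause
    g <- stats::dnorm(sup$tpos, t3, pause_sd)
    extra <- extra + 0.25 * g / sum(g)
    w_extra <- w_extra + 0.25
  }
  shift <- 0
  for (p in as_perturbation_list(perturbation)) {
    if (p$kind == "intron3_stall_release" && !is.na(t3) &&
        p$severity > 0) {
      g <- stats::dnorm(sup$tpos, t3, pause_sd)
      w <- 0.35 * p$severity
      extra <- extra + w * g / sum(g)
      w_extra <- w_extra + w
    }
    if (p$kind == "ser5p_upstream_shift") shift <- shift + p$shift_bp
  }
  d <- (1 - w_extra) * base + extra
  if (shift > 0) {
    # 5'-ward translation; d is stored in genomic order, so on the minus
    # strand "toward the 5' end" means toward larger genomic coordinates
    n <- length(d)
    shift <- min(shift, n - 1L)
    d <- if (gene$strand == "+")
      c(d[(shift + 1):n], numeric(shift))
    else
      c(numeric(shift), d[1:(n - shift)])
  }
  new_density(gene$chrom, sup$s0, d)
}

#' Sample sequencing reads from an occupancy density
#'
#' Fragment midpoints are drawn i.i.d. from the density; fragment lengths
#' are Normal(`fragment_length_mean`, `fragment_length_sd`) truncated to
#' `[100, 250]` bp; reads are clipped to the chromosome. Deterministic
#' given `seed`; with `seed = NULL` the caller's RNG stream is used.
#'
#' @param density An `occupancy_density`.
#' @param n_reads Number of reads to draw.
#' @param config A [sim_config()] (fragment-length model).
#' @param seed Integer seed or `NULL`.
#' @param chrom_len Chromosome length for clipping.
#' @return Data frame `chrom`, `start`, `end`, `strand`, `mapq`.
#' @export
sample_reads <- function(density, n_reads, config, seed = NULL,
                         chrom_len = density$end) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mapq = integer(0))
  if (n_reads == 0L) return(empty)
  with_seed(seed, {
    w <- length(density$values)
    mids <- density$start +
      sample.int(w, n_reads, replace = TRUE, prob = density$values) - 1L
    len <- round(stats::rnorm(n_reads, config$fragment_length_mean,
                              config$fragment_length_sd))
    len <- pmin(pmax(len, 100), 250)
    start <- pmax(0, mids - floor(len / 2))
    end <- pmin(chrom_len, start + len)
    keep <- start < end
    data.frame(chrom = density$chrom, start = start, end = end,
               strand = sample(c("+", "-"), n_reads, replace = TRUE),
               mapq = 60L)[keep, , drop = FALSE]
  })
}

# uniform background density over the chromosome
background_density <- function(chrom, chrom_len) {
  new_density(chrom, 0, rep(1, chrom_len))
}

# one condition's reads: multinomial allocation over genes (+ background)
sample_condition <- function(densities, weights, config, chrom_len,
                             seed) {
  with_seed(seed, {
    n_bg <- stats::rbinom(1L, config$depth, config$background_fraction)
    n_sig <- config$depth - n_bg
    counts <- as.vector(stats::rmultinom(1L, n_sig,
                                         weights / sum(weights)))
    parts <- lapply(seq_along(densities), function(i)
      sample_reads(densities[[i]], counts[i], config,
                   chrom_len = chrom_len))
    bg <- sample_reads(background_density(densities[[1L]]$chrom,
                                          chrom_len),
                       n_bg, config, chrom_len = chrom_len)
    do.call(rbind, c(parts, list(bg)))
  })
}

condition_track <- function(reads, chrom_sizes, mode = "span") {
  normalize_rpm(coverage_from_alignments(reads, chrom_sizes, mode = mode))
}

#' Build a named simulation scenario
#'
#' Generates an annotation, condition-specific occupancy densities,
#' sampled reads, RPM coverage tracks and a truth table for one of the
#' study designs the pipeline is meant to resolve:
#'
#' * `"null"` — two independent samplings of identical (Ser5-P-like)
#'   densities; the no-change baseline.
#' * `"chd1_like"` — wild-type vs remodeler-mutant nucleosome tracks: a
#'   random half of genes have their gene-body array (+2 onward)
#'   disrupted with severity drawn from `disruption_severity`.
#' * `"ser5_shift"` — wild-type vs mutant Ser5-P tracks: only
#'   intron-containing genes acquire a strengthened stall at the intron
#'   3' end plus a 5'-ward shift; intron-less genes are untouched.
#' * `"exchange"` — Flag-H3/Myc-H3 track pairs for wild type and mutant;
#'   the mutant Flag density dips at intron 3' ends (reduced turnover).
#'
#' Tracks are RPM-normalized. The MNase-like `chd1_like` scenario builds
#' dyad-centred (midpoint-mode) coverage — the standard convention for
#' nucleosome-positioning analyses, since span coverage of ~147 bp
#' fragments over a 165 bp repeat nearly cancels the array periodicity —
#' while the ChIP-style scenarios use span coverage.
#'
#' @param name Scenario name.
#' @param config A [sim_config()].
#' @return List of class `sim_scenario` with `name`, `config`,
#'   `annotation`, `scores`, `truth` (data frame), `reads` (named list of
#'   read data frames) and `tracks` (named list of RPM
#'   [coverage_track()]s).
#' @export
build_scenario <- function(name = c("null", "chd1_like", "ser5_shift",
                                    "exchange"),
                           config = sim_config()) {
  if (!is.character(name) || !(name[1L] %in% c("null", "chd1_like",
                                               "ser5_shift", "exchange")))
    stop("unknown scenario '", name[1L],
         "'; valid: null, chd1_like, ser5_shift, exchange", call. = FALSE)
  name <- match.arg(name)
  sim <- simulate_annotation(config)
  ann <- sim$annotation
  genes <- ann$genes
  chrom_len <- ann$chrom_sizes[[1L]]
  tr <- stats::setNames(sim$scores$tr_score, sim$scores$gene_id)
  glen <- vapply(genes, function(g) g$end - g$start, numeric(1L))
  hi <- vapply(genes, has_intron, logical(1L))
  dens <- function(fun, perturb_of = function(g) NULL, ...)
    lapply(genes, function(g) fun(g, config = config,
                                  perturbation = perturb_of(g),
                                  chrom_len = chrom_len, ...))
  reads <- list()
  truth <- data.frame(gene_id = names(genes), has_intron = hi,
                      row.names = NULL)
  if (name == "null") {
    d <- dens(polymerase_density, mode = "ser5_like")
    reads$a <- sample_condition(d, tr[names(genes)], config, chrom_len,
                                config$seed + 11L)
    reads$b <- sample_condition(d, tr[names(genes)], config, chrom_len,
                                config$seed + 12L)
  } else if (name == "chd1_like") {
    sev <- with_seed(config$seed + 5L, {
      disrupted <- sample(names(genes), floor(length(genes) / 2))
      s <- stats::setNames(numeric(length(genes)), names(genes))
      s[disrupted] <- stats::runif(length(disrupted),
                                   config$disruption_severity[1L],
                                   config$disruption_severity[2L])
      s
    })
    d_wt <- dens(nucleosome_density)
    d_mut <- dens(nucleosome_density, perturb_of = function(g)
      perturbation_spec("chd1_body_disruption", sev[[g$gene_id]]))
    reads$wt <- sample_condition(d_wt, glen, config, chrom_len,
                                 config$seed + 21L)
    reads$mut <- sample_condition(d_mut, glen, config, chrom_len,
                                  config$seed + 22L)
    truth$disrupted <- sev[truth$gene_id] > 0
    truth$severity <- unname(sev[truth$gene_id])
  } else if (name == "ser5_shift") {
    d_wt <- dens(polymerase_density, mode = "ser5_like")
    d_mut <- dens(polymerase_density, mode = "ser5_like",
                  perturb_of = function(g) {
                    if (!has_intron(g)) return(NULL)
                    list(perturbation_spec("intron3_stall_release",
                                           config$stall_severity),
                         perturbation_spec("ser5p_upstream_shift",
                                           shift_bp = config$shift_bp))
                  })
    reads$wt <- sample_condition(d_wt, tr[names(genes)], config,
                                 chrom_len, config$seed + 31L)
    reads$mut <- sample_condition(d_mut, tr[names(genes)], config,
                                  chrom_len, config$seed + 32L)
    truth$perturbed <- hi
  } else {  # exchange
    flat_density <- function(g, config, perturbation = NULL, chrom_len) {
      sup <- gene_support(g, config, chrom_len)
      L <- g$end - g$start
      d <- as.numeric(sup$tpos >= 0 & sup$tpos < L)
      t3 <- intron3_tpos(g)
      for (p in as_perturbation_list(perturbation)) {
        if (p$kind == "intron3_stall_release" && !is.na(t3))
          d <- d * (1 - p$severity *
                      exp(-(sup$tpos - t3)^2 / (2 * 80^2)))
      }
      new_density(g$chrom, sup$s0, d)
    }
    d_myc <- dens(flat_density)
    d_flag_wt <- dens(flat_density)
    d_flag_mut <- dens(flat_density, perturb_of = function(g) {
      if (!has_intron(g)) return(NULL)
      perturbation_spec("intron3_stall_release", config$exchange_dip)
    })
    reads$flag_wt <- sample_condition(d_flag_wt, glen, config, chrom_len,
                                      config$seed + 41L)
    reads$myc_wt <- sample_condition(d_myc, glen, config, chrom_len,
                                     config$seed + 42L)
    reads$flag_mut <- sample_condition(d_flag_mut, glen, config,
                                       chrom_len, config$seed + 43L)
    reads$myc_mut <- sample_condition(d_myc, glen, config, chrom_len,
                                      config$seed + 44L)
  }
  # MNase-like scenarios use dyad-centred (midpoint) coverage, the
  # convention for nucleosome positioning: full-fragment span coverage of
  # ~147 bp fragments over a 165 bp repeat nearly cancels the array's
  # periodicity. ChIP-style (polymerase, tagged-H3) scenarios use span.
  track_mode <- if (name == "chd1_like") "midpoint" else "span"
  tracks <- lapply(reads, condition_track, chrom_sizes = ann$chrom_sizes,
                   mode = track_mode)
  structure(list(name = name, config = config, annotation = ann,
                 scores = sim$scores, truth = truth, reads = reads,
                 tracks = tracks),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("<sim_scenario> '%s': %d genes, %s reads/condition,",
                     " tracks: %s\n"),
              x$name, length(x$annotation$genes),
              format(x$config$depth, big.mark = ","),
              paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}

#' Write simulated reads as a minimal SAM file
#'
#' Unpaired, ungapped records (`<len>M` CIGAR, `*` sequence), suitable
#' for round-tripping through standard alignment readers.
#'
#' @param reads Read data frame (see [sample_reads()]).
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_sam <- function(reads, chrom_sizes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                     as.integer(chrom_sizes)), con)
  if (nrow(reads) > 0L)
    writeLines(paste(sprintf("r%06d", seq_len(nrow(reads))),
                     ifelse(reads$strand == "-", 16L, 0L),
                     reads$chrom, format_bp(reads$start + 1),
                     reads$mapq,
                     paste0(format_bp(reads$end - reads$start), "M"),
                     "*", 0L, 0L, "*", "*", sep = "\t"), con)
  invisible(path)
}

#' Write simulated reads as BED6
#' @inheritParams write_sam
#' @export
write_bed6 <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(paste(reads$chrom, format_bp(reads$start),
                   format_bp(reads$end),
                   sprintf("r%06d", seq_len(nrow(reads))), reads$mapq,
                   reads$strand, sep = "\t"), path)
  invisible(path)
}
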