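#' Pipeline configuration
#'
#' Collects every threshold the discovery pipeline applies. The defaults are
#' the study conditions: strand-bias (FS) above 30 or quality-by-depth (QD)
#' below 2 discards a site, 3 SNPs within a 35-base window form a cluster,
#' per-sample depth below 10 discards a site, differential expression requires
#' a linear fold change of at least 4 at FDR at most 0.001, and sequence-search
#' hits require an E-value below 1e-10. RAD tags carry a 96-bp core.
#'
#' @param fs_max maximum tolerated phred-scaled Fisher-strand score
#'   (sites with `fs > fs_max` are removed; the boundary is kept).
#' @param qd_min minimum tolerated quality-by-depth (sites with
#'   `qd < qd_min` are removed; the boundary is kept).
#' @param cluster_size number of SNPs that constitutes a cluster (>= 2).
#' @param cluster_window inclusive span, in bases, within which
#'   `cluster_size` consecutive SNPs count as a cluster.
#' @param min_depth minimum per-sample read depth; a site is removed when any
#'   sample is below this (the boundary is kept).
#' @param fc_cutoff linear fold-change cut-off for calling differential
#'   expression (inclusive).
#' @param fdr_cutoff Benjamini-Hochberg FDR cut-off for calling differential
#'   expression (inclusive).
#' @param evalue_max E-value threshold for sequence-search hits (strict `<`).
#' @param tag_core_length length, in bases, of the RAD-tag core.
#' @param min_agreement minimum per-column read agreement when extending a
#'   RAD-tag consensus beyond its core.
#' @param seed_length exact-match seed length for the ungapped search.
#' @param xdrop X-drop termination threshold for ungapped extension.
#' @param match,mismatch ungapped alignment scores (match positive,
#'   mismatch negative; the expected score per aligned pair must be negative).
#' @param mode segregation mode, `"strict"` or `"literal"` (see
#'   [is_consistent()]).
#' @param rng_seed integer seed for any stochastic step.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(fs_max = 30.0, qd_min = 2.0,
                            cluster_size = 3L, cluster_window = 35L,
                            min_depth = 10L,
                            fc_cutoff = 4, fdr_cutoff = 0.001,
                            evalue_max = 1e-10,
                            tag_core_length = 96L, min_agreement = 0.6,
                            seed_length = 16L, xdrop = 10,
                            match = 1, mismatch = -2,
                            mode = c("strict", "literal"),
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(fs_max = fs_max, qd_min = qd_min,
              cluster_size = as.integer(cluster_size),
              cluster_window = as.integer(cluster_window),
              min_depth = as.integer(min_depth),
              fc_cutoff = fc_cutoff, fdr_cutoff = fdr_cutoff,
              evalue_max = evalue_max,
              tag_core_length = as.integer(tag_core_length),
              min_agreement = min_agreement,
              seed_length = as.integer(seed_length), xdrop = xdrop,
              match = match, mismatch = mismatch,
              mode = mode, rng_seed = as.integer(rng_seed))
  for (nm in c("fs_max", "qd_min", "cluster_size", "cluster_window",
               "min_depth", "fc_cutoff", "fdr_cutoff", "evalue_max",
               "tag_core_length", "min_agreement", "xdrop", "match")) {
    if (!is_num1(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("config field '%s' must be a positive number", nm))
  }
  if (cfg$cluster_size < 2L) stop("cluster_size must be >= 2")
  if (cfg$mismatch >= 0) stop("mismatch score must be negative")
  if (cfg$min_agreement > 1) stop("min_agreement must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [pipeline_config()]; absent keys take
#' the defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Synthetic-study configuration
#'
#' Defines the conditions of the emulated study: 2 brown/unbanded and 2
#' yellow/banded individuals, each sampled in mantle and foot (8 libraries),
#' 2000 transcripts of 300-900 bases each carrying one open reading frame,
#' 50 transcripts planted as mantle-upregulated at 8-fold change, 20
#' transcripts carrying morph-consistent SNPs of which 10 are also planted
#' differentially expressed, negative-binomial count noise with dispersion
#' 0.1, and RAD-tag read stacks whose 96-base core is copied from a
#' transcript.
#'
#' @param n_transcripts number of transcripts in the reference.
#' @param len_min,len_max transcript length bounds (uniform draw).
#' @param n_brown,n_yellow numbers of brown/unbanded and yellow/banded
#'   individuals (each contributes a mantle and a foot sample).
#' @param n_planted_de transcripts planted as upregulated in the mantle.
#' @param n_consistent transcripts carrying planted morph-consistent SNPs
#'   (the supergene-linked block).
#' @param n_overlap how many of the `n_consistent` transcripts are also
#'   planted differentially expressed (the doubly-planted candidates).
#' @param snps_per_consistent planted consistent SNPs per such transcript,
#'   spaced to survive the cluster filter.
#' @param de_fold_change linear mantle/foot fold change of planted
#'   transcripts (must exceed the calling cut-off).
#' @param nb_dispersion negative-binomial dispersion phi (0 gives Poisson).
#' @param mean_expression median of the log-normal baseline mean counts.
#' @param mean_depth mean simulated per-sample variant depth (passing sites
#'   are resampled to stay at or above the depth filter).
#' @param background_snp_rate per-base probability of a morph-independent
#'   background SNP.
#' @param fail_fraction fraction of background sites planted to fail each of
#'   the FS, QD and DEPTH filters, and (in triples) the cluster filter.
#' @param lib_factor_range range of the uniform per-sample library-size
#'   factors (ratio across samples stays at or below 2).
#' @param n_radtags number of RAD-tag read stacks.
#' @param reads_per_stack reads per stack.
#' @param read_length stack read length (> tag core length).
#' @param error_rate per-base substitution error beyond the core.
#' @param rng_seed integer seed; every generator is deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L, len_min = 300L, len_max = 900L,
                       n_brown = 2L, n_yellow = 2L,
                       n_planted_de = 50L, n_consistent = 20L,
                       n_overlap = 10L, snps_per_consistent = 3L,
                       de_fold_change = 8, nb_dispersion = 0.1,
                       mean_expression = 200, mean_depth = 60,
                       background_snp_rate = 2e-4, fail_fraction = 0.05,
                       lib_factor_range = c(0.85, 1.3),
                       n_radtags = 11L, reads_per_stack = 8L,
                       read_length = 120L, error_rate = 0.01,
                       rng_seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              len_min = as.integer(len_min), len_max = as.integer(len_max),
              n_brown = as.integer(n_brown), n_yellow = as.integer(n_yellow),
              n_planted_de = as.integer(n_planted_de),
              n_consistent = as.integer(n_consistent),
              n_overlap = as.integer(n_overlap),
              snps_per_consistent = as.integer(snps_per_consistent),
              de_fold_change = de_fold_change,
              nb_dispersion = nb_dispersion,
              mean_expression = mean_expression, mean_depth = mean_depth,
              background_snp_rate = background_snp_rate,
              fail_fraction = fail_fraction,
              lib_factor_range = lib_factor_range,
              n_radtags = as.integer(n_radtags),
              reads_per_stack = as.integer(reads_per_stack),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_transcripts >= 0L, cfg$len_min > 0L,
            cfg$len_max >= cfg$len_min,
            cfg$n_brown >= 0L, cfg$n_yellow >= 0L,
            cfg$n_planted_de >= 0L, cfg$n_consistent >= 0L,
            cfg$n_overlap >= 0L,
            cfg$n_overlap <= min(cfg$n_planted_de, cfg$n_consistent),
            cfg$de_fold_change > 1,
            cfg$nb_dispersion >= 0,
            cfg$background_snp_rate >= 0, cfg$background_snp_rate < 1,
            cfg$fail_fraction >= 0, cfg$fail_fraction < 1,
            length(cfg$lib_factor_range) == 2L,
            all(cfg$lib_factor_range > 0),
            cfg$read_length > 0L, cfg$error_rate >= 0, cfg$error_rate < 1)
  structure(cfg, class = "sim_config")
}
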