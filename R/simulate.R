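# Synthetic-study generators. Each generator is deterministic given
# cfg$rng_seed; distinct small offsets decorrelate the draws of the four
# generators while keeping a single user-facing seed.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

transcript_ids <- function(n) if (n == 0L) character(0) else sprintf("t%05d", seq_len(n))

# deterministic choice of planted-DE and planted-consistent transcripts,
# shared by the genotype and count generators so their truths agree
select_planted <- function(cfg) {
  n <- cfg$n_transcripts
  ids <- transcript_ids(n)
  need <- cfg$n_planted_de + cfg$n_consistent - cfg$n_overlap
  if (need > n)
    stop("not enough transcripts for the requested planted sets")
  set.seed(cfg$rng_seed)
  perm <- sample.int(n)
  de <- ids[perm[seq_len(cfg$n_planted_de)]]
  extra <- cfg$n_consistent - cfg$n_overlap
  consistent <- c(ids[perm[seq_len(cfg$n_overlap)]],
                  if (extra > 0L)
                    ids[perm[cfg$n_planted_de + seq_len(extra)]])
  list(de = de, consistent = consistent)
}

#' Simulate a reference transcriptome with one ORF per transcript
#'
#' Transcript lengths are uniform on `[len_min, len_max]`. Each transcript
#' carries exactly one open reading frame covering about 60% of its length:
#' an ATG start, stop-free internal codons, and a terminal stop codon,
#' flanked by untranslated ends (whose SNVs later fall in the outside-ORF
#' class). Deterministic given `cfg$rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `sequences` (named character vector) and `orfs`
#'   (0-based half-open annotation `data.frame`).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_transcripts
  if (n == 0L)
    return(list(sequences = character(0),
                orfs = data.frame(transcript_id = character(0),
                                  orf_start = integer(0),
                                  orf_end = integer(0))))
  if (cfg$len_min < 15L)
    stop("transcript length bounds too small to host an ORF (need >= 15)")
  set.seed(cfg$rng_seed)
  sense <- setdiff(all_codons(), STOP_CODONS)
  lens <- sample(seq(cfg$len_min, cfg$len_max), n, replace = TRUE)
  seqs <- character(n)
  orf_start <- integer(n); orf_end <- integer(n)
  for (i in seq_len(n)) {
    len <- lens[i]
    n_codons <- max(3L, (floor(0.6 * len) %/% 3L))
    orf_nt <- 3L * n_codons
    utr5 <- sample.int(len - orf_nt + 1L, 1L) - 1L
    orf <- paste0("ATG",
                  paste(sample(sense, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    seqs[i] <- paste0(random_dna(utr5), orf,
                      random_dna(len - utr5 - orf_nt))
    orf_start[i] <- utr5
    orf_end[i] <- utr5 + orf_nt
  }
  names(seqs) <- transcript_ids(n)
  list(sequences = seqs,
       orfs = data.frame(transcript_id = names(seqs),
                         orf_start = orf_start, orf_end = orf_end))
}

# sample k positions in [lo, hi] pairwise at least min_gap apart
spaced_positions <- function(k, lo, hi, min_gap) {
  for (try in 1:200) {
    p <- sort(sample(seq(lo, hi), k))
    if (k < 2L || all(diff(p) >= min_gap)) return(p)
  }
  stop("could not place ", k, " positions with spacing ", min_gap)
}

#' Simulate genotypes at planted and background SNVs
#'
#' Plants morph-consistent SNPs on the supergene-linked transcript block:
#' yellow/banded individuals are homozygous for one allele and brown/unbanded
#' individuals each carry at least one copy of the other allele (brown
#' dominant, yellow recessive). Background SNPs get Hardy-Weinberg genotypes
#' drawn independently of morph. A `fail_fraction` of background sites is
#' planted to fail each hard-filter class: FS drawn above 30, QD below 2, one
#' sample's depth below 10, or triples of SNPs within a 35-base window.
#' Passing sites draw FS/QD/depth strictly on the passing side of every
#' threshold. The two tissue libraries of an individual share its genotype.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @return list with `variants` (a [variant_set()]), `samples` (sample
#'   sheet), and `truth` (per-SNP `data.frame`: planted filter class,
#'   planted consistency, yellow allele index, ORF placement; plus the
#'   planted-consistent transcript ids as attribute `consistent_transcripts`).
#' @export
simulate_genotypes <- function(cfg, reference) {
  stopifnot(inherits(cfg, "sim_config"))
  seqs <- reference$sequences
  n <- length(seqs)
  if (n == 0L && cfg$n_consistent > 0L)
    stop("zero transcripts but planted SNPs requested")
  pcfg <- pipeline_config()
  ids <- names(seqs)
  lens <- nchar(seqs)

  n_ind <- cfg$n_brown + cfg$n_yellow
  ind <- sprintf("ind%d", seq_len(n_ind))
  morph <- rep(MORPHS, c(cfg$n_brown, cfg$n_yellow))
  samples <- data.frame(
    sample_id = as.vector(t(outer(ind, TISSUES, paste, sep = "_"))),
    individual_id = rep(ind, each = 2L),
    tissue = rep(TISSUES, n_ind),
    morph = rep(morph, each = 2L))

  planted <- if (n > 0L) select_planted(cfg) else list(consistent = character(0))
  set.seed(cfg$rng_seed + 1L)

  tid <- character(0); pos <- integer(0)
  yellow_allele <- integer(0)  # NA for background sites
  gclass <- character(0)       # planted filter-failure class
  ind_gt <- NULL               # n_sites x n_ind genotype strings

  brown_idx <- which(morph == MORPHS[1L])
  yellow_idx <- which(morph == MORPHS[2L])

  plant_consistent_site <- function() {
    # yellow allele a: 0 = ref, 1 = alt
    a <- sample(0:1, 1L)
    g <- character(n_ind)
    g[yellow_idx] <- sprintf("%d/%d", a, a)
    b <- 1L - a
    g[brown_idx] <- ifelse(stats::runif(length(brown_idx)) < 0.5,
                           paste(min(a, b), max(a, b), sep = "/"),
                           sprintf("%d/%d", b, b))
    list(a = a, g = g)
  }

  hw_site <- function() {
    q <- stats::runif(1L, 0.15, 0.85)
    nalt <- stats::rbinom(n_ind, 2L, q)
    c("0/0", "0/1", "1/1")[nalt + 1L]
  }

  add_sites <- function(t_id, p, g, a, cl) {
    tid <<- c(tid, rep(t_id, length(p)))
    pos <<- c(pos, p)
    yellow_allele <<- c(yellow_allele, a)
    gclass <<- c(gclass, cl)
    ind_gt <<- rbind(ind_gt, g)
  }

  # planted consistent SNPs, spaced beyond the cluster window
  for (t_id in planted$consistent) {
    len <- lens[[t_id]]
    p <- spaced_positions(cfg$snps_per_consistent, 10L, len - 9L,
                          pcfg$cluster_window + 5L)
    for (pp in p) {
      s <- plant_consistent_site()
      add_sites(t_id, pp, matrix(s$g, 1L), s$a, "none")
    }
  }

  # background SNPs on non-supergene transcripts
  bg_ids <- setdiff(ids, planted$consistent)
  if (length(bg_ids) && cfg$background_snp_rate > 0) {
    n_bg <- stats::rbinom(length(bg_ids), lens[bg_ids],
                          cfg$background_snp_rate)
    for (k in which(n_bg > 0L)) {
      t_id <- bg_ids[k]
      p <- sort(sample.int(lens[[t_id]], n_bg[k]))
      for (pp in p) add_sites(t_id, pp, matrix(hw_site(), 1L), NA_integer_,
                              "none")
    }
  }

  # planted single-site filter failures among background sites
  is_bg <- is.na(yellow_allele)
  n_bgs <- sum(is_bg)
  if (n_bgs > 0L && cfg$fail_fraction > 0) {
    cl <- sample(c("none", "FS", "QD", "DEPTH"), n_bgs, replace = TRUE,
                 prob = c(1 - 3 * cfg$fail_fraction,
                          rep(cfg$fail_fraction, 3L)))
    gclass[is_bg] <- cl
  }

  # planted cluster triples (extra background-like sites within one window)
  if (cfg$fail_fraction > 0 && length(bg_ids)) {
    n_triples <- max(0L, round(cfg$fail_fraction * n_bgs / 3))
    big <- bg_ids[lens[bg_ids] >= 120L]
    for (i in seq_len(min(n_triples, length(big)))) {
      t_id <- sample(big, 1L)
      start <- sample.int(lens[[t_id]] - pcfg$cluster_window, 1L)
      offs <- sort(sample(seq_len(pcfg$cluster_window - 1L), 2L))
      p <- c(start, start + offs)
      p <- setdiff(p, pos[tid == t_id])
      if (length(p) < 3L) next
      for (pp in p) add_sites(t_id, pp, matrix(hw_site(), 1L), NA_integer_,
                              "CLUSTER")
    }
  }

  n_sites <- length(pos)
  if (n_sites == 0L) {
    gt <- matrix(character(0), 0L, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
    dp <- matrix(integer(0), 0L, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
    out <- variant_set(character(0), integer(0), character(0), character(0),
                       numeric(0), numeric(0), gt, dp)
    truth <- data.frame(transcript_id = character(0), pos = integer(0),
                        planted_class = character(0),
                        planted_consistent = logical(0),
                        yellow_allele = integer(0), in_orf = logical(0))
    attr(truth, "consistent_transcripts") <- character(0)
    return(list(variants = out, samples = samples, truth = truth))
  }

  ord <- order(tid, pos)
  tid <- tid[ord]; pos <- pos[ord]
  yellow_allele <- yellow_allele[ord]; gclass <- gclass[ord]
  ind_gt <- ind_gt[ord, , drop = FALSE]

  ref <- toupper(substring(seqs[tid], pos, pos))
  alt <- other_base(ref)

  # site annotations: passing draws sit strictly inside every threshold
  fs <- stats::runif(n_sites, 0, 20)
  qd <- stats::runif(n_sites, 2.5, 35)
  fs[gclass == "FS"] <- stats::runif(sum(gclass == "FS"),
                                     pcfg$fs_max + 1, pcfg$fs_max + 30)
  qd[gclass == "QD"] <- stats::runif(sum(gclass == "QD"), 0,
                                     pcfg$qd_min - 0.1)

  n_samp <- nrow(samples)
  dp <- matrix(stats::rpois(n_sites * n_samp, cfg$mean_depth),
               n_sites, n_samp)
  while (any(low <- dp < pcfg$min_depth))
    dp[low] <- stats::rpois(sum(low), cfg$mean_depth)
  for (i in which(gclass == "DEPTH"))
    dp[i, sample.int(n_samp, 1L)] <- sample.int(pcfg$min_depth, 1L) - 1L
  colnames(dp) <- samples$sample_id

  gt <- ind_gt[, match(samples$individual_id, ind), drop = FALSE]
  colnames(gt) <- samples$sample_id

  truth <- data.frame(transcript_id = tid, pos = pos,
                      planted_class = gclass,
                      planted_consistent = !is.na(yellow_allele),
                      yellow_allele = yellow_allele,
                      stringsAsFactors = FALSE)
  oi <- match(tid, reference$orfs$transcript_id)
  truth$in_orf <- (pos - 1L) >= reference$orfs$orf_start[oi] &
    (pos - 1L) < reference$orfs$orf_end[oi]
  attr(truth, "consistent_transcripts") <- planted$consistent

  list(variants = variant_set(tid, pos, ref, alt, fs, qd, gt, dp),
       samples = samples, truth = truth)
}

#' Simulate a transcript-by-sample count matrix
#'
#' Counts are negative binomial with common dispersion `nb_dispersion`
#' (Poisson when 0) around log-normally distributed baseline means scaled by
#' per-sample library factors (at most 2-fold apart). Planted transcripts
#' have a mantle mean `de_fold_change` times their foot mean.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param samples a sample sheet.
#' @return list with `counts` (integer matrix) and `truth` (planted-DE
#'   transcript ids).
#' @export
simulate_counts <- function(cfg, reference, samples) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- validate_samples(samples)
  if (cfg$nb_dispersion < 0) stop("dispersion must be >= 0")
  ids <- names(reference$sequences)
  n <- length(ids)
  planted <- if (n > 0L) select_planted(cfg)$de else character(0)
  set.seed(cfg$rng_seed + 2L)
  mu <- stats::rlnorm(n, log(cfg$mean_expression), 0.8)
  sj <- stats::runif(nrow(samples), cfg$lib_factor_range[1L],
                     cfg$lib_factor_range[2L])
  fc <- matrix(1, n, nrow(samples))
  fc[ids %in% planted, samples$tissue == "mantle"] <- cfg$de_fold_change
  mean_mat <- outer(mu, sj) * fc
  counts <- if (cfg$nb_dispersion > 0)
    stats::rnbinom(length(mean_mat), mu = mean_mat,
                   size = 1 / cfg$nb_dispersion)
  else stats::rpois(length(mean_mat), mean_mat)
  counts <- matrix(as.integer(counts), n, nrow(samples),
                   dimnames = list(ids, samples$sample_id))
  list(counts = counts, truth = planted)
}

#' Simulate RAD-tag read stacks
#'
#' Each stack copies a `core_length`-base core from a (possibly
#' reverse-complemented) transcript region, shared exactly by all reads;
#' beyond the core the reads continue along the transcript with per-base
#' substitution error `error_rate`.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param core_length RAD-tag core length in bases.
#' @return list with `stacks` (named list of read vectors) and `truth`
#'   (`data.frame`: tag, source transcript, 1-based start, strand).
#' @export
simulate_radtag_stacks <- function(cfg, reference, core_length = 96L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (core_length > cfg$read_length)
    stop("tag core length exceeds read length")
  seqs <- reference$sequences
  lens <- nchar(seqs)
  eligible <- names(seqs)[lens >= cfg$read_length]
  if (cfg$n_radtags > 0L && !length(eligible))
    stop("no transcript is long enough to source a read stack")
  set.seed(cfg$rng_seed + 3L)
  src <- sample(eligible, cfg$n_radtags,
                replace = cfg$n_radtags > length(eligible))
  stacks <- vector("list", cfg$n_radtags)
  truth <- data.frame(tag_id = sprintf("tag%02d", seq_len(cfg$n_radtags)),
                      transcript_id = src,
                      start = integer(cfg$n_radtags),
                      strand = character(cfg$n_radtags),
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_radtags)) {
    len <- lens[[src[i]]]
    start <- sample.int(len - cfg$read_length + 1L, 1L)
    strand <- sample(c("+", "-"), 1L)
    region <- substr(seqs[[src[i]]], start, start + cfg$read_length - 1L)
    if (strand == "-") region <- revcomp(region)
    chars <- strsplit(region, "", fixed = TRUE)[[1L]]
    reads <- character(cfg$reads_per_stack)
    tail_idx <- seq(core_length + 1L, cfg$read_length)
    for (r in seq_len(cfg$reads_per_stack)) {
      rc <- chars
      if (cfg$error_rate > 0 && length(tail_idx)) {
        err <- tail_idx[stats::runif(length(tail_idx)) < cfg$error_rate]
        if (length(err)) rc[err] <- other_base(rc[err])
      }
      reads[r] <- paste(rc, collapse = "")
    }
    stacks[[i]] <- reads
    truth$start[i] <- start
    truth$strand[i] <- strand
  }
  names(stacks) <- truth$tag_id
  list(stacks = stacks, truth = truth)
}

#' Simulate a complete study and write it to disk
#'
#' Runs all four generators under one seed and writes the reference FASTA,
#' ORF table, VCF, sample sheet, count matrix, RAD-tag stacks and the truth
#' tables into `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return list of file paths plus the in-memory objects and truth tables.
#' @export
simulate_study <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotypes(cfg, ref)
  cnt <- simulate_counts(cfg, ref, geno$samples)
  rad <- simulate_radtag_stacks(cfg, ref)
  paths <- list(fasta = file.path(out_dir, "reference.fa"),
                orfs = file.path(out_dir, "orfs.tsv"),
                vcf = file.path(out_dir, "variants.vcf"),
                samples = file.path(out_dir, "samples.tsv"),
                counts = file.path(out_dir, "counts.tsv"),
                stacks = file.path(out_dir, "stacks"))
  write_fasta(ref$sequences, paths$fasta)
  write_orfs(ref$orfs, paths$orfs)
  write_vcf(geno$variants, paths$vcf)
  write_samples(geno$samples, paths$samples)
  write_counts(cnt$counts, paths$counts)
  write_stacks(rad$stacks, paths$stacks)
  utils::write.table(geno$truth, file.path(out_dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(transcript_id = names(ref$sequences),
               planted_de = names(ref$sequences) %in% cnt$truth,
               planted_consistent = names(ref$sequences) %in%
                 attr(geno$truth, "consistent_transcripts")),
    file.path(out_dir, "truth_transcripts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rad$truth, file.path(out_dir, "truth_radtags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(paths,
    list(reference = ref, genotypes = geno, counts = cnt$counts,
         truth_snps = geno$truth,
         truth_de = cnt$truth,
         truth_consistent = attr(geno$truth, "consistent_transcripts"),
         truth_radtags = rad$truth))
}
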