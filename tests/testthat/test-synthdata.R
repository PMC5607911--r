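# the synthetic-study generators: determinism, construction invariants,
# and the statistical structure the downstream analysis assumes

test_that("reference simulation is deterministic and ORFs are well-formed", {
  cfg <- small_sim(seed = 11)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(ref1, ref2)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ref1$sequences, f1)
  write_fasta(ref2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  orfs <- ref1$orfs
  lens <- nchar(ref1$sequences)
  expect_true(all(orfs$orf_start >= 0L))
  expect_true(all(orfs$orf_end <= lens))
  expect_true(all((orfs$orf_end - orfs$orf_start) %% 3L == 0L))
  for (i in sample(length(lens), 20)) {
    s <- ref1$sequences[[i]]
    a <- orfs$orf_start[i]; b <- orfs$orf_end[i]
    orf <- substr(s, a + 1L, b)
    codons <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("degenerate reference configs are handled", {
  empty <- simulate_reference(
    sim_config(n_transcripts = 0L, n_planted_de = 0L, n_consistent = 0L,
               n_overlap = 0L))
  expect_length(empty$sequences, 0L)
  expect_equal(nrow(empty$orfs), 0L)
  expect_error(simulate_reference(small_sim(len_min = 10L, len_max = 12L)),
               "too small to host an ORF")
})

test_that("with no background and no failures every SNP is planted-consistent", {
  cfg <- small_sim(seed = 3, background_snp_rate = 0, fail_fraction = 0)
  ref <- simulate_reference(cfg)
  g <- simulate_genotypes(cfg, ref)
  expect_gt(n_variants(g$variants), 0L)
  expect_true(all(g$truth$planted_consistent))
  expect_true(all(g$truth$planted_class == "none"))
  expect_setequal(unique(g$truth$transcript_id),
                  attr(g$truth, "consistent_transcripts"))
})

test_that("planted filter failures sit on the failing side of each threshold", {
  cfg <- small_sim(seed = 5, background_snp_rate = 2e-3, fail_fraction = 0.15)
  ref <- simulate_reference(cfg)
  g <- simulate_genotypes(cfg, ref)
  tr <- g$truth
  expect_true(all(c("FS", "QD", "DEPTH", "CLUSTER") %in% tr$planted_class))
  expect_true(all(g$variants$site$fs[tr$planted_class == "FS"] > 30.0))
  expect_true(all(g$variants$site$qd[tr$planted_class == "QD"] < 2.0))
  dmin <- apply(g$variants$dp, 1L, min)
  expect_true(all(dmin[tr$planted_class == "DEPTH"] < 10L))
  expect_true(all(dmin[tr$planted_class != "DEPTH"] >= 10L))
  # each planted cluster triple spans at most the window
  cl <- tr[tr$planted_class == "CLUSTER", ]
  for (t_id in unique(cl$transcript_id)) {
    p <- sort(cl$pos[cl$transcript_id == t_id])
    expect_true(any(diff(p, lag = 2) + 1L <= 35L))
  }
  # genotype draws are deterministic under the seed
  g2 <- simulate_genotypes(cfg, ref)
  expect_identical(g$variants, g2$variants)
})

test_that("background genotypes are independent of morph across seeds", {
  # chi-square test of morph x genotype at background SNPs, pooled per seed
  n_ns <- 0L
  n_seeds <- 100L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(n_transcripts = 40L, n_planted_de = 0L,
                      n_consistent = 0L, n_overlap = 0L,
                      background_snp_rate = 5e-3, fail_fraction = 0,
                      rng_seed = seed)
    ref <- simulate_reference(cfg)
    g <- simulate_genotypes(cfg, ref)
    sheet <- g$samples
    one <- !duplicated(sheet$individual_id)
    gt <- g$variants$gt[, sheet$sample_id[one], drop = FALSE]
    morph <- rep(sheet$morph[one], each = nrow(gt))
    tab <- table(morph, as.vector(gt))
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (is.na(p) || p > 0.01) n_ns <- n_ns + 1L
  }
  expect_gte(n_ns, 0.95 * n_seeds)
})

test_that("count simulation recovers the planted fold change and is deterministic", {
  sheet <- make_sheet()
  cfg <- sim_config(n_transcripts = 60L, n_planted_de = 10L,
                    n_consistent = 0L, n_overlap = 0L,
                    nb_dispersion = 0, de_fold_change = 4,
                    mean_expression = 1000, lib_factor_range = c(1, 1),
                    rng_seed = 9)
  ref <- simulate_reference(cfg)
  cnt <- simulate_counts(cfg, ref, sheet)
  expect_length(cnt$truth, 10L)
  mantle <- sheet$sample_id[sheet$tissue == "mantle"]
  foot <- sheet$sample_id[sheet$tissue == "foot"]
  for (t_id in cnt$truth) {
    ratio <- mean(cnt$counts[t_id, mantle]) / mean(cnt$counts[t_id, foot])
    expect_equal(ratio, 4, tolerance = 0.1)
  }
  expect_identical(cnt$counts, simulate_counts(cfg, ref, sheet)$counts)

  none <- simulate_counts(
    sim_config(n_transcripts = 60L, n_planted_de = 0L, n_consistent = 0L,
               n_overlap = 0L, rng_seed = 9), ref, sheet)
  expect_length(none$truth, 0L)
})

test_that("library sizes vary at most two-fold across samples", {
  # at the default study conditions, including the planted-DE contribution
  cfg <- sim_config(rng_seed = 13)
  ref <- simulate_reference(cfg)
  cnt <- simulate_counts(cfg, ref, make_sheet())
  ls <- colSums(cnt$counts)
  expect_lte(max(ls) / min(ls), 2)
})

test_that("RAD-tag stacks share an exact core traceable to the source", {
  cfg <- small_sim(seed = 21, error_rate = 0)
  ref <- simulate_reference(cfg)
  rad <- simulate_radtag_stacks(cfg, ref)
  expect_length(rad$stacks, cfg$n_radtags)
  for (i in seq_along(rad$stacks)) {
    reads <- rad$stacks[[i]]
    # error-free: all reads identical
    expect_length(unique(reads), 1L)
    core <- substr(reads[1], 1, 96)
    src <- ref$sequences[[rad$truth$transcript_id[i]]]
    found <- grepl(core, src, fixed = TRUE) ||
      grepl(core, revcomp(src), fixed = TRUE)
    expect_true(found)
  }
  expect_identical(rad$stacks, simulate_radtag_stacks(cfg, ref)$stacks)

  # with errors the core is still exact, only the tails differ
  cfg2 <- small_sim(seed = 21, error_rate = 0.2)
  rad2 <- simulate_radtag_stacks(cfg2, ref)
  for (reads in rad2$stacks)
    expect_length(unique(substr(reads, 1, 96)), 1L)
  expect_error(simulate_radtag_stacks(small_sim(read_length = 50L), ref),
               "core length exceeds read length")
})

test_that("truth tables keep planted-consistent SNPs inside the planted block", {
  for (seed in c(2, 4, 6)) {
    cfg <- small_sim(seed = seed, background_snp_rate = 1e-3,
                     fail_fraction = 0.1)
    ref <- simulate_reference(cfg)
    g <- simulate_genotypes(cfg, ref)
    block <- attr(g$truth, "consistent_transcripts")
    expect_true(all(
      g$truth$transcript_id[g$truth$planted_consistent] %in% block))
    # the in-ORF flag matches the ORF annotation
    oi <- match(g$truth$transcript_id, ref$orfs$transcript_id)
    expect_identical(g$truth$in_orf,
                     (g$truth$pos - 1L) >= ref$orfs$orf_start[oi] &
                       (g$truth$pos - 1L) < ref$orfs$orf_end[oi])
  }
})
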