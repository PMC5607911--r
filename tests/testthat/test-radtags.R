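# RAD-tag consensus extension, Karlin-Altschul statistics, and the ungapped
# seed-and-extend search

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("consensus extension follows majority, coverage and tie rules", {
  reads <- rep(paste(rep("ACGT", 30), collapse = ""), 3)  # 120 bp
  tag <- build_consensus(reads, "t", core_length = 96L)
  expect_equal(tag$consensus, reads[1])
  expect_equal(tag$core, substr(reads[1], 1, 96))
  expect_true(all(tag$support == 1))
  expect_true(startsWith(tag$consensus, tag$core))

  # column {A, A, C} beyond the core: majority A at agreement 2/3 >= 0.6
  base <- rand_seq(96)
  reads <- c(paste0(base, "A"), paste0(base, "A"), paste0(base, "C"))
  tag <- build_consensus(reads, "t", min_agreement = 0.6)
  expect_equal(nchar(tag$consensus), 97L)
  expect_equal(substr(tag$consensus, 97, 97), "A")
  expect_equal(tag$support[97], 2 / 3)

  # tie {A, C} truncates before the column
  reads <- c(paste0(base, "A"), paste0(base, "C"))
  tag <- build_consensus(reads, "t")
  expect_equal(tag$consensus, base)

  # coverage below 2 truncates
  reads <- c(paste0(base, "AAAA"), base)
  tag <- build_consensus(reads, "t")
  expect_equal(tag$consensus, base)

  expect_error(build_consensus(character(0)), "empty")
  expect_error(build_consensus(substr(base, 1, 50)), "shorter than")
})

test_that("Karlin-Altschul lambda solves the root equation", {
  ka <- karlin_altschul_params(1, -2)
  resid <- 0.25 * exp(ka$lambda) + 0.75 * exp(-2 * ka$lambda) - 1
  expect_lt(abs(resid), 1e-9)

  # independent bisection oracle
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 0.5; hi <- 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(ka$lambda, (lo + hi) / 2, tolerance = 1e-8)

  # doubling all scores halves lambda exactly
  ka2 <- karlin_altschul_params(2, -4)
  expect_equal(ka2$lambda, ka$lambda / 2, tolerance = 1e-9)

  expect_error(karlin_altschul_params(3, -1), "negative expected")
})

test_that("Karlin-Altschul K and H match published ungapped statistics", {
  # reference values printed by NCBI blastn for these schemes
  ka <- karlin_altschul_params(1, -2)
  expect_equal(ka$lambda, 1.33, tolerance = 0.005)
  expect_equal(ka$K, 0.621, tolerance = 0.005)
  expect_equal(ka$H, 1.12, tolerance = 0.005)
  ka3 <- karlin_altschul_params(1, -3)
  expect_equal(ka3$K, 0.711, tolerance = 0.005)
})

test_that("an exact planted substring is found with full score on both strands", {
  set.seed(31)
  tx <- c(t1 = rand_seq(3000), t2 = rand_seq(2500))
  tag <- substr(tx[["t1"]], 1001, 1100)         # exact 100-mer
  hits <- search_tags(c(q1 = tag), tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$transcript_id, "t1")
  expect_equal(hits$score, 100)
  expect_equal(hits$strand, "+")
  expect_lt(hits$evalue, 1e-10)
  expect_equal(hits$s_start, 1000L)             # 0-based
  expect_equal(hits$s_end, 1100L)
  expect_equal(hits$q_end - hits$q_start, hits$s_end - hits$s_start)

  rc <- search_tags(c(q1 = revcomp(tag)), tx)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$score, 100)
  expect_equal(rc$s_start, 1000L)
})

# brute-force best ungapped local alignment score over all diagonals
bf_best_score <- function(q, s, match = 1, mis = -2) {
  qv <- utf8ToInt(q); sv <- utf8ToInt(s)
  best <- 0
  for (d in (1 - length(qv)):(length(sv) - 1)) {
    i0 <- max(1L, 1L - d); i1 <- min(length(qv), length(sv) - d)
    if (i0 > i1) next
    sc <- ifelse(qv[i0:i1] == sv[(i0:i1) + d], match, mis)
    run <- 0
    for (x in sc) {
      run <- max(0, run + x)
      best <- max(best, run)
    }
  }
  best
}

test_that("reported scores equal the brute-force optimum on small instances", {
  set.seed(41)
  for (i in 1:8) {
    tag <- rand_seq(120)
    # subject: random flanks around a copy with widely spaced mutations
    copy <- strsplit(tag, "")[[1]]
    mut <- seq(20, 110, by = sample(25:35, 1))
    copy[mut] <- vapply(copy[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    subj <- paste0(rand_seq(300), paste(copy, collapse = ""), rand_seq(300))
    hits <- search_tags(c(q = tag), c(s1 = subj))
    expect_gte(nrow(hits), 1L)
    expect_equal(max(hits$score), bf_best_score(tag, subj),
                 info = paste("case", i))
  }
})

test_that("random tags yield no hits below the E-value threshold", {
  set.seed(51)
  for (i in 1:20) {
    tx <- stats::setNames(vapply(1:10, function(j) rand_seq(5000), ""),
                          paste0("t", 1:10))
    hits <- search_tags(c(q = rand_seq(96)), tx)
    expect_equal(nrow(hits), 0L, info = paste("seed", i))
  }
})

test_that("error-free synthetic stacks map back to their source transcripts", {
  cfg <- small_sim(seed = 61, error_rate = 0)
  ref <- simulate_reference(cfg)
  rad <- simulate_radtag_stacks(cfg, ref)
  tags <- build_consensus_tags(rad$stacks)
  # error-free stacks: consensus equals the full read
  for (nm in names(tags))
    expect_equal(tags[[nm]]$consensus, rad$stacks[[nm]][1])
  hits <- search_tags(tags, ref$sequences)
  for (i in seq_len(nrow(rad$truth))) {
    h <- hits[hits$tag_id == rad$truth$tag_id[i], ]
    expect_gte(nrow(h), 1L)
    best <- h[which.min(h$evalue), ]
    expect_equal(best$transcript_id, rad$truth$transcript_id[i])
    expect_equal(best$score, cfg$read_length)
    expect_equal(best$strand, rad$truth$strand[i])
  }
})

test_that("strand symmetry: reverse-complementing the subject flips the hit", {
  set.seed(71)
  tx <- c(t1 = rand_seq(2000))
  tag <- substr(tx[["t1"]], 501, 620)
  fwd <- search_tags(c(q = tag), tx)
  rev <- search_tags(c(q = tag), c(t1 = revcomp(tx[["t1"]])))
  expect_equal(fwd$score, rev$score)
  expect_equal(fwd$evalue, rev$evalue, tolerance = 1e-12)
  expect_setequal(c(fwd$strand, rev$strand), c("+", "-"))
})
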