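# differential-expression stage: TMM, dispersion, exact test, BH, calls,
# sample clustering

test_that("TMM factors satisfy their symmetry and normalisation contracts", {
  set.seed(2)
  m <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]; m[, 4] <- m[, 1]
  expect_equal(unname(tmm_factors(m)), rep(1, 4))

  # a pure depth difference is absorbed by library size, not factors
  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  expect_equal(unname(tmm_factors(m2)), c(1, 1))

  set.seed(3)
  m3 <- matrix(rnbinom(2000 * 6, mu = 50, size = 5), 2000, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  f <- tmm_factors(m3)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
  expect_error(tmm_factors(cbind(a = c(0L, 0L), b = c(1L, 2L))), "all-zero")
  expect_error(tmm_factors(matrix(1:4, 4, 1)), "two samples")
})

test_that("TMM factors match the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  for (i in 1:3) {
    m <- matrix(rnbinom(1500 * 8, mu = exp(rnorm(1500 * 8, log(80), 1)),
                        size = 8), 1500, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    # perturb one sample's composition
    m[1:50, 1] <- m[1:50, 1] * 20L
    want <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(tmm_factors(m)), unname(want), tolerance = 1e-6)
  }
})

test_that("common dispersion is recovered from simulated truth", {
  groups <- rep(c("a", "b"), each = 4)
  set.seed(11)
  # Poisson counts: estimate collapses to (near) zero
  m <- matrix(rpois(200 * 8, 100), 200, 8)
  expect_lte(estimate_common_dispersion(m, groups), 0.02)

  # NB truth phi = 0.2, most seeds land in [0.15, 0.25]
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    mu <- exp(rnorm(2000, log(150), 0.7))
    m <- matrix(rnbinom(2000 * 8, mu = mu, size = 5), 2000, 8)
    phi <- estimate_common_dispersion(m, groups)
    if (phi >= 0.15 && phi <= 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 50)

  # all counts equal: boundary estimate exactly zero
  expect_identical(
    estimate_common_dispersion(matrix(7L, 1, 4), rep(c("a", "b"), 2)), 0)
  expect_error(estimate_common_dispersion(matrix(1:8, 2, 4), c(1, 1, 1, 2)),
               "at least 2 samples")
})

test_that("the exact test honours its degenerate and symmetric cases", {
  # observed split at the conditional mode has p = 1
  expect_equal(nb_exact_test(10, 10, 4, 4, 0), 1)
  expect_equal(nb_exact_test(10, 10, 4, 4, 0.3), 1)
  # zero total
  expect_equal(nb_exact_test(0, 0, 4, 4, 0.1), 1)
  # symmetry when group sizes are equal
  for (phi in c(0, 0.2)) {
    expect_equal(nb_exact_test(3, 9, 4, 4, phi),
                 nb_exact_test(9, 3, 4, 4, phi))
  }
  expect_error(nb_exact_test(3, 9, phi = -1), ">= 0")
  expect_error(nb_exact_test(-1, 9), "non-negative")
})

test_that("at phi = 0 the exact test is the binomial conditional test", {
  # the worked split: 3 vs 9 of total 12, equal sizes
  expect_equal(nb_exact_test(3, 9, 4, 4, 0), 598 / 4096)
  # random spot-checks against direct binomial enumeration
  set.seed(21)
  for (i in 1:20) {
    t <- sample(1:40, 1); a <- sample(0:t, 1)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    pr <- dbinom(0:t, t, n1 / (n1 + n2))
    want <- sum(pr[pr <= pr[a + 1] * (1 + 1e-10)])
    expect_equal(nb_exact_test(a, t - a, n1, n2, 0), want,
                 tolerance = 1e-12)
  }
})

test_that("large totals fall back to a calibrated normal approximation", {
  p_exact <- nb_exact_test(49000, 51000, 4, 4, 0)   # just under the cap
  p_norm <- shellcand:::nb_exact_p1(490000, 510000, 4, 4, 0)
  expect_lt(p_norm, 0.01)
  expect_gt(p_exact, 1e-12)
  # approximate agreement near the cap for a moderate deviation
  a <- 50500; b <- 49500
  lo <- nb_exact_test(a, b, 4, 4, 0)
  hi <- shellcand:::nb_exact_p1(a * 2, b * 2 - (a - b), 4, 4, 0)
  expect_true(is.finite(lo) && is.finite(hi))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order-preservation and the explicit step-up minimum
  p <- c(0.03, 0.002, 0.4, 0.012)
  n <- length(p); o <- order(p)
  stepup <- numeric(n)
  stepup[o] <- rev(cummin(rev(sort(p) * n / seq_len(n))))
  expect_equal(bh_adjust(p), pmin(stepup, 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DE calls apply both cut-offs inclusively", {
  cfg <- pipeline_config()
  expect_equal(call_de(2.5, 5e-4, cfg), "up_in_mantle")
  expect_equal(call_de(2.5, 0.002, cfg), "ns")
  expect_equal(call_de(1.9, 1e-6, cfg), "ns")
  expect_equal(call_de(-2.2, 1e-6, cfg), "down_in_mantle")
  expect_equal(call_de(2, 0.001, cfg), "up_in_mantle")  # both boundaries
})

test_that("dge_analysis finds planted fold changes and nothing else", {
  sheet <- make_sheet()
  cfg <- small_sim(seed = 51, n_planted_de = 8L)
  ref <- simulate_reference(cfg)
  cnt <- simulate_counts(cfg, ref, sheet)
  res <- dge_analysis(cnt$counts, sheet)
  up <- res$transcript_id[res$call == "up_in_mantle"]
  expect_gte(length(intersect(up, cnt$truth)), 7L)
  expect_lte(length(setdiff(up, cnt$truth)), 1L)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # calls imply the thresholds
  called <- res$call != "ns"
  expect_true(all(res$fdr[called] <= 0.001))
  expect_true(all(abs(res$log2_fc[called]) >= 2))
})

test_that("sample clustering separates planted expression blocks", {
  # two identical samples merge at height 0
  set.seed(61)
  base <- rpois(300, 50)
  m <- cbind(s1 = base, s2 = base, s3 = rpois(300, 50))
  h <- cluster_samples(m)
  expect_equal(min(h$height), 0)

  # two orthogonal blocks: the top split recovers them
  blockA <- c(200L, 5L); blockB <- c(5L, 200L)
  toy <- cbind(a1 = rep(blockA, each = 3), a2 = rep(blockA, each = 3) + 1L,
               b1 = rep(blockB, each = 3), b2 = rep(blockB, each = 3) + 1L)
  sp <- top_split(cluster_samples(toy))
  expect_setequal(vapply(sp, paste, "", collapse = ","),
                  c("a1,a2", "b1,b2"))

  expect_error(cluster_samples(cbind(s1 = rep(5L, 10), s2 = 1:10)),
               "constant sample")
})

test_that("dendrograms export as Newick", {
  set.seed(71)
  m <- matrix(rpois(400, 30), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cluster_samples(m), f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, paste0("s", 1:4))
})
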