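# fixtures shared across test files; everything is built in code

# standard 4-individual (2 brown, 2 yellow), 2-tissue sample sheet
make_sheet <- function(n_brown = 2L, n_yellow = 2L) {
  n_ind <- n_brown + n_yellow
  ind <- sprintf("ind%d", seq_len(n_ind))
  morph <- rep(c("brown_unbanded", "yellow_banded"), c(n_brown, n_yellow))
  data.frame(
    sample_id = as.vector(t(outer(ind, c("mantle", "foot"), paste,
                                  sep = "_"))),
    individual_id = rep(ind, each = 2L),
    tissue = rep(c("mantle", "foot"), n_ind),
    morph = rep(morph, each = 2L))
}

# one-site variant set from per-individual genotypes (both tissues agree)
make_site <- function(ind_gt, sheet = make_sheet(),
                      fs = 3, qd = 8, dp = 30L,
                      transcript_id = "t1", pos = 5L,
                      ref = "A", alt = "G") {
  inds <- unique(sheet$individual_id)
  stopifnot(length(ind_gt) == length(inds))
  gt <- matrix(ind_gt[match(sheet$individual_id, inds)], nrow = 1L,
               dimnames = list(NULL, sheet$sample_id))
  dpm <- matrix(dp, 1L, nrow(sheet),
                dimnames = list(NULL, sheet$sample_id))
  variant_set(transcript_id, pos, ref, alt, fs, qd, gt, dpm)
}

# a small multi-site variant set with uniform genotypes, for filter tests
make_sites <- function(transcript_id, pos, fs = NULL, qd = NULL,
                       dp_min = 30L, sheet = make_sheet()) {
  n <- length(pos)
  fs <- fs %||% rep(3, n)
  qd <- qd %||% rep(8, n)
  gt <- matrix("0/1", n, nrow(sheet),
               dimnames = list(NULL, sheet$sample_id))
  dpm <- matrix(dp_min, n, nrow(sheet),
                dimnames = list(NULL, sheet$sample_id))
  variant_set(transcript_id, pos, rep("A", n), rep("G", n), fs, qd, gt, dpm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulation config for fast tests; ... overrides any default
small_sim <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_transcripts = 120L, n_planted_de = 10L, n_consistent = 5L,
         n_overlap = 3L, rng_seed = seed),
    list(...))
  do.call(sim_config, args)
}
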