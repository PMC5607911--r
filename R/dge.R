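# Differential-expression stage: TMM normalisation, common-dispersion
# estimation by conditional maximum likelihood, the negative-binomial exact
# test conditioned on group totals, BH-FDR and threshold calling. The
# algorithms are authored here; the calibration and parameter-recovery
# properties in the test suite are the contract, not bit-equality with any
# published implementation.

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: pairwise log-ratios against a reference sample
#' (the column whose upper-quartile of relative counts is closest to the mean
#' upper-quartile), double-trimmed at 30% on M-values and 5% on A-values,
#' precision-weighted, and normalised so the factors have geometric mean 1.
#' Pure library-depth differences are absorbed by library size, not factors.
#'
#' @param counts non-negative integer matrix (transcripts x samples).
#' @param ref optional reference column index; chosen automatically when
#'   `NULL`.
#' @return numeric vector of positive per-sample factors.
#' @export
tmm_factors <- function(counts, ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  if (is.null(ref)) {
    f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  }
  yr <- counts[, ref]; Nr <- lib[ref]
  one_factor <- function(yo, No) {
    nO <- yo / No; nR <- yr / Nr
    logR <- log2(nO / nR)
    absE <- (log2(nO) + log2(nR)) / 2
    v <- (No - yo) / (No * yo) + (Nr - yr) / (Nr * yr)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    if (!any(keep)) return(1)
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)),
              function(j) one_factor(counts[, j], lib[j]), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# conditional NB log-likelihood of equalised counts given group totals;
# phi = 0 is the exact multinomial (Poisson) limit
cond_loglik <- function(pseudo, groups, phi) {
  ll <- 0
  for (g in levels(groups)) {
    Y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(Y); z <- rowSums(Y)
    if (phi <= 0) {
      ll <- ll + sum(lfactorial(z) - rowSums(lfactorial(Y)) - z * log(n))
    } else {
      r <- 1 / phi
      ll <- ll + sum(rowSums(lgamma(Y + r) - lfactorial(Y)) -
                       n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r) + lfactorial(z))
    }
  }
  ll
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximises the summed conditional log-likelihood of depth-equalised counts
#' given group totals over a bracketed search on `[0, 10]`. Counts are
#' equalised by scaling each sample to the geometric-mean (effective) library
#' size and rounding. The Poisson boundary (`phi = 0`) is evaluated exactly
#' via the multinomial limit.
#'
#' @param counts non-negative integer matrix (transcripts x samples).
#' @param groups factor/vector over samples; every group needs >= 2 samples.
#' @param lib_sizes optional effective library sizes (defaults to column
#'   sums).
#' @return the dispersion estimate `phi >= 0`.
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(counts))
    stop("groups must have one entry per sample")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  N <- lib_sizes %||% colSums(counts)
  Ng <- exp(mean(log(N)))
  pseudo <- round(sweep(counts, 2L, Ng / N, `*`))
  f <- function(phi) cond_loglik(pseudo, groups, phi)
  opt <- stats::optimize(f, c(1e-8, 10), maximum = TRUE, tol = 1e-6)
  if (f(0) >= opt$objective) 0 else opt$maximum
}

# two-sided conditional exact p for one transcript
nb_exact_p1 <- function(a, b, n1, n2, phi) {
  t <- a + b
  if (t == 0) return(1)
  if (t > 1e5) {  # normal approximation to the conditional distribution
    if (phi > 0) {
      r1 <- n1 / phi; r2 <- n2 / phi
      w <- r1 / (r1 + r2)
      v <- t * w * (1 - w) * (r1 + r2 + t) / (r1 + r2 + 1)
    } else {
      w <- n1 / (n1 + n2)
      v <- t * w * (1 - w)
    }
    return(min(1, 2 * stats::pnorm(-(abs(a - t * w) - 0.5) / sqrt(v))))
  }
  y <- 0:t
  if (phi <= 0) {
    lp <- stats::dbinom(y, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    lp <- lgamma(y + r1) - lfactorial(y) + lgamma(t - y + r2) -
      lfactorial(t - y)
  }
  m <- max(lp)
  w <- exp(lp - m)
  sum(w[lp <= lp[a + 1L] + 1e-10]) / sum(w)
}

#' Negative-binomial exact test conditioned on the total
#'
#' Under equal per-sample means and common dispersion `phi`, the two group
#' sums are negative binomial; conditioned on their total the split follows a
#' beta-binomial-type law that reduces to Binomial(total, n1/(n1+n2)) at
#' `phi = 0`. The two-sided p-value sums the conditional masses at most as
#' likely as the observed split, so the conditional mode has p = 1. Totals
#' above 1e5 switch to a normal approximation of the conditional
#' distribution.
#'
#' @param a,b observed group sums (non-negative integers; vectors allowed).
#' @param n1,n2 numbers of samples (equalised libraries) in each group.
#' @param phi common dispersion (>= 0).
#' @return vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(a, b, n1 = 1L, n2 = 1L, phi = 0) {
  if (phi < 0) stop("dispersion must be >= 0")
  if (any(a < 0) || any(b < 0) || any(a != floor(a)) || any(b != floor(b)))
    stop("group sums must be non-negative integers")
  if (length(a) != length(b)) stop("a and b must have equal length")
  vapply(seq_along(a), function(i) nb_exact_p1(a[i], b[i], n1, n2, phi),
         numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of FDR values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression at fold-change and FDR cut-offs
#'
#' `up_in_mantle` iff `log2_fc >= log2(fc_cutoff)` and `fdr <= fdr_cutoff`;
#' `down_in_mantle` for the mirrored fold change; otherwise `ns`. Both
#' comparisons are inclusive.
#'
#' @param log2_fc log2 fold changes (mantle over foot).
#' @param fdr FDR values.
#' @param config a [pipeline_config()].
#' @return character vector of calls.
#' @export
call_de <- function(log2_fc, fdr, config = pipeline_config()) {
  lfc <- log2(config$fc_cutoff)
  ifelse(fdr <= config$fdr_cutoff & log2_fc >= lfc, "up_in_mantle",
         ifelse(fdr <= config$fdr_cutoff & log2_fc <= -lfc,
                "down_in_mantle", "ns"))
}

#' Differential expression between mantle and foot
#'
#' Full DE stage: TMM factors, common dispersion by conditional ML, per-
#' transcript NB exact test on library-equalised group sums, log2 fold change
#' from normalised group means with a pseudo-count of 0.5 per group, BH-FDR
#' and threshold calling.
#'
#' @param counts integer matrix (transcripts x samples).
#' @param samples sample sheet whose `sample_id`s name the count columns.
#' @param config a [pipeline_config()].
#' @param dispersion optional fixed dispersion (estimated when `NULL`).
#' @return a `data.frame` of class `dge_result` with columns
#'   `transcript_id`, `log2_fc`, `log2_cpm`, `p_value`, `fdr`, `call`;
#'   attributes `dispersion` and `norm_factors`.
#' @export
dge_analysis <- function(counts, samples, config = pipeline_config(),
                         dispersion = NULL) {
  counts <- as.matrix(counts)
  samples <- validate_samples(samples)
  missing_s <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_s))
    stop("sheet sample(s) absent from counts: ",
         paste(missing_s, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  groups <- factor(samples$tissue, levels = TISSUES)
  if (any(table(groups) < 2L))
    stop("need at least 2 samples per tissue")
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, groups, lib_sizes = eff)
  Ng <- exp(mean(log(eff)))
  adj <- round(sweep(counts, 2L, Ng / eff, `*`))
  mantle <- groups == "mantle"
  n1 <- sum(mantle); n2 <- sum(!mantle)
  a <- rowSums(adj[, mantle, drop = FALSE])
  b <- rowSums(adj[, !mantle, drop = FALSE])
  p <- nb_exact_test(a, b, n1, n2, dispersion)
  log2_fc <- log2((a / n1 + 0.5) / (b / n2 + 0.5))
  log2_cpm <- log2(((a + b) / (n1 + n2) + 0.5) / Ng * 1e6)
  fdr <- bh_adjust(p)
  out <- data.frame(transcript_id = rownames(counts) %||%
                      as.character(seq_len(nrow(counts))),
                    log2_fc = log2_fc, log2_cpm = log2_cpm,
                    p_value = p, fdr = fdr,
                    call = call_de(log2_fc, fdr, config),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  attr(out, "norm_factors") <- f
  class(out) <- c("dge_result", "data.frame")
  out
}

#' @export
print.dge_result <- function(x, ...) {
  cat(sprintf(
    "dge_result: %d transcripts, dispersion %.4g; up %d, down %d, ns %d\n",
    nrow(x), attr(x, "dispersion"),
    sum(x$call == "up_in_mantle"), sum(x$call == "down_in_mantle"),
    sum(x$call == "ns")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Hierarchically cluster samples by expression profile
#'
#' Complete-linkage agglomerative clustering on the distance `1 - r`, where
#' `r` is the Pearson correlation of `log2(CPM + 1)` profiles. Deterministic
#' given the input order (ties merge lowest index first, the `hclust`
#' convention).
#'
#' @param counts integer matrix (transcripts x samples).
#' @return an [stats::hclust] tree over the samples.
#' @export
cluster_samples <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  lcpm <- log2(sweep(counts, 2L, lib, `/`) * 1e6 + 1)
  if (any(apply(lcpm, 2L, stats::sd) == 0))
    stop("constant sample vector: correlation undefined")
  d <- stats::as.dist(1 - stats::cor(lcpm))
  stats::hclust(d, method = "complete")
}

#' Top bipartition of a sample tree
#'
#' @param h an [stats::hclust] tree.
#' @return list of two character vectors of sample labels.
#' @export
top_split <- function(h) {
  k <- stats::cutree(h, k = 2L)
  split(names(k), k)
}

#' Write a sample tree as Newick
#'
#' @param h an [stats::hclust] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}
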