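# Hard variant filters: strand bias (FS), quality by depth (QD), SNP
# clusters, and per-sample depth. Boundary values are kept throughout: the
# removal conditions are strictly fs > fs_max, qd < qd_min, depth < min_depth.

#' Flag site-level hard filters (FS, QD)
#'
#' A site is flagged `FS` iff its Fisher-strand score strictly exceeds
#' `fs_max` (default 30.0) and `QD` iff its quality-by-depth is strictly
#' below `qd_min` (default 2.0); boundary values pass.
#'
#' @param fs numeric vector of Fisher-strand scores.
#' @param qd numeric vector of quality-by-depth values.
#' @param config a [pipeline_config()].
#' @return data.frame with logical columns `FS` and `QD` (TRUE = flagged).
#' @export
flag_site_filters <- function(fs, qd, config = pipeline_config()) {
  if (length(fs) != length(qd)) stop("fs and qd must have equal length")
  if (any(is.na(fs)) || any(is.na(qd))) stop("missing fs or qd value")
  data.frame(FS = fs > config$fs_max, QD = qd < config$qd_min)
}

#' Flag SNP clusters within one transcript
#'
#' A position is flagged iff it belongs to a run of `cluster_size`
#' consecutive SNPs whose inclusive span (`last - first + 1`) is at most
#' `cluster_window` bases. With the defaults, 3 SNPs within a 35-base window
#' form a cluster. Transcripts are independent; pass one transcript's
#' positions at a time.
#'
#' @param positions sorted, unique integer positions on one transcript.
#' @param config a [pipeline_config()].
#' @return logical vector parallel to `positions` (TRUE = in a cluster).
#' @export
flag_snp_clusters <- function(positions, config = pipeline_config()) {
  n <- length(positions)
  if (anyDuplicated(positions)) stop("duplicate positions")
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  flagged <- logical(n)
  k <- config$cluster_size
  if (n < k) return(flagged)
  span <- positions[k:n] - positions[seq_len(n - k + 1L)] + 1L
  for (i in which(span <= config$cluster_window))
    flagged[i:(i + k - 1L)] <- TRUE
  flagged
}

#' Flag sites failing the per-sample depth filter
#'
#' A site is removed iff its depth is strictly below `min_depth` (default 10)
#' in any sample of the sheet; a site at exactly the threshold in every
#' sample is kept.
#'
#' @param dp integer matrix (sites x samples) of depths.
#' @param config a [pipeline_config()].
#' @return logical vector over sites (TRUE = remove).
#' @export
flag_depth <- function(dp, config = pipeline_config()) {
  dp <- as.matrix(dp)
  if (ncol(dp) == 0L) stop("no samples to evaluate the depth filter on")
  if (any(is.na(dp))) stop("missing depth for a sample")
  apply(dp < config$min_depth, 1L, any)
}

#' Apply all hard filters to a variant set
#'
#' Evaluates the FS, QD, cluster and depth filters for every site (reasons
#' accumulate rather than short-circuit, so per-class tallies are exact) and
#' returns the surviving sites together with a per-site outcome table.
#'
#' @param vs a [variant_set()].
#' @param config a [pipeline_config()].
#' @param samples optional sample sheet; when given, the depth filter is
#'   evaluated on (and restricted to) its samples.
#' @return list with `kept` (the filtered `variant_set`, input order
#'   preserved) and `outcomes` (`data.frame` with `transcript_id`, `pos`,
#'   `kept`, and logical reason columns `FS`, `QD`, `CLUSTER`, `DEPTH`, plus
#'   a comma-separated `reasons` string).
#' @export
apply_hard_filters <- function(vs, config = pipeline_config(),
                               samples = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  dp <- vs$dp
  if (!is.null(samples)) {
    missing_s <- setdiff(samples$sample_id, colnames(dp))
    if (length(missing_s))
      stop("sheet sample(s) absent from variant set: ",
           paste(missing_s, collapse = ", "))
    dp <- dp[, samples$sample_id, drop = FALSE]
  }
  n <- n_variants(vs)
  site <- flag_site_filters(vs$site$fs, vs$site$qd, config)
  cl <- logical(n)
  for (t_id in unique(vs$site$transcript_id)) {
    i <- which(vs$site$transcript_id == t_id)
    o <- order(vs$site$pos[i])
    cl[i[o]] <- flag_snp_clusters(vs$site$pos[i][o], config)
  }
  depth <- if (n > 0L) flag_depth(dp, config) else logical(0)
  out <- data.frame(transcript_id = vs$site$transcript_id,
                    pos = vs$site$pos,
                    FS = site$FS, QD = site$QD, CLUSTER = cl, DEPTH = depth)
  out$kept <- !(out$FS | out$QD | out$CLUSTER | out$DEPTH)
  rn <- cbind(ifelse(out$FS, "FS", NA), ifelse(out$QD, "QD", NA),
              ifelse(out$CLUSTER, "CLUSTER", NA),
              ifelse(out$DEPTH, "DEPTH", NA))
  out$reasons <- apply(rn, 1L, function(r) paste(stats::na.omit(r),
                                                 collapse = ","))
  list(kept = subset_variants(vs, out$kept), outcomes = out)
}
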