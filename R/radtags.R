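# RAD-tag consensus extension and ungapped nucleotide search. Tags are short
# anonymous marker sequences truncated to a fixed core (96 bp in the original
# genotyping); their read stacks extend past the core, so a majority-vote
# consensus recovers a longer query which is then searched against the
# transcriptome with exact-match seeds, ungapped X-drop extension, and
# Karlin-Altschul E-values.

#' Build an extended consensus from a RAD-tag read stack
#'
#' Reads are anchored at position 1 (the restriction site). The core is the
#' per-column majority over the first `core_length` bases; beyond it each
#' column takes the majority base, and the extension truncates at the first
#' column with coverage below 2, agreement below `min_agreement`, or a tie
#' for the majority base.
#'
#' @param reads character vector of stack reads (all at least `core_length`
#'   long).
#' @param tag_id identifier for the tag.
#' @param core_length core length in bases.
#' @param min_agreement minimum fraction of covering reads that must agree.
#' @return object of class `rad_tag`: list with `tag_id`, `core`,
#'   `consensus` (begins with the core), and `support` (per-position
#'   agreement fraction in `[0, 1]`).
#' @export
build_consensus <- function(reads, tag_id = "tag", core_length = 96L,
                            min_agreement = 0.6) {
  if (!length(reads)) stop("empty read stack")
  if (any(nchar(reads) < core_length))
    stop("read(s) shorter than the tag core")
  chars <- strsplit(reads, "", fixed = TRUE)
  maxlen <- max(lengths(chars))
  cons <- character(0); supp <- numeric(0)
  for (j in seq_len(maxlen)) {
    col <- unlist(lapply(chars, function(x) if (length(x) >= j) x[j]))
    tab <- sort(table(col), decreasing = TRUE)
    agree <- tab[1L] / length(col)
    tie <- length(tab) > 1L && tab[2L] == tab[1L]
    if (j > core_length &&
        (length(col) < 2L || tie || agree < min_agreement)) break
    cons <- c(cons, names(tab)[1L])
    supp <- c(supp, as.numeric(agree))
  }
  structure(list(tag_id = tag_id,
                 core = paste(cons[seq_len(core_length)], collapse = ""),
                 consensus = paste(cons, collapse = ""),
                 support = supp),
            class = "rad_tag")
}

#' @export
print.rad_tag <- function(x, ...) {
  cat(sprintf("rad_tag %s: core %d bp, consensus %d bp, mean support %.3f\n",
              x$tag_id, nchar(x$core), nchar(x$consensus), mean(x$support)))
  invisible(x)
}

#' Build consensus tags for a list of read stacks
#'
#' @param stacks named list of read vectors (see [read_stacks()]).
#' @param config a [pipeline_config()].
#' @return named list of `rad_tag` objects.
#' @export
build_consensus_tags <- function(stacks, config = pipeline_config()) {
  out <- lapply(names(stacks), function(nm)
    build_consensus(stacks[[nm]], nm, config$tag_core_length,
                    config$min_agreement))
  stats::setNames(out, names(stacks))
}

#' Karlin-Altschul parameters for ungapped match/mismatch scoring
#'
#' For i.i.d. uniform-background nucleotides, an aligned pair matches with
#' probability `p_match` (1/4) and scores `match`, otherwise `mismatch`.
#' `lambda` is the unique positive root of
#' `p e^(lambda*match) + (1-p) e^(lambda*mismatch) = 1` (bracketed
#' root-finding to 1e-9); `K` follows from the standard lattice series: with
#' step distribution convolved j times, `sigma = sum_j (1/j) * (E[e^(lambda
#' S_j); S_j < 0] + P(S_j >= 0))`, truncated at relative change < 1e-6, and
#' `K = delta*lambda*e^(-2*sigma) / (H*(1 - e^(-lambda*delta)))` where `H`
#' is the relative entropy and `delta` the score lattice spacing.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param p_match background probability that two random bases match.
#' @return list with `lambda` (nats), `K`, and `H`.
#' @export
karlin_altschul_params <- function(match = 1, mismatch = -2,
                                   p_match = 0.25) {
  if (match <= 0 || mismatch >= 0) stop("need match > 0 and mismatch < 0")
  expected <- p_match * match + (1 - p_match) * mismatch
  if (expected >= 0)
    stop("scoring scheme must have negative expected score")
  f <- function(l) p_match * exp(l * match) +
    (1 - p_match) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  H <- lambda * (p_match * match * exp(lambda * match) +
                   (1 - p_match) * mismatch * exp(lambda * mismatch))
  delta <- gcd2(round(match), round(mismatch))
  # sigma series over convolutions of the integer step distribution
  low <- round(mismatch); high <- round(match)
  step <- numeric(high - low + 1L)
  step[high - low + 1L] <- p_match
  step[1L] <- 1 - p_match
  pj <- 1; offj <- 0; sigma <- 0
  for (j in 1:500) {
    newp <- numeric(length(pj) + (high - low))
    for (k in seq_along(step)) if (step[k] > 0) {
      idx <- seq_along(pj) + (k - 1L)
      newp[idx] <- newp[idx] + pj * step[k]
    }
    pj <- newp; offj <- offj + low
    svals <- offj + seq_along(pj) - 1L
    term <- sum(pj[svals < 0] * exp(lambda * svals[svals < 0])) +
      sum(pj[svals >= 0])
    sigma <- sigma + term / j
    if (term / j < 1e-6 * max(sigma, 1e-12)) break
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

# X-drop ungapped extension along one diagonal; returns gains and extents.
# qv/sv are integer-coded sequences; q0/s0 the last position of the seed
# (right extension) or first (left extension, dir = -1).
xdrop_extend <- function(qv, sv, q0, s0, dir, match, mismatch, xdrop) {
  best <- 0; run <- 0; ext <- 0L
  i <- q0 + dir; j <- s0 + dir
  while (i >= 1L && i <= length(qv) && j >= 1L && j <= length(sv)) {
    run <- run + if (qv[i] == sv[j]) match else mismatch
    if (run > best) { best <- run; ext <- abs(i - q0) }
    if (best - run > xdrop) break
    i <- i + dir; j <- j + dir
  }
  list(gain = best, ext = ext)
}

# 2-bit rolling k-mer codes (double-precision exact for w <= 26);
# windows containing non-ACGT letters get NA
kmer_codes <- function(int_seq, w) {
  map <- rep(NA_real_, 128L)
  map[utf8ToInt("ACGT") + 1L] <- 0:3
  codes <- stats::filter(map[int_seq + 1L], 4^(0:(w - 1L)), sides = 1L)
  as.numeric(codes)   # code at index i covers the window ending at i
}

search_one_strand <- function(qseq, subjects, subj_codes, subj_int, offsets,
                              config, ka, m_len, n_total, tag_id, strand) {
  w <- config$seed_length
  qlen <- nchar(qseq)
  if (w > qlen) stop("seed length exceeds tag length")
  qv <- utf8ToInt(qseq)
  q_codes <- kmer_codes(qv, w)[w:qlen]   # q_codes[j]: window starting at j
  match_ends <- which(subj_codes %in% q_codes)
  if (!length(match_ends)) return(NULL)
  hits <- list()
  seen <- character(0)   # transcript:diagonal keys already extended
  for (e in match_ends) {
    s_global <- e - w + 1L
    ti <- findInterval(s_global, offsets)
    s_local <- s_global - offsets[ti] + 1L
    for (q1 in which(q_codes == subj_codes[e])) {
      key <- paste0(ti, ":", s_local - q1)
      if (key %in% seen) next
      seen <- c(seen, key)
      sv <- subj_int[[ti]]
      right <- xdrop_extend(qv, sv, q1 + w - 1L, s_local + w - 1L, 1L,
                            config$match, config$mismatch, config$xdrop)
      left <- xdrop_extend(qv, sv, q1, s_local, -1L,
                           config$match, config$mismatch, config$xdrop)
      score <- w * config$match + right$gain + left$gain
      evalue <- ka$K * m_len * n_total * exp(-ka$lambda * score)
      if (evalue >= config$evalue_max) next
      qs <- q1 - left$ext; qe <- q1 + w - 1L + right$ext
      ss_ <- s_local - left$ext; se <- s_local + w - 1L + right$ext
      hits[[length(hits) + 1L]] <- data.frame(
        tag_id = tag_id, transcript_id = names(subjects)[ti],
        score = score, evalue = evalue,
        q_start = qs - 1L, q_end = qe,       # 0-based half-open
        s_start = ss_ - 1L, s_end = se,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# keep the best-scoring hit among overlapping ones per (tag, transcript,
# strand); overlap is judged on the subject interval
merge_hits <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(hits)
  out <- list()
  for (key in unique(paste(hits$tag_id, hits$transcript_id, hits$strand))) {
    h <- hits[paste(hits$tag_id, hits$transcript_id, hits$strand) == key, ,
              drop = FALSE]
    h <- h[order(-h$score, h$s_start), , drop = FALSE]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      overlaps <- any(h$s_start[i] < kept$s_end & h$s_end[i] > kept$s_start)
      if (!overlaps) kept <- rbind(kept, h[i, ])
    }
    out[[key]] <- kept
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$tag_id, res$evalue), , drop = FALSE]
}

#' Search consensus tags against a transcriptome
#'
#' Ungapped seed-and-extend on both strands: exact-match seeds of
#' `seed_length` (default 16) located through a dictionary match against the
#' transcriptome, one X-drop extension per distinct (transcript, diagonal),
#' scores `match`/`mismatch` (+1/-2), and E-values
#' `E = K * m * n * e^(-lambda * S)` with `m` the consensus length and `n`
#' the total transcriptome length (no edge correction). Hits with
#' `E < evalue_max` are retained; overlapping hits on the same (tag,
#' transcript, strand) are merged keeping the best score. Minus-strand hits
#' report query coordinates on the tag as given.
#'
#' @param tags named character vector of consensus sequences, or a list of
#'   `rad_tag` objects.
#' @param transcriptome named character vector of transcript sequences.
#' @param config a [pipeline_config()].
#' @return `data.frame` of hits: `tag_id`, `transcript_id`, `score`,
#'   `evalue`, `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open),
#'   `strand`.
#' @export
search_tags <- function(tags, transcriptome, config = pipeline_config()) {
  if (!length(transcriptome)) stop("empty transcriptome")
  if (is.list(tags) && length(tags) && inherits(tags[[1L]], "rad_tag"))
    tags <- stats::setNames(vapply(tags, `[[`, "", "consensus"),
                            vapply(tags, `[[`, "", "tag_id"))
  if (is.null(names(tags))) stop("tags must be named")
  if (any(nchar(tags) < config$seed_length))
    stop("seed length exceeds the shortest tag")
  ka <- karlin_altschul_params(config$match, config$mismatch)
  n_total <- sum(nchar(transcriptome))
  spacer <- strrep("N", config$seed_length)
  subj_cat <- paste(toupper(transcriptome), collapse = spacer)
  offsets <- cumsum(c(1L, utils::head(nchar(transcriptome), -1L) +
                        config$seed_length))
  subj_codes <- kmer_codes(utf8ToInt(subj_cat), config$seed_length)
  subj_int <- lapply(toupper(transcriptome), utf8ToInt)
  all_hits <- list()
  for (nm in names(tags)) {
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") tags[[nm]] else revcomp(tags[[nm]])
      h <- search_one_strand(qseq, transcriptome, subj_codes, subj_int,
                             offsets, config, ka, nchar(tags[[nm]]),
                             n_total, nm, strand)
      if (!is.null(h) && strand == "-") {
        # map query interval back to the original tag orientation
        qlen <- nchar(tags[[nm]])
        qs <- qlen - h$q_end; qe <- qlen - h$q_start
        h$q_start <- qs; h$q_end <- qe
      }
      if (!is.null(h)) all_hits[[paste(nm, strand)]] <- h
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(tag_id = character(0), transcript_id = character(0),
               score = numeric(0), evalue = numeric(0),
               q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  res <- merge_hits(hits)
  if (is.null(res)) hits else res
}
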