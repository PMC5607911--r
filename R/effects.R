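# SNV effect classification against the transcript's single annotated open
# reading frame, using the standard genetic code. Transcripts are assembled
# mRNA contigs and are taken sense-strand; the ORF includes its stop codon,
# so substitutions there can be stop_lost.

EFFECT_CLASSES <- c("synonymous", "missense", "stop_gained", "stop_lost",
                    "outside_orf")

#' Classify SNVs against their transcripts' open reading frames
#'
#' For every variant and every alternate allele: a 0-based position outside
#' `[orf_start, orf_end)` is `outside_orf`; otherwise the affected codon is
#' translated before and after substitution with the standard genetic code
#' and the call is `stop_gained` (non-stop to stop), `stop_lost` (stop to
#' non-stop), `synonymous` (identical amino acid) or `missense`. A
#' substitution that destroys the start codon is reported like any other
#' codon change (no start-lost class).
#'
#' @param vs a [variant_set()].
#' @param orfs ORF annotation `data.frame` ([read_orfs()] format).
#' @param sequences named character vector of transcript sequences.
#' @return `data.frame` with one row per variant x alt: `transcript_id`,
#'   `pos`, `ref`, `alt`, `effect`, `codon_before`, `codon_after`,
#'   `aa_before`, `aa_after` (codon/aa fields `NA` outside ORFs).
#' @export
classify_variants <- function(vs, orfs, sequences) {
  stopifnot(inherits(vs, "variant_set"))
  orfs <- validate_orfs(orfs)
  alts <- strsplit(vs$site$alt, ",", fixed = TRUE)
  idx <- rep(seq_len(n_variants(vs)), lengths(alts))
  out <- data.frame(transcript_id = vs$site$transcript_id[idx],
                    pos = vs$site$pos[idx],
                    ref = vs$site$ref[idx],
                    alt = unlist(alts) %||% character(0),
                    stringsAsFactors = FALSE)
  n <- nrow(out)
  if (n == 0L) {
    out[c("effect", "codon_before", "codon_after", "aa_before",
          "aa_after")] <- character(0)
    return(out)
  }
  miss <- setdiff(out$transcript_id, names(sequences))
  if (length(miss)) stop("transcript(s) missing from FASTA: ",
                         paste(unique(miss), collapse = ", "))
  seqv <- sequences[out$transcript_id]
  if (any(out$pos > nchar(seqv)))
    stop("variant position beyond transcript length")
  base_at <- substring(seqv, out$pos, out$pos)
  if (any(base_at != out$ref))
    stop("reference base mismatch between VCF and FASTA at ",
         paste(utils::head(paste0(out$transcript_id, ":", out$pos)[
           base_at != out$ref], 3L), collapse = ", "))

  oi <- match(out$transcript_id, orfs$transcript_id)
  if (any(is.na(oi))) stop("transcript(s) missing from ORF table: ",
                           paste(unique(out$transcript_id[is.na(oi)]),
                                 collapse = ", "))
  ostart <- orfs$orf_start[oi]; oend <- orfs$orf_end[oi]
  p0 <- out$pos - 1L
  inside <- p0 >= ostart & p0 < oend

  effect <- rep("outside_orf", n)
  codon_before <- codon_after <- aa_before <- aa_after <- rep(NA_character_, n)
  if (any(inside)) {
    off <- (p0[inside] - ostart[inside]) %% 3L
    cstart <- out$pos[inside] - off   # 1-based codon start
    cb <- substring(seqv[inside], cstart, cstart + 2L)
    ca <- cb
    substr(ca, off + 1L, off + 1L) <- out$alt[inside]
    code <- Biostrings::GENETIC_CODE
    ab <- unname(code[cb]); aa <- unname(code[ca])
    eff <- ifelse(ab == aa, "synonymous",
                  ifelse(aa == "*", "stop_gained",
                         ifelse(ab == "*", "stop_lost", "missense")))
    effect[inside] <- eff
    codon_before[inside] <- cb; codon_after[inside] <- ca
    aa_before[inside] <- ab; aa_after[inside] <- aa
  }
  out$effect <- effect
  out$codon_before <- codon_before; out$codon_after <- codon_after
  out$aa_before <- aa_before; out$aa_after <- aa_after
  out
}

#' Classify a single SNV
#'
#' Convenience wrapper around [classify_variants()] for one site; returns one
#' row per alternate allele, order-aligned with the alts.
#'
#' @param transcript_id,pos,ref,alt the variant (pos 1-based; `alt` may be
#'   comma-separated).
#' @param orf one-row ORF annotation for the transcript.
#' @param sequence the transcript sequence.
#' @return the [classify_variants()] `data.frame`.
#' @export
classify_snv <- function(transcript_id, pos, ref, alt, orf, sequence) {
  gt <- matrix("0/0", 1L, 1L, dimnames = list(NULL, "s1"))
  dp <- matrix(10L, 1L, 1L, dimnames = list(NULL, "s1"))
  vs <- variant_set(transcript_id, pos, ref, alt, 0, 10, gt, dp)
  seqs <- stats::setNames(sequence, transcript_id)
  classify_variants(vs, orf, seqs)
}

#' Tally effect classes
#'
#' @param effects output of [classify_variants()].
#' @return list with `counts` (named integer vector over all effect classes,
#'   summing to the number of calls) and `ratio`, the synonymous to
#'   non-synonymous ratio `synonymous / (missense + stop_gained + stop_lost)`
#'   (`NA` when the denominator is zero).
#' @export
tally_effects <- function(effects) {
  counts <- table(factor(effects$effect, levels = EFFECT_CLASSES))
  counts <- stats::setNames(as.integer(counts), EFFECT_CLASSES)
  denom <- counts[["missense"]] + counts[["stop_gained"]] +
    counts[["stop_lost"]]
  list(counts = counts,
       ratio = if (denom == 0L) NA_real_ else counts[["synonymous"]] / denom)
}
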