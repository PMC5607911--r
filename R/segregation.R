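# Segregation-consistency filter under the dominance model: the brown
# (unbanded) morph is dominant, the yellow (banded) morph recessive, so at a
# causal or tightly linked SNP the yellow individuals must be homozygous and
# the brown individuals must carry the dominant alternative.

#' Score variants for consistency with the dominant/recessive morph model
#'
#' Genotypes are taken per individual; the two tissue libraries of an
#' individual must agree (a discordant pair is an error). In `literal` mode a
#' site is consistent iff every yellow-morph individual is homozygous (for
#' any allele). In `strict` mode (the default) all yellow individuals must be
#' homozygous for the *same* allele and every brown individual must carry at
#' least one copy of a different allele. Sites where all individuals are
#' identical homozygotes carry no segregation signal and are inconsistent in
#' both modes. Sites with a missing genotype in any individual fail.
#'
#' @param vs a [variant_set()].
#' @param samples sample sheet covering the variant set's samples.
#' @param mode `"strict"` or `"literal"`.
#' @return `data.frame` with `transcript_id`, `pos`, `consistent`, `mode`,
#'   and `yellow_allele` (the shared yellow homozygous allele index;
#'   `NA` unless strict-consistent).
#' @export
is_consistent <- function(vs, samples, mode = c("strict", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vs, "variant_set"))
  samples <- validate_samples(samples)
  if (!any(samples$morph == "yellow_banded") ||
      !any(samples$morph == "brown_unbanded"))
    stop("need at least one individual of each morph")
  missing_s <- setdiff(samples$sample_id, colnames(vs$gt))
  if (length(missing_s))
    stop("sheet sample(s) absent from variant set: ",
         paste(missing_s, collapse = ", "))
  n <- n_variants(vs)
  if (n == 0L)
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      consistent = logical(0), mode = character(0),
                      yellow_allele = integer(0)))
  inds <- unique(samples$individual_id)
  al <- gt_alleles(vs$gt[, samples$sample_id, drop = FALSE])
  # canonical unordered pair per sample
  lo <- pmin(al$a1, al$a2); hi <- pmax(al$a1, al$a2)

  ind_lo <- matrix(NA_integer_, n, length(inds),
                   dimnames = list(NULL, inds))
  ind_hi <- ind_lo
  for (j in seq_along(inds)) {
    cols <- which(samples$individual_id == inds[j])
    l <- lo[, cols, drop = FALSE]; h <- hi[, cols, drop = FALSE]
    if (length(cols) > 1L) {
      agree <- apply(l, 1L, function(x) length(unique(x[!is.na(x)])) <= 1L) &
        apply(h, 1L, function(x) length(unique(x[!is.na(x)])) <= 1L) &
        (rowSums(is.na(l)) %in% c(0L, length(cols)))
      if (any(!agree))
        stop(sprintf(
          "conflicting genotypes between tissue samples of individual %s at %s",
          inds[j],
          paste(utils::head(paste0(vs$site$transcript_id, ":", vs$site$pos)[
            !agree], 3L), collapse = ", ")))
    }
    ind_lo[, j] <- l[, 1L]
    ind_hi[, j] <- h[, 1L]
  }

  ind_morph <- samples$morph[match(inds, samples$individual_id)]
  yellow <- which(ind_morph == "yellow_banded")
  brown <- which(ind_morph == "brown_unbanded")

  any_missing <- rowSums(is.na(ind_lo)) > 0L
  hom <- ind_lo == ind_hi

  ylo <- ind_lo[, yellow, drop = FALSE]
  yhom <- apply(hom[, yellow, drop = FALSE], 1L, all)
  ysame <- apply(ylo, 1L, function(x) length(unique(x)) == 1L)

  # monomorphic: every individual identical homozygote
  mono <- apply(hom, 1L, all) &
    apply(ind_lo, 1L, function(x) length(unique(x)) == 1L)
  mono[any_missing] <- FALSE

  if (mode == "literal") {
    consistent <- !any_missing & yhom & !mono
    yellow_allele <- rep(NA_integer_, n)
  } else {
    a <- ylo[, 1L]
    browns_carry <- rep(TRUE, n)
    for (j in brown)
      browns_carry <- browns_carry &
        (ind_lo[, j] != a | ind_hi[, j] != a)
    consistent <- !any_missing & yhom & ysame & browns_carry & !mono
    consistent[is.na(consistent)] <- FALSE
    yellow_allele <- ifelse(consistent, a, NA_integer_)
  }
  consistent[is.na(consistent)] <- FALSE
  data.frame(transcript_id = vs$site$transcript_id, pos = vs$site$pos,
             consistent = consistent, mode = mode,
             yellow_allele = yellow_allele, stringsAsFactors = FALSE)
}

#' Keep variants consistent with the morph model
#'
#' @param vs a hard-filtered [variant_set()].
#' @param samples sample sheet.
#' @param mode `"strict"` or `"literal"` (see [is_consistent()]).
#' @return list with `variants` (consistent sites), `calls` (the full
#'   [is_consistent()] table), and `transcripts` (distinct transcript ids
#'   among the consistent sites).
#' @export
filter_consistent <- function(vs, samples, mode = c("strict", "literal")) {
  calls <- is_consistent(vs, samples, mode)
  kept <- subset_variants(vs, calls$consistent)
  list(variants = kept, calls = calls,
       transcripts = unique(kept$site$transcript_id))
}
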