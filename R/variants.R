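#' Construct a set of single-nucleotide variant records
#'
#' The package's container for SNVs called on transcriptome contigs: one row
#' per site, with the site annotations the hard filters need (Fisher-strand
#' FS and quality-by-depth QD) and per-sample genotype and depth matrices.
#' Genotypes are unphased diploid strings such as `"0/1"`, with `"./."` for
#' missing; allele 0 is the reference base, alleles 1..k index the `alt`
#' bases. Positions are 1-based on the transcript, as in VCF.
#'
#' @param transcript_id character vector of transcript ids.
#' @param pos integer vector of 1-based positions.
#' @param ref single reference base per site (A/C/G/T).
#' @param alt alternate base(s) per site; multi-allelic sites are
#'   comma-separated single bases.
#' @param fs non-negative Fisher-strand score per site.
#' @param qd non-negative quality-by-depth per site.
#' @param gt character matrix (sites x samples) of genotype strings.
#' @param dp integer matrix (sites x samples) of read depths.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(transcript_id, pos, ref, alt, fs, qd, gt, dp) {
  n <- length(transcript_id)
  gt <- as.matrix(gt); dp <- as.matrix(dp)
  if (n == 0L) {
    gt <- matrix(character(0), 0L, ncol(gt), dimnames = dimnames(gt))
    dp <- matrix(integer(0), 0L, ncol(dp), dimnames = dimnames(dp))
  }
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(fs) == n, length(qd) == n,
            nrow(gt) == n, nrow(dp) == n, ncol(gt) == ncol(dp))
  if (is.null(colnames(gt))) stop("gt matrix must have sample-id colnames")
  if (n > 0L) {
    if (any(pos < 1L)) stop("positions must be >= 1")
    if (!all(ref %in% DNA_BASES)) stop("ref must be a single base A/C/G/T")
    alts <- strsplit(alt, ",", fixed = TRUE)
    if (any(lengths(alts) == 0L)) stop("alt must be non-empty")
    ok <- mapply(function(a, r) all(a %in% DNA_BASES) && !anyDuplicated(a) &&
                   !(r %in% a), alts, ref)
    if (!all(ok)) stop("alts must be single bases, unique, and differ from ref")
    if (any(fs < 0) || any(qd < 0)) stop("fs and qd must be >= 0")
    al <- gt_alleles(gt)
    amax <- pmax(al$a1, al$a2)
    namax <- suppressWarnings(apply(amax, 1L, max, na.rm = TRUE))
    namax[!is.finite(namax)] <- 0L
    if (any(namax > lengths(alts)))
      stop("genotype allele index exceeds number of alleles at a site")
    if (any(dp < 0, na.rm = TRUE)) stop("depths must be >= 0")
  }
  storage.mode(dp) <- "integer"
  structure(list(site = data.frame(transcript_id = as.character(transcript_id),
                                   pos = as.integer(pos),
                                   ref = as.character(ref),
                                   alt = as.character(alt),
                                   fs = as.numeric(fs), qd = as.numeric(qd),
                                   stringsAsFactors = FALSE),
                 gt = gt, dp = dp),
            class = "variant_set")
}

#' Number of variants in a set
#' @param vs a `variant_set`.
#' @return integer count of sites.
#' @export
n_variants <- function(vs) nrow(vs$site)

#' Subset a variant set by site index
#' @param vs a `variant_set`.
#' @param i integer or logical index over sites.
#' @return the subsetted `variant_set`.
#' @export
subset_variants <- function(vs, i) {
  variant_set(vs$site$transcript_id[i], vs$site$pos[i], vs$site$ref[i],
              vs$site$alt[i], vs$site$fs[i], vs$site$qd[i],
              vs$gt[i, , drop = FALSE], vs$dp[i, , drop = FALSE])
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d SNV site(s) x %d sample(s)\n",
              n_variants(x), ncol(x$gt)))
  if (n_variants(x)) print(utils::head(x$site, 6L))
  invisible(x)
}

# split "a/b" genotype strings into two integer allele matrices (NA = missing)
gt_alleles <- function(gt) {
  a1 <- suppressWarnings(array(as.integer(sub("[/|].*$", "", gt)), dim(gt),
                               dimnames(gt)))
  a2 <- suppressWarnings(array(as.integer(sub("^.*[/|]", "", gt)), dim(gt),
                               dimnames(gt)))
  both <- is.na(a1) != is.na(a2)
  if (any(both)) stop("half-missing genotypes are not supported")
  list(a1 = a1, a2 = a2)
}
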