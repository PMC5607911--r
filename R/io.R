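#' Read a transcriptome FASTA file
#'
#' Order is preserved, sequences are uppercased, ids are the first
#' whitespace-delimited token of each header. Empty records and duplicate ids
#' are errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(x) == 0L))
    stop("FASTA record with empty sequence: ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(x))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("sequences must be named")
  if (any(!nzchar(seqs))) stop("refusing to write an empty sequence")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read SNVs from a VCF file
#'
#' Parses a VCFv4.2 file (GATK dialect: per-site INFO fields `FS` and `QD`,
#' per-sample FORMAT fields `GT` and `DP`) into a [variant_set()]. Only
#' biallelic or multi-allelic single-base substitutions are retained; indel
#' and multi-base lines are skipped, and the skip count is logged and attached
#' as attribute `n_skipped`.
#'
#' @param path VCF file.
#' @param samples optional sample sheet (see [read_samples()]); the VCF sample
#'   columns must cover its `sample_id`s and are subset to them.
#' @return a `variant_set` with attribute `n_skipped`.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records")
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  alt[is.na(alt)] <- ""
  is_snv <- ref %in% DNA_BASES &
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) length(a) > 0L && all(a %in% DNA_BASES),
           logical(1))
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L)
    sc_log("read_vcf: skipped %d non-SNV record(s) in %s", n_skipped, path)
  gt <- vcfR::extract.gt(v, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  fs <- suppressWarnings(vcfR::extract.info(v, "FS", as.numeric = TRUE))
  qd <- suppressWarnings(vcfR::extract.info(v, "QD", as.numeric = TRUE))
  keep <- which(is_snv)
  if (any(is.na(fs[keep])) || any(is.na(qd[keep])))
    stop("retained VCF line(s) missing the FS or QD INFO field")
  gt <- gt[keep, , drop = FALSE]
  dp <- dp[keep, , drop = FALSE]
  gt[is.na(gt)] <- "./."
  dp[is.na(dp)] <- 0L
  if (!is.null(samples)) {
    missing_s <- setdiff(samples$sample_id, colnames(gt))
    if (length(missing_s))
      stop("sample sheet sample(s) absent from VCF: ",
           paste(missing_s, collapse = ", "))
    gt <- gt[, samples$sample_id, drop = FALSE]
    dp <- dp[, samples$sample_id, drop = FALSE]
  }
  out <- variant_set(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                     ref[keep], alt[keep], fs[keep], qd[keep], gt, dp)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant set to a VCF file
#'
#' Emits plain-text VCFv4.2 with `FS`/`QD` in INFO and `GT:DP` per sample,
#' the dialect [read_vcf()] consumes.
#'
#' @param vs a `variant_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand-bias score\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(vs$gt)), collapse = "\t"))
  n <- n_variants(vs)
  body <- character(0)
  if (n > 0L) {
    info <- sprintf("FS=%.10g;QD=%.10g", vs$site$fs, vs$site$qd)
    persample <- matrix(paste(vs$gt, vs$dp, sep = ":"), nrow = n)
    body <- paste(vs$site$transcript_id, vs$site$pos, ".", vs$site$ref,
                  vs$site$alt, ".", ".", info, "GT:DP",
                  apply(persample, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a transcript-by-sample count matrix
#'
#' Tab-separated with a header of sample ids and transcript ids in the first
#' column. Counts must be non-negative integers.
#'
#' @param path TSV file.
#' @return integer matrix with transcript rownames; library sizes are its
#'   column sums.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts table needs a transcript column and >=1 sample")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(is.na(m))) stop("counts table has missing values (ragged rows?)")
  if (any(m < 0)) stop("negative count")
  if (any(m != floor(m))) stop("non-integer count")
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a count matrix
#' @param counts integer matrix with transcript rownames and sample colnames.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TISSUES <- c("mantle", "foot")
MORPHS <- c("brown_unbanded", "yellow_banded")

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `individual_id`, `tissue`
#' (mantle/foot) and `morph` (brown_unbanded/yellow_banded). Each individual
#' must have exactly one morph and sample ids must be unique.
#'
#' @param path TSV file.
#' @return a `data.frame` sample sheet.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_samples(df)
}

validate_samples <- function(df) {
  need <- c("sample_id", "individual_id", "tissue", "morph")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(df$tissue %in% TISSUES))
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "))
  if (!all(df$morph %in% MORPHS))
    stop("morph must be one of: ", paste(MORPHS, collapse = ", "))
  mm <- unique(df[, c("individual_id", "morph")])
  if (anyDuplicated(mm$individual_id))
    stop("an individual_id maps to more than one morph")
  df[, need]
}

#' Write a sample sheet
#' @param samples sample sheet `data.frame`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(validate_samples(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ORF annotation table
#'
#' Tab-separated with columns `transcript_id`, `orf_start`, `orf_end`. ORF
#' coordinates are 0-based half-open on the transcript, must satisfy
#' `0 <= orf_start < orf_end`, and span a multiple of 3 (the open reading
#' frame includes its stop codon).
#'
#' @param path TSV file.
#' @return a `data.frame` of ORF annotations.
#' @export
read_orfs <- function(path) {
  if (!file.exists(path)) stop("ORF table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_orfs(df)
}

validate_orfs <- function(df) {
  need <- c("transcript_id", "orf_start", "orf_end")
  if (!all(need %in% names(df)))
    stop("ORF table must have columns: ", paste(need, collapse = ", "))
  if (any(df$orf_start < 0L) || any(df$orf_start >= df$orf_end))
    stop("ORF coordinates must satisfy 0 <= orf_start < orf_end")
  if (any((df$orf_end - df$orf_start) %% 3L != 0L))
    stop("ORF length must be a multiple of 3")
  if (anyDuplicated(df$transcript_id))
    stop("more than one ORF per transcript is not supported")
  df[, need]
}

#' Write an ORF annotation table
#' @param orfs ORF `data.frame`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_orfs <- function(orfs, path) {
  utils::write.table(validate_orfs(orfs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read RAD-tag read stacks from a directory of FASTA files
#'
#' One FASTA file per tag (`<tag_id>.fa` or `.fasta`); each record is one
#' read of the stack.
#'
#' @param dir directory containing stack FASTA files.
#' @return named list of character vectors of reads.
#' @export
read_stacks <- function(dir) {
  if (!dir.exists(dir)) stop("stacks directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA stack files in ", dir)
  stacks <- lapply(files, function(f) unname(read_fasta(f)))
  names(stacks) <- sub("\\.(fa|fasta)$", "", basename(files))
  stacks
}

#' Write RAD-tag read stacks to a directory
#' @param stacks named list of character vectors of reads.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stacks <- function(stacks, dir) {
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stacks)) {
    reads <- stacks[[nm]]
    names(reads) <- sprintf("%s_read%d", nm, seq_along(reads))
    write_fasta(reads, file.path(dir, paste0(nm, ".fa")))
  }
  invisible(dir)
}
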