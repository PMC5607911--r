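# Orchestration: run every stage on one input set, intersect the mantle-
# upregulated transcripts with the morph-consistent variants into the
# candidate set, and emit summary tables.

#' Intersect differential expression with segregation consistency
#'
#' Candidate transcripts are those called `up_in_mantle` that carry at least
#' one morph-consistent SNP (the polymorphism is expressed in the
#' shell-forming mantle, so only upregulation qualifies); candidate SNPs are
#' the consistent SNPs on those transcripts.
#'
#' @param dge a `dge_result` ([dge_analysis()]).
#' @param consistency an [is_consistent()] call table.
#' @return list with `transcripts` (character vector) and `snps`
#'   (`data.frame` of consistent SNPs on candidate transcripts).
#' @export
intersect_candidates <- function(dge, consistency) {
  up <- dge$transcript_id[dge$call == "up_in_mantle"]
  cons <- consistency[consistency$consistent, , drop = FALSE]
  transcripts <- intersect(up, unique(cons$transcript_id))
  snps <- cons[cons$transcript_id %in% transcripts,
               c("transcript_id", "pos"), drop = FALSE]
  rownames(snps) <- NULL
  list(transcripts = transcripts, snps = snps)
}

#' Summarise SNP and transcript counts per pipeline stage
#'
#' The four rows of the study-style summary: all SNPs that passed the hard
#' filters and their transcripts; the morph-consistent subset; the subset on
#' differentially expressed transcripts (either direction); and the
#' candidates (consistent SNPs on mantle-upregulated transcripts).
#'
#' @param kept a hard-filtered [variant_set()].
#' @param consistency an [is_consistent()] table for `kept`.
#' @param dge a `dge_result`.
#' @return `data.frame` with columns `property`, `n_snps`, `n_transcripts`.
#' @export
candidate_summary <- function(kept, consistency, dge) {
  stopifnot(inherits(kept, "variant_set"))
  if (nrow(consistency) != n_variants(kept))
    stop("consistency table and variant set are keyed inconsistently")
  tid <- kept$site$transcript_id
  de_t <- dge$transcript_id[dge$call != "ns"]
  cons <- consistency$consistent
  cand <- intersect_candidates(dge, consistency)
  sum_row <- function(property, snp_mask, transcripts)
    data.frame(property = property, n_snps = sum(snp_mask),
               n_transcripts = length(transcripts))
  rbind(
    sum_row("total", rep(TRUE, length(tid)), unique(tid)),
    sum_row("consistent", cons, unique(tid[cons])),
    sum_row("differentially_expressed", tid %in% de_t,
            intersect(unique(tid), de_t)),
    sum_row("differentially_expressed_and_consistent",
            cons & tid %in% cand$transcripts, cand$transcripts))
}

#' Percentage with half-away-from-zero rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` places, as both a number and a formatted string.
#'
#' @param numerator non-negative count.
#' @param denominator positive count.
#' @param decimals decimal places to keep.
#' @return list with `value` (numeric) and `string` (e.g. `"78.2%"`).
#' @export
report_fraction <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator < 0) stop("numerator must be >= 0")
  x <- 100 * numerator / denominator
  scale <- 10^decimals
  value <- sign(x) * floor(abs(x) * scale + 0.5) / scale
  list(value = value,
       string = paste0(formatC(value, format = "f",
                               digits = as.integer(decimals)), "%"))
}

#' Run the full candidate-discovery pipeline
#'
#' Stage order: hard filters, effect annotation, segregation filter,
#' differential expression, candidate intersection, RAD-tag search
#' (independent of the others), summary. Every intermediate is written to
#' `out_dir`. Deterministic given the inputs. Any stage error aborts with
#' the stage named.
#'
#' @param fasta,orfs,vcf,counts,samples,stacks_dir input file paths
#'   (`stacks_dir` may be `NULL` to skip the RAD-tag stage).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return object of class `candidate_run`: all stage outputs plus the
#'   summary table.
#' @export
run_all <- function(fasta, orfs, vcf, counts, samples, stacks_dir = NULL,
                    config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- with_stage("input", read_fasta(fasta))
  orf_tab <- with_stage("input", read_orfs(orfs))
  sheet <- with_stage("input", read_samples(samples))
  vs <- with_stage("input", read_vcf(vcf, sheet))
  cnt <- with_stage("dge", read_counts(counts))

  filt <- with_stage("hard-filter",
                     apply_hard_filters(vs, config, sheet))
  write_vcf(filt$kept, file.path(out_dir, "filtered.vcf"))
  utils::write.table(filt$outcomes, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eff <- with_stage("effect-annotation",
                    classify_variants(filt$kept, orf_tab, seqs))
  utils::write.table(eff, file.path(out_dir, "effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seg <- with_stage("segregation",
                    is_consistent(filt$kept, sheet, config$mode))
  utils::write.table(seg, file.path(out_dir, "segregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dge <- with_stage("dge", dge_analysis(cnt, sheet, config))
  utils::write.table(as.data.frame(dge), file.path(out_dir, "dge.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tree <- with_stage("dge", cluster_samples(cnt))
  write_dendrogram(tree, file.path(out_dir, "samples.nwk"))

  cand <- with_stage("intersection", intersect_candidates(dge, seg))
  utils::write.table(cand$snps, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hits <- NULL
  if (!is.null(stacks_dir)) {
    hits <- with_stage("radtag-search", {
      stacks <- read_stacks(stacks_dir)
      tags <- build_consensus_tags(stacks, config)
      search_tags(tags, seqs, config)
    })
    utils::write.table(hits, file.path(out_dir, "radtag_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary_tab <- with_stage("summary", candidate_summary(filt$kept, seg, dge))
  utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(filtered = filt, effects = eff, effect_tally =
                   tally_effects(eff),
                 segregation = seg, dge = dge, tree = tree,
                 candidates = cand, radtag_hits = hits,
                 summary = summary_tab, out_dir = out_dir,
                 config = config),
            class = "candidate_run")
}

#' @export
print.candidate_run <- function(x, ...) {
  cat("candidate_run\n")
  cat(sprintf("  SNVs kept after hard filters: %d (of %d)\n",
              n_variants(x$filtered$kept), nrow(x$filtered$outcomes)))
  tal <- x$effect_tally$counts
  cat(sprintf("  effects: %s\n",
              paste(names(tal), tal, sep = "=", collapse = ", ")))
  cat(sprintf("  consistent SNPs: %d on %d transcripts\n",
              sum(x$segregation$consistent),
              length(unique(x$segregation$transcript_id[
                x$segregation$consistent]))))
  cat(sprintf("  DE: %d up / %d down in mantle (dispersion %.3g)\n",
              sum(x$dge$call == "up_in_mantle"),
              sum(x$dge$call == "down_in_mantle"),
              attr(x$dge, "dispersion")))
  cat(sprintf("  candidates: %d SNPs on %d transcripts\n",
              nrow(x$candidates$snps), length(x$candidates$transcripts)))
  if (!is.null(x$radtag_hits))
    cat(sprintf("  RAD-tag hits below E-value threshold: %d\n",
                nrow(x$radtag_hits)))
  invisible(x)
}

#' @export
summary.candidate_run <- function(object, ...) object$summary
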