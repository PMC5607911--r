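---
title: "Candidate-gene discovery for a dominant/recessive shell polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene discovery for a dominant/recessive shell polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellcand)
```

# The analysis model

`shellcand` prioritises candidate transcripts for a Mendelian
dominant/recessive colour polymorphism — the motivating system is the
*Cepaea nemoralis* shell supergene, where brown/unbanded is dominant over
yellow/banded — from three independent signals computed on a de novo
transcriptome: segregation-consistent sequence variants, mantle-specific
upregulation, and sequence matches to supergene-linked RAD-tag markers.
The design assumes a small, pedigree-free sample: a few individuals of each
morph, each sequenced in two tissues (the shell-forming mantle and, as a
contrast, the foot).

## Segregation consistency

At a SNP in tight linkage with the causal locus, recessive-morph (yellow,
banded) individuals must be homozygous for the recessive haplotype's allele,
while dominant-morph (brown, unbanded) individuals may be heterozygous or
homozygous for the dominant allele. With no pedigree and only a handful of
individuals this is a *filter*, not a mapping procedure: it cannot localise,
only discard sites whose genotypes contradict the inheritance model.

Two readings of the rule are implemented because the looser one is what the
rule says literally and the stricter one is what a segregation signal
actually requires:

* `literal`: every yellow individual is homozygous, for any allele; brown
  individuals are unconstrained.
* `strict` (default): all yellow individuals are homozygous for the *same*
  allele $a$, and every brown individual carries at least one allele other
  than $a$. Sites where all individuals are identical homozygotes carry no
  signal and are rejected in both modes.

Strict consistency implies literal consistency, and the verdict is invariant
under relabelling of allele indices (both are property-tested). Genotypes
are taken per individual; the two tissue libraries of one individual must
agree, and a discordant pair is treated as an error rather than silently
resolved, because a within-individual genotype conflict signals an upstream
calling problem. Sites with a missing genotype in any individual simply fail
the filter; the upstream requirement of depth >= 10 in every sample makes
such sites rare by construction.

With 2 + 2 individuals the strict filter is weak on its own: enumerating all
$3^4$ diploid biallelic genotype assignments shows fewer than 25% of
signal-free random sites pass. The filter earns its keep only in
intersection with the expression signal — which is why the candidate set
requires both.

## Hard variant filters

Four standard hard filters precede everything else, with the removal
conditions strictly `FS > 30` (phred-scaled strand bias), `QD < 2`
(variant confidence per covering read), cluster membership, and
`depth < 10` in *any* sheet sample. Boundary values are kept in every
filter, matching the strict wording of the thresholds. A cluster is any run
of 3 consecutive SNPs on one transcript whose inclusive span
(`last - first + 1`) is at most 35 bases; the off-by-one convention is not
published by the upstream tooling, so the inclusive convention was chosen
once and pinned by a boundary test (positions {100, 120, 134}, span exactly
35, are flagged; {100, 120, 136} are not). All four filters are evaluated
for every site rather than short-circuiting so the per-class tallies in the
filter report are exact.

## Effect classification

Each kept SNV is classified against its transcript's single annotated open
reading frame (0-based half-open coordinates, length divisible by three,
stop codon included): `outside_orf`, or — by translating the affected codon
before and after substitution with the standard genetic code —
`synonymous`, `missense`, `stop_gained`, or `stop_lost`. Transcripts are
assembled mRNA contigs and are assumed sense-strand, so there is no strand
logic. Two deliberate simplifications: indels are out of scope (the variant
reader parses and skips them with a logged count), and a substitution that
destroys the ATG start codon is reported like any other codon change — there
is no start-lost class. The classifier is verified exhaustively against a
whole-ORF retranslation oracle over all 64 codons x 9 substitutions.

## Differential expression

The DE stage reimplements the standard small-sample RNA-seq workflow for a
two-group comparison:

* **TMM normalisation.** Factors from trimmed, precision-weighted means of
  pairwise M-values against a reference sample (the column whose
  upper-quartile of relative counts is closest to the mean upper-quartile),
  with 30%/5% trims on M/A values, normalised to geometric mean 1. These are
  the canonical defaults for this method; the implementation agrees with
  edgeR's `calcNormFactors` to 1e-6 in the test suite.
* **Common dispersion.** One negative-binomial dispersion $\varphi$ shared
  by all transcripts, estimated by maximising the conditional log-likelihood
  of depth-equalised counts given group totals over a bracketed search on
  $[0, 10]$. Equalisation scales each sample to the geometric-mean effective
  library size and rounds; the Poisson boundary $\varphi = 0$ is evaluated
  exactly through the multinomial limit, so degenerate inputs (all counts
  equal) return exactly 0. Tag-wise or trended dispersion is out of scope:
  with 4 + 4 samples a common dispersion is the honest choice.
* **Exact test.** Group sums of equalised counts are negative binomial with
  size $n_g/\varphi$; conditioned on their total the split follows a
  Dirichlet-multinomial-type law, and the two-sided p-value sums all
  conditional masses no larger than the observed one (so the conditional
  mode has p = 1). At $\varphi = 0$ this is exactly the binomial conditional
  test, which the suite verifies exhaustively for all totals <= 30. Totals
  above 1e5 switch to a normal approximation with continuity correction —
  at that scale the discrete enumeration is numerically superfluous.
* **Calling.** `up_in_mantle` iff linear fold change >= 4 *and*
  FDR <= 0.001 (both inclusive; the thresholds are stated as cut-off
  scores, not strict bounds). Fold changes use normalised group means with
  a pseudo-count of 0.5 per group, so zero counts cannot produce infinite
  log-ratios; the cut-off is applied to this pseudo-counted value.
* **Sample clustering.** Complete-linkage agglomeration on
  $1 - \mathrm{cor}(\log_2(\mathrm{CPM}+1))$. A constant expression vector
  has no defined correlation and is an error rather than an arbitrary
  distance.

Bit-equality with any published DE package is explicitly *not* the
contract — the doubled-smaller-tail p-value used elsewhere differs from the
minimum-likelihood definition here — the contract is calibration: under a
null simulation the fraction of p < 0.05 stays within [0.03, 0.07], and
8-fold planted changes at typical depth are recovered with >= 90% power at
<= 1% false calls (both in the acceptance suite).

## RAD-tag consensus and search

The original markers are 96-bp tag cores whose read stacks extend further.
`build_consensus` anchors all reads at position 1, takes the per-column
majority, and extends past the core until coverage drops below 2, agreement
drops below `min_agreement`, or the majority is tied. The published
procedure names no majority threshold or tie rule; 0.6 and
truncate-on-tie are this package's choices, made once and flagged as such —
truncation is preferred to guessing because a wrong extension base poisons
the downstream exact-seed search.

`search_tags` is an ungapped seed-and-extend: exact 16-mer seeds located
with a rolling 2-bit k-mer index of the transcriptome, one X-drop extension
(X = 10) per distinct (transcript, diagonal), scores +1/−2, both strands.
Significance uses Karlin-Altschul statistics
$E = K m n e^{-\lambda S}$ with $m$ the consensus length and $n$ the total
transcriptome length, uncorrected for edge effects — simple and
conservative, so E-values differ slightly from NCBI's; the threshold
semantics (`E < 1e-10`) is the contract. $\lambda$ is the positive root of
$\tfrac14 e^{\lambda} + \tfrac34 e^{-2\lambda} = 1$ by bracketed
root-finding to 1e-9, and $K$ comes from the standard lattice series over
convolutions of the step distribution truncated at relative change 1e-6;
for +1/−2 this yields $\lambda = 1.3327$, $K = 0.6210$, $H = 1.1241$,
matching the published ungapped values for this scoring. Gapped alignment
is deliberately absent: the tags are short and near-exact matches to their
transcripts, and an ungapped model keeps the statistics exact.

Seed length 16 and X-drop 10 are chosen, not inherited: a 96-bp or longer
high-identity tag virtually always contains an exact 16-mer (a single
mismatch can break at most one run of 16 in 31), while 16 is long enough
that a random seed match in a megabase-scale transcriptome is rare
(expected chance seeds per tag ~ 2e-3 in 50 kb).

## Candidates and reporting

Candidate transcripts are those called `up_in_mantle` that carry at least
one consistent SNP — upregulation only, because the polymorphism is
expressed in the shell-forming tissue. The four-row summary (total /
consistent / differentially expressed / both) counts DE in *both*
directions in its third row, mirroring how such tables are reported, while
the candidate set itself is up-only; both conventions are documented where
they apply. Reported percentages round half away from zero, the convention
that reproduces every recomputable published percentage exactly
(6/197 = 3%, 2506/40748 = 6.1%, 765/978 = 78.2%, 37/978 = 3.8%).

# The synthetic-study generator

No raw data from the motivating study is deposited, so the generator
emulates the study design and is itself first-class, tested code. Its
defaults are the study conditions: 2 brown + 2 yellow individuals x 2
tissues (8 libraries), 2000 transcripts of 300-900 bases, 50 transcripts
planted mantle-upregulated at 8-fold change, 20 transcripts carrying
planted morph-consistent SNPs (3 per transcript) of which 10 are also
planted DE, negative-binomial dispersion 0.1, log-normal baseline means
with median 200, per-sample library factors within a two-fold band, mean
variant depth 60, a background SNP rate of 2e-4 per base, 5% planted
failures per hard-filter class, and 11 RAD-tag stacks of 8 reads x 120 bp
with a 96-bp exact core and 1% per-base error beyond it. Where the study
states no value (dispersion, depth, background rate, stack geometry) the
defaults are ordinary values for tissue RNA-seq and RAD data, chosen once.

Choices worth knowing when interpreting test results:

* Each transcript carries exactly one ORF covering ~60% of its length, so
  untranslated flanks generate the `outside_orf` effect class.
* FS/QD/depth for passing sites are drawn strictly inside the thresholds
  and for failing sites strictly outside — the published record gives
  thresholds, not score distributions, so recovery of planted failures is
  exact by construction rather than probabilistic.
* Planted consistent SNPs are spaced beyond the cluster window, and
  background SNPs and planted failures avoid the supergene block, so the
  planted signal survives the hard filters by construction; recoverability
  is the generator's purpose.
* Background genotypes are Hardy-Weinberg draws independent of morph
  (property-tested by chi-square across 100 seeds); biallelic diploid
  sites only, though the filters accept multi-allelic sites.
* Everything is deterministic given `rng_seed`; the four generators use
  fixed small offsets of the one seed so a single integer reproduces the
  whole study.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artefacts (mapping error, allele-
specific expression, reference bias in genotype calls), correlated FS/QD
score distributions, linkage between background SNPs, partial or chimeric
ORF annotations, overlapping isoforms sharing reads, and library-size or
GC biases beyond a scalar factor. The pipeline's behaviour under those
conditions must be judged on real inputs.

# Problem sizes and runtime

The test and acceptance suites run the study-scale configuration where the
property demands it (2000 transcripts, 8 samples, 20 seeds for end-to-end
recovery and null calibration; 50 seeds for tissue clustering; 100 seeds
for the random-tag null) and smaller configurations (~120-300 transcripts)
for structural checks; these sizes were chosen so the full suite completes
in about a minute while keeping the Monte-Carlo bands meaningful.

# Known limitations

* The segregation filter requires complete, concordant genotypes per
  individual and discards anything else; with more individuals a
  likelihood-based formulation would retain partial information.
* The DE stage offers common dispersion only, and the exact test's
  minimum-likelihood p-value can differ from doubled-tail definitions in
  discrete edge cases.
* The search is ungapped; an indel inside an otherwise perfect tag match
  splits it into two hits that are reported separately (merged only if
  overlapping).
* Effect classes cover single-nucleotide substitutions only; frameshift
  and in-frame indel classes would require indel support throughout the
  variant model.
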