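---
title: "Methods: scanning two transcriptomes for fixed interspecific divergence"
author: "diverscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning two transcriptomes for fixed interspecific divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diverscan)
```

# The question and the statistic

When two nominal species are so closely related that single mitochondrial
markers cannot separate them, transcriptome-wide comparison offers a
different kind of evidence: the number of nucleotide sites at which the
two species are *fixed* for different states. `diverscan` quantifies this
with the differentiation index of a SNP,

$$D = |FR_m - FR_r|,$$

the absolute difference between the frequencies of the same alternate
allele in the two species, and its unweighted per-transcript mean
$\bar D$. $D = 1$ at a site means one species carries only the reference
state and the other only the alternate; $\bar D = 1$ for a transcript
means every one of its SNPs is such a fixed difference. Transcripts with
$\bar D = 1$ that additionally show protein-level Ka/Ks above 1 in their
ortholog pair are reported as candidate diagnostic markers.

# Pipeline stages and their parameters

## Isoform reduction and CDS prediction

Trinity-style assemblies contain several isoforms per unigene
(`c<contig>_g<gene>_i<isoform>`); mapping reads against all of them
splits coverage, so only the longest isoform per unigene is kept (ties
broken deterministically by the lexicographically smallest identifier).
ORFs are scanned in all six frames as maximal stop-to-stop segments,
trimmed to the first ATG for `complete` calls; segments reaching a
transcript edge are reported as `5'-partial`, `3'-partial` or `internal`.
The only filter is the conventional minimum length, `min_aa = 100`
residues, read inclusively (a 99-residue ORF is dropped, a 100-residue
ORF kept). We deliberately do not re-implement Markov-model coding
scores: the length filter is the stated criterion of the stage this
mirrors, and on the synthetic data the planted ORF is recovered exactly
without them. Coordinates are 0-based half-open on the coding strand
internally, 1-based inclusive in exported tables.

## SNP calling from text pileups

Both species' reads are assumed mapped against the *same* reference
assembly (the more complete of the two; `run_config(reference =)` names
it). The 6-column samtools text pileup is parsed in full: `^X` read
starts (whose marker character is the read's mapping quality), `$` ends,
strand-coded matches and mismatches, `*` deletion placeholders and
`+n/-n` indel suffixes (consumed and ignored — the pipeline calls SNPs
only).

Filters, in order, with defaults:

| parameter | default | meaning |
|---|---|---|
| `min_base_quality` | 30 | Phred floor per call; failing calls are dropped |
| `min_mapping_quality` | 30 | applied where the format exposes a per-read value |
| `min_coverage` | 42 | retained depth required in *each* species |
| `min_alt_reads` | 2 | reads supporting the alternate allele |
| `min_alt_frequency` | 0.20 | alternate fraction of retained depth |

Coverage 42 and the two quality-30 thresholds are the stringent screen
this pipeline is built around; the alternate-read and frequency floors
are not part of that screen but mirror the defaults of standard pileup
callers, and are configurable. The coverage requirement is read
per-species (the stricter reading) since a joint site is only
interpretable when both species are adequately covered. A joint site
needs a variant call in at least one species; the alternate allele is
defined globally, so a site where the two species call *different*
alternates — or where either species has two qualifying alternates — is
multiallelic and excluded: $D$ presumes one shared biallelic axis.

Frequencies are kept as exact ratios of integer read counts. This makes
$D = 1$ decidable without floating-point tolerance: a fixed site has
counts $(n, 0)$ and $(0, m)$, whose ratios are exactly 1 and 0.

## Differentiation classes

Per transcript we report the SNP count, $\bar D$, the number of fixed
SNPs and an `all_fixed` flag. The classification thresholds follow the
conventions of the analysis this package generalizes: "highly
differentiated" is *strictly* $\bar D > 0.9$; the fixed class is exact
equality $\bar D = 1$; and a supported fixed class requires at least
`min_fixed_snps = 3` SNPs. D histograms use left-closed right-open bins
with a closed top bin, so the fixed class sits in the last bin.

## Ortholog pairing and Ka/Ks

Orthologs are paired by reciprocal best hit between the two predicted
proteomes: a shared 4-mer prefilter, Smith–Waterman local scores under
BLOSUM62 with affine gaps (open 11, extend 1), and an acceptance
threshold expressed as an approximate Karlin–Altschul E-value
($E = Kmn e^{-\lambda S}$ with the conventional gapped parameters
$\lambda = 0.267$, $K = 0.041$; default threshold $10^{-12}$). The RBH
decision is score-rank based, so the E-value approximation only moves
the absolute cutoff; an exact score tie removes the query from pairing
rather than guessing.

Each pair is aligned at the protein level by Needleman–Wunsch global
alignment (for two sequences this is the exact optimum of the scoring
scheme, which is why no multiple-alignment heuristic is needed) and
back-translated to codons by threading each residue's source codon and
replacing gaps with `---`.

Divergence is estimated by Nei–Gojobori (1986) counting, chosen over
model-selection-based calculators because it is fully specified and
deterministic: per codon, synonymous site fractions are enumerated over
the nine single-base mutants with stop-codon mutants excluded from the
denominator at their position; differences at codons diverging at $k > 1$
positions are averaged over all $k!$ mutational pathways, excluding
pathways through stop codons (at most 6 pathways, enumerated exactly);
proportions are Jukes–Cantor corrected, $d = -\tfrac34\ln(1-\tfrac43 p)$.
Columns containing gaps, ambiguity codes or stop codons are skipped.

Two conventions complete the estimator. A pair with nonsynonymous but no
synonymous divergence has an undefined quotient; it is reported at the
conventional cap Ka/Ks = 50 with Ks back-set to Ka/50 and flagged
`capped` (the bundled published tables satisfy exactly this identity on
every capped row, which is how the convention was fixed). A proportion
$p \ge 3/4$ cannot be corrected; the pair is flagged `saturated` and no
ratio is reported. Pairs with $K_s \ge 1$ (inclusive) are flagged as
possible paralogs and excluded from selection summaries, as are
saturated pairs, whose $K_s$ cannot be bounded below 1.

## GO enrichment

The study set is the $\bar D = 1$ transcripts; the background is the
reference assembly after isoform reduction. Each term annotated to at
least `min_term_size = 3` background transcripts is tested with the
one-sided hypergeometric tail $P(X \ge x)$ — computed exactly via
`phyper`, no normal approximation — and adjusted by Benjamini–Hochberg
across all tested terms of all three namespaces jointly (nothing in the
problem suggests per-namespace stratification). Classic per-term testing
is used rather than graph-decorrelated variants: the motivating results
show blocks of sibling terms rising together, which is the signature of
non-decorrelated testing, and ancestor propagation would require an
ontology graph that is not an input of this pipeline.

# The synthetic generator: what it emulates and what it does not

The generator exists so that every downstream stage has exact ground
truth. Per transcript it plants one long ORF (guard stop, ATG, sense
codons, stop) on a random strand and then derives two species from the
ancestor:

* **fixed substitutions** at per-site rate `fixed_diff_rate` (default
  0.003 — a few per kilobase, the regime of very recently diverged
  species); species B keeps the ancestral state and doubles as the
  mapping reference, so fixed sites are $(FR_m, FR_r) = (1, 0)$;
* **shared polymorphisms** (`shared_poly_rate`, default 0.001) at equal
  frequency in both species, and **private polymorphisms**
  (`private_poly_rate`, default 0.0005 per species), with minor-allele
  frequencies uniform on [0.25, 0.5];
* inside the CDS, a per-gene $\omega$ steers the accepted substitutions'
  synonymous/nonsynonymous mix by rejection sampling (acceptance
  probabilities in ratio $\omega$), so the expected dN/dS of planted
  changes equals $\omega$ without a full codon-substitution simulator;
  changes that would create or touch a stop codon are rejected.

Sequencing is simulated per site: depth Poisson(`depth_mean`, default
80) truncated at 1; base calls binomial in the true allele frequency;
miscalls at `base_error_rate` uniform over the other three bases; base
qualities two-level (Phred 40 / Phred 20 at `bad_quality_fraction`),
which is exactly enough structure to exercise the quality filter in both
directions. The text pileup format carries per-read mapping quality only
at read-start markers, so the mapping-quality filter is modeled as a
read-inclusion probability at generation time (`low_mapq_fraction`), and
`^]`/`$` markers are emitted on a fraction of lines rather than from
tracked reads. All randomness flows from the single integer seed;
identical configurations give byte-identical outputs.

**Truth convention for exact recovery.** Because read counts are
*sampled* from the true frequencies, a planted polymorphic site can
realize counts that legitimately fail the caller's thresholds. The
generator therefore records, per truth site and species, the realized
retained counts per base — and "exact recovery" means: the caller's
joint-site set and frequencies equal what those realized counts imply
(in practice, running the joint caller on the realized count tables).
This is a genuine round-trip contract on the parser and filter chain,
not a re-derivation of the caller. Under 1% base-calling error a fixed
site will often catch a single stray read, which legitimately moves its
frequency off exactly 1; recovery under noise is therefore scored as
*detection* of the planted fixed sites among called joint SNPs
(recall/precision), not as exact $D = 1$ classification — at depth 60 a
single miscall per sixty reads is expected at roughly one site in five,
so exact-classification recall is not the meaningful quantity.

What the generator does **not** emulate: real read alignment (no
mapping errors, no coverage autocorrelation along reads), indels,
paralogy and assembly artifacts, strand bias, or inter-site linkage.
Passing tests therefore demonstrate correctness of the statistics and
the filter chain under the stated noise model, not robustness to
alignment pathology on real libraries.

# Verification experiments and problem sizes

The shipped tests and the acceptance script use deliberately modest
sizes, chosen so the whole suite exercises every stage end to end while
remaining quick to run on one CPU:

* noise-free and noisy (1% error, depth 60) recovery runs use 40–60
  transcripts of 600–1500 nt (roughly 250–330 joint SNPs); the noisy
  run enables only the two stated noise sources (miscalls and depth),
  leaving the quality-degradation knob at 0 so the measured recall
  reflects the error model rather than an additional, separately
  testable filter;
* $\omega$ recovery simulates 12 genes per class at
  $\omega \in \{0.2, 0.5, 1, 2\}$ with 500-codon CDSs and ~0.06
  substitutions/site, well below saturation; medians land within ±25%
  of truth;
* NG86 counting is checked against an independent pathway-enumeration
  oracle over all 61 sense codons and 200 random 300-codon alignments;
* enrichment power and null calibration use 100 seeded replicates of a
  1000-transcript background with a 60-transcript study set, background
  annotation rate 0.05 over 40 terms, and a 5× planted factor.

# Known limitations

* The E-value attached to RBH hits is approximate (ungapped-statistics
  formula with gapped parameters); it is a threshold, not a calibrated
  significance measure.
* NG86 with Jukes–Cantor correction underestimates rates under strong
  transition/transversion bias; the estimator is intended for the
  low-divergence regime the pipeline targets (sibling species,
  $K_s < 1$ after the paralog filter).
* The longest-ORF rule can pick a spurious ORF over a genuine short CDS
  in transcripts with long UTRs; with the 100-residue floor this is rare
  but not impossible.
* Classic per-term Fisher testing treats GO terms as independent;
  related terms rise and fall together.
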