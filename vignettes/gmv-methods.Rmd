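---
title: "Majority-vote correction of prokaryotic gene start sites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-vote correction of prokaryotic gene start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmvote)
```

## The problem

Microbial gene callers are good at finding genes but noticeably worse at
placing translation start sites: a gene typically offers several in-frame
ATG/GTG/TTG candidates upstream of its (reliably called) stop codon, and the
caller occasionally picks the wrong one. Because close relatives of a genome
carry orthologs of most of its genes, independent start-site errors can be
exposed — and fixed — by comparing orthologs: where most orthologous starts
fall in the same column of a multiple alignment and the outliers have a
caller-proposed alternative start in that very column, the consensus is very
probably right.

`gmvote` implements this *genome majority vote*. Stops are never altered; a
gene can only be reassigned to a start the caller itself proposed; and sets
without a qualifying majority are flagged, not forced.

## The closed-form error model

Let a set of $N$ orthologs have starts called wrongly, independently, with
per-gene probability $e$. The number of errors in the set is binomial:

$$p_i = \binom{N}{i} e^i (1-e)^{N-i}.$$

Two tail quantities matter. The probability that the set *looks* inconsistent
at all is $P_{\ge 1} = 1-(1-e)^N$, and the probability that the vote cannot
rescue it — a strict majority of members being wrong — is
$P_{\mathrm{maj}} = \sum_{i>N/2} p_i$. Expected error counts
$\sum_i i\,p_i = Ne$ and its strict-majority truncation give the expected
fraction of erroneous *genes* the vote corrects,
$1 - \mathbb{E}[i \mid i>N/2\ \text{mass}] / (Ne)$:

```{r}
theory_table(5, 0.05)
```

At five genomes and a 5% per-gene error rate, over a fifth of the sets carry
at least one error, but a majority of errors is a 0.12% event, so the vote is
expected to fix ~98.6% of erroneous genes. Independence across genomes is,
of course, optimistic — phylogenetic correlation makes real errors cluster —
so these numbers are a reference point, not a guarantee. The gene-level
corrected fraction exceeds one half only while $e$ is comfortably below 0.5
(it holds throughout the error-rate range reported for modern gene callers,
roughly 0.015–0.18); the *set*-level analogue
$1 - P_{\mathrm{maj}}/P_{\ge 1}$ stays above one half for every $e<0.5$.

Majorities are strict throughout ($i > N/2$; 3 of 5, 6 of 10). With a strict
majority, at most one alignment column can ever qualify, so the documented
tie-break (most votes, then the most upstream column) exists for form's sake
and cannot fire in the standard vote.

## The pipeline

1. **Inputs.** Per-genome FASTA plus per-genome gene calls carrying, for
   every gene, the chosen start, the fixed stop, and the caller's scored
   alternative starts (a documented TSV dialect; any caller that reports
   alternative starts can be adapted). Coordinates are 1-based; a start
   anchor is the first base of the initiation codon in transcript
   orientation.
2. **Pairwise identities.** All cross-genome protein pairs are scored by
   deterministic global alignment (BLOSUM62, gap open 10, gap extend 0.5).
   Percent identity is counted over aligned residue pairs and normalized by
   the longer sequence length — `pct * aligned_pairs / max(len)` — so that a
   perfect but partial match cannot outrank a full-length one. On large
   inputs an exact amino-acid 6-mer prefilter (two shared 6-mers required)
   restricts which pairs are aligned, the same way a seeded search tool
   behaves; pairs sharing no seeds are no-hits. A precomputed identity TSV
   from an external search tool can be supplied instead.
3. **Ortholog sets.** Pan-reciprocal best hits: exactly one gene per genome,
   every pair of members a *unique* mutual best hit by normalized identity.
   Exact score ties void both candidacies for that genome pair rather than
   picking arbitrarily — ambiguity is not evidence of orthology. Assembly
   seeds from a designated reference genome and checks closure over all
   member pairs; families missing from any genome yield no set. A 30%
   normalized-identity floor (configurable) prunes noise hits.
4. **Alignment.** Each member contributes its nucleotide sequence from 250 bp
   (configurable) upstream of its *earliest* candidate start through the last
   base of the stop codon, truncated at contig edges. Sets are aligned with a
   deterministic center-star progressive aligner over pairwise global
   alignments (match 2, mismatch −3, gap open 5, gap extend 2); the center is
   the row with the highest mean pairwise identity, ties broken by genome id,
   and merging follows once-a-gap-always-a-gap. An adapter accepts aligned
   FASTA from any external aligner instead. Start anchors map to alignment
   columns through per-row coordinate maps; an anchor can never sit on a gap
   of its own row.
5. **Vote.** All chosen starts in one column: accepted as is. A strict
   majority in one column with every remaining member holding an alternative
   there: the minority is reassigned (codons re-read from the genome, never
   copied from the calls file). Otherwise: flagged inconsistent and left
   untouched — downstream files stay complete; the flag carries the
   "no prediction" meaning. Candidate columns are drawn from the whole
   aligned span rather than only the upstream window; since candidates must
   be caller-proposed starts anyway, this restricts nothing and needs no
   extra parameter.

A *preserve* mode refines a curated map with the help of a second,
alternative-bearing call source: curated starts that already coincide, or
that lack a strict majority, are left alone; a curated majority column pulls
the minority onto the alternative source's start in that column, and only if
every minority member has one there.

## The synthetic generator

`simulate_gmv()` generates the conditions the model describes: `F` ortholog
families shared by `N` genomes, each family an ancestral gene carrying 2–4
in-frame candidate starts (ATG/GTG/TTG at realistic 80/12/8 frequencies)
over one ORF, genomes derived by independent per-site substitutions
(default divergence 0.025 per branch, i.e. ~95% pairwise nucleotide
identity — high enough that orthology and alignment are unambiguous, so the
recovery checks isolate start-call error rather than alignment error), and
predicted starts flipped to a uniformly chosen wrong candidate with
independent probability `e` (default 0.05, the low end of reported caller
error rates). Substitutions are suppressed at candidate codons and the stop,
and reverted where they would create an in-frame stop, keeping the planted
truth well defined in every genome.

What it deliberately does **not** emulate: indels (alignment columns map
affinely; indel handling is exercised by dedicated alignment fixtures),
correlated errors along the phylogeny, compositional bias, gene gain/loss,
and paralogy. Passing recovery checks therefore demonstrate that the
pipeline implements the model faithfully — not that real genomes satisfy the
model's independence assumption.

## Evaluation statistics

`consistency_report()` counts sets initially consistent, made consistent,
and the ceiling (sets with *some* column carrying a start for every member).
`validation_report()` scores a run against validated starts of a reference
genome, keyed by (contig, strand, stop): `GP` validated genes whose original
start was wrong, `TP` corrections onto the validated start, `FP` previously
correct starts moved away, `E = FP/(TP+FP)`, `S = TP/GP`. When no false
positive occurs, `E` is reported as undefined by default; an optional
pseudo-count mode reports `(FP+1)/(TP+FP+1)` instead — transparency first,
the ad hoc fix as an explicit choice. Cross-genome scoring transfers the
validated start's alignment column through the reference row and asks
whether the consensus column matches it; this requires the validated anchor
to fall inside the reference member's extracted window.
`codon_change_report()`, `diversity_report()` (per-set minimum and mean
normalized identity, run-level median of minima) and `yield_and_increase()`
($M$ = smallest per-genome gene count, $Y = O/M$, $I$ = sets made consistent
per actual set) complete the table set, and the projection formulas
$n_I = Y\,I\,M$ and $R = C/(MN)$ extrapolate them to genome collections.

## Numerical and design choices

* **Strand handling.** Minus-strand anchors are the *rightmost* genomic base
  of their codon, so one rule — first codon base in transcript orientation —
  covers both strands and survives reverse-complement round trips.
* **Gene identity across sources** is keyed by (contig, strand, stop), since
  stops are treated as fixed.
* **Alternative lists are taken as given**; no score threshold is applied by
  default (a minimum-score filter is a config option). Non-canonical start
  codons are accepted with a warning and tallied separately.
* **Determinism.** The pipeline proper contains no randomness; randomness is
  confined to the generator, which requires an explicit seed and restores
  the RNG state on exit. Repeated runs are byte-identical, and every stage
  can be re-run from its predecessor's on-disk artifact with identical
  output.
* **Degenerate inputs.** Empty ortholog yield produces an empty decisions
  table with a warning; sets whose curated member is missing in preserve
  mode are flagged `no_primary`; anchors outside an extracted window name
  the offending gene.

## Problem sizes used by the checks

The parameter-recovery check runs 5 genomes × 5000 families at `e = 0.05`
(~25,000 genes, ~1250 planted errors) and compares the recovered
fraction-of-families-with-an-error against $1-(1-e)^N$ and the
corrected-error fraction against the closed form, each within three
Monte-Carlo standard errors (delta-method for the ratio). Oracle-equivalence
checks run the vote against a literal column-enumeration evaluator on 210
randomized alignments ($N \in \{3,5,10\}$) and set assembly against
exhaustive one-gene-per-genome tuple search on instances of up to 4 genomes
× 6 genes. The acceptance script reports the same quantities at 2000
families.

## Known limitations

The built-in center-star aligner is adequate for the narrow task of mapping
start anchors across closely related sequences; for distant genomes a
dedicated MSA tool via the aligned-FASTA adapter is the better choice. The
seed prefilter assumes orthologs share exact 6-mers — true at the identity
levels where majority voting is sensible, but not at twilight-zone
divergence. Orthology is single-copy by design: recent duplications void
families (deliberately) rather than resolving them. And the error model's
independence assumption means projected correction rates are upper bounds
for clades with strongly correlated annotation errors.
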