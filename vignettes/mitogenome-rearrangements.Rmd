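---
title: "Detecting rearrangement signatures in plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rearrangement signatures in plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Plant mitochondrial genomes rearrange through recombination between
dispersed repeats. `mitoshift` implements the analyses by which such
rearrangement leaves detectable traces in a single assembled circular
chromosome:

1. **Cis/trans intron classification.** A group II intron whose host
   gene is broken by a rearrangement keeps functioning when its two
   halves are transcribed separately and joined in trans. An intron is
   named `gene + "i" + p`, where `p` is the reference-CDS nucleotide
   after which it is inserted (`nad1i728` sits after position 728 of the
   nad1 CDS). Classification works from exon placements: the intron
   between two consecutive exons is *cis* when the exons lie on one
   strand, in transcription order (origin wrap allowed on a circular
   chromosome), separated by at most `max_intron_len`; any strand flip,
   order violation or excessive separation makes it *trans*. Five
   introns (nad1i394, nad1i669, nad2i542, nad5i1455, nad5i1477) are
   trans-spliced in the common ancestor of seed plants; because a
   reversion from trans to cis splicing is considered implausible, these
   are forced to *trans* even when their exons happen to be contiguous
   (the `override_applied` flag records this).
2. **Breakpoint synteny.** For a trans-spliced intron, the retained 5'
   and 3' ends of the ancestral cis intron are located by aligning a
   cis-spliced relative's intron against the windows flanking the two
   split exons; the unmatched middle is reported as lost sequence.
3. **Repeat-mediated recombination support.** For each repeat pair
   shorter than the library insert, four references are built (two
   principal, two alternative arrangements: repeat plus 300 nt flanks);
   a read pair supports recombination when it maps end-to-end to an
   alternative, fails on both principals, and spans the novel junction
   with at least `min_anchor` nt in each flank.
4. **MTPT scanning.** Plastid-derived insertions (> 100 bp, >= 80%
   identity) are found by local alignment against the plastome and
   merged when overlapping on mitogenome coordinates; plastid genes they
   carry are classified intact / pseudo_truncated / pseudo_frameshift /
   pseudo_internal_stop.
5. **Chimeric-gene screen.** Gene-conversion tracts between taxon pairs
   of a masked alignment are detected by a permutation test; the gene is
   split at detected breakpoints and each region's phylogenetic origin
   is assigned from a bootstrap neighbor-joining tree with the BS >= 70
   decision rule.

# Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_len` (repeats) | 50 nt | dispersed repeats longer than 50 bp |
| `min_ident` | 80 % | identity threshold for all homology searches |
| `mtpt_min_len` | 101 nt | insertions strictly longer than 100 bp |
| `insert_cap` | 350 nt | library insert size; longer repeats cannot be spanned |
| `flank` | 300 nt | context on each side of a repeat in the conformation references |
| `max_intron_len` | 10,000 nt | longest separation still compatible with cis splicing (plant mitochondrial cis introns are at most a few kb; observed trans fragments are separated by ~14 kb or inverted) |
| `max_mismatch` | 2 | per-mate mismatch cap for end-to-end read placement |
| `min_anchor` | 5 nt | junction-spanning requirement per flank |
| `bs_threshold` | 70 % | bootstrap support needed for an origin verdict |
| `penalty_scale` | 1.5 | mismatch penalty scale of the conversion screen (below) |

# The homology engine

Every alignment step runs through one seed-and-extend engine
(`localAlignAll`): exact 11-mer seeds on both subject strands, clustered
by diagonal; ungapped X-drop extension (match +1, mismatch −2, X-drop
20) trimmed to the maximal-scoring segment; collinear candidates
separated by a small gap on both axes are chained (this is what lets a
single small indel sit inside one reported hit); imperfect candidates
are refined with an exact local alignment over the bounded candidate
region (affine gaps: opening 5, extension 2, so a gap of length *g*
costs 5 + 2*g*). Perfect ungapped candidates skip the refinement — an
all-match diagonal is provably optimal over its own interval pair. In
place of database e-value statistics the engine applies a minimum score
derived from `min_len` and `min_ident`; at the scales involved the
length and identity filters dominate. Circular sequences are linearised
with an origin extension (up to 5 kb) and hits are re-wrapped, with
`start > end` encoding an origin-spanning feature.

# The conversion screen statistic

The alignment is condensed to polymorphic columns. For each unordered
taxon pair, a column scores +1 where the pair agrees and −P where it
disagrees, with P = `penalty_scale` · ceil((1 − p̂)/p̂) and p̂ the pair's
disagreement fraction over polymorphic columns. Maximal positive
segments (greedy Kadane enumeration of non-overlapping segments) are
candidate conversion tracts.

Two properties of this statistic matter:

* With `penalty_scale` = 1 the expected per-column score is
  approximately zero for *every* pair, by construction of the ceiling
  penalty. Segment maxima of a zero-drift walk grow like √n, so genuine
  tracts drown in random-walk noise. Any scale above 1 makes the drift
  strictly negative (≤ (1 − p̂)(1 − scale)), giving segment maxima
  exponential tails. The default 1.5 balances sensitivity to long weak
  tracts against short strong ones; the parameter is configurable.
* Taxon pairs differ greatly in p̂, so their raw segment maxima are not
  comparable; a family-wise null taken as the raw maximum across pairs
  is dominated by the closest pairs. The implemented null therefore
  permutes column order (`n_perm` times, one permutation shared by all
  pairs), records each pair's best segment score, standardises by the
  pair's own null moments, and uses the maximum standardised score
  across pairs as the family-wise statistic. Reported p-values are
  `(1 + #{null ≥ observed})/(n_perm + 1)`; under the null the best
  fragment's p-value is uniform, which the test suite verifies
  (Kolmogorov–Smirnov against U(0,1) over 200 replicate alignments).

This screen is a declared approximation in the GENECONV family; it does
not reproduce GENECONV's inner-fragment statistics.

# Origin assignment

Trees are neighbor-joining on Jukes–Cantor distances (pairwise deletion;
a saturated pair falls back to its p-distance and is flagged), with
supports from column-resampled bootstrap replicates; this is the
package's stand-in for maximum-likelihood estimation, with the BS >= 70
decision rule retained. `assignOrigin` walks rootward from the focal tip
to the smallest ancestral clade with support at or above the threshold
and at least one other taxon: all-native members give *native*, members
of a single foreign set give *foreign*, anything else *unresolved*.
Skipping unsupported nodes (rather than failing on them) makes the call
robust to a poorly supported immediate sister while remaining
conservative: a verdict is never issued below the support threshold.
Regions too short to contain a variable column are reported unresolved,
mirroring how a 13 bp terminal region cannot carry origin information.

# What the synthetic data emulate

`makeMitogenome` builds a circular chromosome (default 60 kb, 44% GC)
by laying out blocks with random spacers: genes whose introns are
planted either inline (cis) or split — the downstream half relocated,
optionally inverted, with a configurable middle-loss deletion (the
default set includes a 2 kb reference intron losing 866 nt, and a
contiguity-preserving plant of the ancestrally trans-spliced nad1i394 to
exercise the override); repeat pairs of 60–400 bp at 90–100% identity;
and 150–2,500 bp segments copied from a generated toy plastome at 0–5%
divergence. The layout guarantees the planted truth: split-intron halves
on a shared strand are separated by more than `max_intron_len` plus a
margin, and the two copies of each dispersed repeat lie at least 1 kb
apart (interspersed repeats are dispersed by definition, and the
recombination screen's flank geometry assumes the copies' contexts are
distinct). The first and last three bases of every planted intron are
forced to differ from the continuing CDS bases, so exon alignment
endpoints are exactly the planted boundaries (real splice boundaries are
likewise not CDS-like); without this guard, chance matches would shift
intron insertion positions by a base or two and change intron names.

`simulateReads` draws fragments uniformly on each weighted circle with
Normal(300, 30) insert lengths truncated (by rejection) at twice the
150 nt read length, and applies a 0.001 per-base error rate.
`makeRecombinedGenome` applies the recombination event itself: for an
inverted pair the intervening segment is reverse-complemented (one
circle, an involution); for a direct pair the single circle excises into
two circles, one per alternative junction, conserving total length.

`evolveClades` evolves a 1,506 nt gene down a 12-taxon topology
(native clade containing the focal taxon at 3–5% divergence, a foreign
donor clade at ~8.6% — the background divergence — plus a distant
lineage and an outgroup), then copies the donor's 350 nt segment
(positions 1138–1487) into the focal taxon and applies 2% post-transfer
divergence. There are no indels, so alignment columns equal gene
positions.

What passing tests therefore do **not** show: performance under
alignment error, indels and missing data; RNA-level confirmation of
splicing; repeat copies diverged by indels (read counting is ungapped by
design, mirroring an end-to-end/no-discordant mapping contract);
realistic mutation spectra, coverage bias or quality-score structure;
or recovery of any particular real genome's feature counts.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; `start > end` encodes an
  origin wrap and is rejected on linear sequences.
* `">100 bp"` is implemented as length >= 101; the intact-gene coverage
  threshold is 0.95 (configurable) since only "substantial" truncation
  pseudogenises.
* Repeat and MTPT totals count the union of copy intervals, never the
  sum, so overlapping copies are not double-counted.
* Read-pair placement requires a unique best placement; ties are
  discarded rather than broken arbitrarily.
* An exact repeat of the full genome against itself (the trivial
  identity diagonal) is removed before repeat pairing; self-overlapping
  hits are discarded because repeat copies must be disjoint.
* Identical sequences in an alignment: pairs with zero disagreement are
  skipped by the conversion screen; neighbor joining still returns a
  tree with zero-length terminal branches.

# Problem sizes used by the test suite

The shipped tests run the classification loop on one hundred 28 kb
genomes with seven planted introns each; recombination screening on
2,000 read pairs over a 15–20 kb genome with a binomial spanning
expectation computed from the truncated insert distribution and a
coupled-pool construction for the monotonicity check; the chimera null
on 200 replicate alignments at 1,000 permutations; and the planted-tract
recovery on 50 replicates with 300 bootstrap replicates per origin call.
These sizes were chosen to make the statistical checks sharp at
interactive runtimes; every threshold they test is the analysis default.

# Known limitations

* The conversion screen's penalty and null are approximations; tract
  boundary estimates are maximal-scoring segment ends and can exceed the
  true tract by a few polymorphic sites in either direction.
* Detection power for short tracts is bounded by the tract's own
  post-transfer mutation draw: a 350 nt tract at 2 percent
  donor-recipient divergence carries Binomial(350, 0.02) mismatches, and
  draws in the upper tail (eleven or more, roughly a tenth of cases)
  leave the agreement run indistinguishable from the family-wise
  permutation null at any penalty scale. Simulated recovery at that
  calibration is therefore about 85 percent, with every detected tract
  assigned the correct foreign origin downstream.
* Divergent repeat copies are screened against the copy-A repeat
  sequence with the mismatch cap absorbing copy divergence; highly
  divergent copies (near the 80% floor) lose sensitivity.
* Direct-repeat recombination on a circle produces two product circles;
  stoichiometry of conformations is not estimated, only read-pair
  support counts.
* Breakpoint synteny assumes the reference intron is largely colinear
  with the retained ends; nested rearrangements inside an intron are
  reported as larger middle loss.
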