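---
title: "Methods and design notes for riderscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for riderscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riderscout annotates full-length LTR retrotransposons in genome
assemblies, clusters them into families, dates their insertions from
LTR divergence, tests their promoter regions for cis-regulatory-element
(CRE) enrichment, summarises cross-genome homology screens, and
computes per-locus epigenomic summaries. This vignette records the
models, the parameters that matter, and the design decisions that were
genuinely open, in the package's own words.

## The structural model of a full-length element

An intact LTR retrotransposon consists of two long terminal repeats
(LTRs) in direct orientation flanking an internal coding region. At
integration the target site is duplicated, leaving a short direct
repeat (TSD, 3-20 bp) immediately outside both element ends; the
element itself canonically starts with `TG` and ends with `CA`; and
reverse transcription is primed by a host tRNA whose 3' end anneals to
the primer binding site (PBS) just downstream of the 5' LTR. A solo
LTR (the product of intra-element recombination) has no partner repeat
and must not be called full-length; the same holds for 5'-truncated
copies. The detector (`annotate_genome()`) operationalises exactly
this anatomy:

1. **Repeat-pair discovery** (`find_repeat_pairs()`): exact 20-mer
   seeds shared by two positions at a compatible separation are
   extended along their diagonal by gapless x-drop alignment
   (match +2, mismatch -2, x-drop 7) and trimmed to the
   maximal-scoring segment. Seeds of 20 bp make an 80%-identity 100-bp
   LTR pair (the hardest admissible case) contain an exact seed with
   probability above 0.98, so the seeding stage is not the recall
   bottleneck. The extension is gapless: insertion/deletion divergence
   between two LTRs of one young element is rare, and the TSD
   refinement step re-anchors boundaries anyway.
2. **TSD refinement** (`detect_tsd()`): all exact duplications of
   length 3-20 between the 80-bp windows spanning the two element
   boundaries are enumerated. A duplication is admissible only when it
   flanks a *consistent* adjusted element: LTR lengths stay in bounds,
   the adjusted termini still show `TG...CA` within one mismatch, and
   boundary shifts larger than the maximal TSD length must not change
   the gapless LTR-pair score by more than the x-drop value in the
   unfavourable direction. Without the consistency predicate, chance
   k-mer duplications inside the 80-bp windows would regularly
   out-compete the true TSD (in an 80x80 window pair one expects more
   than one chance 6-mer duplication); with it, the expected number of
   admissible spurious duplications longer than a typical 4-6 bp TSD
   drops well below 0.1 per element. The longest admissible
   duplication wins, ties going to the smallest total boundary
   adjustment, then the leftmost start.
3. **Terminal motif** (`check_terminal_motif()`): mismatches against
   `TG` and `CA` are summed over both termini and compared with the
   allowance (default 1).
4. **PBS screening** (`detect_pbs()`): the reverse complement of each
   tRNA's 3'-terminal 40 nt is Smith-Waterman-aligned (match +1,
   mismatch -1, gap -2) to the 60-bp window downstream of the 5' LTR;
   a hit must have alignment length 8-40, offset 0-10 from the LTR
   end, and identity at least 0.8. Strand is assigned from the PBS:
   a direct LTR pair looks identical on both strands, but the PBS sits
   downstream of the 5' LTR only in the element's own orientation, so
   the orientation whose PBS scores better names the strand. Elements
   with no PBS in either orientation are reported on `+` and fail the
   quality filter anyway.
5. **ORF counting** (`count_orfs()`): six-frame ATG-to-stop scan,
   minimum 300 bp, counted but not required (the default minimum ORF
   count is 0); no splicing model.
6. **Quality filter**: `quality_pass` requires TSD present, terminal
   motif acceptable, and a PBS hit. The upstream tooling this
   parameterization follows does not publish its quality predicate;
   this concretization (the three structural hallmarks that
   distinguish a genuine integration event) is a package decision, not
   imported ground truth. Externally produced protein-domain hits can
   be attached via `domain_table` and are annotated, never required.
7. **Overlap resolution** (`resolve_overlaps()`, mode `"no"`): among
   mutually overlapping calls the highest LTR identity is kept
   greedily (ties: longer, then leftmost).

Default parameters (LTR length 100-5000 bp, start-to-start distance
4000-30000 bp, TSD 3-20 bp, vicinity 80 bp, x-drop 7, one motif
mismatch, PBS radius 60 bp with alignment lengths 8-40 and offsets
0-10, quality filtering on, no ORF requirement) are the parameter
set this workflow standardises on; `min_pair_identity`
defaults to 0.80, the conventional floor of structural LTR detectors,
and `mindist`/`maxdist` are interpreted as 5'LTR-start to 3'LTR-start
distances (the upstream tool's semantics).

## Identity, clustering and family assignment

`global_identity()` aligns two sequences end-to-end
(Needleman-Wunsch, match +2, mismatch -2, gap open -10, gap extend
-1) and reports matches divided by alignment columns, excluding
terminal-gap columns from the denominator, the identity notion of
greedy centroid clustering tools. One deliberate deviation from a
"free end gaps" formulation: end gaps carry the ordinary gap cost
during alignment. A genuinely ends-free score-maximising alignment of
two *unrelated* sequences degenerates to a short chance dovetail
(20-odd columns at 85%+ identity), which would let unrelated sequences
join families; penalised end gaps force the full-length comparison,
at the conservative price that a long overhang of one sequence dilutes
identity. For the intended comparisons - full-length elements of one
family against each other or a reference - overhangs are a few bases
and the effect is negligible.

`cluster_greedy()` is the classic length-sorted greedy centroid
algorithm (process in order of decreasing length, join the first
centroid at >= 0.85 identity on either strand, else found a cluster);
`assign_family()` keeps elements whose full-element identity to a
reference exceeds 0.85 *strictly*.

## Insertion dating

After insertion the two LTRs, identical at integration time, diverge
neutrally. `date_element()` aligns them, takes the p-distance
`d = 1 - identity` and converts it with the molecular clock
`t = d / (2r)`, `r = 6.96e-9` substitutions per site per year (the
tomato synonymous-site rate). Raw p-distance is used by default
because it reproduces the printed class boundary arithmetic
(`0.02 / (2 x 6.96e-9) = 1.44 My`, reported as 1.4 My); a
Jukes-Cantor correction is available via `correction = "JC"` for users
who prefer a multiple-hit model. Identity classes are `98-100`
(>= 0.98), `95-98` ([0.95, 0.98)) and `85-95` ([0.85, 0.95)); the
lowest class is labelled from 85 because family membership already
requires > 85% identity, so 85 is the bound actually attainable for
the oldest class even where an "80-95" label circulates for it.
Identity for dating excludes terminal-gap columns only; internal gap
columns count as differences.

## Phylogenetics

`tn93_distance()` implements the Tamura-Nei distance from the two
transition proportions and the transversion proportion with empirical
base frequencies averaged over both sequences, dropping gap/`N`
columns pairwise; non-positive logarithm arguments return `Inf` with a
`saturated` attribute and such pairs are rejected by `nj_tree()`.
`nj_tree()` is the classic Saitou-Nei agglomeration with two
determinism rules: Q-criterion ties are resolved toward the
lexicographically smallest label pair (internal nodes inherit the
smallest leaf label they contain), and negative branch lengths are
clamped to zero with the deficit moved to the sibling branch so the
pair distance is preserved. Branch lengths are written with 12
decimals so that `patristic_distances(nj_tree(D))` reproduces an
additive `D` to 1e-9 through the Newick text; 6 decimals would bound
the round-trip at about 1e-6. Newick parsing and patristic path sums
go through `ape`.

## CRE scanning and enrichment

`scan_motifs()` reports every exact IUPAC match (overlaps allowed),
1-based inclusive, forward strand by default - promoter logic is
directional - with a `both` mode that reports minus-strand matches at
forward coordinates. The shipped catalogue carries the two literal
MYB-core variants (`CTGTTG`, `CTGTTA`); the CGCG box (`VCGCGB`),
ABRE-like (`YACGTG`), CE3 and CBF/DRE entries are PLACE-style
consensus defaults, flagged as such in the catalogue, because only the
motif families and their positions, not the exact consensus strings,
are established.

`fisher_enrichment()` counts, per motif, the sequences containing at
least one hit (presence mode; a total-occurrence mode is available,
since "motif count data" is ambiguous) and tests the 2x2 table with
the two-sided exact test, summing hypergeometric probabilities not
exceeding the observed table's (with the conventional 1e-7 relative
tie guard). The odds ratio is the sample OR with a 0.5 Haldane
correction when any cell is zero. `enrichment_report()` runs two
backgrounds: 400-bp gene promoters (`promoter_background()`, minimum
50 bp after edge truncation) and random genome loci of the foreground
length with the foreground's strand vector (`sample_random_loci()`,
chromosome chosen proportionally to its valid starts, loci with more
than 10% `N` resampled). Random loci are *not* excluded from
overlapping annotated elements - with a realistically sparse family
the effect is second order and no exclusion rule is standard.

## Homolog screens and per-locus summaries

The homolog module consumes BLAST outfmt-6 tables; the family filter
keeps hits with percent identity >= 50 and alignment length >= 50% of
the query. Whether a "50% coverage/homology" criterion means percent
identity or query coverage per hit is genuinely ambiguous in common
usage; this package reads it as percent identity, and the alternative
is one configuration change.
LTR-query hits are binned into long (350-450 bp) and short
(150-300 bp) alignment-length regimes after filtering. Reciprocal
confirmation takes the top 5 reverse hits by bitscore (the "top
reciprocal hits" rule made concrete) and requires >= 1 bp overlap with
a known family locus. A naive seed-and-extend scanner
(`scan_homologs()`) generates outfmt-6-shaped tables for
self-contained fixtures; it computes no E-values and is not a
substitute for a real aligner.

Methylation is summarised as weighted methylation (read sums, not the
mean of per-site levels), the summary robust at low coverage; loci
with no qualifying cytosines in a context are `NA`, never 0. siRNA
abundance is RPKM with a >= 1 bp overlap rule and the 21-22-nt class
as the union of lengths 21 and 22. Chromatin compartments are
assigned by element midpoint (elements may straddle boundaries; the
midpoint is the least arbitrary single-label rule), gene proximity is
boundary-to-boundary and strand-ignorant with a 2000-bp window, and
table percentages are rounded half-up to one decimal (the rounding
convention of genome-annotation summary tables). In-silico PCR requires a forward-primer site
and a downstream reverse-primer site (no indels) within a 5-kb
product, with the mismatch budget applied per primer - the reading
of "3 mismatches allowed" that most plausibly parameterises each
primer match; a total-budget mode is available. Pericentromere
boundaries are always consumed as user-supplied intervals, never
derived.

## The synthetic-data generator

`build_genome()` plants intact elements, solo LTRs and 5'-truncated
copies at non-overlapping uniform positions in an i.i.d. background
(default GC 0.38, a plant-genome-like value), each intact element
carrying a TSD of 4-6 bp (the integrase-typical range) duplicated on
both flanks, a perfect 18-nt PBS at offset 2, an ORF of ~900 bp, a
polypurine tract, and `TG...CA` termini re-enforced after mutation.
Each LTR copy is independently point-mutated at half the requested
divergence, so the expected pair identity is `1 - divergence`;
mutations are substitutions only, keeping the realized identity on a
clean binomial model, and the *realized* identity is recorded by
re-alignment rather than trusting the nominal rate.
`sample_ltr_pairs_by_class()` additionally re-draws pairs until the
realized identity falls inside a requested identity class, so
class-count fixtures are exact by construction.

What the generator does not emulate: nested insertions, repeat-rich
backgrounds, indel divergence (available as an explicit option is out
of scope), solo-LTR formation dynamics, and read-level methylation or
small-RNA data (per-record tables are generated directly). Passing
tests on this generator therefore demonstrate correct *structural*
logic and calibrated statistics, not performance on repeat-nested real
chromosomes.

A deterministic synthetic reference element
(`synthetic_rider_reference()`) reproduces the documented architecture
of the family's reference element - 4867 bp, 400-bp LTRs, and the
promoter CRE layout (CGCG box at 89-94, `CTGTTG` at 176-181, `CTGTTA`
at 204-209, ABRE-like at 332-337, CE3 from 357) - for positional
fidelity tests. It is generated in code, labelled synthetic
everywhere, and stands in for the real accession, which is not
bundled.

## Test problem sizes and statistical calibration

The test suite runs the detector-recovery property on 25 seeded
100-kb genomes with 4 intact elements (divergences 0.01-0.12), one
solo LTR and one truncated copy each - small enough to keep the whole
suite around a minute, large enough that 100 planted elements bound
the recall estimate usefully. The type-I-error property of the
enrichment pipeline uses 200 null replicates of 71 foreground vs 300
background sequences of 180 bp scanned for a 4-bp core motif; with the
occurrence probability per sequence computed exactly (prefix-automaton
transfer matrix, 0.504 at 180 bp) the exact size of the two-sided
Fisher test at alpha 0.05 under this design is 0.048, calibrated
analytically before any test was run so that the observed rejection
fraction is expected within the acceptance band rather than below it
(Fisher's exact test is conservative; small designs have size nearer
0.03).

## Known limitations

* The detector is gapless end to end; LTR pairs whose divergence is
  dominated by indels will be recovered with degraded boundaries.
* Nested or tandem element arrangements are resolved greedily, not
  dissected.
* `scan_homologs()` has no significance model.
* Identity of heavily length-mismatched pairs is diluted by design
  (see the clustering section); use dedicated tools to align solo
  LTRs against full elements.
* Protein-domain annotation is consumed, never computed: profile-HMM
  scanning is out of scope.
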