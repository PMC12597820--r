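---
title: "Charting telocentric chromosome ends: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting telocentric chromosome ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind each
analysis: the procedures, their assumptions, the tunable parameters, the
synthetic data used to validate them, and the design decisions taken where
the underlying methodology left choices open.

## Coordinate convention

All coordinates inside the package are 0-based half-open `[start, end)`.
File formats that use 1-based inclusive coordinates (AGP, RepeatMasker
`.out`, GFF3) are converted at the parse boundary and converted back on
write; PAF and BED pass through unchanged. A single arithmetic convention
across modules removes the most common source of off-by-one drift in
interval pipelines.

## Telomere detection

Mouse chromosomes end in arrays of the canonical telomere repeat
`TTAGGG`. The detector scans one end of a sequence for all (possibly
overlapping) motif occurrences and chains them from the terminus inward: an
occurrence joins the chain while the motif-free gap to the previous
occurrence is at most `max_interruption` (default 60 bp, ten motif units).
The call is the maximal chained segment whose motif coverage (purity) is at
least `min_purity` (default 0.9); if purity falls short, innermost
occurrences are trimmed until it is met. Calls shorter than `min_length`
(default 300 bp) are discarded, and the outermost occurrence must lie
within `end_slack` (default 1 kb) of the sequence terminus.

Orientation: the G-rich strand points outward, so the right end is searched
for `TTAGGG` and the left end for its reverse complement `CCCTAA`. A flag
(`either_orientation`) accepts either motif at either end. Left-end
detection literally runs the right-end detector on the reverse complement,
which makes the strand-symmetry property (`detect_telomere` on a
reverse-complemented genome yields mirrored calls of identical length) true
by construction rather than by approximation.

The defaults are chosen to call essentially pure terminal arrays robustly
while rejecting interstitial motif scatter: a purity threshold of 0.9
rejects arrays in which more than every tenth motif is disrupted, and the
60-bp interruption allowance tolerates isolated indel/substitution damage
without bridging into unrelated motif occurrences. For heavily degraded
arrays (e.g. 5% per-base substitution) the caller remains usable with a
lowered purity threshold; the test suite checks a 3,000-bp array at 5%
substitution against a brute-force coverage-mask oracle and recovers the
length within 120 bp.

## Centromeric region delineation

In telocentric genomes the centromere core is the minor satellite (120-bp
monomer) and the flanking pericentromere is the major satellite (234-bp
monomer); the two together are treated as one "centromeric region" adjacent
to the telomere. The delineator merges all major/minor satellite
annotations on a chromosome whose gaps are at most `merge_gap` (default
100 kb) and returns the merged block nearest the telomere-bearing end, with
the major and minor bp totals inside it. This is deliberately a merged
annotation block rather than a sliding-window density call: it is exactly
reproducible from the annotation table and matches the "satellite block
next to the telomere" definition. Satellite annotations are recognized by
name (`GSAT_MM`/`MajSat`, `SYNREP_MM`/`MinSat`, both configurable), since
RepeatMasker satellite class labels alone do not distinguish major from
minor arrays.

Coverage anomalies (possible collapsed duplications) are flagged as maximal
intervals inside the centromeric regions where per-base depth exceeds
`factor` (default 2) times the genome-wide mean — at 35x coverage the
threshold is 70x. Depth is supplied as a per-base track; the package does
not compute depth from alignments.

## Subtelomere tokenization and TLC patterns

Between the telomere and the centromeric satellite, telocentric chromosome
ends carry a characteristic ordered structure: an L1 LINE element, then
arrays of the TLC subtelomeric repeat punctuated by other elements, ending
in the minor satellite. The profiler tokenizes all annotations within
`window` (default 5 Mb) of the telomere's inner boundary, ordered by
distance from the telomere, drops features shorter than `min_feature`
(default 100 bp), and merges adjacent identical tokens (summing TLC array
bp). TLC repeats are identified by annotation name against a configurable
set, mirroring practice where the TLC monomer is annotated by targeted
BLAST rather than by the standard repeat library. Simple-repeat identity is
the unit string normalized to its lexicographically minimal rotation, so
`(TATA)n` and `(ATAT)n` compare equal.

Patterns are assigned from the tokens between consecutive TLC arrays:
`LTR_punctuated` when every separating stretch contains an LTR token,
`single_simple` / `double_simple` when every stretch is exactly one / two
simple-repeat tokens, `nonstandard` otherwise — including ends with no
separated TLC arrays at all, which is the observed situation on exceptional
chromosomes where various LINEs/SINEs/LTRs follow the telomere with no
clear order. The 5-Mb window is a free parameter: there is no established
definition of how far from the telomere a punctuating element still belongs
to the subtelomeric structure, and the known exceptional chromosomes show
relevant features out to a few megabases.

## Placement of unplaced satellite contigs

Unplaced telomere/satellite-bearing contigs are assigned to chromosome
scaffolds using the within-array similarity premise: a satellite array is
more similar to the rest of its own chromosome's array than to other
chromosomes' arrays. Alignments below `min_identity` (default 0.95,
matching the 95%-identity mapping cutoff used for this task) and secondary
alignments are discarded; the remaining aligned target bp are summed per
chromosome and the argmax is the alignment assignment. Hi-C mate-pair
counts per chromosome provide the second argmax. Design decisions:

- A tie in cumulative bp refuses assignment (`unassigned`) rather than
  picking arbitrarily — a silent wrong placement would corrupt every
  downstream per-chromosome count.
- Hi-C is confirmatory, never sufficient alone (`hic_only` does not assign
  unless explicitly allowed): mate links support linkage but do not
  localize a satellite contig within a chromosome group as reliably as
  sequence similarity.
- Minimum-evidence floors (`min_aligned_bp`, `min_links`) default to 0 but
  are exposed, since no principled universal threshold exists.

An assigned contig is joined to its scaffold across a 100-bp `N` model gap
(`contig_join` AGP component), reverse-complemented when the majority of
its aligned bp are on the minus strand. After joining, a telomere-bearing
contig restores a terminal telomere call at the joined end — the package
tests exactly this round trip.

## Gap-fill classification

For each real (non-model) gap in the reference AGP — model gaps with types
`centromere`, `telomere`, `short_arm` are excluded, the set is
configurable — the flanking reference sequence is aligned to the complete
assembly. A flank is *anchored* when it has exactly one primary alignment
covering at least `unique_fraction` (default 0.8) of its length. With both
flanks anchored on the same chromosome and strand and ordered consistently
with the reference, the inserted sequence is the target interval between
the anchors, orientation-normalized (on the minus strand the left flank
lies to the right, and the inserted sequence is reverse-complemented back
into reference orientation — classification is therefore invariant to
reverse-complementing the whole assembly chromosome). Status follows the
fill taxonomy: `completely_filled` (non-N sequence added, no N remaining),
`partially_filled` (non-N added, N remaining), `not_filled` (fewer than two
anchors, or zero non-N bases added). Anchors may overlap by up to
`overlap_tolerance` (default 1 kb, counted as completely filled with zero
inserted length); larger overlaps are refused as inconsistent.

Flank lengths escalate through a schedule (default 50, 100, 200 kb on real
data; the synthetic drivers use 2 kb, scaled to their 1-Mb chromosomes)
until both flanks anchor — a repeat-rich short flank that aligns ambiguously
often becomes unique once extended. The package ships an exact-substring
flank aligner valid for error-free synthetic assemblies; real data should
supply aligner-produced PAF instead.

The novel-gene filter keeps de novo genes with at least 3 exons, strictly
more than 200 bp of coding sequence and zero bp overlap with any
lifted-over gene. The CDS threshold is strict (`> 200`) because the
observed minimum among reported novel genes is 201 bp; the exon threshold
is inclusive (`>= 3`).

## Inversion filtering, enrichment and NAHR mechanisms

Raw inversion calls between two assemblies are filtered before analysis:
calls not strictly longer than 1 kb; calls whose satellite + simple +
low-complexity coverage exceeds `satellite_max_fraction` (default 0.5 —
"primarily composed" is not quantified in the source methodology, so the
threshold is exposed); and calls covered at least 95% by L1 annotations,
which are the signature of twin-priming during L1 retrotransposition — an
internally inverted L1 insertion masquerading as a genomic inversion — not
of a true inversion.

Enrichment uses the two 1-kb flanks outside each inversion (outside-flank
semantics; windows clipped at chromosome edges are flagged). Under the
null, every window is relocated independently to a uniform position in the
workspace, preserving its length; windows may overlap each other, which
keeps the null exchangeable for sum-type metrics. The workspace defaults to
the assembled (non-N) chromosome intervals so windows are never placed into
gaps. With 1,000 permutations (the default; exposed as `n_perm`) the
smallest attainable two-sided p is 2/1001. p-values use the add-one
estimator and are BH-adjusted across the five tested classes (SD, LINE,
SINE, LTR, Satellite).

NAHR calling uses the 500-bp windows on each side of each breakpoint. SDs
take priority: a duplicated pair (matching pair identifier when present)
overlapping both windows calls mechanism `SD`. Otherwise the TE family — at
`class_family` granularity (e.g. LINE/L1) by default, `subfamily` optional
— with at least `min_overlap` (50 bp) in both windows is sought; among
qualifying families the one maximizing the smaller of its two window
overlaps wins, with the deterministic tie-break LINE > LTR > SINE. This
makes the mechanism taxonomy mutually exclusive by priority; whether the
original four-way percentages were computed by priority or by strongest
evidence is not stated, so the priority rule is a package decision. The
`class_family` default reproduces a four-way LINE/LTR/SINE/SD taxonomy.

Length statistics: SD-mechanism inversion lengths are compared with
TE-mechanism lengths by a two-sided Mann-Whitney U test — exact by full
enumeration of label assignments (ties included) when the combined n is at
most 16, tie-corrected normal approximation otherwise — and inversion
length is correlated with the mean length of the evidence SD intervals by
Kendall's tau-b, exact by full permutation enumeration for n <= 8. The
exact paths are implemented in the package because the standard
`wilcox.test`/`cor.test` routines fall back to approximations in the
presence of ties; the approximation paths delegate to those standard
routines. Only the rank correlation is computed for the SD-length
relationship; a regression slope is out of scope.

## The walking assembler

The targeted assembler reconstructs a repetitive locus outward from a known
seed: (1) select reads sharing a contiguous match of at least `min_match`
(default 4 kb) with the current terminal seed, allowing
`max_mismatch_per_kb` mismatches per kb (default 0 — the selection
criterion is identity, with a flag standing in for the manual allowance of
obvious polymorphisms; indels are not tolerated); (2) assemble the selected
reads by greedy maximal exact suffix-prefix overlap (`min_overlap`,
default 2 kb), absorbing contained reads — with exact overlaps every layout
column is unanimous, so consensus is concatenation; (3) take the contig
built from the most reads (ties: longest, then smallest id); (4) merge it
onto the growing sequence at the midpoint of the shared anchor, never
rewriting already-accepted sequence (every round's result contains the
previous sequence as a prefix); (5) reseed from the terminal 10 kb
(`seed_len`) and repeat until no reads are selected, no progress is made,
or a previously used seed recurs.

The greedy exact-overlap assembler deliberately replaces a general-purpose
overlap-layout-consensus assembler: it is valid for the low-error synthetic
reads the package targets, and the contribution being reproduced is the
walking loop, not noisy-read assembly. The seed-recurrence guard is the
package's mechanical substitute for the manual dot-plot inspection used to
judge whether a walk is proceeding correctly: a tandem array longer than
the read length either stalls the walk (zero extension on a
collapsed-repeat contig) or triggers the cycle guard — the same situation
in which a large repeat structure genuinely cannot be resolved by walking.

On a 100-kb random target with error-free 15-kb reads at depth 10 the walk
reconstructs the target exactly, extending 3.5-12.5 kb per full round
(about 9-10 kb on average); the terminal round is bounded by the template
end and is excluded from the envelope.

## The synthetic genome pair

`simulate_genome_pair()` builds each chromosome as: left telomere
(`CCCTAA` array, 2-5 kb) - subtelomeric pattern - minor satellite
(20-40 kb) - major satellite (60-120 kb) - arm - right telomere (`TTAGGG`
array). The default is six 1-Mb chromosomes; all suites run in minutes on
one CPU. The reference genome is derived from the complete one by replacing
the telomere/satellite ends with `centromere`/`telomere` model gaps,
replacing planted fills with `N` runs of the estimated gap length, and
presenting inversions in the opposite orientation. Structural choices and
what they emulate:

- **Satellite arrays** are tandem monomer copies with 2% per-base
  substitution noise, built on a per-chromosome private consensus derived
  from the shared monomer at 5% substitution. This reproduces the
  within-chromosome-greater-than-between-chromosome similarity structure
  that placement relies on; pure arrays would make placement trivially
  degenerate. Cross-chromosome alignment identities in the emitted
  bookkeeping PAF follow from these rates (about 0.96 within, 0.87
  between), so the 95% identity cutoff separates them.
- **Subtelomeres** follow the four patterns with one L1 (`L1MdA3`), TLC
  arrays of 3-6 kb (per-chromosome totals of 6-12 kb), and the planted
  punctuators; the `nonstandard` pattern is a SINE/LTR jumble with no TLC.
- **Gaps** cycle through complete / partial / absent fills; a partial fill
  carries an interior `N` run, an absent fill adds no non-N base.
- **Inversions** cycle through the mechanisms: TE-mechanism inversions get
  a same-family element copy immediately outside each breakpoint in
  inverted orientation; SD-mechanism inversions get a duplicated segment
  pair, are drawn from the upper half of the length range, and their SD
  length scales with inversion length (emulating the association between
  larger repeats and larger rearrangements); twin-priming "inversions" are
  fully covered by an L1 annotation; `none` inversions have clean
  breakpoints.
- **Alignments** (reference vs complete, contig vs scaffold) are emitted
  from construction bookkeeping, not from running an aligner, keeping tests
  download-free and deterministic.
- **Hi-C links** are Poisson counts, mean 50 on the true chromosome and 2
  elsewhere.
- **Reads** have uniform start positions at the requested depth; the two
  terminal reads of the (linear) template are always included, as the ends
  of a linear fragment are represented in a real read pool. With zero error
  rate every read is an exact substring.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: sequencing-error profiles (HiFi/ONT), diploid
heterozygosity, higher-order satellite structure, repeat families with
internal divergence gradients, aligner-specific artifacts, and Hi-C
contact-distance decay. Results on real assemblies depend on upstream
aligner and RepeatMasker behavior that the synthetic path bypasses.

## Problem sizes and determinism

The shipped analyses use six 1-Mb chromosomes (seed 1), 1,000 permutations
for enrichment, 200 calibration replicates of 200 permutations, and a
100-kb walking target — sizes chosen so the full study runs in a few
minutes on a single core while every recovery is exact. All stochastic
steps take explicit integer seeds; identical seeds give byte-identical
outputs, including the emitted file set.

## Known limitations

- The flank aligner shipped for synthetic data is exact-match only; real
  assemblies need an external aligner's PAF.
- `class_family` NAHR granularity cannot separate co-located families of
  the same class (e.g. nested L1 subfamilies); use `subfamily` when the
  annotation is reliable at that depth.
- The permutation null relocates windows independently; it does not
  condition on inter-window spacing, so extremely clustered window sets are
  tested against a slightly broader null.
- The walking assembler assumes effectively error-free reads; a single
  mid-read error breaks an exact overlap and can fragment the layout.
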