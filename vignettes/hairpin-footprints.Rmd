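---
title: "Structural footprints of miRNA biogenesis: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural footprints of miRNA biogenesis: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRfootprint)
```

## The problem

Animal microRNAs mature through an ordered series of structure-guided
cuts: Drosha crops the hairpin out of the primary transcript, and Dicer
releases the miRNA duplex near the terminal loop, canonically leaving
2 nt 3′ overhangs at both ends. Mirtrons bypass Drosha — splicing (plus
exonucleolytic trimming of "tailed" mirtrons) defines the hairpin base
instead — yet are handled by the same downstream machinery. Each step
leaves a footprint in the precursor's secondary structure: where the
duplex ends fall relative to the closing base pairs, how far miRNA ends
sit from single-stranded regions, which mature positions are unwound,
where sequence variation accumulates, and (for mirtrons) where the
splicing branchpoint sits inside the hairpin. This package turns each of
those footprints into a reproducible computation on hairpin records
(sequence + nested pairing table + hairpin-relative mature coordinates).

## Data model and coordinate conventions

All coordinates are 1-based, inclusive, and hairpin-relative; converters
to other systems belong at file boundaries. A `HairpinRecord` validates
that the pairing table is a nested involution of the sequence length and
that at most two non-overlapping matures are annotated, with the left
mature on the 5′ arm. `T` is silently converted to `U` and case is
normalised, since public hairpin collections mix conventions. Records
violating the record invariants, containing non-canonical nucleotides, or
annotated with more than two matures are excluded at load time with
recorded reasons — mirroring the exclusions applied when such datasets
are curated — rather than aborting the load.

When only one mature is annotated, its arm is assigned by the midpoint
rule (5′ arm iff the mature midpoint lies left of the hairpin midpoint),
so single-mature records still contribute to arm-stratified profiles.

## Overhang geometry

The miRNA duplex inside a hairpin is delimited by its **basal** and
**apical closing pairs**: the outermost and innermost base pairs joining
the two mature intervals (found by scanning the 5′ mature for partners in
the 3′ mature; a brute-force enumeration oracle confirms the scan in the
tests). With closing pairs (a, b), (c, d) and matures [s5, e5], [s3, e3]:

    basal  = (e3 − b) − (a − s5)
    apical = (e5 − c) − (d − s3)

This counts *excessive nucleotides beyond the closing pair regardless of
their structural state* — deliberately not the length of the hanging
single-stranded end, because structure prediction may pair overhang
nucleotides. Positive values are 3′ overhangs; the canonical duplex
scores (+2, +2); negative values are atypical 5′ overhangs. A second
definition (`hanging_end`) replaces the closing pairs by the
outermost/innermost mature nucleotides paired to *anything*; the two
definitions provably coincide whenever the duplex termini pair within the
duplex, which is how the robustness of downstream statistics to the
definition is assessed. Overhang magnitudes above 15 nt almost always
indicate a mispredicted terminal loop; they are flagged `suspect` but
kept, so summaries can include or exclude them explicitly.

For multi-stem structures the duplex search is restricted to pairs
joining the two matures, and the terminal loop is the candidate loop
nearest the region between the matures; no attempt is made to repair
dubious structures.

## The independence null model for cleavage coherence

If Drosha and Dicer cut independently, the joint distribution of the two
overhang lengths over the near-canonical classes {1, 2, 3} nt factorises
as P(i, j) = q_i·q_j with a *single shared marginal*
q = (p_short, 1 − p_short − p_long, p_long) — two free parameters,
justified by the empirical similarity of the two sites' marginals. The
maximum-likelihood fit has the closed form q_i = (row_i + col_i)/(2n)
(the tests confirm it against a grid search at 10⁻⁴ resolution); a
least-squares fit on cell frequencies and a 4-parameter per-site variant
are available for comparison, since either estimation route is defensible
— both are reported by the pipeline. Model violation is summarised by
observed/expected cell ratios and a likelihood-ratio statistic against
the saturated multinomial (df = 6 shared, 4 per-site).

Coherent cleavage imprecision — both sites short or both long together —
appears as enrichment of the (1,1) and (3,3) cells and as a positive
Spearman correlation of the overhang pairs. Note a subtlety verified in
the tests: doubling the diagonal cells of a product table shows ratio 2
against the *generating* expectation, but less under the refit, because
the refitted marginal absorbs part of the boost.

The restriction to near-canonical pairs (both lengths in {1, 2, 3})
removes three artefact sources before the coherence test: excluded big
bulges, mispredicted terminal loops, and guanine avoidance at duplex
boundaries; the latter is checked directly by
`boundaryBaseFrequencies()`, which tallies base composition at offsets
−1/0/+1 around any mature end.

`rankCorrelation()` uses midranks for ties; the asymptotic p-value is the
standard large-sample approximation, and the permutation p-value shuffles
one variable (two-sided on |rho|), enumerating all n! orderings exactly
when n! does not exceed the shuffle budget (default 10,000) and using the
add-one estimator otherwise.

## Loop-counting distances

For a mature end whose terminal nucleotide t is paired, the backbone is
scanned in both directions for the nearest single-stranded nucleotide:
outside the mature, d = |u − t| − 1 (0 when the end sits immediately at a
single-strand boundary); inside, d = −|u − t| (nucleotides to cut off to
reach the loop). The reported distance is the one of smaller magnitude;
ties return the outside value, because the loop-counting rule concerns
loops upstream of the cleavage site — the tie rule is fixed and recorded
in every report header. Ends whose terminal nucleotide is single-stranded
are *undefined* (excluded with a reason), not zero. Scanning never
crosses to the partner arm in practice because an unpaired nucleotide
(terminal loop or hairpin tail) is always encountered first on nested
structures; the brute-force positional-scan oracle in the tests covers
1,000 random nested structures.

## UNF profiles

The unpaired nucleotide frequency at aligned mature position p (1 = the
mature's 5′ end, negative = 5′ flank, no position 0) is the fraction of
matures of that arm whose hairpin nucleotide at p is single-stranded.
Denominators are per-position: a record only counts where the position
exists (inside the hairpin, and not beyond that mature's length), which
is why profiles are reliable at the ends of long matures only where data
exist. The identity 1 − UNF = paired fraction is asserted on every
fixture. The default flank width is 10 nt — wide enough to show the
single-stranded basal signature of mirtron 5′ ends, narrow enough that
denominators stay near the dataset size.

Position groups used in summaries follow the standard functional anatomy:
seed = 2–8, additional binding site = 13–16, transition = 9 and 17–19.
Correlation of a UNF profile with a per-position substitution-rate table
(consumed as input, not derived here) uses the same Spearman machinery;
the characteristic empirical pattern is stepwise — two position groups,
with correlation between but not within groups — which the tests
reproduce on two-block synthetic data.

## SNP densities

Each hairpin is partitioned into disjoint regions: per-mature seed
(positions 2–8), the rest of each mature (including position 1), the
pre-miRNA excluding matures, and upstream/downstream flanks (default
200 nt, configurable; flank coordinates extend the hairpin axis below 1
and above its length). Density is N_snp × 1000/L pooled over the dataset,
reported per region with flanks both separate and pooled (the pooling
choice is ambiguous in published figures, so both are emitted).
Common/rare stratification (common = minor allele frequency > 0.01) is a
filter on one pipeline, not a separate pipeline. Density is additive
under region splitting, which the tests assert, and any subset
restriction (robust ids, common-only) re-runs without error — ordering
claims like seed < miRNA < pre-miRNA < flanks are dataset properties,
checked only on synthetic data built to satisfy them.

Mean SNPs per precursor stratified by disease association × mirtron
status uses SNPs within the hairpin span only, with zero-SNP hairpins
contributing zeros and empty groups reported as undefined.

## Branchpoints

Branchpoint offsets count nucleotides upstream of the intron's last
nucleotide (offset 0 = the last intron nucleotide); the convention is
applied identically to mirtron-linked and plain-intron records, so
comparisons are unaffected by the choice. Mapping an offset into hairpin
coordinates assumes 3′-coterminality (bp_position = hairpin length −
offset), appropriate for untailed and 5′-tailed mirtrons — the common
case — while 3′-tailed mirtrons must supply an explicit position.
Compartments are assigned against the terminal loop [ls, le]: 5′ strand,
terminal loop, or 3′ strand; d_loop counts the first nucleotide after the
loop as 1; d_dicer = s3 − bp is negative when the branchpoint lies inside
the 3′ miRNA. All conventions (inclusive counting, sign choices) are
emitted in report headers because they cannot be recovered from published
figures alone.

## The synthetic generator: what it emulates and what it does not

`generateHairpin()` builds a tail–stem–loop–stem–tail structure with
Watson–Crick stems (G·U off by default — the simplest structures
satisfying every invariant), optional internal loops, and matures placed
so the designed (basal, apical) overhang pair is returned *exactly* by
`computeOverhangs()` — negative overhangs extend a mature into a tail,
positive apical overhangs into the terminal loop (hence |apical| must not
exceed the loop length; unrealisable specs error out). One RNG stream per
cohort with per-record derived seeds makes fixtures reproducible.

`cohortSpec()` defaults encode the study conditions the analyses expect,
chosen once from the field's reported regime and not tuned thereafter:

- overhang joint distribution over −2..4 nt with the canonical class
  dominant, short/long classes depleted 4-/7-fold, roughly two thirds of
  mass in the near-canonical block, and the coherent (1,1)/(3,3) cells
  doubled relative to independence;
- stem lengths 19–25 bp, loops 6–12 nt, one optional internal loop per
  hairpin (typical pre-miRNA dimensions);
- SNP rates per kb with the seed < miRNA < pre-miRNA < flank hierarchy
  (8/9/12/15), mirtron pre-miRNA rates scaled ×1.6 (inverting the
  pre-miRNA/flank contrast), and disease multipliers 0.6 for canonical
  precursors vs 1.5 for mirtrons (the opposed selection regimes);
- mirtron branchpoint offsets discretised around a 21 ± 4 nt peak inside
  the expected 10–40 nt window.

The generator deliberately does **not** emulate: thermodynamic folding or
misfolding (so "suspect" long-overhang artefacts do not arise naturally),
G·U wobble stems, sequence-dependent cleavage preferences, multi-hairpin
transcripts, or evolutionary correlation between positions. Passing
recovery tests therefore demonstrates correctness of the *computations*
under controlled truth, not that real databases will show the same
effect sizes — database-scale results additionally depend on annotation
noise the generator omits.

## Numerical and design choices

- Problem sizes in the test-suite and acceptance computations: 1,000
  hairpins for exact overhang recovery, 10,000 pairs for
  independence-parameter recovery (±0.02), 1,000 random structures for
  the distance oracle, cohorts of a few hundred for SNP/branchpoint
  recovery — sizes at which multinomial sampling error is far below the
  assertion tolerances.
- Permutation tests switch to exhaustive enumeration for n! within the
  shuffle budget, making small-n p-values exact.
- Degenerate inputs: constant vectors are correlation errors (not NA);
  empty overhang tables are valid empty results; zero-length regions are
  skipped with warnings; fit tables with all mass in one cell hit the
  simplex boundary and are flagged.
- The pipeline writes deterministic reports (no timestamps); identical
  config + seed reproduces byte-identical TSV/JSON.

## Limitations

Structures are consumed as given: no refolding, no repair of mispredicted
terminal loops, no pseudoknots. The duplex requires both matures; hairpins
with a single annotated mature contribute to UNF/distance/SNP analyses
but not to overhang statistics. Branchpoint mapping without explicit
positions is only as good as the 3′-coterminality assumption. The
independence model addresses the near-canonical block only; conclusions
about extreme overhangs rest on the flagged full table.
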