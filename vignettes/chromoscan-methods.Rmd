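---
title: "chromoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chromoviruses are a lineage of Ty3-gypsy LTR retrotransposons that carry a
chromodomain at the C-terminus of their integrase.  In plants they fall into
four clades — CRM, Tekay, Reina and Galadriel — that differ in a structural
character that is easy to score from sequence alone: in CRM elements the
chromodomain coding region sits *downstream* of the polypurine tract (PPT),
inside the 3' LTR, and the gag-pol reading frame runs through the PPT into
the LTR; in the other three clades the chromodomain is the last domain of
the integrase, *upstream* of the PPT.  `chromoscan` turns this structural
knowledge into a desk-scale pipeline: detect candidate elements de novo in
genomic contigs, validate them by their target-site duplications (TSDs),
annotate the internal anatomy (PBS, PPT, gag-pol ORF, protein domain
cassette), classify the chromodomain and clade, cluster families by LTR
identity, summarize RT diversity with neighbor-joining dendrograms, and
date insertions from LTR divergence.

Because no public assembly accompanies the motivating survey, the package
ships a synthetic-genome generator whose output carries a complete truth
channel; every stage of the pipeline is validated against it.

## Element model

A full-length element is modeled as

```
TSD | 5' LTR | (0-3 nt) PBS ... gag-pol ORF ... PPT | 3' LTR | TSD
```

with the clade-specific variations described above.  The criteria for the
`full_length` call are: an exact flanking TSD (5 nt, 0 mismatches by
default), an undisrupted gag-pol ORF (the longest stop-free stretch must
cover at least 80% of the internal region), every cassette domain detected
(GAG zinc finger, protease, RT, RNaseH, integrase HHCC / DD35E / GPF-GPY
blocks, chromodomain), a functional PPT (7-14 purines ending exactly at the
3' LTR), and a PBS beginning within 3 nt of the 5' LTR.  An element failing
any criterion but still carrying a recognizable RT is `incomplete`;
anything else is `degenerate`.  The 80% ORF-coverage convention is ours:
"undisrupted" is not defined quantitatively in the source literature, so
the default is deliberately permissive and configurable
(`coverage_min` in `annotate_element()`).

## Detection

`find_ltr_pairs()` is a self-comparison scanner in the LTRharvest mold:

1. exact k-mer seeds (k = 13) shared by two windows whose distance is
   compatible with an element (defaults: LTRs 100-3500 nt, elements
   4000-13000 nt — bracketing the observed 293-3000 nt LTRs and
   5.2-11.6 kb elements with margin);
2. seeds chained along diagonals, merged across nearby diagonals,
   extended ungapped with an X-drop;
3. the two LTR windows validated by a global alignment (match +1,
   mismatch -1, gap open -4, gap extend -1) at `min_identity = 0.80`;
4. overlapping candidates resolved to the highest-identity, longest-LTR,
   leftmost representative.

A direct repeat is its own reverse complement's mirror image, so a single
forward scan covers both strands; the element's *sense* strand is decided
later, at annotation time, by where the PBS, functional PPT, intact ORF and
RT evidence accumulate.  The strand-symmetry property (scanning the reverse
complement yields the mirrored candidate set) is tested.

`refine_boundaries()` polishes the four coordinates within a ±25 nt slack
by maximizing a joint score: *boundary contrast* (the LTR copies must agree
in a 12-nt window just inside each boundary and disagree in an 8-nt window
just outside — agreement alone cannot place a boundary because near-identical
LTR copies agree at any interior offset), doubled TSD agreement, a bonus for
an *exact* TSD, and a small bonus for the canonical TG...CA LTR termini.
The motif bonus only breaks ties between boundary placements that are
equally consistent with an exact duplication (a ±1 shift of both ends can
reproduce a 5-mer duplication exactly when the flanking base cooperates);
the hard terminal-motif *filter* familiar from other annotators is
deliberately not applied, since the source survey does not state one.
Ties prefer the unshifted position, which makes refinement idempotent.

## Domain detection

Protein domains are scored with fixed-length ungapped PSSMs (log2 odds
against a uniform amino-acid background, pseudocount 1) built from the
bundled exemplar peptides, scanned at every offset of the translated ORF.
This replaces profile HMMs: on intact cassettes at desk scale the two
approaches agree, and the PSSM scan is dependency-free.  Each profile's
detection threshold is half its weakest training self-score; at that
setting the false-positive rate on shuffled proteins is far below 1%
(tested with 400 shuffles; scaled down from 1000 for suite runtime, with
the threshold untouched).  RT mining additionally enforces the
conventional bit-score > 50 and segment length > 200 aa rules across all
six frames.  When a premature stop pushes the RT out of the longest ORF, a
six-frame rescue scan of the element keeps disrupted copies classifiable
as `incomplete` rather than `degenerate`.

The bundled reference panel is **synthetic**: offline builds cannot fetch
GenBank records, so the exemplars are generated once from a shared scaffold
per domain with the canonical catalytic motifs (CCHC, DTG, LPQG/YIDD,
DEDD, HHCC + DD35E + GPF/GPY) pinned at fixed positions and clade variants
at ~15% mutual divergence (`inst/extdata/synthetic_domain_panel.faa`).
They behave like a real exemplar panel for every structural purpose the
pipeline needs, but carry no natural sequence information — conclusions
about real clade phylogeny must not be drawn from them.

## Chromodomain groups and clades

The chromodomain window is taken downstream of the integrase GPF/GPY motif
(upstream-layout clades) or from the functional PPT to the ORF stop inside
the 3' LTR (CRM layout).  It is aligned to a bundled HP1-like reference
chromodomain (also synthetic, with annotated aromatic-cage columns) with
free end gaps, and the three cage columns are read off: all three aromatic
(Y/W/F) gives group I; positions 1 and 3 non-aromatic with 2 aromatic gives
group II; a non-aromatic column 2 leaves the call `unclassified` rather
than forcing a group.  F is accepted as aromatic although the canonical
cage is Y-W-Y, since group-I membership generally tolerates it.  The CR
motif of CRM elements is defined by its position downstream of the PPT,
not by cage content.

Clade assignment is CRM whenever the chromodomain is downstream of the
PPT; otherwise a nearest-reference vote on global RT identity against the
clade exemplars (threshold 0.40, below which `unassigned`).  Conflicting
evidence (e.g. a downstream chromodomain with a non-CRM nearest RT) is
recorded in the call, never silently resolved.

## Distances, trees, families

All protein alignments use BLOSUM62 with affine gaps (open 11, extend 1);
nucleotide alignments use the single scheme quoted above, shared by LTR
validation, family clustering and dating so that "identity" is one
quantity.  Identity denominators include gap columns (stricter and stable
under indels); an ungapped-denominator mode is available
(`denominator = "ungapped"`) because the convention used for the published
box-plot statistics is unstated.

`build_nj_tree()` is a from-scratch Saitou-Nei implementation: standard Q
criterion, deterministic tie-breaking (the pair whose smallest contained
leaf labels sort first), negative branch estimates clamped to zero with
the excess moved to the sister branch (toggleable).  On additive matrices
it recovers the generating tree exactly; the suite checks 100 random
additive matrices (n ≤ 6) for exact topology and branch lengths, the
3-taxon closed form, and agreement with `ape::nj()` as an independent
oracle on perturbed matrices.  Bootstrap supports resample alignment
columns with replacement, rebuild the tree per replicate, and report the
percentage of replicates containing each internal-edge bipartition.
`center_star_msa()` provides the projection MSA used for bootstrapping;
it is a stand-in for a full progressive aligner and is exact only in the
sense of the center-star construction.

Families are single-linkage clusters at ≥ 80% LTR identity (inclusive
threshold); the linkage rule is our choice, as the family concept is cited
in the literature without one.

## Dating

`estimate_age()` applies t = K/(2r) with r = 1.5e-8 substitutions/site/year
by default.  K defaults to the *uncorrected* p-distance over non-gap
aligned columns: round-tripping the printed per-element table (e.g.
2.88% → 0.96 Mya, 3.96% → 1.32 Mya) shows that the published ages used the
raw divergence, so Jukes-Cantor correction is provided but off by default.
Two printed rows (Bingo4: 0.77% → 0.026 Mya; Bingo1-1: 1.68% → 0.6 Mya)
are inconsistent with the formula (0.257 and 0.56 Mya respectively) and
are treated as typography — they are excluded from the round-trip test and
asserted to be inconsistent.  Partial-LTR pairs are dated on the aligned
overlap and flagged.

## The synthetic generator: what it emulates, what it does not

`generate_genome()` emits an i.i.d. background at GC 0.36 (a plant-like
convention; the source gives no base-composition statistics) and splices in
elements built from the four clade templates: default LTR lengths 900 /
2600 / 430 / 631 nt and internal regions sized so totals fall in the
observed 5.2-11.6 kb range (the Galadriel default reproduces the 6038 =
631 + 4776 + 631 reference layout exactly); 5-nt TSDs; a PBS
(`TGGTATCAGAGC`, the reverse complement of the 3' end of the plant
initiator tRNA-Met — the tRNA is named in the source but its sequence is
not, so the motif is configurable) within 0-3 nt of the 5' LTR; a 12-13
purine PPT abutting the 3' LTR; optionally a duplicated internal PPT_a
overlapping the ORF stop (the Bongo3 layout).  The coding region is a
reverse translation (uniform codon choice, no stops) of the exemplar
cassette, padded with random linker residues so the ORF covers ~90% of the
internal region.  Divergence is applied to the 3' LTR copy only, with
uniform substitution among the three alternatives — the 5' copy is the
master, which keeps the truth channel simple; realized divergence is
recorded per element.  Truncation modes (5'/3' partial LTR, internal
deletion), an injected-premature-stop mode, reverse orientation, and a
tandem low-complexity decoy option exercise the failure paths.

What a green test on this world does *not* establish: robustness to nested
insertions, solo-LTR recombination products, indel-rich LTR divergence
(the generator substitutes but never indels the LTR copies — the aligner
tolerates indels but recall under heavy indel load is untested), natural
codon usage, or repeat-dense backgrounds beyond the decoy option.

## Numerical and interface conventions

Internal coordinates are 0-based half-open in genome space; GFF3 output is
1-based inclusive.  All randomness flows from a single seed through a
private RNG stream that never disturbs the caller's `.Random.seed`.
Identical (config, seed) pairs give byte-identical artifacts.  CLI exit
codes: 0 success, 2 configuration error, 3 input error.  The `classify`
and `age` subcommands are aliases of `annotate` — the pipeline is single
pass and their outputs are columns of `elements.tsv`; this keeps every
stage's artifact inspectable without a stage-resume mechanism.

## Known limitations

* Genome-scale published quantities (921 mined RTs, 16 families, 20+2
  full-length elements, the per-clade identity box plots) are not
  reproducible without the unreleased assembly; the suite covers them with
  property-based and scaled-down analogues only.
* PSSMs are ungapped: a domain split by an in-frame indel larger than the
  profile tolerance will be missed (the RT rescue scan mitigates this for
  classification).
* The center-star MSA is not a substitute for a progressive aligner on
  deeply diverged inputs.
* `detect_ppt` truncates purine runs at the search-window edge; output is
  invariant to sequence outside the window by construction.
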