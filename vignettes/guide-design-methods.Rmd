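---
title: "Guide design methods: pegRNAs, nicking guides and base-editor gRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegbe)
```

## Scope and model

`pegbe` designs guides for two editing modalities that install small,
programmable changes without double-strand breaks:

* **Prime editing.** A Cas9 nickase–reverse-transcriptase fusion is
  programmed by a pegRNA: a 20-nt spacer, the sgRNA scaffold, and a 3′
  extension consisting of a reverse-transcriptase template (RTT) followed
  by a primer binding site (PBS). The nicked strand's free 3′ end anneals
  to the PBS and the RTT templates new DNA carrying the edit.
* **Base editing.** A deaminase–Cas9 fusion converts A→G (ABE) or C→T
  (CBE) within an *editing window* of the protospacer, without cutting
  both strands.

Everything in the package reduces to careful bookkeeping on one working
sense sequence. Internally all coordinates are 0-based and half-open;
every user-facing surface (constructors, CLI, tables) is 1-based, the
genomics display convention.

## Prime-editing geometry

For a PAM whose 5′-most base sits at coordinate $p$ in its own strand's
frame, the protospacer occupies $[p-20, p)$ and the nick falls between
protospacer positions 17 and 18, i.e. the bond at $n = p - 3$. Writing
`edited` for the post-edit sequence, a candidate pegRNA with PBS length
$b$ and RTT length $r$ satisfies the package's central contract:

$$\mathrm{extension}_{3'} \;=\; \mathrm{revcomp}\big(\,\mathrm{edited}[\,n-b,\; n+r\,)\big)$$

with the RTT written first (5′→3′). A candidate exists iff the entire
alternate allele lies in the RTT window $[n, n+r)$; for deletions the
junction must lie in the window with at least one templated nucleotide 3′
of it. This contract is enforced by a property-style test against an
independent slice-and-reverse-complement oracle over ≥ 10,000 random
(sequence, edit, PAM) draws, for all three edit kinds, on both strands.

**Edit position** is the 1-based distance from the nick to the edit's
nick-proximal end on the edited PAM strand: position 1 is the first
nucleotide 3′ of the nick (protospacer position 18), so positions 1–3 lie
in the residual protospacer and 4–6 in the PAM. This is the only
convention under which "edit position 1–6" spans exactly the protospacer
plus PAM, and under which the best observed scores of −1 are attainable
(see Scoring). For multi-nucleotide edits the position is measured to the
alt allele's nick-proximal end.

**PAM scan window.** Candidate NGG PAMs are collected on both strands
wherever the PAM's 5′-most base lies between 100 nt 5′ and 6 nt 3′ of the
edit's 3′ end, each strand evaluated in its own 5′→3′ frame. We read the
window anchoring literally from its description; since any geometrically
impossible PAM on the 3′ side is subsequently removed by the RTT-coverage
filter, the exact boundary interpretation affects only which *untargetable*
PAMs are enumerated, never the produced candidates. The window is clipped
at the sequence ends: short flanks yield fewer hits rather than an error
(≥ 120 nt of context per side is recommended; an error is raised only when
no 20-nt protospacer plus PAM can exist at all). Non-NGG PAMs are not
scanned for prime editing, reflecting current experimental validation;
the base-editing module is where PAM diversity lives.

**Defaults.** PBS and RTT lengths default to 13 nt, the suggested starting
values; PBS length is capped at 17 nt, the nick-to-protospacer-5′-end
span. Both are per-job tunable, and targetability is monotone
non-decreasing in RTT length (tested by sweep).

## Scoring

The pegRNA score automates heuristic design rules; it is a triage signal,
not an efficiency predictor. Components, each independent:

| penalty | trigger | value |
|---|---|---|
| first-base C | extension starts with C (can pair with Cas9 G81) | −28 |
| poly-T | > 4 *consecutive* T anywhere in the extension (Pol III terminator) | −50 |
| short homology | < 5 homologous nt 3′ of the edit within the RTT | −6 |
| edit distance | per nick-relative edit position | −1 × position |

The score is the sum, so it is always ≤ −1. Two readings were genuinely
open. First, whether "more than 4 thymines" counts consecutive or total T:
we count consecutive runs (≥ 5), because the stated mechanism —
recognition of T stretches as Pol III termination signals — is a property
of runs, not of total composition. Second, the homology guidance ("more
than 5, or even more than 10 nt if possible") versus the penalty rule: the
penalty fires only below 5 nt; the 10-nt advice is treated as guidance,
not a second penalty. Candidates are ranked by score, with ties broken
deterministically by smaller edit position, then "+" strand, then lower
coordinate, so identical runs are byte-identical.

## Nicking guides

* **PE3** guides are opposite-strand NGG protospacers whose nick lies
  40–100 nt from the pegRNA nick. The bounds are inclusive and distance is
  measured nick-to-nick as an absolute value in either direction.
* **PE3b** guides are opposite-strand protospacer+PAM footprints that
  overlap the pegRNA's protospacer+PAM footprint by at least one
  nucleotide, with the overlap reported. We require footprint overlap
  rather than insisting the protospacer span the edited base itself —
  "partial overlap" is the stated criterion — but guides are always
  extracted from the *edited* sequence, so a seed that does span the edit
  only matches after successful editing, which is the PE3b safety
  rationale. PE2 (no nicking guide) is the default; PE3b is the
  recommended choice where re-nicking risk matters.

## Base-editor design

A single-base change is reachable by exactly one (deaminase, strand)
combination: A→G by an ABE on the sense strand, T→C by an ABE acting on
the antisense A, C→T by a CBE on the sense strand, G→A by a CBE acting on
the antisense C. Transversions return a structured "not base-editable"
record rather than an error. In revert mode the variant base is first
written into the sequence, then converted back, so guides always target
the variant-carrying sequence.

The registry ships 4 CBEs (engineered low-off-target BE3 variants and
Target-AID, all NGG) and 7 ABEs covering the PAM motifs NGG, NGA, NGCG,
NNGRRT, NNNRRT, NGN and NRN. Only the ABEmax window (protospacer positions
5–7, position 1 PAM-distal) is anchored by its published description; the
other windows are registry defaults taken from the respective editor
literature (CBE NGG variants 4–8, Target-AID 2–4, other ABEs 5–7) and are
deliberately stored in an editable flat config
(`read_editor_registry()` / `write_editor_registry()`), not in code.
Likewise the printed NGCG/SpCas9-NG pairing is kept exactly as printed and
can be overridden in the registry. SpRY's optional NYN acceptance is a
flag (`spry_nyn`, off by default) so the distinct ABE PAM count stays 7.
Protospacers are fixed at 20 nt for all editors, including SaCas9
variants, matching the output-table definition this design follows rather
than the 21–22 nt SaCas9 literature convention.

**Bystanders** are same-identity editable bases inside the window other
than the target. They never filter a candidate — they are reported and
used for ranking only (fewer bystanders first, then editors without an
efficiency caveat such as SpRY's, then registry order). A symmetry
property replaces a tempting but chemically false invariant: reverting a
variant is *not* the mirror image of installing it (reverting an A→G
variant is a CBE task), so the suite instead verifies that designing the
complementary change on the reverse-complemented sequence yields the
strand-swapped, otherwise identical guide set.

## Synthetic data

`make_sequence()` builds backgrounds on restricted alphabets (A/T or the
CA-repeat used in the tests, both of which cannot form an NGG on either
strand) with motif realizations planted at exact positions, and verifies
post-generation that no accidental match of a forbidden motif exists —
rejecting infeasible specs instead of silently patching them.

`make_variant_table()` emulates, at desk scale, a pathogenic-variant table
over the four prime-editable classes, with a synthetic random contig
written as FASTA and an exact ground-truth ledger of expected post-filter
jobs. The default class mixture (65% SNV, 22% deletion, 10% duplication,
3% insertion) mirrors the SNV-dominated composition of real pathogenic
variant sets; deletions span 1–5 nt, duplications 1–4 nt and insertions
1–6 nt, small-indel scales typical of such tables. Variants are spaced
250 nt apart so each has clean design context. What the generator does
*not* emulate: real genomic GC structure and PAM density, allele
frequencies, repeat context, or any snapshot of a real database — so
passing tests demonstrate correctness of the design logic, not the
targetable percentages of any particular human variant snapshot. The
headline targetable-fraction figures the acceptance script reports are
properties of this synthetic mixture (they happen to land near published
full-scale values because NGG density on a uniform random genome resembles
the genome-wide average, but they are not a reproduction of them).

All generators are pure functions of their arguments and seed; the test
suite uses one documented seed (1729) so failures reproduce verbatim.
Problem sizes were chosen to exercise every path at interactive speeds:
10,000 draws for the reconstruction property, a 200-variant table for the
RTT sweep, 20-variant batches for batch/single equivalence.

## Degenerate inputs and numerical choices

* Lower-case input is upper-cased; U (RNA) is rejected; N is accepted only
  in genome-derived input and never appears in designed output.
* Indels use a minimal left-aligned representation with no anchor base,
  avoiding anchor ambiguity when slicing windows.
* Batch readers are total over malformed rows: a bad row is flagged and
  surfaces as an `invalid` output row with its reason; output row count
  always conserves input job count.
* Zero-candidate runs are results, not errors: a structured row explains
  whether no PAM was in the scan window or the RTT could not cover the
  edit.
* All orderings (candidates, nicking guides, editors, oligo records) are
  fully specified, so repeated runs are byte-identical.

## The command line

The package is also a shell tool (`inst/cli/pegbe`): `pe`, `be` and
`batch` subcommands expose single-sample and batch design, `template`
emits the shipped CSV templates, and edits use the compact
`POS:REF>ALT` / `POS:ins:SEQ` / `POS:del:SEQ` syntax. Golden-Gate adapter
overhangs for oligo export are configuration
(`inst/extdata/oligo_adapters.yml`), since acceptor vectors differ between
labs; tests assert oligo *structure* (adapter + payload + adapter, bottom
strand reverse-complementary over the payload), not particular adapter
bases.

## Known limitations

* Off-target search is out of scope; use a dedicated off-target scanner
  on the designed spacers.
* The pegRNA score is a heuristic triage, not a learned efficiency model;
  similarly-scored pegRNAs should be tested experimentally.
* No RNA secondary-structure modelling of the extension.
* Editor windows other than ABEmax's are literature defaults, declared and
  editable, not package-verified facts.
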