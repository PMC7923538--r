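# pegbe

Design guide RNAs for the two mainstream precision genome-editing
modalities:

* **Prime editing (PE2/PE3/PE3b)** — for a requested edit (substitution,
  insertion or deletion), find every candidate 5′-NGG-3′ protospacer on
  either strand, assemble the pegRNA 3′ extension (reverse-transcriptase
  template + primer binding site), score each candidate with a heuristic
  penalty model, and pick secondary nicking guides for the PE3 and PE3b
  systems.
* **Base editing (ABE/CBE)** — for a single-nucleotide change, work out
  which deaminase can perform it on which strand, search a registry of
  eleven Cas9–deaminase fusions spanning seven distinct ABE PAM motifs, and
  report every guide that places the target base inside the editor's
  activity window, together with bystander bases that could be co-edited.

The package is aimed at genome-engineering labs designing guides for single
variants or for batches of variants (including ClinVar-style tables), from
raw sequence or from genomic coordinates against any user-supplied FASTA.

## The models

**pegRNA geometry.** A pegRNA consists of a 20-nt spacer, the sgRNA
scaffold, and a 3′ extension written 5′→3′ as RTT then PBS. With the Cas9
nick placed between protospacer positions 17 and 18 (3 nt 5′ of the PAM),
the extension is the reverse complement of the *edited* PAM-strand segment

```
extension_3p = revcomp( edited[nick − pbs_len, nick + rtt_len) )
```

A candidate exists iff the whole alternate allele lies inside the RTT
window `[nick, nick + rtt_len)`. PAMs are scanned on both strands from 6 nt
3′ of the edit to 100 nt 5′ of it; PBS and RTT default to 13 nt each.

**pegRNA score.** The sum of four penalties, larger-negative = worse:
−28 if the extension starts with C (pairs with Cas9 G81), −50 for a run of
more than 4 consecutive T (Pol III terminator), −6 if fewer than 5
homologous nt follow the edit, and −1 per nick-relative edit position. The
best attainable score is therefore −1.

**Nicking guides.** PE3: opposite-strand NGG protospacers whose nick lies
40–100 nt (inclusive) from the pegRNA nick. PE3b: opposite-strand
protospacer+PAM footprints overlapping the pegRNA footprint by ≥ 1 nt,
taken from the *edited* sequence so the second nick fires only after
successful editing.

**Base editors.** ABEs convert A→G, CBEs C→T, each on the strand the
deaminase acts on; a genomic C→T variant is reverted by A→G on the
antisense strand, and transversions are structurally not base-editable.
Editing windows are protospacer positions counted from the PAM-distal end
(ABEmax: 5–7). The registry is a flat editable table; BE3(R33A/K34A)
carries its 5′-T sequence constraint, and near-PAMless SpRY carries a
lower-efficiency note used in ranking.

## Worked example

```r
library(pegbe)

# a 240-nt A/T background with one planted TGG PAM
seq <- make_sequence(240, plant = data.frame(strand = "+", pos = 121, seq = "TGG"),
                     seed = 1729)
res <- design_pegrnas(seq, edit_substitution(128, substr(seq, 128, 128), "G"),
                      show_all = TRUE)
res[, c("score", "protospacer", "edit_position", "pam_seq", "strand")]
#> # A tibble: 1 × 5
#>   score protospacer          edit_position pam_seq strand
#>   <int> <chr>                        <int> <chr>   <chr>
#> 1   -17 ATATATTATATTAATAAATT            11 TGG     +
```

One pegRNA is found: the edit sits 11 nt from the nick (edit-distance
penalty −11) and only 2 homologous nt follow it within the 13-nt RTT
(short-homology penalty −6), so the score −17 warns this is a mediocre
design — lengthening the RTT would help. `glance(res)` summarises a run,
`autoplot(res)` draws the penalty breakdown, and `export_oligos(res)`
emits Golden-Gate-ready cloning oligos.

Base editing:

```r
s <- paste0(strrep("C", 30), "CCCCCA", strrep("C", 14), "TGG", strrep("C", 30))
be <- design_be_guides(s, 36, "A", "G")
be[1, c("editor", "edit_position", "pam_seq", "n_bystanders")]
#> # A tibble: 1 × 4
#>   editor        edit_position pam_seq n_bystanders
#>   <chr>                 <int> <chr>          <int>
#> 1 ABEmax-SpCas9             6 TGG                0
```

A command-line front end ships at `inst/cli/pegbe`
(`pe`, `be`, `batch` and `template` subcommands; see `run_cli()`).

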