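---
title: "Methods: in-silico analysis of Thermus-family Type IIC/IIL restriction-modification systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Thermus-family Type IIC/IIL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermusRM)
```

## The system being modelled

Thermus-family Type IIC/IIL enzymes such as TaqII (5'-GACCGA-3') and TaqIII
(5'-CACCCA-3') are single-polypeptide restriction-methyltransferases. They
recognize an asymmetric site, methylate the adenine at the last position of
the motif strand, and cleave downstream of the site at a fixed distance:
11 nt on the motif ("top") strand and 9 nt on the opposite strand, measured
from the bond just 3' of the methylated adenine. Because the top cut lies
further downstream than the bottom cut, every cleavage junction carries a
2-nt 3'-protruding single-stranded end.

This package implements the computational side of characterizing such a
system: digestion simulation, inversion of run-off sequencing reads into
cleavage geometry, a residue-to-base recognition code for the
target-recognition domain (TRD), protein physicochemical profiling and
paralog comparison, and synthetic-data generation with known ground truth.

## Coordinate conventions

All DNA coordinates are 0-based and half-open; scissile bonds are encoded as
the index of the base immediately 3' of the bond on the top strand, so the
top-strand length of a fragment between bonds `a` and `b` is simply `b - a`.
Motif hits on either strand are reported by their top-strand start. For a
`+` site with last motif base at index `e`, the cuts are `e + 1 + 11` (top)
and `e + 1 + 9` (bottom); a `-` site is the mirror image (top-strand cut at
`start - 9`, bottom at `start - 11`). On linear substrates, a site whose cut
bonds do not fit within the molecule is reported as present but not
cleavable — this matches the physical behaviour of offset cutters near
fragment ends. We considered exposing a "nicking" mode for sites where only
one strand's bond fits, but since nothing in the characterized family
documents single-strand cutting near ends, the engine simply declines to cut
such sites; single-strand nicks are not modelled at all.

Degenerate (IUPAC) motifs are matched with `Biostrings`; an `N` in a
substrate is treated conservatively and matches nothing, so ambiguous
regions can never create phantom sites. Circular substrates are scanned
across the origin by internally extending the sequence by `motif length - 1`
bases; duplicate hits at `start >= length` are discarded.

## Digestion model

`digest()` cleaves every cleavable site in complete mode, or an explicit
subset of sites in partial mode — Thermus-family enzymes characteristically
leave substrates incompletely digested, so partial products are first-class
objects here, with `enumerate_partial_digests()` producing all `2^k` subset
digests (capped at `k = 12`; above that the enumeration is refused rather
than silently truncated). Coinciding scissile bonds from different sites are
counted once. One cut linearizes a circular substrate into a single
full-length fragment. Methylation-based self-protection can be switched on
(`respect_methylation`), in which case flagged sites are never cut; it is
off by default because the simulated substrates are unmethylated PCR
products.

A useful identity worth stating precisely: digesting the reverse complement
of a substrate yields the same duplex fragments with the strand roles
swapped, so the mirrored digest's top-strand lengths equal the original
digest's *bottom*-strand lengths. The two multisets differ by the 2-nt
overhang at each junction; tests assert the exact swapped form.

## Run-off inference

Run-off Sanger sequencing reads across a cleaved terminus reveal the
scissile bonds: a read synthesizing the bottom strand travels toward
decreasing coordinates and stops at the top-strand bond; a top-synthesizing
read stops at the bottom-strand bond. Sequencing polymerases typically
append exactly one template-independent base, which `simulate_runoff()`
models as a flag (`plus_one_artifact`, default on) that shifts the apparent
terminus by one position in the direction of travel — a single base, always,
never a heuristic. Whether the artifact applies to one or both read
directions is not settled by the characterization data, so both directions
accept the flag independently and neither behaviour is asserted as "the"
condition.

`infer_cleavage()` inverts the two termini into bond coordinates, expresses
them as offsets downstream of the motif's terminal adenine, and reports the
overhang (length and 3'/5'/blunt polarity). With a single read it returns a
partial call: one offset, overhang undetermined. The simulate-then-infer
round trip is exact by construction and is property-tested over random
motifs, offsets 0-20, both strands and both artifact settings.

## The recognition code

The predictor rests on the observation that the TRDs of the TspGWI branch
align with those of Type ISP enzymes whose base-contacting residues are
known from crystal structures. Anchors are defined in TaqII numbering
(586, 594, 683, 688, 737, 777, 817, the 818-822 loop, 823/824, 1056, 1058)
and transferred to a query protein by pairwise global alignment (BLOSUM62,
gap open 10 / extend 0.5) rather than through a fixed multiple alignment:
pairwise transfer is reproducible with nothing but the reference, and the
anchor coordinates are published in TaqII numbering anyway. If fewer than
80% of anchor slots land on residues, extraction fails loudly rather than
returning a low-quality map.

The rules, one ordered list per motif position 0-6 with position 5 fixed to
the methylatable adenine, are first-match-wins and every position ends in a
fallback to `N`, so the predictor never invents a base without a supporting
rule and degrades gracefully on unknown anchor combinations. The table is
also shipped as a YAML config (`inst/extdata/recognition_rules.yaml`) so
uncharacterized homologs can be screened against edited rules without code
changes. Two deliberate exclusions: the 683/688 auxiliary pair for position
2 is recorded in the anchor map but not used by any rule, because the
available description of those positions is internally ambiguous; and the
position-1 major-groove contacts have no assigned TaqII indices, so the
position-1 rule uses only the 1056/1058 minor-groove anchors. The
position-4 loop is scanned in *all* registers for the `S.R` / `R.S`
patterns — the 3-aa insertion variant shifts the register, and when both
patterns occur the first match wins and the conflict is recorded in the
prediction's evidence table. Predictions for enzymes outside the TspGWI
branch emit a scope warning.

`covary()` is the complementary data-driven scan: for each non-invariant
alignment column and each motif position it scores, over all enzyme pairs,
whether same-residue agrees with same-base (a fraction in [0, 1]), flagging
perfect covariation. Enzymes with `N` at a motif position contribute no base
observation there and are excluded from that position's comparison — `N`
means "no specificity", not a fourth base.

### The reference scaffold is synthetic

The deposited TaqII/TaqIII protein sequences are not redistributed with the
package, so the default alignment reference is a *synthetic* 1105-aa
scaffold (`synthetic_taqII_protein()`) carrying the documented anchor
residues at the documented TaqII coordinates over a random background, with
TaqIII-like and TspGWI-like derivatives constructed by the documented anchor
edits plus controlled background divergence. Only the anchor residues and
their coordinates are real; everything between them is generated. What
passing self-consistency tests show is therefore that the rule table and the
alignment-transfer machinery reproduce the three known motifs from the known
anchor residues — not that the package has re-derived them from the deposited
sequences. Anyone with the GenBank downloads can substitute the real
proteins via `taqII_reference()`.

## Protein analytics

`protein_profile()` mirrors the ExPASy ProtParam conventions: molecular
weight as the sum of average residue masses plus one water (the ExPASy mass
table, embedded with provenance comments); theoretical pI by bisection of
the Henderson-Hasselbalch net charge to zero using the Bjellqvist pK set
including residue-specific terminal pKs (bisection tolerance 1e-4 pH units;
the net charge at the returned pI is zero to better than 1e-3 elementary
charges); the Guruprasad dipeptide-weight instability index with the
classical "unstable above 40" call; and the Ikai aliphatic index. These are
implemented in the package because no installed R package provides the
ProtParam-equivalent set; values are cross-checked in the tests against
independently computed references.

`global_identity()` uses Needleman-Wunsch with affine gaps via `Biostrings`.
Percent identity divides by the full alignment length by default, so gap
columns count as differences; a `denominator = "shorter"` flag is provided
because a rounded published identity figure cannot disambiguate the
convention. Substitutions and indel columns are tallied separately — a
published count of "amino-acid differences" may or may not include indels,
so the report exposes both rather than asserting one sum. Differences are
assigned to domains via a user-supplied domain map; the package's default
(`synthetic_domain_map()`) is an approximate REase / helical / MTase / TRD
band model for the 1105-aa frame, a config input rather than a claim about
exact domain boundaries, which are not numerically established.

Theoretical tryptic digestion cleaves after K/R except before P
(0-2 missed cleavages); `classify_peptides()` marks peptides shared between
two digests versus unique, with domain of origin. Matching of experimental
spectra is out of scope: the observed shared/unique peptide counts of a real
mass-spectrometry run depend on raw spectra and are not reproduced here.

## Synthetic data: what it emulates, and what it does not

`make_substrate()` plants exact motif occurrences into random background at
66% G+C — matching the composition of the genes encoding these enzymes — and
rejects backgrounds containing spurious occurrences of any planted motif
(rejection sampling keeps the background statistics honest; masking would
not). Truth records (sites, bonds, complete-digest fragment sizes) are
computed by deliberately duplicated arithmetic, independent of the digest
engine, so generator and engine cross-validate. The default study-condition
sizes are those of the assay substrates: 390 bp for digestion layouts,
497 bp for the run-off substrate.

The generators emulate site placement, cleavage geometry and read-terminus
arithmetic. They do not emulate sequencing noise, chromatogram artifacts
beyond the single +1 base, partial-digestion kinetics, methylation kinetics,
or gel migration; passing tests therefore validate the coordinate logic and
the inference algebra, not robustness to noisy real traces.

All generators are seed-deterministic, and scaffold proteins are fixed
constants (internal fixed seeds), so every fixture is reproducible from
source.

## Problem sizes and numerical choices

The property suites run at desk scale: 500 random substrates for the
scanner-vs-brute-force and conservation ensembles, 200 random enzyme
geometries for the run-off round trip, 10-enzyme families for the
covariation scan. Alignment scoring is BLOSUM62 with gap open 10, extension
0.5 throughout; pI bisection runs on [0, 14] to 1e-4; the partial-digest
enumeration cap is 2^12. Ties among coinciding scissile bonds collapse to a
single cut. Self-site screening of a gene "and its flanking regions" takes
whatever region the caller passes — flank width is an explicit caller
choice, since no particular width is canonical.

## Known limitations

* The accession loaders (`load_taq_rm_gene()`) require a user-supplied
  download of CP020571/CP020572; the quantitative checks that depend on the
  deposited sequences (published pI / instability / aliphatic values, the
  93.4% identity, 66% G+C, zero self-sites) run only when those files are
  present.
* The recognition rules cover the TspGWI branch; TspDTI-subfamily and
  Type ISP enzymes are outside their validated scope (a warning is raised).
* The GenBank reader is minimal (sequence + simple CDS locations), by
  design; records with compound join locations need preprocessing.
* Gel-band emulation orders fragments by exact length; co-migration of
  near-equal fragments is not modelled.
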