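---
title: "Methods: screening proteomes for PTS2 peroxisomal targeting signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening proteomes for PTS2 peroxisomal targeting signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pts2screen)
```

## The model

Peroxisomal matrix proteins are imported by one of two receptor
pathways. PEX5 recognizes a C-terminal **PTS1** tripeptide; the plant
consensus `[SA]-[KR]-[LMI]>` enumerates 2 × 2 × 3 = 12 canonical
tripeptides, and additional non-canonical tripeptides are known from
experimental work. PEX7 recognizes an N-terminal **PTS2** nonapeptide
whose four informative positions follow the grammar
`[RK]-[LVI]-x5-[HQ]-[LAF]`; the five `x` positions are variable with a
hydrophobic tendency at the middle one (position 5 of the nonapeptide).
A functional PTS2 almost always sits within the first ~40 residues of
the precursor and is removed after import by the DEG15 protease, whose
processing region carries a conserved Cys shortly downstream of the
nonapeptide.

The screen implemented here is deliberately **set-membership only**:
a 9-residue window matches iff every constrained position holds a
residue from its class. No position-specific scoring matrix, no
probabilistic model — the scientific claim such a screen supports is
"this proteome contains sequences compatible with the PTS2 grammar",
and a deterministic grammar keeps that claim auditable. The grammar is
compiled to a regular expression wrapped in a zero-width lookahead so
that overlapping windows are all reported; an independent per-window
set-membership loop (`scan_pts2_exhaustive()`) exists as a second code
path and defines simulation ground truth.

Two presets are provided. The **stringent** grammar is the one above.
The **relaxed** grammar additionally admits Met at position 2 and
Met/Val at position 9, variants observed in functional nonapeptides of
stramenopile orthologs (e.g. `RMx5HL`, `RLx5HV`). The conservation
module classifies a nonapeptide on the hierarchy stringent → relaxed →
none, so the two grammars also serve as a coarse conservation scale.

## Coordinate and parsing conventions

* Coordinates are 1-based inclusive, with the initiator Met counted as
  residue 1; a match therefore always satisfies `end − start = 8`, and
  reports print spans like `10–18`.
* Sequences are uppercased on input; a single trailing stop symbol `*`
  is stripped; an internal `*` is rejected as a truncated gene model.
* Ambiguity codes (X, B, Z, U, …) never satisfy a constrained position
  — a constrained position demands evidence of a specific residue —
  but do satisfy unconstrained positions.
* The N-terminal window rule is **start-based**: a match qualifies iff
  `start ≤ window` (default 40). The alternative reading, requiring
  the entire nonapeptide inside the window, would exclude a match at
  35–43, which established screens count as inside the N-terminal
  40-residue domain; start-based is the simplest rule consistent with
  that practice.
* When a protein has several in-window matches it contributes one
  candidate whose primary match is the earliest (smallest start;
  unique because starts are distinct). All matches stay available in
  the screen object.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | 40 aa | N-terminal region a qualifying match must start in |
| `motif_mode` | `stringent` | grammar preset |
| `cys_window` | 10 aa | how far downstream of the nonapeptide end to look for the cleavage Cys |
| `hydrophobic_set` | A,V,L,I,M,F,W | residues counted hydrophobic at position 5 |
| `enforce_pos5` | off | make position-5 hydrophobicity a scan constraint rather than a flag |
| `extended_pts1` | AHL, SHL, SLL, SSL, SAL | non-canonical tripeptides reported as `listed_noncanonical` |
| `e_max`, `id_min`, `cov_min` | 0.001, 30 %, 0.5 | homology significance thresholds, all strict |

The cleavage-site literature says only "closely downstream", so
`cys_window = 10` is a choice: wide enough to span reported processing
regions, narrow enough that background Cys (≈5 % of residues) only
occasionally lands inside. Position-5 hydrophobicity is reported but
not enforced by default because experimentally supported nonapeptides
with polar position-5 residues exist; the default hydrophobic set is
the common seven-residue one, while surveys of functional PTS2 report
mainly Ile/Leu/Val at that position. The extended PTS1 list is **not**
a reimplementation of a PTS1 predictor: it is a small, replaceable
list of tripeptides treated as predicted PTS1 in the literature this
screen accompanies, and the `canonical` category is computed from the
consensus alone.

## Homology filtering

BLAST tabular input (`outfmt 6`, 12 columns, or 13 with `qlen`
appended) is filtered with strict inequalities — `E < 0.001`,
`identity > 30`, `coverage > 0.5` — following the wording
"*E*-value < 0.001, > 30 % identity, > 50 % of query length" exactly;
a hit at any boundary fails. Coverage defaults to
`alignment_length / query_length`, the plainest reading of "% of query
length"; because alignment length counts gap columns, a gap-free
alternative `(qend − qstart + 1) / query_length` sits behind
`coverage_mode = "query_span"`. Coverage above 1.5 is flagged as a
suspicious length join rather than rejected. A candidate linked by at
least one passing hit to a subject in the user-supplied known-family
set is a `known_family_homolog`; with hits loaded but no such link it
is `novel`; with no hit file it stays `unassigned`. The known-family
subject list is configuration, not package data.

## Conservation and alignment concordance

Conservation runs alignment-free by default: each ortholog is scanned
with the relaxed grammar (a superset of the stringent one, so
relaxed-only signals are classified rather than missed), the earliest
in-window match is taken as its best match, and per-set fractions are
reported. PTS1 calls ride along so the evolutionary PTS2-to-PTS1
transition — N-terminally shortened orthologs that gained a canonical
tripeptide, as in diatoms — is visible in one table.

The optional MSA check maps each sequence's match to alignment columns
(gap characters `-` and `.` are equivalent) and calls the set
concordant iff every match-bearing sequence shares at least
`min_overlap = 5` of 9 columns with the reference's match. No
published cutoff exists for this; majority overlap is the weakest
defensible default and it is configurable. The package never computes
alignments — they are inputs, checked to be ungapped-identical to the
raw sequences when those are supplied.

## The synthetic proteome generator

`generate_proteome()` draws background residues i.i.d. from a
configurable composition (default uniform over the 20 standard
residues) with lengths uniform on 100–600 aa, then overwrites planted
segments at stated coordinates (overwrite, not insertion, keeps
lengths exact). Plant kinds cover the cases the screen must
distinguish: an in-window nonapeptide, the same nonapeptide planted
after the window, a broken nonapeptide (positions 8–9 violated, so it
matches neither preset), a C-terminal tripeptide, and a nonapeptide
with a planted downstream Cys.

Ground truth is defined by **post-hoc exhaustive scanning**, not by
planting bookkeeping: background residues occasionally form genuine
motifs (per-window probability 2.25 × 10⁻⁴ under the stringent grammar
and uniform composition), and the truth ledger labels them truthfully
so they never read as false positives. One seed fully determines the
output; per-protein substreams are derived by counter so plants are
order-independent and proteins are reproducible individually.

The generator emulates composition, length and planted short motifs —
nothing else. Real proteomes have biased composition, domain
structure, low-complexity regions and homology between sequences, none
of which the generator models. Passing tests on synthetic data
therefore demonstrate correctness of the scanning, filtering and
bookkeeping machinery, not the biological precision or recall of the
grammar on real proteomes. The packaged "mirror" plant table
reproduces the *structure* of a published screen outcome (13 in-window
candidates among >50 motif-bearing proteins, split 4 known-family / 9
novel) for end-to-end exercise; its sequences are synthetic stand-ins,
as their filenames state.

## Numerical and degenerate-input choices

* Sequences shorter than 9 residues yield an empty match list, never
  an error; proteins shorter than 3 get PTS1 category `none` with an
  absent tripeptide.
* The Cys search truncates silently at the sequence end.
* The analytic per-window match probability is the product of class
  masses over constrained positions; the per-protein probability
  `1 − (1 − p)^W` ignores overlap dependence between windows and is
  documented as an approximation (overlapping windows are positively
  correlated, so it slightly overstates the per-protein rate).
* `empirical_match_rate()` draws windows independently (9 fresh
  residues each) precisely so its estimator is exactly binomial and
  comparable to the analytic value by standard-error bands.
* The first-exon check ignores the CDS `phase` attribute (first
  segment assumed in frame) and uses the rule
  `3 × match_end ≤ first-CDS-length`; minus-strand transcripts are
  handled by taking translation order from the highest-coordinate
  segment.
* Report spans use the typographic en-dash to match the field's table
  style; `ascii = TRUE` switches to a plain hyphen for downstream
  tools that dislike multibyte output.

## Problem sizes used in the test suite

The suite validates scanner/oracle equivalence on 1000 random
sequences up to 500 aa, end-to-end planted-signal recovery on a
500-protein simulated proteome (150 in-window plants, 250 decoys), and
match-rate calibration on 10⁶ independent windows per preset (3
binomial standard errors around the analytic rates). These sizes give
tight Monte-Carlo bands while keeping the whole suite under a minute
on one core.

## Known limitations

* Set-membership scanning has no notion of signal strength; two
  matches are indistinguishable beyond their flags.
* The screen cannot detect internal PTS2 signals by design (the window
  filter is the point), and known internal-PTS2 exceptions exist.
* Homology classes depend entirely on the hit files and known-subject
  list supplied; the package runs no alignments itself.
* The first-exon annotation requires GFF3 `Parent` identifiers to
  match protein identifiers exactly.
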