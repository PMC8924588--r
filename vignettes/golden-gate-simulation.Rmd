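---
title: "Simulating BsaI Golden Gate assembly for Yarrowia pathway construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating BsaI Golden Gate assembly for Yarrowia pathway construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yaliclone)
```

## The system being modelled

Golden Gate cloning exploits type IIS restriction enzymes, which cut at a
fixed distance *outside* their recognition sequence. Because the overhang
left behind is not part of the recognition site, it can be chosen freely:
a set of mutually incompatible 4-mers acts as an addressing scheme that
dictates the order in which fragments ligate. Digestion and ligation run
in the same tube, cycling between 37&nbsp;°C and 16&nbsp;°C; any product
that still contains a recognition site is eventually re-cut, while correct
junctions — which fuse two half-sites without regenerating either — are
irreversible. The reaction therefore funnels material into the designed
product.

`yaliclone` models a concrete instantiation of this idea aimed at
*Yarrowia lipolytica* metabolic engineering: three destination vectors
(pGGYL1, pGGYL2, pGGYL3) accept 4, 7 or 10 fragments — a selection marker
plus one, two or three promoter–gene–terminator transcription units —
between junction overhangs numbered 1–11. The assembled plasmid is
linearized with SwaI, which releases the marker-plus-TU cassette for
NHEJ-mediated random chromosomal integration, and colonies are screened
blue/white via a lacZ stuffer that the assembly replaces.

## Sequence model and cut geometry

Sequences are strings over `{A,C,G,T}` with linear or circular topology
and 0-based, half-open feature coordinates; circular positions are reduced
modulo length, which makes origin-spanning sites and features unambiguous.
Ambiguity codes are rejected: every part in this toolkit is a fully
specified sequence, and the downstream string-equality ligation rule
requires exact bases.

BsaI is modelled as recognition `GGTCTC`, spacer 1, overhang 4. For a
plus-strand site starting at $p$, the top strand is cut at
$p + 6 + 1$ and the bottom strand four nucleotides further; a minus-strand
site mirrors this arithmetic. Each cut is represented as the window
$[\mathrm{top\_cut}, \mathrm{bottom\_cut})$, whose top-strand content is
the 4-nt 5′ overhang. SwaI (`ATTTAAAT`) cuts bluntly in the middle of its
palindrome. Methylation sensitivity, star activity, partial digestion and
ligation thermodynamics are out of scope — the simulator answers "what can
this pool of ends form", not "how fast".

A digestion fragment stores its full top-strand footprint (both overhang
windows included) plus the two windows as *normalized* overhangs: always
the top-strand 5′→3′ reading of the window. Under this normalization, two
ends are ligation-compatible **iff their strings are equal**, and flipping
a fragment maps `(left, right)` to `(rc(right), rc(left))`. This collapses
all strand bookkeeping into string comparisons, which is what makes the
closure search below simple and fast. Conservation holds by construction:
summing fragment lengths with each shared window counted once returns the
parent length, and re-ligating the fragments in order reconstructs the
parent exactly — a property the test suite exercises on seeded random
digests.

## The one-pot closure search

All input plasmids are digested and the fragments pooled. A candidate
product is a simple cycle: an ordered, oriented sequence of distinct
fragments in which every junction joins equal normalized overhangs. The
search walks a directed graph with overhang 4-mers as nodes and oriented
fragments as edges, enumerating simple cycles up to a size bound (default
12 pieces) and deduplicating by a canonical form invariant to rotation and
reflection. A brute-force oracle — every subset, permutation and
orientation assignment of up to six fragments — is shipped alongside and
the two are required to agree on seeded pools; this is the package's
primary guard against search bugs.

Circles are divided into **stable** closures, built entirely from
fragments free of internal BsaI sites, and **transient** ones (the
vector–stuffer religation, donor-plasmid religations and their
combinations), which still carry recognition sites and are re-cut by the
cycling reaction. The intended product must be a stable closure containing
the vector body; under a faithful overhang table it is provably the only
one, and the simulator flags any additional stable closure as a potential
mis-join. Transient circles are still reported as side products because
they transform perfectly well — the vector–stuffer religation is exactly
the blue-colony background, and a mis-joined circle that lost the stuffer
is a white false positive, which is why the verification PCR and junction
sequencing exist. When no stable closure contains the vector body the
simulation raises an `assembly failure` condition carrying the longest
linear extension as a diagnostic and the side products it did find.

Stoichiometry is deliberately ignored: each fragment exists once,
mirroring an equimolar setup, and concentration or ligase-brand effects on
efficiency are not modelled. The wet-lab observables tied to them
(efficiency percentages, transformant counts) are replaced by the
structural properties above.

## Overhang fidelity

A usable fusion-site set must not cross-talk. `check_overhang_set` fails a
set for duplicate 4-mers, reverse-complement pairs (their ends anneal to
each other's partners) and self-palindromes (such an end anneals to a copy
of itself), and warns about pairs at Hamming distance 1, which ligases
join at reduced fidelity. The published toolkit's actual 4-mers are not in
the main text, so the package ships a synthetic 11-entry table that passes
all checks; any user table can be substituted and is validated the same
way. Junction labels place overhang 1 between vector and marker and
overhang 5, 8 or 11 at the closing vector junction, so a donor plasmid is
reusable across every backbone that shares its slot position; re-using a
part in another slot position is modelled as an explicit re-clone
(`retarget_part`), which is how the physical library handles it too.

## Domestication

Internal BsaI or SwaI sites inside a part would be cut during assembly, so
they must be removed beforehand. In coding sequence this is free of
phenotypic cost: for each motif occurrence (either strand), the algorithm
tries every synonymous replacement of every overlapping codon, requires
that the replacement destroy the site and create no new forbidden motif in
a ±10 nt window, and applies the one changing the fewest bases. Ties break
deterministically — leftmost codon, then lexicographically smallest new
codon; the first two criteria are this package's own refinement to make
the published "synonymous mutation" rule a deterministic procedure. The
loop repeats until a full-sequence scan is clean; since motifs are at most
8 nt, any motif created or destroyed by an edit lies inside the rescan
window, so the global motif count strictly decreases and termination is
guaranteed. Translation equality is asserted on every call.

Non-coding sequence (promoters, terminators, vector regions) is only ever
*flagged*: there is no synonymous-substitution argument there, and an
automated edit could silently change promoter strength. This mirrors the
practice of fixing vector sites by targeted PCR rather than by rule.

## Post-assembly operations

SwaI digestion of a correct product yields exactly two blunt fragments;
the one carrying the marker feature is the integration cassette, and the
package checks base conservation and that kanR/ori stay on the vector
fragment. In silico colony PCR uses the toolkit's F/R primers
(`TCTCCCCGCGCGTTGGCCGATT` / `GTCTCGCGCGTTTCGGTGATG`), which bind the
vector just outside the SwaI sites; binding is exact-match only, because
these are verification primers designed against exact targets, and the
shortest spanning amplicon is reported (both ways around a circle).
Marker recycling has two modes: Cre/loxP excision between the first
direct-orientation pair of canonical 34-nt loxP sites, leaving a single
scar (inverted pairs error out — inversion is not modelled), and
hisG-URA3-hisG pop-out, which collapses two identical direct hisG repeats
to one and deletes URA3, the deterministic outcome that 5-FOA
counter-selection selects for. Both are idempotent-to-error: re-running
them on their own output reports nothing to excise.

## Combinatorics and the improvement ladder

`enumerate_designs` expands per-slot candidate lists into the full
Cartesian product in deterministic lexicographic order (later slots vary
fastest) — shuffling 8 promoters against 9 terminators around a fixed gene
gives the expected 72 designs. `plan_rounds` maps gene sets to the
smallest backbone that fits (a marker plus $k$ TUs needs $1+3k$
fragments), assigns promoters/terminators slot-positionally and genes in
input order, and enforces that a marker reused in a later round is
recyclable. The metrics layer is deliberately tiny — fold change, percent
increase, volumetric productivity, and a best-of-round ladder with ties
broken by strain id — because its value is reproducibility: the report is
invariant to input order and rounds the way the field prints (folds to one
decimal, collapsing to integers within 0.05; percentages to one or two
decimals as printed).

## The synthetic demo toolkit

No real sequences ship with the package; a seeded generator builds a
catalog with the published structure — 8 promoters (300–800 nt), 9
terminators (100–300 nt), the 8 mevalonate-pathway CDSs plus a
bisabolol-synthase stand-in (600–1,800 nt, codon-sampled with a single
stop), and 6 markers (1,000–2,000 nt; one hisG-URA3-hisG, five
loxP-flanked), GC content drawn from 0.35–0.65. These ranges are the
package's defaults for what a realistic yeast part library looks like.
Every part is rejection-sampled to be free of BsaI/SwaI sites on both
strands, and — one step further than per-part validation — every junction
context the slot grammar can ever produce (part tail + overhang + part
head, and the donor/backbone joints) is scanned for accidental sites, with
offending parts redrawn deterministically. This guarantees the scar-free
product invariant for *every* design expressible in the grammar, not just
the ones tested.

What the synthetic toolkit does **not** emulate: real promoter/terminator
sequence composition (the placeholders are random DNA), actual marker
genes, genome context for integration, or any expression phenotype. Tests
passing on this toolkit demonstrate the combinatorial and geometric
correctness of the simulator, not biological activity of the parts.

## Numerical and scale choices

Everything is deterministic given a seed: the generator derives per-part
sub-seeds from a string hash, RNG state is saved and restored around every
draw, and GenBank output pins its header date to a sentinel so files are
byte-reproducible. The canonical form used to deduplicate circles is the
lexicographically least rotation of the sequence or its reverse
complement, computed by candidate refinement. The shipped verification
scale — 200 seeded designs for the digest→assemble roundtrip, 30 pools of
at most 6 fragments for oracle equivalence, several hundred motif-planted
CDSs for domestication — was chosen as the point where every code path
(all three backbones, all marker types, mixed pool compositions) is
exercised many times over while a full run stays comfortable on a laptop.

## Known limitations

- Ligation is all-or-nothing on exact 4-mer equality; single-mismatch
  ligation, the physical route to rare mis-joins, is only surfaced as a
  fidelity *warning* on the overhang table, not simulated in the pool.
- PCR requires exact primer matches; degenerate or mismatched priming is
  out of scope.
- Side-product enumeration is bounded (12 pieces by default); the physical
  reaction is unbounded, so the report is a curated, deduplicated summary
  rather than a census.
- Assembly efficiency, transformant counts, expression levels and titers
  are not predicted — the package checks designs and verifies arithmetic
  on measured values, it does not model the biology that produces them.
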