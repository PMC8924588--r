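# yaliclone

In silico Golden Gate assembly for *Yarrowia lipolytica* pathway
engineering.

Multi-gene pathway construction in *Y. lipolytica* can be done quickly by
assembling promoter–gene–terminator units plus a selection marker into a
destination vector in a single BsaI/T4-ligase reaction, excising the
assembled cassette with SwaI, and integrating it into the chromosome by
non-homologous end joining (NHEJ). `yaliclone` models that workflow for
anyone designing or debugging such constructs: it validates parts against
the toolkit grammar, simulates the one-pot digestion–ligation reaction
(including the side products that cause blue and false-white colonies),
domesticates coding sequences, plans combinatorial and multi-round builds,
and checks the strain-improvement arithmetic of an engineering campaign.

## The model

A type IIS enzyme (BsaI, recognition `GGTCTC`, one-nucleotide spacer) cuts
*outside* its recognition site, leaving a programmable 4-nt 5′ overhang.
Parts are stored in donor plasmids between two inward-pointing BsaI sites;
the destination vectors pGGYL1/2/3 carry a lacZ stuffer between
outward-pointing sites, so digestion hands the vector body two junction
overhangs and discards both recognition sites. Junction overhangs are
numbered 1–11 across the maximal design:

```
pGGYL1 (4 fragments):  [1] marker [2] promoter [3] cds [4] terminator [5]
pGGYL2 (7 fragments):  [1] marker [2] P [3] C [4] T [5] P [6] C [7] T [8]
pGGYL3 (10 fragments): [1] marker [2] ... three P-C-T units ... [11]
```

Two sticky ends ligate iff their overhangs anneal; with overhangs
normalized to the top-strand reading this collapses to string equality, and
the one-pot reaction becomes a cycle search on a graph whose nodes are
4-mers and whose edges are fragments in either orientation. Correct
products contain no recognition site and therefore accumulate as the
digestion–ligation cycling re-cuts everything else.

## Worked example

```r
library(yaliclone)

kit <- gen_demo_toolkit(fixture_config(seed = 1001))
reg <- kit$registry
reg
#> <ggyl_registry> 32 parts (marker=6, promoter=8, cds=9, terminator=9,
#>                 stuffer=0, mva_cds=8), 3 backbones, 11 overhangs

design <- design_with_retargeting(
  "pGGYL1", c("HUH", "PTEF", "ERG10", "TXPR2"), reg)
product <- simulate_assembly(design)
product
#> <assembly_product> 3534 bp circular, 5 junctions, colony white
product$junctions
#>   label sequence
#> 1     1     AATG
#> 2     2     AGGT
#> 3     3     GCTT
#> 4     4     CCAG
#> 5     5     TGCC
```

The intended circle was the unique stable closure: the colony is white, the
junctions run in slot order, and `scan_sites(product$sequence, bsaI())`
finds nothing. The side-product list contains the vector–stuffer religation
(blue colonies) and the transient donor-vector circles. Downstream:

```r
recommend_protocol(4)          # 600 U T4 ligase, 60 cycles
cassette <- extract_cassette(product)$cassette
cassette                       # 3083 bp: HUH marker + PTEF-ERG10-TXPR2
in_silico_pcr(product$sequence)$length
#> 3154                         # F/R colony-PCR amplicon spans the insert
hisG_popout(cassette)          # 2167 bp: URA3 popped out, one hisG left
```

After each integration round the best strain seeds the next one; the
ladder report turns a titer ledger into fold improvements:

```r
ladder_report(data.frame(strain = paste0("best-", 1:6), round = 1:6,
                         titer = c(2.5, 70.6, 135.3, 242.6, 275.3, 573.7)))
#>   round best_strain titer fold_prev fold_cumulative
#> 2     2      best-2  70.6     28.24           28.24
#> 4     4      best-4 242.6      1.79           97.04
#> 6     6      best-6 573.7      2.08          229.48   (abridged)
```

A command-line wrapper lives in `inst/cli/ggclone.R`
(`gen-fixtures`, `validate-part`, `domesticate`, `assemble`,
`extract-cassette`, `ipcr`, `recycle`, `shuffle`, `plan-rounds`, `ladder`).

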