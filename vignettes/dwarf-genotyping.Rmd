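---
title: "Marker-assisted dwarf genotyping and cross prediction in sorghum"
author: "DwTyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-assisted dwarf genotyping and cross prediction in sorghum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DwTyper)
```

## The problem

Plant height in grain sorghum (*Sorghum bicolor*) is classically
controlled by four loci, *Dw1*–*Dw4*. At each locus the dominant allele
(*Dw*) confers tallness and the recessive allele (*dw*) shortens
internodes, so a genotype is usefully summarised by how many loci are
recessive-homozygous: the five-level "dwarf class" scale from zero-dwarf
to four-dwarf, where a heterozygous locus counts as dominant. Breeding
programmes aim for short, lodging-resistant hybrids, but two parents of
the *same* dwarf class and similar height can still produce much taller
F1s when the *identity* of their dwarfing loci differs — a three-dwarf
line carrying *Dw1* crossed with a three-dwarf line carrying *Dw2*
yields a two-dwarf F1 heterozygous at both loci. Knowing which locus
carries which allele in the parental pool is therefore the operative
question, and three of the four loci are cloned and directly assayable
from PCR amplicons:

* **Dw1** — a single diagnostic base in a 427-bp product: A for
  *dw1*, T for *Dw1* (an A-to-T change created the dominant allele).
* **Dw2** — a 2-bp GA dinucleotide in a 997-bp product: present for
  *Dw2*, deleted (995 bp) for *dw2*.
* **Dw3** — an 882-bp tandem duplication: the *dw3* product is
  1263 bp, the *Dw3* product 1263 + 882 = 2145 bp, a difference easily
  scored on an agarose gel.
* **Dw4** — uncloned; in the grain-sorghum breeding pool modelled here
  every line is *dw4dw4*, so the package emits a constant recessive
  call with an explanatory note rather than pretending to assay it.

`DwTyper` implements the full desk pipeline around these assays:
allele calling from sequence or gel evidence, four-locus genotype
assembly and classification, Mendelian F1 prediction for diallel and
test-cross designs, and per-genotype-class summaries of the five
architecture traits.

## Genotype representation

A `DwGenotype` stores a 4 × 2 logical matrix (locus × allele copy,
`TRUE` = dominant). The pair at a locus is unordered; serialization
always emits the dominant copy first and the loci in *Dw1..Dw4* order,
so string equality is genotype equality after one round trip through
`parseGenotype()`/`formatGenotype()`. The parser accepts the shorthand
used for fully homozygous inbreds (`"Dw1-Dw2-dw3-dw4"` expands each
token to a homozygous pair) and decides dominance of each copy solely
by its leading capital `D`, tolerating the second letter's case. That
tolerance is deliberate: published tables contain the typeset variant
`"Dw2DW2"`, and the rule makes them machine-readable without manual
correction.

```{r}
g <- parseGenotype("dw1dw1-Dw2DW2-dw3dw3-dw4dw4")
formatGenotype(g)
classifyDwarfType(g)
```

## Marker calling

Marker definitions (`loadMarkerDefinitions()`) bundle each locus's
primer pair, a reference amplicon for the recessive allele, the feature
kind (SNP / deletion / insertion), its offset, and the expected product
lengths, which are checked at load time (the dominant-minus-recessive
difference must be 0, +2 and +882 bp respectively). Published
coordinates for the features are genome-scale labels that cannot be
resolved inside an amplicon, so they are carried as metadata only and
all working coordinates are amplicon-internal. Because full amplicon
sequences are not published, the shipped references are **synthetic**:
fixed-seed random sequences bracketed by the published primers with the
documented features at documented internal offsets
(`inst/extdata/synthetic_reference_amplicons.fasta`). Everything that
matters to the calling logic — primers, feature kinds, length
arithmetic — is real; only the neutral sequence between them is
simulated.

Calling locates the marker site with exact 15-mer flanking anchors. If
an exact anchor match fails, a fallback scan allowing up to two
mismatches within ±30 bp of the expected position is tried and flagged
`ANCHOR_SHIFTED`; Sanger amplicons are near-identical to their
reference, so nothing heavier than this banded scan is warranted.
Decision rules per locus:

* *Dw1*: the base between the anchors — A → `dw1dw1`, T → `Dw1Dw1`,
  anything else (including IUPAC ambiguity codes, which are ignored
  everywhere except at the site itself) → uncallable with
  `AMBIGUOUS_BASE`.
* *Dw2*: the gap between the anchors — `GA` → `Dw2Dw2`, empty →
  `dw2dw2`; any other content, e.g. a partial single-base deletion, is
  uncallable.
* *Dw3*, gel mode: a band within ±5 % of 1263 bp → `dw3dw3`, within
  ±5 % of 2145 bp → `Dw3Dw3`, otherwise uncallable. The 5 % default
  reflects typical agarose sizing error and keeps the two windows
  disjoint; a tolerance that merged them would be a configuration error
  and is rejected rather than silently resolved. Bands accepted away
  from the exact expected length carry `SIZE_TOLERANCE_USED`.
* *Dw3*, sequence mode: the duplication junction is probed with
  anchors; a 0-bp gap is the recessive allele and a gap of exactly the
  duplication length the dominant one.

All callers assume homozygous inbred material — every line in a
breeding panel of sterile and restorer lines is an inbred, and
heterozygosity arises only in *predicted* F1s, which are never
sequenced here. Double-peak (heterozygous) chromatogram evidence is
out of scope.

```{r}
defs <- loadMarkerDefinitions()
obs <- ampliconObservation("demo", "DW3", bandLength = 2145)
callDw3(obs, defs$DW3)
```

## Mendelian cross prediction

`predictF1()` enumerates, per locus, the offspring genotype
distribution from the parents' copy counts (each copy transmitted with
probability ½) and combines loci independently — the classical model
for these four unlinked factors; no linkage, recombination or
quantitative additive model is attempted, and measured F1 heights are
treated as data, not predictions. Identical multi-locus genotypes are
collapsed by summing probabilities, so homozygous × homozygous crosses
collapse to one genotype with probability 1. The implementation is
property-tested against an independent oracle that exhaustively pairs
all 2⁴ × 2⁴ gamete combinations, and reciprocal crosses are equal by
construction (no parent-of-origin effects; reciprocal F1s of real crosses differ
somewhat in measured height, but nothing attributes this to genetics,
so it is not modelled).

`buildDiallel()` fills every ordered off-diagonal pair of a parent set;
`groupTestcrosses()` clusters single-offspring crosses by their
canonical F1 genotype string, which is stable because serialization is
canonical. A/B line pairs (e.g. `A2V4A`/`A2V4B`) are treated as
genotypically identical — the maintainer B line is the one genotyped,
the sterile A line the one crossed — and "female should be an A line"
is a soft warning rather than an error, since cytoplasmic male
sterility itself is not modelled.

```{r}
cr <- predictF1("Dw1-dw2-dw3-dw4", "dw1-Dw2-dw3-dw4",
                femaleId = "A2V4A", maleId = "SX1042")
offspring(cr)
predictF1Class(cr)
```

## Trait analytics

Five traits are measured at wax maturity, in cm, per accession (each
value itself the mean of three field replicates; replicate-level data
is not modelled): plant height, stem height, spike stalk length (the
stem segment from the flag-leaf ring to the panicle base) and spike
length, plus the derived height under the flag leaf
(stem − spike stalk) and the unitless spike-stalk/stem-height ratio.
`deriveMetrics()` recomputes the derived pair and *flags* (does not
reject) rows whose plant height deviates from stem + spike by more
than 0.05 cm — the rounding slack of values reported to two decimals.

`summarizeGroup()` reports n, the arithmetic mean, the **sample**
standard deviation (n − 1 denominator) and the coefficient of
variation as a fraction. The n − 1 choice is empirically forced: the
published 4-accession block SD of 17.24 and 3-accession block SD of
12.25 are reproduced by the sample SD and not by the population SD
(14.93 for the former). SD and COV are reported as `NA` for singleton
groups. `compareGroupMeans()` differences means **after** rounding to
the 2-decimal reporting scale, which is how the published deltas
(+22.37 cm and +67.86 cm between test-cross groups) were evidently
computed; on this data the distinction never exceeds 0.01 cm.

`summarizePanel()` orders genotype blocks by dwarf class (most
recessive loci first) and, within a class, by first occurrence in the
panel. No single lexicographic rule on genotype strings reproduces the
conventional table layout, so first-occurrence order — which does, on
a panel transcribed in that layout — was chosen as the tie-break. The
package performs no inferential statistics: the reference tables
report none, and class membership — not significance — is the
deliverable of this kind of analysis.

## Synthetic data

`simulatePanel()` generates everything the pipeline consumes:
homozygous lines per genotype class with allele-true amplicons for the
three callable loci, and phenotypes drawn per class. Its default class
parameters *are* the study conditions — the per-block mean and SD of
the 95-accession reference panel (`dwClassDefaults()`). The two
singleton blocks print no SD, so their simulation SDs default to 10 %
of the class mean, consistent with the coefficients of variation
(0.12–0.35) of the multi-accession blocks; this was chosen once and is
not tuned.

Traits are drawn independently per trait (no within-class covariance
structure is published for these materials) except the additive identities, which hold by
construction: plant height and spike length are drawn, stem height is
their difference, spike stalk length is drawn truncated to the stem,
and height under the flag leaf follows. Normal draws are truncated at
zero by resampling; at these parameter scales truncation is negligible
except for a slight upward bias (≈1 cm) in the widest class. Sequence
noise is uniform substitution at a configurable rate (≤0.05) that
never touches marker sites or anchors, so calling failures under noise
can only arise through anchor disruption elsewhere; gel sizing error
is Gaussian in bp. A single master seed fully determines output, and
per-line, per-locus hashed substreams mean that enlarging a simulation
never reshuffles previously generated lines.

What passing tests on simulated data do **not** show: the simulator has
no field replicate or block structure, no genotype × environment
effects, no minor-gene height modifiers, and no within-class trait
correlations — all features real panels have. Recovery of generating
parameters here validates the pipeline's arithmetic, not the field
design.

## Numerical choices and problem sizes

* Gel tolerance ±5 % (configurable); windows at 1263/2145 bp stay
  disjoint up to ±25 %.
* Anchor width 15 nt, fuzzy fallback ≤2 mismatches within ±30 bp.
* Trait-identity flagging tolerance 0.05 cm; fixture checks at 0.01.
* Property tests run 200 random genotypes for round-trip/classification
  invariants, 25–30 random parent pairs against the exhaustive gamete
  oracle, allele recovery over all loci × alleles × 100 seeds, and
  parameter recovery on simulated panels of 50 (unit tests) and 200
  (acceptance) lines per class — sizes at which every check completes
  in seconds while leaving Monte-Carlo noise well below the tolerances
  tested.

## Limitations

* Dw4 is a stipulated constant, not an assay; panels from pools where
  *Dw4* segregates would need a cloned marker first.
* Heterozygous sequencing evidence is out of scope (inbred assumption).
* No linkage or quantitative height model: dwarf class is a category,
  not a height prediction.
* The synthetic reference amplicons are stand-ins; calling real traces
  requires replacing them with the true amplicon sequences in the YAML
  config, after which all logic applies unchanged.
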