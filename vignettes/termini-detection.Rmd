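---
title: "Detecting phage genome termini and packaging strategies with pacscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage genome termini and packaging strategies with pacscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacscope)
```

## The biological model

Tailed bacteriophages replicate their circular genome into long
head-to-tail concatemers and cut virion-sized molecules out of them. The
cutting style leaves a signature at the physical ends of the packaged DNA:

* **Cohesive ends (cos)**: the terminase cuts at one fixed site, producing
  identical unit-length molecules with short single-stranded 5' or 3'
  overhangs. Both termini are the same in every virion.
* **Direct terminal repeats (DTR)**: two fixed cuts one-genome-plus-repeat
  apart; every molecule carries the repeat at both ends, so the repeat
  region is present twice per molecule.
* **Headful with a pac site**: the first cut of a processive series is made
  at a preferred initiation site (*pac*); subsequent cuts are made whenever
  the capsid is full, after slightly more than one genome length
  (headful length H > genome length G). Molecules are terminally redundant
  and, after the first in a series, circularly permuted.
* **Headful without a preferred site**: as above but initiation is
  effectively random; all termini are dispersed.

Because shotgun-library shearing always leaves the *physical* molecule
termini as fragment ends, sequencing reads pile their 5' ends on those
termini. The strategy can therefore be read off the genome-wide
distribution of read start positions.

## The SPC statistic and the decision table

`computeSpc()` tallies, per genome position and strand, the number of
alignments whose 5'-mapped end falls there (starting-position coverage,
SPC), treating the reference as circular. For a reverse-strand alignment
the 5' end is its rightmost aligned base.

`peakRatio()` summarizes a strand profile as
*R* = top count / second-highest count, reported to two decimals. A tie at
the maximum yields R = 1 and is never a site call.

`detectTermini()` applies a significance test per strand -- the top count
must be at least `minTopCount` (default 20), R at least `minRatio`
(default 5), and the top count improbable under a Poisson background with
the strand-mean rate (tail probability below `pTail`, default 1e-6) --
and then classifies:

| forward peak | reverse peak | call |
|---|---|---|
| yes | no (or vice versa) | `HEADFUL_PAC`, pac at the peak |
| yes | yes | `FIXED_TERMINI_DTR` if the inter-termini interval is shorter than the genome and its mean coverage is at least `dtrCoverageFactor` (default 1.5) times the genome mean, else `FIXED_TERMINI_COS` |
| no | no | `HEADFUL_RANDOM_OR_PERMUTED` |
| no alignments | | `UNDETERMINED` |

The DTR discriminator works because the repeat is packaged twice per
molecule, doubling its coverage; cos molecules are exactly unit length and
show no such excess, and they also produce zero reads spanning the
termini junction (`junctionSpanningReads()`), whereas terminally redundant
molecules always produce some.

Calls made below 200x mean depth carry a low-coverage warning; pac peaks
scale with depth and become unreliable in shallow libraries.

## Why headful cut positions are jittered

A naive headful simulator that places the cuts of a series at exact
offsets 0, H, 2H, 3H from pac puts every series' molecule starts on the
same S genome positions (S = series length). The SPC profile then shows S
equally tall peaks -- a tie, ratio 1.00 -- and the pac site is
undetectable, which contradicts both the biology (real pac libraries show
a single dominant peak with ratios around 7-9) and the purpose of the
simulator.

The physical reason is that only the initiating cut is sequence-specific;
every later cut is triggered by capsid filling, a mechanically noisy
process. `pacscope` therefore draws each molecule's length from
Normal(H, `headfulSd`) with `headfulSd` defaulting to 1% of H (integer
rounded), while the series-initiating cut stays exactly at pac
(`startFuzz` default 0). Across ~50 series at 200x depth this
concentrates ~50 read starts on the single pac base while the remaining
cut positions disperse over hundreds of bases, reproducing observed peak
ratios of roughly 7-10.

## Parameter defaults and units

All coordinates are 1-based and inclusive; circular positions wrap modulo
G. Defaults (all lengths in bases):

* genome length G = 86,193; GC fraction 0.4907
* headful length H = 1.04 G (`headfulFactor`), i.e. ~4% terminal
  redundancy; `headfulSd` = 0.01 H
* series length S = 4 molecules per initiation event
* DTR length 500 (`DTR_SHORT`) or 5,000 (`DTR_LONG`); cos overhang 12
* shotgun fragments Normal(550, 55), minimum 50; read length 251; both
  fragment ends sequenced (paired reads)
* target depth 200x
* gel criteria: resolvable band range 250-10,000; bands closer than 15%
  relative length are ambiguous; pac fragments under 400 are flagged
  faint; recognition sequences containing CpG are flagged
  methylation-sensitive
* clade-rule support threshold 95 (bootstrap-style 0-100 scale; missing
  supports count as 0)

## What the simulator emulates -- and what it does not

Emulated: the molecule populations of five packaging strategies, random
shearing with terminus-pinned fragment ends, paired-end read geometry,
circular alignment coordinates (including SAM output with the wrapped
portion soft-clipped), optional uniform substitution errors, and exact
reproducibility from a single seed.

Not emulated: base-quality decay, indels and chimeric reads, GC-coverage
bias, alignment ambiguity or mapping-quality filtering, host DNA
contamination, multiple concurrent packaging strategies in one library,
and nicked or partially denatured molecules. Substitution errors do not
move read start positions, so SPC statistics are unaffected by
`errorRate`.

## Virtual digestion and verification design

After `reorganize()` rotates (and, for a minus-strand pac,
reverse-complements) the assembly so the packaging start is base 1,
`digestLinear()` cuts the linearized genome with IUPAC-aware recognition
matching on both strands; the first fragment is the diagnostic terminal
pac fragment, which is submolar on a gel because only series-initiating
molecules contribute it. `selectEnzymes()` ranks candidate enzymes by
flag count and by closeness of the pac fragment to the geometric mean of
the resolvable range. `planVerification()` proposes primer windows just
inside both genome ends for run-off Sanger confirmation.

## Label propagation on TerL trees

The terminase large subunit tracks packaging strategy. Given a rooted
tree with support values and a partial tip labeling,
`propagateLabels()` applies, per strategy: take the MRCA of its labeled
tips; if the MRCA clade contains a tip verified as a different strategy,
record a conflict and propagate nothing; otherwise, if the MRCA support
meets the threshold, assign the strategy to the clade's unlabeled tips.
A single labeled tip is its own MRCA and never propagates. Input labels
are never overwritten.

## Numerical choices and problem sizes

* SPC and coverage are computed by `tabulate()` plus a cumulative-sum
  difference array -- O(n + G) for n alignments, exact integer counts.
* The Poisson tail uses `ppois(top - 1, mean, lower.tail = FALSE)`; at
  200x depth the background SPC mean is ~0.4 per strand per base and the
  observed pac counts (~50) sit far beyond the 1e-6 tail.
* Peak ratios are reported with `round(x, 2)`; all published comparisons
  are at that precision.
* Typical problem sizes: G = 40,000-86,193; ~30,000-70,000 alignments per
  library; trees up to a few hundred tips (propagation is O(tips^2) in
  the worst case via iterative clade descent).

## Limitations

* The detector assumes a single strategy per library; mixed populations
  produce intermediate profiles it will classify as the dominant signal or
  as random.
* 3' cos overhangs are annotated but not physically modeled in read
  space, so `COS_5P` and `COS_3P` are both (correctly) called
  `FIXED_TERMINI_COS`; distinguishing overhang polarity requires wet-lab
  data.
* SAM ingestion recovers wrapped reads written with the trailing
  soft-clip convention; aligners that truncate reads at the reference
  ends instead will shift some reverse-strand 5' ends.
* The clade rule is deliberately conservative: it neither re-roots trees
  nor reasons about paraphyly, and unsupported or conflicted clades
  simply propagate nothing.

## A minimal session

```{r example, eval = FALSE}
g <- makeReference(40000, gc = 0.4907, seed = 1)
spec <- PackagingSpec("HEADFUL_PAC", 40000, pacPosition = 12345)
sim <- simulateShotgun(g, spec, depth = 200, seed = 1)
call <- detectTermini(computeSpc(alignmentTable(sim), 40000))
call
reorg <- reorganize(genomeSequence(g), peakPosition(pacSite(call)))
digestSummary(selectEnzymes(reorg))
```
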