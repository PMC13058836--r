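---
title: "Genotyping adenine-base-edited clones from amplicon NGS"
author: "abeGenotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping adenine-base-edited clones from amplicon NGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adenine base editors (ABE) convert A·T to G·C within a narrow deaminase
window of the protospacer, without double-strand breaks. After editing and
single-cell cloning, each picked colony must be genotyped: does it carry the
intended substitution, at what allele fraction, with which bystander edits,
and is it a clean monoclonal line or a mosaic mixture? When a screen
produces more than a hundred clones, Sanger sequencing of individual
amplicons becomes the bottleneck; deep sequencing of a short targeted
amplicon (paired-end 150 bp, roughly 10,000 read pairs per clone) resolves
allele fractions down to about 2% per clone and scales to whole plates in
one run.

`abeGenotyper` implements that genotyping workflow as a package:

1. **reference model** — the amplicon sequence anchored to genomic
   coordinates, guide/protospacer geometry, and codon-level synonymy
   annotation of candidate edits;
2. **read simulation** — seeded paired-end amplicon reads for clones with
   arbitrary haplotype mixtures, so the whole downstream path is testable
   without sequencing data;
3. **alignment and quantification** — a banded semi-global aligner against
   the known amplicon, fragment-level reconciliation of read pairs, and
   per-position base-count pileups aggregated into a cohort
   allele-frequency matrix;
4. **clone classification** — efficiency summaries, zygosity bands and
   mosaicism flags;
5. **phasing** — fragment-level co-occurrence of the induced edit with a
   germline heterozygous variant, giving a cis/trans call and a
   monoclonality verdict;
6. **cost model** — Sanger-versus-NGS total cost with the
   square-root-of-N indexing-primer component and exact crossover scan.

## The built-in locus

The package ships a ready-made model of an AUTS2 exon-10 editing locus
(`auts2Amplicon()`, `auts2Guides()`, `auts2PhasingSites()`). Two guides
target third-codon-position adenines so that the intended A→G conversions
are synonymous:

```{r}
library(abeGenotyper)
ref <- auts2Amplicon()
guides <- auts2Guides()
guides$H044
classifyCodonEdit(ref, 70768044L, "G")  # AAA>AAG, Lys>Lys
classifyCodonEdit(ref, 70768068L, "C")  # AGT>AGC, Ser>Ser
```

H044 is a plus-strand guide whose protospacer position 5 maps to
chr7:70768044; H068 is a minus-strand guide targeting chr7:70768068 (T→C on
the plus strand). The target of H044 sits at the 3' end of a run of four
adenines (protospacer positions 2–5), which is why bystander editing at
position 4 (chr7:70768043) is a first-class output of the classifier.

The amplicon sequence is **synthetic where the genome is not pinned by the
design**: the 33 bp spanned by the two protospacers (chr7:70768040–70768072)
and the rs3829006 reference base at chr7:70768282 are genuine; the flanks
are fixed random sequence generated once (with every 12-mer unique, which
keeps alignment seeding unambiguous). Analyses of real data should load
their own reference with `readAmpliconReference()` (single-record FASTA plus
a JSON sidecar carrying the genomic anchor and optional coding frame).

Coordinate conventions: all user-facing coordinates are 1-based inclusive
plus-strand genomic positions; protospacer position 1 is the PAM-distal 5'
end, as in standard base-editing usage. The default editing window is
protospacer positions 4–7 — the usual description of the active ABE window —
but it is configurable per guide because narrower conventions (4–6) are
also in circulation; the package takes no position beyond the default.

## Alignment and quantification

Because the amplicon is a single short known sequence, reads are aligned
directly with a banded semi-global dynamic program (read end-to-end, free
end gaps on the reference, unit mismatch/gap costs) instead of invoking a
genome mapper. Candidate diagonals come from exact 12-mer seeds; the band
half-width is 15. Two safeguards keep banding exact in practice: an exact
match along a seeded diagonal is accepted outright (edit distance 0 is a
global optimum), and whenever seeding fails or the banded distance exceeds
6, the alignment is recomputed without a band. Reads whose edit distance
exceeds 20% of their length are flagged unmapped and counted, never
silently dropped. Pre-aligned SAM/BAM input is supported through
`pileupFromBam()` (per-read counts, without mate reconciliation).

Counting is fragment-based: the two mates of a pair are reconciled into at
most one call per amplicon position. Overlapping mates that agree count
once; disagreeing positions are masked rather than arbitrated by quality —
at several-thousand-fold depth, discarding a handful of ambiguous calls
costs nothing and avoids inventing a tie-break. Base calls below the Q20
quality floor are discarded before reconciliation. Depth at a position is
defined as the number of counted calls, so `A + C + G + T + del == depth`
holds everywhere by construction. Deletions decrement nothing (they are
calls); insertion starts are tallied separately against the reference
column that follows them and are never part of depth. Indels are reported
in mosaicism scans but never counted as "edits" — the ABE chemistry
produces substitutions.

Two frequency notions are exposed deliberately: the **alt-specific
fraction** of the expected alternate base at the target (used for
classification) and the **non-reference fraction** (used for mosaicism
scans and the cohort matrix). At a position with zero depth the frequency
is `NA`, explicitly distinct from an observed 0.

```{r}
reads <- simulateClone(ref,
    list(haplotype("WT", weight = 0.5),
         haplotype("edit", 24L, "G", 0.5)),
    simConfig(depth = 2000L, seed = 1L))
pu <- quantifySample(reads, ref)
altFraction(pu, 70768044L, "G")
```

## The simulator: what it emulates, and what it does not

`simulateClone()` draws each fragment from one haplotype with probability
equal to its weight, reads the fragment's two ends (R1 = 5' prefix, R2 =
reverse complement of the 3' suffix), and applies independent per-base
substitution errors, uniform over the three alternative bases. Defaults
mirror the genotyping protocol: 150-bp paired reads, a 363-bp product
(jointly covering the edit site and the germline phasing variant 238 bp
away), 10,000 fragments per clone for quantification and 5,000 pairs for
phasing, constant Q30 qualities, and an error rate of 0.001/base — a
typical Illumina-class figure chosen here as a stated assumption, since
the platform error profile is not part of the protocol.

The simulator deliberately does **not** model PCR duplicates or jackpot
amplification, chimeric products of the two-round indexing PCR, index
hopping, quality-score decay along the read, or indel sequencing errors
(an edited clone's biology is substitutions; indel robustness is exercised
in tests by splicing indels into reads explicitly). Consequently, passing
end-to-end tests demonstrates correctness of the *computational* pipeline
under binomial sampling plus uniform substitution noise — not robustness
to library-preparation artifacts, which on real data add extra-binomial
variance to allele fractions.

`simulateCohort()` reproduces a two-guide screen of 69 + 48 = 117 clones.
The default design (`cohortDesign()`) fixes, per clone, the weight of the
intended-edit haplotype and (for H044) of a bystander haplotype carrying
the position-4 edit, with target and bystander on distinct haplotypes
(clones with both edits on one chromatid were not observed at this locus).
The weights are chosen so the cohort reproduces the screen's headline
rates: 31/69 clones positive at the target (~45% positional positivity),
12/69 at the bystander position (~17%), a union of 37/69 = 54% detected at
the 2% threshold, 9/69 = 13% at or above 30% (including two potential
homozygotes at 0.68 and 0.89), and 15/48 = 31% / 2/48 = 4% for the second
guide. Every weight keeps at least three binomial standard deviations of
margin from the nearest classification threshold at the default simulated
depth of 2,000 fragments, so band membership is deterministic in practice
rather than a coin flip at a boundary.

## Clone classification

`classifyClone()` bands the target alt fraction with inclusive thresholds:

| band | rule | default |
|---|---|---|
| `unedited` | `f < detect` | detect = 0.02 |
| `low_fraction_edited` | `detect <= f < het` | het = 0.30 |
| `heterozygous_candidate` | `het <= f < hom` | hom = 0.65 |
| `potential_homozygous` | `f >= hom` | |

The 2% detection limit is the practical sensitivity of amplicon NGS (versus
roughly 20% for Sanger trace inspection); 30% is the usual filter for
candidate heterozygotes. There is no published cutoff for "potentially
homozygous" — clones at 68% and 89% were flagged as such — so the default
0.65 places both in the band while remaining configurable; the band edge is
a configuration choice, not a biological claim.

Mosaicism: any unintended allele — substitution or indel, at any amplicon
position, excluding the intended edit — at or above 5% flags the clone as
mosaic. Alleles above a 0.5% noise floor are reported as subclonal
candidates without flagging; the floor separates sequencing noise from
real subclones at typical depth and is a stated assumption (configurable),
not a protocol constant. Bystander edits at editable window positions are
reported separately and also count toward mosaicism when they reach the
mosaic threshold.

Printed efficiencies use half-up integer rounding (`37/69 -> 54%`), which
reproduces all four published ratios exactly; `summarizeEfficiency()` is
non-increasing in the threshold by construction.

## Phasing and monoclonality

With the edit site and the germline variant 238 bp apart and 150-bp reads,
no single read spans both sites; the phasing unit is therefore the
**fragment** — R1 covers the edit site and R2 the germline site of the same
PCR product. Each fragment with a usable call at both sites increments one
cell of a 2×2 joint table; masked, conflicting or unexpected-base calls
make the fragment uninformative (informative + uninformative = total,
asserted in tests).

`callPhase()` takes the majority germline allele among edited fragments;
the call is `ambiguous` below 100 informative edited fragments or below
90% purity. Both cutoffs are conservative choices for ~5,000-pair depth
(the original procedure was manual inspection in a genome browser and
states no numbers) and are arguments, not constants. `assessMonoclonality()`
combines three explicit criteria — germline balance within 0.5 ± 0.15,
phase purity at least 0.9, and (when supplied) an edit fraction inside its
expected category band — and reports each failed criterion as a diagnostic:
a mixed colony with the edit split across alleles fails purity, allelic
dropout or unequal subclone contributions fail balance.

```{r}
sites <- auts2PhasingSites()
res <- phaseSample(
    simulatePhasedClone(ref, sites, "cis", simConfig(depth = 5000L,
                                                     seed = 2L)),
    ref, sites)
res
```

## Cost model

`Sanger(N) = s·N` against `NGS(N) = F + c·N (+ u·2·ceil(sqrt(N)))`. The
square-root term is the dual-index primer set: genotyping N samples needs
`ceil(sqrt(N))` primers per index axis across two axes — the standard
dual-index combinatorics concretizing the "cost scales as sqrt(N)" claim.
`costCrossover()` is an exact integer scan (the primer staircase makes the
with-primers curve non-monotone relative to Sanger, so a closed form would
mislead). The shipped parameter file
(`inst/extdata/cost_params_synthetic.json`) is illustrative — the actual
price table is vendor- and currency-specific — and is chosen to land the
two crossovers at 81 samples (buying index primers) and 8 samples (primers
in hand), mirroring the ">80 / >7 samples" pattern reported for this
workflow.

## Numerical and design choices, in brief

- **Coordinates** 1-based inclusive externally, 0-based half-open
  internally (alignment offsets).
- **Aligner determinism**: traceback prefers diagonal over insertion over
  deletion, so tied alignments resolve toward substitutions, and insertion
  starts anchor to the following reference column.
- **Adapter trimming** removes the suffix at the best adapter match
  (lowest mismatch rate, at least 3 matched columns, at most 10%
  mismatches, leftmost on ties); reads without a match are untouched.
- **Degenerate inputs** raise classed errors rather than silent defaults:
  empty samples (`quantifySample`), zero target depth (`classifyClone`,
  an explicit no-call), zero informative fragments (`countJointAlleles`),
  haplotype weights not summing to one, mixed references in
  `aggregateMatrix`.
- **Recovery checks** compare estimates with the exact binomial 99%
  interval of the *expected* alt fraction under the error model,
  `p = w(1-e) + (1-w)e/3` — the observable quantity given substitution
  noise; an interval around the raw weight would be degenerate at w = 0.
- **Problem sizes** used by the test suite and the acceptance script: a
  117-clone cohort at 2,000 fragments per clone, 200 recovery clones at
  10,000 fragments, 100 phased clones at 5,000 pairs — the phasing and
  recovery depths of the protocol, with the cohort depth scaled to a
  fifth as the package's choice for routine verification.

## Limitations

- The built-in locus carries synthetic flanking sequence; results at
  non-pinned positions characterize the pipeline, not the genome.
- Allele-depth counting replaces a likelihood-based variant caller; at
  thousands-fold amplicon depth the two coincide in practice, but no
  claim is made for low-coverage data.
- Phasing covers exactly two sites on one fragment; multi-site haplotype
  assembly and population phasing are out of scope.
- Classification is threshold banding, not a genotype likelihood or
  copy-number model; band edges near 30% and 65% are sensitive to
  extra-binomial dispersion on real libraries.
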