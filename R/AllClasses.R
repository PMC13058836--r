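#' @include abeGenotyper-package.R
NULL

## ---------------------------------------------------------------------------
## Reference model

#' Reference amplicon anchored to genomic coordinates
#'
#' An `AmpliconReference` holds the sequence of the PCR product used for
#' clone genotyping together with its genomic anchor: the 1-based plus-strand
#' coordinate of the amplicon's first base. Amplicon position `i` therefore
#' corresponds to genomic coordinate `genomicStart + i - 1`. An optional
#' coding frame (`frameOffset` 0-2 plus the coding strand) enables
#' codon-level annotation of substitutions via [classifyCodonEdit()].
#'
#' @slot name amplicon name.
#' @slot contig contig/chromosome name (e.g. `"chr7"`).
#' @slot genomicStart 1-based genomic coordinate of amplicon position 1.
#' @slot sequence uppercase DNA string over A/C/G/T.
#' @slot frameOffset integer 0-2 or `NA`: offset, on the coding strand and
#'   counted from its 5' end within the amplicon, of the first complete codon.
#' @slot codingStrand `"+"`, `"-"` or `NA`.
#' @seealso [ampliconReference()], [auts2Amplicon()]
#' @exportClass AmpliconReference
setClass("AmpliconReference",
    slots = c(
        name = "character", contig = "character", genomicStart = "integer",
        sequence = "character", frameOffset = "integer",
        codingStrand = "character"
    )
)

setValidity("AmpliconReference", function(object) {
    s <- object@sequence
    if (length(s) != 1L || nchar(s) < 1L)
        return("sequence must be a single non-empty string")
    if (grepl("[^ACGT]", s))
        return("sequence alphabet restricted to A/C/G/T (uppercase)")
    if (length(object@genomicStart) != 1L || is.na(object@genomicStart) ||
        object@genomicStart < 1L)
        return("genomicStart must be a positive 1-based coordinate")
    fo <- object@frameOffset
    if (!is.na(fo) && (fo < 0L || fo > 2L))
        return("frameOffset must be 0, 1, 2 or NA")
    cs <- object@codingStrand
    if (!is.na(cs) && !cs %in% c("+", "-"))
        return("codingStrand must be '+', '-' or NA")
    if (is.na(fo) != is.na(cs))
        return("frameOffset and codingStrand must be set together")
    TRUE
})

#' Guide RNA / protospacer design
#'
#' Describes a base-editing guide: the 20-nt protospacer as printed in guide
#' designs (position 1 = PAM-distal, 5' end), its strand relative to the
#' reference plus strand, the genomic plus-strand coordinate of protospacer
#' position 1 (`anchor`), the deaminase editing window (inclusive protospacer
#' positions, default 4-7) and the intended target position, which must hold
#' an adenine (the ABE substrate).
#'
#' @slot guideId guide name.
#' @slot protospacer 20-nt DNA string.
#' @slot strand `"+"` or `"-"`.
#' @slot anchor genomic plus-strand coordinate of protospacer position 1.
#' @slot window length-2 integer vector, inclusive window within 1-20.
#' @slot targetPosition intended edited protospacer position (1-20).
#' @seealso [guideDesign()], [mapProtospacerPosition()]
#' @exportClass GuideDesign
setClass("GuideDesign",
    slots = c(
        guideId = "character", protospacer = "character", strand = "character",
        anchor = "integer", window = "integer", targetPosition = "integer"
    )
)

setValidity("GuideDesign", function(object) {
    p <- object@protospacer
    if (length(p) != 1L || nchar(p) != 20L || grepl("[^ACGT]", p))
        return("protospacer must be a 20-nt string over A/C/G/T")
    if (!object@strand %in% c("+", "-"))
        return("strand must be '+' or '-'")
    w <- object@window
    if (length(w) != 2L || any(is.na(w)) || w[1] > w[2] || w[1] < 1L ||
        w[2] > 20L)
        return("window must be an ascending pair within 1-20")
    k <- object@targetPosition
    if (length(k) != 1L || is.na(k) || k < 1L || k > 20L)
        return("targetPosition must lie in 1-20")
    if (substr(p, k, k) != "A")
        return("protospacer base at targetPosition must be 'A' (ABE edits adenines)")
    TRUE
})

#' Codon-level annotation of a substitution
#'
#' @slot codonBefore,codonAfter 3-nt codons on the coding strand.
#' @slot aaBefore,aaAfter single-letter amino-acid codes.
#' @slot synonymous `TRUE` when the amino acid is unchanged.
#' @seealso [classifyCodonEdit()]
#' @exportClass CodonEdit
setClass("CodonEdit",
    slots = c(
        codonBefore = "character", codonAfter = "character",
        aaBefore = "character", aaAfter = "character", synonymous = "logical"
    )
)

setValidity("CodonEdit", function(object) {
    if ((object@aaBefore == object@aaAfter) != object@synonymous)
        return("synonymous flag inconsistent with amino acids")
    TRUE
})

## ---------------------------------------------------------------------------
## Simulation

#' Clone haplotype for read simulation
#'
#' A haplotype is a set of substitutions relative to the reference amplicon
#' plus the fraction of cells (hence, in expectation, of sequenced fragments)
#' carrying it. Weights across a clone's haplotypes must sum to 1.
#'
#' @slot label haplotype label (carried into read names as ground truth).
#' @slot positions 1-based amplicon positions of the substitutions.
#' @slot alts alternate bases, same length as `positions`.
#' @slot weight fraction in `[0, 1]`.
#' @seealso [haplotype()], [simulateClone()]
#' @exportClass Haplotype
setClass("Haplotype",
    slots = c(
        label = "character", positions = "integer", alts = "character",
        weight = "numeric"
    )
)

setValidity("Haplotype", function(object) {
    if (length(object@positions) != length(object@alts))
        return("positions and alts lengths differ")
    if (any(!object@alts %in% .BASES))
        return("alts must be single bases A/C/G/T")
    if (length(object@weight) != 1L || is.na(object@weight) ||
        object@weight < 0 || object@weight > 1)
        return("weight must lie in [0, 1]")
    if (anyDuplicated(object@positions))
        return("duplicated substitution positions")
    TRUE
})

#' Amplicon sequencing simulation settings
#'
#' @slot depth fragments (read pairs) per clone.
#' @slot readLength read length in bp (150 by default).
#' @slot fragmentLength sequenced PCR product length (363 by default).
#' @slot fragmentStart 1-based amplicon position where the fragment begins.
#' @slot perBaseError independent per-base substitution error rate.
#' @slot baseQuality constant Phred quality written to FASTQ.
#' @slot seed integer RNG seed, or `NA` to use the current RNG stream.
#' @seealso [simConfig()], [simulateClone()]
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        depth = "integer", readLength = "integer", fragmentLength = "integer",
        fragmentStart = "integer", perBaseError = "numeric",
        baseQuality = "integer", seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@readLength < 1L || object@readLength > object@fragmentLength)
        return("need readLength <= fragmentLength")
    if (object@perBaseError < 0 || object@perBaseError >= 0.25)
        return("perBaseError must lie in [0, 0.25)")
    if (object@baseQuality < 2L || object@baseQuality > 41L)
        return("baseQuality must be a plausible Phred score (2-41)")
    TRUE
})

#' Simulated paired-end reads for one clone
#'
#' In-memory paired FASTQ records plus the simulation ground truth: the
#' haplotype label of every fragment and the realized per-haplotype fragment
#' counts (the oracle against which downstream quantification is checked).
#'
#' @slot id sample identifier.
#' @slot r1,r2 read sequences (R2 as sequenced, i.e. reverse strand).
#' @slot q1,q2 quality strings (Phred+33).
#' @slot hap per-fragment haplotype label.
#' @slot truth list with elements `labels`, `weights`, `realizedCounts`.
#' @slot config the [SimConfig][SimConfig-class] used.
#' @seealso [simulateClone()], [writeFastqPair()]
#' @exportClass CloneReads
setClass("CloneReads",
    slots = c(
        id = "character", r1 = "character", r2 = "character",
        q1 = "character", q2 = "character", hap = "character",
        truth = "list", config = "SimConfig"
    )
)

setValidity("CloneReads", function(object) {
    n <- length(object@r1)
    if (length(object@r2) != n || length(object@q1) != n ||
        length(object@q2) != n || length(object@hap) != n)
        return("R1/R2/quality/haplotype vectors must have equal length")
    TRUE
})

## ---------------------------------------------------------------------------
## Quantification

#' Per-position base-count pileup for one sample
#'
#' Fragment-reconciled base counts over the amplicon: rows `A`, `C`, `G`,
#' `T`, `del` and `ins` (insertion starts, anchored at the reference column
#' following the insertion; not part of depth). Depth at a position is the
#' number of counted calls, `A + C + G + T + del`; bases masked for low
#' quality or mate disagreement contribute nothing.
#'
#' @slot counts 6 x n integer matrix.
#' @slot ref the [AmpliconReference][AmpliconReference-class].
#' @slot sampleId sample identifier.
#' @slot nFragments,nMappedFragments,nUnmappedReads mapping bookkeeping.
#' @seealso [quantifySample()], [nonRefFraction()], [altFraction()]
#' @exportClass Pileup
setClass("Pileup",
    slots = c(
        counts = "matrix", ref = "AmpliconReference", sampleId = "character",
        nFragments = "integer", nMappedFragments = "integer",
        nUnmappedReads = "integer"
    )
)

setValidity("Pileup", function(object) {
    if (nrow(object@counts) != 6L ||
        !identical(rownames(object@counts), c(.BASES, "del", "ins")))
        return("counts must have rows A,C,G,T,del,ins")
    if (ncol(object@counts) != nchar(object@ref@sequence))
        return("counts columns must span the amplicon")
    if (any(object@counts < 0L)) return("negative counts")
    TRUE
})

#' Cohort allele-frequency matrix
#'
#' A `RangedSummarizedExperiment` with one row per amplicon position
#' (`rowRanges` carry the genomic coordinates) and one column per sample,
#' and assays `frequency` (non-reference fraction, `NA` where a sample has
#' zero depth -- distinct from an observed frequency of 0) and `depth`.
#'
#' @seealso [aggregateMatrix()], [positivityProfile()]
#' @exportClass AlleleFrequencyMatrix
setClass("AlleleFrequencyMatrix",
    contains = "RangedSummarizedExperiment"
)

setValidity("AlleleFrequencyMatrix", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("frequency", "depth") %in% an))
        return("assays 'frequency' and 'depth' required")
    f <- SummarizedExperiment::assay(object, "frequency")
    if (any(f < 0 | f > 1, na.rm = TRUE))
        return("frequencies must lie in [0, 1]")
    d <- SummarizedExperiment::assay(object, "depth")
    if (any(is.na(f) & d > 0) || any(!is.na(f) & d == 0))
        return("frequency must be NA exactly where depth is 0")
    TRUE
})

## ---------------------------------------------------------------------------
## Classification

#' Clone classification thresholds
#'
#' Threshold bands used for clone triage. All comparisons are inclusive
#' (`>=`). Defaults follow the screening protocol: detection at 2 percent
#' allele frequency, heterozygous candidates at 30 percent, mosaicism flagged
#' at 5 percent unintended alleles, with a 0.5 percent noise floor separating
#' sequencing noise from subclonal alleles.
#'
#' @slot detectThreshold,hetThreshold,homozygousThreshold category bands.
#' @slot mosaicAlleleThreshold unintended-allele fraction flagging mosaicism.
#' @slot noiseFloor minimum fraction reported as a subclonal allele at all.
#' @seealso [classifierConfig()], [classifyClone()]
#' @exportClass ClassifierConfig
setClass("ClassifierConfig",
    slots = c(
        detectThreshold = "numeric", hetThreshold = "numeric",
        homozygousThreshold = "numeric", mosaicAlleleThreshold = "numeric",
        noiseFloor = "numeric"
    )
)

setValidity("ClassifierConfig", function(object) {
    ok <- 0 < object@noiseFloor &&
        object@noiseFloor < object@detectThreshold &&
        object@detectThreshold < object@hetThreshold &&
        object@hetThreshold < object@homozygousThreshold &&
        object@homozygousThreshold <= 1
    if (!ok)
        return("need 0 < noiseFloor < detectThreshold < hetThreshold < homozygousThreshold <= 1")
    TRUE
})

#' Per-clone genotype call
#'
#' @slot sampleId sample identifier.
#' @slot guideId guide used for this clone.
#' @slot targetEditFraction fraction of fragments carrying the intended
#'   alternate base at the target position.
#' @slot targetDepth informative depth at the target position.
#' @slot category one of `unedited`, `low_fraction_edited`,
#'   `heterozygous_candidate`, `potential_homozygous`.
#' @slot mosaic `TRUE` when some unintended allele reaches the mosaic
#'   threshold.
#' @slot mosaicAlleles data.frame (position, genomic_position, alt, fraction)
#'   of unintended alleles above the noise floor.
#' @slot bystanders data.frame (window_position, genomic_position, alt,
#'   fraction) of detected bystander edits at editable window positions.
#' @seealso [classifyClone()], [cloneRoster()]
#' @exportClass CloneCall
setClass("CloneCall",
    slots = c(
        sampleId = "character", guideId = "character",
        targetEditFraction = "numeric", targetDepth = "integer",
        category = "character", mosaic = "logical",
        mosaicAlleles = "data.frame", bystanders = "data.frame"
    )
)

.CLONE_CATEGORIES <- c(
    "unedited", "low_fraction_edited", "heterozygous_candidate",
    "potential_homozygous"
)

setValidity("CloneCall", function(object) {
    if (!object@category %in% .CLONE_CATEGORIES)
        return("unknown category")
    f <- object@targetEditFraction
    if (!is.na(f) && (f < 0 || f > 1)) return("fraction outside [0, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## Phasing

#' Two-site phasing design
#'
#' The induced edit site and a germline heterozygous variant used as the
#' allelic anchor, both as plus-strand coordinates inside the phasing
#' amplicon.
#'
#' @slot contig contig name.
#' @slot editPos,editRef,editAlt induced substitution site and alleles.
#' @slot germlinePos,allele1,allele2 germline heterozygous site and alleles.
#' @seealso [phasingSites()], [expectedDistance()], [phaseSample()]
#' @exportClass PhasingSites
setClass("PhasingSites",
    slots = c(
        contig = "character", editPos = "integer", editRef = "character",
        editAlt = "character", germlinePos = "integer",
        allele1 = "character", allele2 = "character"
    )
)

setValidity("PhasingSites", function(object) {
    if (object@editPos == object@germlinePos) return("sites must be distinct")
    bases <- c(object@editRef, object@editAlt, object@allele1, object@allele2)
    if (any(!bases %in% .BASES)) return("alleles must be single bases")
    if (object@editRef == object@editAlt) return("edit alleles identical")
    if (object@allele1 == object@allele2) return("germline alleles identical")
    TRUE
})

#' Fragment-level phasing result
#'
#' @slot jointCounts 2 x 2 table, rows = edit allele (ref, alt), columns =
#'   germline allele (allele1, allele2).
#' @slot informative,uninformative fragment counts.
#' @slot phaseCall `cis_with_allele_1`, `cis_with_allele_2` or `ambiguous`.
#' @slot purity majority-column share among alt-edit fragments.
#' @slot germlineBalance allele-1 share among informative fragments.
#' @slot monoclonal monoclonality verdict.
#' @slot diagnostics character vector naming failed monoclonality criteria.
#' @seealso [phaseSample()], [callPhase()], [assessMonoclonality()]
#' @exportClass PhasingResult
setClass("PhasingResult",
    slots = c(
        jointCounts = "matrix", informative = "integer",
        uninformative = "integer", phaseCall = "character",
        purity = "numeric", germlineBalance = "numeric",
        monoclonal = "logical", diagnostics = "character"
    )
)

setValidity("PhasingResult", function(object) {
    jc <- object@jointCounts
    if (!identical(dim(jc), c(2L, 2L))) return("jointCounts must be 2 x 2")
    if (any(jc < 0)) return("negative joint counts")
    if (sum(jc) != object@informative)
        return("informative fragment count must equal the table sum")
    if (!is.na(object@purity) &&
        (object@purity < 0.5 || object@purity > 1))
        return("purity must lie in [0.5, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## Cost model

#' Sanger-versus-NGS genotyping cost parameters
#'
#' Per-sample Sanger cost, per-sample NGS sequencing cost, fixed NGS run
#' overhead, and the unit cost of synthesizing one indexing primer. Under
#' dual indexing, genotyping N samples needs `ceiling(sqrt(N))` primers per
#' index axis, two axes, hence the total cost scales as `sqrt(N)`.
#'
#' @slot sangerPerSample,ngsPerSample,ngsFixed,primerUnitCost non-negative
#'   costs in a common currency unit.
#' @seealso [costParams()], [costCurves()], [costCrossover()]
#' @exportClass CostParams
setClass("CostParams",
    slots = c(
        sangerPerSample = "numeric", ngsPerSample = "numeric",
        ngsFixed = "numeric", primerUnitCost = "numeric"
    )
)

setValidity("CostParams", function(object) {
    v <- c(object@sangerPerSample, object@ngsPerSample, object@ngsFixed,
           object@primerUnitCost)
    if (any(is.na(v)) || any(v < 0)) return("all costs must be >= 0")
    TRUE
})

#' Cohort-level report
#'
#' @slot roster one row per clone: identifier, target fraction, category,
#'   mosaicism flag, bystander summary.
#' @slot shortlist roster subset: non-mosaic heterozygous candidates.
#' @slot profiles named list of per-group positional positivity profiles.
#' @slot efficiency per-group editing efficiency at both thresholds.
#' @seealso [exportCohort()]
#' @exportClass CohortReport
setClass("CohortReport",
    slots = c(
        roster = "data.frame", shortlist = "data.frame", profiles = "list",
        efficiency = "data.frame"
    )
)

setValidity("CohortReport", function(object) {
    if (!all(object@shortlist$sample_id %in% object@roster$sample_id))
        return("shortlist must be a subset of the roster")
    TRUE
})
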