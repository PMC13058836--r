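#' @include AllClasses.R
NULL

#' Construct a reference amplicon
#'
#' @param name amplicon name.
#' @param contig contig name, e.g. `"chr7"`.
#' @param genomicStart 1-based plus-strand genomic coordinate of the
#'   amplicon's first base.
#' @param sequence DNA string over A/C/G/T (coerced to uppercase).
#' @param frameOffset,codingStrand optional coding frame for codon-level
#'   annotation; `frameOffset` (0-2) is the offset of the first complete
#'   codon counted from the coding strand's 5' end within the amplicon.
#' @return An [AmpliconReference][AmpliconReference-class].
#' @examples
#' ref <- ampliconReference("amp", "chr1", 1000L, "ACGTACGTACGT",
#'     frameOffset = 0L, codingStrand = "+")
#' ampliconLength(ref)
#' @export
ampliconReference <- function(name, contig, genomicStart, sequence,
                              frameOffset = NA_integer_,
                              codingStrand = NA_character_) {
    new("AmpliconReference",
        name = as.character(name), contig = as.character(contig),
        genomicStart = as.integer(genomicStart),
        sequence = toupper(as.character(sequence)),
        frameOffset = as.integer(frameOffset),
        codingStrand = as.character(codingStrand))
}

#' @describeIn ampliconReference amplicon length in bp.
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @export
ampliconLength <- function(ref) nchar(ref@sequence)

#' @describeIn ampliconReference the sequence as a [Biostrings::DNAString].
#' @export
ampliconDNA <- function(ref) Biostrings::DNAString(ref@sequence)

#' @describeIn ampliconReference amplicon footprint as a
#'   [GenomicRanges::GRanges] of width-1 positions.
#' @export
ampliconPositions <- function(ref) {
    n <- ampliconLength(ref)
    GenomicRanges::GRanges(
        seqnames = ref@contig,
        ranges = IRanges::IRanges(
            start = ref@genomicStart + seq_len(n) - 1L, width = 1L))
}

## genomic coordinate <-> amplicon position (1-based both ways)
.toAmplicon <- function(ref, gpos) {
    i <- as.integer(gpos) - ref@genomicStart + 1L
    if (any(i < 1L | i > ampliconLength(ref)))
        .stopDomain("genomic position outside the amplicon")
    i
}

.toGenomic <- function(ref, i) ref@genomicStart + as.integer(i) - 1L

#' Reference base at a genomic position
#'
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param gpos genomic plus-strand coordinate(s) inside the amplicon.
#' @return Character vector of plus-strand reference bases.
#' @export
refBaseAt <- function(ref, gpos) {
    i <- .toAmplicon(ref, gpos)
    substring(ref@sequence, i, i)
}

#' Construct a guide design
#'
#' @param guideId guide name.
#' @param protospacer 20-nt protospacer as printed (position 1 PAM-distal).
#' @param strand `"+"` or `"-"` relative to the reference plus strand.
#' @param anchor genomic plus-strand coordinate of protospacer position 1.
#' @param window inclusive editing window, default `c(4L, 7L)`.
#' @param targetPosition intended edited protospacer position.
#' @return A [GuideDesign][GuideDesign-class].
#' @examples
#' g <- guideDesign("N044", "CAAAAGTTGACCCATTCTAC", "+", 70768040L,
#'     targetPosition = 5L)
#' mapProtospacerPosition(g, 5L)
#' @export
guideDesign <- function(guideId, protospacer, strand, anchor,
                        window = c(4L, 7L), targetPosition) {
    new("GuideDesign",
        guideId = as.character(guideId),
        protospacer = toupper(as.character(protospacer)),
        strand = as.character(strand), anchor = as.integer(anchor),
        window = as.integer(window),
        targetPosition = as.integer(targetPosition))
}

#' Map a protospacer position to its genomic coordinate
#'
#' For a plus-strand guide, protospacer position `k` maps to
#' `anchor + k - 1`; for a minus-strand guide, to `anchor - (k - 1)`.
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param k protospacer position(s) in 1-20.
#' @param contig optional contig name to place in the result.
#' @return A [GenomicRanges::GRanges] of width-1 positions, one per `k`.
#' @export
mapProtospacerPosition <- function(guide, k, contig = "chr7") {
    k <- as.integer(k)
    if (any(is.na(k) | k < 1L | k > 20L))
        .stopDomain("protospacer position k must lie in 1-20")
    pos <- if (guide@strand == "+") guide@anchor + k - 1L
           else guide@anchor - (k - 1L)
    GenomicRanges::GRanges(
        seqnames = contig,
        ranges = IRanges::IRanges(start = pos, width = 1L),
        strand = guide@strand)
}

#' Protospacer position at a genomic coordinate (inverse mapping)
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param gpos genomic plus-strand coordinate(s).
#' @return Integer protospacer position(s) in 1-20.
#' @export
protospacerPositionAt <- function(guide, gpos) {
    gpos <- as.integer(gpos)
    k <- if (guide@strand == "+") gpos - guide@anchor + 1L
         else guide@anchor - gpos + 1L
    if (any(k < 1L | k > 20L))
        .stopDomain("genomic position outside the protospacer")
    k
}

#' Genomic position and expected alternate base of the intended edit
#'
#' The ABE converts the target adenine to guanine on the guide strand; on
#' the reference plus strand this reads A>G for plus-strand guides and T>C
#' for minus-strand guides.
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param contig contig name.
#' @return `targetGenomicPosition()`: integer coordinate;
#'   `targetAltBase()` / `targetRefBase()`: plus-strand bases.
#' @export
targetGenomicPosition <- function(guide, contig = "chr7") {
    GenomicRanges::start(mapProtospacerPosition(guide, guide@targetPosition,
                                                contig))
}

#' @rdname targetGenomicPosition
#' @export
targetAltBase <- function(guide) if (guide@strand == "+") "G" else "C"

#' @rdname targetGenomicPosition
#' @export
targetRefBase <- function(guide) if (guide@strand == "+") "A" else "T"

#' Editable adenine positions within the editing window
#'
#' Returns the protospacer positions inside the (inclusive) window that hold
#' an adenine -- the positions the deaminase can act on, i.e. the candidate
#' target and bystander positions.
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param window inclusive window; defaults to the guide's own.
#' @return Sorted integer vector of protospacer positions.
#' @export
editablePositions <- function(guide, window = guide@window) {
    window <- as.integer(window)
    if (length(window) != 2L || any(is.na(window)) || window[1] > window[2] ||
        window[1] < 1L || window[2] > 20L)
        .stopDomain("window must be an ascending pair within 1-20")
    ks <- window[1]:window[2]
    bases <- substring(guide@protospacer, ks, ks)
    sort(ks[bases == "A"])
}

#' Length of the adenine run containing a protospacer position
#'
#' The maximal run of consecutive adenines in the protospacer containing
#' position `k`; quantifies adenine clustering around a target (long runs
#' raise the bystander-editing risk).
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param k protospacer position holding an 'A'.
#' @return Integer run length.
#' @export
adenineRunLength <- function(guide, k) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 1L || k > 20L)
        .stopDomain("k must lie in 1-20")
    p <- strsplit(guide@protospacer, "", fixed = TRUE)[[1]]
    if (p[k] != "A") .stopDomain("protospacer base at k is not 'A'")
    lo <- k
    while (lo > 1L && p[lo - 1L] == "A") lo <- lo - 1L
    hi <- k
    while (hi < 20L && p[hi + 1L] == "A") hi <- hi + 1L
    hi - lo + 1L
}

#' Check a guide against the reference amplicon
#'
#' Asserts the geometric invariant linking the guide to the reference: at
#' every protospacer position the plus-strand reference base equals the
#' protospacer base (plus-strand guides) or its complement (minus-strand
#' guides).
#'
#' @param guide a [GuideDesign][GuideDesign-class].
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @return Invisibly `TRUE`; errors when the guide does not match.
#' @export
checkGuideAgainstReference <- function(guide, ref) {
    ks <- 1:20
    gpos <- GenomicRanges::start(mapProtospacerPosition(guide, ks,
                                                        ref@contig))
    got <- refBaseAt(ref, gpos)
    want <- substring(guide@protospacer, ks, ks)
    if (guide@strand == "-") want <- unname(.COMP[want])
    if (!all(got == want))
        .stopValidation("guide '", guide@guideId,
                        "' does not match the reference at protospacer ",
                        "position(s) ", paste(ks[got != want], collapse = ","))
    invisible(TRUE)
}

#' Codon-level classification of a substitution
#'
#' Reconstructs the codon containing a genomic position on the coding
#' strand, applies the substitution, translates both codons under the
#' standard genetic code and reports whether the change is synonymous.
#' The substitution is given on the plus strand; for minus-strand coding it
#' is complemented internally.
#'
#' @param ref an [AmpliconReference][AmpliconReference-class] with a coding
#'   frame.
#' @param gpos genomic plus-strand coordinate of the substituted base.
#' @param altBase plus-strand alternate base.
#' @return A [CodonEdit][CodonEdit-class].
#' @examples
#' ref <- auts2Amplicon()
#' classifyCodonEdit(ref, 70768044L, "G")  # AAA>AAG, Lys>Lys, synonymous
#' @export
classifyCodonEdit <- function(ref, gpos, altBase) {
    if (is.na(ref@frameOffset))
        .stopDomain("reference has no coding frame")
    altBase <- toupper(altBase)
    if (!altBase %in% .BASES) .stopDomain("altBase must be A/C/G/T")
    i <- .toAmplicon(ref, gpos)
    n <- ampliconLength(ref)

    if (ref@codingStrand == "+") {
        coding <- ref@sequence
        j <- i
        alt <- altBase
    } else {
        coding <- .revcompChr(ref@sequence)
        j <- n - i + 1L
        alt <- unname(.COMP[altBase])
    }
    fo <- ref@frameOffset
    if (j <= fo) .stopDomain("position precedes the first complete codon")
    start <- fo + 3L * ((j - fo - 1L) %/% 3L) + 1L
    if (start + 2L > n) .stopDomain("codon truncated by the amplicon end")

    before <- substr(coding, start, start + 2L)
    after <- before
    substr(after, j - start + 1L, j - start + 1L) <- alt
    code <- Biostrings::GENETIC_CODE
    new("CodonEdit",
        codonBefore = before, codonAfter = after,
        aaBefore = unname(code[[before]]), aaAfter = unname(code[[after]]),
        synonymous = code[[before]] == code[[after]])
}
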