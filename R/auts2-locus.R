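#' @include reference-model.R
NULL

## Synthetic stand-in for the AUTS2 exon-10 genotyping amplicon. Only a
## 33-bp core (chr7:70768040-70768072, fully determined by the two guide
## protospacers) and the rs3829006 reference base at chr7:70768282 are real
## genomic sequence; the flanks are fixed random sequence generated once
## (every 12-mer unique, which keeps alignment seeding unambiguous).
.AUTS2_AMPLICON_SEQ <- paste0(
    "GCGCCAGCTGCAGCAGATACAAAAGTTGACCCATTCTACCGGCACAGTGTGAATCCATAA",
    "TTTCCGCGTGGCCTCCATAAAGCTTTTGATTCATGTTACAGGCCATTTTTACATTGGGGT",
    "AAACCTCGTGCTCGCCGTTCTGAGGATGCATTCATAGTGTCAAAGCAAGGGCAAAATGTC",
    "AAGTTATGTCCCCAGTAGGGACCGCGAGGCGGTCGGGCTCTGTGTGTATATAGCTCGCGA",
    "ATTCTGGTAAAGCGTTAGAGAGCAGGTAGCCGGGCGATTCGGCATTACATTTGTAGTACG",
    "TTAATACTAATCGTCTAAGTAGTTGTTGAATTGACGGTGGTTGGCCGCCCAGCGAAACGA",
    "ATA")

#' Built-in AUTS2 exon-10 genotyping locus (synthetic flanks)
#'
#' A ready-made 363-bp amplicon model of the AUTS2 exon-10 editing locus:
#' the region genuinely pinned by the experimental design -- the two
#' protospacers spanning chr7:70768040-70768072 (hg38) and the rs3829006
#' reference G at chr7:70768282 -- embedded in fixed synthetic flanking
#' sequence (the full genomic amplicon is not deposited). The amplicon is
#' anchored at chr7:70768021, so it jointly covers the edit site
#' (chr7:70768044) and the germline phasing variant 238 bp away. The coding
#' frame places chr7:70768042-70768044 in one codon (AAA, Lys), matching
#' the synonymous-design constraint.
#'
#' @return `auts2Amplicon()`: an
#'   [AmpliconReference][AmpliconReference-class]; `auts2Guides()`: named
#'   list of the two [GuideDesign][GuideDesign-class] objects H044 (plus
#'   strand, target protospacer position 5 at chr7:70768044) and H068
#'   (minus strand, target position 5 at chr7:70768068);
#'   `auts2PhasingSites()`: the [PhasingSites][PhasingSites-class] pairing
#'   the H044 edit with rs3829006 G/A.
#' @examples
#' ref <- auts2Amplicon()
#' guides <- auts2Guides()
#' checkGuideAgainstReference(guides$H044, ref)
#' editablePositions(guides$H044)
#' @export
auts2Amplicon <- function() {
    ampliconReference(
        name = "AUTS2_exon10_synthetic", contig = "chr7",
        genomicStart = 70768021L, sequence = .AUTS2_AMPLICON_SEQ,
        frameOffset = 0L, codingStrand = "+")
}

#' @rdname auts2Amplicon
#' @export
auts2Guides <- function() {
    list(
        H044 = guideDesign("H044", "CAAAAGTTGACCCATTCTAC", "+",
                           anchor = 70768040L, targetPosition = 5L),
        H068 = guideDesign("H068", "TCACACTGTGCCGGTAGAAT", "-",
                           anchor = 70768072L, targetPosition = 5L))
}

#' @rdname auts2Amplicon
#' @export
auts2PhasingSites <- function() {
    phasingSites(
        contig = "chr7", editPos = 70768044L, editRef = "A", editAlt = "G",
        germlinePos = 70768282L, allele1 = "G", allele2 = "A")
}
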