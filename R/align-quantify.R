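#' @include AllClasses.R
NULL

#' Single-read alignment to the amplicon
#'
#' @slot readId read identifier.
#' @slot offset 0-based amplicon offset of the first aligned base.
#' @slot editDistance unit-cost edit distance of the alignment.
#' @slot mapped `FALSE` when the edit distance exceeds the mapping
#'   threshold (20 percent of the read length by default).
#' @slot calls integer matrix with columns `position` (1-based amplicon),
#'   `code` (0-3 = A/C/G/T, 4 = deletion) and `read_position` (1-based; 0
#'   for deletions).
#' @slot insertionAnchors 1-based amplicon columns following an insertion.
#' @seealso [alignToAmplicon()]
#' @exportClass ReadAlignment
setClass("ReadAlignment",
    slots = c(
        readId = "character", offset = "integer", editDistance = "integer",
        mapped = "logical", calls = "matrix", insertionAnchors = "integer"
    )
)

.CALL_CODES <- c("A", "C", "G", "T", "del")

#' Align a read to the reference amplicon
#'
#' Banded semi-global alignment: the read aligns end-to-end with unit
#' mismatch and gap costs, the reference contributes free end gaps (the
#' amplicon is short and known, so no genome-scale mapper is needed).
#' Candidate diagonals come from exact 12-mer seeds; the dynamic program
#' runs in a band of half-width `halfBand` around each candidate, falling
#' back to an unrestricted alignment when seeding fails or the banded
#' distance stays high, so banding never loses a recoverable alignment.
#'
#' @param read read sequence (>= 20 nt).
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param halfBand band half-width (default 15).
#' @param maxEditFrac mapping threshold: reads with edit distance above
#'   `maxEditFrac * nchar(read)` are flagged unmapped (never dropped).
#' @param readId identifier stored in the result.
#' @return A [ReadAlignment][ReadAlignment-class].
#' @examples
#' ref <- auts2Amplicon()
#' aln <- alignToAmplicon(substr(ref@sequence, 51, 200), ref)
#' aln@offset; aln@editDistance
#' @export
alignToAmplicon <- function(read, ref, halfBand = 15L, maxEditFrac = 0.2,
                            readId = "read") {
    read <- toupper(read)
    if (nchar(read) < 20L)
        .stopDomain("read shorter than 20 nt")
    res <- .cppAlignRead(read, ref@sequence, as.integer(halfBand),
                         maxEditFrac)
    calls <- res$calls
    colnames(calls) <- c("position", "code", "read_position")
    new("ReadAlignment",
        readId = readId, offset = as.integer(res$offset),
        editDistance = as.integer(res$edit_distance),
        mapped = res$mapped, calls = calls,
        insertionAnchors = as.integer(res$insertion_anchors))
}

#' Reconcile a read pair into per-position fragment calls
#'
#' Combines the aligned calls of the two mates of one fragment into at most
#' one base call per amplicon position: positions covered by one mate keep
#' its call, positions where the mates agree are counted once, positions
#' where they disagree are masked, and base calls below `qualityFloor` are
#' discarded before reconciliation (deletions carry no quality and always
#' pass).
#'
#' @param aln1,aln2 [ReadAlignment][ReadAlignment-class] objects for the
#'   two mates (`aln2` may be `NULL`); unmapped alignments contribute
#'   nothing.
#' @param refLength amplicon length.
#' @param q1,q2 quality strings in read orientation matching the
#'   `read_position` column of the alignments (optional).
#' @param qualityFloor minimum base quality for a call (default Q20).
#' @return Named list: `calls` -- character vector over amplicon positions
#'   (`"A"`..`"T"`, `"del"`, or `NA` for no call / masked conflict);
#'   `insertionAnchors` -- unique 1-based insertion anchor columns.
#' @export
buildFragmentPileup <- function(aln1, aln2 = NULL, refLength,
                                q1 = NULL, q2 = NULL, qualityFloor = 20L) {
    frag <- rep(NA_integer_, refLength)
    conflict <- rep(FALSE, refLength)
    addMate <- function(aln, qual) {
        if (is.null(aln) || !aln@mapped) return()
        calls <- aln@calls
        for (i in seq_len(nrow(calls))) {
            code <- calls[i, "code"]
            rp <- calls[i, "read_position"]
            if (code <= 3L && !is.null(qual) && rp > 0L) {
                q <- utf8ToInt(substr(qual, rp, rp)) - 33L
                if (q < qualityFloor) next
            }
            p <- calls[i, "position"]
            if (conflict[p]) next
            if (is.na(frag[p])) frag[p] <<- code
            else if (frag[p] != code) { frag[p] <<- NA_integer_
                                        conflict[p] <<- TRUE }
        }
    }
    addMate(aln1, q1)
    addMate(aln2, q2)
    ins <- unique(c(
        if (!is.null(aln1) && aln1@mapped) aln1@insertionAnchors,
        if (!is.null(aln2) && aln2@mapped) aln2@insertionAnchors))
    list(calls = .CALL_CODES[frag + 1L], insertionAnchors = sort(ins))
}

## internal: run the C++ bulk quantifier over a CloneReads object,
## optionally watching specific amplicon positions (for phasing)
.quantifyRaw <- function(reads, ref, qualityFloor, halfBand, maxEditFrac,
                         watchPositions = integer(0)) {
    .cppQuantifyPairs(reads@r1, reads@q1, reads@r2, reads@q2,
                      ref@sequence, as.integer(halfBand), maxEditFrac,
                      as.integer(qualityFloor), 33L,
                      as.integer(watchPositions))
}

.asCloneReads <- function(reads, id) {
    if (is(reads, "CloneReads")) return(reads)
    if (is.character(reads) && length(reads) == 2L)
        return(readFastqPair(reads[1], reads[2], id = id))
    .stopValidation("reads must be a CloneReads or a length-2 vector of ",
                    "FASTQ paths")
}

#' Quantify per-position allele frequencies for one sample
#'
#' The computational core of the genotyping protocol: every read pair is
#' aligned to the amplicon, mates are reconciled into fragment-level base
#' calls (overlap conflicts masked, qualities below the floor discarded),
#' and per-position counts of A/C/G/T/deletions plus insertion starts are
#' accumulated. Depth at a position is the number of counted calls, so the
#' pileup conserves `A + C + G + T + del == depth` everywhere by
#' construction. Unmapped reads are counted and reported, never silently
#' dropped.
#'
#' @param reads a [CloneReads][CloneReads-class] or a length-2 character
#'   vector of (optionally gzipped) FASTQ paths (R1, R2).
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param sampleId sample identifier (defaults to the reads' id).
#' @param qualityFloor base-quality floor, default Q20.
#' @param halfBand,maxEditFrac alignment settings, see [alignToAmplicon()].
#' @param adapter optional 3' adapter to trim from both mates first.
#' @return A [Pileup][Pileup-class].
#' @examples
#' ref <- auts2Amplicon()
#' haps <- list(haplotype("WT", weight = 0.7),
#'              haplotype("edit", 24L, "G", 0.3))
#' reads <- simulateClone(ref, haps, simConfig(depth = 300L, seed = 7L))
#' pu <- quantifySample(reads, ref)
#' altFraction(pu, 70768044L, "G")
#' @export
quantifySample <- function(reads, ref, sampleId = NULL, qualityFloor = 20L,
                           halfBand = 15L, maxEditFrac = 0.2,
                           adapter = NULL) {
    reads <- .asCloneReads(reads, id = sampleId %||% "sample")
    if (!is.null(adapter)) reads <- trimAdapter(reads, adapter)
    res <- .quantifyRaw(reads, ref, qualityFloor, halfBand, maxEditFrac)
    if (res$n_mapped_fragments == 0L)
        .stopValidation("empty sample: no fragment mapped to the amplicon")
    counts <- res$counts
    dimnames(counts) <- list(c(.BASES, "del", "ins"),
                             as.character(.toGenomic(ref,
                                 seq_len(ampliconLength(ref)))))
    new("Pileup",
        counts = counts, ref = ref,
        sampleId = sampleId %||% reads@id,
        nFragments = res$n_fragments,
        nMappedFragments = res$n_mapped_fragments,
        nUnmappedReads = res$n_unmapped_reads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pileup accessors
#'
#' `pileupCounts()` returns the 6 x n count matrix; `pileupDepth()` the
#' per-position depth (`A + C + G + T + del`); `nonRefFraction()` the
#' fraction of counted calls differing from the reference base (`NA` at
#' zero depth); `altFraction()` the fraction of a specific alternate base
#' (or `"del"`) at given genomic positions.
#'
#' @param pileup a [Pileup][Pileup-class].
#' @return Numeric vector(s); see details above.
#' @export
pileupCounts <- function(pileup) pileup@counts

#' @rdname pileupCounts
#' @export
pileupDepth <- function(pileup) colSums(pileup@counts[1:5, , drop = FALSE])

#' @rdname pileupCounts
#' @export
nonRefFraction <- function(pileup) {
    depth <- pileupDepth(pileup)
    refBases <- strsplit(pileup@ref@sequence, "", fixed = TRUE)[[1]]
    refCount <- pileup@counts[cbind(match(refBases, .BASES),
                                    seq_along(refBases))]
    ifelse(depth > 0, (depth - refCount) / depth, NA_real_)
}

#' @rdname pileupCounts
#' @param gpos genomic plus-strand position(s).
#' @param alt alternate base (`"A"`/`"C"`/`"G"`/`"T"`) or `"del"`.
#' @export
altFraction <- function(pileup, gpos, alt) {
    i <- .toAmplicon(pileup@ref, gpos)
    if (!all(alt %in% c(.BASES, "del")))
        .stopDomain("alt must be a base or 'del'")
    depth <- pileupDepth(pileup)[i]
    cnt <- pileup@counts[cbind(match(alt, c(.BASES, "del")), i)]
    unname(ifelse(depth > 0, cnt / depth, NA_real_))
}

#' Trim a 3' adapter from reads
#'
#' Removes the read suffix starting at the best adapter match: the
#' lowest-mismatch-rate alignment of the adapter's prefix against any read
#' suffix with at least 3 matched columns and at most 10 percent
#' mismatches; reads without such a match are untouched.
#'
#' @param reads a [CloneReads][CloneReads-class] or character vector of
#'   read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param maxMismFrac maximum mismatch fraction within the match.
#' @param minLen minimum matched length.
#' @return Same type as `reads`, with matched suffixes (and the
#'   corresponding quality bases) removed.
#' @export
trimAdapter <- function(reads, adapter, maxMismFrac = 0.1, minLen = 3L) {
    adapter <- toupper(adapter)
    if (!nzchar(adapter)) .stopDomain("adapter must be non-empty")
    trimVec <- function(x) {
        starts <- .cppTrimStarts(x, adapter, maxMismFrac, as.integer(minLen))
        ifelse(starts > 0L, substr(x, 1L, starts - 1L), x)
    }
    if (is.character(reads)) return(trimVec(toupper(reads)))
    if (!is(reads, "CloneReads"))
        .stopValidation("reads must be character or CloneReads")
    s1 <- .cppTrimStarts(reads@r1, adapter, maxMismFrac, as.integer(minLen))
    s2 <- .cppTrimStarts(reads@r2, adapter, maxMismFrac, as.integer(minLen))
    cut <- function(x, s) ifelse(s > 0L, substr(x, 1L, s - 1L), x)
    initialize(reads,
               r1 = cut(reads@r1, s1), q1 = cut(reads@q1, s1),
               r2 = cut(reads@r2, s2), q2 = cut(reads@q2, s2))
}

#' Aggregate per-sample quantifications into a cohort matrix
#'
#' Stacks per-sample non-reference fractions into an
#' [AlleleFrequencyMatrix][AlleleFrequencyMatrix-class] (positions x
#' samples). Positions with zero depth in a sample are `NA` in the
#' `frequency` assay -- explicitly distinct from an observed frequency of
#' zero. All samples must share the same reference amplicon.
#'
#' @param pileups list of [Pileup][Pileup-class] objects.
#' @param sampleIds sample identifiers (default: each pileup's own).
#' @return An [AlleleFrequencyMatrix][AlleleFrequencyMatrix-class].
#' @export
aggregateMatrix <- function(pileups, sampleIds = NULL) {
    if (!length(pileups)) .stopValidation("empty sample list")
    ref <- pileups[[1]]@ref
    same <- vapply(pileups, function(p) {
        identical(p@ref@sequence, ref@sequence) &&
            identical(p@ref@genomicStart, ref@genomicStart) &&
            identical(p@ref@contig, ref@contig)
    }, logical(1))
    if (!all(same)) .stopValidation("samples quantified against mixed references")
    if (is.null(sampleIds))
        sampleIds <- vapply(pileups, function(p) p@sampleId, character(1))
    if (anyDuplicated(sampleIds)) .stopValidation("duplicated sample ids")

    freq <- vapply(pileups, nonRefFraction, numeric(ampliconLength(ref)))
    depth <- vapply(pileups, pileupDepth, numeric(ampliconLength(ref)))
    dimnames(freq) <- dimnames(depth) <- list(NULL, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(frequency = freq, depth = depth),
        rowRanges = ampliconPositions(ref),
        colData = S4Vectors::DataFrame(sample_id = sampleIds,
                                       row.names = sampleIds))
    new("AlleleFrequencyMatrix", se)
}

#' @rdname pileupCounts
#' @param path output TSV path.
#' @export
writePileupTsv <- function(pileup, path) {
    ref <- pileup@ref
    df <- data.frame(
        contig = ref@contig,
        position = .toGenomic(ref, seq_len(ampliconLength(ref))),
        t(pileup@counts),
        depth = as.integer(pileupDepth(pileup)),
        non_ref_frac = sprintf("%.6f", nonRefFraction(pileup)),
        check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read the cohort frequency matrix as TSV
#'
#' One row per sample, one column per genomic position (named
#' `contig:position`), frequencies formatted at a fixed 6 decimal places
#' (missing positions written as `NA`), so a write/read cycle is exact at
#' that precision.
#'
#' @param afm an [AlleleFrequencyMatrix][AlleleFrequencyMatrix-class].
#' @param path TSV path.
#' @return `readMatrixTsv()`: numeric matrix, samples x positions.
#' @export
writeMatrixTsv <- function(afm, path) {
    f <- t(SummarizedExperiment::assay(afm, "frequency"))
    gr <- SummarizedExperiment::rowRanges(afm)
    colnames(f) <- paste0(GenomicRanges::seqnames(gr), ":",
                          GenomicRanges::start(gr))
    out <- data.frame(sample_id = rownames(f),
                      apply(f, 2, function(x)
                          ifelse(is.na(x), "NA", sprintf("%.6f", x))),
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df$sample_id
    m
}

#' Pileup from a pre-aligned SAM/BAM file
#'
#' Alternative input path for externally aligned reads: per-position
#' nucleotide/deletion/insertion counts are taken from
#' [Rsamtools::pileup()] over the amplicon region. Counts here are per
#' aligned read, without the fragment-level mate reconciliation applied by
#' [quantifySample()] (overlapping proper pairs count twice).
#'
#' @param file BAM (or SAM-convertible) file path; requires the
#'   `Rsamtools` package.
#' @param ref an [AmpliconReference][AmpliconReference-class]; the file
#'   must be aligned against a sequence named `ref@name` or `ref@contig`.
#' @param qualityFloor minimum base quality.
#' @return A [Pileup][Pileup-class].
#' @export
pileupFromBam <- function(file, ref, qualityFloor = 20L) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("pileupFromBam() requires the Rsamtools package")
    n <- ampliconLength(ref)
    pp <- Rsamtools::PileupParam(
        max_depth = 1000000L, min_base_quality = as.integer(qualityFloor),
        min_mapq = 0L, min_nucleotide_depth = 1L,
        distinguish_strands = FALSE, include_deletions = TRUE,
        include_insertions = TRUE)
    res <- Rsamtools::pileup(file, pileupParam = pp)
    counts <- matrix(0L, 6L, n,
                     dimnames = list(c(.BASES, "del", "ins"), NULL))
    keep <- res$seqnames %in% c(ref@name, ref@contig) &
        res$pos >= 1L & res$pos <= n
    res <- res[keep, , drop = FALSE]
    code <- match(as.character(res$nucleotide), c(.BASES, "-", "+"))
    ok <- !is.na(code)
    for (r in which(ok))
        counts[code[r], res$pos[r]] <- counts[code[r], res$pos[r]] +
            res$count[r]
    colnames(counts) <- as.character(.toGenomic(ref, seq_len(n)))
    new("Pileup",
        counts = counts, ref = ref, sampleId = basename(file),
        nFragments = NA_integer_, nMappedFragments = NA_integer_,
        nUnmappedReads = NA_integer_)
}
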