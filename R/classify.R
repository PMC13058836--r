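#' @include align-quantify.R
NULL

#' Construct classifier thresholds
#'
#' @param detectThreshold allele fraction counted as a detected edit
#'   (default 0.02, the sensitivity limit claimed for amplicon NGS versus
#'   about 0.2 for Sanger traces).
#' @param hetThreshold lower bound of the heterozygous-candidate band
#'   (default 0.30).
#' @param homozygousThreshold lower bound of the potential-homozygous band
#'   (default 0.65, placing the observed 0.68/0.89 clones in the band; no
#'   published cutoff exists, so this is configurable).
#' @param mosaicAlleleThreshold unintended-allele fraction flagging a clone
#'   as mosaic (default 0.05).
#' @param noiseFloor minimum fraction reported as a subclonal allele
#'   (default 0.005).
#' @return A [ClassifierConfig][ClassifierConfig-class].
#' @export
classifierConfig <- function(detectThreshold = 0.02, hetThreshold = 0.30,
                             homozygousThreshold = 0.65,
                             mosaicAlleleThreshold = 0.05,
                             noiseFloor = 0.005) {
    new("ClassifierConfig",
        detectThreshold = detectThreshold, hetThreshold = hetThreshold,
        homozygousThreshold = homozygousThreshold,
        mosaicAlleleThreshold = mosaicAlleleThreshold,
        noiseFloor = noiseFloor)
}

#' Band a target-edit fraction into a genotype category
#'
#' Inclusive threshold bands: `f < detect` is `unedited`;
#' `detect <= f < het` is `low_fraction_edited`; `het <= f < homozygous` is
#' `heterozygous_candidate`; `f >= homozygous` is `potential_homozygous`.
#' Every fraction in `[0, 1]` maps to exactly one category.
#'
#' @param f target-edit fraction(s) in `[0, 1]`.
#' @param config a [ClassifierConfig][ClassifierConfig-class].
#' @return Character vector of categories.
#' @export
categoryBand <- function(f, config = classifierConfig()) {
    if (any(f < 0 | f > 1, na.rm = TRUE))
        .stopDomain("fractions must lie in [0, 1]")
    cut(f,
        breaks = c(-Inf, config@detectThreshold, config@hetThreshold,
                   config@homozygousThreshold, Inf),
        labels = .CLONE_CATEGORIES, right = FALSE) |> as.character()
}

#' Classify one clone from its pileup
#'
#' Computes the fraction of the intended alternate base at the guide's
#' target position, bands it into a genotype category, flags mosaicism
#' when any unintended allele (substitution or indel, at any amplicon
#' position, excluding the intended edit) reaches the mosaic threshold, and
#' reports bystander edits at the guide's other editable window positions.
#'
#' @param pileup a [Pileup][Pileup-class].
#' @param guide the [GuideDesign][GuideDesign-class] used for this clone.
#' @param config a [ClassifierConfig][ClassifierConfig-class].
#' @return A [CloneCall][CloneCall-class].
#' @examples
#' ref <- auts2Amplicon()
#' g <- auts2Guides()$H044
#' reads <- simulateClone(ref,
#'     list(haplotype("WT", weight = 0.5), haplotype("edit", 24L, "G", 0.5)),
#'     simConfig(depth = 500L, seed = 3L))
#' classifyClone(quantifySample(reads, ref), g)
#' @export
classifyClone <- function(pileup, guide, config = classifierConfig()) {
    ref <- pileup@ref
    tpos <- targetGenomicPosition(guide, ref@contig)
    ti <- .toAmplicon(ref, tpos)
    depth <- pileupDepth(pileup)
    if (depth[ti] == 0)
        stop(errorCondition(
            paste0("no call for '", pileup@sampleId,
                   "': zero depth at the target position ", tpos),
            class = c("abeNoCallError", "error")))
    alt <- targetAltBase(guide)
    f <- pileup@counts[alt, ti] / depth[ti]

    ## scan every amplicon position for unintended alleles above the floor
    refBases <- strsplit(ref@sequence, "", fixed = TRUE)[[1]]
    rows <- c(.BASES, "del")
    mos <- data.frame(position = integer(0), genomic_position = integer(0),
                      alt = character(0), fraction = numeric(0))
    for (b in rows) {
        frac <- ifelse(depth > 0, pileup@counts[b, ] / depth, 0)
        hit <- which(frac >= config@noiseFloor & refBases != b)
        if (length(hit))
            mos <- rbind(mos, data.frame(
                position = hit, genomic_position = .toGenomic(ref, hit),
                alt = b, fraction = unname(frac[hit])))
    }
    intended <- mos$position == ti & mos$alt == alt
    mos <- mos[!intended, , drop = FALSE]
    mos <- mos[order(mos$position, mos$alt), , drop = FALSE]
    rownames(mos) <- NULL
    mosaic <- any(mos$fraction >= config@mosaicAlleleThreshold)

    ## bystanders: editable window positions other than the target
    bks <- setdiff(editablePositions(guide), guide@targetPosition)
    by <- data.frame(window_position = integer(0),
                     genomic_position = integer(0), alt = character(0),
                     fraction = numeric(0))
    for (k in bks) {
        gp <- GenomicRanges::start(mapProtospacerPosition(guide, k,
                                                          ref@contig))
        bf <- altFraction(pileup, gp, targetAltBase(guide))
        if (!is.na(bf) && bf >= config@detectThreshold)
            by <- rbind(by, data.frame(window_position = k,
                                       genomic_position = gp,
                                       alt = targetAltBase(guide),
                                       fraction = unname(bf)))
    }
    new("CloneCall",
        sampleId = pileup@sampleId, guideId = guide@guideId,
        targetEditFraction = unname(f), targetDepth = as.integer(depth[ti]),
        category = categoryBand(f, config), mosaic = mosaic,
        mosaicAlleles = mos, bystanders = by)
}

#' Tabulate clone calls into a roster
#'
#' @param calls list of [CloneCall][CloneCall-class] objects.
#' @return data.frame with one row per clone: `sample_id`, `guide_id`,
#'   `target_fraction`, `target_depth`, `category`, `mosaic`,
#'   `n_bystanders`, `bystanders` (collapsed `position:fraction` string).
#' @export
cloneRoster <- function(calls) {
    do.call(rbind, lapply(calls, function(cc) {
        data.frame(
            sample_id = cc@sampleId, guide_id = cc@guideId,
            target_fraction = cc@targetEditFraction,
            target_depth = cc@targetDepth, category = cc@category,
            mosaic = cc@mosaic, n_bystanders = nrow(cc@bystanders),
            bystanders = paste(sprintf("%d:%.4f",
                                       cc@bystanders$window_position,
                                       cc@bystanders$fraction),
                               collapse = ";"))
    }))
}

#' Editing efficiency as an integer percentage
#'
#' The proportion of clones whose target-edit fraction reaches `threshold`,
#' as `100 * positives / total` rounded half-up to the nearest integer
#' percent (so 37/69 prints as 54). Accepts either explicit counts or a
#' list of clone calls / a roster from which positives are counted.
#'
#' @param x positive count, list of [CloneCall][CloneCall-class] objects,
#'   or a [cloneRoster()] data.frame.
#' @param total total clone count (only with explicit counts).
#' @param threshold allele-fraction threshold (used when counting calls).
#' @return Integer percent.
#' @examples
#' summarizeEfficiency(37, 69)  # 54
#' summarizeEfficiency(9, 69)   # 13
#' @export
summarizeEfficiency <- function(x, total = NULL, threshold = 0.02) {
    if (is.numeric(x)) {
        positives <- x
        if (is.null(total)) .stopDomain("total required with explicit counts")
    } else {
        fr <- if (is.data.frame(x)) x$target_fraction
              else vapply(x, function(cc) cc@targetEditFraction, numeric(1))
        positives <- sum(fr >= threshold, na.rm = TRUE)
        total <- length(fr)
    }
    if (total < 1) .stopDomain("total must be >= 1")
    if (positives > total || positives < 0)
        .stopDomain("positives must lie in 0..total")
    as.integer(floor(100 * positives / total + 0.5))  # half-up
}

#' Per-position clone positivity profile
#'
#' For each amplicon position, the fraction of samples whose allele
#' frequency reaches `threshold` -- the aggregated per-guide-group profile
#' used to visualise where in (and around) the editing window clones carry
#' substitutions. Samples with missing data (zero depth) at a position
#' count as not positive.
#'
#' @param afm an [AlleleFrequencyMatrix][AlleleFrequencyMatrix-class].
#' @param threshold allele-fraction threshold (default 0.02).
#' @return Named numeric vector over genomic positions, each in `[0, 1]`.
#' @export
positivityProfile <- function(afm, threshold = 0.02) {
    if (ncol(afm) == 0L) .stopValidation("empty matrix")
    f <- SummarizedExperiment::assay(afm, "frequency")
    pos <- !is.na(f) & f >= threshold
    prof <- rowSums(pos) / ncol(f)
    gr <- SummarizedExperiment::rowRanges(afm)
    names(prof) <- paste0(GenomicRanges::seqnames(gr), ":",
                          GenomicRanges::start(gr))
    prof
}
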