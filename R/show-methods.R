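#' @include phasing.R
#' @include report-cost.R
NULL

setMethod("show", "AmpliconReference", function(object) {
    n <- ampliconLength(object)
    cat("AmpliconReference '", object@name, "': ", n, " bp at ",
        object@contig, ":", object@genomicStart, "-",
        object@genomicStart + n - 1L, "\n", sep = "")
    if (!is.na(object@frameOffset))
        cat("  coding frame: offset ", object@frameOffset, " on strand ",
            object@codingStrand, "\n", sep = "")
})

setMethod("show", "GuideDesign", function(object) {
    cat("GuideDesign '", object@guideId, "' (", object@strand,
        "): 5'-", object@protospacer, "-3'\n", sep = "")
    cat("  anchor ", object@anchor, ", window ", object@window[1], "-",
        object@window[2], ", target position ", object@targetPosition,
        " -> ", targetGenomicPosition(object), " ",
        targetRefBase(object), ">", targetAltBase(object), "\n", sep = "")
})

setMethod("show", "CodonEdit", function(object) {
    cat("CodonEdit: ", object@codonBefore, ">", object@codonAfter, " (",
        object@aaBefore, ">", object@aaAfter, "), ",
        if (object@synonymous) "synonymous" else "non-synonymous", "\n",
        sep = "")
})

setMethod("show", "CloneReads", function(object) {
    cat("CloneReads '", object@id, "': ", length(object@r1),
        " fragments, ", object@config@readLength, " bp paired reads\n",
        sep = "")
    if (length(object@truth))
        cat("  haplotypes: ",
            paste(sprintf("%s=%.3g", names(object@truth$weights),
                          object@truth$weights), collapse = ", "),
            "\n", sep = "")
})

setMethod("show", "Pileup", function(object) {
    cat("Pileup '", object@sampleId, "': ", ncol(object@counts),
        " positions, ", object@nMappedFragments, "/", object@nFragments,
        " fragments mapped (", object@nUnmappedReads,
        " unmapped reads)\n", sep = "")
})

setMethod("show", "CloneCall", function(object) {
    cat("CloneCall '", object@sampleId, "' [", object@guideId, "]: ",
        sprintf("%.1f%%", 100 * object@targetEditFraction),
        " target edit (depth ", object@targetDepth, ") -> ",
        object@category, if (object@mosaic) ", MOSAIC" else "", "\n",
        sep = "")
    if (nrow(object@bystanders))
        cat("  bystanders: ",
            paste(sprintf("pos %d @ %.1f%%",
                          object@bystanders$window_position,
                          100 * object@bystanders$fraction),
                  collapse = "; "), "\n", sep = "")
})

setMethod("show", "PhasingSites", function(object) {
    cat("PhasingSites: edit ", object@contig, ":", object@editPos, " ",
        object@editRef, ">", object@editAlt, "; germline ", object@contig,
        ":", object@germlinePos, " ", object@allele1, "/", object@allele2,
        " (", expectedDistance(object), " bp apart)\n", sep = "")
})

setMethod("show", "PhasingResult", function(object) {
    cat("PhasingResult: ", object@phaseCall, " (purity ",
        sprintf("%.3f", object@purity), ", germline balance ",
        sprintf("%.3f", object@germlineBalance), ")\n", sep = "")
    print(object@jointCounts)
    cat("  informative ", object@informative, ", uninformative ",
        object@uninformative, "; ",
        if (object@monoclonal) "monoclonal"
        else paste("NOT monoclonal:",
                   paste(object@diagnostics, collapse = "; ")),
        "\n", sep = "")
})

setMethod("show", "CohortReport", function(object) {
    cat("CohortReport: ", nrow(object@roster), " clones, ",
        nrow(object@shortlist), " shortlisted, ",
        length(object@profiles), " group profile(s)\n", sep = "")
    print(object@efficiency)
})
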