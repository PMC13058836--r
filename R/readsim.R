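#' @include reference-model.R
NULL

#' Construct simulation settings
#'
#' Defaults emulate the genotyping protocol: paired-end 150-bp reads from a
#' 363-bp amplicon product, about 10,000 fragments per clone for
#' quantification (5,000 for phasing), constant Q30 base qualities and an
#' independent per-base substitution error rate of 0.001 (a typical
#' Illumina-class figure; the platform error profile is not part of the
#' protocol and is configurable).
#'
#' @param depth fragments (read pairs) per clone.
#' @param readLength read length in bp.
#' @param fragmentLength sequenced product length in bp.
#' @param fragmentStart 1-based amplicon position where the product starts.
#' @param perBaseError per-base substitution error rate in `[0, 0.25)`.
#' @param baseQuality constant Phred quality for simulated bases.
#' @param seed integer seed (`NA`: use the current RNG stream).
#' @return A [SimConfig][SimConfig-class].
#' @export
simConfig <- function(depth = 10000L, readLength = 150L,
                      fragmentLength = 363L, fragmentStart = 1L,
                      perBaseError = 0.001, baseQuality = 30L,
                      seed = NA_integer_) {
    new("SimConfig",
        depth = as.integer(depth), readLength = as.integer(readLength),
        fragmentLength = as.integer(fragmentLength),
        fragmentStart = as.integer(fragmentStart),
        perBaseError = as.numeric(perBaseError),
        baseQuality = as.integer(baseQuality), seed = as.integer(seed))
}

#' Construct a haplotype
#'
#' @param label haplotype label.
#' @param positions 1-based amplicon positions of substitutions (may be
#'   empty for the wild-type haplotype).
#' @param alts alternate bases matching `positions`.
#' @param weight fraction of the clone's cells carrying this haplotype.
#' @return A [Haplotype][Haplotype-class].
#' @examples
#' wt <- haplotype("WT", weight = 0.5)
#' ed <- haplotype("edit", positions = 24L, alts = "G", weight = 0.5)
#' @export
haplotype <- function(label, positions = integer(0), alts = character(0),
                      weight) {
    new("Haplotype",
        label = as.character(label), positions = as.integer(positions),
        alts = toupper(as.character(alts)), weight = as.numeric(weight))
}

## apply a haplotype's substitutions to the fragment sequence, validating
## them against the reference
.haplotypeFragment <- function(ref, hap, fragStart, fragLen) {
    fragEnd <- fragStart + fragLen - 1L
    if (fragEnd > ampliconLength(ref))
        .stopValidation("fragment extends beyond the amplicon")
    frag <- substr(ref@sequence, fragStart, fragEnd)
    for (i in seq_along(hap@positions)) {
        p <- hap@positions[i]
        if (p < fragStart || p > fragEnd)
            .stopValidation("haplotype '", hap@label, "': substitution at ",
                            "amplicon position ", p,
                            " lies outside the fragment")
        j <- p - fragStart + 1L
        if (substr(frag, j, j) == hap@alts[i])
            .stopValidation("haplotype '", hap@label, "': alt at position ",
                            p, " equals the reference base")
        substr(frag, j, j) <- hap@alts[i]
    }
    frag
}

## independent per-base substitution errors, uniform over the three
## alternative bases; vectorised draw of error sites, per-site patching
.injectErrors <- function(reads, rate) {
    n <- length(reads)
    if (rate <= 0 || n == 0L) return(reads)
    len <- nchar(reads[1L])
    nerr <- rbinom(1L, n * len, rate)
    if (nerr == 0L) return(reads)
    idx <- sample.int(n * len, nerr)
    ri <- (idx - 1L) %/% len + 1L
    pos <- (idx - 1L) %% len + 1L
    pick <- sample.int(3L, nerr, replace = TRUE)
    for (e in seq_len(nerr)) {
        cur <- substr(reads[ri[e]], pos[e], pos[e])
        substr(reads[ri[e]], pos[e], pos[e]) <- setdiff(.BASES, cur)[pick[e]]
    }
    reads
}

#' Simulate amplicon sequencing of one clone
#'
#' Draws `depth` fragments, each from one haplotype with probability equal
#' to its weight, and emits paired reads: R1 is the fragment's 5' prefix of
#' `readLength` bases, R2 the reverse complement of its 3' suffix.
#' Sequencing noise is modelled as independent per-base substitution errors
#' at `perBaseError`, uniform over the three alternative bases. With a
#' fixed `seed` the output is byte-identical across runs.
#'
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param haplotypes list of [Haplotype][Haplotype-class] objects; weights
#'   must sum to 1 (tolerance 1e-9).
#' @param config a [SimConfig][SimConfig-class].
#' @param id sample identifier.
#' @return A [CloneReads][CloneReads-class] whose `truth` slot records the
#'   nominal weights and the realized per-haplotype fragment counts.
#' @examples
#' ref <- auts2Amplicon()
#' haps <- list(haplotype("WT", weight = 0.7),
#'              haplotype("edit", 24L, "G", 0.3))
#' reads <- simulateClone(ref, haps, simConfig(depth = 200L, seed = 1L))
#' table(reads@hap)
#' @export
simulateClone <- function(ref, haplotypes, config = simConfig(),
                          id = "clone") {
    if (!length(haplotypes))
        .stopValidation("at least one haplotype required")
    for (h in haplotypes) validObject(h)
    w <- vapply(haplotypes, function(h) h@weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-9)
        .stopValidation("haplotype weights must sum to 1 (got ", sum(w), ")")
    labels <- vapply(haplotypes, function(h) h@label, character(1))
    if (anyDuplicated(labels)) .stopValidation("duplicated haplotype labels")

    cfg <- config
    fragStart <- cfg@fragmentStart
    fragLen <- cfg@fragmentLength
    frags <- vapply(haplotypes, .haplotypeFragment, character(1),
                    ref = ref, fragStart = fragStart, fragLen = fragLen)
    r1hap <- substr(frags, 1L, cfg@readLength)
    r2hap <- .revcompChr(substr(frags, fragLen - cfg@readLength + 1L,
                                fragLen))

    .withSeed(cfg@seed, {
        assign <- sample.int(length(haplotypes), cfg@depth, replace = TRUE,
                             prob = w)
        r1 <- .injectErrors(r1hap[assign], cfg@perBaseError)
        r2 <- .injectErrors(r2hap[assign], cfg@perBaseError)
        qual <- strrep(rawToChar(as.raw(cfg@baseQuality + 33L)),
                       cfg@readLength)
        realized <- tabulate(assign, nbins = length(haplotypes))
        names(realized) <- labels
        new("CloneReads",
            id = id, r1 = r1, r2 = r2,
            q1 = rep(qual, cfg@depth), q2 = rep(qual, cfg@depth),
            hap = labels[assign],
            truth = list(labels = labels, weights = setNames(w, labels),
                         realizedCounts = realized),
            config = cfg)
    })
}

#' Simulate a phased heterozygous clone
#'
#' Builds a clone heterozygous for the induced edit and for the germline
#' variant, with the edit in `cis` (edited fragments carry `allele1`-tagged
#' chromatids) or `trans` (they carry `allele2`). The germline allele
#' balance is 0.5 in expectation.
#'
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param sites a [PhasingSites][PhasingSites-class]; both sites must fall
#'   within the simulated fragment.
#' @param phase `"cis"` (edit on the allele-1 chromatid) or `"trans"`.
#' @param config a [SimConfig][SimConfig-class].
#' @param editFraction fraction of fragments carrying the edit (at most
#'   0.5, the single-chromatid share of a diploid heterozygote).
#' @param id sample identifier.
#' @return A [CloneReads][CloneReads-class].
#' @export
simulatePhasedClone <- function(ref, sites, phase = c("cis", "trans"),
                                config = simConfig(depth = 5000L),
                                editFraction = 0.5, id = "clone") {
    phase <- match.arg(phase)
    if (editFraction <= 0 || editFraction > 0.5)
        .stopValidation("editFraction must lie in (0, 0.5]")
    cfg <- config
    fragEnd <- cfg@fragmentStart + cfg@fragmentLength - 1L
    ei <- .toAmplicon(ref, sites@editPos)
    gi <- .toAmplicon(ref, sites@germlinePos)
    if (ei < cfg@fragmentStart || ei > fragEnd ||
        gi < cfg@fragmentStart || gi > fragEnd)
        .stopValidation("both phasing sites must lie within the fragment")
    if (refBaseAt(ref, sites@editPos) != sites@editRef)
        .stopValidation("editRef does not match the reference")

    gRef <- refBaseAt(ref, sites@germlinePos)
    subsFor <- function(edited, allele) {
        pos <- integer(0); alt <- character(0)
        if (edited) { pos <- c(pos, ei); alt <- c(alt, sites@editAlt) }
        if (allele != gRef) { pos <- c(pos, gi); alt <- c(alt, allele) }
        list(pos = pos, alt = alt)
    }
    cisAllele <- if (phase == "cis") sites@allele1 else sites@allele2
    otherAllele <- if (phase == "cis") sites@allele2 else sites@allele1
    e <- subsFor(TRUE, cisAllele)
    u1 <- subsFor(FALSE, cisAllele)
    u2 <- subsFor(FALSE, otherAllele)
    haps <- list(
        haplotype(paste0("edit_", cisAllele), e$pos, e$alt, editFraction),
        haplotype(paste0("wt_", otherAllele), u2$pos, u2$alt, 0.5))
    if (editFraction < 0.5) {
        haps <- c(haps, list(haplotype(paste0("wt_", cisAllele), u1$pos,
                                       u1$alt, 0.5 - editFraction)))
    }
    simulateClone(ref, haps, cfg, id = id)
}

## ---------------------------------------------------------------------------
## Cohort simulation mirroring the published screen

#' Default cohort design mirroring the published screen
#'
#' A 117-clone design: 69 clones edited with H044 and 48 with H068. Target
#' and bystander haplotype weights are chosen so the cohort reproduces the
#' screen's headline rates at sequencing depth: 31/69 clones positive at
#' the H044 target (protospacer position 5, about 45 percent), 12/69 at
#' bystander position 4 (about 17 percent), union 37/69 detected at the 2
#' percent threshold (54 percent) with 9/69 at or above 30 percent
#' (13 percent) including two potential homozygotes at 0.68 and 0.89; and
#' for H068, 15/48 (31 percent) detected with 2/48 (4 percent) at or above
#' 30 percent. Target and bystander edits are placed on distinct
#' haplotypes (no double substitutions within one allele). Low-fraction
#' weights start at 0.04 so band membership is unambiguous at the default
#' simulated depth.
#'
#' @return data.frame with columns `sample_id`, `guide_id`,
#'   `target_weight`, `bystander_weight`.
#' @export
cohortDesign <- function() {
    h044_het <- c(0.33, 0.35, 0.38, 0.41, 0.44, 0.47, 0.50, 0.68, 0.89)
    h044_low <- round(seq(0.04, 0.28, length.out = 22), 3)
    h044_target <- c(h044_het, h044_low)                       # 31 positive
    h044_by <- rep(0, 69)
    h044_by[10:15] <- c(0.05, 0.08, 0.10, 0.12, 0.15, 0.20)   # 6 with both
    h044_by[32:37] <- c(0.05, 0.07, 0.09, 0.11, 0.14, 0.18)   # 6 bystander-only
    h044 <- data.frame(
        sample_id = sprintf("H044_c%02d", 1:69), guide_id = "H044",
        target_weight = c(h044_target, rep(0, 38)),
        bystander_weight = h044_by)

    h068_target <- c(0.35, 0.50, round(seq(0.04, 0.28, length.out = 13), 3))
    h068 <- data.frame(
        sample_id = sprintf("H068_c%02d", 1:48), guide_id = "H068",
        target_weight = c(h068_target, rep(0, 33)),
        bystander_weight = 0)
    rbind(h044, h068)
}

#' Simulate a clone cohort
#'
#' Simulates every clone of a design (see [cohortDesign()]): each clone
#' mixes a wild-type haplotype, an intended-edit haplotype at
#' `target_weight`, and (H044 only) a bystander haplotype carrying the
#' protospacer-position-4 edit at `bystander_weight`.
#'
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param guides named list of [GuideDesign][GuideDesign-class] objects
#'   covering every `guide_id` in the design.
#' @param design design data.frame, by default [cohortDesign()].
#' @param depth fragments per clone.
#' @param perBaseError per-base error rate.
#' @param seed RNG seed governing the whole cohort.
#' @return list with `reads` (list of [CloneReads][CloneReads-class]) and
#'   `manifest` (the design plus each clone's realized target fraction).
#' @export
simulateCohort <- function(ref, guides = auts2Guides(),
                           design = cohortDesign(), depth = 2000L,
                           perBaseError = 0.001, seed = 1L) {
    missingGuides <- setdiff(unique(design$guide_id), names(guides))
    if (length(missingGuides))
        .stopValidation("design references unknown guide(s): ",
                        paste(missingGuides, collapse = ", "))
    cfg <- simConfig(depth = depth, perBaseError = perBaseError)
    .withSeed(seed, {
        reads <- vector("list", nrow(design))
        realized <- numeric(nrow(design))
        for (i in seq_len(nrow(design))) {
            g <- guides[[design$guide_id[i]]]
            tpos <- .toAmplicon(ref, targetGenomicPosition(g, ref@contig))
            tw <- design$target_weight[i]
            bw <- design$bystander_weight[i]
            haps <- list(haplotype("WT", weight = 1 - tw - bw))
            if (tw > 0)
                haps <- c(haps, list(haplotype("target", tpos,
                                               targetAltBase(g), tw)))
            if (bw > 0) {
                bk <- setdiff(editablePositions(g), g@targetPosition)[1]
                bpos <- .toAmplicon(ref, GenomicRanges::start(
                    mapProtospacerPosition(g, bk, ref@contig)))
                haps <- c(haps, list(haplotype("bystander", bpos,
                                               targetAltBase(g), bw)))
            }
            reads[[i]] <- simulateClone(ref, haps, cfg,
                                        id = design$sample_id[i])
            rc <- reads[[i]]@truth$realizedCounts
            realized[i] <- if ("target" %in% names(rc))
                rc[["target"]] / depth else 0
        }
        manifest <- design
        manifest$realized_target_fraction <- realized
        list(reads = reads, manifest = manifest)
    })
}
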