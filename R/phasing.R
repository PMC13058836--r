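#' @include align-quantify.R
NULL

#' Construct a two-site phasing design
#'
#' @param contig contig name.
#' @param editPos genomic position of the induced substitution.
#' @param editRef,editAlt reference and edited base at `editPos`.
#' @param germlinePos genomic position of the germline heterozygous
#'   variant anchoring the two alleles.
#' @param allele1,allele2 the two germline alleles.
#' @return A [PhasingSites][PhasingSites-class].
#' @examples
#' sites <- phasingSites("chr7", 70768044L, "A", "G",
#'                       70768282L, "G", "A")  # rs3829006
#' expectedDistance(sites)  # 238
#' @export
phasingSites <- function(contig, editPos, editRef, editAlt, germlinePos,
                         allele1, allele2) {
    new("PhasingSites",
        contig = as.character(contig), editPos = as.integer(editPos),
        editRef = toupper(editRef), editAlt = toupper(editAlt),
        germlinePos = as.integer(germlinePos),
        allele1 = toupper(allele1), allele2 = toupper(allele2))
}

#' @rdname phasingSites
#' @param sites a [PhasingSites][PhasingSites-class].
#' @return `expectedDistance()`: distance between the two sites in bp.
#' @export
expectedDistance <- function(sites) abs(sites@germlinePos - sites@editPos)

#' Count fragment-level joint alleles at the two phasing sites
#'
#' Each fragment with a usable base call at both sites (call present, not
#' quality-masked or mate-conflicted, and matching one of the expected
#' alleles at each site) increments exactly one cell of the 2 x 2 joint
#' table (edit allele x germline allele). All other fragments are tallied
#' as uninformative.
#'
#' @param editCalls,germlineCalls per-fragment base calls at the two sites
#'   (characters, `NA` for no call), equal length.
#' @param sites a [PhasingSites][PhasingSites-class].
#' @return list with `jointCounts` (2 x 2 integer matrix, rows
#'   `c(ref, alt)`, columns `c(allele1, allele2)`), `informative` and
#'   `uninformative` fragment counts.
#' @export
countJointAlleles <- function(editCalls, germlineCalls, sites) {
    if (length(editCalls) != length(germlineCalls))
        .stopValidation("per-site call vectors differ in length")
    er <- match(editCalls, c(sites@editRef, sites@editAlt))
    gr <- match(germlineCalls, c(sites@allele1, sites@allele2))
    ok <- !is.na(er) & !is.na(gr)
    jc <- matrix(0L, 2L, 2L,
                 dimnames = list(edit = c(sites@editRef, sites@editAlt),
                                 germline = c(sites@allele1,
                                              sites@allele2)))
    if (any(ok)) {
        tab <- table(factor(er[ok], levels = 1:2),
                     factor(gr[ok], levels = 1:2))
        jc[] <- as.integer(tab)
    }
    n <- length(editCalls)
    if (sum(jc) == 0L)
        stop(errorCondition("no informative fragments covering both sites",
                            class = c("abeNoPhaseError", "error")))
    list(jointCounts = jc, informative = sum(jc),
         uninformative = n - sum(jc))
}

#' Call the phase from a joint-allele table
#'
#' Among fragments carrying the edited allele, the phase purity is the
#' majority germline-allele share; the call assigns the edit to that
#' allele. The call is `ambiguous` when fewer than `minFragments` edited
#' fragments are informative or the purity falls below `minPurity`
#' (defaults chosen conservatively for about 5,000-pair depth; the
#' original protocol phased by eye in a genome browser and states no
#' numeric cutoffs).
#'
#' @param jointCounts 2 x 2 table from [countJointAlleles()].
#' @param minFragments minimum informative edited fragments.
#' @param minPurity minimum majority share.
#' @return list with `phaseCall` (`cis_with_allele_1`, `cis_with_allele_2`
#'   or `ambiguous`), `purity` and `nAltFragments`.
#' @export
callPhase <- function(jointCounts, minFragments = 100L, minPurity = 0.9) {
    altRow <- jointCounts[2L, ]
    nAlt <- sum(altRow)
    purity <- if (nAlt > 0) max(altRow) / nAlt else NA_real_
    call <- "ambiguous"
    if (nAlt >= minFragments && !is.na(purity) && purity >= minPurity &&
        altRow[1L] != altRow[2L]) {
        call <- if (altRow[1L] > altRow[2L]) "cis_with_allele_1"
                else "cis_with_allele_2"
    }
    list(phaseCall = call, purity = unname(purity),
         nAltFragments = unname(nAlt))
}

#' Assess clone monoclonality from phasing evidence
#'
#' A monoclonal heterozygously edited colony should show (i) a balanced
#' germline allele ratio (each chromosome sampled equally), (ii) high phase
#' purity (the edit consistently on one chromosome), and (iii) an edit
#' fraction inside its expected category band when a band is supplied.
#' Mixed colonies violate purity (edit split across alleles) and/or
#' balance (unequal subclone contributions or allelic dropout).
#'
#' @param jointCounts 2 x 2 table from [countJointAlleles()].
#' @param balanceTolerance allowed deviation of the germline allele-1
#'   share from 0.5 (default 0.15).
#' @param minFragments,minPurity forwarded to [callPhase()].
#' @param editFraction,expectedBand optional: the clone's target-edit
#'   fraction and the category band it should occupy (see
#'   [categoryBand()]); checked when both are given.
#' @param config [ClassifierConfig][ClassifierConfig-class] used for the
#'   band check.
#' @return list with `monoclonal` and `diagnostics` (character vector
#'   naming each failed criterion, empty when monoclonal).
#' @export
assessMonoclonality <- function(jointCounts, balanceTolerance = 0.15,
                                minFragments = 100L, minPurity = 0.9,
                                editFraction = NULL, expectedBand = NULL,
                                config = classifierConfig()) {
    balance <- sum(jointCounts[, 1L]) / sum(jointCounts)
    ph <- callPhase(jointCounts, minFragments, minPurity)
    diag <- character(0)
    if (abs(balance - 0.5) > balanceTolerance)
        diag <- c(diag, sprintf(
            "germline allele balance %.3f outside 0.5 +/- %.2f (clone mixture or allelic dropout)",
            balance, balanceTolerance))
    if (is.na(ph$purity) || ph$purity < minPurity)
        diag <- c(diag, sprintf(
            "phase purity %.3f below %.2f (edit split across alleles)",
            ph$purity, minPurity))
    if (!is.null(editFraction) && !is.null(expectedBand)) {
        band <- categoryBand(editFraction, config)
        if (band != expectedBand)
            diag <- c(diag, sprintf(
                "edit fraction %.3f bands as '%s', expected '%s'",
                editFraction, band, expectedBand))
    }
    list(monoclonal = length(diag) == 0L, diagnostics = diag,
         germlineBalance = unname(balance), purity = ph$purity)
}

#' Phase one sample end to end
#'
#' Aligns every read pair, reconciles mate calls, extracts the fragment
#' base at the edit site and at the germline site, builds the joint table,
#' calls the phase and assesses monoclonality. The phasing unit is the
#' fragment: with the two sites 238 bp apart and 150-bp reads, no single
#' read spans both, but R1 covers one site and R2 the other within the
#' same PCR product.
#'
#' @param reads a [CloneReads][CloneReads-class] or length-2 vector of
#'   FASTQ paths.
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @param sites a [PhasingSites][PhasingSites-class].
#' @param qualityFloor,halfBand,maxEditFrac see [quantifySample()].
#' @param minFragments,minPurity,balanceTolerance see [callPhase()] and
#'   [assessMonoclonality()].
#' @param editFraction,expectedBand optional band-consistency inputs for
#'   the monoclonality check.
#' @return A [PhasingResult][PhasingResult-class].
#' @examples
#' ref <- auts2Amplicon()
#' sites <- auts2PhasingSites()
#' reads <- simulatePhasedClone(ref, sites, "cis",
#'     simConfig(depth = 400L, seed = 11L))
#' phaseSample(reads, ref, sites)
#' @export
phaseSample <- function(reads, ref, sites, qualityFloor = 20L,
                        halfBand = 15L, maxEditFrac = 0.2,
                        minFragments = 100L, minPurity = 0.9,
                        balanceTolerance = 0.15, editFraction = NULL,
                        expectedBand = NULL) {
    reads <- .asCloneReads(reads, id = "phasing")
    watch <- c(.toAmplicon(ref, sites@editPos),
               .toAmplicon(ref, sites@germlinePos))
    raw <- .quantifyRaw(reads, ref, qualityFloor, halfBand, maxEditFrac,
                        watchPositions = watch)
    wc <- raw$watch_calls
    toBase <- function(v) ifelse(v >= 0L & v <= 3L, .BASES[v + 1L],
                                 NA_character_)
    jc <- countJointAlleles(toBase(wc[, 1L]), toBase(wc[, 2L]), sites)
    ph <- callPhase(jc$jointCounts, minFragments, minPurity)
    mono <- assessMonoclonality(jc$jointCounts, balanceTolerance,
                                minFragments, minPurity, editFraction,
                                expectedBand)
    new("PhasingResult",
        jointCounts = jc$jointCounts,
        informative = as.integer(jc$informative),
        uninformative = as.integer(jc$uninformative),
        phaseCall = ph$phaseCall,
        purity = ph$purity,
        germlineBalance = mono$germlineBalance,
        monoclonal = mono$monoclonal,
        diagnostics = mono$diagnostics)
}
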