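#' @include classify.R
NULL

#' Construct cost-model parameters
#'
#' @param sangerPerSample Sanger cost per sample.
#' @param ngsPerSample NGS sequencing cost per sample.
#' @param ngsFixed fixed NGS run overhead.
#' @param primerUnitCost cost of synthesizing one indexing primer.
#' @return A [CostParams][CostParams-class].
#' @export
costParams <- function(sangerPerSample, ngsPerSample, ngsFixed = 0,
                       primerUnitCost = 0) {
    new("CostParams",
        sangerPerSample = as.numeric(sangerPerSample),
        ngsPerSample = as.numeric(ngsPerSample),
        ngsFixed = as.numeric(ngsFixed),
        primerUnitCost = as.numeric(primerUnitCost))
}

#' Genotyping cost curves: Sanger versus NGS
#'
#' Per-sample-count total costs. `Sanger(N) = sangerPerSample * N`.
#' `NGS_without(N) = ngsFixed + ngsPerSample * N` ignores indexing-primer
#' synthesis (an existing primer set). Under dual indexing, N samples need
#' `ceiling(sqrt(N))` primers per index axis across two axes, so
#' `NGS_with(N) = NGS_without(N) + primerUnitCost * 2 * ceiling(sqrt(N))`
#' -- the primer cost component scales as `sqrt(N)`.
#'
#' @param params a [CostParams][CostParams-class].
#' @param nMax maximum sample count.
#' @return data.frame with columns `n`, `sanger`, `ngs_without_primers`,
#'   `ngs_with_primers`, `primers_needed`.
#' @examples
#' p <- costParams(150, 10, ngsFixed = 1000, primerUnitCost = 570)
#' head(costCurves(p, 10))
#' costCrossover(p, includePrimers = TRUE)
#' @export
costCurves <- function(params, nMax) {
    if (nMax < 1) .stopDomain("nMax must be >= 1")
    n <- seq_len(nMax)
    primers <- 2 * ceiling(sqrt(n))
    without <- params@ngsFixed + params@ngsPerSample * n
    data.frame(
        n = n,
        sanger = params@sangerPerSample * n,
        ngs_without_primers = without,
        ngs_with_primers = without + params@primerUnitCost * primers,
        primers_needed = primers)
}

#' Smallest cohort size at which NGS undercuts Sanger
#'
#' Exact integer scan of the cost curves: the smallest `N` with
#' `NGS(N) < Sanger(N)` (strictly), or `NA` when NGS is never cheaper up
#' to `nMax`.
#'
#' @param params a [CostParams][CostParams-class].
#' @param includePrimers include the indexing-primer synthesis component.
#' @param nMax scan limit.
#' @return Integer crossover sample count, or `NA_integer_`.
#' @export
costCrossover <- function(params, includePrimers = TRUE, nMax = 10000L) {
    cc <- costCurves(params, nMax)
    ngs <- if (includePrimers) cc$ngs_with_primers
           else cc$ngs_without_primers
    hit <- which(ngs < cc$sanger)
    if (!length(hit)) NA_integer_ else as.integer(hit[1L])
}

#' Export a cohort report
#'
#' Cohort-level bookkeeping after classification: the clone roster, the
#' shortlist of clones suitable for banking (non-mosaic heterozygous
#' candidates), per-group positional positivity profiles (the aggregated
#' per-guide view of where clones carry substitutions) and efficiency
#' summaries at the detection and heterozygous thresholds. When `dir` is
#' given, writes `matrix.tsv`, `roster.tsv`, `shortlist.tsv` and one
#' `profile_<group>.tsv` per group.
#'
#' @param afm an [AlleleFrequencyMatrix][AlleleFrequencyMatrix-class].
#' @param calls list of [CloneCall][CloneCall-class] objects (same
#'   samples).
#' @param groups named list mapping group names to sample-id vectors;
#'   defaults to grouping by guide.
#' @param config a [ClassifierConfig][ClassifierConfig-class].
#' @param dir optional output directory.
#' @return A [CohortReport][CohortReport-class].
#' @export
exportCohort <- function(afm, calls, groups = NULL,
                         config = classifierConfig(), dir = NULL) {
    if (!length(calls)) .stopValidation("empty cohort")
    roster <- cloneRoster(calls)
    if (!setequal(roster$sample_id, colnames(afm)))
        .stopValidation("calls and matrix cover different samples")
    if (is.null(groups))
        groups <- split(roster$sample_id, roster$guide_id)
    unknown <- setdiff(unlist(groups), roster$sample_id)
    if (length(unknown))
        .stopValidation("group references unknown sample(s): ",
                        paste(unknown, collapse = ", "))

    profiles <- lapply(groups, function(ids)
        positivityProfile(afm[, ids], threshold = config@detectThreshold))
    efficiency <- do.call(rbind, lapply(names(groups), function(g) {
        sub <- roster[roster$sample_id %in% groups[[g]], ]
        data.frame(
            group = g, n = nrow(sub),
            detect_threshold = config@detectThreshold,
            pct_detect = summarizeEfficiency(sub,
                threshold = config@detectThreshold),
            het_threshold = config@hetThreshold,
            pct_het = summarizeEfficiency(sub,
                threshold = config@hetThreshold))
    }))
    shortlist <- roster[roster$category == "heterozygous_candidate" &
                            !roster$mosaic, , drop = FALSE]

    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeMatrixTsv(afm, file.path(dir, "matrix.tsv"))
        write.table(roster, file.path(dir, "roster.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(shortlist, file.path(dir, "shortlist.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        for (g in names(profiles)) {
            prof <- profiles[[g]]
            write.table(
                data.frame(position = names(prof),
                           positivity = sprintf("%.6f", prof)),
                file.path(dir, paste0("profile_", g, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
        }
    }
    new("CohortReport",
        roster = roster, shortlist = shortlist, profiles = profiles,
        efficiency = efficiency)
}
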