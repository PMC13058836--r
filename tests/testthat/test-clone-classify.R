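test_that("every fraction maps to exactly one category band", {
    cfg <- classifierConfig()
    f <- seq(0, 1, by = 0.001)
    bands <- categoryBand(f, cfg)
    expect_false(anyNA(bands))
    expect_setequal(unique(bands),
                    c("unedited", "low_fraction_edited",
                      "heterozygous_candidate", "potential_homozygous"))
    # inclusive boundaries
    expect_identical(categoryBand(0.02, cfg), "low_fraction_edited")
    expect_identical(categoryBand(0.30, cfg), "heterozygous_candidate")
    expect_identical(categoryBand(0.65, cfg), "potential_homozygous")
    expect_identical(categoryBand(0.0199, cfg), "unedited")
    # both published high-fraction clones land in the homozygous band
    expect_identical(categoryBand(c(0.68, 0.89), cfg),
                     rep("potential_homozygous", 2))
    expect_error(categoryBand(1.2, cfg), class = "abeDomainError")
    expect_error(classifierConfig(detectThreshold = 0.5,
                                  hetThreshold = 0.3))
})

test_that("clone classification applies the threshold rule table", {
    g <- guidesAuts2$H044
    depth <- 10000L
    # f = 0.50 with a 3% bystander at window position 4 (chr7:70768043)
    pu <- makePileup(refAuts2, depth, list(
        list(pos = 24L, alt = "G", frac = 0.50),
        list(pos = 23L, alt = "G", frac = 0.03)))
    cc <- classifyClone(pu, g)
    expect_identical(cc@category, "heterozygous_candidate")
    expect_equal(cc@targetEditFraction, 0.50)
    expect_equal(cc@bystanders$window_position, 4L)
    expect_equal(cc@bystanders$fraction, 0.03)
    expect_false(cc@mosaic)              # 0.03 < 0.05
    # the 3% bystander is still listed among subclonal alleles
    expect_true(any(cc@mosaicAlleles$genomic_position == 70768043L))

    # a 6% bystander crosses the mosaic-allele threshold
    ccm <- classifyClone(makePileup(refAuts2, depth, list(
        list(pos = 24L, alt = "G", frac = 0.50),
        list(pos = 23L, alt = "G", frac = 0.06))), g)
    expect_true(ccm@mosaic)

    # unintended alleles outside the window also flag mosaicism
    cco <- classifyClone(makePileup(refAuts2, depth, list(
        list(pos = 24L, alt = "G", frac = 0.50),
        list(pos = 100L, alt = "T", frac = 0.07))), g)
    expect_true(cco@mosaic)
    expect_equal(nrow(cco@bystanders), 0L)

    # clean homozygous-band clone, as in the published 89% example
    cch <- classifyClone(makePileup(refAuts2, depth, list(
        list(pos = 24L, alt = "G", frac = 0.89))), g)
    expect_identical(cch@category, "potential_homozygous")
    expect_false(cch@mosaic)

    # clean wild type
    ccw <- classifyClone(makePileup(refAuts2, depth), g)
    expect_identical(ccw@category, "unedited")
    expect_false(ccw@mosaic)
    expect_equal(nrow(ccw@mosaicAlleles), 0L)
})

test_that("zero depth at the target yields an explicit no-call", {
    pu <- makePileup(refAuts2, 100L)
    pu@counts[, 24L] <- 0L
    expect_error(classifyClone(pu, guidesAuts2$H044),
                 class = "abeNoCallError")
})

test_that("efficiency summaries reproduce half-up integer percentages", {
    expect_identical(summarizeEfficiency(37, 69), 54L)
    expect_identical(summarizeEfficiency(9, 69), 13L)
    expect_identical(summarizeEfficiency(15, 48), 31L)
    expect_identical(summarizeEfficiency(2, 48), 4L)
    expect_identical(summarizeEfficiency(0, 48), 0L)
    expect_identical(summarizeEfficiency(1, 200), 1L)   # 0.5 rounds up
    expect_error(summarizeEfficiency(1, 0), class = "abeDomainError")
    expect_error(summarizeEfficiency(5, 4), class = "abeDomainError")
})

test_that("efficiency is non-increasing in the threshold", {
    g <- guidesAuts2$H044
    set.seed(31)
    fracs <- c(0, 0, 0.01, 0.02, 0.05, 0.10, 0.30, 0.50, 0.68, 0.89)
    calls <- lapply(seq_along(fracs), function(i) {
        pu <- makePileup(refAuts2, 1000L,
            if (fracs[i] > 0) list(list(pos = 24L, alt = "G",
                                        frac = fracs[i])) else list(),
            sampleId = paste0("c", i))
        classifyClone(pu, g)
    })
    sweep <- vapply(seq(0, 1, by = 0.05), function(th)
        summarizeEfficiency(calls, threshold = th), integer(1))
    expect_true(all(diff(sweep) <= 0L))
    expect_identical(summarizeEfficiency(calls, threshold = 0.02), 70L)
    roster <- cloneRoster(calls)
    expect_identical(summarizeEfficiency(roster, threshold = 0.02), 70L)
})

test_that("positivity profiles summarise thresholded clone fractions", {
    cfg <- simConfig(depth = 200L, perBaseError = 0, seed = 32L)
    mk <- function(w, id) quantifySample(simulateClone(refAuts2,
        if (w > 0) list(haplotype("WT", weight = 1 - w),
                        haplotype("edit", 24L, "G", w))
        else list(haplotype("WT", weight = 1)), cfg, id = id), refAuts2)
    pus <- list(mk(0.5, "a"), mk(0.3, "b"), mk(0, "c"), mk(0, "d"))
    afm <- aggregateMatrix(pus)
    prof <- positivityProfile(afm, 0.02)
    expect_equal(unname(prof["chr7:70768044"]), 0.5)
    expect_true(all(prof >= 0 & prof <= 1))
    # a threshold no fraction can reach gives an all-zero profile
    expect_true(all(positivityProfile(afm, 1.01) == 0))
    # all-zero matrix gives an all-zero profile
    afm0 <- aggregateMatrix(pus[3:4])
    expect_true(all(positivityProfile(afm0, 0.02) == 0))
    # a single clone profiles as its own thresholded indicator vector
    afm1 <- aggregateMatrix(pus[1])
    f1 <- SummarizedExperiment::assay(afm1, "frequency")[, 1]
    expect_equal(unname(positivityProfile(afm1, 0.02)),
                 as.numeric(!is.na(f1) & f1 >= 0.02))
})

test_that("classification recovers ground-truth bands on simulated clones", {
    # noiseless clones across all bands: the measured fraction equals the
    # realized haplotype draw, so band agreement must be perfect
    g <- guidesAuts2$H044
    ccfg <- classifierConfig()
    set.seed(33)
    weights <- rep(c(0, 0.01, 0.02, 0.05, 0.15, 0.3, 0.5, 0.68, 0.89, 1),
                   each = 20)
    agree <- vapply(seq_along(weights), function(i) {
        w <- weights[i]
        haps <- if (w == 0) list(haplotype("WT", weight = 1))
                else if (w == 1) list(haplotype("edit", 24L, "G", 1))
                else list(haplotype("WT", weight = 1 - w),
                          haplotype("edit", 24L, "G", w))
        reads <- simulateClone(refAuts2, haps,
                               simConfig(depth = 400L, perBaseError = 0))
        cc <- classifyClone(quantifySample(reads, refAuts2), g, ccfg)
        rc <- reads@truth$realizedCounts
        trueFrac <- if ("edit" %in% names(rc)) rc[["edit"]] / 400 else 0
        cc@category == categoryBand(trueFrac, ccfg)
    }, logical(1))
    expect_equal(mean(agree), 1)
})
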