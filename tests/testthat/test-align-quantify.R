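test_that("adapter trimming matches the brute-force oracle", {
    adapter <- "AGATCGGAAGAGC"
    insert <- substr(refAuts2@sequence, 1, 40)

    full <- paste0(insert, adapter)
    expect_identical(trimAdapter(full, adapter), insert)    # exact suffix
    expect_identical(trimAdapter(insert, adapter), insert)  # no adapter

    # 12-nt adapter prefix at the 3' end with one mismatch
    ap <- substr(adapter, 1, 12)
    substr(ap, 6, 6) <- "T"
    withMism <- paste0(insert, ap)
    expect_identical(trimAdapter(withMism, adapter),
                     oracleTrim(withMism, adapter))
    expect_identical(trimAdapter(withMism, adapter), insert)

    # property sweep: random reads, random adapter placement/truncation
    set.seed(11)
    for (i in 1:50) {
        r <- randomSeq(sample(30:80, 1))
        if (i %% 2 == 0) {
            keep <- sample(3:nchar(adapter), 1)
            r <- paste0(substr(r, 1, sample(10:30, 1)),
                        substr(adapter, 1, keep))
        }
        expect_identical(trimAdapter(r, adapter), oracleTrim(r, adapter))
    }
    expect_error(trimAdapter("ACGT", ""), class = "abeDomainError")
})

test_that("error-free and substituted reads align at the true offset", {
    read <- substr(refAuts2@sequence, 51, 170)
    a <- alignToAmplicon(read, refAuts2)
    expect_true(a@mapped)
    expect_equal(a@offset, 50L)          # 0-based
    expect_equal(a@editDistance, 0L)

    twoSub <- read
    substr(twoSub, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, 30, 30))[1]
    substr(twoSub, 90, 90) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, 90, 90))[1]
    a2 <- alignToAmplicon(twoSub, refAuts2)
    expect_equal(a2@editDistance, 2L)
    expect_equal(a2@offset, 50L)
    expect_equal(a2@editDistance,
                 oracleSemiGlobalDistance(twoSub, refAuts2@sequence))

    expect_error(alignToAmplicon("ACGTACGT", refAuts2),
                 class = "abeDomainError")  # < 20 nt
})

test_that("random sequences are flagged unmapped, never dropped silently", {
    set.seed(12)
    for (i in 1:100) {
        a <- alignToAmplicon(randomSeq(150), refAuts2)
        expect_false(a@mapped)
        expect_gt(a@editDistance, 30L)  # 0.2 * 150
    }
})

test_that("banded aligner equals the full dynamic-programming oracle", {
    # reads <= 60 nt carved from the amplicon with up to 6 mixed edits
    set.seed(13)
    for (i in 1:80) {
        len <- sample(25:60, 1)
        off <- sample(1:(363 - len), 1)
        nEdits <- sample(0:6, 1)
        read <- mutateSeq(substr(refAuts2@sequence, off, off + len - 1L),
                          nEdits)
        a <- alignToAmplicon(read, refAuts2)
        expect_equal(a@editDistance,
                     oracleSemiGlobalDistance(read, refAuts2@sequence),
                     info = sprintf("case %d: off=%d len=%d edits=%d",
                                    i, off, len, nEdits))
    }
})

test_that("fragment reconciliation counts overlaps once and masks conflicts", {
    n <- ampliconLength(refAuts2)
    r1 <- substr(refAuts2@sequence, 1, 60)
    r2seq <- substr(refAuts2@sequence, 31, 90)   # overlap 31-60

    a1 <- alignToAmplicon(r1, refAuts2)
    a2 <- alignToAmplicon(r2seq, refAuts2)
    fp <- buildFragmentPileup(a1, a2, refLength = n)
    expect_equal(sum(!is.na(fp$calls)), 90L)     # union, single call each
    expect_true(all(is.na(fp$calls[91:n])))

    # disagreeing overlap base: masked, contributes no call
    conflict <- r2seq
    substr(conflict, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                        substr(r2seq, 15, 15))[1]  # pos 45
    a2c <- alignToAmplicon(conflict, refAuts2)
    fpc <- buildFragmentPileup(a1, a2c, refLength = n)
    expect_true(is.na(fpc$calls[45]))
    expect_equal(sum(!is.na(fpc$calls)), 89L)

    # low-quality bases are discarded before reconciliation
    qual <- strrep("I", 60)                       # Q40
    substr(qual, 10, 10) <- "#"                   # Q2 at read pos 10
    fpq <- buildFragmentPileup(a1, NULL, refLength = n, q1 = qual,
                               qualityFloor = 20L)
    expect_true(is.na(fpq$calls[10]))
    expect_equal(sum(!is.na(fpq$calls)), 59L)

    # non-overlapping mates: plain union
    far <- alignToAmplicon(substr(refAuts2@sequence, 201, 260), refAuts2)
    fpu <- buildFragmentPileup(a1, far, refLength = n)
    expect_equal(which(!is.na(fpu$calls)), c(1:60, 201:260))
})

test_that("bulk quantifier agrees with per-fragment reconciliation", {
    reads <- simulateClone(refAuts2,
        list(haplotype("WT", weight = 0.5),
             haplotype("edit", 24L, "G", 0.5)),
        simConfig(depth = 40L, perBaseError = 0.01, seed = 21L))
    pu <- quantifySample(reads, refAuts2, qualityFloor = 20L)
    n <- ampliconLength(refAuts2)
    manual <- matrix(0L, 5L, n)
    rownames(manual) <- c("A", "C", "G", "T", "del")
    strReverse <- function(s) vapply(s, function(x)
        paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
        "", USE.NAMES = FALSE)
    for (f in seq_len(40L)) {
        a1 <- alignToAmplicon(reads@r1[f], refAuts2)
        a2 <- alignToAmplicon(revcompStr(reads@r2[f]), refAuts2)
        fp <- buildFragmentPileup(a1, a2, refLength = n,
                                  q1 = reads@q1[f],
                                  q2 = strReverse(reads@q2[f]),
                                  qualityFloor = 20L)
        hit <- which(!is.na(fp$calls))
        for (p in hit)
            manual[fp$calls[p], p] <- manual[fp$calls[p], p] + 1L
    }
    expect_equal(unname(pileupCounts(pu)[1:5, ]), unname(manual))
})

test_that("pileup counts conserve depth at every position", {
    reads <- simulateClone(refAuts2,
        list(haplotype("WT", weight = 0.7),
             haplotype("edit", 24L, "G", 0.3)),
        simConfig(depth = 300L, perBaseError = 0.005, seed = 22L))
    # splice an insertion and a deletion into a few reads
    reads@r1[1] <- paste0(substr(reads@r1[1], 1, 50), "A",
                          substr(reads@r1[1], 51, 149))
    reads@r1[2] <- paste0(substr(reads@r1[2], 1, 50),
                          substr(reads@r1[2], 52, 150))
    pu <- quantifySample(reads, refAuts2)
    counts <- pileupCounts(pu)
    expect_true(all(colSums(counts[1:5, ]) == pileupDepth(pu)))
    expect_gte(sum(counts["ins", ]), 1L)
    expect_gte(sum(counts["del", ]), 1L)
})

test_that("quantification recovers per-position fractions exactly at zero noise", {
    cfg <- simConfig(depth = 500L, perBaseError = 0, seed = 23L)
    wt <- quantifySample(simulateClone(refAuts2,
        list(haplotype("WT", weight = 1)), cfg), refAuts2)
    nr <- nonRefFraction(wt)
    covered <- pileupDepth(wt) > 0
    expect_true(all(nr[covered] == 0))
    expect_true(all(is.na(nr[!covered])))
    # read geometry: R1 spans 1-150, R2 spans 214-363, gap in between
    expect_true(all(pileupDepth(wt)[c(1:150, 214:363)] == 500))
    expect_true(all(pileupDepth(wt)[151:213] == 0))

    mix <- simulateClone(refAuts2,
        list(haplotype("WT", weight = 0.7), haplotype("edit", 24L, "G", 0.3)),
        cfg)
    pu <- quantifySample(mix, refAuts2)
    expect_equal(altFraction(pu, 70768044L, "G"),
                 mix@truth$realizedCounts[["edit"]] / 500)
})

test_that("unmappable samples raise an explicit empty-sample error", {
    set.seed(24)
    junk <- new("CloneReads", id = "junk",
                r1 = vapply(1:5, function(i) randomSeq(150), ""),
                r2 = vapply(1:5, function(i) randomSeq(150), ""),
                q1 = rep(strrep("I", 150), 5),
                q2 = rep(strrep("I", 150), 5),
                hap = rep("", 5), truth = list(),
                config = simConfig(depth = 5L))
    expect_error(quantifySample(junk, refAuts2),
                 class = "abeValidationError")
})

test_that("minus-strand guide descriptions yield the same genomic matrix", {
    # the H068 edit simulated as its plus-strand substitution (T>C at
    # chr7:70768068) must be seen identically through the minus-strand guide
    cfg <- simConfig(depth = 400L, perBaseError = 0, seed = 25L)
    reads <- simulateClone(refAuts2,
        list(haplotype("WT", weight = 0.6),
             haplotype("edit68", 48L, "C", 0.4)), cfg)
    pu <- quantifySample(reads, refAuts2)
    g68 <- guidesAuts2$H068
    expect_equal(targetGenomicPosition(g68), 70768068L)
    expect_identical(targetAltBase(g68), "C")
    expect_equal(altFraction(pu, targetGenomicPosition(g68),
                             targetAltBase(g68)),
                 reads@truth$realizedCounts[["edit68"]] / 400)
    expect_equal(unname(nonRefFraction(pu)[48]),
                 reads@truth$realizedCounts[["edit68"]] / 400)
})

test_that("matrices aggregate with explicit missingness and round-trip", {
    cfg <- simConfig(depth = 100L, perBaseError = 0, seed = 26L)
    p1 <- quantifySample(simulateClone(refAuts2,
        list(haplotype("WT", weight = 1)), cfg, id = "s1"), refAuts2)
    p2 <- quantifySample(simulateClone(refAuts2,
        list(haplotype("WT", weight = 0.5),
             haplotype("edit", 24L, "G", 0.5)), cfg, id = "s2"), refAuts2)
    afm <- aggregateMatrix(list(p1, p2))
    expect_s4_class(afm, "AlleleFrequencyMatrix")
    expect_identical(colnames(afm), c("s1", "s2"))
    f <- SummarizedExperiment::assay(afm, "frequency")
    expect_equal(unname(f[, "s1"]), unname(nonRefFraction(p1)))
    # zero-depth gap is NA, not zero
    expect_true(all(is.na(f[151:213, ])))
    expect_true(all(f[1:150, "s1"] == 0))

    expect_error(aggregateMatrix(list()), class = "abeValidationError")
    otherRef <- ampliconReference("o", "chr1", 1L, refAuts2@sequence)
    p3 <- makePileup(otherRef, 10L)
    expect_error(aggregateMatrix(list(p1, p3)),
                 class = "abeValidationError")

    tmp <- withr::local_tempdir()
    mt <- file.path(tmp, "matrix.tsv")
    writeMatrixTsv(afm, mt)
    back <- readMatrixTsv(mt)
    expect_identical(dim(back), c(2L, 363L))
    # fixed 6-decimal formatting: a second write cycle is byte-identical
    afm2 <- afm
    SummarizedExperiment::assay(afm2, "frequency") <-
        matrix(t(back), ncol = 2, dimnames = list(NULL, c("s1", "s2")))
    mt2 <- file.path(tmp, "matrix2.tsv")
    writeMatrixTsv(afm2, mt2)
    expect_identical(readLines(mt), readLines(mt2))

    pt <- file.path(tmp, "pileup.tsv")
    writePileupTsv(p2, pt)
    tab <- read.delim(pt)
    expect_equal(nrow(tab), 363L)
    expect_equal(tab$depth, unname(as.integer(pileupDepth(p2))))
})
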