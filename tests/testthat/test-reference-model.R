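test_that("protospacer positions map to the printed genomic anchors", {
    g44 <- guidesAuts2$H044
    g68 <- guidesAuts2$H068
    expect_equal(GenomicRanges::start(mapProtospacerPosition(g44, 5L)),
                 70768044L)
    expect_equal(GenomicRanges::start(mapProtospacerPosition(g44, 4L)),
                 70768043L)
    expect_equal(GenomicRanges::start(mapProtospacerPosition(g44, 1L)),
                 70768040L)
    expect_equal(GenomicRanges::start(mapProtospacerPosition(g68, 5L)),
                 70768068L)
    expect_error(mapProtospacerPosition(g44, 0L), class = "abeDomainError")
    expect_error(mapProtospacerPosition(g44, 21L), class = "abeDomainError")
})

test_that("coordinate mapping round-trips on both strands", {
    for (g in guidesAuts2) {
        gpos <- GenomicRanges::start(mapProtospacerPosition(g, 1:20))
        expect_identical(protospacerPositionAt(g, gpos), 1:20)
    }
    expect_error(protospacerPositionAt(guidesAuts2$H044, 70768039L),
                 class = "abeDomainError")
})

test_that("guides match the reference on both strands", {
    expect_true(checkGuideAgainstReference(guidesAuts2$H044, refAuts2))
    expect_true(checkGuideAgainstReference(guidesAuts2$H068, refAuts2))
    # minus-strand invariant: protospacer == revcomp of the covered slice
    g68 <- guidesAuts2$H068
    gpos <- sort(GenomicRanges::start(mapProtospacerPosition(g68, 1:20)))
    slice <- paste(refBaseAt(refAuts2, gpos), collapse = "")
    expect_identical(revcompStr(slice), g68@protospacer)
    # property: guides built from random references always validate
    set.seed(101)
    for (rep in 1:10) {
        seq <- randomSeq(60)
        ref <- ampliconReference("r", "chrT", 500L, seq)
        off <- sample(1:40, 1)
        plusSlice <- substr(seq, off, off + 19L)
        minusProto <- revcompStr(plusSlice)
        kA <- regexpr("A", minusProto)[1]
        if (kA < 1) next
        g <- guideDesign("m", minusProto, "-", 500L + off + 18L,
                         window = c(1L, 20L), targetPosition = kA)
        expect_true(checkGuideAgainstReference(g, ref))
    }
})

test_that("editable window positions are exactly the window adenines", {
    expect_identical(editablePositions(guidesAuts2$H044), c(4L, 5L))
    expect_identical(editablePositions(guidesAuts2$H068), 5L)
    expect_identical(editablePositions(guidesAuts2$H044, c(1L, 20L)),
                     which(strsplit(guidesAuts2$H044@protospacer,
                                    "")[[1]] == "A"))
    expect_error(editablePositions(guidesAuts2$H044, c(7L, 4L)),
                 class = "abeDomainError")
})

test_that("adenine run length measures the cluster containing the target", {
    expect_equal(adenineRunLength(guidesAuts2$H044, 5L), 4L)  # positions 2-5
    expect_equal(adenineRunLength(guidesAuts2$H068, 5L), 1L)
    polyA <- guideDesign("polyA", strrep("A", 20), "+", 100L,
                         targetPosition = 1L)
    expect_equal(adenineRunLength(polyA, 1L), 20L)
    expect_error(adenineRunLength(guidesAuts2$H044, 6L),
                 class = "abeDomainError")  # G at position 6
})

test_that("guide validity enforces an adenine at the target position", {
    expect_error(guideDesign("bad", "CCCCCGTTGACCCATTCTAC", "+", 1L,
                             targetPosition = 5L),
                 "must be 'A'")
    expect_error(guideDesign("bad", "CAAAAGTTGACCCATTCTAC", "+", 1L,
                             window = c(0L, 7L), targetPosition = 5L))
})

test_that("codon classification reproduces both designed synonymous edits", {
    ce1 <- classifyCodonEdit(refAuts2, 70768044L, "G")
    expect_identical(ce1@codonBefore, "AAA")
    expect_identical(ce1@codonAfter, "AAG")
    expect_identical(ce1@aaBefore, "K")  # Lys
    expect_true(ce1@synonymous)

    ce2 <- classifyCodonEdit(refAuts2, 70768068L, "C")
    expect_identical(ce2@codonBefore, "AGT")
    expect_identical(ce2@codonAfter, "AGC")
    expect_identical(ce2@aaBefore, "S")  # Ser
    expect_true(ce2@synonymous)

    # identity substitution: codon unchanged, trivially synonymous
    refBase <- refBaseAt(refAuts2, 70768044L)
    ce3 <- classifyCodonEdit(refAuts2, 70768044L, refBase)
    expect_identical(ce3@codonBefore, ce3@codonAfter)
    expect_true(ce3@synonymous)

    expect_error(classifyCodonEdit(refAuts2, 70769000L, "G"),
                 class = "abeDomainError")
    noFrame <- ampliconReference("nf", "chr1", 1L, "ACGTACGT")
    expect_error(classifyCodonEdit(noFrame, 2L, "G"),
                 class = "abeDomainError")
})

test_that("codon logic agrees with a translation oracle over all codons", {
    # amplicon carrying all 64 codons in frame; classify one substitution in
    # each codon and compare with Biostrings translation of the mutated codon
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    ref <- ampliconReference("codons", "chrT", 1L,
                             paste(codons, collapse = ""),
                             frameOffset = 0L, codingStrand = "+")
    set.seed(7)
    for (ci in seq_along(codons)) {
        pos <- (ci - 1L) * 3L + sample(1:3, 1)
        cur <- substr(ref@sequence, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        ce <- classifyCodonEdit(ref, pos, alt)
        mutated <- ce@codonAfter
        aaOracle <- as.character(Biostrings::translate(
            Biostrings::DNAString(mutated), no.init.codon = TRUE))
        aaRefOracle <- as.character(Biostrings::translate(
            Biostrings::DNAString(ce@codonBefore), no.init.codon = TRUE))
        expect_identical(ce@aaAfter, aaOracle)
        expect_identical(ce@aaBefore, aaRefOracle)
        expect_identical(ce@synonymous, aaOracle == aaRefOracle)
    }
    # every third-position A>G in a Lys codon (AAA) is synonymous (AAG=Lys)
    aaaStarts <- (which(codons == "AAA") - 1L) * 3L + 1L
    ce <- classifyCodonEdit(ref, aaaStarts + 2L, "G")
    expect_true(ce@synonymous)
})

test_that("minus-strand coding frames are handled", {
    # coding strand minus: plus sequence is revcomp of codons TTT (Phe), AAA
    ref <- ampliconReference("m", "chrT", 1L,
                             revcompStr("TTTAAA"), frameOffset = 0L,
                             codingStrand = "-")
    # plus-strand pos 6 is the complement of coding pos 1 (T of TTT)
    ce <- classifyCodonEdit(ref, 6L, "G")   # coding T>C: TTT>CTT, F>L
    expect_identical(ce@codonBefore, "TTT")
    expect_identical(ce@codonAfter, "CTT")
    expect_false(ce@synonymous)
})

test_that("reference and guide files round-trip", {
    tmp <- withr::local_tempdir()
    fa <- file.path(tmp, "amp.fa")
    js <- file.path(tmp, "amp.json")
    writeAmpliconReference(refAuts2, fa, js)
    back <- readAmpliconReference(fa, js)
    expect_identical(back@sequence, refAuts2@sequence)
    expect_identical(back@genomicStart, refAuts2@genomicStart)
    expect_identical(back@frameOffset, refAuts2@frameOffset)
    expect_identical(back@codingStrand, refAuts2@codingStrand)

    gtsv <- file.path(tmp, "guides.tsv")
    df <- data.frame(
        guide_id = c("H044", "H068"),
        protospacer = c("CAAAAGTTGACCCATTCTAC", "TCACACTGTGCCGGTAGAAT"),
        strand = c("+", "-"), anchor = c(70768040L, 70768072L),
        window_start = 4L, window_end = 7L, target_position = 5L)
    write.table(df, gtsv, sep = "\t", quote = FALSE, row.names = FALSE)
    guides <- readGuides(gtsv)
    expect_identical(guides$H044@protospacer, guidesAuts2$H044@protospacer)
    expect_identical(guides$H068@anchor, guidesAuts2$H068@anchor)
})
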