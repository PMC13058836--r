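# Shared fixtures and independent oracles for the test suite. The oracles
# here deliberately avoid the package's aligner/trimmer code paths: plain-R
# dynamic programming and brute-force scans.

refAuts2 <- auts2Amplicon()
guidesAuts2 <- auts2Guides()
sitesAuts2 <- auts2PhasingSites()

revcompStr <- function(x) {
    chartr("ACGT", "TGCA", vapply(x, function(s)
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
        character(1), USE.NAMES = FALSE))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# full (unbanded) semi-global edit distance: read end-to-end, reference
# with free end gaps; unit mismatch/gap costs. Row-sequential DP in R.
oracleSemiGlobalDistance <- function(read, ref) {
    m <- nchar(read)
    n <- nchar(ref)
    rv <- utf8ToInt(read)
    fv <- utf8ToInt(ref)
    prev <- rep(0L, n + 1L)
    for (i in seq_len(m)) {
        cur <- integer(n + 1L)
        cur[1L] <- i
        M <- pmin(prev[1:n] + as.integer(rv[i] != fv),
                  prev[2:(n + 1L)] + 1L)
        for (j in seq_len(n)) {
            cur[j + 1L] <- min(M[j], cur[j] + 1L)
        }
        prev <- cur
    }
    min(prev)
}

# brute-force 3' adapter trim: scan every start, keep the lowest mismatch
# rate among candidates with >= minLen matched columns and <= maxMismFrac
oracleTrim <- function(read, adapter, maxMismFrac = 0.1, minLen = 3L) {
    len <- nchar(read)
    alen <- nchar(adapter)
    rch <- strsplit(read, "", fixed = TRUE)[[1]]
    ach <- strsplit(adapter, "", fixed = TRUE)[[1]]
    best <- 0L
    bestRate <- 2
    for (s in seq_len(len)) {
        L <- min(alen, len - s + 1L)
        if (L < minLen) break
        mm <- sum(rch[s:(s + L - 1L)] != ach[seq_len(L)])
        if (mm <= floor(maxMismFrac * L) && mm / L < bestRate) {
            bestRate <- mm / L
            best <- s
        }
    }
    if (best == 0L) read else substr(read, 1L, best - 1L)
}

# apply k random substitution/insertion/deletion edits to a sequence
mutateSeq <- function(s, nEdits) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (e in seq_len(nEdits)) {
        op <- sample(c("sub", "ins", "del"), 1L,
                     prob = c(0.6, 0.2, 0.2))
        p <- sample(length(ch), 1L)
        if (op == "sub") {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        } else if (op == "ins") {
            ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = p)
        } else if (length(ch) > 25L) {
            ch <- ch[-p]
        }
    }
    paste(ch, collapse = "")
}

# recount the target-alt fraction straight from emitted reads (R1 covers
# the amplicon prefix), independent of the aligner
tagRecountAltFraction <- function(reads, ampliconPos, alt) {
    stopifnot(ampliconPos <= reads@config@readLength)
    mean(substr(reads@r1, ampliconPos, ampliconPos) == alt)
}

# minimal hand-built pileup: given per-position fractions of a single alt
# base over a reference, at fixed depth
makePileup <- function(ref, depth, altFracs = list(), sampleId = "manual") {
    n <- ampliconLength(ref)
    counts <- matrix(0L, 6L, n,
                     dimnames = list(c("A", "C", "G", "T", "del", "ins"),
                                     NULL))
    refBases <- strsplit(ref@sequence, "", fixed = TRUE)[[1]]
    counts[cbind(match(refBases, rownames(counts)), seq_len(n))] <- depth
    for (af in altFracs) {   # af: list(pos = amplicon pos, alt, frac)
        k <- as.integer(round(af$frac * depth))
        counts[af$alt, af$pos] <- counts[af$alt, af$pos] + k
        counts[refBases[af$pos], af$pos] <-
            counts[refBases[af$pos], af$pos] - k
    }
    colnames(counts) <- as.character(ref@genomicStart + seq_len(n) - 1L)
    new("Pileup", counts = counts, ref = ref, sampleId = sampleId,
        nFragments = depth, nMappedFragments = depth,
        nUnmappedReads = 0L)
}
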