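#' @include reference-model.R
NULL

#' Read and write a reference amplicon (FASTA + JSON sidecar)
#'
#' The amplicon sequence travels as a single-record FASTA file; the genomic
#' anchor and optional coding frame travel in a JSON sidecar with fields
#' `contig`, `genomic_start` and optionally
#' `coding_frame: {frame_offset, coding_strand}`.
#'
#' @param fasta path to a single-record FASTA file.
#' @param json path to the JSON sidecar.
#' @return `readAmpliconReference()`: an
#'   [AmpliconReference][AmpliconReference-class].
#' @export
readAmpliconReference <- function(fasta, json) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) != 1L)
        .stopValidation("expected a single FASTA record, found ",
                        length(seqs))
    meta <- jsonlite::read_json(json, simplifyVector = TRUE)
    cf <- meta$coding_frame
    ampliconReference(
        name = names(seqs)[1], contig = meta$contig,
        genomicStart = meta$genomic_start,
        sequence = as.character(seqs[[1]]),
        frameOffset = if (is.null(cf)) NA_integer_ else cf$frame_offset,
        codingStrand = if (is.null(cf)) NA_character_ else cf$coding_strand)
}

#' @rdname readAmpliconReference
#' @param ref an [AmpliconReference][AmpliconReference-class].
#' @export
writeAmpliconReference <- function(ref, fasta, json) {
    dna <- Biostrings::DNAStringSet(ref@sequence)
    names(dna) <- ref@name
    Biostrings::writeXStringSet(dna, fasta)
    meta <- list(contig = ref@contig, genomic_start = ref@genomicStart)
    if (!is.na(ref@frameOffset))
        meta$coding_frame <- list(frame_offset = ref@frameOffset,
                                  coding_strand = ref@codingStrand)
    jsonlite::write_json(meta, json, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(fasta, json))
}

#' Read guide designs from TSV or JSON
#'
#' TSV columns (or JSON array object fields): `guide_id`, `protospacer`,
#' `strand`, `anchor`, `window_start`, `window_end`, `target_position`.
#'
#' @param path file path; format chosen by extension (`.json` vs tabular).
#' @return Named list of [GuideDesign][GuideDesign-class] objects.
#' @export
readGuides <- function(path) {
    df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    } else {
        read.delim(path, stringsAsFactors = FALSE)
    }
    need <- c("guide_id", "protospacer", "strand", "anchor",
              "window_start", "window_end", "target_position")
    if (!all(need %in% names(df)))
        .stopValidation("guide table must have columns: ",
                        paste(need, collapse = ", "))
    guides <- lapply(seq_len(nrow(df)), function(i) {
        guideDesign(df$guide_id[i], df$protospacer[i], df$strand[i],
                    df$anchor[i],
                    window = c(df$window_start[i], df$window_end[i]),
                    targetPosition = df$target_position[i])
    })
    names(guides) <- df$guide_id
    guides
}

## ---------------------------------------------------------------------------
## FASTQ (4-line records; plain or gzip by extension). The writer places the
## simulation ground-truth haplotype label in the header comment field.

.readFastq <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) %% 4L != 0L)
        .stopValidation("truncated FASTQ: ", path)
    idx <- seq(1L, length(lines), by = 4L)
    header <- sub("^@", "", lines[idx])
    list(id = sub("[ \t].*$", "", header),
         comment = ifelse(grepl("[ \t]", header),
                          sub("^[^ \t]+[ \t]+", "", header), ""),
         seq = toupper(lines[idx + 1L]),
         qual = lines[idx + 3L])
}

.writeFastq <- function(path, id, seq, qual, comment = NULL) {
    header <- if (is.null(comment)) paste0("@", id)
              else paste0("@", id, " ", comment)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(rbind(header, seq, "+", qual), con)
    invisible(path)
}

#' Write / read a simulated clone as a FASTQ pair
#'
#' `writeFastqPair()` emits Illumina-style paired FASTQ (gzip when the
#' paths end in `.gz`), carrying each fragment's ground-truth haplotype
#' label in the header comment field (`hap:<label>`). `readFastqPair()`
#' reads any paired FASTQ back into a [CloneReads][CloneReads-class];
#' ground-truth labels are recovered when present, otherwise empty.
#'
#' @param reads a [CloneReads][CloneReads-class].
#' @param r1Path,r2Path output/input paths for the two mates.
#' @param id sample identifier for `readFastqPair()`.
#' @return `writeFastqPair()`: the two paths, invisibly;
#'   `readFastqPair()`: a [CloneReads][CloneReads-class].
#' @export
writeFastqPair <- function(reads, r1Path, r2Path) {
    n <- length(reads@r1)
    ids <- sprintf("%s:%06d", reads@id, seq_len(n))
    comment <- paste0("hap:", reads@hap)
    .writeFastq(r1Path, ids, reads@r1, reads@q1, paste0("1 ", comment))
    .writeFastq(r2Path, ids, reads@r2, reads@q2, paste0("2 ", comment))
    invisible(c(r1Path, r2Path))
}

#' @rdname writeFastqPair
#' @export
readFastqPair <- function(r1Path, r2Path, id = "sample") {
    a <- .readFastq(r1Path)
    b <- .readFastq(r2Path)
    if (length(a$seq) != length(b$seq))
        .stopValidation("R1/R2 record counts differ")
    if (length(a$id) && !all(a$id == b$id))
        .stopValidation("R1/R2 read names differ")
    hap <- sub("^.*hap:", "", a$comment)
    hap[!grepl("hap:", a$comment)] <- ""
    new("CloneReads",
        id = id, r1 = a$seq, r2 = b$seq, q1 = a$qual, q2 = b$qual,
        hap = hap, truth = list(), config = simConfig(depth = max(
            1L, length(a$seq))))
}

#' Read cost-model parameters from JSON
#'
#' JSON fields: `sanger_per_sample`, `ngs_per_sample`, `ngs_fixed`,
#' `primer_unit_cost`. The package ships an illustrative synthetic set in
#' `system.file("extdata", "cost_params_synthetic.json",
#' package = "abeGenotyper")`.
#'
#' @param path JSON file path.
#' @return A [CostParams][CostParams-class].
#' @export
readCostParams <- function(path) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    costParams(p$sanger_per_sample, p$ngs_per_sample, p$ngs_fixed,
               p$primer_unit_cost)
}
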