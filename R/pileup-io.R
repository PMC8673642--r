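#' Phred quality to error probability
#'
#' @param Q Phred-scaled quality (> 0); vectorized.
#' @return the per-base error probability \code{10^(-Q/10)}. Q20 is a 1\%
#'   error rate; the Q ~ 20.5 typical of current long-read basecalls is
#'   about 0.9\%, while early chemistries at Q 6.9-9.4 ran at 20.5-11.5\%.
#' @export
#' @examples
#' phredErrorRate(c(10, 20, 30))
phredErrorRate <- function(Q) {
    if (any(Q <= 0)) stop("Phred quality must be > 0", call. = FALSE)
    10^(-Q / 10)
}

# Decode one mpileup read-bases string into ref/alt/other counts.
# Handles '^q' read-start (skip quality char), '$' read-end, '+n<seq>' /
# '-n<seq>' indels (skip n bases), '*' deletion placeholders and '<'/'>'
# reference skips (all stripped), '.'/',' as reference observations and
# explicit bases matched case-insensitively against the locus alleles.
decodeReadBases <- function(bases, refAllele, altAllele) {
    chars <- strsplit(bases, "", fixed = TRUE)[[1]]
    nref <- 0L; nalt <- 0L; noth <- 0L
    i <- 1L; n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (ch == "^") {
            i <- i + 2L            # caret plus mapping-quality char
        } else if (ch == "$" || ch == "*" || ch == "<" || ch == ">") {
            i <- i + 1L
        } else if (ch == "+" || ch == "-") {
            j <- i + 1L
            while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
            len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
            i <- j + len
        } else if (ch == "." || ch == ",") {
            nref <- nref + 1L; i <- i + 1L
        } else {
            b <- toupper(ch)
            if (b == toupper(altAllele)) nalt <- nalt + 1L
            else if (b == toupper(refAllele)) nref <- nref + 1L
            else noth <- noth + 1L
            i <- i + 1L
        }
    }
    c(ref = nref, alt = nalt, other = noth)
}

#' Read a samtools mpileup text stream into allele counts
#'
#' Consumes the 6-column mpileup text format (chrom, pos, ref, depth,
#' read bases, base qualities) and tallies, at each target locus, reads
#' supporting the locus reference allele, its alternate allele, and any
#' other base. Loci absent from the stream get zero counts. Pileup lines
#' whose reference base disagrees with the locus table are still counted
#' but collected in the \code{"flagged"} attribute. The base-quality
#' column is not used.
#'
#' @param file path to (or connection for) an mpileup text file; all
#'   lines are assumed to belong to one sample.
#' @param loci target locus table (see \linkS4class{HaplotypePanel}).
#' @param sampleId column name for the resulting single-sample object.
#' @return an \linkS4class{AlleleCounts} with one column.
#' @export
readMpileup <- function(file, loci, sampleId = "sample1") {
    loci <- lociAsDataFrame(loci)
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    m <- nrow(loci)
    ref <- alt <- oth <- matrix(0L, nrow = m, ncol = 1L,
                                dimnames = list(loci$locus_id, sampleId))
    key <- paste(loci$chrom, loci$pos)
    flagged <- character()
    for (ln in seq_along(lines)) {
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
        if (length(f) < 6L)
            stop("malformed mpileup line ", ln, ": expected 6 columns, got ",
                 length(f), call. = FALSE)
        idx <- match(paste(f[1], as.integer(f[2])), key)
        if (is.na(idx)) next
        if (toupper(f[3]) != toupper(loci$ref[idx]))
            flagged <- c(flagged, paste0(f[1], ":", f[2],
                                         " pileup ref ", f[3],
                                         " != locus ref ", loci$ref[idx]))
        cnt <- decodeReadBases(f[5], loci$ref[idx], loci$alt[idx])
        ref[idx, 1L] <- ref[idx, 1L] + cnt[["ref"]]
        alt[idx, 1L] <- alt[idx, 1L] + cnt[["alt"]]
        oth[idx, 1L] <- oth[idx, 1L] + cnt[["other"]]
    }
    out <- AlleleCounts(ref, alt, oth, loci)
    attr(out, "flagged") <- flagged
    out
}

#' Thin allele counts to a lower target coverage
#'
#' Binomially subsamples every read: each unit of each count is retained
#' independently with probability \code{targetCoverage / fullCoverage}.
#' Under uniform coverage this is distributionally equivalent to
#' subsampling the underlying reads before pileup.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param fullCoverage coverage (x) the counts were generated at.
#' @param targetCoverage desired coverage; must satisfy
#'   \code{0 < target <= full}.
#' @param seed RNG seed for this operation.
#' @return a thinned \linkS4class{AlleleCounts}; identical to the input
#'   when \code{target == full}.
#' @export
thinCounts <- function(counts, fullCoverage, targetCoverage, seed) {
    validObject(counts)
    if (targetCoverage <= 0 || targetCoverage > fullCoverage)
        stop("need 0 < targetCoverage <= fullCoverage", call. = FALSE)
    if (targetCoverage == fullCoverage) return(counts)
    pKeep <- targetCoverage / fullCoverage
    withSeed(substreamSeed(seed, 5L), {
        thin1 <- function(x) {
            out <- matrix(stats::rbinom(length(x), as.vector(x), pKeep),
                          nrow = nrow(x), dimnames = dimnames(x))
            out
        }
        AlleleCounts(thin1(assay(counts, "ref")),
                     thin1(assay(counts, "alt")),
                     thin1(assay(counts, "other")),
                     rowData(counts))
    })
}

#' Summarize per-sample sequencing run statistics
#'
#' Takes a per-sample table of run metrics (average read length,
#' flow-cell yield, mean base quality, ...) and returns per-sample
#' effective-read percentages together with column means across samples.
#' The effective-read percentage is \code{(1 - (MQ0 + unmapped) / total)
#' * 100} — reads mapped with nonzero mapping quality as a share of all
#' raw reads; it is computed from \code{mq0_reads}, \code{unmapped_reads}
#' and \code{total_reads} columns when present, otherwise an
#' \code{effective_pct} column is taken as given.
#'
#' @param records a data.frame, one row per sample; numeric columns are
#'   averaged.
#' @return list with \code{perSample} (the table plus
#'   \code{effective_pct}) and \code{means} (named numeric vector of
#'   column means).
#' @export
#' @examples
#' summarizeRun(data.frame(sample_id = "s1", read_length = 1500,
#'                         mq0_reads = 5, unmapped_reads = 5,
#'                         total_reads = 100))$perSample$effective_pct
summarizeRun <- function(records) {
    if (!is.data.frame(records) || nrow(records) < 1L)
        stop("need at least one per-sample record", call. = FALSE)
    if (all(c("mq0_reads", "unmapped_reads", "total_reads")
            %in% colnames(records))) {
        if (any(records$total_reads == 0))
            stop("effective-read percentage undefined for total_reads == 0",
                 call. = FALSE)
        records$effective_pct <-
            (1 - (records$mq0_reads + records$unmapped_reads) /
                 records$total_reads) * 100
    } else if (!"effective_pct" %in% colnames(records)) {
        stop("records need either mq0/unmapped/total read counts or an ",
             "effective_pct column", call. = FALSE)
    }
    num <- vapply(records, is.numeric, logical(1))
    list(perSample = records,
         means = colMeans(records[, num, drop = FALSE]))
}

#' Read and write the allele-count TSV interchange format
#'
#' Long format with columns \code{sample_id}, \code{chrom}, \code{pos},
#' \code{ref_count}, \code{alt_count}, \code{other_count}. Writing then
#' reading round-trips exactly.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param file path to read from / write to.
#' @param loci locus table to attach when reading.
#' @return \code{readAlleleCountsTsv} returns an
#'   \linkS4class{AlleleCounts}; \code{writeAlleleCountsTsv} the file
#'   path, invisibly.
#' @name alleleCountsTsv
NULL

#' @rdname alleleCountsTsv
#' @export
writeAlleleCountsTsv <- function(counts, file) {
    loci <- rowData(counts)
    long <- data.frame(
        sample_id = rep(colnames(counts), each = nrow(counts)),
        chrom = rep(loci$chrom, ncol(counts)),
        pos = rep(loci$pos, ncol(counts)),
        ref_count = as.vector(assay(counts, "ref")),
        alt_count = as.vector(assay(counts, "alt")),
        other_count = as.vector(assay(counts, "other")))
    utils::write.table(long, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname alleleCountsTsv
#' @export
readAlleleCountsTsv <- function(file, loci) {
    loci <- lociAsDataFrame(loci)
    long <- utils::read.delim(file, stringsAsFactors = FALSE)
    samples <- unique(long$sample_id)
    key <- paste(loci$chrom, loci$pos)
    idx <- match(paste(long$chrom, long$pos), key)
    if (anyNA(idx))
        stop("allele-count TSV contains loci absent from the locus list",
             call. = FALSE)
    if (anyDuplicated(cbind(long$sample_id, idx)))
        stop("duplicate (sample, locus) records in allele-count TSV",
             call. = FALSE)
    m <- nrow(loci)
    mk <- function(col) {
        x <- matrix(0L, nrow = m, ncol = length(samples),
                    dimnames = list(loci$locus_id, samples))
        x[cbind(idx, match(long$sample_id, samples))] <- long[[col]]
        x
    }
    AlleleCounts(mk("ref_count"), mk("alt_count"), mk("other_count"), loci)
}

#' Read and write locus list TSVs
#'
#' Columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{alt_freq}, \code{locus_id}.
#'
#' @param loci locus table; \code{file} a path.
#' @return \code{readLociTsv} a \linkS4class{DataFrame};
#'   \code{writeLociTsv} the path, invisibly.
#' @name lociTsv
NULL

#' @rdname lociTsv
#' @export
writeLociTsv <- function(loci, file) {
    utils::write.table(as.data.frame(loci), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname lociTsv
#' @export
readLociTsv <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
    out <- lociAsDataFrame(df)
    msg <- validLoci(out)
    if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
    out
}
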