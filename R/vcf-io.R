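#' Write a haplotype panel as a phased VCF
#'
#' Haplotypes are paired in column order into diploid phased GT entries
#' (\code{h1|h2}); an odd trailing haplotype is dropped with a warning.
#' The panel alternate-allele frequency is written as an INFO AF field.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePanelVcf <- function(panel, file) {
    validObject(panel)
    H <- ncol(panel@alleles)
    if (H %% 2L == 1L) {
        warning("odd haplotype count; dropping the last haplotype")
        H <- H - 1L
    }
    i1 <- seq(1L, H, by = 2L)
    loci <- panel@loci
    gt <- matrix(paste0(panel@alleles[, i1, drop = FALSE], "|",
                        panel@alleles[, i1 + 1L, drop = FALSE]),
                 nrow = nrow(loci))
    sampleIds <- sprintf("panel%03d", seq_along(i1))
    writeVcfBody(loci, gt, sampleIds, file,
                 info = sprintf("AF=%.6g", loci$alt_freq),
                 phased = TRUE)
}

#' Write genotype calls as VCF
#'
#' Hard calls become GT entries (\code{0/0}, \code{0/1}, \code{1/1});
#' missing cells \code{./.}. A DS FORMAT field always carries the dosage
#' so continuous (allele-frequency or tie-averaged) values survive the
#' round trip; continuous cells get GT \code{./.}.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeGenotypeVcf <- function(calls, file) {
    validObject(calls)
    g <- assay(calls, "dosage")
    gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    hard <- !is.na(g) & g %% 1 == 0
    gt[hard] <- c("0/0", "0/1", "1/1")[g[hard] + 1L]
    ds <- ifelse(is.na(g), ".", format(g, trim = TRUE, digits = 6))
    writeVcfBody(rowData(calls), matrix(paste0(gt, ":", ds), nrow = nrow(g)),
                 colnames(g), file, format = "GT:DS")
}

writeVcfBody <- function(loci, gt, sampleIds, file, info = ".",
                         format = "GT", phased = FALSE) {
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=skimGEBV",
        "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds), collapse = "\t"))
    body <- paste(loci$chrom, loci$pos, loci$locus_id, loci$ref,
                  loci$alt, ".", "PASS", info, format,
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), file)
    invisible(file)
}

#' Read genotypes from a VCF into a GenotypeCalls object
#'
#' Uses \pkg{vcfR} to parse the file; GT fields are converted to
#' alternate-allele dosages (\code{./.} to missing), with a DS field
#' preferred when present. Records are matched to \code{loci} by
#' (chrom, pos); loci absent from the file are missing.
#'
#' @param file VCF path (plain or gzipped).
#' @param loci target locus table.
#' @return a \linkS4class{GenotypeCalls}.
#' @export
readGenotypeVcf <- function(file, loci) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package", call. = FALSE)
    loci <- lociAsDataFrame(loci)
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    idx <- match(paste(loci$chrom, loci$pos),
                 paste(fix[, "CHROM"], as.integer(fix[, "POS"])))
    gtChar <- vcfR::extract.gt(v, element = "GT")
    dsChar <- tryCatch(vcfR::extract.gt(v, element = "DS"),
                       error = function(e) NULL)
    toDosage <- function(x) {
        alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
        vapply(alleles, function(a) {
            if (!length(a) || anyNA(a) || any(a == ".")) NA_real_
            else sum(as.numeric(a))
        }, numeric(1))
    }
    d <- apply(gtChar, 2L, toDosage)
    d <- matrix(d, nrow = nrow(gtChar), dimnames = dimnames(gtChar))
    if (!is.null(dsChar)) {
        dsNum <- suppressWarnings(
            matrix(as.numeric(dsChar), nrow = nrow(dsChar),
                   dimnames = dimnames(dsChar)))
        d[!is.na(dsNum)] <- dsNum[!is.na(dsNum)]
    }
    m <- nrow(loci)
    out <- matrix(NA_real_, nrow = m, ncol = ncol(d),
                  dimnames = list(loci$locus_id, colnames(d)))
    ok <- !is.na(idx)
    out[ok, ] <- d[idx[ok], , drop = FALSE]
    src <- matrix(ifelse(is.na(out), "missing", "called"),
                  nrow = m, dimnames = dimnames(out))
    # continuous dosages read back from DS are fills, not hard calls
    cont <- !is.na(out) & out %% 1 != 0
    src[cont] <- "filled-af"
    newGenotypeCalls(out, src, loci)
}

#' Read a phased panel VCF into a HaplotypePanel
#'
#' Phased GT entries (\code{a|b}) are split into two haplotypes per
#' sample. Loci are taken from the VCF records themselves; the
#' alternate-allele frequency is recomputed from the panel.
#'
#' @param file VCF path.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
readPanelVcf <- function(file) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package", call. = FALSE)
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gtChar <- vcfR::extract.gt(v, element = "GT")
    if (!all(grepl("|", gtChar, fixed = TRUE)))
        stop("panel VCF must contain phased (|) genotypes", call. = FALSE)
    split1 <- function(k) {
        vapply(strsplit(gtChar[, k], "|", fixed = TRUE),
               function(a) as.integer(a), integer(2))
    }
    hapList <- lapply(seq_len(ncol(gtChar)), split1)   # each 2 x m
    alleles <- do.call(cbind, lapply(hapList, t))
    colnames(alleles) <- sprintf("hap%03d", seq_len(ncol(alleles)))
    loci <- S4Vectors::DataFrame(
        chrom = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]),
        ref = fix[, "REF"],
        alt = fix[, "ALT"],
        alt_freq = rowMeans(alleles),
        locus_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                          paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                          fix[, "ID"]))
    new("HaplotypePanel", alleles = alleles, loci = loci)
}

#' Write unphased true/called genotypes as VCF
#'
#' Convenience wrapper around [writeGenotypeVcf()] kept for symmetry
#' with [writePanelVcf()].
#'
#' @param truth a \linkS4class{TrueGenotypes} (or any
#'   \linkS4class{GenotypeCalls}).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeTruthVcf <- function(truth, file) writeGenotypeVcf(truth, file)
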