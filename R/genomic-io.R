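#' Read peaks from a BED6 file
#'
#' Parses a 6-column BED file of predicted binding regions into a `GRanges`.
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual 1-based closed convention internally, so `start(gr) == bedStart + 1`
#' and `end(gr) == bedEnd`.
#'
#' @param path path to a tab-separated BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand).  Lines starting with
#'   `#`, `track` or `browser` are skipped.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] (e.g. from
#'   [readChromSizes()]); when supplied, peaks are validated against
#'   chromosome bounds and unknown chromosomes are an error.
#'
#' @return A [GenomicRanges::GRanges] with metadata columns `name` and
#'   `score`, in file order.  Strand characters other than `+`/`-` are
#'   normalized to `*` (unstranded).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t40\tp1\t0\t+", bed)
#' readPeaks(bed)
#' @export
readPeaks <- function(path, seqinfo = NULL) {
    if (!file.exists(path)) stop("peak file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("no peak records in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 6L)
    if (length(bad))
        stop(sprintf("line %d of %s: expected >= 6 tab-separated columns, got %d",
                     lineno[bad[1L]], path, lengths(fields)[bad[1L]]))
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    badc <- which(is.na(start) | is.na(end))
    if (length(badc))
        stop(sprintf("line %d of %s: non-integer coordinates", lineno[badc[1L]], path))
    badr <- which(start >= end | start < 0L)
    if (length(badr))
        stop(sprintf("line %d of %s: invalid interval [%d, %d)",
                     lineno[badr[1L]], path, start[badr[1L]], end[badr[1L]]))
    strand <- vapply(fields, `[[`, "", 6L)
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start + 1L, end = end),
        strand = strand,
        name = vapply(fields, `[[`, "", 4L),
        score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))))
    if (!is.null(seqinfo)) {
        unknown <- setdiff(unique(chrom), GenomeInfoDb::seqnames(seqinfo))
        if (length(unknown))
            stop("chromosome(s) absent from sizes table: ",
                 paste(unknown, collapse = ", "))
        over <- GenomicRanges::end(gr) >
            GenomeInfoDb::seqlengths(seqinfo)[as.character(GenomeInfoDb::seqnames(gr))]
        if (any(over))
            stop("peak(s) extend beyond chromosome end: ",
                 paste(gr$name[over], collapse = ", "))
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
        GenomeInfoDb::seqinfo(gr) <- seqinfo
    }
    gr
}

#' Read a chromosome-sizes table
#'
#' Reads a two-column whitespace-separated table (UCSC `chrom.sizes` layout:
#' chromosome name, length in nucleotides) into a
#' [GenomeInfoDb::Seqinfo] object.
#'
#' @param path path to the sizes file.
#' @return A `Seqinfo` with one entry per chromosome.
#' @examples
#' f <- tempfile()
#' writeLines("chrS\t100000", f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
    if (!file.exists(path)) stop("chromosome sizes file not found: ", path)
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("chrom", "size"),
                             colClasses = c("character", "numeric"))
    if (anyDuplicated(tab$chrom))
        stop("duplicate chromosome in sizes table: ",
             tab$chrom[duplicated(tab$chrom)][1L])
    if (any(is.na(tab$size)) || any(tab$size <= 0))
        stop("chromosome lengths must be positive integers")
    GenomeInfoDb::Seqinfo(seqnames = tab$chrom, seqlengths = as.integer(tab$size))
}

#' Per-nucleotide read coverage over peaks
#'
#' Computes the depth of aligned reads at every position of every peak,
#' the per-peak coverage profile on which both the CV evaluation and the
#' shape classification operate.  Reads may come from an indexed BAM file
#' (spliced alignments contribute only their aligned blocks) or from a
#' `GRanges`/BED of read intervals.
#'
#' @param reads a path to a BAM file (a `.bai` index is created if missing),
#'   a path to a BED file of read intervals, or a `GRanges` of read intervals.
#' @param peaks `GRanges` of peaks; minus-strand profiles are reported
#'   5'->3', i.e. reversed with respect to genomic order.
#' @param strandMode `"same"` counts only reads on the peak's strand
#'   (unstranded peaks count all reads); `"ignore"` counts reads on both
#'   strands.  CLIP libraries are strand-specific, hence the default.
#'
#' @return A list with one numeric vector of depths per peak (named by peak
#'   name), each of length `width(peak)`.  Peaks on chromosomes absent from
#'   the reads source get an all-zero profile with a warning.
#' @examples
#' reads <- GenomicRanges::GRanges("chrS", IRanges::IRanges(11, 20), strand = "+")
#' peak  <- GenomicRanges::GRanges("chrS", IRanges::IRanges(13, 18), strand = "+",
#'                                 name = "p1")
#' computeCoverage(reads, peak)
#' @export
computeCoverage <- function(reads, peaks, strandMode = c("same", "ignore")) {
    strandMode <- match.arg(strandMode)
    blocks <- .readBlocks(reads)
    covByStrand <- list()
    strandsNeeded <- if (strandMode == "ignore") "*" else
        unique(as.character(GenomicRanges::strand(peaks)))
    for (s in strandsNeeded) {
        sel <- if (s %in% c("+", "-"))
            blocks[as.character(GenomicRanges::strand(blocks)) == s]
        else blocks
        covByStrand[[s]] <- GenomicRanges::coverage(sel)
    }
    missing_warned <- character()
    profs <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
        pk <- peaks[i]
        chr <- as.character(GenomeInfoDb::seqnames(pk))
        s <- if (strandMode == "ignore") "*" else as.character(GenomicRanges::strand(pk))
        cov <- covByStrand[[s]]
        if (!chr %in% names(cov)) {
            if (!chr %in% missing_warned) {
                warning("chromosome ", chr,
                        " absent from reads source; zero coverage reported")
                missing_warned <- c(missing_warned, chr)
            }
            d <- numeric(GenomicRanges::width(pk))
        } else {
            rle <- cov[[chr]]
            lo <- GenomicRanges::start(pk); hi <- GenomicRanges::end(pk)
            d <- numeric(GenomicRanges::width(pk))
            inb <- seq(max(lo, 1L), min(hi, length(rle)))
            if (length(inb) && inb[1L] <= inb[length(inb)])
                d[inb - lo + 1L] <- as.numeric(rle[inb])
        }
        if (as.character(GenomicRanges::strand(pk)) == "-") d <- rev(d)
        profs[[i]] <- d
    }
    names(profs) <- if (!is.null(peaks$name)) make.unique(as.character(peaks$name))
                    else sprintf("peak_%d", seq_along(peaks))
    profs
}

# Read intervals/alignment blocks from BAM, BED or GRanges, as a GRanges
# with strand. BAM alignments are split into exonic blocks (CIGAR N).
.readBlocks <- function(reads) {
    if (methods::is(reads, "GRanges")) return(reads)
    if (!is.character(reads) || length(reads) != 1L)
        stop("reads must be a GRanges or a path to a BAM/BED file")
    if (!file.exists(reads)) stop("reads file not found: ", reads)
    if (grepl("\\.bam$", reads, ignore.case = TRUE)) {
        if (!file.exists(paste0(reads, ".bai")) &&
            !file.exists(sub("\\.bam$", ".bai", reads, ignore.case = TRUE)))
            Rsamtools::indexBam(reads)
        aln <- GenomicAlignments::readGAlignments(reads)
        unlist(GenomicAlignments::grglist(aln), use.names = FALSE)
    } else {
        readPeaks(reads)  # BED6 read intervals share the peak parser
    }
}

#' Assemble the final per-peak result table
#'
#' Collects the processed peak coordinates, original coordinates, CV scores,
#' specificity labels and shape clusters of a fully processed
#' [PeakShapeExperiment] into one data frame, sorted by CV from highest
#' (most specific) to lowest.  Ties keep input order (stable sort).
#'
#' @param x a `PeakShapeExperiment` after [evaluatePeaks()] (and optionally
#'   [classifyShapes()]).
#' @return A `data.frame` with columns chrom, start, end (0-based half-open,
#'   BED convention), name, score, strand, original coordinates, `cv`,
#'   `cv_normalized`, `specificity` (0 specific / 1 unspecific),
#'   `penalty_factor`, and when available `cluster` and `sharp`.
#' @export
resultTable <- function(x) {
    stopifnot(methods::is(x, "PeakShapeExperiment"))
    cv <- peakCV(x)
    if (is.null(cv)) stop("run evaluatePeaks() before building the result table")
    rr <- SummarizedExperiment::rowRanges(x)
    rd <- SummarizedExperiment::rowData(x)
    tab <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        start = GenomicRanges::start(rr) - 1L,
        end = GenomicRanges::end(rr),
        name = names(rr),
        score = if (!is.null(rr$score)) rr$score else 0,
        strand = as.character(GenomicRanges::strand(rr)),
        stringsAsFactors = FALSE)
    tab$strand[tab$strand == "*"] <- "."
    for (col in c("origChrom", "origStart", "origEnd"))
        if (col %in% colnames(rd)) tab[[sub("orig", "orig_", tolower(col))]] <- rd[[col]]
    tab$cv <- cv
    tab$cv_normalized <- normalizedCV(x)
    tab$specificity <- specificityLabel(x)
    if ("penaltyFactor" %in% colnames(rd)) tab$penalty_factor <- rd$penaltyFactor
    if (!is.null(shapeCluster(x))) {
        tab$cluster <- shapeCluster(x)
        tab$sharp <- as.integer(sharpPeaks(x))
    }
    ord <- order(-tab$cv)       # radix sort: stable, ties keep input order
    tab[ord, , drop = FALSE]
}

#' Write the CV-sorted result table
#'
#' Writes [resultTable()] as a tab-separated file with a header line,
#' one row per peak, sorted by CV descending.
#'
#' @param x a processed [PeakShapeExperiment].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeResultTable <- function(x, path) {
    tab <- resultTable(x)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
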