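test_that("BED6 peaks map to GRanges fields and preserve order", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t40\tp1\t0\t+",
                 "chr2\t5\t25\tp2\t3.5\t-",
                 "chr1\t100\t150\tp3\t0\t?"), bed)
    gr <- readPeaks(bed)
    expect_length(gr, 3L)
    expect_equal(as.character(GenomeInfoDb::seqnames(gr)), c("chr1", "chr2", "chr1"))
    expect_equal(GenomicRanges::start(gr), c(11L, 6L, 101L))  # 1-based internal
    expect_equal(GenomicRanges::end(gr), c(40L, 25L, 150L))
    expect_equal(gr$name, c("p1", "p2", "p3"))
    expect_equal(gr$score, c(0, 3.5, 0))
    # invalid strand normalized to unstranded
    expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-", "*"))
})

test_that("malformed BED lines raise errors naming the line", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t40\tp1\t0\t+", "chr1\t40\t10\tp2\t0\t+"), bed)
    expect_error(readPeaks(bed), "line 2.*invalid interval")
    writeLines(c("chr1\t10\t40\tp1\t0"), bed)
    expect_error(readPeaks(bed), "line 1.*6 tab-separated")
    writeLines(c("chr1\tten\t40\tp1\t0\t+"), bed)
    expect_error(readPeaks(bed), "line 1.*non-integer")
})

test_that("a generated 899-peak BED yields 899 intervals in file order", {
    bed <- tempfile(fileext = ".bed")
    n <- 899L
    writeLines(sprintf("chr1\t%d\t%d\tpk%d\t0\t+",
                       (1:n) * 100L, (1:n) * 100L + 30L, 1:n), bed)
    gr <- readPeaks(bed)
    expect_length(gr, n)
    expect_equal(gr$name, sprintf("pk%d", 1:n))
})

test_that("chrom sizes parse, reject duplicates and non-positive lengths", {
    f <- tempfile()
    writeLines("chrT\t1000", f)
    si <- readChromSizes(f)
    expect_equal(unname(GenomeInfoDb::seqlengths(si)["chrT"]), 1000L)
    writeLines(c("chrT\t1000", "chrT\t500"), f)
    expect_error(readChromSizes(f), "duplicate")
    writeLines("chrT\t0", f)
    expect_error(readChromSizes(f), "positive")
    writeLines(sprintf("chr%d\t%d", 1:25, 1000 + 1:25), f)
    expect_equal(length(GenomeInfoDb::seqlengths(readChromSizes(f))), 25L)
})

test_that("peaks are validated against chromosome bounds when sizes attached", {
    bed <- tempfile(fileext = ".bed")
    sizes <- tempfile()
    writeLines("chrT\t100", sizes)
    si <- readChromSizes(sizes)
    writeLines("chrT\t10\t120\tp1\t0\t+", bed)
    expect_error(readPeaks(bed, seqinfo = si), "beyond chromosome end")
    writeLines("chrX\t10\t20\tp1\t0\t+", bed)
    expect_error(readPeaks(bed, seqinfo = si), "absent from sizes")
})

test_that("coverage matches hand-worked examples", {
    # one read fully covering the peak
    r <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 20), strand = "+")
    pk <- GenomicRanges::GRanges("chrT", IRanges::IRanges(13, 18), strand = "+",
                                 name = "p")
    expect_equal(computeCoverage(r, pk)[[1]], rep(1, 6))
    # two overlapping reads: depths from the brute-force counter
    r2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 11), c(15, 30)),
                                 strand = "+")
    pk2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(9, 16), strand = "+",
                                  name = "p")
    expect_equal(computeCoverage(r2, pk2)[[1]], c(1, 1, 2, 2, 2, 2, 2, 1))
    # opposite-strand read is excluded in same-strand mode, counted otherwise
    rm <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 20), strand = "-")
    expect_equal(computeCoverage(rm, pk, strandMode = "same")[[1]], rep(0, 6))
    expect_equal(computeCoverage(rm, pk, strandMode = "ignore")[[1]], rep(1, 6))
})

test_that("coverage equals the brute-force counter on random fixtures", {
    for (seed in 1:25) {
        fx <- randomReadFixture(seed)
        for (mode in c("same", "ignore")) {
            got <- computeCoverage(fx$reads, fx$peaks, strandMode = mode)
            for (i in seq_along(fx$peaks)) {
                expect_equal(got[[i]],
                             bruteCoverage(fx$reads, fx$peaks[i], mode),
                             info = sprintf("seed %d mode %s peak %d",
                                            seed, mode, i))
            }
        }
    }
})

test_that("total depth over a peak equals the summed read overlap", {
    fx <- randomReadFixture(99)
    got <- computeCoverage(fx$reads, fx$peaks, strandMode = "ignore")
    for (i in seq_along(fx$peaks)) {
        ov <- sum(IRanges::width(IRanges::pintersect(
            IRanges::findOverlapPairs(GenomicRanges::ranges(fx$reads),
                                      GenomicRanges::ranges(fx$peaks[i])))))
        expect_equal(sum(got[[i]]), ov)
    }
})

test_that("minus-strand profiles are reported 5'->3'", {
    r <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10, 12), strand = "-")
    pk <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10, 15), strand = "-",
                                 name = "p")
    # genomic depths (1,1,1,0,0,0) reversed onto the transcript orientation
    expect_equal(computeCoverage(r, pk)[[1]], c(0, 0, 0, 1, 1, 1))
})

test_that("peaks on chromosomes absent from the reads give zero with warning", {
    r <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 10), strand = "+")
    pk <- GenomicRanges::GRanges("chrB", IRanges::IRanges(1, 5), strand = "+",
                                 name = "p")
    expect_warning(cov <- computeCoverage(r, pk), "absent from reads")
    expect_equal(cov[[1]], rep(0, 5))
})

test_that("result table is CV-sorted with stable ties and round-trips", {
    cov <- rbind(c(5, 5, 5, 5),      # cv 0
                 c(0, 9, 0, 0),      # high cv
                 c(2, 6, 2, 2),      # middle
                 c(2, 6, 2, 2))      # tie with row 3
    pse <- evaluatePeaks(pseFromMatrix(cov))
    tab <- resultTable(pse)
    expect_equal(tab$name, c("p2", "p3", "p4", "p1"))  # ties keep input order
    out <- tempfile(fileext = ".tsv")
    writeResultTable(pse, out)
    back <- utils::read.delim(out)
    expect_equal(nrow(back), 4L)
    expect_equal(back$cv, sort(back$cv, decreasing = TRUE))
    # BED round trip of the processed coordinates
    bed <- tempfile(fileext = ".bed")
    utils::write.table(back[, c("chrom", "start", "end", "name", "score", "strand")],
                       bed, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    gr2 <- readPeaks(bed)
    expect_equal(GenomicRanges::start(gr2), back$start + 1L)
    expect_equal(GenomicRanges::end(gr2), back$end)
})

test_that("result table scales to a large peak set", {
    set.seed(42)
    cov <- matrix(rpois(899 * 20, 5), nrow = 899)
    tab <- resultTable(evaluatePeaks(pseFromMatrix(cov)))
    expect_equal(nrow(tab), 899L)
})

test_that("BAM and BED read sources give identical coverage", {
    prof <- c(1, 3, 5, 3, 1)
    reads <- profileToReads(prof, readLength = 2, chrom = "chrS", offset = 50)
    si <- GenomeInfoDb::Seqinfo("chrS", 500L)
    bam <- writeReadsBam(reads, tempfile(fileext = ".bam"), si)
    bed <- writeReadsBed(reads, tempfile(fileext = ".bed"))
    pk <- GenomicRanges::GRanges("chrS", IRanges::IRanges(51, 55), strand = "+",
                                 name = "p")
    expect_equal(computeCoverage(bam, pk)[[1]], prof)
    expect_equal(computeCoverage(bed, pk)[[1]], prof)
})
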