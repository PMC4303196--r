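## gene-by-bin matrix with a consistent window/bin pairing
mkBinding2 <- function(signal) {
    ng <- nrow(signal); nb <- ncol(signal)
    rownames(signal) <- sprintf("g%02d", seq_len(ng))
    tss <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1e5 * seq_len(ng), width = 1),
                                  strand = "+", gene_id = rownames(signal))
    BindingWindowMatrix(signal, tss, windowHalfWidth = 50 * nb, binSize = 100)
}

test_that("binding weight profile and gene scores match hand computation", {
    b <- mkBinding2(matrix(c(8, 0, 0, 2, 1, 1), 3, 2, byrow = TRUE))
    tt <- tipGeneScores(b)
    ## weights = colMeans normalized: (3, 1)/4 = (0.75, 0.25)
    expect_equal(tt$score, c(6.0, 0.5, 1.0))
    expect_identical(order(-tt$score), c(1L, 3L, 2L))
    expect_true(all(tt$p >= 0 & tt$p <= 1))
    expect_true(all(tt$q >= tt$p))

    ## equal scores -> sd 0 -> error
    b2 <- mkBinding2(matrix(c(4, 0, 0, 4, 2, 2), 3, 2, byrow = TRUE))
    expect_error(tipGeneScores(b2), "zero standard deviation")

    ## an all-zero gene gets the lowest score, exactly 0
    b3 <- mkBinding2(matrix(c(0, 0, 2, 1, 3, 4), 3, 2, byrow = TRUE))
    t3 <- tipGeneScores(b3)
    expect_equal(t3$score[1], 0)
    expect_true(t3$score[1] == min(t3$score))

    b4 <- mkBinding2(matrix(0, 3, 2))
    expect_error(tipGeneScores(b4), "zero total signal")
})

test_that("scores are invariant to positive rescaling of the signal", {
    set.seed(21)
    sig <- matrix(rpois(40 * 6, 4), 40, 6)
    a <- tipGeneScores(mkBinding2(sig))
    b <- tipGeneScores(mkBinding2(sig * 7.5))
    expect_equal(b$z, a$z)
    expect_equal(b$p, a$p)
    expect_equal(b$q, a$q)
})

test_that("FDR target calling follows Benjamini-Hochberg", {
    p <- c(0.001, 0.004, 0.03, 0.8)
    tab <- S4Vectors::DataFrame(gene_id = paste0("g", 1:4),
                                score = 4:1, z = 4:1, p = p,
                                q = p.adjust(p, "BH"))
    expect_equal(tab$q, c(0.004, 0.008, 0.04, 0.8))
    called <- callTargets(tab, fdr = 0.01)
    expect_identical(geneIds(called), c("g1", "g2"))
    ## the default threshold is 1% FDR
    expect_identical(geneIds(callTargets(tab)), c("g1", "g2"))
    ## raw-p thresholding flag
    expect_identical(geneIds(callTargets(tab, 0.05, useRawP = TRUE)),
                     c("g1", "g2", "g3"))

    flat <- S4Vectors::DataFrame(gene_id = paste0("g", 1:4), score = 1:4,
                                 z = 1:4, p = rep(1, 4), q = rep(1, 4))
    expect_warning(empty <- callTargets(flat, 0.01), "empty")
    expect_length(geneIds(empty), 0L)

    expect_error(callTargets(flat[0, ], 0.01), "empty score table")
})

test_that("BH q-values are monotone in p after sorting", {
    set.seed(7)
    for (i in 1:20) {
        b <- mkBinding2(matrix(rpois(50 * 4, 3) + 1, 50, 4))
        q <- tipGeneScores(b)$q
        pp <- tipGeneScores(b)$p
        expect_true(all(diff(q[order(pp)]) >= -1e-15))
    }
})

test_that("consensus intersection preserves sources, sorts genes", {
    s1 <- TargetSignature("hela", c("C", "A", "B"))
    s2 <- TargetSignature("k562", c("B", "C", "A"))
    s3 <- TargetSignature("gm", c("A", "C", "B"))
    cons <- intersectSignatures(list(s1, s2, s3))
    expect_identical(geneIds(cons), c("A", "B", "C"))
    expect_identical(names(signatureSources(cons)), c("hela", "k562", "gm"))

    d1 <- TargetSignature("a", c("X", "Y"))
    d2 <- TargetSignature("b", c("Z"))
    expect_warning(e <- intersectSignatures(list(d1, d2)), "empty")
    expect_length(geneIds(e), 0L)

    expect_error(intersectSignatures(list(s1)), "at least 2")
})

test_that("bedGraph binning recovers bin averages and flips minus strands", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t999\t1200\tgeneA\t0\t+",
                 "chr1\t4000\t5000\tgeneB\t0\t-"), bed)
    tss <- readTssAnnotation(bed, "bed")
    expect_equal(BiocGenerics::start(tss), c(1000L, 5000L))

    bg <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(c("chr1\t700\t1300\t3", "chr1\t4800\t5000\t2"), bg)
    b <- bindingWindowMatrix(tss, bg, windowHalfWidth = 200, binSize = 100)
    expect_equal(dim(b@signal), c(2L, 4L))
    ## gene A fully covered at score 3
    expect_equal(unname(b@signal["geneA", ]), rep(3, 4))
    ## gene B: left-shoulder coverage, flipped to the right after orienting
    expect_equal(unname(b@signal["geneB", ]), c(0, 0.02, 2, 1.98))

    neg <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines("chr1\t700\t1300\t-1", neg)
    expect_error(bindingWindowMatrix(tss, neg, 200, 100), "non-negative")
})

test_that("planted binding targets are recovered at the FDR threshold", {
    sim <- genBindingData(nGenes = 500, nTargets = 25, signalStrength = 3,
                          seed = 31)
    called <- geneIds(callTargets(tipGeneScores(sim$binding), 0.01))
    truth <- names(which(sim$truth$targetFlag))
    expect_gte(mean(truth %in% called), 0.9)
    expect_lte(mean(!(called %in% truth)), 0.05)

    ## exact null: calls consistent with the FDR level
    null <- genBindingData(nGenes = 500, nTargets = 50, signalStrength = 0,
                           seed = 32)
    suppressWarnings(
        ncalled <- length(geneIds(callTargets(tipGeneScores(null$binding),
                                              0.01))))
    expect_lte(ncalled, 3L)
})
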