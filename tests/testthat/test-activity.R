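test_that("iRAS matches hand-enumerated differential-CDF values", {
    x <- c(g1 = 5, g2 = 4, g3 = 1, g4 = 0)
    expect_equal(computeIras(x, TargetSignature("s", c("g1", "g2"))), 1)
    expect_equal(computeIras(-x, TargetSignature("s", c("g1", "g2"))), -1)
    ## interleaved targets: d = (0.5, 0, 0.5, 0), first max at rank 1
    expect_equal(computeIras(x, TargetSignature("s", c("g1", "g3"))), 0.5)

    expect_error(computeIras(x, TargetSignature("tiny", "g1")), "tiny")
    expect_error(computeIras(c(x, g5 = 2),
                             TargetSignature("big", names(x)[1:4])),
                 "non-target")

    ## all-equal expression: only the lexicographic tie rule defines ranking
    eq <- setNames(rep(1, 4), names(x))
    expect_error(computeIras(eq, TargetSignature("s", c("g1", "g2"))),
                 "forceTies")
    forced <- computeIras(eq, TargetSignature("s", c("g1", "g2")),
                          forceTies = TRUE)
    lex <- setNames(c(4, 3, 2, 1), names(x))   # same order as the tie rule
    expect_equal(forced, computeIras(lex, TargetSignature("s", c("g1", "g2"))))
})

test_that("iRAS is rank-invariant and antisymmetric", {
    set.seed(101)
    for (i in 1:50) {
        N <- sample(20:120, 1)
        x <- setNames(rnorm(N), sprintf("g%03d", seq_len(N)))
        sig <- TargetSignature("s", sample(names(x), sample(3:10, 1)))
        base <- computeIras(x, sig)
        expect_identical(computeIras(exp(x), sig), base)
        expect_identical(computeIras(2 * x + 3, sig), base)
        expect_identical(computeIras(x^3, sig), base)
        neg <- computeIras(-x, sig)
        expect_equal(abs(neg), abs(base))
        ## the sign flips exactly unless the two CDF-difference extremes tie
        ## in magnitude, where the first-index tie rule decides instead
        ext <- dExtremes(x, sig)
        if (abs(ext[1] + ext[2]) > 1e-12)
            expect_equal(neg, -base)
    }
})

test_that("absolute iRAS equals the classical two-sample KS D statistic", {
    set.seed(5)
    for (i in 1:300) {
        N <- sample(10:200, 1)
        m <- sample(3:(N - 3), 1)
        x <- setNames(runif(N), sprintf("g%03d", seq_len(N)))
        tg <- sample(names(x), m)
        ir <- computeIras(x, TargetSignature("t", tg))
        D <- unname(suppressWarnings(
            ks.test(x[tg], x[setdiff(names(x), tg)])$statistic))
        expect_equal(abs(ir), D, tolerance = 1e-12)
    }
})

test_that("compiled statistic agrees bitwise with the reference formula", {
    set.seed(17)
    for (i in 1:200) {
        N <- sample(8:150, 1)
        m <- sample(2:(N - 2), 1)
        pos <- sort(sample.int(N, m))
        ind <- logical(N); ind[pos] <- TRUE
        expect_identical(regact:::cpp_signed_ks(pos, N),
                         regact:::.iras_from_indicator(ind))
    }
})

test_that("matrix scoring separates extreme samples and is deterministic", {
    genes <- sprintf("g%02d", 1:20)
    vA <- setNames(seq(20, 1), genes)      # targets on top
    vB <- setNames(seq(1, 20), genes)      # targets at the bottom
    m <- mkExpr(cbind(A = vA, B = vB))
    sig <- TargetSignature("s", genes[1:5])
    res <- computeIrasMatrix(m, sig, nPerm = 200, seed = 3)
    expect_equal(unname(iras(res)), c(1, -1))
    expect_identical(as.character(activityGroups(res)),
                     c("positive", "negative"))
    expect_true(all(activityTable(res)$p_emp <= 1 &
                    activityTable(res)$p_emp > 0))

    res2 <- computeIrasMatrix(m, sig, nPerm = 200, seed = 3)
    expect_identical(activityTable(res), activityTable(res2))

    expect_error(computeIrasMatrix(m, TargetSignature("none", c("zz1", "zz2")),
                                   nPerm = 10),
                 "< 2 genes")
    m1 <- mkExpr(exprValues(m), "one_channel_log")
    expect_error(computeIrasMatrix(m1, sig, nPerm = 10), "medianCenter")
})

test_that("shared and per-sample permutation nulls give the same scores", {
    sim <- genCohort(simConfig(nGenes = 300, nSamples = 12,
                               signatureSize = 30, seed = 8))
    a <- computeIrasMatrix(sim$expr, sim$signature, nPerm = 300, seed = 1)
    b <- computeIrasMatrix(sim$expr, sim$signature, nPerm = 300, seed = 1,
                           shareNull = TRUE)
    expect_identical(iras(a), iras(b))
    expect_true(all(abs(activityTable(a)$z - activityTable(b)$z) < 1))
})

test_that("empirical p uses the add-one estimator and never reaches 0", {
    x <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
    ## no random 100-gene set separates perfectly, so zero exceedances
    ps <- permutationSignificance(x, 100, observed = 1, nPerm = 9999, seed = 2)
    expect_equal(ps$p_emp, 1 / 10000)
    ps2 <- permutationSignificance(x, 100, observed = 0, nPerm = 99, seed = 2)
    expect_equal(ps2$p_emp, 1)   # everything exceeds |0|
})

test_that("dichotomization sends zero scores to the negative group", {
    g <- dichotomize(c(a = 0.3, b = -0.2, c = 0))
    expect_identical(as.character(g), c("positive", "negative", "negative"))
    expect_identical(levels(g), c("negative", "positive"))
    ## a single-group outcome must break downstream two-group tests
    allpos <- dichotomize(c(a = 0.5, b = 0.1))
    expect_error(kmLogrank(c(5, 10), c(1, 1), allpos), "zero subjects")
})

test_that("scores track planted activity in simulated cohorts", {
    sim <- genCohort(simConfig(nGenes = 2000, nSamples = 200,
                               signatureSize = 100, effectBeta = 1,
                               noiseSd = 1, seed = 77))
    sc <- vapply(sampleIds(sim$expr), function(s)
        computeIras(exprValues(sim$expr)[, s], sim$signature), numeric(1))
    expect_gt(cor(sc, sim$truth$activity), 0.9)
    expect_gte(mean(sign(sc) == sign(sim$truth$activity)), 0.95)
})

test_that("permutation z-scores are standard normal under the null", {
    set.seed(303)
    N <- 500; m <- 50
    x <- setNames(rnorm(N), sprintf("g%04d", 1:N))
    z <- numeric(1000); ir <- numeric(1000)
    for (r in 1:1000) {
        tg <- sample(names(x), m)
        ir[r] <- computeIras(x, TargetSignature("t", tg))
        z[r] <- permutationSignificance(x, m, ir[r], nPerm = 10000)$z
    }
    expect_lt(abs(mean(ir)), 0.02)
    expect_lt(abs(mean(z)), 0.05)
    expect_lt(abs(sd(z) - 1), 0.1)
})
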