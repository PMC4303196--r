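test_that("log-rank behaves on identical, separated and degenerate groups", {
    ## two identical groups: no difference at all
    t0 <- c(5, 10, 15, 20, 25)
    e0 <- c(1, 1, 0, 1, 0)
    res <- kmLogrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
    expect_equal(res$chisq, 0, tolerance = 1e-12)
    expect_equal(res$p, 1)

    ## complete separation, no censoring
    res2 <- kmLogrank(c(1:10, 101:110), rep(1, 20),
                      rep(c("early", "late"), each = 10))
    expect_lt(res2$p, 0.01)

    expect_error(kmLogrank(t0, e0, rep("only", 5)), "at least 2 groups")
    g <- factor(rep("a", 5), levels = c("a", "b"))
    expect_error(kmLogrank(t0, e0, g), "zero subjects")
    expect_error(kmLogrank(c(-1, t0[-1], t0), c(e0, e0),
                           rep(c("a", "b"), each = 5)), ">= 0")
})

test_that("log-rank p agrees with a label-permutation oracle", {
    set.seed(61)
    n <- 40
    grp <- rep(c("a", "b"), each = n / 2)
    tm <- rexp(n, rate = 0.05 * exp(0.8 * (grp == "b")))
    ev <- rbinom(n, 1, 0.8)
    obs <- kmLogrank(tm, ev, grp)
    R <- 3000
    exceed <- 0L
    d <- data.frame(tm = tm, ev = ev)
    for (r in seq_len(R)) {
        gperm <- sample(grp)
        chi <- survival::survdiff(survival::Surv(tm, ev) ~ gperm,
                                  data = d)$chisq
        if (chi >= obs$chisq - 1e-12) exceed <- exceed + 1L
    }
    pPerm <- (1 + exceed) / (R + 1)
    mcse <- sqrt(pPerm * (1 - pPerm) / R)
    expect_lt(abs(pPerm - obs$p), 4 * mcse + 0.005)
})

test_that("Cox fits recover a planted hazard ratio with nominal coverage", {
    set.seed(19)
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n, rate = 0.03 * exp(log(2) * x))
    res <- fitCox(data.frame(x = x), tm, rep(1, n))
    tab <- coxTable(res)
    expect_gt(tab$hr, 1.7); expect_lt(tab$hr, 2.4)
    expect_true(tab$ci_low <= 2 && 2 <= tab$ci_high)
    expect_identical(res@nEvents, as.integer(n))

    ## 95% CI coverage across replicates
    set.seed(20)
    cover <- logical(500)
    for (i in 1:500) {
        xi <- rbinom(400, 1, 0.5)
        ti <- rexp(400, rate = 0.03 * exp(log(2) * xi))
        ci <- coxTable(fitCox(data.frame(x = xi), ti, rep(1, 400)))
        cover[i] <- ci$ci_low <= 2 && 2 <= ci$ci_high
    }
    expect_gte(mean(cover), 0.92)
    expect_lte(mean(cover), 0.98)
})

test_that("Cox fit errors on constant covariates, null effects stay null", {
    set.seed(23)
    tm <- rexp(50, 0.05)
    expect_error(fitCox(data.frame(flat = rep(1, 50), ok = rnorm(50)),
                        tm, rep(1, 50)), "flat")
    expect_error(fitCox(data.frame(x = rnorm(10)), rexp(10), rep(0, 10)),
                 "at least one event")

    ## covariate independent of survival: HR near 1
    x <- rnorm(800)
    tm <- rexp(800, 0.05)
    tab <- coxTable(fitCox(data.frame(x = x), tm, rep(1, 800)))
    expect_lt(abs(log(tab$hr)), 0.25)
})

test_that("complete separation raises a convergence error", {
    ## all events in one arm before any event in the other, monstrous HR
    tm <- c(rep(1, 20), rep(100, 20))
    ev <- c(rep(1, 20), rep(0, 20))
    x <- rep(c(1, 0), each = 20)
    expect_error(fitCox(data.frame(x = x), tm, ev), "converge|separation")
})

test_that("gene-wise screen controls type-I error and finds planted genes", {
    set.seed(40)
    n <- 300
    v <- matrix(rnorm(500 * n), 500, n,
                dimnames = list(sprintf("g%03d", 1:500),
                                sprintf("s%03d", 1:n)))
    tm <- rexp(n, 0.05)
    clin <- ClinicalTable(data.frame(sample_id = colnames(v), surv_time = tm,
                                     surv_event = 1L, endpoint = "OS"))
    scr <- geneSurvivalScreen(mkExpr(v), clin, alpha = 0.05)
    frac <- length(scr$significant) / 500
    expect_gte(frac, 0.03); expect_lte(frac, 0.07)

    ## alpha = 1 returns every testable gene
    expect_length(geneSurvivalScreen(mkExpr(v), clin, alpha = 1)$significant,
                  500L)

    ## planted prognostic genes: latent factor drives both hazard and genes
    set.seed(41)
    n2 <- 400
    u <- rnorm(n2)
    vp <- matrix(rnorm(500 * n2), 500, n2,
                 dimnames = list(sprintf("g%03d", 1:500),
                                 sprintf("s%03d", 1:n2)))
    planted <- sprintf("g%03d", 1:20)
    vp[planted, ] <- vp[planted, ] * 0.6 + rep(u, each = 20)
    tm2 <- rexp(n2, 0.05 * exp(0.8 * u))
    clin2 <- ClinicalTable(data.frame(sample_id = colnames(vp),
                                      surv_time = tm2, surv_event = 1L,
                                      endpoint = "OS"))
    scr2 <- geneSurvivalScreen(mkExpr(vp), clin2, alpha = 0.05)
    expect_gte(sum(planted %in% scr2$significant), 16L)

    ## adjusted screens accept clinical covariates
    cd <- clinicalData(clin2)
    cd$er_status <- rep_len(c("positive", "negative"), n2)
    scr3 <- geneSurvivalScreen(mkExpr(vp), ClinicalTable(cd),
                               adjust = "er_status", alpha = 0.05)
    expect_gte(sum(planted %in% scr3$significant), 16L)

    few <- ClinicalTable(data.frame(sample_id = colnames(v), surv_time = tm,
                                    surv_event = rep(c(1L, rep(0L, 59)), 5),
                                    endpoint = "OS"))
    expect_error(geneSurvivalScreen(mkExpr(v), few), "fewer than 10 events")
})

test_that("enrichment folds reproduce the printed-count ratios", {
    e1 <- enrichmentFold(10333, 751, 102, 58)
    expect_identical(round(e1@fold), 8)
    expect_equal(e1@fold, (58 / 102) / (751 / 10333), tolerance = 1e-12)
    expect_lt(e1@pFisher, 1e-30)

    e2 <- enrichmentFold(10333, 83, 102, 17)
    expect_identical(round(e2@fold), 21)
    expect_lt(e2@pFisher, 1e-15)

    ## equal proportions give exactly fold 1
    expect_equal(enrichmentFold(1000, 100, 50, 5)@fold, 1)

    expect_error(enrichmentFold(1000, 0, 50, 0), "denominator")
    expect_error(enrichmentFold(1000, 100, 0, 0), "denominator")
    expect_error(enrichmentFold(100, 50, 20, 30), "inconsistent|mSigSet")
})

test_that("NPI bands samples at the 3.4 and 5.4 thresholds", {
    expect_equal(npiRisk(20, 1, 1)$npi, 2.4)
    expect_identical(as.character(npiRisk(20, 1, 1)$group), "low")
    ## exactly 3.4 and 5.4 fall in the (inclusive) medium band
    expect_identical(as.character(npiRisk(20, 1, 2)$group), "medium")  # 3.4
    expect_identical(as.character(npiRisk(20, 2, 3)$group), "medium")  # 5.4
    expect_equal(npiRisk(40, 3, 3)$npi, 6.8)
    expect_identical(as.character(npiRisk(40, 3, 3)$group), "high")
    expect_error(npiRisk(-5, 2, 1), "positive")
    expect_error(npiRisk(20, 4, 1), "grade")
    expect_error(npiRisk(20, 2, 0), "nodal")
})

test_that("median-split stratification respects the tie-to-low rule", {
    m <- mkExpr(matrix(c(1, 2, 3, 4), 1, 4,
                       dimnames = list("gX", paste0("s", 1:4))))
    g <- stratifyByGene(m, "gX")
    expect_identical(as.character(g), c("low", "low", "high", "high"))

    modd <- mkExpr(matrix(c(1, 2, 3), 1, 3,
                          dimnames = list("gX", paste0("s", 1:3))))
    godd <- stratifyByGene(modd, "gX")
    expect_identical(as.character(godd), c("low", "low", "high"))

    flat <- mkExpr(matrix(2, 1, 4, dimnames = list("gX", paste0("s", 1:4))))
    expect_error(stratifyByGene(flat, "gX"), "constant")
    expect_error(stratifyByGene(m, "nope"), "not found")

    ## well-separated bimodal gene recovers the mixture components up to
    ## the overlap error of the two components (about 2% at 4 sd apart)
    set.seed(55)
    comp <- rbinom(200, 1, 0.5)
    vals <- rnorm(200, mean = 4 * comp, sd = 1)
    mb <- mkExpr(matrix(vals, 1, 200,
                        dimnames = list("gB", sprintf("s%03d", 1:200))))
    gb <- stratifyByGene(mb, "gB")
    expect_gte(mean((gb == "high") == (comp == 1)), 0.95)
})
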