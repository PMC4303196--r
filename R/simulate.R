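## Simulators with planted ground truth.  Every generator is a pure
## function of its configuration (seed included) and produces objects that
## pass the package validators; the latent parameters are returned in a
## separate ground-truth list that is never written into pipeline inputs.

#' Simulation configuration for the cohort generator
#'
#' Defaults emulate a desk-scale breast-cancer expression cohort: a
#' 2,000-gene universe with a 100-gene target signature (about the
#' signature-to-universe ratio of a genome-wide microarray study), unit
#' log-expression noise, covariate marginals loosely matching published
#' breast-cancer cohorts (ER+ 75 percent), exponential survival at a
#' baseline rate of 0.01 events per month, a planted log hazard ratio of
#' 0.7 between positive- and negative-activity samples, and 30 percent
#' independent uniform censoring.
#'
#' @param nGenes gene universe size.
#' @param nSamples cohort size.
#' @param signatureSize number of target genes (< nGenes).
#' @param effectBeta target-gene shift per unit latent activity
#'   (log-expression units).
#' @param noiseSd residual log-expression noise sd.
#' @param surv list with \code{baselineRate} (events/month),
#'   \code{logHrActivity} (log HR of the positive-activity group),
#'   \code{censorFraction} in [0, 1), and \code{covEffects} (named log-HR
#'   increments for age/grade/size in centred units and for
#'   er/ln/treatment indicators).
#' @param seed RNG seed (mandatory).
#' @return a validated \code{simConfig} list.
#' @seealso \code{\link{genCohort}}
#' @export
simConfig <- function(nGenes = 2000, nSamples = 200, signatureSize = 100,
                      effectBeta = 1, noiseSd = 1,
                      surv = list(), seed) {
    if (missing(seed)) stop("seed is mandatory")
    survDefaults <- list(baselineRate = 0.01, logHrActivity = 0.7,
                         censorFraction = 0.3,
                         covEffects = c(age = 0.01, grade = 0.2, size = 0.01,
                                        er = -0.2, ln = 0.3,
                                        treatment = -0.3))
    surv <- utils::modifyList(survDefaults, surv)
    cfg <- list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
                signatureSize = as.integer(signatureSize),
                effectBeta = effectBeta, noiseSd = noiseSd, surv = surv,
                seed = as.integer(seed))
    .validate_sim_config(cfg)
    class(cfg) <- "simConfig"
    cfg
}

.validate_sim_config <- function(cfg) {
    with(cfg, {
        if (nGenes < 4L || nSamples < 2L)
            stop("need at least 4 genes and 2 samples")
        if (signatureSize < 2L || signatureSize >= nGenes)
            stop("signatureSize must be in [2, nGenes)")
        if (noiseSd <= 0) stop("noiseSd must be positive")
        if (effectBeta < 0) stop("effectBeta must be non-negative")
        if (surv$baselineRate <= 0) stop("baselineRate must be positive")
        if (surv$censorFraction < 0 || surv$censorFraction >= 1)
            stop("censorFraction must lie in [0, 1)")
        if (is.na(seed)) stop("seed must be an integer")
    })
    invisible(TRUE)
}

## Uniform censoring horizon tuned so the expected censored fraction over
## the drawn event times matches the target: P(C < T) = E[min(T/tau, 1)].
.censor_horizon <- function(T, frac) {
    f <- function(tau) mean(pmin(T / tau, 1)) - frac
    uniroot(f, lower = min(T) * 1e-6, upper = max(T) * 1e6)$root
}

#' Simulate an expression cohort with planted activity and survival
#'
#' Latent per-sample activity \code{a ~ N(0, 1)} shifts the target genes by
#' \code{effectBeta * a} on top of Gaussian noise; non-targets are pure
#' noise.  Clinical covariates are drawn from documented marginals, and
#' exponential survival times get log-hazard
#' \code{logHrActivity * 1[a > 0]} plus centred covariate terms, with
#' independent uniform censoring tuned to the configured fraction.
#'
#' @param cfg a \code{\link{simConfig}}; validated before any sampling.
#' @return list with \code{expr} (\code{\linkS4class{RegExprSet}},
#'   two-channel), \code{clinical} (\code{\linkS4class{ClinicalTable}}),
#'   \code{signature} (\code{\linkS4class{TargetSignature}}) and
#'   \code{truth} (latent activity, target flags, hazard multipliers).
#' @examples
#' sim <- genCohort(simConfig(nGenes = 300, nSamples = 50, seed = 1))
#' sim$expr
#' @export
genCohort <- function(cfg) {
    if (!inherits(cfg, "simConfig")) stop("cfg must come from simConfig()")
    .validate_sim_config(cfg)
    set.seed(cfg$seed)
    ng <- cfg$nGenes; ns <- cfg$nSamples
    genes <- sprintf("g%05d", seq_len(ng))
    samples <- sprintf("s%04d", seq_len(ns))
    a <- rnorm(ns)
    target <- setNames(logical(ng), genes)
    target[sample.int(ng, cfg$signatureSize)] <- TRUE

    v <- matrix(rnorm(ng * ns, sd = cfg$noiseSd), ng, ns,
                dimnames = list(genes, samples))
    v[target, ] <- v[target, ] + rep(cfg$effectBeta * a,
                                     each = cfg$signatureSize)
    expr <- RegExprSet(v, "two_channel_logratio")

    age <- round(pmin(pmax(rnorm(ns, 58, 10), 25), 90))
    er <- ifelse(runif(ns) < 0.75, "positive", "negative")
    pr <- ifelse(runif(ns) < 0.65, "positive", "negative")
    grade <- sample(1:3, ns, replace = TRUE, prob = c(0.2, 0.45, 0.35))
    size <- round(pmin(pmax(stats::rlnorm(ns, log(20), 0.4), 4), 90))
    ln <- ifelse(runif(ns) < 0.35, "positive", "negative")
    trt <- ifelse(runif(ns) < 0.5, "treated", "untreated")

    ce <- cfg$surv$covEffects
    lp <- cfg$surv$logHrActivity * (a > 0) +
        ce["age"] * (age - 58) + ce["grade"] * (grade - 2) +
        ce["size"] * (size - 20) + ce["er"] * (er == "positive") +
        ce["ln"] * (ln == "positive") + ce["treatment"] * (trt == "treated")
    lp <- unname(lp)
    T <- rexp(ns, rate = cfg$surv$baselineRate * exp(lp))
    if (cfg$surv$censorFraction > 0) {
        tau <- .censor_horizon(T, cfg$surv$censorFraction)
        C <- runif(ns, 0, tau)
        time <- pmin(T, C)
        event <- as.integer(T <= C)
    } else {
        time <- T
        event <- rep(1L, ns)
    }
    clin <- ClinicalTable(data.frame(
        sample_id = samples, age = age, er_status = er, pr_status = pr,
        grade = grade, tumor_size = size, ln_status = ln, treatment = trt,
        surv_time = time, surv_event = event, endpoint = "RFS",
        stringsAsFactors = FALSE))
    sig <- TargetSignature("planted", genes[target],
                           sources = list(planted = genes[target]))
    list(expr = expr, clinical = clin, signature = sig,
         truth = list(activity = setNames(a, samples), targetFlag = target,
                      hazardMultiplier = setNames(exp(lp), samples)))
}

#' Simulate a periodic expression time course
#'
#' Target genes oscillate as
#' \code{amplitude * cos(2*pi*t/period + phase jitter)} on top of Gaussian
#' noise; non-targets are pure noise.  The period must divide the number of
#' points so the oscillation sits exactly on a Fourier frequency.
#'
#' @param nPoints number of time points (>= 8).
#' @param period oscillation period in sampling steps; must divide
#'   \code{nPoints}.
#' @param amplitude oscillation amplitude (log-expression units).
#' @param noiseSd residual noise sd.
#' @param seed RNG seed.
#' @param nGenes gene universe size.
#' @param signatureSize number of oscillating target genes.
#' @param phaseJitterSd per-gene phase jitter sd (radians).
#' @return list with \code{expr} (genes x time points,
#'   \code{\linkS4class{RegExprSet}}), \code{signature}, \code{times}.
#' @export
genTimecourse <- function(nPoints = 48, period = 16, amplitude = 1,
                          noiseSd = 1, seed, nGenes = 500,
                          signatureSize = 50, phaseJitterSd = 0.3) {
    if (missing(seed)) stop("seed is mandatory")
    if (nPoints < 8L) stop("at least 8 time points are required")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    if (amplitude < 0) stop("amplitude must be non-negative")
    if (signatureSize < 2L || signatureSize >= nGenes)
        stop("signatureSize must be in [2, nGenes)")
    if (nPoints %% period != 0)
        stop("period must divide nPoints (oscillation must sit on a Fourier frequency)")
    set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nGenes))
    t <- seq_len(nPoints) - 1
    target <- setNames(logical(nGenes), genes)
    target[sample.int(nGenes, signatureSize)] <- TRUE
    v <- matrix(rnorm(nGenes * nPoints, sd = noiseSd), nGenes, nPoints,
                dimnames = list(genes, sprintf("t%02d", seq_len(nPoints))))
    phase <- rnorm(signatureSize, 0, phaseJitterSd)
    v[target, ] <- v[target, ] +
        amplitude * cos(outer(phase, 2 * pi * t / period, "+"))
    list(expr = RegExprSet(v, "two_channel_logratio"),
         signature = TargetSignature("planted", genes[target],
                                     sources = list(planted = genes[target])),
         times = t,
         truth = list(targetFlag = target))
}

#' Simulate TSS-proximal binding signal
#'
#' Planted targets receive a Gaussian-shaped mean enrichment centred at the
#' TSS (\code{background * (1 + signalStrength * exp(-d^2/(2*(window/4)^2))})
#' at offset d) on top of Poisson background; non-targets are background
#' only.  \code{signalStrength = 0} is the exact null.
#'
#' @param nGenes number of genes.
#' @param nTargets number of planted targets (< nGenes).
#' @param signalStrength peak enrichment over background, in background
#'   units (default 3).
#' @param window half window width in bp.
#' @param bin bin width in bp.
#' @param background mean background counts per bin.
#' @param seed RNG seed.
#' @return list with \code{binding}
#'   (\code{\linkS4class{BindingWindowMatrix}}) and \code{truth}
#'   (target flags).
#' @export
genBindingData <- function(nGenes = 2000, nTargets = 100, signalStrength = 3,
                           window = 10000, bin = 100, background = 5, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (nTargets >= nGenes || nTargets < 1L)
        stop("nTargets must be in [1, nGenes)")
    if (signalStrength < 0) stop("signalStrength must be non-negative")
    if (background <= 0) stop("background must be positive")
    if ((2 * window) %% bin != 0) stop("bin must divide 2*window")
    set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nGenes))
    target <- setNames(logical(nGenes), genes)
    target[sample.int(nGenes, nTargets)] <- TRUE
    nb <- as.integer(2 * window / bin)
    offsets <- -window + (seq_len(nb) - 0.5) * bin
    gauss <- exp(-offsets^2 / (2 * (window / 4)^2))
    lam <- matrix(background, nGenes, nb)
    lam[target, ] <- background *
        (1 + rep(signalStrength, each = nTargets) *
             matrix(gauss, nTargets, nb, byrow = TRUE))
    sig <- matrix(rpois(nGenes * nb, lam), nGenes, nb,
                  dimnames = list(genes, NULL))
    tss <- GRanges("chr1",
                   IRanges(start = 1e5 * seq_len(nGenes), width = 1L),
                   strand = rep_len(c("+", "-"), nGenes),
                   gene_id = genes)
    list(binding = BindingWindowMatrix(sig, tss, window, bin),
         truth = list(targetFlag = target))
}

#' Simulate a centroid-structured cohort with class-linked activity
#'
#' Subtype centroids are random Gaussian profiles over a dedicated centroid
#' gene block; each sample is its class centroid plus noise.  A latent
#' activity, optionally shifted per class, drives a separate target-gene
#' block so that subtype assignment and activity scoring can be validated
#' jointly.
#'
#' @param nSamples cohort size.
#' @param subtypes subtype names (centroid file order).
#' @param nCentroidGenes genes in the centroid block.
#' @param nOtherGenes additional genes (hosting the activity signature).
#' @param signatureSize number of activity target genes.
#' @param centroidSd sd of centroid profiles (the class "signal").
#' @param noiseSd per-sample noise sd around the centroid.
#' @param activityByClass optional named vector of per-class mean activity;
#'   default NULL draws activity N(0, 1) independently of class.
#' @param effectBeta target-gene shift per unit activity.
#' @param seed RNG seed.
#' @return list with \code{expr}, \code{centroids}
#'   (\code{\linkS4class{CentroidMatrix}}), \code{signature} and
#'   \code{truth} (class labels, latent activity, target flags).
#' @export
genSubtypedCohort <- function(nSamples = 250,
                              subtypes = c("LumA", "LumB", "Her2", "Basal",
                                           "Normal"),
                              nCentroidGenes = 50, nOtherGenes = 450,
                              signatureSize = 50, centroidSd = 1,
                              noiseSd = 0.5, activityByClass = NULL,
                              effectBeta = 1, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (noiseSd <= 0 || centroidSd <= 0) stop("sds must be positive")
    if (signatureSize < 2L || signatureSize >= nOtherGenes)
        stop("signatureSize must be in [2, nOtherGenes)")
    if (!is.null(activityByClass) &&
        !all(subtypes %in% names(activityByClass)))
        stop("activityByClass must name every subtype")
    set.seed(seed)
    K <- length(subtypes)
    cg <- sprintf("cg%04d", seq_len(nCentroidGenes))
    og <- sprintf("og%04d", seq_len(nOtherGenes))
    cent <- matrix(rnorm(K * nCentroidGenes, sd = centroidSd),
                   K, nCentroidGenes, dimnames = list(subtypes, cg))
    cls <- sample(subtypes, nSamples, replace = TRUE)
    a <- if (is.null(activityByClass)) rnorm(nSamples)
         else rnorm(nSamples, mean = activityByClass[cls], sd = 0.5)
    target <- setNames(logical(nOtherGenes), og)
    target[sample.int(nOtherGenes, signatureSize)] <- TRUE

    samples <- sprintf("s%04d", seq_len(nSamples))
    vc <- t(cent[cls, , drop = FALSE]) +
        matrix(rnorm(nCentroidGenes * nSamples, sd = noiseSd),
               nCentroidGenes, nSamples)
    vo <- matrix(rnorm(nOtherGenes * nSamples, sd = 1), nOtherGenes, nSamples)
    vo[target, ] <- vo[target, ] + rep(effectBeta * a, each = signatureSize)
    v <- rbind(vc, vo)
    dimnames(v) <- list(c(cg, og), samples)
    list(expr = RegExprSet(v, "two_channel_logratio"),
         centroids = CentroidMatrix(cent),
         signature = TargetSignature("planted", og[target],
                                     sources = list(planted = og[target])),
         truth = list(class = setNames(cls, samples),
                      activity = setNames(a, samples),
                      targetFlag = target))
}
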