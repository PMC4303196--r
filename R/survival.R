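## Survival machinery around the activity groups: Kaplan-Meier / log-rank
## comparison, Cox proportional-hazards fits (Efron ties), a gene-wise
## survival screen, signature enrichment among survival genes, Nottingham
## Prognostic Index banding and single-gene median-split stratification.
## Model fitting is delegated to the survival package throughout.

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (0 = censored, 1 = event).
#' @param group group labels; >= 2 non-empty groups are required, and a
#'   factor with an empty level is an error.
#' @return list with \code{curves} (a \code{survfit} object, censor marks
#'   retained), \code{chisq}, \code{df}, \code{p} (log-rank) and \code{n}
#'   (per-group sizes).
#' @examples
#' sim <- genCohort(simConfig(nGenes = 200, nSamples = 120, seed = 3))
#' grp <- dichotomize(computeIrasMatrix(sim$expr, sim$signature,
#'                                      nPerm = 50, seed = 1))
#' cd <- clinicalData(sim$clinical)
#' kmLogrank(cd$surv_time, cd$surv_event, grp)$p
#' @export
kmLogrank <- function(time, event, group) {
    stopifnot(length(time) == length(event), length(time) == length(group))
    if (any(time < 0, na.rm = TRUE)) stop("survival times must be >= 0")
    group <- as.factor(group)
    tab <- table(group)
    if (any(tab == 0L))
        stop(sprintf("group(s) with zero subjects: %s",
                     paste(names(tab)[tab == 0L], collapse = ", ")))
    if (nlevels(group) < 2L)
        stop("at least 2 groups are required for a log-rank comparison")
    d <- data.frame(time = time, event = event, group = group)
    sdf <- survdiff(Surv(time, event) ~ group, data = d)
    df <- nlevels(group) - 1L
    list(curves = survfit(Surv(time, event) ~ group, data = d),
         chisq = sdf$chisq,
         df = df,
         p = pchisq(sdf$chisq, df, lower.tail = FALSE),
         n = tab)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron tie approximation.  Constant
#' covariates and non-convergence (for instance complete separation) are
#' errors, never silent output.
#'
#' @param covariates data.frame of covariates (factors and numerics); one
#'   row per sample.
#' @param time follow-up times.
#' @param event event indicators (>= 1 event required).
#' @return a \code{\linkS4class{CoxResult}}.
#' @examples
#' set.seed(1)
#' x <- rbinom(300, 1, 0.5)
#' t <- rexp(300, 0.05 * exp(log(2) * x))
#' coxTable(fitCox(data.frame(x = x), t, rep(1, 300)))
#' @export
fitCox <- function(covariates, time, event) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(time), length(time) == length(event))
    if (sum(event, na.rm = TRUE) < 1)
        stop("at least one event is required")
    for (nm in names(covariates)) {
        v <- covariates[[nm]]
        if (length(unique(v[!is.na(v)])) < 2L)
            stop(sprintf("covariate '%s' is constant", nm))
    }
    d <- cbind(data.frame(.time = time, .event = event), covariates)
    convWarn <- NULL
    fit <- withCallingHandlers(
        coxph(Surv(.time, .event) ~ ., data = d[, c(".time", ".event",
                                                    names(covariates))],
              ties = "efron"),
        warning = function(w) {
            if (grepl("infinite|converge|beta", conditionMessage(w)))
                convWarn <<- conditionMessage(w)
            invokeRestart("muffleWarning")
        })
    if (!is.null(convWarn))
        stop("Cox model did not converge (possible complete separation): ",
             convWarn)
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    tab <- data.frame(term = rownames(co),
                      hr = unname(co[, "exp(coef)"]),
                      se = unname(co[, "se(coef)"]),
                      ci_low = unname(ci[, "lower .95"]),
                      ci_high = unname(ci[, "upper .95"]),
                      p = unname(co[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
    if (any(is.na(tab$hr)))
        stop("Cox fit produced undefined coefficients")
    new("CoxResult", table = tab, n = as.integer(s$n),
        nEvents = as.integer(s$nevent), fit = fit)
}

#' Gene-wise Cox survival screen
#'
#' Fits one Cox model per gene with continuous expression (plus optional
#' adjustment covariates from the clinical table) and returns the genes
#' whose Wald p-value falls below \code{alpha}.
#'
#' @param m a \code{\linkS4class{RegExprSet}}.
#' @param clin a \code{\linkS4class{ClinicalTable}}; samples are matched to
#'   the expression columns by \code{sample_id}.
#' @param adjust optional character vector of clinical column names to
#'   adjust for (e.g. \code{c("er_status", "ln_status")}).
#' @param alpha significance threshold in (0, 1]; \code{alpha = 1} returns
#'   every testable gene.
#' @return list with \code{significant} (gene ids) and \code{table}
#'   (per-gene coefficient, hazard ratio and p).
#' @export
geneSurvivalScreen <- function(m, clin, adjust = NULL, alpha = 0.05) {
    stopifnot(is(m, "RegExprSet"), is(clin, "ClinicalTable"),
              alpha > 0, alpha <= 1)
    cd <- clinicalData(clin)
    ids <- intersect(sampleIds(m), cd$sample_id)
    if (length(ids) < 2L)
        stop("expression and clinical tables share fewer than 2 samples")
    cd <- cd[match(ids, cd$sample_id), , drop = FALSE]
    if (sum(cd$surv_event, na.rm = TRUE) < 10)
        stop("fewer than 10 events: gene-wise screen is not meaningful")
    v <- exprValues(m)[, ids, drop = FALSE]
    adj <- NULL
    if (length(adjust)) {
        missing_cols <- setdiff(adjust, names(cd))
        if (length(missing_cols))
            stop("adjustment column(s) not in clinical table: ",
                 paste(missing_cols, collapse = ", "))
        adj <- cd[, adjust, drop = FALSE]
    }
    genes <- rownames(v)
    coefv <- rep(NA_real_, length(genes))
    pv <- rep(NA_real_, length(genes))
    base <- data.frame(.time = cd$surv_time, .event = cd$surv_event)
    if (!is.null(adj)) base <- cbind(base, adj)
    fml <- stats::as.formula(paste("Surv(.time, .event) ~ .expr",
                                   if (length(adjust))
                                       paste("+", paste(adjust, collapse = " + "))
                                   else ""))
    for (i in seq_along(genes)) {
        base$.expr <- v[i, ]
        fit <- tryCatch(suppressWarnings(coxph(fml, data = base,
                                               ties = "efron")),
                        error = function(e) NULL)
        if (is.null(fit)) next
        s <- summary(fit)$coefficients
        if (!".expr" %in% rownames(s)) next
        coefv[i] <- s[".expr", "coef"]
        pv[i] <- s[".expr", "Pr(>|z|)"]
    }
    ok <- !is.na(pv)
    sig <- if (alpha >= 1) genes[ok] else genes[ok & pv < alpha]
    list(significant = sig,
         table = data.frame(gene_id = genes, coef = coefv, hr = exp(coefv),
                            p = pv, stringsAsFactors = FALSE))
}

#' Fold enrichment of a signature among survival-significant genes
#'
#' Compares the significant fraction inside the signature with the
#' genome-wide significant fraction and tests the disjoint 2x2 table with a
#' two-sided Fisher exact test.
#'
#' @param nTotal genes measured genome-wide.
#' @param nSigTotal survival-significant genes genome-wide.
#' @param mSet signature genes measured.
#' @param mSigSet significant genes inside the signature.
#' @return an \code{\linkS4class{EnrichmentResult}}.
#' @examples
#' enrichmentFold(10333, 751, 102, 58)   # about 8-fold
#' @export
enrichmentFold <- function(nTotal, nSigTotal, mSet, mSigSet) {
    nTotal <- as.integer(nTotal); nSigTotal <- as.integer(nSigTotal)
    mSet <- as.integer(mSet); mSigSet <- as.integer(mSigSet)
    if (any(c(nTotal, nSigTotal, mSet, mSigSet) < 0))
        stop("counts must be non-negative")
    if (mSet > nTotal || mSigSet > mSet || mSigSet > nSigTotal ||
        nSigTotal > nTotal)
        stop("inconsistent counts: need mSigSet <= mSet <= nTotal and ",
             "mSigSet <= nSigTotal <= nTotal")
    if (nSigTotal == 0L || mSet == 0L)
        stop("zero denominator: nSigTotal and mSet must be positive")
    fold <- (mSigSet / mSet) / (nSigTotal / nTotal)
    tab <- matrix(c(mSigSet, mSet - mSigSet,
                    nSigTotal - mSigSet,
                    nTotal - mSet - (nSigTotal - mSigSet)),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    new("EnrichmentResult", nTotal = nTotal, nSigTotal = nSigTotal,
        mSet = mSet, mSigSet = mSigSet, fold = fold, pFisher = p)
}

#' Nottingham Prognostic Index and risk group
#'
#' \code{NPI = 0.2 x size(cm) + grade + nodal category}; risk bands are
#' \code{low} below 3.4, \code{medium} from 3.4 to 5.4 (both bounds
#' inclusive) and \code{high} above 5.4.  Binary lymph-node status without
#' node counts maps to nodal category 2 for positive and 1 for negative.
#'
#' @param sizeMm tumour size in millimetres (> 0).
#' @param grade tumour grade (1-3).
#' @param nodalCategory nodal category (1-3).
#' @return data.frame with columns \code{npi} and \code{group}
#'   (factor low/medium/high), one row per input.
#' @examples
#' npiRisk(20, 1, 1)    # 2.4, low
#' npiRisk(40, 3, 3)    # 6.8, high
#' @export
npiRisk <- function(sizeMm, grade, nodalCategory) {
    n <- max(length(sizeMm), length(grade), length(nodalCategory))
    sizeMm <- rep_len(sizeMm, n)
    grade <- rep_len(grade, n)
    nodalCategory <- rep_len(nodalCategory, n)
    if (any(sizeMm <= 0, na.rm = TRUE))
        stop("tumour size (mm) must be positive")
    if (!all(grade %in% c(1L, 2L, 3L, NA)))
        stop("grade must be 1, 2 or 3")
    if (!all(nodalCategory %in% c(1L, 2L, 3L, NA)))
        stop("nodal category must be 1, 2 or 3")
    npi <- 0.2 * (sizeMm / 10) + grade + nodalCategory
    group <- factor(ifelse(npi < 3.4, "low",
                           ifelse(npi <= 5.4, "medium", "high")),
                    levels = c("low", "medium", "high"))
    data.frame(npi = npi, group = group)
}

#' Median-split stratification by a single gene
#'
#' Labels samples \code{low} or \code{high} by the gene's expression; with
#' the median-split rule samples at or below the median (including the
#' median sample for odd n) go to \code{low}.
#'
#' @param m a \code{\linkS4class{RegExprSet}}.
#' @param geneId the stratifying gene; must be present and non-constant.
#' @param rule stratification rule; only \code{"median_split"} is defined.
#' @return named factor with levels \code{low}, \code{high} (NA expression
#'   gives NA labels).
#' @export
stratifyByGene <- function(m, geneId, rule = c("median_split")) {
    rule <- match.arg(rule)
    stopifnot(is(m, "RegExprSet"))
    if (!geneId %in% geneIds(m))
        stop(sprintf("gene '%s' not found in the expression matrix", geneId))
    v <- exprValues(m)[geneId, ]
    if (diff(range(v, na.rm = TRUE)) == 0)
        stop(sprintf("gene '%s' is constant across samples", geneId))
    med <- median(v, na.rm = TRUE)
    setNames(factor(ifelse(v <= med, "low", "high"),
                    levels = c("low", "high")), names(v))
}
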