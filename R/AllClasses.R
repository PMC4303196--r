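## Central S4 containers.  Validity functions enforce the invariants the
## statistical code relies on: unique identifiers, finite-or-missing values,
## count consistency, score/group coherence.

.CHANNEL_MODES <- c("two_channel_logratio", "one_channel_log")
.ENDPOINTS <- c("OS", "RFS", "DMFS")

## ---------------------------------------------------------------------------
## RegExprSet
## ---------------------------------------------------------------------------

#' Gene-by-sample relative expression container
#'
#' Extends \linkS4class{SummarizedExperiment} with a declared channel mode.
#' Two-channel log-ratios are already relative expression values and can be
#' scored directly; one-channel log intensities are absolute and must be
#' gene-wise median-centred first (see \code{\link{medianCenter}}).
#' Missing measurements are stored as \code{NA}, never as zero.
#'
#' @slot channelMode \code{"two_channel_logratio"} or \code{"one_channel_log"}.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); log-scale relative or absolute expression.
#' @param channelMode how the values were measured (see above).
#'
#' @return \code{RegExprSet()} returns a validated \code{RegExprSet}.
#' @seealso \code{\link{readExpression}}, \code{\link{medianCenter}}
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' es <- RegExprSet(m, "two_channel_logratio")
#' channelMode(es)
#' @aliases RegExprSet geneIds,RegExprSet-method sampleIds,RegExprSet-method
#'   channelMode,RegExprSet-method exprValues,RegExprSet-method
#' @export RegExprSet
#' @exportClass RegExprSet
setClass("RegExprSet",
         contains = "SummarizedExperiment",
         slots = c(channelMode = "character"))

setValidity("RegExprSet", function(object) {
    msg <- NULL
    if (length(object@channelMode) != 1L ||
        !object@channelMode %in% .CHANNEL_MODES)
        msg <- c(msg, sprintf("channelMode must be one of: %s",
                              paste(.CHANNEL_MODES, collapse = ", ")))
    if (!"exprs" %in% assayNames(object)) {
        msg <- c(msg, "an assay named 'exprs' is required")
    } else {
        v <- assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "expression values must be numeric")
        else if (any(is.infinite(v)))
            msg <- c(msg, "expression values must be finite or NA")
    }
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
        msg <- c(msg, "gene identifiers must be present, non-empty and unique")
    if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
        msg <- c(msg, "sample identifiers must be present, non-empty and unique")
    if (is.null(msg)) TRUE else msg
})

RegExprSet <- function(values, channelMode = .CHANNEL_MODES) {
    channelMode <- match.arg(channelMode)
    if (!is.matrix(values))
        values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(exprs = values))
    new("RegExprSet", se, channelMode = channelMode)
}

#' @export
setMethod("geneIds", "RegExprSet", function(x) rownames(x))

#' @export
setMethod("sampleIds", "RegExprSet", function(x) colnames(x))

#' @export
setMethod("channelMode", "RegExprSet", function(x) x@channelMode)

#' @export
setMethod("exprValues", "RegExprSet", function(x) assay(x, "exprs"))

setMethod("show", "RegExprSet", function(object) {
    cat(sprintf("RegExprSet: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), object@channelMode))
    callNextMethod()
})

## ---------------------------------------------------------------------------
## TargetSignature
## ---------------------------------------------------------------------------

#' A named set of transcription-factor target genes
#'
#' Carrier for a target-gene signature (for instance a consensus set called
#' from ChIP-seq binding in several cell lines).  \code{sources} optionally
#' records the per-source gene sets the signature was intersected from.
#' An empty gene set is permitted (a cross-source intersection can come up
#' empty) but is flagged with a warning wherever one is produced.
#'
#' @slot name signature name.
#' @slot genes unique gene identifiers.
#' @slot sources named list of character vectors, one per contributing source.
#'
#' @param name signature name (length-1 character).
#' @param genes gene identifiers; duplicates are removed, order preserved.
#' @param sources optional named list of per-source gene sets; when present,
#'   \code{genes} must be contained in their union.
#'
#' @return a \code{TargetSignature}.
#' @seealso \code{\link{readGmt}}, \code{\link{intersectSignatures}},
#'   \code{\link{callTargets}}
#' @examples
#' TargetSignature("SIG", c("A", "B", "A"))
#' @aliases TargetSignature geneIds,TargetSignature-method
#'   signatureSources,TargetSignature-method
#' @export TargetSignature
#' @exportClass TargetSignature
setClass("TargetSignature",
         slots = c(name = "character", genes = "character", sources = "list"))

setValidity("TargetSignature", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "signature genes must be unique")
    if (length(object@sources)) {
        if (!all(vapply(object@sources, is.character, logical(1))))
            msg <- c(msg, "sources must be character vectors")
        else if (!all(object@genes %in% unique(unlist(object@sources))))
            msg <- c(msg, "genes must be contained in the union of the sources")
    }
    if (is.null(msg)) TRUE else msg
})

TargetSignature <- function(name, genes, sources = list()) {
    new("TargetSignature", name = as.character(name),
        genes = unique(as.character(genes)), sources = sources)
}

#' @export
setMethod("geneIds", "TargetSignature", function(x) x@genes)

#' @export
setMethod("signatureSources", "TargetSignature", function(x) x@sources)

setMethod("length", "TargetSignature", function(x) length(x@genes))

setMethod("show", "TargetSignature", function(object) {
    cat(sprintf("TargetSignature '%s': %d genes", object@name,
                length(object@genes)))
    if (length(object@sources))
        cat(sprintf(" (intersection of %d sources: %s)",
                    length(object@sources),
                    paste(names(object@sources), collapse = ", ")))
    cat("\n")
    if (length(object@genes))
        cat("  ", paste(utils::head(object@genes, 8), collapse = ", "),
            if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ClinicalTable
## ---------------------------------------------------------------------------

#' Per-sample clinical covariates and survival outcome
#'
#' Validated wrapper around a clinical data frame with one row per sample.
#' Required columns: \code{sample_id}, \code{surv_time} (months, >= 0),
#' \code{surv_event} (0 = censored, 1 = event) and \code{endpoint}
#' (\code{OS}, \code{RFS} or \code{DMFS}).  Recognised optional columns:
#' \code{age} (years), \code{er_status}, \code{pr_status}, \code{ln_status}
#' (\code{positive}/\code{negative}/\code{NA}), \code{grade} (1-3),
#' \code{tumor_size} (millimetres), \code{treatment}
#' (\code{treated}/\code{untreated}/\code{NA}).  Any further columns (for
#' instance precomputed risk strata) are preserved untouched.
#'
#' @slot data the validated data frame.
#' @param data a data frame as described above.
#' @return a \code{ClinicalTable}.
#' @seealso \code{\link{readClinical}}
#' @aliases ClinicalTable clinicalData,ClinicalTable-method
#'   sampleIds,ClinicalTable-method
#' @export ClinicalTable
#' @exportClass ClinicalTable
setClass("ClinicalTable", slots = c(data = "data.frame"))

.STATUS_LEVELS <- c("positive", "negative")
.TREATMENT_LEVELS <- c("treated", "untreated")

setValidity("ClinicalTable", function(object) {
    d <- object@data
    msg <- NULL
    need <- c("sample_id", "surv_time", "surv_event", "endpoint")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols))
        return(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(d$sample_id))
        msg <- c(msg, "sample_id must be unique (one row per sample)")
    if (any(d$surv_time < 0, na.rm = TRUE))
        msg <- c(msg, "surv_time must be >= 0")
    if (!all(d$surv_event %in% c(0L, 1L, NA)))
        msg <- c(msg, "surv_event must be 0 or 1")
    if (!all(d$endpoint %in% c(.ENDPOINTS, NA)))
        msg <- c(msg, sprintf("endpoint must be one of: %s",
                              paste(.ENDPOINTS, collapse = ", ")))
    if ("grade" %in% names(d) && !all(d$grade %in% c(1L, 2L, 3L, NA)))
        msg <- c(msg, "grade must be 1, 2 or 3 when present")
    for (col in c("er_status", "pr_status", "ln_status"))
        if (col %in% names(d) && !all(d[[col]] %in% c(.STATUS_LEVELS, NA)))
            msg <- c(msg, sprintf("%s must be 'positive', 'negative' or NA", col))
    if ("treatment" %in% names(d) &&
        !all(d$treatment %in% c(.TREATMENT_LEVELS, NA)))
        msg <- c(msg, "treatment must be 'treated', 'untreated' or NA")
    if ("tumor_size" %in% names(d) && any(d$tumor_size <= 0, na.rm = TRUE))
        msg <- c(msg, "tumor_size (mm) must be positive")
    if (is.null(msg)) TRUE else msg
})

ClinicalTable <- function(data) {
    data <- as.data.frame(data)
    ## tolerate "missing" spelled out in status-like columns
    for (col in c("er_status", "pr_status", "ln_status", "treatment"))
        if (col %in% names(data)) {
            v <- as.character(data[[col]])
            v[v %in% c("missing", "")] <- NA_character_
            data[[col]] <- v
        }
    data$sample_id <- as.character(data$sample_id)
    data$surv_event <- as.integer(data$surv_event)
    if ("grade" %in% names(data)) data$grade <- as.integer(data$grade)
    rownames(data) <- NULL
    new("ClinicalTable", data = data)
}

#' @export
setMethod("clinicalData", "ClinicalTable", function(x) x@data)

#' @export
setMethod("sampleIds", "ClinicalTable", function(x) x@data$sample_id)

setMethod("show", "ClinicalTable", function(object) {
    d <- object@data
    cat(sprintf("ClinicalTable: %d samples, %d events (endpoint %s)\n",
                nrow(d), sum(d$surv_event, na.rm = TRUE),
                paste(unique(stats::na.omit(d$endpoint)), collapse = "/")))
    cat("  columns:", paste(names(d), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ActivityScores
## ---------------------------------------------------------------------------

#' Per-sample regulatory activity scores
#'
#' Result of \code{\link{computeIrasMatrix}}: for every sample the raw
#' signed differential-CDF score (iRAS, in [-1, 1]), the permutation
#' z-score, the empirical two-sided p-value and the activity group
#' (\code{positive} iff iRAS > 0).
#'
#' @slot results \code{DataFrame} with columns \code{sample_id},
#'   \code{iras}, \code{z}, \code{p_emp}, \code{group}.
#' @slot nPerm number of permutations behind \code{z} and \code{p_emp}.
#' @slot signatureName name of the scored signature.
#' @aliases ActivityScores iras,ActivityScores-method
#'   activityGroups,ActivityScores-method activityTable,ActivityScores-method
#'   sampleIds,ActivityScores-method
#' @seealso \code{\link{computeIrasMatrix}}, \code{\link{dichotomize}}
#' @exportClass ActivityScores
setClass("ActivityScores",
         slots = c(results = "DataFrame", nPerm = "integer",
                   signatureName = "character"))

setValidity("ActivityScores", function(object) {
    r <- object@results
    msg <- NULL
    need <- c("sample_id", "iras", "z", "p_emp", "group")
    if (!all(need %in% colnames(r)))
        return(sprintf("results must have columns: %s",
                       paste(need, collapse = ", ")))
    if (any(abs(r$iras) > 1 + 1e-12))
        msg <- c(msg, "|iras| must be <= 1")
    if (any(r$p_emp <= 0 | r$p_emp > 1, na.rm = TRUE))
        msg <- c(msg, "p_emp must lie in (0, 1]")
    if (length(object@nPerm) != 1L || object@nPerm < 1L)
        msg <- c(msg, "nPerm must be a single integer >= 1")
    pos <- r$iras > 0
    if (!all((r$group == "positive") == pos))
        msg <- c(msg, "group must be 'positive' iff iras > 0")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("iras", "ActivityScores",
          function(x) setNames(x@results$iras, x@results$sample_id))

#' @export
setMethod("activityGroups", "ActivityScores",
          function(x) setNames(factor(x@results$group,
                                      levels = c("negative", "positive")),
                               x@results$sample_id))

#' @export
setMethod("activityTable", "ActivityScores",
          function(x) as.data.frame(x@results))

#' @export
setMethod("sampleIds", "ActivityScores", function(x) x@results$sample_id)

setMethod("length", "ActivityScores", function(x) nrow(x@results))

setMethod("show", "ActivityScores", function(object) {
    r <- object@results
    cat(sprintf(
        "ActivityScores for '%s': %d samples (%d positive, %d negative), %d permutations\n",
        object@signatureName, nrow(r), sum(r$group == "positive"),
        sum(r$group == "negative"), object@nPerm))
    cat(sprintf("  iras range: [%.3f, %.3f]\n",
                min(r$iras), max(r$iras)))
})

## ---------------------------------------------------------------------------
## CentroidMatrix
## ---------------------------------------------------------------------------

#' Subtype-by-gene centroid expression matrix
#'
#' Published intrinsic-subtype centroids (for instance the five breast-cancer
#' centroids) against which samples are classified by Spearman correlation.
#'
#' @slot values numeric matrix, subtypes in rows, genes in columns.
#' @param values the centroid matrix (unique rownames, >= 2 genes).
#' @return a \code{CentroidMatrix}.
#' @seealso \code{\link{assignSubtypes}}, \code{\link{readCentroids}}
#' @aliases CentroidMatrix geneIds,CentroidMatrix-method
#'   subtypeNames,CentroidMatrix-method centroidValues,CentroidMatrix-method
#' @export CentroidMatrix
#' @exportClass CentroidMatrix
setClass("CentroidMatrix", slots = c(values = "matrix"))

setValidity("CentroidMatrix", function(object) {
    v <- object@values
    msg <- NULL
    if (!is.numeric(v)) msg <- c(msg, "centroid values must be numeric")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "subtype names must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (ncol(v) < 2L) msg <- c(msg, "at least 2 genes are required")
    if (is.null(msg)) TRUE else msg
})

CentroidMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("CentroidMatrix", values = values)
}

#' @export
setMethod("geneIds", "CentroidMatrix", function(x) colnames(x@values))

#' @export
setMethod("subtypeNames", "CentroidMatrix", function(x) rownames(x@values))

#' @export
setMethod("centroidValues", "CentroidMatrix", function(x) x@values)

setMethod("show", "CentroidMatrix", function(object) {
    cat(sprintf("CentroidMatrix: %d subtypes x %d genes\n",
                nrow(object@values), ncol(object@values)))
    cat("  subtypes:", paste(rownames(object@values), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## BindingWindowMatrix
## ---------------------------------------------------------------------------

#' Binned TSS-proximal binding signal
#'
#' Gene-by-position matrix of non-negative binding intensity binned over a
#' symmetric window around each gene's transcription start site, oriented
#' 5' to 3' (rows of minus-strand genes are already flipped).
#'
#' @slot signal numeric gene-by-bin matrix, non-negative.
#' @slot tss \code{GRanges} of 1-based TSS positions with strand and a
#'   \code{gene_id} metadata column, parallel to the rows of \code{signal}.
#' @slot windowHalfWidth half window width in bp.
#' @slot binSize bin width in bp; \code{ncol(signal) == 2*windowHalfWidth/binSize}.
#' @param signal,tss,windowHalfWidth,binSize see slots.
#' @return a \code{BindingWindowMatrix}.
#' @seealso \code{\link{bindingWindowMatrix}}, \code{\link{tipGeneScores}}
#' @aliases BindingWindowMatrix geneIds,BindingWindowMatrix-method
#' @export BindingWindowMatrix
#' @exportClass BindingWindowMatrix
setClass("BindingWindowMatrix",
         slots = c(signal = "matrix", tss = "GRanges",
                   windowHalfWidth = "numeric", binSize = "numeric"))

setValidity("BindingWindowMatrix", function(object) {
    msg <- NULL
    s <- object@signal
    if (!is.numeric(s)) msg <- c(msg, "signal must be numeric")
    else {
        if (any(!is.finite(s))) msg <- c(msg, "signal must be finite")
        else if (any(s < 0)) msg <- c(msg, "signal must be non-negative")
    }
    if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (length(object@tss) != nrow(s))
        msg <- c(msg, "tss must be parallel to the rows of signal")
    w <- object@windowHalfWidth; b <- object@binSize
    if (length(w) != 1L || w <= 0) msg <- c(msg, "windowHalfWidth must be > 0")
    if (length(b) != 1L || b <= 0) msg <- c(msg, "binSize must be > 0")
    if (length(w) == 1L && length(b) == 1L && w > 0 && b > 0 &&
        ncol(s) != 2 * w / b)
        msg <- c(msg, "ncol(signal) must equal 2*windowHalfWidth/binSize")
    if (is.null(msg)) TRUE else msg
})

BindingWindowMatrix <- function(signal, tss, windowHalfWidth, binSize) {
    signal <- as.matrix(signal)
    storage.mode(signal) <- "double"
    new("BindingWindowMatrix", signal = signal, tss = tss,
        windowHalfWidth = as.numeric(windowHalfWidth),
        binSize = as.numeric(binSize))
}

#' @export
setMethod("geneIds", "BindingWindowMatrix", function(x) rownames(x@signal))

setMethod("show", "BindingWindowMatrix", function(object) {
    cat(sprintf(
        "BindingWindowMatrix: %d genes x %d bins (+/- %d bp, %d bp bins)\n",
        nrow(object@signal), ncol(object@signal),
        as.integer(object@windowHalfWidth), as.integer(object@binSize)))
})

## ---------------------------------------------------------------------------
## TimeCourse
## ---------------------------------------------------------------------------

#' An evenly indexed activity or expression time course
#'
#' @slot times strictly increasing acquisition indices (>= 8 points).
#' @slot values finite series values (activity or expression units).
#' @param times,values see slots.
#' @return a \code{TimeCourse}.
#' @seealso \code{\link{fishersGTest}}
#' @aliases TimeCourse
#' @export TimeCourse
#' @exportClass TimeCourse
setClass("TimeCourse", slots = c(times = "numeric", values = "numeric"))

setValidity("TimeCourse", function(object) {
    msg <- NULL
    if (length(object@times) != length(object@values))
        msg <- c(msg, "times and values must have equal length")
    if (length(object@values) < 8L)
        msg <- c(msg, "at least 8 time points are required")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "values must be finite")
    if (any(!is.finite(object@times)) || is.unsorted(object@times, strictly = TRUE))
        msg <- c(msg, "times must be finite and strictly increasing")
    if (is.null(msg)) TRUE else msg
})

TimeCourse <- function(times, values) {
    new("TimeCourse", times = as.numeric(times), values = as.numeric(values))
}

setMethod("length", "TimeCourse", function(x) length(x@values))

setMethod("show", "TimeCourse", function(object) {
    cat(sprintf("TimeCourse: %d points over [%g, %g]\n",
                length(object@values), min(object@times), max(object@times)))
})

## ---------------------------------------------------------------------------
## CoxResult / EnrichmentResult
## ---------------------------------------------------------------------------

#' Cox proportional-hazards fit summary
#'
#' Per-covariate hazard ratios with standard errors on the log-HR scale,
#' 95 percent confidence intervals and Wald p-values; ties handled by the
#' Efron approximation.  The underlying \code{\link[survival]{coxph}} fit is
#' kept in the \code{fit} slot.
#'
#' @slot table data.frame with columns \code{term}, \code{hr}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{p}.
#' @slot n number of samples used.
#' @slot nEvents number of events.
#' @slot fit the \code{coxph} object.
#' @aliases CoxResult coxTable,CoxResult-method
#' @seealso \code{\link{fitCox}}
#' @exportClass CoxResult
setClass("CoxResult",
         slots = c(table = "data.frame", n = "integer", nEvents = "integer",
                   fit = "ANY"))

setValidity("CoxResult", function(object) {
    t <- object@table
    msg <- NULL
    if (!all(c("term", "hr", "se", "ci_low", "ci_high", "p") %in% names(t)))
        return("table must have columns term, hr, se, ci_low, ci_high, p")
    if (any(t$hr <= 0, na.rm = TRUE)) msg <- c(msg, "hazard ratios must be > 0")
    if (any(t$ci_low > t$hr | t$hr > t$ci_high, na.rm = TRUE))
        msg <- c(msg, "confidence interval must bracket the hazard ratio")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("coxTable", "CoxResult", function(x) x@table)

setMethod("show", "CoxResult", function(object) {
    cat(sprintf("CoxResult: %d samples, %d events\n", object@n, object@nEvents))
    t <- object@table
    for (i in seq_len(nrow(t)))
        cat(sprintf("  %-24s HR %.3f (95%% CI %.2f-%.2f), p = %.3g\n",
                    t$term[i], t$hr[i], t$ci_low[i], t$ci_high[i], t$p[i]))
})

#' Signature enrichment among survival-associated genes
#'
#' Ratio of the significant fraction inside a gene signature to the
#' significant fraction genome-wide, with a two-sided Fisher exact test on
#' the disjoint 2x2 table.
#'
#' @slot nTotal genes measured; @slot nSigTotal survival-significant genes;
#'   @slot mSet signature genes measured; @slot mSigSet significant signature
#'   genes; @slot fold ratio of proportions; @slot pFisher two-sided Fisher
#'   exact p.
#' @aliases EnrichmentResult
#' @seealso \code{\link{enrichmentFold}}
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
         slots = c(nTotal = "integer", nSigTotal = "integer", mSet = "integer",
                   mSigSet = "integer", fold = "numeric", pFisher = "numeric"))

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (object@mSigSet > object@mSet || object@mSet > object@nTotal)
        msg <- c(msg, "require mSigSet <= mSet <= nTotal")
    if (object@mSigSet > object@nSigTotal || object@nSigTotal > object@nTotal)
        msg <- c(msg, "require mSigSet <= nSigTotal <= nTotal")
    if (object@fold < 0) msg <- c(msg, "fold must be >= 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult: %d/%d in set vs %d/%d overall -> %.2f-fold (Fisher p = %.3g)\n",
        object@mSigSet, object@mSet, object@nSigTotal, object@nTotal,
        object@fold, object@pFisher))
})
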