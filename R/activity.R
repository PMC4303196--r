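## Per-sample regulatory activity: the iRAS statistic and its permutation
## null.  Genes are sorted by decreasing relative expression (ties broken
## lexicographically by gene id); two empirical CDFs track how fast the
## target and non-target sets accumulate down the ranking, and the score is
## the signed value of their difference at the first rank maximizing its
## absolute value.  |iRAS| is exactly the two-sample Kolmogorov-Smirnov D
## between target and non-target ranks; the sign is positive when targets
## concentrate at high expression.

## Rank positions (1-based, in decreasing-expression order) of the target
## genes; the permutation null re-draws these positions uniformly, which is
## valid because a tie-free ranking makes the null rank-distribution-free.
.iras_from_indicator <- function(isTarget) {
    m <- sum(isTarget)
    N <- length(isTarget)
    ct <- cumsum(isTarget)
    d <- ct / m - (seq_len(N) - ct) / (N - m)
    d[which.max(abs(d))]
}

.order_expression <- function(x) {
    order(-x, names(x), method = "radix")
}

#' Compute the iRAS of one sample
#'
#' @param x named numeric vector of per-gene relative expression for one
#'   sample (log-ratio semantics); missing values are dropped before
#'   ranking.
#' @param sig a \code{\linkS4class{TargetSignature}}; at least 2 of its
#'   genes and 2 non-members must be measured in \code{x}.
#' @param forceTies with all expression values equal the ranking is defined
#'   only by the lexicographic tie rule; this errors unless
#'   \code{forceTies = TRUE}, which returns the tie-rule result.
#' @return the signed score in [-1, 1]; positive when target genes
#'   concentrate at high relative expression.
#' @examples
#' x <- c(g1 = 5, g2 = 4, g3 = 1, g4 = 0)
#' computeIras(x, TargetSignature("sig", c("g1", "g2")))
#' @export
computeIras <- function(x, sig, forceTies = FALSE) {
    stopifnot(is(sig, "TargetSignature"))
    x <- x[!is.na(x)]
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("expression vector must have unique gene names")
    isT <- names(x) %in% geneIds(sig)
    if (sum(isT) < 2L)
        stop(sprintf("fewer than 2 usable target genes for signature '%s'",
                     sig@name))
    if (sum(!isT) < 2L)
        stop(sprintf("fewer than 2 usable non-target genes for signature '%s'",
                     sig@name))
    if (diff(range(x)) == 0 && !forceTies)
        stop("all expression values are equal; ranking is undefined beyond ",
             "the tie rule (set forceTies = TRUE to force)")
    .iras_from_indicator(isT[.order_expression(x)])
}

#' Permutation significance of an observed iRAS
#'
#' Null scores are computed for \code{nPerm} random gene sets of size
#' \code{sigSize} drawn without replacement from the sample's usable gene
#' universe.  The z-score standardizes the observed score against this
#' null; the empirical two-sided p-value uses the add-one estimator
#' \code{(1 + #(|null| >= |observed|)) / (nPerm + 1)}, so it is never 0.
#'
#' @param x the sample's expression vector (only its usable-gene count
#'   matters: the null is rank-distribution-free).
#' @param sigSize number of target genes (>= 2).
#' @param observed the observed signed score.
#' @param nPerm number of permutations (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @return list with elements \code{z} and \code{p_emp}.
#' @export
permutationSignificance <- function(x, sigSize, observed, nPerm = 10000,
                                    seed = NULL) {
    x <- x[!is.na(x)]
    N <- length(x)
    stopifnot(sigSize >= 2L, sigSize < N, nPerm >= 1L)
    if (!is.null(seed)) set.seed(seed)
    null <- cpp_perm_null(N, as.integer(sigSize), as.integer(nPerm))
    sdn <- sd(null)
    if (sdn == 0) stop("permutation null has zero standard deviation")
    list(z = (observed - mean(null)) / sdn,
         p_emp = (1 + sum(abs(null) >= abs(observed))) / (nPerm + 1))
}

#' Score regulatory activity for every sample of an expression matrix
#'
#' Computes the iRAS of each sample, its permutation z-score and empirical
#' p-value, and the activity group (\code{positive} iff iRAS > 0).  The
#' expression matrix must hold relative values
#' (\code{two_channel_logratio}); one-channel data must be passed through
#' \code{\link{medianCenter}} first.
#'
#' @param m a \code{\linkS4class{RegExprSet}}.
#' @param sig a \code{\linkS4class{TargetSignature}} overlapping the gene
#'   universe in >= 2 genes.
#' @param nPerm permutations per sample (default 10000).
#' @param seed optional RNG seed; identical seed and input give identical
#'   results.
#' @param shareNull when TRUE and all samples share the same usable-gene and
#'   target counts, one permutation null is drawn and reused for every
#'   sample (the null depends only on those counts).  Off by default.
#' @return an \code{\linkS4class{ActivityScores}} object.
#' @examples
#' sim <- genCohort(simConfig(nGenes = 300, nSamples = 20, seed = 7))
#' res <- computeIrasMatrix(sim$expr, sim$signature, nPerm = 200, seed = 1)
#' head(activityTable(res))
#' @export
computeIrasMatrix <- function(m, sig, nPerm = 10000, seed = NULL,
                              shareNull = FALSE) {
    stopifnot(is(m, "RegExprSet"), is(sig, "TargetSignature"), nPerm >= 1L)
    if (channelMode(m) != "two_channel_logratio")
        stop("expression must be relative (two_channel_logratio); ",
             "run medianCenter() on one-channel data first")
    v <- exprValues(m)
    if (sum(rownames(v) %in% geneIds(sig)) < 2L)
        stop(sprintf("signature '%s' overlaps the gene universe in < 2 genes",
                     sig@name))
    if (!is.null(seed)) set.seed(seed)
    ns <- ncol(v)
    scores <- numeric(ns)
    Ns <- integer(ns)
    ms <- integer(ns)
    for (j in seq_len(ns)) {
        x <- v[, j]
        x <- x[!is.na(x)]
        isT <- names(x) %in% geneIds(sig)
        if (sum(isT) < 2L || sum(!isT) < 2L)
            stop(sprintf("sample '%s' has < 2 usable target or non-target genes",
                         colnames(v)[j]))
        scores[j] <- .iras_from_indicator(isT[.order_expression(x)])
        Ns[j] <- length(x)
        ms[j] <- sum(isT)
    }
    z <- numeric(ns)
    p <- numeric(ns)
    if (shareNull && length(unique(Ns)) == 1L && length(unique(ms)) == 1L) {
        null <- cpp_perm_null(Ns[1L], ms[1L], as.integer(nPerm))
        mn <- mean(null); sdn <- sd(null)
        if (sdn == 0) stop("permutation null has zero standard deviation")
        absn <- abs(null)
        for (j in seq_len(ns)) {
            z[j] <- (scores[j] - mn) / sdn
            p[j] <- (1 + sum(absn >= abs(scores[j]))) / (nPerm + 1)
        }
    } else {
        for (j in seq_len(ns)) {
            null <- cpp_perm_null(Ns[j], ms[j], as.integer(nPerm))
            sdn <- sd(null)
            if (sdn == 0) stop("permutation null has zero standard deviation")
            z[j] <- (scores[j] - mean(null)) / sdn
            p[j] <- (1 + sum(abs(null) >= abs(scores[j]))) / (nPerm + 1)
        }
    }
    group <- ifelse(scores > 0, "positive", "negative")
    new("ActivityScores",
        results = DataFrame(sample_id = colnames(v), iras = scores, z = z,
                            p_emp = p, group = group),
        nPerm = as.integer(nPerm), signatureName = sig@name)
}

#' Dichotomize activity scores into positive and negative groups
#'
#' Samples with iRAS > 0 form the \code{positive} (high-activity) group and
#' the rest the \code{negative} group; a score of exactly 0 goes to
#' \code{negative}.
#'
#' @param x an \code{\linkS4class{ActivityScores}} object or a named numeric
#'   vector of raw scores.
#' @return a named factor with levels \code{negative}, \code{positive}.
#' @export
dichotomize <- function(x) {
    if (is(x, "ActivityScores")) x <- iras(x)
    stopifnot(is.numeric(x))
    setNames(factor(ifelse(x > 0, "positive", "negative"),
                    levels = c("negative", "positive")), names(x))
}
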