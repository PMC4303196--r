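## Intrinsic-subtype assignment by Spearman correlation to published
## centroids, and the subtype-by-activity composition table.

#' Assign intrinsic subtypes by centroid correlation
#'
#' Each sample's median-centred expression is correlated (Spearman) with
#' every centroid over the shared gene set; the sample is assigned to the
#' subtype with the highest coefficient, and excluded when every
#' correlation is below \code{corThreshold} (default 0.1).  One-channel
#' matrices are median-centred internally.  Correlation ties between
#' subtypes are broken by centroid file order and flagged.
#'
#' @param m a \code{\linkS4class{RegExprSet}}.
#' @param centroids a \code{\linkS4class{CentroidMatrix}}.
#' @param minOverlap minimum number of shared genes (default 10) below
#'   which rank correlations are considered degenerate.
#' @param corThreshold exclusion threshold on the best correlation.
#' @return data.frame with columns \code{sample_id}, \code{subtype} (factor
#'   over the centroid names plus \code{"excluded"}), \code{tie}, and one
#'   \code{cor_<subtype>} column per centroid.
#' @examples
#' sim <- genSubtypedCohort(nSamples = 30, seed = 11)
#' table(assignSubtypes(sim$expr, sim$centroids)$subtype)
#' @export
assignSubtypes <- function(m, centroids, minOverlap = 10, corThreshold = 0.1) {
    stopifnot(is(m, "RegExprSet"), is(centroids, "CentroidMatrix"))
    if (channelMode(m) == "one_channel_log")
        m <- medianCenter(m)
    cv <- centroidValues(centroids)
    shared <- intersect(geneIds(m), colnames(cv))
    if (!length(shared))
        stop("no genes shared between the expression matrix and the centroids")
    if (length(shared) < minOverlap)
        stop(sprintf("only %d shared gene(s) (< minOverlap = %d); rank correlations would be degenerate",
                     length(shared), minOverlap))
    v <- exprValues(m)[shared, , drop = FALSE]
    cv <- cv[, shared, drop = FALSE]
    subtypes <- rownames(cv)
    ns <- ncol(v)
    cors <- matrix(NA_real_, ns, length(subtypes),
                   dimnames = list(colnames(v), subtypes))
    assigned <- character(ns)
    tie <- logical(ns)
    for (j in seq_len(ns)) {
        x <- v[, j]
        ok <- !is.na(x)
        if (sum(ok) < minOverlap || diff(range(x[ok])) == 0) {
            warning(sprintf("sample '%s': correlation undefined (constant or too sparse); excluded",
                            colnames(v)[j]))
            assigned[j] <- "excluded"
            next
        }
        cc <- suppressWarnings(
            apply(cv[, ok, drop = FALSE], 1L, cor, y = x[ok],
                  method = "spearman"))
        cors[j, ] <- cc
        if (all(is.na(cc)) || max(cc, na.rm = TRUE) < corThreshold) {
            assigned[j] <- "excluded"
        } else {
            best <- which.max(cc)          # first centroid wins ties
            assigned[j] <- subtypes[best]
            tie[j] <- sum(cc == cc[best], na.rm = TRUE) > 1L
        }
    }
    out <- data.frame(sample_id = colnames(v),
                      subtype = factor(assigned,
                                       levels = c(subtypes, "excluded")),
                      tie = tie, stringsAsFactors = FALSE)
    colnames(cors) <- paste0("cor_", subtypes)
    cbind(out, as.data.frame(cors, row.names = NULL))
}

#' Activity composition of each subtype
#'
#' Counts of positive- and negative-activity samples per assigned subtype
#' (excluded samples are dropped; subtypes left empty after exclusion keep
#' a zero row).
#'
#' @param assignments data.frame from \code{\link{assignSubtypes}}.
#' @param activity an \code{\linkS4class{ActivityScores}} object for the
#'   same samples.
#' @return data.frame with columns \code{subtype}, \code{n_positive},
#'   \code{n_negative}, \code{fraction_positive} (NA for empty subtypes).
#' @export
subtypeActivityTable <- function(assignments, activity) {
    stopifnot(is.data.frame(assignments),
              all(c("sample_id", "subtype") %in% names(assignments)))
    grp <- if (is(activity, "ActivityScores")) activityGroups(activity)
           else activity
    onlyA <- setdiff(assignments$sample_id, names(grp))
    onlyB <- setdiff(names(grp), assignments$sample_id)
    if (length(onlyA) || length(onlyB))
        stop("sample id mismatch between assignments and activity; ",
             "only in assignments: [", paste(onlyA, collapse = ", "),
             "]; only in activity: [", paste(onlyB, collapse = ", "), "]")
    grp <- grp[assignments$sample_id]
    subtypes <- setdiff(levels(assignments$subtype), "excluded")
    keep <- assignments$subtype != "excluded"
    tab <- table(factor(assignments$subtype[keep], levels = subtypes),
                 factor(grp[keep], levels = c("negative", "positive")))
    npos <- as.integer(tab[, "positive"])
    nneg <- as.integer(tab[, "negative"])
    tot <- npos + nneg
    data.frame(subtype = subtypes,
               n_positive = npos,
               n_negative = nneg,
               fraction_positive = ifelse(tot > 0, npos / tot, NA_real_),
               stringsAsFactors = FALSE)
}
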