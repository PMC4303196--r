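## Readers and writers for the plain-text interchange formats: expression
## TSV (genes in rows), GMT gene sets, clinical CSV, centroid TSV.  All
## readers accept LF or CRLF line endings; values written with 17 significant
## digits so that write -> read round-trips doubles exactly.

.fmt_num <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Tab-separated text with gene identifiers in the first column and a header
#' row of sample identifiers.  Empty cells and \code{NA} are recorded as
#' missing, never as zero.
#'
#' @param path path to the TSV file.
#' @param channelMode \code{"two_channel_logratio"} for log-ratio data that
#'   is already relative, or \code{"one_channel_log"} for log absolute
#'   intensities that still need \code{\link{medianCenter}}.
#' @return a \code{\linkS4class{RegExprSet}}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0.5\t-0.5", "g2\t1\t0"), tf)
#' es <- readExpression(tf, "two_channel_logratio")
#' exprValues(es)
#' @export
readExpression <- function(path, channelMode = .CHANNEL_MODES) {
    channelMode <- match.arg(channelMode)
    d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
    if (ncol(d) < 2L)
        stop("expression file must have a gene column plus >= 1 sample column")
    genes <- d[[1L]]
    dup <- genes[duplicated(genes)]
    if (length(dup))
        stop(sprintf("duplicate gene identifier(s): %s",
                     paste(unique(dup), collapse = ", ")))
    samples <- colnames(d)[-1L]
    v <- matrix(NA_real_, nrow(d), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        raw <- d[[j + 1L]]
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(num) & !is.na(raw))
        if (length(bad))
            stop(sprintf(
                "non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
                raw[bad[1L]], genes[bad[1L]], bad[1L], samples[j]))
        v[, j] <- num
    }
    RegExprSet(v, channelMode)
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpression}}; missing values are written as
#' \code{NA} and doubles round-trip exactly.
#'
#' @param x a \code{\linkS4class{RegExprSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "RegExprSet"))
    v <- exprValues(x)
    body <- apply(v, 2, .fmt_num)
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(v))
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i], body[i, ]), collapse = "\t"),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read gene-set signatures from a GMT file
#'
#' Standard GMT dialect: one signature per line,
#' \code{name TAB description TAB gene TAB gene ...}.  Duplicate genes within
#' a line are removed.
#'
#' @param path path to the GMT file.
#' @return a list of \code{\linkS4class{TargetSignature}} objects (empty list
#'   for an empty file).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                         i, length(f)))
        out[[i]] <- TargetSignature(f[1L], f[-c(1L, 2L)])
    }
    names(out) <- vapply(out, function(s) s@name, character(1))
    out
}

#' Write signatures to a GMT file
#'
#' @param sigs a \code{\linkS4class{TargetSignature}} or list of them.
#' @param path output path.
#' @param description description field (recycled).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sigs, path, description = "regact signature") {
    if (is(sigs, "TargetSignature")) sigs <- list(sigs)
    description <- rep_len(description, length(sigs))
    lines <- vapply(seq_along(sigs), function(i)
        paste(c(sigs[[i]]@name, description[i], sigs[[i]]@genes),
              collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a per-sample clinical table from CSV
#'
#' See \code{\linkS4class{ClinicalTable}} for the documented column set;
#' unrecognised columns (for instance precomputed risk strata) are preserved.
#'
#' @param path path to the CSV file.
#' @return a \code{\linkS4class{ClinicalTable}}.
#' @export
readClinical <- function(path) {
    d <- read.csv(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE, na.strings = c("NA", ""))
    ClinicalTable(d)
}

#' Write a clinical table as CSV
#'
#' @param x a \code{\linkS4class{ClinicalTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(x, path) {
    stopifnot(is(x, "ClinicalTable"))
    d <- clinicalData(x)
    num <- vapply(d, is.double, logical(1))
    d[num] <- lapply(d[num], .fmt_num)
    write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
    invisible(path)
}

#' Read a subtype centroid matrix from TSV
#'
#' Tab-separated text with subtype names in the first column and a header
#' row of gene identifiers.
#'
#' @param path path to the TSV file.
#' @return a \code{\linkS4class{CentroidMatrix}}.
#' @export
readCentroids <- function(path) {
    d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("NA", ""))
    v <- as.matrix(d[, -1L, drop = FALSE])
    rownames(v) <- as.character(d[[1L]])
    CentroidMatrix(v)
}

#' Write a centroid matrix as TSV
#'
#' @param x a \code{\linkS4class{CentroidMatrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCentroids <- function(x, path) {
    stopifnot(is(x, "CentroidMatrix"))
    v <- centroidValues(x)
    lines <- c(paste(c("subtype", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i], .fmt_num(v[i, ])), collapse = "\t"),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Gene-wise median centring of one-channel expression
#'
#' One-channel arrays report log absolute intensities; subtracting each
#' gene's median across samples converts them into relative values
#' comparable to two-channel log-ratios, which is what the activity score
#' ranks.  Missing cells are ignored when computing the median and stay
#' missing.  Applying it to data that is already relative is almost always a
#' mistake (double normalization) and errors unless \code{force = TRUE};
#' with \code{force} the operation is idempotent.
#'
#' @param m a \code{\linkS4class{RegExprSet}}.
#' @param force allow centring a matrix whose channel mode is already
#'   \code{two_channel_logratio}.
#' @return a \code{\linkS4class{RegExprSet}} with per-gene median 0 and
#'   channel mode \code{two_channel_logratio}.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, 3,
#'             dimnames = list("g1", c("s1", "s2", "s3")))
#' exprValues(medianCenter(RegExprSet(m, "one_channel_log")))
#' @export
medianCenter <- function(m, force = FALSE) {
    stopifnot(is(m, "RegExprSet"))
    if (channelMode(m) == "two_channel_logratio" && !force)
        stop("matrix is already two_channel_logratio; re-centring would ",
             "double-normalize (use force = TRUE to override)")
    if (ncol(m) < 1L) stop("at least one sample is required")
    v <- exprValues(m)
    med <- apply(v, 1L, median, na.rm = TRUE)
    RegExprSet(v - med, "two_channel_logratio")
}
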