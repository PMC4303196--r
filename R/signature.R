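## Target-gene calling from TSS-proximal binding signal and consensus
## signature construction.  The probabilistic scoring scheme: the average
## binding profile across genes, normalized to sum 1, acts as a position
## weight; each gene's weighted signal sum is standardized across genes and
## an upper-tail normal p-value is corrected by Benjamini-Hochberg.

#' Read TSS annotation from BED or TSV
#'
#' BED input is 0-based half-open; the stored TSS is 1-based and
#' strand-aware (interval start for plus-strand genes, interval end for
#' minus-strand genes).  TSV input needs columns \code{gene_id},
#' \code{chrom}, \code{tss} (1-based), \code{strand}.
#'
#' @param path annotation file.
#' @param format \code{"bed"} (chrom, start, end, name, score, strand) or
#'   \code{"tsv"}.
#' @return a \code{GRanges} of width-1 TSS positions with a \code{gene_id}
#'   metadata column.
#' @export
readTssAnnotation <- function(path, format = c("bed", "tsv")) {
    format <- match.arg(format)
    if (format == "bed") {
        d <- read.delim(path, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE)
        if (ncol(d) < 6L)
            stop("BED annotation needs 6 columns (chrom, start, end, name, score, strand)")
        strand <- as.character(d[[6L]])
        tss <- ifelse(strand == "-", d[[3L]], d[[2L]] + 1L)  # 0-based -> 1-based
        gr <- GRanges(as.character(d[[1L]]), IRanges(tss, width = 1L),
                      strand = strand, gene_id = as.character(d[[4L]]))
    } else {
        d <- read.delim(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
        need <- c("gene_id", "chrom", "tss", "strand")
        if (!all(need %in% names(d)))
            stop("TSV annotation needs columns: ", paste(need, collapse = ", "))
        gr <- GRanges(as.character(d$chrom), IRanges(d$tss, width = 1L),
                      strand = as.character(d$strand),
                      gene_id = as.character(d$gene_id))
    }
    if (anyDuplicated(mcols(gr)$gene_id))
        stop("duplicate gene_id in TSS annotation")
    gr
}

#' Bin binding signal around transcription start sites
#'
#' Averages bedGraph-style coverage into fixed-width bins over
#' \code{[TSS - window, TSS + window)} for every annotated gene, orienting
#' each row 5' to 3' (minus-strand rows are reversed).  Bins without signal
#' are 0.
#'
#' @param tss a \code{GRanges} of TSS positions as returned by
#'   \code{\link{readTssAnnotation}}.
#' @param signal binding signal: a bedGraph file path or a \code{GRanges}
#'   with a numeric \code{score} column (non-negative).
#' @param windowHalfWidth half window width in bp (default 10000).
#' @param binSize bin width in bp (default 100); must divide
#'   \code{2*windowHalfWidth}.
#' @return a \code{\linkS4class{BindingWindowMatrix}}.
#' @export
bindingWindowMatrix <- function(tss, signal, windowHalfWidth = 10000,
                                binSize = 100) {
    stopifnot(is(tss, "GRanges"), length(tss) >= 1L)
    if ((2 * windowHalfWidth) %% binSize != 0)
        stop("binSize must divide 2*windowHalfWidth")
    if (is.character(signal))
        signal <- rtracklayer::import(signal, format = "bedGraph")
    stopifnot(is(signal, "GRanges"))
    sc <- score(signal)
    if (is.null(sc)) stop("signal must carry a numeric score")
    if (any(sc < 0)) stop("binding signal must be non-negative")

    nb <- as.integer(2 * windowHalfWidth / binSize)
    ng <- length(tss)
    pos <- BiocGenerics::start(tss)
    chrom <- as.character(GenomicRanges::seqnames(tss))
    ## genomic-frame bins for all genes at once
    binStart <- rep(pos - windowHalfWidth, each = nb) +
        rep.int(seq_len(nb) - 1L, ng) * binSize
    bins <- GRanges(rep(chrom, each = nb),
                    IRanges(start = binStart, width = binSize))
    hits <- findOverlaps(bins, signal)
    ov <- width(pintersect(bins[queryHits(hits)], signal[subjectHits(hits)]))
    contrib <- ov * sc[subjectHits(hits)] / binSize
    binned <- numeric(length(bins))
    agg <- tapply(contrib, queryHits(hits), sum)
    binned[as.integer(names(agg))] <- agg
    m <- matrix(binned, nrow = ng, ncol = nb, byrow = TRUE,
                dimnames = list(mcols(tss)$gene_id, NULL))
    neg <- as.character(strand(tss)) == "-"
    if (any(neg))
        m[neg, ] <- m[neg, nb:1, drop = FALSE]
    BindingWindowMatrix(m, tss, windowHalfWidth, binSize)
}

#' Score genes for TSS-proximal binding
#'
#' The column means of the binned signal across genes define a binding
#' weight profile (normalized to sum 1); each gene's score is its
#' weight-profile-weighted signal sum.  Scores are standardized across genes
#' and assigned upper-tail standard-normal p-values with
#' Benjamini-Hochberg correction.
#'
#' @param b a \code{\linkS4class{BindingWindowMatrix}} with >= 2 genes.
#' @return a \code{DataFrame} with columns \code{gene_id}, \code{score},
#'   \code{z}, \code{p}, \code{q}, ordered as the input genes.
#' @examples
#' sim <- genBindingData(nGenes = 200, nTargets = 20, seed = 1)
#' head(tipGeneScores(sim$binding))
#' @export
tipGeneScores <- function(b) {
    stopifnot(is(b, "BindingWindowMatrix"))
    s <- b@signal
    if (nrow(s) < 2L) stop("at least 2 genes are required")
    tot <- sum(s)
    if (tot == 0)
        stop("zero total signal across all genes; weight profile undefined")
    w <- colMeans(s)
    w <- w / sum(w)
    sc <- as.numeric(s %*% w)
    sdev <- sd(sc)
    if (sdev == 0)
        stop("gene scores have zero standard deviation; cannot standardize")
    z <- (sc - mean(sc)) / sdev
    p <- pnorm(z, lower.tail = FALSE)
    DataFrame(gene_id = rownames(s), score = sc, z = z, p = p,
              q = p.adjust(p, method = "BH"))
}

#' Call target genes at an FDR threshold
#'
#' Genes with Benjamini-Hochberg q below \code{fdr} (default 1 percent)
#' form the target set; \code{useRawP = TRUE} thresholds the raw upper-tail
#' p-value instead.
#'
#' @param scores a score table from \code{\link{tipGeneScores}}.
#' @param fdr FDR (or raw-p) threshold in (0, 1); default 0.01.
#' @param useRawP threshold the unadjusted p-value instead of q.
#' @param name name for the resulting signature.
#' @return a \code{\linkS4class{TargetSignature}}; empty (with a warning)
#'   when nothing passes.
#' @export
callTargets <- function(scores, fdr = 0.01, useRawP = FALSE,
                        name = "targets") {
    if (is.null(scores) || nrow(scores) == 0L)
        stop("empty score table")
    stopifnot(fdr > 0, fdr < 1)
    crit <- if (useRawP) scores$p else scores$q
    genes <- scores$gene_id[crit < fdr]
    if (!length(genes))
        warning(sprintf("no targets at %s < %g; returning an empty signature",
                        if (useRawP) "p" else "FDR", fdr))
    TargetSignature(name, genes, sources = setNames(list(genes), name))
}

#' Intersect per-source target signatures into a consensus
#'
#' The consensus signature is the set of genes called in every source (for
#' instance every cell line), in deterministic lexicographic order, with the
#' per-source sets preserved for provenance.
#'
#' @param sigs list of >= 2 \code{\linkS4class{TargetSignature}} objects.
#' @param name name for the consensus signature.
#' @return a \code{\linkS4class{TargetSignature}}; empty (with a warning)
#'   when the sources share no gene.
#' @export
intersectSignatures <- function(sigs, name = "consensus") {
    if (length(sigs) < 2L)
        stop("at least 2 signatures are required")
    stopifnot(all(vapply(sigs, is, logical(1), "TargetSignature")))
    genes <- sort(Reduce(intersect, lapply(sigs, geneIds)))
    if (!length(genes))
        warning("empty intersection; returning an empty signature")
    src <- lapply(sigs, geneIds)
    names(src) <- vapply(sigs, function(s) s@name, character(1))
    TargetSignature(name, genes, sources = src)
}
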