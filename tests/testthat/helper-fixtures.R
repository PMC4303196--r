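## Shared fixture builders; everything is generated in code.

mkExpr <- function(values, mode = "two_channel_logratio") {
    RegExprSet(values, mode)
}

## random gene-by-sample matrix with optional missing cells
randExpr <- function(ng = 50, ns = 10, naFrac = 0, seed = 1,
                     mode = "two_channel_logratio") {
    set.seed(seed)
    v <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(sprintf("g%04d", seq_len(ng)),
                                sprintf("s%03d", seq_len(ns))))
    if (naFrac > 0)
        v[sample(length(v), round(naFrac * length(v)))] <- NA
    RegExprSet(v, mode)
}

## extreme deviations of the target/non-target CDF difference; the signed
## score is only strictly antisymmetric when these do not tie in magnitude
dExtremes <- function(x, sig) {
    x <- x[!is.na(x)]
    isT <- names(x) %in% geneIds(sig)
    ind <- isT[order(-x, names(x), method = "radix")]
    m <- sum(ind); N <- length(ind)
    ct <- cumsum(ind)
    d <- ct / m - (seq_len(N) - ct) / (N - m)
    c(max(d), min(d))
}

## small valid clinical data frame
mkClinDf <- function(n = 4) {
    data.frame(sample_id = sprintf("s%03d", seq_len(n)),
               age = seq(45, length.out = n, by = 3),
               er_status = rep_len(c("positive", "negative"), n),
               grade = rep_len(1:3, n),
               tumor_size = seq(12, length.out = n, by = 4),
               ln_status = rep_len(c("negative", "positive"), n),
               surv_time = seq(10, length.out = n, by = 12),
               surv_event = rep_len(c(0L, 1L), n),
               endpoint = "RFS",
               stringsAsFactors = FALSE)
}
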