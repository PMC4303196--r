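## Fisher's g-test for a periodic component: the largest periodogram
## ordinate at the Fourier frequencies relative to total spectral power,
## with the exact null distribution under Gaussian white noise.

#' Fisher's g-test for periodicity
#'
#' The series is mean-removed (optionally linearly detrended), its
#' periodogram \eqn{I(\omega_k)} evaluated at the Fourier frequencies
#' \eqn{k = 1, \dots, q} with \eqn{q = \lfloor (n-1)/2 \rfloor}, and
#' \eqn{g = \max_k I(\omega_k) / \sum_k I(\omega_k)}.  The exact null
#' p-value is
#' \deqn{p = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1} \binom{q}{j} (1 - jg)^{q-1},}
#' clipped to [0, 1].  Unevenly spaced time points are rejected rather than
#' interpolated.
#'
#' @param tc a \code{\linkS4class{TimeCourse}} or a numeric series of >= 8
#'   evenly indexed, finite values.
#' @param detrend remove a linear trend (least squares) instead of only the
#'   mean.
#' @return list with \code{g}, \code{p}, and \code{freq_index} (the Fourier
#'   index k of the dominant ordinate, i.e. k cycles over the series).
#' @examples
#' t <- 0:47
#' fishersGTest(cos(2 * pi * t / 16))           # exact Fourier frequency
#' @export
fishersGTest <- function(tc, detrend = FALSE) {
    if (is(tc, "TimeCourse")) {
        dt <- diff(tc@times)
        if (any(abs(dt - dt[1L]) > 1e-8 * abs(dt[1L])))
            stop("time points must be evenly spaced; uneven series are ",
                 "rejected rather than interpolated")
        x <- tc@values
    } else {
        x <- as.numeric(tc)
    }
    n <- length(x)
    if (n < 8L) stop("at least 8 time points are required")
    if (any(!is.finite(x))) stop("series values must be finite")
    x <- x - mean(x)
    if (detrend) {
        idx <- seq_len(n)
        x <- residuals(lm(x ~ idx))
    }
    q <- (n - 1L) %/% 2L
    I <- (Mod(fft(x))^2 / n)[2:(q + 1L)]
    tot <- sum(I)
    if (tot <= 0 || diff(range(x)) == 0)
        stop("constant series: total spectral power is zero")
    g <- max(I) / tot
    jmax <- min(q, floor(1 / g))
    j <- seq_len(jmax)
    terms <- (-1)^(j - 1) * exp(lchoose(q, j) + (q - 1) * log1p(-j * g))
    terms[!is.finite(terms)] <- 0     # 1 - j*g == 0 boundary
    p <- min(max(sum(terms), 0), 1)
    list(g = g, p = p, freq_index = which.max(I))
}
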