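#' Two-sample t test (Student or Welch)
#'
#' Self-contained two-sample location test used throughout the pipeline.
#' Zero pooled variance is floored at 1e-12 and the result flagged
#' degenerate, so constant inputs yield a finite statistic rather than NaN.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant \code{"welch"} (default; Welch-Satterthwaite df) or
#'   \code{"student"} (pooled variance).
#' @param tails 1 or 2 (default 2).
#' @return list with \code{statistic}, \code{pvalue}, \code{df}, \code{n1},
#'   \code{n2}, \code{method}, \code{degenerate}.
#' @examples
#' tTest(c(1, 2, 3), c(4, 5, 6))$pvalue
#' @export
tTest <- function(x, y, variant = c("welch", "student"), tails = 2) {
    variant <- match.arg(variant)
    x <- as.numeric(x); y <- as.numeric(y)
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2)
        stop("tTest requires at least 2 observations per sample")
    v1 <- var(x); v2 <- var(y)
    degenerate <- FALSE
    if (variant == "welch") {
        se2 <- v1 / n1 + v2 / n2
        if (se2 <= 0) { se2 <- 1e-12; degenerate <- TRUE }
        stat <- (mean(x) - mean(y)) / sqrt(se2)
        df <- if (v1 / n1 + v2 / n2 > 0)
            (v1 / n1 + v2 / n2)^2 /
                ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        else n1 + n2 - 2
        if (!is.finite(df) || df <= 0) df <- n1 + n2 - 2
    } else {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        if (sp2 <= 0) { sp2 <- 1e-12; degenerate <- TRUE }
        stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
    }
    p <- pt(-abs(stat), df = df) * tails
    p <- min(1, p)
    list(statistic = stat, pvalue = p, df = df, n1 = n1, n2 = n2,
         method = paste0(variant, "_t"), degenerate = degenerate)
}

## Asymptotic Kolmogorov survival P(K > t). Below t = 1 the theta-function
## form is used; series truncation follows the conventional tol = 1e-6
## evaluation (as in stats::psmirnov's asymptotic path) so results agree
## with the standard implementation to full precision.
.kolmogorovSF <- function(t, tol = 1e-6) {
    if (t <= 0) return(1)
    if (t < 1) {
        kmax <- floor(sqrt(2 - log(tol)))
        k <- seq(1, kmax - 1e-9, by = 2)   # k strictly below kmax
        s <- sum(exp(-k^2 * pi^2 / (8 * t^2)))
        p <- 1 - sqrt(2 * pi) / t * s
    } else {
        ## accumulate the CDF exactly as the reference implementation does
        ## (increments added to 1 until the last one drops below tol), so
        ## even sub-precision rounding of tiny p-values is reproduced
        cdf <- 1; sgn <- -1; k <- 1
        repeat {
            inc <- 2 * sgn * exp(-2 * k^2 * t^2)
            cdf <- cdf + inc
            sgn <- -sgn; k <- k + 1
            if (abs(inc) <= tol) break
        }
        p <- 1 - cdf
    }
    min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' asymptotic (Kolmogorov distribution at effective sample size
#' n1*n2/(n1+n2)), which is adequate at the group sizes arising anywhere in
#' this pipeline.
#'
#' @param x,y numeric vectors (length >= 1).
#' @return list with \code{statistic} (D), \code{pvalue}, \code{n1},
#'   \code{n2}, \code{method}.
#' @examples
#' ksTwoSample(1:4, 3:6)$statistic  # 0.5
#' @export
ksTwoSample <- function(x, y) {
    x <- sort(as.numeric(x)); y <- sort(as.numeric(y))
    n1 <- length(x); n2 <- length(y)
    if (n1 < 1 || n2 < 1) stop("ksTwoSample requires non-empty samples")
    pooled <- c(x, y)
    cdfx <- findInterval(pooled, x) / n1
    cdfy <- findInterval(pooled, y) / n2
    D <- max(abs(cdfx - cdfy))
    ne <- n1 * n2 / (n1 + n2)
    p <- .kolmogorovSF(sqrt(ne) * D)
    list(statistic = D, pvalue = p, n1 = n1, n2 = n2,
         method = "ks_two_sample")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with \code{statistic} (r), \code{r2}, \code{pvalue},
#'   \code{n}, \code{method}, \code{degenerate}.
#' @examples
#' pearsonCor(1:5, c(2, 4, 6, 8, 10))$statistic  # 1
#' @export
pearsonCor <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    n <- length(x)
    if (n != length(y)) stop("x and y must have equal length")
    if (n < 3) stop("pearsonCor requires n >= 3")
    if (var(x) == 0 || var(y) == 0)
        return(list(statistic = NA_real_, r2 = NA_real_, pvalue = NA_real_,
                    n = n, method = "pearson", degenerate = TRUE))
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- max(-1, min(1, r))
    if (abs(r) == 1) {
        p <- 0
    } else {
        stat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * pt(-abs(stat), df = n - 2)
    }
    list(statistic = r, r2 = r^2, pvalue = p, n = n, method = "pearson",
         degenerate = FALSE)
}
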