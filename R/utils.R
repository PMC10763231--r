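## Shared numerical helpers: rank correlation, seed derivation, ARI.

#' Spearman rank correlation with a significance test
#'
#' Midranks are used for ties; the default p-value comes from the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom (adequate for n >= 10).  `method = "exact"`
#' enumerates all `n!` rank permutations (intended for n < 10) and reports
#' the two-sided tail probability of `|rho|`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param method `"t"` (default), `"exact"`, or `"auto"` (exact when n < 10).
#' @return List with `rho`, `p`, `n`, `method`.
#' @examples
#' spearmanTest(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanTest <- function(x, y, method = c("t", "exact", "auto")) {
    method <- match.arg(method)
    stopifnot(length(x) == length(y))
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3) stop("spearmanTest needs at least 3 paired observations")
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
    rho <- stats::cor(rx, ry)
    if (method == "auto") method <- if (n < 10) "exact" else "t"
    if (method == "t") {
        r <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    } else {
        perms <- .allPermutations(n)
        ryp <- matrix(ry[perms], nrow = nrow(perms))
        rxc <- rx - mean(rx)
        num <- as.vector(ryp %*% rxc)
        den <- sqrt(sum(rxc^2)) * stats::sd(ry) * sqrt(n - 1)
        rhos <- num / den
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    }
    list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Pearson correlation with the two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List with `r`, `p`, `n`.
#' @export
pearsonTest <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 4) stop("pearsonTest needs at least 4 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, p = NA_real_, n = n))
    r <- stats::cor(x, y)
    rc <- min(max(r, -1 + 1e-15), 1 - 1e-15)
    tstat <- rc * sqrt((n - 2) / (1 - rc^2))
    list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

## All permutations of 1..n as a matrix (n! rows); n <= 9 guarded.
.allPermutations <- function(n) {
    if (n > 9) stop("exact enumeration limited to n <= 9")
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- .allPermutations(n - 1)
    out <- matrix(0L, nrow(sub) * n, n)
    k <- 0L
    for (pos in seq_len(n)) {
        block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                       sub[, seq.int(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
        out[k + seq_len(nrow(sub)), ] <- as.matrix(block)
        k <- k + nrow(sub)
    }
    out
}

#' Derive a stage-local seed from the master seed
#'
#' Every randomized stage of the pipeline draws its seed deterministically
#' from the master seed and a stage name, so stages stay reproducible and
#' independent of execution order.  Result is kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
deriveSeed <- function(seed, stage) {
    h <- as.double(seed) %% 2147483647
    for (code in utf8ToInt(stage))
        h <- (h * 31 + code) %% 2147483647
    as.integer(h)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted structure (functional groups, host
#' modules) against generator truth; 1 means identical partitions up to
#' label names, 0 the chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjustedRandIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(length(a), 2)
    expected <- ai * bj / n2
    maxi <- (ai + bj) / 2
    if (maxi == expected) return(1)
    (nij - expected) / (maxi - expected)
}

## Significance tier annotation used by the module association heatmaps.
.pTier <- function(p) {
    ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*",
    ifelse(p < 0.1, "$", ""))))
}

## Permutation p-value on the (b+1)/(B+1) lattice.
.permP <- function(permStats, observed, tail = c("greater", "less", "two.sided")) {
    tail <- match.arg(tail)
    eps <- 1e-12
    b <- switch(tail,
                greater = sum(permStats >= observed - eps),
                less = sum(permStats <= observed + eps),
                two.sided = sum(abs(permStats) >= abs(observed) - eps))
    (b + 1) / (length(permStats) + 1)
}
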