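## Alpha diversity, rarefaction, Bray-Curtis, PCoA and the permutation
## tests (PERMANOVA, ANOSIM).  Permutation p-values always follow the
## (b + 1)/(B + 1) rule, counting the observed statistic among the
## permutations, so the smallest attainable p is 1/(B + 1).

#' Alpha diversity indices (ACE, Chao1, Shannon, Simpson)
#'
#' Shannon is computed with the natural log; Simpson as the Gini-Simpson
#' index `1 - sum(p_i^2)`; Chao1 in its bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`; ACE as the abundance-based
#' coverage estimator with the conventional rare-species cutoff of 10.
#' ACE and Chao1 are defined on integer counts: non-integer input is
#' rounded with a warning.
#'
#' @param counts Non-negative count vector, or a samples-by-features
#'   matrix / raw [FeatureProfile-class] (one result row per sample).
#' @param rareCutoff ACE rare-species abundance cutoff (default 10).
#' @return data.frame with columns `sample_id`, `observed`, `ace`,
#'   `chao1`, `shannon`, `simpson`.
#' @examples
#' alphaDiversity(c(5, 3, 1, 1))
#' @export
alphaDiversity <- function(counts, rareCutoff = 10) {
    if (is(counts, "FeatureProfile")) counts <- profileValues(counts)
    if (is.null(dim(counts))) {
        counts <- matrix(counts, 1, dimnames = list("sample", NULL))
    }
    out <- lapply(seq_len(nrow(counts)), function(i)
        .alphaRow(counts[i, ], rareCutoff))
    res <- do.call(rbind, out)
    data.frame(sample_id = rownames(counts), res, stringsAsFactors = FALSE,
               row.names = NULL)
}

.alphaRow <- function(x, rareCutoff) {
    if (any(x < 0) || all(x == 0))
        stop("alpha diversity needs non-negative counts with at least one positive")
    x <- x[x > 0]
    if (any(abs(x - round(x)) > 1e-8)) {
        warning("non-integer counts rounded for ACE/Chao1")
    }
    xi <- round(x)
    xi <- xi[xi > 0]
    p <- x / sum(x)
    shannon <- -sum(p * log(p))
    simpson <- 1 - sum(p^2)
    sObs <- length(xi)
    f1 <- sum(xi == 1); f2 <- sum(xi == 2)
    chao1 <- sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
    ## ACE: split at the rare cutoff
    rare <- xi[xi <= rareCutoff]
    sAbund <- sum(xi > rareCutoff)
    sRare <- length(rare)
    nRare <- sum(rare)
    if (sRare == 0) {
        ace <- sObs
    } else if (f1 == nRare) {
        ## sample coverage 0 (all rare species are singletons): undefined
        ace <- NA_real_
    } else {
        cAce <- 1 - f1 / nRare
        fk <- tabulate(rare, nbins = rareCutoff)
        g2 <- max(sRare / cAce * sum(seq_len(rareCutoff) *
                                     (seq_len(rareCutoff) - 1) * fk) /
                  (nRare * (nRare - 1)) - 1, 0)
        ace <- sAbund + sRare / cAce + f1 / cAce * g2
    }
    data.frame(observed = sObs, ace = ace, chao1 = chao1,
               shannon = shannon, simpson = simpson)
}

#' Analytic rarefaction curve
#'
#' Expected richness in a random subsample of `d` reads without
#' replacement: `E[S(d)] = sum_i (1 - choose(N - n_i, d)/choose(N, d))`,
#' evaluated with log-binomials for stability.
#'
#' @param counts Non-negative integer count vector.
#' @param depths Subsampling depths, each `<= sum(counts)`.
#' @return data.frame with columns `depth`, `expected_richness`.
#' @examples
#' rarefactionCurve(c(2, 2), depths = c(1, 2, 4))
#' @export
rarefactionCurve <- function(counts, depths) {
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
        stop("rarefaction needs non-negative integer counts")
    counts <- round(counts[counts > 0])
    N <- sum(counts)
    if (any(depths > N))
        stop("depth exceeds the total count (", N, ")")
    if (any(depths < 1)) stop("depths must be at least 1")
    er <- vapply(depths, function(d) {
        lp <- lchoose(N - counts, d) - lchoose(N, d)
        sum(1 - exp(lp))
    }, numeric(1))
    data.frame(depth = depths, expected_richness = er)
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over all features; a pair
#' of all-zero samples has an undefined distance and is rejected.
#'
#' @param profile A [FeatureProfile-class] or samples-by-features matrix.
#' @return Symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @export
brayCurtis <- function(profile) {
    m <- if (is(profile, "FeatureProfile")) profileValues(profile) else
        as.matrix(profile)
    if (nrow(m) < 2) stop("need at least 2 samples")
    if (any(m < 0)) stop("Bray-Curtis needs non-negative values")
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
            tot <- sum(m[i, ] + m[j, ])
            if (tot == 0)
                stop(sprintf("samples '%s' and '%s' are both all-zero",
                             rownames(m)[i], rownames(m)[j]))
            d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / tot
        }
    }
    d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.
#' Axes are ordered by eigenvalue; coordinates are returned for the
#' positive eigenvalues only, and negative eigenvalues are reported but
#' excluded from the proportion-explained denominator.
#'
#' @param dist Symmetric distance matrix with zero diagonal (n >= 3).
#' @return List with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, sorted decreasing), `proportion_explained`
#'   (over positive eigenvalues).
#' @export
pcoa <- function(dist) {
    d <- as.matrix(dist)
    .checkDistanceMatrix(d)
    n <- nrow(d)
    if (n < 3) stop("PCoA needs at least 3 samples")
    A <- -0.5 * d^2
    J <- diag(n) - matrix(1 / n, n, n)
    B <- J %*% A %*% J
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    vals <- eig$values
    pos <- which(vals > max(vals) * 1e-10 & vals > 0)
    coords <- eig$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(vals[pos]), length(pos))
    dimnames(coords) <- list(rownames(d),
                             paste0("PCo", seq_along(pos)))
    list(coordinates = coords, eigenvalues = vals,
         proportion_explained = vals[pos] / sum(vals[pos]))
}

.checkDistanceMatrix <- function(d) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
        stop("distance matrix must be symmetric")
    if (max(abs(diag(d))) > 1e-12)
        stop("distance matrix must have a zero diagonal")
    if (any(d < 0)) stop("distances must be non-negative")
    invisible(d)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic from between/within sums of squared distances, with a
#' p-value from `B` free label permutations under the (b+1)/(B+1) rule.
#'
#' @param dist Symmetric distance matrix.
#' @param labels Group labels, one per sample (>= 2 groups, each with
#'   >= 2 samples).
#' @param B Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List with `statistic` (pseudo-F), `p_value`, `n_permutations`,
#'   `method = "permanova"`.
#' @export
permanova <- function(dist, labels, B = 999, seed = NULL) {
    d <- as.matrix(dist)
    .checkDistanceMatrix(d)
    labels <- as.character(labels)
    .checkGroups(labels, nrow(d))
    if (!is.null(seed)) set.seed(seed)
    d2 <- d^2
    n <- nrow(d)
    aGroups <- length(unique(labels))
    obs <- .pseudoF(d2, labels, n, aGroups)
    perm <- vapply(seq_len(B), function(b)
        .pseudoF(d2, sample(labels), n, aGroups), numeric(1))
    list(statistic = obs, p_value = .permP(perm, obs, "greater"),
         n_permutations = B, method = "permanova")
}

.pseudoF <- function(d2, labels, n, aGroups) {
    ssTotal <- sum(d2[upper.tri(d2)]) / n
    ssWithin <- 0
    for (g in unique(labels)) {
        idx <- which(labels == g)
        sub <- d2[idx, idx, drop = FALSE]
        ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ssBetween <- ssTotal - ssWithin
    (ssBetween / (aGroups - 1)) / (ssWithin / (n - aGroups))
}

.checkGroups <- function(labels, n) {
    if (length(labels) != n)
        stop("one label per sample required")
    tab <- table(labels)
    if (length(tab) < 2)
        stop("at least 2 groups required")
    if (any(tab < 2))
        stop("every group needs at least 2 samples")
    invisible(labels)
}

#' ANOSIM on a distance matrix
#'
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` pairwise distances ranked with midranks; p-value from
#' `B` label permutations under the (b+1)/(B+1) rule.
#'
#' @inheritParams permanova
#' @return List with `statistic` (ANOSIM R in [-1, 1]), `p_value`,
#'   `n_permutations`, `method = "anosim"`.
#' @export
anosim <- function(dist, labels, B = 999, seed = NULL) {
    d <- as.matrix(dist)
    .checkDistanceMatrix(d)
    labels <- as.character(labels)
    .checkGroups(labels, nrow(d))
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(d)
    ut <- upper.tri(d)
    rk <- rank(d[ut])                      # midranks on ties
    M <- n * (n - 1) / 2
    pairRows <- row(d)[ut]; pairCols <- col(d)[ut]
    statOf <- function(lab) {
        between <- lab[pairRows] != lab[pairCols]
        (mean(rk[between]) - mean(rk[!between])) / (M / 2)
    }
    obs <- statOf(labels)
    perm <- vapply(seq_len(B), function(b) statOf(sample(labels)), numeric(1))
    list(statistic = obs, p_value = .permP(perm, obs, "greater"),
         n_permutations = B, method = "anosim")
}

#' One-way ANOVA with Tukey honest significant differences
#'
#' Thin convenience wrapper used for three-group comparisons of ratios or
#' diversity indices.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @return List with the ANOVA `p_value` and the Tukey pairwise table.
#' @export
tukeyComparison <- function(values, groups) {
    df <- data.frame(y = values, g = factor(groups))
    fit <- stats::aov(y ~ g, data = df)
    tk <- stats::TukeyHSD(fit)$g
    list(p_value = summary(fit)[[1]][["Pr(>F)"]][1],
         tukey = data.frame(comparison = rownames(tk), tk,
                            row.names = NULL, check.names = FALSE))
}
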