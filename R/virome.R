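## Virome-bacteriome coupling: alpha-diversity correlation, the Mantel
## test on beta-diversity matrices, and the taxon-phage correlation grid.

#' Correlate viral and bacterial alpha diversity
#'
#' Spearman correlation (midranks, t-approximation p-value) between the
#' matching alpha-diversity columns of the viral and bacterial tables.
#'
#' @param alphaViral,alphaBacterial data.frames from [alphaDiversity()]
#'   over the same samples.
#' @param indices Index columns to correlate (default all four).
#' @return data.frame with columns `index`, `rho`, `p`, `n`.
#' @export
alphaCoupling <- function(alphaViral, alphaBacterial,
                          indices = c("ace", "chao1", "shannon", "simpson")) {
    if (!setequal(alphaViral$sample_id, alphaBacterial$sample_id))
        stop("sample ids of the two alpha tables do not match")
    if (nrow(alphaViral) < 5) stop("need at least 5 samples")
    ord <- match(alphaViral$sample_id, alphaBacterial$sample_id)
    out <- lapply(indices, function(ix) {
        st <- spearmanTest(alphaViral[[ix]], alphaBacterial[[ix]][ord])
        data.frame(index = ix, rho = st$rho, p = st$p, n = st$n)
    })
    do.call(rbind, out)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, Pearson optional) over the
#' `n(n-1)/2` off-diagonal pairs, with a one-sided (greater) permutation
#' p-value from permuting one matrix's sample order, on the
#' (b+1)/(B+1) lattice.
#'
#' @param distA,distB Symmetric distance matrices over the same samples
#'   in the same order (n >= 5).
#' @param B Number of permutations (default 999).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed Optional permutation seed.
#' @return List with `r`, `p`, `n_permutations`, `method`.
#' @export
mantelTest <- function(distA, distB, B = 999,
                       method = c("spearman", "pearson"), seed = NULL) {
    method <- match.arg(method)
    a <- as.matrix(distA); b <- as.matrix(distB)
    .checkDistanceMatrix(a)
    .checkDistanceMatrix(b)
    if (nrow(a) != nrow(b)) stop("distance matrices differ in size")
    if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
        !identical(rownames(a), rownames(b)))
        stop("distance matrices must cover the same samples in the same order")
    n <- nrow(a)
    if (n < 5) stop("Mantel test needs at least 5 samples")
    if (!is.null(seed)) set.seed(seed)
    ut <- upper.tri(a)
    xa <- a[ut]
    if (method == "spearman") xa <- rank(xa)
    corOf <- function(bm) {
        xb <- bm[ut]
        if (method == "spearman") xb <- rank(xb)
        stats::cor(xa, xb)
    }
    obs <- corOf(b)
    perm <- vapply(seq_len(B), function(i) {
        p <- sample(n)
        corOf(b[p, p])
    }, numeric(1))
    list(r = obs, p = .permP(perm, obs, "greater"),
         n_permutations = B, method = method)
}

#' Pairwise bacterial-taxon / phage-taxon Spearman correlations
#'
#' Spearman rho and t-approximation p for every (bacterial taxon, viral
#' taxon) pair; constant features yield `NA` entries rather than errors.
#' BH correction of the p grid is available behind a flag (default off).
#'
#' @param bactProfile,viralProfile [FeatureProfile-class] objects (or
#'   samples-by-taxa matrices) over the same samples.
#' @param bhCorrect Apply Benjamini-Hochberg correction across all pairs.
#' @return List with matrices `rho` and `p` (bacterial taxa x viral taxa).
#' @export
taxonPhageCorrelations <- function(bactProfile, viralProfile,
                                   bhCorrect = FALSE) {
    bm <- if (is(bactProfile, "FeatureProfile")) profileValues(bactProfile)
          else as.matrix(bactProfile)
    vm <- if (is(viralProfile, "FeatureProfile")) profileValues(viralProfile)
          else as.matrix(viralProfile)
    if (!identical(rownames(bm), rownames(vm)))
        stop("bacterial and viral profiles must cover the same samples")
    rho <- matrix(NA_real_, ncol(bm), ncol(vm),
                  dimnames = list(colnames(bm), colnames(vm)))
    p <- rho
    for (i in seq_len(ncol(bm))) {
        for (j in seq_len(ncol(vm))) {
            if (stats::sd(bm[, i]) == 0 || stats::sd(vm[, j]) == 0) next
            st <- spearmanTest(bm[, i], vm[, j])
            rho[i, j] <- st$rho
            p[i, j] <- st$p
        }
    }
    if (bhCorrect) p[] <- stats::p.adjust(p, "BH")
    list(rho = rho, p = p)
}
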