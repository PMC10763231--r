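## Core-taxon selection, signed Spearman co-occurrence networks, the
## random-matrix-theory threshold scan, and the two-group partition.

#' Select core taxa present in every diet-by-week cell
#'
#' Candidates are the `topN` taxa by overall mean relative abundance; the
#' core set keeps the candidates whose mean abundance exceeds
#' `presenceRule` in every diet-by-week cell.  Also reports, per cell, the
#' fraction of total abundance contributed by the core set.
#'
#' @param profile A relative [FeatureProfile-class] (typically genus level).
#' @param meta Validated sample metadata covering all profile samples.
#' @param topN Candidate pool size (default 30).
#' @param presenceRule Per-cell mean-abundance detection threshold
#'   (default 0: any presence).
#' @return List with `core` (character), `candidates`, and `contribution`
#'   (data.frame diet, week, fraction of abundance from core taxa).
#' @export
coreTaxa <- function(profile, meta, topN = 30, presenceRule = 0) {
    stopifnot(is(profile, "FeatureProfile"))
    meta <- validateSampleMetadata(meta)
    m <- profileValues(profile)
    if (!all(rownames(m) %in% meta$sample_id))
        stop("metadata does not cover all profile samples")
    meta <- meta[match(rownames(m), meta$sample_id), ]
    cellOf <- interaction(meta$diet, meta$week, drop = TRUE)
    if (any(table(cellOf) == 0)) stop("empty diet-by-week cell")
    cand <- names(sort(colMeans(m), decreasing = TRUE))
    cand <- utils::head(cand, topN)
    inEveryCell <- vapply(cand, function(tx) {
        all(tapply(m[, tx], cellOf, mean) > presenceRule)
    }, logical(1))
    core <- cand[inEveryCell]
    contrib <- do.call(rbind, lapply(levels(cellOf), function(cl) {
        idx <- cellOf == cl
        data.frame(cell = cl,
                   fraction = sum(m[idx, core, drop = FALSE]) /
                       sum(m[idx, , drop = FALSE]))
    }))
    list(core = core, candidates = cand, contribution = contrib)
}

#' Signed Spearman co-occurrence network
#'
#' All taxon pairs are tested with Spearman's rank correlation (midranks
#' on ties; p from the t approximation by default, exact enumeration for
#' small n on request).  An edge is kept when `|rho| > rMin` and
#' `p < pMax`; negative edges are co-exclusions.  Constant (zero-variance)
#' taxa are excluded with a warning.  No multiple-testing correction is
#' applied by default; `bhCorrect = TRUE` switches the cutoff to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param profile A [FeatureProfile-class] or samples-by-taxa matrix
#'   (>= 5 samples, >= 2 taxa).
#' @param rMin Correlation threshold (default 0.5).
#' @param pMax p-value cutoff (default 0.05).
#' @param pMethod `"t"` (default) or `"exact"` Spearman p-values.
#' @param bhCorrect Apply Benjamini-Hochberg correction before the p
#'   cutoff (default FALSE).
#' @return A [CooccurrenceNetwork-class].
#' @export
correlationNetwork <- function(profile, rMin = 0.5, pMax = 0.05,
                               pMethod = c("t", "exact"), bhCorrect = FALSE) {
    pMethod <- match.arg(pMethod)
    m <- if (is(profile, "FeatureProfile")) profileValues(profile) else
        as.matrix(profile)
    if (nrow(m) < 5) stop("need at least 5 samples")
    if (ncol(m) < 2) stop("need at least 2 taxa")
    keep <- apply(m, 2, function(x) stats::sd(x) > 0)
    if (any(!keep)) {
        warning("excluding constant taxa: ",
                paste(colnames(m)[!keep], collapse = ", "))
        m <- m[, keep, drop = FALSE]
    }
    taxa <- colnames(m)
    pairs <- utils::combn(taxa, 2)
    res <- apply(pairs, 2, function(pr) {
        st <- spearmanTest(m[, pr[1]], m[, pr[2]], method = pMethod)
        c(rho = st$rho, p = st$p)
    })
    edges <- data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
                        rho = res["rho", ], p = res["p", ],
                        stringsAsFactors = FALSE)
    if (bhCorrect) edges$p <- stats::p.adjust(edges$p, "BH")
    edges <- edges[abs(edges$rho) > rMin & edges$p < pMax, , drop = FALSE]
    edges$sign <- ifelse(edges$rho < 0, "co-exclusion", "co-occurrence")
    rownames(edges) <- NULL
    nodes <- data.frame(node = taxa, mean_abundance = colMeans(m),
                        row.names = NULL, stringsAsFactors = FALSE)
    new("CooccurrenceNetwork", nodes = nodes, edges = edges,
        thresholdUsed = rMin, pMax = pMax)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans a grid of candidate thresholds; at each, entries below the
#' threshold are zeroed, the eigenvalue spectrum is unfolded with a
#' smoothing spline, and the nearest-neighbour spacing distribution is
#' compared (chi-square on fixed bins) against the Poisson law
#' `exp(-s)` (uncorrelated, modular spectrum) versus the Wigner-Dyson
#' (GOE) law.  The smallest threshold whose spacings fit Poisson better
#' is returned; if none qualifies, `fallback` is returned with a warning.
#'
#' @param corr Square symmetric correlation matrix with unit diagonal
#'   (>= 10 taxa).
#' @param grid Candidate thresholds (default 0.30 to 0.90 by 0.01).
#' @param fallback Threshold returned when no grid value qualifies
#'   (default 0.5, the fixed-rule default).
#' @return List with `threshold`, `from_rmt` (logical), and the per-grid
#'   diagnostics in `scan`.
#' @export
rmtThreshold <- function(corr, grid = seq(0.30, 0.90, by = 0.01),
                         fallback = 0.5) {
    corr <- as.matrix(corr)
    if (nrow(corr) < 10)
        stop("matrix too small for the RMT scan; use the fixed threshold")
    if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8)
        stop("expected a symmetric correlation matrix with unit diagonal")
    scan <- do.call(rbind, lapply(grid, function(t0) {
        fit <- .spacingFit(corr, t0)
        data.frame(threshold = t0, chi2_poisson = fit["poisson"],
                   chi2_wigner = fit["wigner"])
    }))
    ok <- is.finite(scan$chi2_poisson) & is.finite(scan$chi2_wigner) &
        scan$chi2_poisson < scan$chi2_wigner
    if (!any(ok)) {
        warning("no threshold produced Poisson-like spacings; ",
                "falling back to ", fallback)
        return(list(threshold = fallback, from_rmt = FALSE, scan = scan))
    }
    list(threshold = min(scan$threshold[ok]), from_rmt = TRUE, scan = scan)
}

## Chi-square goodness of fit of unfolded eigenvalue spacings against the
## Poisson and Wigner-Dyson laws; NA when the spectrum is degenerate.
.spacingFit <- function(corr, t0) {
    ct <- corr
    ct[abs(ct) < t0] <- 0
    diag(ct) <- 1
    ev <- sort(eigen(ct, symmetric = TRUE, only.values = TRUE)$values)
    ev <- unique(round(ev, 10))
    nEv <- length(ev)
    if (nEv < 10) return(c(poisson = NA_real_, wigner = NA_real_))
    ## unfold with a smoothing spline through the cumulative density
    sp <- stats::smooth.spline(ev, seq_along(ev) / nEv, df = min(10, nEv - 2))
    unf <- stats::predict(sp, ev)$y * nEv
    s <- diff(unf)
    s <- s[s > 0]
    if (length(s) < 8) return(c(poisson = NA_real_, wigner = NA_real_))
    s <- s / mean(s)
    breaks <- c(seq(0, 3, by = 0.5), Inf)
    obsN <- as.vector(table(cut(s, breaks)))
    pPois <- diff(stats::pexp(breaks, rate = 1))
    pWig <- diff(1 - exp(-pi * breaks^2 / 4))
    chi2 <- function(p) {
        e <- length(s) * p
        sum((obsN - e)^2 / pmax(e, 1e-9))
    }
    c(poisson = chi2(pPois), wigner = chi2(pWig))
}

#' Partition network nodes into two functional groups
#'
#' Scores a bipartition by summing, over the edges, `+|rho|` when the edge
#' is consistent with it (positive within a group, negative across) and
#' `-|rho|` otherwise, and maximizes the score: exhaustively over all
#' bipartitions for networks of up to 15 nodes, otherwise by sign-guided
#' agglomeration refined with local moves from 20 seeded random restarts.
#' Group `G_A` is the group containing the first node; among equal-score
#' partitions the lexicographically smallest `G_A` membership wins.
#'
#' @param net A [CooccurrenceNetwork-class] with at least one edge.
#' @param restarts Random restarts of the greedy search (default 20).
#' @param seed Seed for the restarts (default 1).
#' @return A [PartitionResult-class].
#' @export
partitionFunctionalGroups <- function(net, restarts = 20, seed = 1) {
    stopifnot(is(net, "CooccurrenceNetwork"))
    e <- net@edges
    if (nrow(e) == 0) stop("cannot partition an edgeless network")
    nodes <- sort(unique(c(e$node_a, e$node_b)))
    nn <- length(nodes)
    if (nn < 2) stop("need at least 2 connected nodes")
    W <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
    W[cbind(match(e$node_a, nodes), match(e$node_b, nodes))] <- e$rho
    W <- W + t(W)
    absTotal <- sum(abs(e$rho))
    ## score(sides) for sides in {-1, +1}^n: consistent edges contribute
    ## +|rho|: rho > 0 same side, rho < 0 opposite; i.e. sign agreement
    ## sum_{edges} |rho| * sign(rho * side_i * side_j)
    scoreOf <- function(sides) {
        sum(W * outer(sides, sides)) / 2
    }
    if (nn <= 15) {
        best <- NULL; bestScore <- -Inf
        for (mask in 0:(2^(nn - 1) - 1)) {
            sides <- c(1, ifelse(bitwAnd(mask, 2^(seq_len(nn - 1) - 1)) > 0,
                                 -1, 1))
            sc <- scoreOf(sides)
            if (sc > bestScore + 1e-12 ||
                (abs(sc - bestScore) <= 1e-12 && .lexBefore(sides, best))) {
                bestScore <- sc; best <- sides
            }
        }
        exhaustive <- TRUE
    } else {
        set.seed(seed)
        best <- NULL; bestScore <- -Inf
        for (r in seq_len(restarts + 1)) {
            sides <- if (r == 1) .signSeed(W) else
                sample(c(-1, 1), nn, replace = TRUE)
            sides <- .localMoves(W, sides)
            sides <- sides * sides[1]           # fix node 1 on side +1
            sc <- scoreOf(sides)
            if (sc > bestScore + 1e-12 ||
                (abs(sc - bestScore) <= 1e-12 && .lexBefore(sides, best))) {
                bestScore <- sc; best <- sides
            }
        }
        exhaustive <- FALSE
    }
    grp <- stats::setNames(ifelse(best > 0, "G_A", "G_B"), nodes)
    new("PartitionResult", groupOfNode = grp, score = bestScore,
        isExhaustive = exhaustive)
}

## TRUE when candidate's G_A membership is lexicographically before
## best's (at the first differing node, candidate has it in G_A).
.lexBefore <- function(candidate, best) {
    if (is.null(best)) return(TRUE)
    d <- which(candidate != best)
    length(d) > 0 && candidate[d[1]] > best[d[1]]
}

## Seed sides by agglomerating along the strongest edges: same side for
## positive rho, opposite for negative.
.signSeed <- function(W) {
    nn <- nrow(W)
    sides <- rep(0, nn)
    ord <- order(-abs(W[upper.tri(W)]))
    ij <- which(upper.tri(W), arr.ind = TRUE)[ord, , drop = FALSE]
    sides[ij[1, 1]] <- 1
    for (k in seq_len(nrow(ij))) {
        i <- ij[k, 1]; j <- ij[k, 2]
        if (W[i, j] == 0) break
        s <- sign(W[i, j])
        if (sides[i] != 0 && sides[j] == 0) sides[j] <- s * sides[i]
        if (sides[j] != 0 && sides[i] == 0) sides[i] <- s * sides[j]
    }
    sides[sides == 0] <- 1
    sides
}

## Greedy single-node side swaps until no improvement.
.localMoves <- function(W, sides) {
    repeat {
        gain <- -sides * (W %*% sides)       # score change of flipping i
        i <- which.max(gain)
        if (gain[i] <= 1e-12) break
        sides[i] <- -sides[i]
    }
    sides
}

#' Export a network as an edge-list TSV (and optionally GraphML)
#'
#' @param net A [CooccurrenceNetwork-class].
#' @param path Output TSV path.
#' @param graphml Optional GraphML path (requires the igraph package).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, graphml = NULL) {
    .writeTsv(net@edges[, c("node_a", "node_b", "rho", "p", "sign")], path)
    if (!is.null(graphml)) {
        if (!requireNamespace("igraph", quietly = TRUE))
            stop("GraphML export needs the igraph package")
        g <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                           vertices = net@nodes)
        igraph::write_graph(g, graphml, format = "graphml")
    }
    invisible(path)
}
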