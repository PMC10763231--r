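test_that("alpha indices hit their closed forms", {
    a <- alphaDiversity(c(5, 5, 5, 5))
    expect_equal(a$shannon, log(4), tolerance = 1e-12)
    expect_equal(a$simpson, 0.75, tolerance = 1e-12)
    expect_equal(a$chao1, 4)            # no singletons: chao1 = S_obs
    single <- alphaDiversity(c(0, 7, 0))
    expect_equal(single$shannon, 0)
    expect_equal(single$simpson, 0)
    ## hand-derived Chao1: S_obs 4, F1 2, F2 0 -> 4 + 2*1/2 = 5
    expect_equal(alphaDiversity(c(5, 3, 1, 1))$chao1, 5)
    expect_error(alphaDiversity(c(0, 0)), "positive")
})

test_that("alpha indices agree with the vegan oracles on random communities", {
    skip_if_not_installed("vegan")
    set.seed(101)
    for (i in 1:30) {
        x <- stats::rpois(sample(5:40, 1), lambda = stats::rexp(1, 1 / 8))
        if (sum(x) == 0 || sum(x > 0) < 2) next
        a <- alphaDiversity(x)
        est <- vegan::estimateR(x)
        expect_equal(a$chao1, unname(est["S.chao1"]), tolerance = 1e-9)
        if (is.finite(est["S.ACE"]) && !is.na(a$ace))
            expect_equal(a$ace, unname(est["S.ACE"]), tolerance = 1e-9)
        expect_equal(a$shannon, unname(vegan::diversity(x)),
                     tolerance = 1e-12)
        expect_equal(a$simpson, unname(vegan::diversity(x, "simpson")),
                     tolerance = 1e-12)
    }
})

test_that("rarefaction expectation matches enumeration and is monotone", {
    ## (2,2) at depth 2: direct enumeration gives 5/3
    expect_equal(rarefactionCurve(c(2, 2), 2)$expected_richness, 5 / 3,
                 tolerance = 1e-12)
    expect_equal(rarefactionCurve(c(3, 1, 2), 6)$expected_richness, 3)
    expect_equal(rarefactionCurve(c(4, 9), 1)$expected_richness, 1)
    expect_error(rarefactionCurve(c(2, 2), 5), "depth")
    set.seed(11)
    for (i in 1:10) {
        counts <- sample(1:4, sample(2:4, 1), replace = TRUE)
        d <- sample(seq_len(sum(counts)), 1)
        expect_equal(rarefactionCurve(counts, d)$expected_richness,
                     bruteForceRarefaction(counts, d), tolerance = 1e-9)
    }
    curve <- rarefactionCurve(c(12, 5, 3, 1, 1), 1:22)
    expect_true(all(diff(curve$expected_richness) >= -1e-12))
})

test_that("rarefaction expectation matches Monte-Carlo subsampling", {
    counts <- c(30, 12, 5, 2, 1)
    d <- 20
    set.seed(21)
    items <- rep(seq_along(counts), counts)
    draws <- replicate(10000, length(unique(sample(items, d))))
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(rarefactionCurve(counts, d)$expected_richness -
                  mean(draws)), 3 * se)
})

test_that("Bray-Curtis distances are exact and match vegan", {
    m <- rbind(a = c(1, 1), b = c(1, 0), c = c(1, 1), d = c(0, 2))
    d <- brayCurtis(m)
    expect_equal(d["a", "b"], 1 / 3, tolerance = 1e-12)
    expect_equal(d["a", "c"], 0)
    expect_equal(d["b", "d"], 1)       # disjoint supports
    expect_true(isSymmetric(d))
    skip_if_not_installed("vegan")
    set.seed(31)
    x <- matrix(stats::rexp(40), 5, 8,
                dimnames = list(paste0("s", 1:5), NULL))
    expect_equal(brayCurtis(x), as.matrix(vegan::vegdist(x, "bray")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    zz <- rbind(s1 = c(0, 0), s2 = c(0, 0))
    expect_error(brayCurtis(zz), "all-zero")
})

test_that("PCoA embeds Euclidean configurations isometrically", {
    set.seed(41)
    x <- matrix(stats::rnorm(20), 5, 4)
    rownames(x) <- paste0("s", 1:5)
    d <- as.matrix(stats::dist(x))
    out <- pcoa(d)
    emb <- as.matrix(stats::dist(out$coordinates))
    expect_equal(emb, d, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(out$proportion_explained), 1, tolerance = 1e-12)
    ## cross-check coordinates against cmdscale up to sign
    cm <- stats::cmdscale(d, k = 4)
    k <- ncol(out$coordinates)
    for (j in seq_len(min(k, ncol(cm))))
        expect_equal(abs(out$coordinates[, j]), abs(cm[, j]),
                     tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PCoA handles simplex geometry and duplicated samples", {
    ## three equidistant points: two equal positive eigenvalues
    d3 <- matrix(1, 3, 3) - diag(3)
    dimnames(d3) <- list(letters[1:3], letters[1:3])
    out <- pcoa(d3)
    pos <- out$eigenvalues[out$eigenvalues > 1e-10]
    expect_equal(length(pos), 2L)
    expect_equal(pos[1], pos[2], tolerance = 1e-9)
    ## duplicated sample lands on identical coordinates
    m <- rbind(a = c(1, 3), b = c(1, 3), c = c(4, 0), d = c(2, 2))
    out2 <- pcoa(brayCurtis(m))
    expect_equal(out2$coordinates["a", ], out2$coordinates["b", ],
                 tolerance = 1e-9)
    expect_error(pcoa(matrix(0, 2, 2)), "3 samples")
})

test_that("PERMANOVA separates planted clusters and is relabeling-invariant", {
    set.seed(51)
    n2 <- 10
    x <- rbind(matrix(stats::rnorm(2 * n2, 0), n2, 2),
               matrix(stats::rnorm(2 * n2, 8), n2, 2))
    rownames(x) <- paste0("s", seq_len(2 * n2))
    d <- as.matrix(stats::dist(x))
    lab <- rep(c("A", "B"), each = n2)
    res <- permanova(d, lab, B = 999, seed = 1)
    ## the only permutations reaching the observed F reproduce the
    ## observed bipartition itself, so p sits at (or within a tie of)
    ## the 1/(B+1) lattice minimum
    expect_equal(res$p_value, 0.001)
    ## permuting sample order together with labels leaves F unchanged
    ord <- sample(2 * n2)
    res2 <- permanova(d[ord, ord], lab[ord], B = 99, seed = 1)
    expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
    expect_error(permanova(d, rep("A", 2 * n2)), "2 groups")
    skip_if_not_installed("vegan")
    ad <- vegan::adonis2(stats::as.dist(d) ~ g,
                         data = data.frame(g = lab), permutations = 19)
    expect_equal(res$statistic, ad$F[1], tolerance = 1e-9)
})

test_that("ANOSIM matches the hand rank formula and vegan", {
    ## 4 samples (2+2): within distances 1, 2; between 3, 4, 5, 6
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d["a", "b"] <- d["b", "a"] <- 1        # within group 1
    d["c", "d"] <- d["d", "c"] <- 2        # within group 2
    d["a", "c"] <- d["c", "a"] <- 3
    d["a", "d"] <- d["d", "a"] <- 4
    d["b", "c"] <- d["c", "b"] <- 5
    d["b", "d"] <- d["d", "b"] <- 6
    lab <- c("g1", "g1", "g2", "g2")
    res <- anosim(d, lab, B = 99, seed = 1)
    ## ranks: within (1, 2), between (3, 4, 5, 6); M = 6
    oracle <- (mean(c(3, 4, 5, 6)) - mean(c(1, 2))) / (6 / 2)
    expect_equal(res$statistic, oracle, tolerance = 1e-12)
    expect_equal(res$statistic, 1)        # all between > all within
    skip_if_not_installed("vegan")
    set.seed(61)
    x <- matrix(stats::rnorm(36), 12, 3)
    rownames(x) <- paste0("s", 1:12)
    dd <- as.matrix(stats::dist(x))
    lab2 <- rep(c("A", "B", "C"), each = 4)
    mine <- anosim(dd, lab2, B = 99, seed = 2)
    vg <- vegan::anosim(stats::as.dist(dd), grouping = lab2,
                        permutations = 19)
    expect_equal(mine$statistic, vg$statistic, tolerance = 1e-9)
})

test_that("ANOSIM is centred near zero under label-independent distances", {
    set.seed(71)
    x <- matrix(stats::rnorm(60), 20, 3)
    rownames(x) <- paste0("s", 1:20)
    d <- as.matrix(stats::dist(x))
    stats <- vapply(1:200, function(i)
        anosim(d, sample(rep(c("A", "B"), each = 10)), B = 0 + 9,
               seed = i)$statistic, numeric(1))
    expect_lt(abs(mean(stats)), 0.05)
})

test_that("Tukey utility reports a sensible three-group comparison", {
    set.seed(81)
    vals <- c(stats::rnorm(6, 0), stats::rnorm(6, 0), stats::rnorm(6, 5))
    g <- rep(c("CD", "OD", "HD"), each = 6)
    out <- tukeyComparison(vals, g)
    expect_lt(out$p_value, 0.01)
    expect_equal(nrow(out$tukey), 3L)
})
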