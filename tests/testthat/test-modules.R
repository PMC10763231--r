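test_that("separable correlation blocks give exactly two modules", {
    set.seed(1)
    n <- 20
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    expr <- cbind(sapply(1:6, function(i) f1 * (1 + 0.1 * i)),
                  sapply(1:6, function(i) -f2 * (1 + 0.1 * i)))
    colnames(expr) <- paste0("g", 1:12)
    rownames(expr) <- paste0("s", 1:n)
    ms <- detectModules(expr, minSize = 3, cutHeight = 0.25)
    mods <- setdiff(unique(moduleOfGene(ms)), "grey")
    expect_equal(length(mods), 2L)
    ## perfectly correlated genes: eigengene explains everything
    expect_equal(unname(varianceExplained(ms)[mods[1]]), 1, tolerance = 1e-9)
})

test_that("constant genes are dropped with a message, not an error", {
    set.seed(2)
    expr <- cbind(matrix(stats::rnorm(40), 10, 4), flat = rep(2, 10))
    colnames(expr)[1:4] <- paste0("g", 1:4)
    rownames(expr) <- paste0("s", 1:10)
    expect_message(ms <- detectModules(expr, minSize = 2, cutHeight = 0.9),
                   "flat")
    expect_false("flat" %in% names(moduleOfGene(ms)))
    expect_error(detectModules(matrix(1, 10, 3,
                                      dimnames = list(paste0("s", 1:10),
                                                      paste0("g", 1:3)))),
                 "constant")
})

test_that("planted modules are recovered from synthetic expression", {
    sim <- simulateDataset(simulationParams(seed = 3, moduleCoupling = 0.9))
    ms <- detectModules(sim$hostExpression$gut, minSize = 30,
                        cutHeight = 0.3)
    truth <- sim$truth@moduleOfGene
    got <- moduleOfGene(ms)[names(truth)]
    expect_gte(adjustedRandIndex(got, truth), 0.9)
})

test_that("eigengenes match a direct eigendecomposition oracle", {
    set.seed(4)
    n <- 15
    ## identical genes: ME equals the standardized common profile
    common <- stats::rnorm(n)
    exprId <- matrix(common, n, 3)
    dimnames(exprId) <- list(paste0("s", 1:n), paste0("g", 1:3))
    me <- moduleEigengenes(exprId, stats::setNames(rep("blue", 3),
                                                   colnames(exprId)))
    expect_equal(unname(me$eigengenes[, "blue"]),
                 as.vector(scale(common)), tolerance = 1e-9)
    expect_equal(unname(me$varianceExplained["blue"]), 1, tolerance = 1e-12)
    ## random 5-gene module vs eigen() on the covariance of standardized
    ## expression, up to sign
    expr <- matrix(stats::rnorm(n * 5), n, 5,
                   dimnames = list(paste0("s", 1:n), paste0("g", 1:5)))
    me2 <- moduleEigengenes(expr, stats::setNames(rep("red", 5),
                                                  colnames(expr)))
    z <- scale(expr)
    eg <- eigen(stats::cov(z))
    pc1 <- z %*% eg$vectors[, 1]
    pc1 <- pc1 / stats::sd(pc1)
    expect_equal(abs(unname(me2$eigengenes[, "red"])), abs(as.vector(pc1)),
                 tolerance = 1e-9)
    expect_equal(unname(me2$varianceExplained["red"]),
                 eg$values[1] / sum(eg$values), tolerance = 1e-9)
    ## sign orientation: positive correlation with the module mean
    expect_gt(stats::cor(me2$eigengenes[, "red"], rowMeans(z)), 0)
})

test_that("eigengene variance explained dominates any single gene's share", {
    set.seed(5)
    for (i in 1:10) {
        n <- 20; g <- sample(3:8, 1)
        z <- scale(matrix(stats::rnorm(n * g), n, g))
        colnames(z) <- paste0("g", seq_len(g))
        rownames(z) <- paste0("s", 1:n)
        me <- moduleEigengenes(z, stats::setNames(rep("m", g), colnames(z)))
        C <- stats::cor(z)
        singleShare <- max(diag(C %*% C)) / g
        expect_gte(me$varianceExplained[["m"]] + 1e-9, singleShare)
    }
})

test_that("module-group association matches hand-computed Pearson", {
    set.seed(6)
    n <- 5
    me <- matrix(c(1, 3, 2, 5, 4), n, 1,
                 dimnames = list(paste0("s", 1:n), "blue"))
    ab <- matrix(c(2, 6, 5, 9, 7), n, 1,
                 dimnames = list(paste0("s", 1:n), "Proteobacteria"))
    out <- associateModules(me, ab)
    x <- me[, 1]; y <- ab[, 1]
    rOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r, rOracle, tolerance = 1e-12)
    ## self-association and constructed orthogonality
    outSelf <- associateModules(me, matrix(x, n, 1,
                 dimnames = list(rownames(me), "self")))
    expect_equal(outSelf$r, 1, tolerance = 1e-12)
    resid <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
    outOrth <- associateModules(me, matrix(resid, n, 1,
                 dimnames = list(rownames(me), "orth")))
    expect_lt(abs(outOrth$r), 1e-9)
    ## affine invariance
    outAff <- associateModules(me * 3 - 1, ab / 10 + 2)
    expect_equal(outAff$r, out$r, tolerance = 1e-12)
    expect_error(associateModules(me[1:3, , drop = FALSE],
                                  ab[1:3, , drop = FALSE]), "4")
})

test_that("significance tiers follow the heatmap convention", {
    p <- c(0.0005, 0.005, 0.03, 0.07, 0.5)
    expect_equal(gutFG:::.pTier(p), c("***", "**", "*", "$", ""))
})

test_that("the opposite-pattern statistic is -1/+1 at the extremes", {
    mods <- paste0("M", 1:8)
    v <- c(0.9, -0.6, 0.4, -0.2, 0.7, -0.8, 0.1, -0.3)
    mk <- function(cols) {
        do.call(rbind, lapply(names(cols), function(g)
            data.frame(module = mods, group = g, r = cols[[g]],
                       p = 0.5, tier = "")))
    }
    assocOpp <- mk(list(Proteobacteria = v, Fusobacteria = -v,
                        Firmicutes = -v, Bacteroidetes = -v))
    res <- oppositePatternTest(assocOpp, B = 99, seed = 1)
    expect_equal(res$statistic, -1, tolerance = 1e-12)
    expect_equal(res$p_value, 1 / 100)
    assocSame <- mk(list(Proteobacteria = v, Fusobacteria = v,
                         Firmicutes = v, Bacteroidetes = v))
    res2 <- oppositePatternTest(assocSame, B = 99, seed = 1)
    expect_equal(res2$statistic, 1, tolerance = 1e-12)
    expect_error(oppositePatternTest(assocOpp[assocOpp$module %in%
                                              mods[1:3], ]), "5 modules")
})

test_that("eigengenes track the planted module latents with group signature", {
    sim <- simulateDataset(simulationParams(seed = 7, moduleCoupling = 0.9))
    ms <- detectModules(sim$hostExpression$liver)
    latent <- sim$truth@latent
    tms <- sim$truth@moduleLatent$liver
    truth <- sim$truth@moduleOfGene
    for (m in colnames(eigengenes(ms))) {
        genes <- names(moduleOfGene(ms))[moduleOfGene(ms) == m]
        planted <- names(sort(table(truth[genes]), decreasing = TRUE))[1]
        me <- eigengenes(ms)[, m]
        ## the eigengene recovers the module's own latent profile ...
        expect_gt(abs(stats::cor(me, tms[, planted])), 0.9)
        ## ... and carries the signed group-factor signature
        zg <- if (sim$truth@moduleSign[planted] > 0) latent[, "fg1"] else
            latent[, "fg2"]
        r <- stats::cor(me, zg) * sign(stats::cor(me, tms[, planted]))
        expect_gt(r, 0.4)
    }
})
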