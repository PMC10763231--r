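test_that("core taxa are the abundant genera present in every cell", {
    ## 5-taxon toy with a known presence pattern over 6 cells
    meta <- data.frame(sample_id = paste0("s", 1:12),
                       diet = rep(c("CD", "OD", "HD"), each = 4)[c(1:12)],
                       week = rep(c(1, 3), 6),
                       replicate = rep(1:2, 6))
    m <- matrix(0.2, 12, 5, dimnames = list(meta$sample_id,
                paste0("t", 1:5)))
    ## t4 absent from the CD/week-1 cell, t5 rare everywhere
    m[meta$diet == "CD" & meta$week == 1, "t4"] <- 0
    m[, "t5"] <- 0.01
    m <- m / rowSums(m)
    prof <- FeatureProfile(m, "genus", "relative")
    out <- coreTaxa(prof, meta, topN = 4)
    expect_true(all(c("t1", "t2", "t3") %in% out$core))
    expect_false("t4" %in% out$core)      # absent from one cell
    expect_false("t5" %in% out$core)      # below the top-4 candidate pool
    ## hand enumeration of the contribution fraction in one cell
    idx <- meta$sample_id[meta$diet == "CD" & meta$week == 1]
    expect_equal(out$contribution$fraction[out$contribution$cell == "CD.1"],
                 sum(m[idx, out$core]) / sum(m[idx, ]), tolerance = 1e-12)
})

test_that("network edges follow the rho and p thresholds with correct signs", {
    set.seed(1)
    n <- 12
    up <- sort(stats::rexp(n)); noise <- stats::rnorm(n)
    m <- cbind(inc1 = up, inc2 = up + 0.01 * seq_len(n),
               dec = max(up) - up, rand = noise)
    rownames(m) <- paste0("s", 1:n)
    net <- correlationNetwork(m, rMin = 0.5, pMax = 0.05)
    e <- networkEdges(net)
    pair <- function(a, b) e[(e$node_a == a & e$node_b == b) |
                             (e$node_a == b & e$node_b == a), ]
    expect_equal(pair("inc1", "inc2")$rho, 1)
    expect_equal(pair("inc1", "inc2")$sign, "co-occurrence")
    expect_equal(pair("inc1", "dec")$rho, -1)
    expect_equal(pair("inc1", "dec")$sign, "co-exclusion")
    expect_true(validObject(net))
})

test_that("a pair with sample rho below the threshold yields no edge", {
    ## construct ranks with Spearman rho = 0.3, below the 0.5 threshold
    x <- 1:5
    y <- c(1, 5, 2, 4, 3)
    rho <- stats::cor(x, y, method = "spearman")   # rank-correlation oracle
    expect_equal(rho, 0.3, tolerance = 1e-12)
    filler <- c(1.7, 0.3, 2.2, 0.9, 1.1)           # uncorrelated third taxon
    m <- cbind(a = x, b = y, c = filler)
    rownames(m) <- paste0("s", 1:5)
    net <- correlationNetwork(m, rMin = 0.5, pMax = 0.999, pMethod = "exact")
    e <- networkEdges(net)
    expect_false(any((e$node_a == "a" & e$node_b == "b") |
                     (e$node_a == "b" & e$node_b == "a")))
})

test_that("constant taxa are excluded with a warning, not an error", {
    set.seed(2)
    m <- cbind(a = stats::rnorm(10), b = stats::rnorm(10), flat = rep(3, 10))
    rownames(m) <- paste0("s", 1:10)
    expect_warning(net <- correlationNetwork(m), "flat")
    expect_false("flat" %in% networkNodes(net)$node)
})

test_that("the edge set shrinks monotonically as the threshold grows", {
    set.seed(3)
    sim <- simulateDataset(smallSimParams(seed = 3))
    gm <- profileValues(toRelative(aggregateByCategory(
        sim$abundance, sim$annotations, "genus")))
    sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r)
        nrow(networkEdges(correlationNetwork(gm, rMin = r))), numeric(1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("exact Spearman p-values match cor.test on small samples", {
    set.seed(4)
    for (i in 1:10) {
        n <- sample(5:8, 1)
        x <- sample(100, n); y <- sample(100, n)
        mine <- spearmanTest(x, y, method = "exact")
        ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
        expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    }
})

test_that("the RMT scan finds structure when present and falls back when not", {
    expect_warning(out <- rmtThreshold(diag(12)), "falling back")
    expect_false(out$from_rmt)
    expect_equal(out$threshold, 0.5)
    ## two planted blocks: returned threshold below the block correlation,
    ## and thresholding at it keeps both blocks connected
    set.seed(5)
    n <- 50
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    x <- cbind(sapply(1:10, function(i) 3 * f1 + stats::rnorm(n)),
               sapply(1:10, function(i) 3 * f2 + stats::rnorm(n)))
    corr <- stats::cor(x)
    out2 <- rmtThreshold(corr)
    expect_true(out2$from_rmt)
    expect_lt(out2$threshold, 0.9)
    keep <- abs(corr) >= out2$threshold
    blockDensity <- function(idx) {
        k <- keep[idx, idx]; mean(k[upper.tri(k)])
    }
    expect_gt(blockDensity(1:10), 0.9)
    expect_gt(blockDensity(11:20), 0.9)
    ## pure noise: the thresholded network stays sparse (whether the scan
    ## finds a Poisson-fitting threshold or falls back to the fixed rule)
    set.seed(6)
    noise <- matrix(stats::rnorm(50 * 20), 50, 20)
    cn <- stats::cor(noise)
    outN <- suppressWarnings(rmtThreshold(cn))
    kn <- abs(cn) >= outN$threshold
    diag(kn) <- FALSE
    expect_lt(mean(kn[upper.tri(kn)]), 0.05)
})

test_that("partition maximizes the signed score (exhaustive oracle)", {
    mkNet <- function(edges) {
        nodes <- sort(unique(c(edges$node_a, edges$node_b)))
        new("CooccurrenceNetwork",
            nodes = data.frame(node = nodes, mean_abundance = 1),
            edges = transform(edges,
                              sign = ifelse(rho < 0, "co-exclusion",
                                            "co-occurrence"),
                              p = 1e-4),
            thresholdUsed = 0, pMax = 0.05)
    }
    ## two nodes, one negative edge -> opposite groups, score |rho|
    net2 <- mkNet(data.frame(node_a = "x", node_b = "y", rho = -0.8))
    p2 <- partitionFunctionalGroups(net2)
    expect_equal(partitionScore(p2), 0.8)
    expect_false(groupOfNode(p2)[["x"]] == groupOfNode(p2)[["y"]])
    ## random signed toys vs brute force
    set.seed(7)
    for (i in 1:10) {
        nn <- sample(4:8, 1)
        nodes <- paste0("n", seq_len(nn))
        pairs <- t(utils::combn(nodes, 2))
        keep <- stats::runif(nrow(pairs)) < 0.7
        edges <- data.frame(node_a = pairs[keep, 1],
                            node_b = pairs[keep, 2],
                            rho = stats::runif(sum(keep), -1, 1))
        if (nrow(edges) == 0) next
        net <- mkNet(edges)
        part <- partitionFunctionalGroups(net)
        expect_true(part@isExhaustive)
        expect_equal(partitionScore(part), bruteForcePartitionScore(net),
                     tolerance = 1e-12)
        ## score invariant under swapping group labels
        swapped <- ifelse(groupOfNode(part) == "G_A", "G_B", "G_A")
        sc <- function(g) sum(ifelse(
            net@edges$rho * ifelse(g[net@edges$node_a] == g[net@edges$node_b],
                                   1, -1) > 0,
            abs(net@edges$rho), -abs(net@edges$rho)))
        expect_equal(sc(groupOfNode(part)), sc(swapped), tolerance = 1e-12)
    }
    edgeless <- new("CooccurrenceNetwork",
                    nodes = data.frame(node = c("x", "y"),
                                       mean_abundance = 1),
                    edges = data.frame(node_a = character(0),
                                       node_b = character(0),
                                       rho = numeric(0), p = numeric(0),
                                       sign = character(0)),
                    thresholdUsed = 0.5, pMax = 0.05)
    expect_error(partitionFunctionalGroups(edgeless), "edgeless")
})

test_that("the greedy search recovers planted groups beyond 15 nodes", {
    set.seed(8)
    nn <- 20
    side <- rep(c(1, -1), each = 10)
    nodes <- paste0("n", 1:nn)
    pairs <- t(utils::combn(seq_len(nn), 2))
    rho <- 0.6 * side[pairs[, 1]] * side[pairs[, 2]] +
        stats::runif(nrow(pairs), -0.05, 0.05)
    net <- new("CooccurrenceNetwork",
               nodes = data.frame(node = nodes, mean_abundance = 1),
               edges = data.frame(node_a = nodes[pairs[, 1]],
                                  node_b = nodes[pairs[, 2]],
                                  rho = rho, p = 1e-4,
                                  sign = ifelse(rho < 0, "co-exclusion",
                                                "co-occurrence")),
               thresholdUsed = 0, pMax = 0.05)
    part <- partitionFunctionalGroups(net)
    expect_false(part@isExhaustive)
    truth <- ifelse(side > 0, "P", "Q")
    names(truth) <- nodes
    expect_equal(adjustedRandIndex(groupOfNode(part)[nodes], truth), 1)
})

test_that("the partition recovers the planted functional groups", {
    sim <- simulateDataset(simulationParams(seed = 42, groupAnticorr = 0.9))
    fg <- sim$truth@fgOfPhylum[sim$truth@phylumOfTaxon]
    names(fg) <- names(sim$truth@phylumOfTaxon)
    gm <- profileValues(toRelative(aggregateByCategory(
        sim$abundance, sim$annotations, "genus")))
    net <- correlationNetwork(gm[, names(fg)[fg != "other"]])
    part <- partitionFunctionalGroups(net)
    expect_equal(adjustedRandIndex(groupOfNode(part),
                                   fg[names(groupOfNode(part))]), 1)
})
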