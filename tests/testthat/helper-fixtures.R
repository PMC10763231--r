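## Small fixtures built in code.

## A hand-written annotation table: 6 genes over 2 phyla, with KO, CAZy,
## VF and ARG labels exercising every optional field.
tinyAnnotation <- function() {
    lineage <- data.frame(
        superkingdom = rep("Bacteria", 6),
        phylum = c("Proteobacteria", "Proteobacteria", "Firmicutes",
                   "Firmicutes", "Fusobacteria", "unknown"),
        class = "unknown", order = "unknown", family = "unknown",
        genus = c("Aeromonas", "Shewanella", "Clostridium", "Bacillus",
                  "Cetobacterium", "unknown"),
        species = "unknown", stringsAsFactors = FALSE)
    GeneAnnotationTable(
        gene_id = paste0("g", 1:6),
        length_bp = c(900, 1200, 1500, 600, 800, 1000),
        lineage = lineage,
        ko = c("K01938", NA, "K00929", "K00001", NA, NA),
        cazy = list(c("GH13"), character(0), c("GH43", "GH28"),
                    c("GH32"), c("GH3"), character(0)),
        vf_class = c("toxin", "adherence", NA, NA, NA, NA),
        arg_class = c("multidrug", NA, "macrolide", NA, NA, NA))
}

## Matching 3-sample abundance matrix.
tinyAbundance <- function() {
    m <- matrix(c(5, 2, 1, 3, 4, 0,
                  1, 1, 6, 2, 3, 1,
                  2, 0, 2, 2, 5, 2), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), paste0("g", 1:6)))
    m
}

## A small relative phylum profile with known FG composition.
tinyPhylumProfile <- function() {
    m <- rbind(s1 = c(0.50, 0.20, 0.15, 0.10, 0.05),
               s2 = c(0.25, 0.25, 0.25, 0.25, 0.00))
    colnames(m) <- c("Proteobacteria", "Bacteroidetes", "Firmicutes",
                     "Fusobacteria", "Actinobacteria")
    FeatureProfile(m, level = "phylum", normalization = "relative")
}

## Cheap simulation parameters for pipeline smoke tests.
smallSimParams <- function(seed = 1, ...) {
    simulationParams(genesPerTaxon = 10, nHostGenes = 240, nModules = 6,
                     nViralTaxa = 6, seed = seed, ...)
}

## Exhaustive bipartition oracle: maximum signed-agreement score of a
## network, independent of the package's search.
bruteForcePartitionScore <- function(net) {
    e <- networkEdges(net)
    nodes <- sort(unique(c(e$node_a, e$node_b)))
    nn <- length(nodes)
    best <- -Inf
    for (mask in 0:(2^(nn - 1) - 1)) {
        sides <- c(1, ifelse(bitwAnd(mask, 2^(seq_len(nn - 1) - 1)) > 0, -1, 1))
        names(sides) <- nodes
        sc <- sum(ifelse(e$rho * sides[e$node_a] * sides[e$node_b] > 0,
                         abs(e$rho), -abs(e$rho)))
        best <- max(best, sc)
    }
    best
}

## Exact Mann-Whitney two-sided p by enumeration of all label
## assignments, independent of compareGroups.
bruteForceMannWhitneyP <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    mid <- n * m / 2
    combs <- utils::combn(n + m, n)
    Us <- apply(combs, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
    mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
}

## Analytic-free rarefaction oracle: enumerate every subsample of size d.
bruteForceRarefaction <- function(counts, d) {
    items <- rep(seq_along(counts), counts)
    combs <- utils::combn(length(items), d)
    mean(apply(combs, 2, function(idx) length(unique(items[idx]))))
}
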