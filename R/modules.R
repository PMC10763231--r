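## WGCNA-style co-expression modules: detection by average-linkage
## clustering of the 1 - |Pearson r| dissimilarity with a static tree cut,
## module eigengenes (sign-oriented first principal components), Pearson
## association with taxon-group abundances, and the opposite-association
## permutation test.

#' Detect co-expression modules
#'
#' Genes are standardized, the dissimilarity `1 - |Pearson r|` is
#' clustered by average linkage, the tree is cut at `cutHeight`, and
#' clusters smaller than `minSize` are merged into the unassigned
#' `"grey"` module.  Retained modules receive WGCNA-style color labels in
#' decreasing size order.  Constant genes are dropped with a message.
#'
#' After the cut, unassigned genes are rescued into the module whose
#' eigengene they correlate with at `|r| >= rescueThreshold` (the usual
#' module-membership reassignment); eigengenes are then recomputed.
#'
#' @param expr Samples-by-genes expression matrix (>= 8 samples).
#' @param minSize Smallest retained module (default 30).
#' @param cutHeight Static cut height on the dissimilarity scale
#'   (default 0.3, i.e. average within-module |r| above 0.7).
#' @param rescueThreshold Module-membership |r| needed to pull a grey gene
#'   into a module (default 0.7, matching the cut height; 1 disables).
#' @return A [ModuleSet-class].
#' @export
detectModules <- function(expr, minSize = 30, cutHeight = 0.3,
                          rescueThreshold = 0.7) {
    expr <- as.matrix(expr)
    if (nrow(expr) < 8) stop("module detection needs at least 8 samples")
    sds <- apply(expr, 2, stats::sd)
    if (all(sds == 0)) stop("all genes are constant")
    if (any(sds == 0)) {
        message("dropping ", sum(sds == 0), " constant gene(s): ",
                .abbrev(colnames(expr)[sds == 0]))
        expr <- expr[, sds > 0, drop = FALSE]
    }
    z <- scale(expr)
    diss <- 1 - abs(stats::cor(z))
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    cl <- stats::cutree(hc, h = cutHeight)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= minSize]
    assignment <- rep("grey", ncol(expr))
    names(assignment) <- colnames(expr)
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep))
        assignment[cl == as.integer(keep[i])] <- .MODULE_COLORS[i]
    if (length(keep) > length(.MODULE_COLORS))
        stop("more modules than available color labels")
    me <- .eigengeneMatrix(z, assignment)
    grey <- names(assignment)[assignment == "grey"]
    if (length(grey) > 0 && ncol(me$eigengenes) > 0 && rescueThreshold < 1) {
        km <- stats::cor(z[, grey, drop = FALSE], me$eigengenes)
        best <- max.col(abs(km), ties.method = "first")
        hit <- abs(km)[cbind(seq_along(grey), best)] >= rescueThreshold
        assignment[grey[hit]] <- colnames(me$eigengenes)[best[hit]]
        if (any(hit)) me <- .eigengeneMatrix(z, assignment)
    }
    new("ModuleSet", moduleOfGene = assignment, eigengenes = me$eigengenes,
        varianceExplained = me$varianceExplained)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardized expression of its genes, scaled to unit variance and
#' sign-oriented to correlate positively with the module's mean
#' expression profile.  A single-gene module's eigengene is that gene's
#' standardized profile.
#'
#' @param expr Samples-by-genes expression matrix.
#' @param modules A [ModuleSet-class] (its eigengenes are recomputed on
#'   `expr`), or a named gene -> module character vector.
#' @return List with `eigengenes` (samples x modules, unit variance) and
#'   `varianceExplained` (per module share of PC1).
#' @export
moduleEigengenes <- function(expr, modules) {
    assignment <- if (is(modules, "ModuleSet")) modules@moduleOfGene else
        modules
    expr <- as.matrix(expr)
    genes <- intersect(colnames(expr), names(assignment))
    if (length(genes) == 0) stop("no module gene found in the expression matrix")
    z <- scale(expr[, genes, drop = FALSE])
    .eigengeneMatrix(z, assignment[genes])
}

.eigengeneMatrix <- function(z, assignment) {
    mods <- setdiff(unique(assignment), "grey")
    n <- nrow(z)
    me <- matrix(0, n, length(mods), dimnames = list(rownames(z), mods))
    ve <- stats::setNames(numeric(length(mods)), mods)
    for (m in mods) {
        zm <- z[, assignment == m, drop = FALSE]
        if (ncol(zm) == 1) {
            v <- zm[, 1]
            ve[m] <- 1
        } else {
            sv <- svd(zm, nu = 1, nv = 0)
            v <- sv$u[, 1]
            ve[m] <- sv$d[1]^2 / sum(sv$d^2)
        }
        v <- v / stats::sd(v)
        if (stats::cor(v, rowMeans(zm)) < 0) v <- -v
        me[, m] <- v
    }
    list(eigengenes = me, varianceExplained = ve)
}

#' Associate module eigengenes with taxon-group abundances
#'
#' Pearson correlation and two-sided t-test p-value for every
#' (module, group) pair, annotated with the significance tiers used in
#' module-trait heatmaps (`$` p < 0.1, `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001).
#'
#' @param eigengenes Samples-by-modules matrix (or a [ModuleSet-class]).
#' @param groupAbundance Samples-by-groups matrix of relative abundances
#'   (e.g. per-phylum and summed FG1/FG2 columns); rows matched by name.
#' @return data.frame with columns `module`, `group`, `r`, `p`, `tier`.
#' @export
associateModules <- function(eigengenes, groupAbundance) {
    if (is(eigengenes, "ModuleSet")) eigengenes <- eigengenes@eigengenes
    groupAbundance <- as.matrix(groupAbundance)
    shared <- intersect(rownames(eigengenes), rownames(groupAbundance))
    if (length(shared) < 4)
        stop("need at least 4 shared samples")
    if (length(shared) < nrow(eigengenes) ||
        length(shared) < nrow(groupAbundance))
        stop("eigengene and abundance samples do not match")
    me <- eigengenes[shared, , drop = FALSE]
    ga <- groupAbundance[shared, , drop = FALSE]
    out <- expand.grid(module = colnames(me), group = colnames(ga),
                       stringsAsFactors = FALSE)
    rp <- mapply(function(m, g) {
        pt <- pearsonTest(me[, m], ga[, g])
        c(pt$r, pt$p)
    }, out$module, out$group)
    out$r <- rp[1, ]
    out$p <- rp[2, ]
    out$tier <- .pTier(out$p)
    out
}

#' Permutation test for the opposite association pattern
#'
#' Tests whether the FG1 phylum's module-association profile runs
#' opposite to the FG2 phyla's: the statistic is the Pearson correlation
#' between the FG1 column of the module-by-phylum correlation matrix and
#' each FG2 phylum's column (reported per phylum and averaged), and the
#' p-value comes from permuting the module rows of the FG1 vector
#' (one-sided, lower tail).  A consistently opposite pattern shows as a
#' negative average statistic with p < 0.05.
#'
#' @param assoc Association table from [associateModules()] whose groups
#'   include every FG1 and FG2 phylum.
#' @param fgmap Named phylum -> group map (default
#'   [defaultFunctionalGroups()]).
#' @param B Number of permutations (default 999).
#' @param seed Optional permutation seed.
#' @return List with `statistic` (average over FG2 phyla), `per_phylum`,
#'   `p_value`, `n_permutations`.
#' @export
oppositePatternTest <- function(assoc, fgmap = defaultFunctionalGroups(),
                                B = 999, seed = NULL) {
    fg1 <- names(fgmap)[fgmap == "FG1"]
    fg2 <- names(fgmap)[fgmap == "FG2"]
    need <- c(fg1, fg2)
    if (!all(need %in% assoc$group))
        stop("association table lacks phylum column(s): ",
             paste(setdiff(need, assoc$group), collapse = ", "))
    rmat <- .assocToMatrix(assoc)
    if (nrow(rmat) < 5) stop("need at least 5 modules")
    if (!is.null(seed)) set.seed(seed)
    v1 <- rowMeans(rmat[, fg1, drop = FALSE])
    perPhylum <- vapply(fg2, function(ph) stats::cor(v1, rmat[, ph]),
                        numeric(1))
    obs <- mean(perPhylum)
    perm <- vapply(seq_len(B), function(b) {
        v1p <- v1[sample(length(v1))]
        mean(vapply(fg2, function(ph) stats::cor(v1p, rmat[, ph]),
                    numeric(1)))
    }, numeric(1))
    list(statistic = obs, per_phylum = perPhylum,
         p_value = .permP(perm, obs, "less"), n_permutations = B)
}

.assocToMatrix <- function(assoc) {
    mods <- unique(assoc$module)
    grps <- unique(assoc$group)
    m <- matrix(NA_real_, length(mods), length(grps),
                dimnames = list(mods, grps))
    m[cbind(match(assoc$module, mods), match(assoc$group, grps))] <- assoc$r
    m
}
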