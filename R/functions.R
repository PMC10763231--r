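## CAZy substrate attribution, SCFA key-enzyme profiles, VF/ARG class
## profiles per functional group, low-abundance filtering, and the
## Mann-Whitney two-group comparison.

#' Default CAZy substrate map
#'
#' The six substrate classes with their CAZy family lists.  Families may
#' legitimately appear under several substrates (GH1, GH3 and GH5 do);
#' multi-membership is honored, not deduplicated.
#'
#' @return Named list substrate -> character vector of CAZy families.
#' @export
defaultSubstrateMap <- function() {
    list(arabinoxylan = c("CE1", "CE2", "CE4", "CE6", "CE7", "GH10", "GH11",
                          "GH115", "GH43", "GH51", "GH67", "GH3", "GH5"),
         pectin = c("CE12", "CE8", "GH28", "PL1", "PL9"),
         mucin = c("GH1", "GH2", "GH3", "GH4", "GH18", "GH19", "GH20",
                   "GH29", "GH33", "GH38", "GH58", "GH79", "GH84", "GH85",
                   "GH88", "GH89", "GH92", "GH95", "GH98", "GH99", "GH101",
                   "GH105", "GH109", "GH110", "GH113", "PL6", "PL8", "PL12",
                   "PL13", "PL21"),
         inulin = c("GH32", "GH91"),
         cellulose = c("GH1", "GH44", "GH48", "GH8", "GH9", "GH3", "GH5"),
         starch = c("GH13", "GH31", "GH97"))
}

#' Default SCFA key-enzyme map
#'
#' Marker genes for short-chain fatty acid production capacity: FTHFS
#' (formate-tetrahydrofolate ligase; acetate), PcoAt (propionate
#' CoA-transferase; propionate) and Buk/AtoA/AtoD (butyrate kinase and
#' the two acetoacetate CoA-transferase subunits; butyrate).  The KO
#' identifiers are editable defaults, not fixed constants: pass your own
#' map to [scfaGeneProfile()] to override them.
#'
#' @return Named list SCFA -> named character vector (enzyme -> KO id).
#' @export
defaultScfaEnzymes <- function() {
    list(acetate = c(FTHFS = "K01938"),
         propionate = c(PcoAt = "K01026"),
         butyrate = c(Buk = "K00929", AtoA = "K01035", AtoD = "K01034"))
}

## Resolve each gene's functional group from its phylum; "other" for
## phyla outside the map.
.fgOfGenes <- function(annot, fgmap) {
    phylum <- annot@annot$phylum
    fg <- fgmap[phylum]
    fg[is.na(fg)] <- "other"
    unname(fg)
}

#' Per-group CAZy substrate utilization profile
#'
#' For each sample and functional group, the abundance of the group's
#' genes carrying at least one family of a substrate's CAZy list, divided
#' by the group's total CAZy-gene abundance in that sample and scaled to
#' 100,000.  A gene whose families hit k substrates contributes its full
#' abundance to all k.
#'
#' @param abund Samples-by-genes abundance matrix.
#' @param annot A [GeneAnnotationTable-class].
#' @param fgmap Phylum -> group map (default [defaultFunctionalGroups()]).
#' @param smap Substrate map (default [defaultSubstrateMap()]).
#' @param scale Normalization scale (default 100,000).
#' @return List of per-group [FeatureProfile-class] objects
#'   (samples x substrates, per_100k).
#' @export
cazySubstrateProfile <- function(abund, annot, fgmap = defaultFunctionalGroups(),
                                 smap = defaultSubstrateMap(), scale = 1e5) {
    validateAbundanceMatrix(abund)
    a <- annot@annot[match(colnames(abund), annot@annot$gene_id), ]
    if (any(is.na(a$gene_id)))
        stop("abundance matrix contains unannotated gene ids")
    fg <- .fgOfGenes(annot, fgmap)[match(colnames(abund), annot@annot$gene_id)]
    hasCazy <- lengths(a$cazy) > 0
    groups <- intersect(c("FG1", "FG2"), unique(fg))
    out <- list()
    for (g in groups) {
        inG <- fg == g
        cazyAb <- rowSums(abund[, inG & hasCazy, drop = FALSE])
        if (any(cazyAb == 0))
            stop("group ", g, " has zero CAZy-gene abundance in sample(s) ",
                 paste(rownames(abund)[cazyAb == 0], collapse = ", "))
        vals <- vapply(names(smap), function(sub) {
            hit <- inG & vapply(as.list(a$cazy), function(f)
                any(f %in% smap[[sub]]), logical(1))
            rowSums(abund[, hit, drop = FALSE])
        }, numeric(nrow(abund)))
        out[[g]] <- FeatureProfile(scale * vals / cazyAb,
                                   level = "substrate",
                                   normalization = "per_100k")
    }
    out
}

#' SCFA key-enzyme gene profile
#'
#' Sums KO-level abundances over each SCFA's mapped KO identifiers;
#' missing KOs contribute zero.
#'
#' @param koProfile A KO-level [FeatureProfile-class].
#' @param emap SCFA enzyme map (default [defaultScfaEnzymes()]).
#' @return A [FeatureProfile-class], samples x SCFAs, in the input's
#'   normalization.
#' @export
scfaGeneProfile <- function(koProfile, emap = defaultScfaEnzymes()) {
    stopifnot(is(koProfile, "FeatureProfile"))
    if (koProfile@level != "KO") stop("expected a KO-level profile")
    if (length(emap) == 0) stop("empty enzyme map")
    m <- profileValues(koProfile)
    vals <- vapply(names(emap), function(s) {
        kos <- intersect(unname(emap[[s]]), colnames(m))
        if (length(kos) == 0) return(numeric(nrow(m)))
        rowSums(m[, kos, drop = FALSE])
    }, numeric(nrow(m)))
    if (is.null(dim(vals)))
        vals <- matrix(vals, nrow(m), dimnames = list(rownames(m), names(emap)))
    FeatureProfile(vals, level = "SCFA",
                   normalization = koProfile@normalization)
}

#' VF or ARG class counts per functional group, per 100,000 genes
#'
#' Counts the genes of each virulence-factor or antibiotic-resistance
#' class in each functional group and normalizes to the group's total
#' annotated genes via [normalizePerGroup()].  Genes whose phylum maps to
#' `"other"` are excluded from both groups.  `weights` switches to
#' abundance-weighted counts (summed mean gene abundance instead of gene
#' number).
#'
#' @param annot A [GeneAnnotationTable-class].
#' @param fgmap Phylum -> group map.
#' @param field `"vf_class"` or `"arg_class"`.
#' @param weights Optional named per-gene abundance weights for the
#'   abundance-weighted variant (default NULL: plain gene counts).
#' @param scale Normalization scale (default 100,000).
#' @return A per-100k [FeatureProfile-class], groups x classes.
#' @export
classCountProfile <- function(annot, fgmap = defaultFunctionalGroups(),
                              field = c("vf_class", "arg_class"),
                              weights = NULL, scale = 1e5) {
    field <- match.arg(field)
    a <- annot@annot
    fg <- .fgOfGenes(annot, fgmap)
    w <- if (is.null(weights)) stats::setNames(rep(1, nrow(a)), a$gene_id)
         else weights[a$gene_id]
    groups <- c("FG1", "FG2")
    totals <- vapply(groups, function(g) sum(w[fg == g]), numeric(1))
    if (any(totals == 0))
        stop("no annotated gene in group(s): ",
             paste(groups[totals == 0], collapse = ", "))
    cls <- sort(unique(a[[field]][!is.na(a[[field]])]))
    counts <- matrix(0, length(groups), length(cls),
                     dimnames = list(groups, cls))
    for (g in groups)
        for (cl in cls)
            counts[g, cl] <- sum(w[fg == g & !is.na(a[[field]]) &
                                   a[[field]] == cl])
    normalizePerGroup(counts, totals, scale = scale,
                      level = if (field == "vf_class") "VF-class" else "ARG-class")
}

#' Drop features below an abundance floor in every sample
#'
#' Applies the per-100k exclusion rule: a feature is removed only when
#' its value is below `minValue` in all samples; a feature at or above
#' the floor in any single sample is retained.
#'
#' @param profile A per-100k [FeatureProfile-class].
#' @param minValue Exclusion floor (default 1 per 100,000).
#' @return The filtered [FeatureProfile-class].
#' @export
filterLowAbundance <- function(profile, minValue = 1.0) {
    stopifnot(is(profile, "FeatureProfile"))
    if (profile@normalization != "per_100k")
        stop("filterLowAbundance expects a per-100k profile")
    m <- profileValues(profile)
    keep <- apply(m, 2, function(x) any(x >= minValue))
    FeatureProfile(m[, keep, drop = FALSE], level = profile@level,
                   normalization = "per_100k")
}

#' Mann-Whitney (Wilcoxon rank-sum) two-group comparison
#'
#' `mode = "auto"` enumerates the exact null distribution when both
#' samples have at most 8 observations and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections.  The exact two-sided p-value is the null probability of a
#' U statistic at least as far from its mean `nm/2` as the observed one.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `U` (statistic for `x`), `p` (two-sided), `mode`.
#' @examples
#' compareGroups(c(1, 2), c(3, 4))
#' @export
compareGroups <- function(x, y, mode = c("auto", "exact", "approx")) {
    mode <- match.arg(mode)
    if (length(x) < 2 || length(y) < 2)
        stop("each sample needs at least 2 observations")
    n <- length(x); m <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    hasTies <- anyDuplicated(pooled) > 0
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    if (mode == "auto")
        mode <- if (n <= 8 && m <= 8 && !hasTies) "exact" else "approx"
    if (mode == "exact") {
        if (hasTies)
            stop("exact mode requires untied data; use approx")
        combs <- utils::combn(n + m, n)
        ranks <- seq_len(n + m)
        Us <- colSums(matrix(ranks[combs], nrow = n)) - n * (n + 1) / 2
        mid <- n * m / 2
        p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
    } else {
        mu <- n * m / 2
        tieTab <- table(pooled)
        tieAdj <- sum(tieTab^3 - tieTab) / ((n + m) * (n + m - 1))
        sigma <- sqrt(n * m / 12 * ((n + m + 1) - tieAdj))
        z <- max(0, abs(U - mu) - 0.5) / sigma
        p <- 2 * stats::pnorm(-z)
    }
    list(U = U, p = min(p, 1), mode = mode)
}
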