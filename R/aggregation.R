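## Gene -> category aggregation, relative-abundance normalization, the
## Functional Group 2 / Functional Group 1 ratio, and ratio labelling.

#' Aggregate gene abundances into category abundances
#'
#' Category abundance is the sum of the abundances of the genes annotated
#' to that category.  Genes lacking a label at the requested level (an
#' `"unknown"` lineage rank, or absent KO/CAZy/VF/ARG annotation) are
#' excluded from every category; their total abundance is tracked per
#' sample and available through [unassignedMass()].  At the CAZy level a
#' gene contributes its full abundance once to each family it carries.
#'
#' @param abund Samples-by-genes abundance matrix.
#' @param annot A [GeneAnnotationTable-class] covering every gene.
#' @param level One of the lineage ranks (`"phylum"`, `"genus"`, ...) or
#'   `"KO"`, `"CAZy"`, `"VF-class"`, `"ARG-class"`.
#' @return A raw [FeatureProfile-class] at the requested level.
#' @examples
#' sim <- simulateDataset(simulationParams(seed = 1))
#' phy <- aggregateByCategory(sim$abundance, sim$annotations, "phylum")
#' @export
aggregateByCategory <- function(abund, annot, level) {
    stopifnot(is(annot, "GeneAnnotationTable"))
    validateAbundanceMatrix(abund)
    a <- annot@annot
    unknown <- setdiff(colnames(abund), a$gene_id)
    if (length(unknown) > 0)
        stop("gene id(s) absent from the annotation table: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    a <- a[match(colnames(abund), a$gene_id), ]

    if (level %in% .LINEAGE_RANKS) {
        lab <- a[[level]]
        lab[lab == "unknown"] <- NA_character_
        labels <- as.list(lab)
        labels[is.na(lab)] <- list(character(0))
    } else if (level == "KO") {
        labels <- as.list(a$ko)
        labels[is.na(a$ko)] <- list(character(0))
    } else if (level == "CAZy") {
        labels <- as.list(a$cazy)
    } else if (level == "VF-class") {
        labels <- as.list(a$vf_class)
        labels[is.na(a$vf_class)] <- list(character(0))
    } else if (level == "ARG-class") {
        labels <- as.list(a$arg_class)
        labels[is.na(a$arg_class)] <- list(character(0))
    } else {
        stop("unsupported aggregation level: ", level)
    }

    nlab <- lengths(labels)
    cats <- sort(unique(unlist(labels)))
    if (length(cats) == 0)
        stop("no gene carries a label at level '", level, "'")
    ## gene -> category incidence (a CAZy gene can hit several categories)
    geneIdx <- rep(seq_along(labels), nlab)
    catIdx <- match(unlist(labels), cats)
    inc <- matrix(0, ncol(abund), length(cats),
                  dimnames = list(colnames(abund), cats))
    inc[cbind(geneIdx, catIdx)] <- 1
    values <- abund %*% inc
    unassigned <- rowSums(abund[, nlab == 0, drop = FALSE])
    FeatureProfile(values, level = level, normalization = "raw",
                   unassigned = unassigned)
}

#' Convert a raw profile to relative abundance
#'
#' Each sample is divided by its total under the chosen denominator.  With
#' `denominatorMode = "bacteria_only"` the profile is first restricted to
#' the features named in `bacterialFeatures` (e.g. the bacterial phyla),
#' matching the exclusion of scarce Eukaryota/Metazoa from community
#' denominators; after normalization every sample sums to 1.
#'
#' @param profile A raw [FeatureProfile-class].
#' @param denominatorMode `"classified_all"` (default) or `"bacteria_only"`.
#' @param bacterialFeatures Feature ids forming the denominator when
#'   `denominatorMode = "bacteria_only"`.
#' @return A relative [FeatureProfile-class]; feature order preserved.
#' @export
toRelative <- function(profile, denominatorMode = c("classified_all",
                                                    "bacteria_only"),
                       bacterialFeatures = NULL) {
    denominatorMode <- match.arg(denominatorMode)
    stopifnot(is(profile, "FeatureProfile"))
    if (profile@normalization != "raw")
        stop("toRelative expects a raw profile")
    m <- profileValues(profile)
    if (denominatorMode == "bacteria_only") {
        if (is.null(bacterialFeatures))
            stop("bacteria_only mode needs 'bacterialFeatures'")
        keep <- intersect(colnames(m), bacterialFeatures)
        if (length(keep) == 0)
            stop("no bacterial feature present in the profile")
        m <- m[, keep, drop = FALSE]
    }
    tot <- rowSums(m)
    if (any(tot == 0))
        stop("zero-sum sample(s) under the chosen denominator: ",
             paste(rownames(m)[tot == 0], collapse = ", "))
    FeatureProfile(m / tot, level = profile@level, normalization = "relative")
}

#' The Functional Group 2 / Functional Group 1 ratio
#'
#' For each sample, the summed relative abundance of the FG2 phyla
#' (Fusobacteria, Firmicutes, Bacteroidetes) divided by the relative
#' abundance of the FG1 phylum (Proteobacteria).  Because both terms are
#' relative abundances from the same sample, the ratio is invariant to any
#' positive rescaling of the sample's raw abundances and to the
#' denominator mode used in [toRelative()].  A zero FG1 abundance is an
#' error unless a positive pseudocount is supplied (added to both terms).
#'
#' @param phylumProfile A relative phylum-level [FeatureProfile-class]
#'   whose columns include every FG1 phylum.
#' @param fgmap Named character phylum -> `"FG1"`/`"FG2"` (default
#'   [defaultFunctionalGroups()]).
#' @param pseudocount Non-negative pseudocount (default 0).
#' @return data.frame with columns `sample_id`, `ratio`.
#' @examples
#' comp <- matrix(c(53.74, 16.99, 13.81, 6.86, 8.60) / 100, 1,
#'                dimnames = list("S1", c("Proteobacteria", "Bacteroidetes",
#'                                        "Firmicutes", "Fusobacteria",
#'                                        "Actinobacteria")))
#' fgRatio(FeatureProfile(comp, "phylum", "relative"))
#' @export
fgRatio <- function(phylumProfile, fgmap = defaultFunctionalGroups(),
                    pseudocount = 0) {
    stopifnot(is(phylumProfile, "FeatureProfile"), pseudocount >= 0)
    if (phylumProfile@normalization != "relative")
        stop("fgRatio expects a relative profile")
    if (phylumProfile@level != "phylum")
        stop("fgRatio expects a phylum-level profile")
    fg1 <- names(fgmap)[fgmap == "FG1"]
    fg2 <- names(fgmap)[fgmap == "FG2"]
    if (length(fg1) == 0 || length(fg2) == 0)
        stop("functional group map must name both FG1 and FG2 phyla")
    m <- profileValues(phylumProfile)
    missing1 <- setdiff(fg1, colnames(m))
    if (length(missing1) > 0)
        stop("FG1 phylum column(s) absent from the profile: ",
             paste(missing1, collapse = ", "))
    s1 <- rowSums(m[, fg1, drop = FALSE])
    s2 <- rowSums(m[, intersect(fg2, colnames(m)), drop = FALSE])
    if (pseudocount == 0 && any(s1 == 0))
        stop("Functional Group 1 abundance is zero in sample(s) ",
             paste(rownames(m)[s1 == 0], collapse = ", "),
             "; supply a positive pseudocount")
    data.frame(sample_id = rownames(m),
               ratio = (s2 + pseudocount) / (s1 + pseudocount),
               stringsAsFactors = FALSE)
}

#' Label samples by their FG2/FG1 ratio
#'
#' A sample is `high_FG2` when its ratio strictly exceeds the threshold and
#' `high_FG1` otherwise (ties go to `high_FG1`).
#'
#' @param ratios data.frame from [fgRatio()].
#' @param threshold Positive ratio threshold (default 1: FG2 mass exceeds
#'   FG1 mass).
#' @return The input with a `label` column appended.
#' @export
labelByRatio <- function(ratios, threshold = 1.0) {
    stopifnot(threshold > 0, all(c("sample_id", "ratio") %in% colnames(ratios)))
    ratios$label <- ifelse(ratios$ratio > threshold, "high_FG2", "high_FG1")
    ratios
}

#' Normalize per-group category counts to genes per 100,000
#'
#' `scale * count / groupTotal` for each category, where `groupTotal` is
#' the number of annotated genes in the functional group.
#'
#' @param categoryCounts Numeric matrix, groups as rows, categories as
#'   columns (or a named vector for a single group).
#' @param groupTotals Named positive totals per group.
#' @param scale Normalization scale (default 100,000).
#' @param level Feature level tag of the result.
#' @return A per-100k [FeatureProfile-class] (groups play the sample role).
#' @export
normalizePerGroup <- function(categoryCounts, groupTotals, scale = 1e5,
                              level = "ARG-class") {
    if (is.null(dim(categoryCounts)))
        categoryCounts <- matrix(categoryCounts, 1,
                                 dimnames = list(names(groupTotals)[1],
                                                 names(categoryCounts)))
    groups <- rownames(categoryCounts)
    if (!all(groups %in% names(groupTotals)))
        stop("groupTotals must name every group")
    tot <- groupTotals[groups]
    if (any(tot <= 0))
        stop("zero annotated-gene total for group(s): ",
             paste(groups[tot <= 0], collapse = ", "))
    if (any(categoryCounts > tot + 1e-9))
        stop("category count exceeds its group total")
    FeatureProfile(scale * categoryCounts / tot, level = level,
                   normalization = "per_100k")
}
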