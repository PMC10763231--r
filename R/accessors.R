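## Constructors, accessors and show methods for the core classes.

#' Construct a FeatureProfile from a samples-by-features matrix
#'
#' @param values Numeric matrix, samples as rows, features as columns, with
#'   row and column names.
#' @param level Feature level tag (e.g. `"phylum"`, `"genus"`, `"KO"`,
#'   `"CAZy"`).
#' @param normalization `"raw"` (default), `"relative"` or `"per_100k"`.
#' @param unassigned Optional per-sample vector of abundance mass excluded
#'   during aggregation.
#' @return A [FeatureProfile-class] object.
#' @examples
#' m <- matrix(c(2, 3, 1, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("Proteobacteria", "Firmicutes")))
#' FeatureProfile(m, level = "phylum")
#' @export
FeatureProfile <- function(values, level, normalization = "raw",
                           unassigned = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' needs sample (row) and feature (column) names")
    se <- SummarizedExperiment(assays = list(abundance = t(values)))
    fp <- new("FeatureProfile", se, level = level,
              normalization = normalization)
    if (!is.null(unassigned))
        metadata(fp)$unassigned <- unassigned
    fp
}

#' Extract the samples-by-features abundance matrix of a profile
#'
#' @param x A [FeatureProfile-class].
#' @return Numeric matrix with samples as rows and features as columns.
#' @export
profileValues <- function(x) {
    stopifnot(is(x, "FeatureProfile"))
    t(assay(x, "abundance"))
}

#' @rdname profileValues
#' @export
profileLevel <- function(x) x@level

#' @rdname profileValues
#' @export
profileNormalization <- function(x) x@normalization

#' @rdname profileValues
#' @export
sampleIds <- function(x) {
    if (is(x, "FeatureProfile")) return(colnames(x))
    if (is.data.frame(x) && "sample_id" %in% colnames(x))
        return(x$sample_id)
    stop("cannot extract sample ids from a ", class(x)[1])
}

#' @rdname profileValues
#' @export
featureIds <- function(x) {
    stopifnot(is(x, "FeatureProfile"))
    rownames(x)
}

#' Unassigned abundance mass tracked by an aggregation
#'
#' @param x A [FeatureProfile-class] produced by [aggregateByCategory()].
#' @return Named per-sample numeric vector (zeroes if nothing was excluded).
#' @export
unassignedMass <- function(x) {
    stopifnot(is(x, "FeatureProfile"))
    u <- metadata(x)$unassigned
    if (is.null(u)) u <- stats::setNames(numeric(ncol(x)), colnames(x))
    u
}

setMethod("show", "FeatureProfile", function(object) {
    cat(sprintf("FeatureProfile: %d samples x %d features [level=%s, %s]\n",
                ncol(object), nrow(object), object@level,
                object@normalization))
    cat("  features:", .abbrev(rownames(object)), "\n")
    cat("  samples: ", .abbrev(colnames(object)), "\n")
})

#' Construct a GeneAnnotationTable
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param length_bp Positive gene lengths in bp.
#' @param lineage Character matrix or data.frame with the seven rank
#'   columns (superkingdom..species); unresolved ranks as `"unknown"`.
#' @param ko Optional KO identifiers (`NA` where unannotated).
#' @param cazy Optional list of CAZy family label vectors per gene.
#' @param vf_class,arg_class Optional class labels (`NA` where unannotated).
#' @return A [GeneAnnotationTable-class].
#' @export
GeneAnnotationTable <- function(gene_id, length_bp, lineage,
                                ko = NULL, cazy = NULL,
                                vf_class = NULL, arg_class = NULL) {
    n <- length(gene_id)
    lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
    stopifnot(identical(colnames(lineage), .LINEAGE_RANKS), nrow(lineage) == n)
    if (is.null(ko)) ko <- rep(NA_character_, n)
    if (is.null(vf_class)) vf_class <- rep(NA_character_, n)
    if (is.null(arg_class)) arg_class <- rep(NA_character_, n)
    if (is.null(cazy)) cazy <- replicate(n, character(0), simplify = FALSE)
    a <- DataFrame(gene_id = as.character(gene_id),
                   length_bp = as.numeric(length_bp),
                   lineage,
                   ko = as.character(ko),
                   cazy = CharacterList(cazy),
                   vf_class = as.character(vf_class),
                   arg_class = as.character(arg_class))
    new("GeneAnnotationTable", annot = a)
}

#' Accessors for GeneAnnotationTable
#'
#' `geneIds` returns the gene identifiers; `annotations` the underlying
#' DataFrame; `geneLineage` the rank columns as a data.frame.
#'
#' @param x A [GeneAnnotationTable-class].
#' @return See description.
#' @export
geneIds <- function(x) x@annot$gene_id

#' @rdname geneIds
#' @export
annotations <- function(x) x@annot

#' @rdname geneIds
#' @export
geneLineage <- function(x) as.data.frame(x@annot[, .LINEAGE_RANKS])

setMethod("show", "GeneAnnotationTable", function(object) {
    a <- object@annot
    cat(sprintf("GeneAnnotationTable: %d genes\n", nrow(a)))
    cat(sprintf("  with KO: %d | with CAZy: %d | with VF: %d | with ARG: %d\n",
                sum(!is.na(a$ko)), sum(lengths(a$cazy) > 0),
                sum(!is.na(a$vf_class)), sum(!is.na(a$arg_class))))
})

setMethod("length", "GeneAnnotationTable", function(x) nrow(x@annot))

setMethod("show", "CooccurrenceNetwork", function(object) {
    e <- object@edges
    cat(sprintf("CooccurrenceNetwork: %d nodes, %d edges (|rho| > %.3g, p < %.3g)\n",
                nrow(object@nodes), nrow(e), object@thresholdUsed,
                object@pMax))
    if (nrow(e) > 0)
        cat(sprintf("  co-occurrence: %d | co-exclusion: %d\n",
                    sum(e$sign == "co-occurrence"),
                    sum(e$sign == "co-exclusion")))
})

#' Accessors for CooccurrenceNetwork
#'
#' @param x A [CooccurrenceNetwork-class].
#' @return `networkEdges`/`networkNodes` return data.frames;
#'   `networkThreshold` the |rho| cutoff actually used.
#' @export
networkEdges <- function(x) x@edges

#' @rdname networkEdges
#' @export
networkNodes <- function(x) x@nodes

#' @rdname networkEdges
#' @export
networkThreshold <- function(x) x@thresholdUsed

setMethod("show", "PartitionResult", function(object) {
    cat(sprintf("PartitionResult: %d nodes, score %.4f (%s)\n",
                length(object@groupOfNode), object@score,
                if (object@isExhaustive) "exhaustive" else "greedy"))
    for (g in c("G_A", "G_B"))
        cat(sprintf("  %s: %s\n", g,
                    .abbrev(names(object@groupOfNode)[object@groupOfNode == g])))
})

#' Accessors for PartitionResult
#'
#' @param x A [PartitionResult-class].
#' @return `groupOfNode` a named character vector; `partitionScore` the
#'   signed agreement score.
#' @export
groupOfNode <- function(x) x@groupOfNode

#' @rdname groupOfNode
#' @export
partitionScore <- function(x) x@score

setMethod("show", "ModuleSet", function(object) {
    mods <- setdiff(unique(object@moduleOfGene), "grey")
    cat(sprintf("ModuleSet: %d modules over %d genes (%d grey)\n",
                length(mods), length(object@moduleOfGene),
                sum(object@moduleOfGene == "grey")))
})

#' Accessors for ModuleSet
#'
#' @param x A [ModuleSet-class].
#' @return `moduleOfGene` the named gene -> module vector; `eigengenes` the
#'   samples x modules matrix; `varianceExplained` per-module PC1 variance
#'   share.
#' @export
moduleOfGene <- function(x) x@moduleOfGene

#' @rdname moduleOfGene
#' @export
eigengenes <- function(x) x@eigengenes

#' @rdname moduleOfGene
#' @export
varianceExplained <- function(x) x@varianceExplained

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d taxa, %d phyla, %d host genes, %d phage (seed %d)\n",
                length(object@phylumOfTaxon),
                length(object@fgOfPhylum),
                length(object@moduleOfGene),
                length(object@hostOfVirus), object@seed))
})

setMethod("show", "SimulationParams", function(object) {
    cat(sprintf(paste0("SimulationParams: %d samples/cell, taxa per phylum [%s],\n",
                       "  anticorr %.2f, dietEffect %.2f, %d host genes / %d modules ",
                       "(coupling %.2f),\n  %d phage (coupling %.2f), noiseSd %.2f, seed %d\n"),
                object@nSamplesPerCell,
                paste(sprintf("%s=%d", names(object@nTaxaPerPhylum),
                              object@nTaxaPerPhylum), collapse = ", "),
                object@groupAnticorr, object@dietEffect, object@nHostGenes,
                object@nModules, object@moduleCoupling, object@nViralTaxa,
                object@viromeCoupling, object@noiseSd, object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(paste0("PipelineConfig: denominator=%s, |rho|>%.2f, p<%.3g, ",
                       "RMT=%s,\n  B=%d, pseudocount=%.3g, label threshold=%.2f, ",
                       "modules(min=%d, cut=%.2f), seed=%d\n"),
                object@denominatorMode, object@spearmanRMin, object@pMax,
                object@useRmtThreshold, object@permutations,
                object@ratioPseudocount, object@ratioLabelThreshold,
                object@moduleMinSize, object@moduleCutHeight, object@rngSeed))
})

.abbrev <- function(x, n = 6) {
    if (length(x) <= n) return(paste(x, collapse = ", "))
    paste0(paste(utils::head(x, n), collapse = ", "), ", ... (",
           length(x), " total)")
}
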