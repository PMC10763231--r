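#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Taxonomic ranks carried by every gene lineage, outermost first.
.LINEAGE_RANKS <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species")

.PROFILE_LEVELS <- c(.LINEAGE_RANKS, "KO", "CAZy", "VF-class", "ARG-class",
                     "viral-family", "viral-genus", "substrate", "SCFA",
                     "module")

.NORMALIZATIONS <- c("raw", "relative", "per_100k")

.DIETS <- c("CD", "OD", "HD")
.WEEKS <- c(1L, 3L)

#' GeneAnnotationTable: per-gene taxonomy and functional labels
#'
#' One row per non-redundant gene, carrying its taxonomic lineage
#' (superkingdom down to species, with `"unknown"` for unresolved ranks)
#' and optional functional labels: a KEGG orthology (KO) identifier, a set
#' of CAZy family labels, a virulence-factor (VF) class, and an antibiotic
#' resistance gene (ARG) class.  Missing functional annotation is stored as
#' `NA` (or an empty CAZy set), never as an empty-string category, so that
#' category sums can never silently absorb unannotated genes.
#'
#' @slot annot A [S4Vectors::DataFrame] with columns `gene_id`, `length_bp`,
#'   the seven lineage ranks, `ko`, `cazy` (a [IRanges::CharacterList]),
#'   `vf_class` and `arg_class`.
#' @seealso [readGeneAnnotations()], [aggregateByCategory()]
#' @export
setClass("GeneAnnotationTable", slots = c(annot = "DFrame"))

setValidity("GeneAnnotationTable", function(object) {
    a <- object@annot
    need <- c("gene_id", "length_bp", .LINEAGE_RANKS,
              "ko", "cazy", "vf_class", "arg_class")
    miss <- setdiff(need, colnames(a))
    if (length(miss) > 0)
        return(paste("missing annotation columns:",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(a$gene_id))
        return(sprintf("duplicated gene_id: %s",
                       paste(unique(a$gene_id[duplicated(a$gene_id)]),
                             collapse = ", ")))
    if (any(!is.finite(a$length_bp)) || any(a$length_bp <= 0))
        return("length_bp must be a positive number for every gene")
    for (rk in .LINEAGE_RANKS) {
        v <- a[[rk]]
        if (any(is.na(v)) || any(!nzchar(v)))
            return(sprintf("lineage rank '%s' contains empty labels; use 'unknown'", rk))
    }
    if (!is(a$cazy, "CharacterList"))
        return("cazy column must be a CharacterList")
    TRUE
})

#' FeatureProfile: a tagged samples-by-features abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] (features as rows, samples
#' as columns, single assay `"abundance"`) tagged with the feature level it
#' was aggregated at (phylum, genus, KO, CAZy family, VF class, ...) and its
#' normalization state: `"raw"` summed gene abundance, `"relative"`
#' (each sample sums to 1) or `"per_100k"` (counts per 100,000 annotated
#' genes).  Unassigned gene mass excluded during aggregation is kept in
#' `metadata(x)$unassigned` as a per-sample vector.
#'
#' @slot level Character scalar, the feature level.
#' @slot normalization One of `"raw"`, `"relative"`, `"per_100k"`.
#' @seealso [aggregateByCategory()], [toRelative()], [profileValues()]
#' @export
setClass("FeatureProfile",
         contains = "SummarizedExperiment",
         slots = c(level = "character", normalization = "character"))

setValidity("FeatureProfile", function(object) {
    if (length(object@level) != 1L || !object@level %in% .PROFILE_LEVELS)
        return(paste("level must be one of:",
                     paste(.PROFILE_LEVELS, collapse = ", ")))
    if (length(object@normalization) != 1L ||
        !object@normalization %in% .NORMALIZATIONS)
        return(paste("normalization must be one of:",
                     paste(.NORMALIZATIONS, collapse = ", ")))
    m <- assay(object)
    if (any(!is.finite(m)))
        return("abundance values must be finite")
    if (any(m < 0))
        return("abundance values must be non-negative")
    if (anyDuplicated(colnames(object)))
        return("sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        return("feature ids must be unique")
    if (object@normalization == "relative") {
        s <- colSums(m)
        if (any(abs(s - 1) > 1e-9))
            return("relative profile columns (samples) must each sum to 1")
    }
    TRUE
})

#' CooccurrenceNetwork: signed taxon co-occurrence graph
#'
#' Nodes are taxa (with their mean relative abundance); edges are pairs
#' whose Spearman correlation passed `|rho| > threshold` and `p < pMax`.
#' Negative-rho edges are co-exclusions, positive-rho edges co-occurrences.
#'
#' @slot nodes data.frame with columns `node`, `mean_abundance`.
#' @slot edges data.frame with columns `node_a`, `node_b`, `rho`, `p`, `sign`.
#' @slot thresholdUsed Numeric, the |rho| threshold actually applied.
#' @slot pMax Numeric, the p-value cutoff applied.
#' @seealso [correlationNetwork()], [partitionFunctionalGroups()]
#' @export
setClass("CooccurrenceNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame",
                   thresholdUsed = "numeric", pMax = "numeric"))

setValidity("CooccurrenceNetwork", function(object) {
    e <- object@edges
    need <- c("node_a", "node_b", "rho", "p", "sign")
    if (!all(need %in% colnames(e)))
        return("edges must have columns node_a, node_b, rho, p, sign")
    if (nrow(e) > 0) {
        if (any(e$node_a == e$node_b))
            return("self-edges are not allowed")
        if (any(abs(e$rho) > 1 + 1e-12))
            return("edge rho out of [-1, 1]")
        if (any(abs(e$rho) < object@thresholdUsed - 1e-12))
            return("edge below the correlation threshold")
        if (any(e$p > object@pMax))
            return("edge p-value above pMax")
        ok <- ifelse(e$rho < 0, e$sign == "co-exclusion",
                     e$sign == "co-occurrence")
        if (!all(ok))
            return("edge sign inconsistent with rho")
    }
    TRUE
})

#' PartitionResult: a two-group split of network nodes
#'
#' @slot groupOfNode Named character, values `"G_A"`/`"G_B"`.
#' @slot score Numeric, the signed agreement score of the partition.
#' @slot isExhaustive Logical, whether every bipartition was enumerated.
#' @seealso [partitionFunctionalGroups()]
#' @export
setClass("PartitionResult",
         slots = c(groupOfNode = "character", score = "numeric",
                   isExhaustive = "logical"))

setValidity("PartitionResult", function(object) {
    g <- object@groupOfNode
    if (is.null(names(g)) || anyDuplicated(names(g)))
        return("groupOfNode must be uniquely named by node")
    if (!all(g %in% c("G_A", "G_B")))
        return("groups must be G_A or G_B")
    TRUE
})

#' ModuleSet: host co-expression modules and their eigengenes
#'
#' Gene-to-module assignment (WGCNA-style color labels, `"grey"` for
#' unassigned genes), the samples-by-modules eigengene matrix (each column
#' scaled to unit variance), and the share of module expression variance
#' each eigengene explains.
#'
#' @slot moduleOfGene Named character, gene -> module label.
#' @slot eigengenes Numeric matrix, samples x modules.
#' @slot varianceExplained Named numeric in (0, 1], per module.
#' @seealso [detectModules()], [moduleEigengenes()], [associateModules()]
#' @export
setClass("ModuleSet",
         slots = c(moduleOfGene = "character", eigengenes = "matrix",
                   varianceExplained = "numeric"))

setValidity("ModuleSet", function(object) {
    mods <- setdiff(unique(object@moduleOfGene), "grey")
    if (!setequal(mods, colnames(object@eigengenes)))
        return("eigengene columns must match the non-grey module labels")
    v <- apply(object@eigengenes, 2, stats::var)
    if (length(v) > 0 && any(abs(v - 1) > 1e-6))
        return("eigengene columns must have unit variance")
    ve <- object@varianceExplained
    if (!setequal(names(ve), mods))
        return("varianceExplained must be named by module")
    if (length(ve) > 0 && (any(ve <= 0) || any(ve > 1 + 1e-9)))
        return("varianceExplained must lie in (0, 1]")
    TRUE
})

#' SyntheticTruth: the planted structure of a simulated dataset
#'
#' Records everything the generator planted, so recovery can be scored:
#' taxon -> phylum and phylum -> functional-group maps, the two per-sample
#' latent community factors, gene -> host module assignment, each module's
#' coupling sign (+1 tracks the Functional Group 1 factor, -1 the
#' Functional Group 2 factor), the planted bacterial host of each viral
#' taxon, and the seed.
#'
#' @slot phylumOfTaxon Named character, taxon -> phylum.
#' @slot fgOfPhylum Named character, phylum -> FG1/FG2/other.
#' @slot latent Numeric matrix, samples x 2 (`fg1`, `fg2` factors).
#' @slot moduleOfGene Named character, host gene -> module (or "grey").
#' @slot moduleSign Named integer, module -> +1/-1.
#' @slot moduleLatent List with one samples-by-modules matrix per tissue:
#'   each module's own latent profile (a `moduleSign`-weighted blend of
#'   the group factor with a module-private factor).
#' @slot hostOfVirus Named character, viral taxon -> bacterial taxon.
#' @slot seed Integer seed used by the generator.
#' @seealso [simulateDataset()]
#' @export
setClass("SyntheticTruth",
         slots = c(phylumOfTaxon = "character", fgOfPhylum = "character",
                   latent = "matrix", moduleOfGene = "character",
                   moduleSign = "integer", moduleLatent = "list",
                   hostOfVirus = "character", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    if (!all(object@moduleSign %in% c(-1L, 1L)))
        return("module signs must be +1 or -1")
    if (!all(object@phylumOfTaxon %in% names(object@fgOfPhylum)))
        return("every taxon's phylum must be mapped to a functional group")
    if (!identical(colnames(object@latent), c("fg1", "fg2")))
        return("latent factor columns must be named fg1, fg2")
    TRUE
})

#' SimulationParams: configuration of the synthetic community generator
#'
#' Defaults mirror the study design the generator emulates: 3 diets
#' (carnivorous CD, omnivorous OD, herbivorous HD) x 2 weeks x 6 replicates
#' = 36 samples; four dominant phyla with Proteobacteria anti-correlated to
#' Fusobacteria/Firmicutes/Bacteroidetes; a diet-driven log-scale boost of
#' the latter three in OD/HD; host co-expression modules coupled with
#' opposite signs to the two community factors; and phage profiles coupled
#' to their bacterial hosts.
#'
#' @slot nSamplesPerCell Samples per diet-by-week cell (default 6).
#' @slot nTaxaPerPhylum Named integer, taxa simulated per phylum.
#' @slot genesPerTaxon Genes per bacterial taxon.
#' @slot groupAnticorr Strength in `[0, 1]` of the FG1/FG2 anti-correlation.
#' @slot dietEffect Log-scale displacement in OD/HD vs CD: `+dietEffect`
#'   on FG2 taxa, `-dietEffect` on FG1 taxa.
#' @slot nHostGenes Host genes per tissue expression matrix.
#' @slot nModules Number of planted host co-expression modules.
#' @slot moduleCoupling Correlation in `[0, 1]` between a module gene and its
#'   module latent profile.
#' @slot nViralTaxa Number of viral (phage) taxa.
#' @slot viromeCoupling Correlation strength in `[0, 1]` between a phage and
#'   its planted bacterial host.
#' @slot noiseSd Log-scale abundance noise standard deviation.
#' @slot seed Integer RNG seed.
#' @seealso [simulationParams()], [simulateDataset()]
#' @export
setClass("SimulationParams",
         slots = c(nSamplesPerCell = "integer", nTaxaPerPhylum = "integer",
                   genesPerTaxon = "integer", groupAnticorr = "numeric",
                   dietEffect = "numeric", nHostGenes = "integer",
                   nModules = "integer", moduleCoupling = "numeric",
                   nViralTaxa = "integer", viromeCoupling = "numeric",
                   noiseSd = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
    cnt <- c(object@nSamplesPerCell, object@nTaxaPerPhylum,
             object@genesPerTaxon, object@nHostGenes, object@nModules,
             object@nViralTaxa)
    if (any(cnt <= 0L))
        return("all counts must be positive")
    if (object@groupAnticorr < 0 || object@groupAnticorr > 1)
        return("groupAnticorr must lie in [0, 1]")
    if (object@moduleCoupling < 0 || object@moduleCoupling > 1)
        return("moduleCoupling must lie in [0, 1]")
    if (object@viromeCoupling < 0 || object@viromeCoupling > 1)
        return("viromeCoupling must lie in [0, 1]")
    if (object@dietEffect < 0)
        return("dietEffect must be non-negative")
    if (object@noiseSd <= 0)
        return("noiseSd must be positive")
    if (is.null(names(object@nTaxaPerPhylum)))
        return("nTaxaPerPhylum must be named by phylum")
    TRUE
})

#' PipelineConfig: knobs of the end-to-end analysis pipeline
#'
#' @slot denominatorMode `"classified_all"` or `"bacteria_only"`: which genes
#'   enter relative-abundance denominators.
#' @slot spearmanRMin Network edge threshold on |rho| (default 0.5).
#' @slot pMax Network edge p-value cutoff (default 0.05).
#' @slot useRmtThreshold Replace the fixed rho threshold with the
#'   random-matrix-theory scan.
#' @slot permutations Permutations for PERMANOVA/ANOSIM/Mantel (default 999).
#' @slot ratioPseudocount Pseudocount added to both terms of the FG2/FG1
#'   ratio (default 0).
#' @slot ratioLabelThreshold Ratio above which a sample is labelled
#'   `high_FG2` (default 1).
#' @slot moduleMinSize Smallest retained co-expression module.
#' @slot moduleCutHeight Static tree-cut height on the 1 - |r| scale.
#' @slot rngSeed Master seed; all stage seeds derive from it.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
         slots = c(denominatorMode = "character", spearmanRMin = "numeric",
                   pMax = "numeric", useRmtThreshold = "logical",
                   permutations = "integer", ratioPseudocount = "numeric",
                   ratioLabelThreshold = "numeric", moduleMinSize = "integer",
                   moduleCutHeight = "numeric", rngSeed = "integer"))

setValidity("PipelineConfig", function(object) {
    if (!object@denominatorMode %in% c("classified_all", "bacteria_only"))
        return("denominatorMode must be classified_all or bacteria_only")
    if (object@spearmanRMin <= 0 || object@spearmanRMin >= 1)
        return("spearmanRMin must lie in (0, 1)")
    if (object@pMax <= 0 || object@pMax >= 1)
        return("pMax must lie in (0, 1)")
    if (object@permutations < 99L)
        return("permutations must be at least 99")
    if (object@ratioPseudocount < 0)
        return("ratioPseudocount must be non-negative")
    if (object@ratioLabelThreshold <= 0)
        return("ratioLabelThreshold must be positive")
    TRUE
})
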