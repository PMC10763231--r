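## Synthetic community generator.
##
## The generator plants the structure the downstream analyses assume:
## a logistic-normal bacterial community driven by two anti-correlated
## latent factors (one per functional group), a diet-dependent log-scale
## boost of Functional Group 2 in the omnivorous/herbivorous diets, host
## co-expression modules coupled with opposite signs to the two factors,
## functional labels (CAZy/VF/ARG/KO) biased by group, and phage profiles
## coupled to planted bacterial hosts.  Everything planted is recorded in
## a SyntheticTruth so recovery can be scored.

.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue")

## Share of a module latent profile that is the group factor; the rest is
## a module-private factor.  Must be low enough that distinct modules
## tracking the same group factor remain separable by co-expression
## clustering (their latents correlate at this share), yet high enough
## that every module's eigengene carries a clear group signature.
.MODULE_GROUP_SHARE <- 0.6

## Log-scale standard deviation of the two community-state factors.  This
## sets how much whole-community composition drifts between replicate
## samples relative to the per-taxon noise (noiseSd) and the diet shift
## (dietEffect); see the methods vignette for the power analysis behind
## the value.
.LATENT_SD <- 0.3

.VF_CLASSES <- c("adherence", "antiphagocytosis", "endotoxin", "iron uptake",
                 "manganese uptake", "secretion system", "toxin", "invasion",
                 "immune evasion", "motility", "regulation", "stress protein")

.ARG_CLASSES <- c("multidrug", "beta-lactam", "tetracycline", "macrolide",
                  "aminoglycoside", "oxazolidinone", "rifamycin",
                  "bicyclomycin", "lincosamide", "streptogramin",
                  "fluoroquinolone")

#' Create simulation parameters
#'
#' Defaults describe the study design the generator emulates: 6 replicates
#' per diet (CD/OD/HD) by week (1/3) cell; four dominant bacterial phyla
#' with Proteobacteria carrying the largest mean abundance; a strong
#' (0.9) anti-correlation between the Functional Group 1 and Functional
#' Group 2 latent factors; reciprocal one-log-unit diet shifts of the two
#' groups in OD/HD; five host modules at coupling 0.9; and twelve phage
#' taxa at coupling 0.9.  See the methods vignette for the rationale
#' behind each default.
#'
#' @param nSamplesPerCell Replicates per diet-by-week cell.
#' @param nTaxaPerPhylum Named integer vector of taxa per phylum.
#' @param genesPerTaxon Genes per bacterial taxon.
#' @param groupAnticorr FG1/FG2 latent anti-correlation in `[0, 1]`.
#' @param dietEffect Log-scale displacement in OD/HD vs CD, applied as
#'   `+dietEffect` to FG2 taxa and `-dietEffect` to FG1 taxa (>= 0).
#' @param nHostGenes Host genes per tissue.
#' @param nModules Planted host modules.
#' @param moduleCoupling Gene-to-module-latent correlation in `[0, 1]`.
#' @param nViralTaxa Phage taxa.
#' @param viromeCoupling Phage-to-host coupling in `[0, 1]`.
#' @param noiseSd Log-scale abundance noise SD (> 0).
#' @param seed Integer seed.
#' @return A [SimulationParams-class].
#' @export
simulationParams <- function(nSamplesPerCell = 6,
                             nTaxaPerPhylum = c(Proteobacteria = 8,
                                                Bacteroidetes = 6,
                                                Firmicutes = 6,
                                                Fusobacteria = 4,
                                                Actinobacteria = 2),
                             genesPerTaxon = 40,
                             groupAnticorr = 0.9,
                             dietEffect = 1.0,
                             nHostGenes = 300,
                             nModules = 5,
                             moduleCoupling = 0.9,
                             nViralTaxa = 12,
                             viromeCoupling = 0.9,
                             noiseSd = 0.5,
                             seed = 1) {
    np <- as.integer(nTaxaPerPhylum)
    names(np) <- names(nTaxaPerPhylum)
    new("SimulationParams",
        nSamplesPerCell = as.integer(nSamplesPerCell),
        nTaxaPerPhylum = np,
        genesPerTaxon = as.integer(genesPerTaxon),
        groupAnticorr = groupAnticorr, dietEffect = dietEffect,
        nHostGenes = as.integer(nHostGenes), nModules = as.integer(nModules),
        moduleCoupling = moduleCoupling, nViralTaxa = as.integer(nViralTaxa),
        viromeCoupling = viromeCoupling, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Default phylum-to-functional-group map
#'
#' Functional Group 1 is Proteobacteria; Functional Group 2 is
#' Fusobacteria, Firmicutes and Bacteroidetes; every other phylum maps to
#' `"other"` on lookup.
#'
#' @return Named character vector phylum -> `"FG1"`/`"FG2"`.
#' @export
defaultFunctionalGroups <- function() {
    c(Proteobacteria = "FG1", Fusobacteria = "FG2", Firmicutes = "FG2",
      Bacteroidetes = "FG2")
}

## Log-scale mean abundance per phylum: Proteobacteria dominates the
## community as in a typical carnivorous-baseline fish gut.
.phylumBaseLog <- function(phyla) {
    base <- c(Proteobacteria = log(12), Bacteroidetes = log(3),
              Firmicutes = log(2.5), Fusobacteria = log(2))
    out <- base[phyla]
    out[is.na(out)] <- log(0.3)
    names(out) <- phyla
    out
}

#' Simulate a fully labelled multi-omics dataset
#'
#' Draws bacterial taxon abundances logistic-normally from two latent
#' factors with correlation `-groupAnticorr`, shifts FG2 taxa up and FG1
#' taxa down by `dietEffect` log units in OD/HD samples, splits each
#' taxon's abundance
#' over its genes, assigns biased functional labels (FG2 carries
#' fibre-degrading CAZy families and SCFA enzyme KOs; FG1 starch families
#' plus 3x the VF/ARG label probability), generates gut and liver host
#' expression from signed module latents, and couples each phage taxon to
#' a planted bacterial host.  Identical seeds give identical output.
#'
#' @param params A [SimulationParams-class] from [simulationParams()].
#' @return Named list with elements `annotations`
#'   ([GeneAnnotationTable-class]), `abundance` (samples x genes matrix),
#'   `metadata` (data.frame), `hostExpression` (list of `gut` and `liver`
#'   samples x genes matrices), `viralProfile` ([FeatureProfile-class],
#'   raw viral-genus level), and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateDataset(simulationParams(seed = 7))
#' dim(sim$abundance)
#' @export
simulateDataset <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    set.seed(params@seed)

    ## -- samples ---------------------------------------------------------
    cells <- expand.grid(replicate = seq_len(params@nSamplesPerCell),
                         diet = .DIETS, week = .WEEKS,
                         stringsAsFactors = FALSE)
    n <- nrow(cells)
    meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                       diet = cells$diet, week = as.integer(cells$week),
                       replicate = as.integer(cells$replicate),
                       stringsAsFactors = FALSE)
    meta <- validateSampleMetadata(meta)

    ## -- latent community factors ---------------------------------------
    a <- params@groupAnticorr
    e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
    z1 <- .LATENT_SD * e1
    z2 <- .LATENT_SD * (-a * e1 + sqrt(1 - a^2) * e2)
    latent <- cbind(fg1 = z1, fg2 = z2)
    rownames(latent) <- meta$sample_id

    ## -- taxa ------------------------------------------------------------
    phyla <- names(params@nTaxaPerPhylum)
    taxa <- unlist(lapply(phyla, function(ph)
        sprintf("%s_g%02d", ph, seq_len(params@nTaxaPerPhylum[[ph]]))))
    phylumOfTaxon <- rep(phyla, params@nTaxaPerPhylum)
    names(phylumOfTaxon) <- taxa
    fgmap <- defaultFunctionalGroups()
    fgOfPhylum <- stats::setNames(
        ifelse(phyla %in% names(fgmap), fgmap[phyla], "other"), phyla)
    fgOfTaxon <- stats::setNames(unname(fgOfPhylum[phylumOfTaxon]), taxa)

    baseLog <- .phylumBaseLog(phylumOfTaxon) +
        stats::rnorm(length(taxa), sd = 0.3)
    loading <- ifelse(fgOfTaxon == "FG1", latent[, "fg1"],
               ifelse(fgOfTaxon == "FG2", latent[, "fg2"], 0))
    ## loading is resolved per (sample, taxon) below
    ## Plant-rich diets push the community both ways: FG2 taxa gain
    ## dietEffect log units in OD/HD while FG1 (Proteobacteria) taxa lose
    ## the same amount, mirroring the reciprocal abundance shifts the
    ## analysis is meant to detect.
    dietBoost <- as.numeric(meta$diet %in% c("OD", "HD")) * params@dietEffect

    logAbund <- matrix(0, n, length(taxa),
                       dimnames = list(meta$sample_id, taxa))
    for (j in seq_along(taxa)) {
        zj <- switch(fgOfTaxon[j],
                     FG1 = latent[, "fg1"],
                     FG2 = latent[, "fg2"],
                     rep(0, n))
        boost <- switch(fgOfTaxon[j], FG2 = dietBoost, FG1 = -dietBoost, 0)
        logAbund[, j] <- baseLog[j] + zj + boost +
            stats::rnorm(n, sd = params@noiseSd)
    }
    taxonAbund <- exp(logAbund)

    ## -- genes -----------------------------------------------------------
    g <- params@genesPerTaxon
    geneTaxon <- rep(taxa, each = g)
    geneIds <- sprintf("gene%05d", seq_along(geneTaxon))
    ## Dirichlet(1) split of each taxon's abundance over its genes
    w <- stats::rexp(length(geneIds))
    wsum <- tapply(w, geneTaxon, sum)[geneTaxon]
    w <- w / wsum
    abundance <- taxonAbund[, geneTaxon, drop = FALSE] *
        matrix(w, n, length(geneIds), byrow = TRUE)
    colnames(abundance) <- geneIds

    annotations <- .simulateAnnotations(geneIds, geneTaxon,
                                        phylumOfTaxon, fgOfTaxon[geneTaxon])

    ## -- host expression -------------------------------------------------
    nMod <- params@nModules
    modNames <- .MODULE_COLORS[seq_len(nMod)]
    moduleSign <- stats::setNames(
        as.integer(rep(c(1L, -1L), length.out = nMod)), modNames)
    nAssigned <- floor(0.8 * params@nHostGenes / nMod) * nMod
    hostGenes <- sprintf("host%04d", seq_len(params@nHostGenes))
    moduleOfGene <- stats::setNames(
        c(rep(modNames, each = nAssigned / nMod),
          rep("grey", params@nHostGenes - nAssigned)), hostGenes)
    mkTissue <- function() {
        expr <- matrix(stats::rnorm(n * params@nHostGenes), n,
                       params@nHostGenes,
                       dimnames = list(meta$sample_id, hostGenes))
        tms <- matrix(0, n, nMod, dimnames = list(meta$sample_id, modNames))
        for (m in modNames) {
            ## unit-variance version of the tracked community factor
            zg <- (if (moduleSign[m] > 0) latent[, "fg1"] else
                   latent[, "fg2"]) / .LATENT_SD
            tm <- sqrt(.MODULE_GROUP_SHARE) * zg +
                sqrt(1 - .MODULE_GROUP_SHARE) * stats::rnorm(n)
            tms[, m] <- tm
            idx <- which(moduleOfGene == m)
            cpl <- params@moduleCoupling
            expr[, idx] <- cpl * tm +
                sqrt(1 - cpl^2) * matrix(stats::rnorm(n * length(idx)),
                                         n, length(idx))
        }
        list(expr = expr, latent = tms)
    }
    gut <- mkTissue(); liver <- mkTissue()
    hostExpression <- list(gut = gut$expr, liver = liver$expr)
    moduleLatent <- list(gut = gut$latent, liver = liver$latent)

    ## -- virome ----------------------------------------------------------
    bactTaxa <- taxa[fgOfTaxon != "other"]
    hostOfVirus <- stats::setNames(
        sample(bactTaxa, params@nViralTaxa, replace = TRUE),
        sprintf("Phage_v%02d", seq_len(params@nViralTaxa)))
    vc <- params@viromeCoupling
    viral <- vapply(names(hostOfVirus), function(v) {
        hostLog <- as.vector(scale(logAbund[, hostOfVirus[v]]))
        exp(log(2) + vc * hostLog +
            sqrt(1 - vc^2) * stats::rnorm(n, sd = 1))
    }, numeric(n))
    rownames(viral) <- meta$sample_id
    viralProfile <- FeatureProfile(viral, level = "viral-genus",
                                   normalization = "raw")

    truth <- new("SyntheticTruth",
                 phylumOfTaxon = phylumOfTaxon, fgOfPhylum = fgOfPhylum,
                 latent = latent, moduleOfGene = moduleOfGene,
                 moduleSign = moduleSign, moduleLatent = moduleLatent,
                 hostOfVirus = hostOfVirus, seed = params@seed)
    list(annotations = annotations, abundance = abundance, metadata = meta,
         hostExpression = hostExpression, viralProfile = viralProfile,
         truth = truth)
}

## Functional labels: FG2 genes carry fibre-substrate CAZy families and
## SCFA-enzyme KOs preferentially; FG1 genes starch families plus 3x the
## VF/ARG Bernoulli rate of FG2.
.simulateAnnotations <- function(geneIds, geneTaxon, phylumOfTaxon, fgOfGene) {
    nG <- length(geneIds)
    phylum <- phylumOfTaxon[geneTaxon]
    lineage <- data.frame(superkingdom = rep("Bacteria", nG),
                          phylum = unname(phylum),
                          class = "unknown", order = "unknown",
                          family = "unknown", genus = unname(geneTaxon),
                          species = "unknown", stringsAsFactors = FALSE)
    lengthBp <- round(stats::runif(nG, 300, 3000))

    smap <- defaultSubstrateMap()
    fibreFams <- unique(unlist(smap[c("arabinoxylan", "pectin", "cellulose")]))
    starchFams <- smap$starch
    otherFams <- unique(unlist(smap[c("mucin", "inulin")]))
    cazy <- replicate(nG, character(0), simplify = FALSE)
    drawFams <- function(pool) sample(pool, sample(1:2, 1))
    for (i in seq_len(nG)) {
        fg <- fgOfGene[i]
        u <- stats::runif(1)
        if (fg == "FG2" && u < 0.25) cazy[[i]] <- drawFams(fibreFams)
        else if (fg == "FG1" && u < 0.25) cazy[[i]] <- drawFams(starchFams)
        else if (u < 0.10) cazy[[i]] <- drawFams(otherFams)
    }

    emap <- defaultScfaEnzymes()
    scfaKos <- unlist(lapply(emap, function(e) unname(e)))
    koPool <- sprintf("K%05d", 1:150)
    ko <- rep(NA_character_, nG)
    pScfa <- ifelse(fgOfGene == "FG2", 0.05, 0.01)
    isScfa <- stats::runif(nG) < pScfa
    ko[isScfa] <- sample(scfaKos, sum(isScfa), replace = TRUE)
    isGeneric <- !isScfa & stats::runif(nG) < 0.40
    ko[isGeneric] <- sample(koPool, sum(isGeneric), replace = TRUE)

    pVf <- ifelse(fgOfGene == "FG1", 0.09, 0.03)
    vf <- ifelse(stats::runif(nG) < pVf,
                 sample(.VF_CLASSES, nG, replace = TRUE), NA_character_)
    pArg <- ifelse(fgOfGene == "FG1", 0.09, 0.03)
    arg <- ifelse(stats::runif(nG) < pArg,
                  sample(.ARG_CLASSES, nG, replace = TRUE), NA_character_)

    GeneAnnotationTable(gene_id = geneIds, length_bp = lengthBp,
                        lineage = lineage, ko = ko, cazy = cazy,
                        vf_class = vf, arg_class = arg)
}

#' Write a simulated dataset to disk in the package dialect
#'
#' Writes `annotations.tsv`, `abundance.tsv`, `metadata.tsv`,
#' `host_gut.tsv`, `host_liver.tsv`, `viral_abundance.tsv` and the truth
#' tables `truth_taxa.tsv`, `truth_modules.tsv`, `truth_virome.tsv`,
#' `truth_latent.tsv`.
#'
#' @param sim Output of [simulateDataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    writeGeneAnnotations(sim$annotations, p("annotations.tsv"))
    writeAbundanceMatrix(sim$abundance, p("abundance.tsv"))
    writeSampleMetadata(sim$metadata, p("metadata.tsv"))
    writeAbundanceMatrix(sim$hostExpression$gut, p("host_gut.tsv"))
    writeAbundanceMatrix(sim$hostExpression$liver, p("host_liver.tsv"))
    writeFeatureProfile(sim$viralProfile, p("viral_abundance.tsv"))
    tr <- sim$truth
    .writeTsv(data.frame(taxon = names(tr@phylumOfTaxon),
                         phylum = unname(tr@phylumOfTaxon),
                         functional_group = unname(tr@fgOfPhylum[tr@phylumOfTaxon])),
              p("truth_taxa.tsv"))
    .writeTsv(data.frame(gene = names(tr@moduleOfGene),
                         module = unname(tr@moduleOfGene),
                         sign = unname(ifelse(tr@moduleOfGene == "grey", 0L,
                                              tr@moduleSign[tr@moduleOfGene]))),
              p("truth_modules.tsv"))
    .writeTsv(data.frame(virus = names(tr@hostOfVirus),
                         host_taxon = unname(tr@hostOfVirus)),
              p("truth_virome.tsv"))
    .writeTsv(data.frame(sample_id = rownames(tr@latent),
                         fg1 = tr@latent[, "fg1"], fg2 = tr@latent[, "fg2"]),
              p("truth_latent.tsv"))
    invisible(dir)
}
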