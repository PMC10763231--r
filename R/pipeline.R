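## End-to-end orchestration: simulate or read inputs, aggregate, network,
## ratio, host modules, functional profiles, virome coupling; write one
## TSV per stage output plus a run log.  Every randomized stage draws a
## seed derived from the single master seed, so a rerun with the same
## configuration is bit-identical.

#' Create a pipeline configuration
#'
#' @param denominatorMode Relative-abundance denominator:
#'   `"classified_all"` (default) or `"bacteria_only"`.
#' @param spearmanRMin Network |rho| threshold (default 0.5).
#' @param pMax Network p-value cutoff (default 0.05).
#' @param useRmtThreshold Use the random-matrix threshold scan instead of
#'   the fixed `spearmanRMin` (default FALSE).
#' @param permutations Permutations for PERMANOVA/ANOSIM/Mantel and the
#'   opposite-pattern test (default 999).
#' @param ratioPseudocount Pseudocount for the FG2/FG1 ratio (default 0).
#' @param ratioLabelThreshold Ratio label cutoff (default 1).
#' @param moduleMinSize Minimum co-expression module size (default 30).
#' @param moduleCutHeight Module tree-cut height (default 0.3).
#' @param rngSeed Master seed (default 1).
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(denominatorMode = "classified_all",
                           spearmanRMin = 0.5, pMax = 0.05,
                           useRmtThreshold = FALSE, permutations = 999,
                           ratioPseudocount = 0, ratioLabelThreshold = 1.0,
                           moduleMinSize = 30, moduleCutHeight = 0.3,
                           rngSeed = 1) {
    new("PipelineConfig", denominatorMode = denominatorMode,
        spearmanRMin = spearmanRMin, pMax = pMax,
        useRmtThreshold = useRmtThreshold,
        permutations = as.integer(permutations),
        ratioPseudocount = ratioPseudocount,
        ratioLabelThreshold = ratioLabelThreshold,
        moduleMinSize = as.integer(moduleMinSize),
        moduleCutHeight = moduleCutHeight, rngSeed = as.integer(rngSeed))
}

#' Run the full analysis pipeline
#'
#' `inputs` may be a [SimulationParams-class] (the dataset is generated
#' with a seed derived from the config's master seed), the list returned
#' by [simulateDataset()], or a named list of file paths (`annotations`,
#' `abundance`, `metadata`, optionally `host_gut`, `host_liver`,
#' `viral`).  Stages: `aggregate`, `ecology`, `network`, `ratio`,
#' `modules`, `functions`, `virome` (default all).  Each stage writes its
#' TSV outputs under `outDir`; a `run_log.txt` records the configuration
#' and seed.
#'
#' @param config A [PipelineConfig-class].
#' @param inputs See description.
#' @param outDir Output directory (created if needed).
#' @param stages Character vector of stages to run (default all).
#' @return Invisibly, a named list with all stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), inputs, outDir,
                        stages = c("aggregate", "ecology", "network",
                                   "ratio", "modules", "functions",
                                   "virome")) {
    stopifnot(is(config, "PipelineConfig"))
    validObject(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    dat <- .resolveInputs(config, inputs)
    .checkSampleConsistency(dat)
    meta <- dat$metadata
    res <- list(config = config)

    ## -- aggregation -----------------------------------------------------
    phyRaw <- aggregateByCategory(dat$abundance, dat$annotations, "phylum")
    genRaw <- aggregateByCategory(dat$abundance, dat$annotations, "genus")
    phyRel <- toRelative(phyRaw, config@denominatorMode,
                         bacterialFeatures = .bacterialFeatures(dat$annotations,
                                                                "phylum"))
    genRel <- toRelative(genRaw, config@denominatorMode,
                         bacterialFeatures = .bacterialFeatures(dat$annotations,
                                                                "genus"))
    res$profiles <- list(phylum_raw = phyRaw, phylum_relative = phyRel,
                         genus_raw = genRaw, genus_relative = genRel)
    if ("aggregate" %in% stages) {
        writeFeatureProfile(phyRaw, p("phylum_raw.tsv"))
        writeFeatureProfile(phyRel, p("phylum_relative.tsv"))
        writeFeatureProfile(genRaw, p("genus_raw.tsv"))
        writeFeatureProfile(genRel, p("genus_relative.tsv"))
    }

    ## -- ecology ---------------------------------------------------------
    if ("ecology" %in% stages) {
        counts <- round(profileValues(genRaw))
        counts <- counts[, colSums(counts) > 0, drop = FALSE]
        alpha <- alphaDiversity(counts)
        bc <- brayCurtis(genRel)
        ord <- pcoa(bc)
        tests <- do.call(rbind, lapply(unique(meta$week), function(wk) {
            idx <- meta$sample_id[meta$week == wk]
            sub <- bc[idx, idx]
            lab <- as.character(meta$diet[match(idx, meta$sample_id)])
            pm <- permanova(sub, lab, B = config@permutations,
                            seed = deriveSeed(config@rngSeed,
                                              paste0("permanova", wk)))
            an <- anosim(sub, lab, B = config@permutations,
                         seed = deriveSeed(config@rngSeed,
                                           paste0("anosim", wk)))
            data.frame(week = wk, test = c("permanova", "anosim"),
                       statistic = c(pm$statistic, an$statistic),
                       p_value = c(pm$p_value, an$p_value),
                       n_permutations = config@permutations)
        }))
        res$ecology <- list(alpha = alpha, bray_curtis = bc, pcoa = ord,
                            tests = tests)
        .writeTsv(alpha, p("alpha.tsv"))
        writeAbundanceMatrix(bc, p("bray_curtis.tsv"))
        writeAbundanceMatrix(ord$coordinates, p("pcoa_coords.tsv"))
        .writeTsv(tests, p("tests.tsv"))
    }

    ## -- co-occurrence network ------------------------------------------
    if ("network" %in% stages) {
        core <- coreTaxa(genRel, meta)
        coreProf <- profileValues(genRel)[, core$core, drop = FALSE]
        rMin <- config@spearmanRMin
        if (config@useRmtThreshold) {
            corr <- stats::cor(apply(coreProf, 2, rank))
            rmt <- rmtThreshold(corr, fallback = config@spearmanRMin)
            rMin <- rmt$threshold
            res$rmt <- rmt
        }
        net <- correlationNetwork(coreProf, rMin = rMin, pMax = config@pMax)
        part <- partitionFunctionalGroups(net,
                                          seed = deriveSeed(config@rngSeed,
                                                            "partition"))
        res$network <- net
        res$partition <- part
        writeNetwork(net, p("network_edges.tsv"))
        .writeTsv(data.frame(node = names(groupOfNode(part)),
                             group = unname(groupOfNode(part))),
                  p("partition.tsv"))
        .writeTsv(data.frame(taxon = core$core), p("core_taxa.tsv"))
    }

    ## -- FG ratio --------------------------------------------------------
    ratios <- labelByRatio(fgRatio(phyRel, pseudocount = config@ratioPseudocount),
                           threshold = config@ratioLabelThreshold)
    res$ratios <- ratios
    if ("ratio" %in% stages) {
        ratioTests <- do.call(rbind, lapply(unique(meta$week), function(wk) {
            sub <- merge(ratios, meta, by = "sample_id")
            sub <- sub[sub$week == wk, ]
            cg <- compareGroups(sub$ratio[sub$diet %in% c("OD", "HD")],
                                sub$ratio[sub$diet == "CD"])
            data.frame(week = wk, comparison = "OD+HD vs CD",
                       U = cg$U, p_value = cg$p, mode = cg$mode)
        }))
        res$ratio_tests <- ratioTests
        .writeTsv(ratios, p("ratios.tsv"))
        .writeTsv(ratioTests, p("ratio_tests.tsv"))
    }

    ## -- host modules ----------------------------------------------------
    if ("modules" %in% stages && !is.null(dat$hostExpression)) {
        fgAb <- .groupAbundanceMatrix(phyRel)
        res$modules <- lapply(names(dat$hostExpression), function(tissue) {
            expr <- dat$hostExpression[[tissue]]
            ms <- detectModules(expr, minSize = config@moduleMinSize,
                                cutHeight = config@moduleCutHeight)
            assoc <- associateModules(ms, fgAb)
            ## the opposite-pattern test needs >= 5 modules to permute
            opp <- if (length(unique(assoc$module)) >= 5)
                oppositePatternTest(assoc, B = config@permutations,
                                    seed = deriveSeed(config@rngSeed,
                                                      paste0("opp", tissue)))
            else list(statistic = NA_real_, per_phylum = NULL,
                      p_value = NA_real_,
                      n_permutations = config@permutations)
            .writeTsv(data.frame(gene = names(moduleOfGene(ms)),
                                 module = unname(moduleOfGene(ms))),
                      p(sprintf("modules_%s.tsv", tissue)))
            writeAbundanceMatrix(eigengenes(ms),
                                 p(sprintf("eigengenes_%s.tsv", tissue)))
            .writeTsv(assoc, p(sprintf("association_%s.tsv", tissue)))
            list(modules = ms, association = assoc, opposite = opp)
        })
        names(res$modules) <- names(dat$hostExpression)
        .writeTsv(do.call(rbind, lapply(names(res$modules), function(t)
            data.frame(tissue = t,
                       statistic = res$modules[[t]]$opposite$statistic,
                       p_value = res$modules[[t]]$opposite$p_value))),
            p("opposite_pattern.tsv"))
    }

    ## -- functional profiles --------------------------------------------
    if ("functions" %in% stages) {
        caz <- cazySubstrateProfile(dat$abundance, dat$annotations)
        koProf <- aggregateByCategory(dat$abundance, dat$annotations, "KO")
        scfa <- scfaGeneProfile(koProf)
        vf <- classCountProfile(dat$annotations, field = "vf_class")
        arg <- classCountProfile(dat$annotations, field = "arg_class")
        argFilt <- filterLowAbundance(arg)
        cmp <- do.call(rbind, lapply(names(defaultSubstrateMap()), function(s) {
            x <- profileValues(caz$FG1)[, s]
            y <- profileValues(caz$FG2)[, s]
            cg <- compareGroups(x, y)
            data.frame(feature = s, median_FG1 = stats::median(x),
                       median_FG2 = stats::median(y), U = cg$U,
                       p_value = cg$p)
        }))
        res$functions <- list(cazy = caz, scfa = scfa, vf = vf,
                              arg = argFilt, comparisons = cmp)
        writeFeatureProfile(caz$FG1, p("cazy_substrates_FG1.tsv"))
        writeFeatureProfile(caz$FG2, p("cazy_substrates_FG2.tsv"))
        writeFeatureProfile(scfa, p("scfa_genes.tsv"))
        writeFeatureProfile(vf, p("vf_classes.tsv"))
        writeFeatureProfile(argFilt, p("arg_classes.tsv"))
        .writeTsv(cmp, p("comparisons.tsv"))
    }

    ## -- virome ----------------------------------------------------------
    if ("virome" %in% stages && !is.null(dat$viralProfile)) {
        viralRel <- toRelative(dat$viralProfile)
        vAlpha <- alphaDiversity(round(profileValues(dat$viralProfile)) + 1)
        counts <- round(profileValues(genRaw))
        counts <- counts[, colSums(counts) > 0, drop = FALSE]
        bAlpha <- alphaDiversity(counts)
        coupling <- alphaCoupling(vAlpha, bAlpha,
                                  indices = c("shannon", "simpson"))
        mt <- mantelTest(brayCurtis(genRel), brayCurtis(viralRel),
                         B = config@permutations,
                         seed = deriveSeed(config@rngSeed, "mantel"))
        tp <- taxonPhageCorrelations(genRel, viralRel)
        res$virome <- list(alpha_coupling = coupling, mantel = mt,
                           taxon_phage = tp)
        .writeTsv(coupling, p("virome_alpha_coupling.tsv"))
        .writeTsv(data.frame(r = mt$r, p_value = mt$p,
                             n_permutations = mt$n_permutations,
                             method = mt$method),
                  p("virome_mantel.tsv"))
        writeAbundanceMatrix(tp$rho, p("taxon_phage_corr.tsv"),
                             idColumn = "taxon")
    }

    writeLines(c("gutFG pipeline run",
                 utils::capture.output(show(config)),
                 paste("stages:", paste(stages, collapse = ", "))),
               p("run_log.txt"))
    invisible(res)
}

.resolveInputs <- function(config, inputs) {
    if (is(inputs, "SimulationParams")) {
        inputs@seed <- deriveSeed(config@rngSeed, "simulate")
        return(simulateDataset(inputs))
    }
    if (is.list(inputs) && !is.null(inputs$abundance) &&
        is.matrix(inputs$abundance))
        return(inputs)
    if (is.list(inputs) && all(vapply(inputs, is.character, logical(1)))) {
        dat <- list(annotations = readGeneAnnotations(inputs$annotations),
                    abundance = readAbundanceMatrix(inputs$abundance),
                    metadata = readSampleMetadata(inputs$metadata))
        if (!is.null(inputs$host_gut))
            dat$hostExpression <- list(
                gut = readExpressionMatrix(inputs$host_gut),
                liver = readExpressionMatrix(inputs$host_liver))
        if (!is.null(inputs$viral))
            dat$viralProfile <- readFeatureProfile(inputs$viral,
                                                   level = "viral-genus")
        return(dat)
    }
    stop("inputs must be SimulationParams, a simulated dataset, or file paths")
}

.checkSampleConsistency <- function(dat) {
    ids <- rownames(dat$abundance)
    sets <- list(metadata = dat$metadata$sample_id)
    if (!is.null(dat$hostExpression))
        sets <- c(sets, lapply(dat$hostExpression, rownames))
    if (!is.null(dat$viralProfile))
        sets$viral <- colnames(dat$viralProfile)
    for (nm in names(sets)) {
        if (!setequal(ids, sets[[nm]])) {
            diff <- c(setdiff(ids, sets[[nm]]), setdiff(sets[[nm]], ids))
            stop("sample ids of '", nm, "' do not match the abundance ",
                 "matrix; symmetric difference: ",
                 paste(diff, collapse = ", "))
        }
    }
    invisible(dat)
}

## Feature ids (at the given rank) whose genes are bacterial.
.bacterialFeatures <- function(annot, level) {
    a <- annot@annot
    unique(a[[level]][a$superkingdom == "Bacteria" & a[[level]] != "unknown"])
}

## Per-phylum relative abundances plus summed FG1/FG2 columns.
.groupAbundanceMatrix <- function(phylumRel,
                                  fgmap = defaultFunctionalGroups()) {
    m <- profileValues(phylumRel)
    fg1 <- intersect(names(fgmap)[fgmap == "FG1"], colnames(m))
    fg2 <- intersect(names(fgmap)[fgmap == "FG2"], colnames(m))
    cbind(m[, c(fg1, fg2), drop = FALSE],
          FG1 = rowSums(m[, fg1, drop = FALSE]),
          FG2 = rowSums(m[, fg2, drop = FALSE]))
}
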