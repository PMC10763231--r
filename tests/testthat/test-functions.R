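test_that("substrate membership follows the family lists, including overlaps", {
    smap <- defaultSubstrateMap()
    ## GH32 is inulin-only; GH3 sits under arabinoxylan, mucin and cellulose
    hits <- names(smap)[vapply(smap, function(f) "GH32" %in% f, logical(1))]
    expect_equal(hits, "inulin")
    hits3 <- names(smap)[vapply(smap, function(f) "GH3" %in% f, logical(1))]
    expect_setequal(hits3, c("arabinoxylan", "mucin", "cellulose"))
    hits5 <- names(smap)[vapply(smap, function(f) "GH5" %in% f, logical(1))]
    expect_setequal(hits5, c("arabinoxylan", "cellulose"))
})

test_that("CAZy substrate profiles match a hand-computed oracle", {
    ## 6 genes over 2 groups; g6 has no CAZy annotation
    lineage <- data.frame(
        superkingdom = "Bacteria",
        phylum = c("Proteobacteria", "Proteobacteria", "Firmicutes",
                   "Firmicutes", "Fusobacteria", "Proteobacteria"),
        class = "unknown", order = "unknown", family = "unknown",
        genus = paste0("G", 1:6), species = "unknown")
    annot <- GeneAnnotationTable(
        gene_id = paste0("g", 1:6), length_bp = rep(1000, 6),
        lineage = lineage,
        cazy = list("GH13", "GH32", c("GH43", "GH28"), "GH3", "GH13",
                    character(0)))
    abund <- matrix(c(4, 2, 3, 1, 5, 7,
                      1, 1, 1, 1, 1, 1), 2, 6, byrow = TRUE,
                    dimnames = list(c("s1", "s2"), paste0("g", 1:6)))
    out <- cazySubstrateProfile(abund, annot)
    ## FG1 CAZy genes: g1 (GH13), g2 (GH32); totals per sample
    fg1Tot <- abund[, "g1"] + abund[, "g2"]
    expect_equal(profileValues(out$FG1)[, "starch"],
                 1e5 * abund[, "g1"] / fg1Tot, tolerance = 1e-9)
    expect_equal(profileValues(out$FG1)[, "inulin"],
                 1e5 * abund[, "g2"] / fg1Tot, tolerance = 1e-9)
    expect_equal(unname(profileValues(out$FG1)[, "pectin"]), c(0, 0))
    ## FG2 CAZy genes: g3 (GH43 arabinoxylan + GH28 pectin),
    ## g4 (GH3: arabinoxylan, mucin, cellulose), g5 (GH13 starch)
    fg2Tot <- abund[, "g3"] + abund[, "g4"] + abund[, "g5"]
    expect_equal(profileValues(out$FG2)[, "arabinoxylan"],
                 1e5 * (abund[, "g3"] + abund[, "g4"]) / fg2Tot,
                 tolerance = 1e-9)
    expect_equal(profileValues(out$FG2)[, "pectin"],
                 1e5 * abund[, "g3"] / fg2Tot, tolerance = 1e-9)
    expect_equal(profileValues(out$FG2)[, "mucin"],
                 1e5 * abund[, "g4"] / fg2Tot, tolerance = 1e-9)
    expect_equal(profileValues(out$FG2)[, "starch"],
                 1e5 * abund[, "g5"] / fg2Tot, tolerance = 1e-9)
    ## invariance to per-sample rescaling of raw abundances
    out2 <- cazySubstrateProfile(abund * c(10, 0.2), annot)
    expect_equal(profileValues(out2$FG2), profileValues(out$FG2),
                 tolerance = 1e-9)
})

test_that("SCFA profiles sum the mapped KO abundances", {
    m <- matrix(c(7, 2), 1, dimnames = list("s1", c("K01938", "K00001")))
    prof <- FeatureProfile(m, "KO")
    out <- scfaGeneProfile(prof)
    expect_equal(unname(profileValues(out)[1, c("acetate", "propionate",
                                                "butyrate")]), c(7, 0, 0))
    ## profile lacking every mapped KO: all zeros
    none <- FeatureProfile(matrix(5, 1, 1,
                                  dimnames = list("s1", "K99999")), "KO")
    expect_equal(unname(profileValues(scfaGeneProfile(none))[1, ]),
                 c(0, 0, 0))
    ## random KO table vs a per-KO summation oracle
    set.seed(1)
    emap <- defaultScfaEnzymes()
    kos <- c(unlist(emap, use.names = FALSE), sprintf("K%05d", 1:5))
    mm <- matrix(stats::rexp(3 * length(kos)), 3,
                 dimnames = list(paste0("s", 1:3), kos))
    out2 <- scfaGeneProfile(FeatureProfile(mm, "KO"), emap)
    for (s in names(emap))
        expect_equal(profileValues(out2)[, s],
                     rowSums(mm[, unname(emap[[s]]), drop = FALSE]),
                     tolerance = 1e-12)
    expect_error(scfaGeneProfile(FeatureProfile(mm, "KO"), list()), "empty")
})

test_that("VF/ARG class counts normalize per functional group", {
    ## 5 labelled genes in a 50,000-gene group -> 10 per 100,000
    out <- normalizePerGroup(
        matrix(c(5, 2), 2, 1, dimnames = list(c("FG1", "FG2"), "toxin")),
        c(FG1 = 50000, FG2 = 40000))
    expect_equal(unname(profileValues(out)["FG1", "toxin"]), 10)
    ## genes of unmapped phyla are excluded from both groups
    lineage <- data.frame(
        superkingdom = "Bacteria",
        phylum = c("Proteobacteria", "Actinobacteria", "Firmicutes"),
        class = "unknown", order = "unknown", family = "unknown",
        genus = paste0("G", 1:3), species = "unknown")
    annot <- GeneAnnotationTable(gene_id = paste0("g", 1:3),
                                 length_bp = rep(500, 3), lineage = lineage,
                                 vf_class = c("toxin", "toxin", NA))
    prof <- classCountProfile(annot, field = "vf_class")
    expect_equal(unname(profileValues(prof)["FG1", "toxin"]), 1e5)
    expect_equal(unname(profileValues(prof)["FG2", "toxin"]), 0)
    ## class sums never exceed the scale
    sim <- simulateDataset(smallSimParams(seed = 2))
    vf <- classCountProfile(sim$annotations, field = "vf_class")
    expect_true(all(rowSums(profileValues(vf)) <= 1e5 + 1e-6))
})

test_that("the planted VF enrichment of FG1 is detectable", {
    hits <- vapply(1:10, function(s) {
        sim <- simulateDataset(smallSimParams(seed = s))
        vf <- profileValues(classCountProfile(sim$annotations,
                                              field = "vf_class"))
        sum(vf["FG1", ]) > sum(vf["FG2", ])
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("low-abundance filtering drops features below the floor everywhere", {
    m <- rbind(s1 = c(a = 0.5, b = 0.2, c = 3.0, d = 1.0),
               s2 = c(a = 0.5, b = 1.4, c = 0.0, d = 1.0))
    prof <- FeatureProfile(m, "ARG-class", "per_100k")
    kept <- featureIds(filterLowAbundance(prof, minValue = 1.0))
    expect_setequal(kept, c("b", "c", "d"))   # "d" sits exactly on the floor
    expect_equal(featureIds(filterLowAbundance(prof, minValue = 0)),
                 featureIds(prof))            # identity at 0
    expect_equal(profileValues(filterLowAbundance(prof))[, "b"], m[, "b"])
})

test_that("Mann-Whitney p-values match exact enumeration", {
    out <- compareGroups(c(1, 2), c(3, 4))
    expect_equal(out$U, 0)
    expect_equal(out$p, 2 / 6, tolerance = 1e-12)
    expect_equal(out$mode, "exact")
    ## identical multisets: p = 1 under the tie-corrected approximation
    same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$p, 1)
    ## random untied samples vs the full enumeration oracle
    set.seed(3)
    for (i in 1:8) {
        x <- sample(1000, 6); y <- sample(2000, 6) + 0.5
        mine <- compareGroups(x, y, mode = "exact")
        expect_equal(mine$p, bruteForceMannWhitneyP(x, y), tolerance = 1e-12)
        ## symmetry in (x, y)
        expect_equal(compareGroups(y, x, mode = "exact")$p, mine$p,
                     tolerance = 1e-12)
        expect_true(mine$p > 0 && mine$p <= 1)
    }
    ## the approximation tracks wilcox.test with corrections
    set.seed(4)
    x <- stats::rnorm(15); y <- stats::rnorm(15, 1)
    mine <- compareGroups(x, y, mode = "approx")
    ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_error(compareGroups(1, c(1, 2)), "at least 2")
})
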