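## Tabular readers and writers.  One dialect everywhere: UTF-8 TSV with a
## header row; taxonomy lineage serialized as semicolon-joined ranks
## (superkingdom;phylum;...;species); CAZy family sets comma-joined;
## missing functional labels as empty fields.  Numeric tables are written
## with 15 significant digits so a write/read round trip is exact at
## double precision for all practical purposes.

.readTsv <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8")
}

.writeTsv <- function(df, path, rowNames = FALSE) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rowNames, col.names = TRUE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns `gene_id`, `length`, `lineage`
#' (semicolon-joined ranks, superkingdom first) and optional `ko`, `cazy`
#' (comma-joined family labels), `vf_class`, `arg_class`.  Lineages with
#' fewer than seven ranks are filled with `"unknown"` at the trailing
#' ranks; empty functional fields become absent annotation.
#'
#' @param path Path to the TSV file.
#' @return A [GeneAnnotationTable-class].
#' @export
readGeneAnnotations <- function(path) {
    df <- .readTsv(path)
    need <- c("gene_id", "length", "lineage")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0)
        stop("annotation file lacks mandatory column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene_id in ", path, ": ",
             paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
    if (any(!is.finite(df$length) | df$length <= 0))
        stop("non-positive gene length for: ",
             paste(df$gene_id[!is.finite(df$length) | df$length <= 0],
                   collapse = ", "))
    lin <- .parseLineage(df$lineage)
    getOpt <- function(col) {
        if (!col %in% colnames(df)) return(rep(NA_character_, nrow(df)))
        v <- as.character(df[[col]])
        v[is.na(v) | !nzchar(v)] <- NA_character_
        v
    }
    cazyRaw <- getOpt("cazy")
    cazy <- lapply(cazyRaw, function(s) {
        if (is.na(s)) character(0) else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
    GeneAnnotationTable(gene_id = df$gene_id, length_bp = df$length,
                        lineage = lin, ko = getOpt("ko"), cazy = cazy,
                        vf_class = getOpt("vf_class"),
                        arg_class = getOpt("arg_class"))
}

.parseLineage <- function(strings) {
    parts <- strsplit(as.character(strings), ";", fixed = TRUE)
    k <- length(.LINEAGE_RANKS)
    mat <- t(vapply(parts, function(p) {
        p <- trimws(p)
        p <- p[nzchar(p)]
        if (length(p) > k)
            stop("lineage has more than ", k, " ranks: ",
                 paste(p, collapse = ";"))
        c(p, rep("unknown", k - length(p)))
    }, character(k)))
    colnames(mat) <- .LINEAGE_RANKS
    mat
}

#' Write a gene annotation table in the package dialect
#'
#' @param annot A [GeneAnnotationTable-class].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeGeneAnnotations <- function(annot, path) {
    a <- annot@annot
    lin <- apply(as.matrix(as.data.frame(a[, .LINEAGE_RANKS])), 1,
                 paste, collapse = ";")
    blank <- function(v) ifelse(is.na(v), "", v)
    df <- data.frame(gene_id = a$gene_id,
                     length = a$length_bp,
                     lineage = lin,
                     ko = blank(a$ko),
                     cazy = vapply(a$cazy, paste, "", collapse = ","),
                     vf_class = blank(a$vf_class),
                     arg_class = blank(a$arg_class),
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read a samples-by-genes abundance matrix
#'
#' First column holds sample ids, remaining header fields gene ids; column
#' order is preserved.  Negative or non-numeric cells are rejected with
#' their location.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, samples as rows, genes as columns.
#' @export
readAbundanceMatrix <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2)
        stop("abundance matrix in ", path, " has no gene columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicated sample ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated gene ids in header")
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("non-numeric abundance at sample '%s', gene '%s'",
                     ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
        stop(sprintf("negative abundance at sample '%s', gene '%s'",
                     ids[neg[1, 1]], colnames(m)[neg[1, 2]]))
    rownames(m) <- ids
    validateAbundanceMatrix(m)
    m
}

#' Read a samples-by-genes expression matrix
#'
#' Same layout as [readAbundanceMatrix()] but values may be negative
#' (host expression is stored on a signed, roughly standardized scale).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, samples as rows, genes as columns.
#' @export
readExpressionMatrix <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2)
        stop("expression matrix in ", path, " has no gene columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicated sample ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("non-numeric value at sample '%s', gene '%s'",
                     ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    rownames(m) <- ids
    m
}

#' Validate a samples-by-genes abundance matrix
#'
#' @param m Numeric matrix, samples as rows, genes as columns.
#' @return The matrix, invisibly, or an error.
#' @export
validateAbundanceMatrix <- function(m) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("abundance matrix needs sample (row) and gene (column) names")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        stop("sample and gene ids must be unique")
    if (any(!is.finite(m)) || any(m < 0))
        stop("abundance values must be finite and non-negative")
    zero <- rowSums(m) == 0
    if (any(zero))
        stop("sample(s) with no positive abundance: ",
             paste(rownames(m)[zero], collapse = ", "))
    invisible(m)
}

#' Write a samples-by-genes (or samples-by-features) matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output TSV path.
#' @param idColumn Header label of the first (sample id) column.
#' @return The path, invisibly.
#' @export
writeAbundanceMatrix <- function(m, path, idColumn = "sample_id") {
    df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    .writeTsv(df, path)
}

#' Read/write a FeatureProfile
#'
#' The TSV holds the samples-by-features matrix; `level` and
#' `normalization` are supplied by the caller (they are recorded in the
#' file name by the pipeline, not inside the table).
#'
#' @param path TSV path.
#' @param level Feature level tag.
#' @param normalization Normalization state of the stored values.
#' @return `readFeatureProfile` a [FeatureProfile-class];
#'   `writeFeatureProfile` the path, invisibly.
#' @export
readFeatureProfile <- function(path, level, normalization = "raw") {
    df <- .readTsv(path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    FeatureProfile(m, level = level, normalization = normalization)
}

#' @rdname readFeatureProfile
#' @param profile A [FeatureProfile-class] to write.
#' @export
writeFeatureProfile <- function(profile, path) {
    writeAbundanceMatrix(profileValues(profile), path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `diet` (CD/OD/HD), `week` (1/3),
#' `replicate`.
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
readSampleMetadata <- function(path) {
    validateSampleMetadata(.readTsv(path))
}

#' Validate sample metadata
#'
#' @param meta data.frame with columns `sample_id`, `diet`, `week`,
#'   `replicate`.
#' @return The validated data.frame (diet as factor CD/OD/HD, week integer).
#' @export
validateSampleMetadata <- function(meta) {
    need <- c("sample_id", "diet", "week", "replicate")
    miss <- setdiff(need, colnames(meta))
    if (length(miss) > 0)
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(meta$sample_id))
        stop("duplicated sample ids in metadata")
    if (!all(meta$diet %in% .DIETS))
        stop("diet must be one of ", paste(.DIETS, collapse = "/"))
    if (!all(meta$week %in% .WEEKS))
        stop("week must be one of ", paste(.WEEKS, collapse = "/"))
    meta$diet <- factor(meta$diet, levels = .DIETS)
    meta$week <- as.integer(meta$week)
    meta$replicate <- as.integer(meta$replicate)
    meta
}

#' @rdname readSampleMetadata
#' @param meta Validated metadata data.frame.
#' @param path Output TSV path.
#' @export
writeSampleMetadata <- function(meta, path) {
    m <- meta
    m$diet <- as.character(m$diet)
    .writeTsv(m, path)
}

#' Diet formulation table bundled for fixture validation
#'
#' Ingredient masses (g/kg diet) of the carnivorous (CD), omnivorous (OD)
#' and herbivorous (HD) experimental diets, plus the printed totals; used
#' only to sanity-check fixtures, not by any analysis step.
#'
#' @return data.frame with columns `ingredient`, `CD`, `OD`, `HD`.
#' @export
dietFormulations <- function() {
    path <- system.file("extdata", "diet_formulations.tsv", package = "gutFG",
                        mustWork = TRUE)
    .readTsv(path)
}
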