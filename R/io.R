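readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and sample sheet
#'
#' Expression TSV: first column `gene`, remaining columns one per sample.
#' Sample sheet TSV: columns `sample`, `condition`, `donor`. All invariants
#' are checked at load and the first violation is reported with its
#' coordinates.
#'
#' @param exprPath path to the expression TSV.
#' @param samplesPath path to the sample sheet TSV.
#' @return A [MacrophageExperiment-class].
#' @export
readExpression <- function(exprPath, samplesPath) {
  tab <- readTsv(exprPath)
  if (colnames(tab)[1] != "gene")
    stop("first column of ", exprPath, " must be 'gene'")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene symbols in ", exprPath, ": ",
         tab$gene[duplicated(tab$gene)][1])
  if (anyDuplicated(colnames(tab)))
    stop("duplicated sample column in ", exprPath, ": ",
         colnames(tab)[duplicated(colnames(tab))][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    for (j in seq(2, ncol(tab))) {
      v <- suppressWarnings(as.numeric(tab[[j]]))
      bad <- which(is.na(v) & !is.na(tab[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric expression value at row %d, column '%s'",
                     bad[1], colnames(tab)[j]))
    }
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing expression value at row %d, column '%s'",
                 bad[1, 1], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- tab$gene
  ss <- readTsv(samplesPath)
  need <- c("sample", "condition", "donor")
  if (!all(need %in% colnames(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!setequal(ss$sample, colnames(m)))
    stop("sample sheet and expression columns disagree")
  ss <- ss[match(colnames(m), ss$sample), ]
  MacrophageExperiment(m, condition = ss$condition, donor = ss$donor)
}

#' @rdname readExpression
#' @param experiment a [MacrophageExperiment-class] to write.
#' @export
writeExpression <- function(experiment, exprPath, samplesPath) {
  m <- exprMatrix(experiment)
  writeTsv(data.frame(gene = rownames(m), m, check.names = FALSE),
           exprPath)
  writeTsv(data.frame(sample = colnames(m),
                      condition = conditionLabels(experiment),
                      donor = donorLabels(experiment)), samplesPath)
  invisible(c(exprPath, samplesPath))
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path file path.
#' @return [readGMT()]: a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  GeneSetCollection(sets, desc)
}

#' @rdname readGMT
#' @param collection a [GeneSetCollection-class] to write.
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  desc <- collection@description
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(desc) && nzchar(desc[nm])) desc[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write typed interaction edge lists
#'
#' TSV columns: `gene_a`, `gene_b`, `channel` (`physical`/`soluble`),
#' `directed` (0/1), `confidence` in `[0, 1]` (may be empty).
#'
#' @param path file path.
#' @return [readEdges()]: an [InteractionNetwork-class].
#' @export
readEdges <- function(path) {
  e <- readTsv(path)
  need <- c("gene_a", "gene_b", "channel", "directed")
  if (!all(need %in% colnames(e)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  badChan <- setdiff(unique(e$channel), c("physical", "soluble"))
  if (length(badChan))
    stop("unknown channel label: ", paste(badChan, collapse = ", "))
  InteractionNetwork(e)
}

#' @rdname readEdges
#' @param network an [InteractionNetwork-class] to write.
#' @export
writeEdges <- function(network, path) {
  e <- edgeTable(network)
  e$directed <- as.integer(e$directed)
  writeTsv(e, path)
}

#' Read / write gene annotation tables
#'
#' TSV columns: `gene`, `class`; (gene, class) pairs must be unique.
#'
#' @param path file path.
#' @return [readAnnotations()]: a data.frame `gene`, `class`.
#' @export
readAnnotations <- function(path) {
  a <- readTsv(path)
  if (!all(c("gene", "class") %in% colnames(a)))
    stop("annotation table must have columns gene, class")
  if (anyDuplicated(a[, c("gene", "class")]))
    stop("duplicate (gene, class) annotation rows")
  a
}

#' Read / write partner-cell expression profiles
#'
#' TSV with a `gene` column followed by one numeric column per cell type.
#'
#' @param path file path.
#' @return [readCellProfiles()]: a matrix genes x cell types.
#' @export
readCellProfiles <- function(path) {
  tab <- readTsv(path)
  if (colnames(tab)[1] != "gene")
    stop("first column of ", path, " must be 'gene'")
  if (anyDuplicated(tab$gene)) stop("duplicate genes in cell profiles")
  if (anyDuplicated(colnames(tab)[-1]))
    stop("duplicate cell type columns")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("cell profile values must be numeric")
  rownames(m) <- tab$gene
  m
}

#' @rdname readCellProfiles
#' @param profiles matrix to write.
#' @export
writeCellProfiles <- function(profiles, path) {
  writeTsv(data.frame(gene = rownames(profiles), profiles,
                      check.names = FALSE), path)
}

#' Write every synthetic-data artefact to a directory
#'
#' Emits `expression.tsv`, `samples.tsv`, `annotations.tsv`,
#' `genesets.gmt`, `edges.tsv`, `cell_profiles.tsv`, `truth.tsv`, all in the
#' dialects read back by the package's readers (round-trip identity).
#'
#' @param sim result of [simulateAll()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeExpression(sim$experiment, p("expression.tsv"), p("samples.tsv"))
  writeTsv(sim$annotations, p("annotations.tsv"))
  writeGMT(sim$geneSets, p("genesets.gmt"))
  writeEdges(sim$network, p("edges.tsv"))
  writeCellProfiles(sim$cellProfiles, p("cell_profiles.tsv"))
  truth <- sim$truth
  truth$is_de <- as.integer(truth$is_de)
  writeTsv(truth, p("truth.tsv"))
  invisible(setNames(
    p(c("expression.tsv", "samples.tsv", "annotations.tsv", "genesets.gmt",
        "edges.tsv", "cell_profiles.tsv", "truth.tsv")),
    c("expression", "samples", "annotations", "genesets", "edges",
      "cell_profiles", "truth")))
}
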