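#' Filter a DEG table by annotation class
#'
#' Restricts a DEG table to genes carrying a given annotation class
#' (`cytokine`, `membrane`, `regulator`, `innate`), preserving all columns;
#' heatmap-ready. Classes may overlap, so a gene annotated with two classes
#' appears under both filters.
#'
#' @param deg DEG table with a `gene` column.
#' @param annotations data.frame with `gene`, `class` columns.
#' @param class annotation class label to keep.
#' @return the filtered DEG table.
#' @export
filterByAnnotation <- function(deg, annotations, class) {
  valid <- unique(annotations$class)
  if (!class %in% valid)
    stop("unknown class '", class, "'; valid classes: ",
         paste(sort(valid), collapse = ", "))
  keep <- annotations$gene[annotations$class == class]
  out <- deg[deg$gene %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-condition mean expression
#'
#' Collapses samples to condition means (averaging across donors), the form
#' in which macrophage expression enters the interaction propensity model.
#'
#' @param experiment a [MacrophageExperiment-class].
#' @return matrix genes x conditions.
#' @export
conditionMeans <- function(experiment) {
  y <- exprMatrix(experiment)
  cond <- conditionLabels(experiment)
  lev <- unique(cond)
  out <- vapply(lev, function(cn)
    rowMeans(y[, cond == cn, drop = FALSE]), numeric(nrow(y)))
  dimnames(out) <- list(rownames(y), lev)
  out
}

#' Standardize an expression matrix per gene
#'
#' Per-row z-scores across the matrix columns (conditions for the macrophage
#' matrix, cell types for the partner-cell reference), using the sample
#' standard deviation (n - 1 denominator) by default. Zero-variance rows
#' become all-zero with a warning.
#'
#' @param x numeric matrix (genes x columns), at least 2 columns.
#' @param populationSd use the n-denominator standard deviation instead
#'   (default `FALSE`).
#' @return z-score matrix of the same shape.
#' @export
standardizeExpression <- function(x, populationSd = FALSE) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("standardization needs >= 2 columns")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (populationSd) s <- s * sqrt((ncol(x) - 1) / ncol(x))
  zeroVar <- s == 0
  if (any(zeroVar))
    warning(sum(zeroVar), " zero-variance rows standardized to zero")
  s[zeroVar] <- 1
  z <- (x - mu) / s
  z[zeroVar, ] <- 0
  z
}

propensityChannelSum <- function(macroZ, cellZ, edges, channel) {
  conds <- colnames(macroZ)
  cells <- colnames(cellZ)
  score <- matrix(0, length(conds), length(cells),
                  dimnames = list(conds, cells))
  used <- 0L
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    hit <- FALSE
    if (a %in% rownames(macroZ) && b %in% rownames(cellZ)) {
      score <- score + outer(macroZ[a, ], cellZ[b, ])
      hit <- TRUE
    }
    if (channel == "physical" &&
        b %in% rownames(macroZ) && a %in% rownames(cellZ)) {
      score <- score + outer(macroZ[b, ], cellZ[a, ])
      hit <- TRUE
    }
    used <- used + as.integer(hit)
  }
  list(score = score, used = used, skipped = nrow(edges) - used)
}

#' Cell-cell interaction propensity
#'
#' The propensity of a macrophage condition to interact with a partner
#' immune cell is the sum, over curated interaction edges of a channel, of
#' the product of the standardized expression of the two partners:
#' `score(c, t) = sum over edges (a, b) of zMacro[a, c] * zCell[b, t]`.
#' Soluble edges are macrophage-outgoing (cytokine on the macrophage side,
#' receptor on the partner side); physical edges are undirected and summed
#' over both orientations. Edges whose genes are absent from a matrix are
#' skipped and tallied in the coverage report (attribute `"coverage"`).
#'
#' @param macroZ standardized condition-mean macrophage matrix
#'   ([conditionMeans()] then [standardizeExpression()]).
#' @param cellZ standardized partner-cell profile matrix
#'   (genes x cell types).
#' @param network an [InteractionNetwork-class].
#' @param channel `"physical"` or `"soluble"`.
#' @return data.frame `condition`, `cell_type`, `channel`, `score`, with a
#'   `"coverage"` attribute (`used`, `skipped`, `total`).
#' @export
interactionPropensity <- function(macroZ, cellZ, network, channel) {
  stopifnot(channel %in% c("physical", "soluble"))
  edges <- edgeTable(network, channel)
  if (nrow(edges) == 0) {
    warning("no ", channel, " edges; all scores are 0")
    res <- list(score = matrix(0, ncol(macroZ), ncol(cellZ),
                               dimnames = list(colnames(macroZ),
                                               colnames(cellZ))),
                used = 0L, skipped = 0L)
  } else {
    res <- propensityChannelSum(macroZ, cellZ, edges, channel)
  }
  out <- data.frame(
    condition = rep(rownames(res$score), times = ncol(res$score)),
    cell_type = rep(colnames(res$score), each = nrow(res$score)),
    channel = channel, score = as.vector(res$score),
    stringsAsFactors = FALSE)
  attr(out, "coverage") <- data.frame(
    channel = channel, used = res$used, skipped = res$skipped,
    total = res$used + res$skipped)
  out
}

#' Propensity deltas relative to a reference condition
#'
#' Radar-chart-ready differences: `delta(c, t) = score(c, t) -
#' score(reference, t)` per channel.
#'
#' @param scores an [interactionPropensity()] table (or several, rbound).
#' @param reference reference condition label (default `"uM"`).
#' @return `scores` with an added `delta_vs_ref` column.
#' @export
relativeToReference <- function(scores, reference = "uM") {
  if (!reference %in% scores$condition)
    stop("reference condition '", reference, "' not present")
  key <- paste(scores$cell_type, scores$channel)
  refRows <- scores$condition == reference
  refScore <- setNames(scores$score[refRows], key[refRows])
  scores$delta_vs_ref <- scores$score - unname(refScore[key])
  scores
}

#' Gene-level drivers of a propensity difference between two conditions
#'
#' Decomposes the propensity difference between macrophage conditions
#' `condA` and `condB` into per-gene contributions on the macrophage side:
#' `contribution(g) = sum over edges through g of (zA[g] - zB[g]) *
#' zCell[partner, t]`, summed over all partner cell types, so that the
#' contributions add up exactly to the total propensity delta summed over
#' cell types. `interaction_count` is the number of distinct partner cell
#' types reached through at least one covered edge of the gene with nonzero
#' partner expression. Rows are ordered by `interaction_count`, then by
#' absolute contribution; bar-chart-ready.
#'
#' @param macroZ,cellZ,network,channel as in [interactionPropensity()].
#' @param condA,condB condition labels to compare (delta = A - B).
#' @param meanExpr optional unstandardized condition-mean matrix; adds a
#'   `mean_expr` column (mean of the two compared conditions).
#' @return data.frame `gene`, `contribution_delta`, `interaction_count`
#'   (+ `mean_expr`).
#' @export
interactionDrivers <- function(macroZ, condA, condB, cellZ, network,
                               channel, meanExpr = NULL) {
  stopifnot(channel %in% c("physical", "soluble"))
  for (cn in c(condA, condB))
    if (!cn %in% colnames(macroZ)) stop("condition absent: ", cn)
  edges <- edgeTable(network, channel)
  contrib <- list()
  partners <- list()
  addEdge <- function(g, partner) {
    if (!g %in% rownames(macroZ) || !partner %in% rownames(cellZ))
      return(invisible())
    dz <- macroZ[g, condA] - macroZ[g, condB]
    inc <- sum(dz * cellZ[partner, ])
    contrib[[g]] <<- (if (is.null(contrib[[g]])) 0 else contrib[[g]]) + inc
    hitTypes <- colnames(cellZ)[cellZ[partner, ] != 0]
    partners[[g]] <<- union(partners[[g]], hitTypes)
  }
  for (i in seq_len(nrow(edges))) {
    addEdge(edges$gene_a[i], edges$gene_b[i])
    if (channel == "physical") addEdge(edges$gene_b[i], edges$gene_a[i])
  }
  if (length(contrib) == 0)
    return(data.frame(gene = character(), contribution_delta = numeric(),
                      interaction_count = integer(),
                      stringsAsFactors = FALSE))
  out <- data.frame(gene = names(contrib),
                    contribution_delta = unlist(contrib, use.names = FALSE),
                    interaction_count = lengths(partners)[names(contrib)],
                    stringsAsFactors = FALSE)
  if (!is.null(meanExpr))
    out$mean_expr <- rowMeans(meanExpr[out$gene, c(condA, condB),
                                       drop = FALSE])
  out <- out[order(-out$interaction_count, -abs(out$contribution_delta),
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
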