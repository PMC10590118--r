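#' Expression-matched background for over-representation analysis
#'
#' Over-representation tests on microarray data are biased unless the
#' background universe matches the expression level of the test genes: genes
#' are binned by their mean expression across all samples into equal-frequency
#' bins, and the background is the union of every gene falling in a bin
#' occupied by at least one DEG. The background is always a superset of the
#' DEG.
#'
#' @param deg character vector of DEG symbols (subset of the matrix genes).
#' @param experiment a [MacrophageExperiment-class] (or a numeric matrix).
#' @param bins number of equal-frequency mean-expression bins (default 10).
#' @return character vector: the background gene universe.
#' @export
matchedBackground <- function(deg, experiment, bins = 10) {
  y <- if (is(experiment, "MacrophageExperiment")) exprMatrix(experiment)
       else experiment
  if (length(deg) == 0) stop("DEG set must be non-empty")
  if (!all(deg %in% rownames(y)))
    stop("DEG absent from the expression matrix: ",
         paste(setdiff(deg, rownames(y)), collapse = ", "))
  m <- rowMeans(y)
  # equal-frequency bins by rank; ties broken deterministically by gene order
  bin <- ceiling(rank(m, ties.method = "first") * bins / length(m))
  occupied <- unique(bin[rownames(y) %in% deg])
  union(deg, rownames(y)[bin %in% occupied])
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the DEG overlap the set more than
#' expected under uniform sampling from the background universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' background size, `K` the set size within the background, `n` the DEG
#' count, `k` the observed overlap. Sets with no background member are
#' dropped; p-values are Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param deg character vector of DEG (must be a subset of `background`).
#' @param background character vector, the gene universe.
#' @param collection a [GeneSetCollection-class].
#' @return data.frame `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`, ordered by
#'   `p`.
#' @export
oraHypergeometric <- function(deg, background, collection) {
  deg <- unique(deg)
  background <- unique(background)
  if (!all(deg %in% background))
    stop("DEG must be a subset of the background universe")
  sets <- geneSets(collection)
  if (length(sets) == 0)
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  N <- length(background)
  n <- length(deg)
  rows <- lapply(names(sets), function(nm) {
    inBg <- intersect(sets[[nm]], background)
    K <- length(inBg)
    if (K == 0) return(NULL)
    k <- length(intersect(inBg, deg))
    # upper tail including k: P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  out$p_adj <- adjustBH(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-contrast biological theme comparison
#'
#' Joins per-contrast enrichment tables over the union of sets significant
#' (adjusted p below `sigCut`) in at least one contrast. Every such set is
#' reported for every contrast, flagged significant or not, with a direction
#' tag derived from the sign of the mean logFC of the set's member DEG
#' (`"up"`, `"down"`, or `"mixed"` on a zero mean); dot-plot ready.
#'
#' @param enrichments named list (one element per contrast) of
#'   [oraHypergeometric()] tables.
#' @param degTables named list (same names) of DEG tables with `gene` and
#'   `logFC` columns, used for the direction tag.
#' @param collection the [GeneSetCollection-class] that was tested.
#' @param sigCut adjusted-p threshold defining the reported union
#'   (default 0.1).
#' @return long data.frame `set`, `contrast`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `significant`, `direction`.
#' @export
themeCompare <- function(enrichments, degTables, collection, sigCut = 0.1) {
  if (length(enrichments) < 2)
    stop("theme comparison needs >= 2 contrasts")
  stopifnot(identical(names(enrichments), names(degTables)))
  keep <- unique(unlist(lapply(enrichments, function(e)
    e$set[e$p_adj < sigCut])))
  sets <- geneSets(collection)
  rows <- lapply(names(enrichments), function(ct) {
    e <- enrichments[[ct]]
    e <- e[e$set %in% keep, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    degs <- degTables[[ct]]
    e$significant <- e$p_adj < sigCut
    e$direction <- vapply(e$set, function(nm) {
      lfc <- degs$logFC[degs$gene %in% sets[[nm]]]
      if (length(lfc) == 0) return("mixed")
      m <- mean(lfc)
      if (m > 0) "up" else if (m < 0) "down" else "mixed"
    }, character(1))
    e$contrast <- ct
    e
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), contrast = character(),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[, c("set", "contrast", "k", "K", "n", "N", "p", "p_adj",
          "significant", "direction")]
}

#' DEG-to-pathway adjacency for chord diagrams
#'
#' Restricts the DEG to high-contrast genes (|logFC| strictly above
#' `lfcFilter`, default 2.5) and records their membership in the enriched
#' sets, both as a 0/1 adjacency matrix and as a chord-diagram-ready edge
#' list.
#'
#' @param deg DEG table with `gene` and `logFC` columns.
#' @param enrichedSets character vector of enriched set names.
#' @param collection the [GeneSetCollection-class].
#' @param lfcFilter absolute logFC filter, strict (default 2.5).
#' @return list with `adjacency` (genes x sets 0/1 matrix, genes carrying
#'   their logFC as attribute `"logFC"`) and `edges` (data.frame `gene`,
#'   `set`, `logFC`).
#' @export
degPathwayAdjacency <- function(deg, enrichedSets, collection,
                                lfcFilter = 2.5) {
  sets <- geneSets(collection)
  unknown <- setdiff(enrichedSets, names(sets))
  if (length(unknown))
    stop("enriched sets absent from the collection: ",
         paste(unknown, collapse = ", "))
  keep <- deg[deg$logFC > lfcFilter | deg$logFC < -lfcFilter, , drop = FALSE]
  adj <- matrix(0L, nrow(keep), length(enrichedSets),
                dimnames = list(keep$gene, enrichedSets))
  for (nm in enrichedSets)
    adj[, nm] <- as.integer(keep$gene %in% sets[[nm]])
  lfc <- setNames(keep$logFC, keep$gene)
  attr(adj, "logFC") <- lfc
  if (length(adj) && sum(adj) > 0) {
    idx <- which(adj == 1L, arr.ind = TRUE)
    edges <- data.frame(gene = rownames(adj)[idx[, 1]],
                        set = colnames(adj)[idx[, 2]],
                        logFC = unname(lfc[rownames(adj)[idx[, 1]]]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$set, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene = character(), set = character(),
                        logFC = numeric(), stringsAsFactors = FALSE)
  }
  list(adjacency = adj, edges = edges)
}
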