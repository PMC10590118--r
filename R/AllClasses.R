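#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor dhyper fisher.test lm median model.matrix p.adjust
#'   pf phyper pnorm pt ptukey quantile rnorm runif sd setNames var aov
#'   TukeyHSD ave
#' @importFrom utils read.delim write.table head
NULL

#' MacrophageExperiment: a log2 expression matrix with condition and donor
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single `log2` assay (genes x samples) together with per-sample `condition`
#' and `donor` labels in `colData`. The paired 2x2 design of the modelled
#' study (differentiation with/without lactoferrin, each with/without LPS,
#' shared donors) is the canonical shape, but any factorial design with at
#' least one condition column is accepted.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("MacrophageExperiment",
         contains = "SummarizedExperiment")

setValidity("MacrophageExperiment", function(object) {
  msg <- character()
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  else {
    a <- SummarizedExperiment::assay(object, "log2")
    if (anyNA(a)) msg <- c(msg, "assay 'log2' contains missing values")
    if (!is.numeric(a)) msg <- c(msg, "assay 'log2' must be numeric")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("condition", "donor"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MacrophageExperiment
#'
#' @param log2 numeric matrix of log2 expression, genes x samples, with
#'   unique rownames (gene symbols) and colnames (sample ids).
#' @param condition character/factor of per-sample condition labels.
#' @param donor character/factor of per-sample donor labels.
#' @return A [MacrophageExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
#' me <- MacrophageExperiment(m, condition = c("a", "a", "b", "b"),
#'                            donor = c("d1", "d2", "d1", "d2"))
#' @export
MacrophageExperiment <- function(log2, condition, donor) {
  stopifnot(is.matrix(log2))
  if (length(condition) != ncol(log2) || length(donor) != ncol(log2))
    stop("condition and donor must have one entry per sample column")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2),
    colData = S4Vectors::DataFrame(
      condition = as.character(condition),
      donor = as.character(donor),
      row.names = colnames(log2)))
  new("MacrophageExperiment", se)
}

#' @describeIn MacrophageExperiment per-sample condition labels
#' @param x a `MacrophageExperiment`
#' @export
conditionLabels <- function(x) SummarizedExperiment::colData(x)$condition

#' @describeIn MacrophageExperiment per-sample donor labels
#' @export
donorLabels <- function(x) SummarizedExperiment::colData(x)$donor

#' @describeIn MacrophageExperiment the log2 expression matrix
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "log2")

#' Gene set collection
#'
#' Named collection of gene symbol sets (pathways, regulator target sets).
#' Set names are unique and every set is non-empty.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot description named character vector, one optional description per set.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "set names must be present, non-empty and unique")
    if (any(lengths(object@sets) == 0))
      msg <- c(msg, "empty gene sets are not allowed")
    if (!all(vapply(object@sets, is.character, logical(1))))
      msg <- c(msg, "sets must be character vectors of gene symbols")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets = list(), description = character()) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (length(description) == 0 && length(sets))
    description <- setNames(rep("", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets, description = description)
}

#' @describeIn GeneSetCollection the named list of gene sets
#' @param x a `GeneSetCollection`
#' @export
geneSets <- function(x) x@sets

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz),
        "(median", median(sz), ")\n")
  }
})

#' Typed molecular interaction network
#'
#' Edge list between gene symbols with two channels: `physical`
#' (contact-dependent membrane protein-protein interactions, undirected) and
#' `soluble` (secreted cytokine to receptor interactions, directed from the
#' cytokine, column `gene_a`, to the receptor, column `gene_b`). Edges may
#' carry a confidence score in [0, 1].
#'
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `channel`,
#'   `directed` (logical), `confidence` (numeric or NA).
#' @export
setClass("InteractionNetwork", representation(edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("gene_a", "gene_b", "channel", "directed", "confidence")
  if (!all(need %in% colnames(e)))
    return(paste("edge table must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$channel %in% c("physical", "soluble")))
      msg <- c(msg, "channel must be 'physical' or 'soluble'")
    if (any(e$channel == "soluble" & !e$directed))
      msg <- c(msg, "soluble edges must be directed (cytokine -> receptor)")
    if (any(e$channel == "physical" & e$directed))
      msg <- c(msg, "physical edges must be undirected")
    if (any(e$gene_a == e$gene_b))
      msg <- c(msg, "self-loops are not allowed")
    conf <- e$confidence[!is.na(e$confidence)]
    if (length(conf) && (any(conf < 0) || any(conf > 1)))
      msg <- c(msg, "confidence must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#' @param edges data.frame with columns `gene_a`, `gene_b`, `channel`
#'   (`"physical"` or `"soluble"`), `directed` (logical/0-1), optional
#'   `confidence` in `[0, 1]`.
#' @return An [InteractionNetwork-class].
#' @export
InteractionNetwork <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"confidence" %in% colnames(edges)) edges$confidence <- NA_real_
  edges$directed <- as.logical(edges$directed)
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  rownames(edges) <- NULL
  new("InteractionNetwork", edges = edges)
}

#' @describeIn InteractionNetwork the edge table
#' @param x an `InteractionNetwork`
#' @param channel optional channel filter (`"physical"` or `"soluble"`)
#' @export
edgeTable <- function(x, channel = NULL) {
  e <- x@edges
  if (!is.null(channel)) {
    stopifnot(channel %in% c("physical", "soluble"))
    e <- e[e$channel == channel, , drop = FALSE]
  }
  e
}

#' @export
setMethod("show", "InteractionNetwork", function(object) {
  e <- object@edges
  cat("InteractionNetwork with", nrow(e), "edges",
      sprintf("(%d physical, %d soluble)\n",
              sum(e$channel == "physical"), sum(e$channel == "soluble")))
})
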