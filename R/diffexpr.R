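#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the common reference distribution defined by the
#' row-wise mean of the per-column sorted values. Tied values within a column
#' receive the mean of the reference quantiles their positions span, so the
#' operation is well defined in the presence of ties.
#'
#' @param x numeric matrix (genes x samples) or a
#'   [MacrophageExperiment-class], in which case the assay is normalized in
#'   place.
#' @return Same type as the input.
#' @export
quantileNormalize <- function(x) {
  if (is(x, "MacrophageExperiment")) {
    SummarizedExperiment::assay(x, "log2") <-
      quantileNormalize(exprMatrix(x))
    return(x)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x)) stop("missing values are not allowed")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    pos <- integer(length(col))
    pos[order(col)] <- seq_along(col)
    # ave() groups equal values; tied entries get the mean reference quantile
    ave(ref[pos], col, FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Gene-wise least-squares fit
#'
#' @slot coefficients genes x coefficients matrix of least-squares estimates.
#' @slot covUnscaled unscaled coefficient covariance `(X'X)^-1`.
#' @slot sigma2 per-gene residual variance.
#' @slot df residual degrees of freedom (scalar, shared design).
#' @slot design the design matrix used.
#' @export
setClass("GeneWiseFit", representation(
  coefficients = "matrix", covUnscaled = "matrix", sigma2 = "numeric",
  df = "numeric", design = "matrix"))

#' Gene-wise fit with empirical-Bayes moderated variances
#'
#' Extends [GeneWiseFit-class] with the estimated prior degrees of freedom
#' `d0`, prior variance `s02`, and the per-gene posterior variances
#' `s2Post = (d0*s02 + df*sigma2) / (d0 + df)`.
#' @slot d0 prior degrees of freedom (may be `Inf`).
#' @slot s02 prior variance.
#' @slot s2Post per-gene posterior (moderated) variance.
#' @export
setClass("ModeratedFit", contains = "GeneWiseFit",
         representation(d0 = "numeric", s02 = "numeric", s2Post = "numeric"))

setValidity("ModeratedFit", function(object) {
  msg <- character()
  if (length(object@s2Post) != length(object@sigma2))
    msg <- c(msg, "s2Post must have one entry per gene")
  if (!is.na(object@d0) && object@d0 < 0)
    msg <- c(msg, "d0 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GeneWiseFit", function(object) {
  cat(class(object), "on", length(object@sigma2), "genes,",
      ncol(object@coefficients), "coefficients, residual df",
      object@df, "\n")
  if (is(object, "ModeratedFit"))
    cat("  prior df d0 =", format(object@d0),
        " prior variance s0^2 =", format(object@s02), "\n")
})

#' Fit the per-gene linear model of a condition/donor design
#'
#' Ordinary least squares per gene with a shared design matrix built from the
#' condition labels and, by default, additive donor blocking terms (paired
#' design: the same donors contribute to every condition).
#'
#' @param experiment a [MacrophageExperiment-class].
#' @param donorBlocking include additive donor terms (default `TRUE`).
#' @return A [GeneWiseFit-class].
#' @export
fitLinearModel <- function(experiment, donorBlocking = TRUE) {
  y <- exprMatrix(experiment)
  cd <- data.frame(condition = factor(conditionLabels(experiment)),
                   donor = factor(donorLabels(experiment)))
  X <- if (donorBlocking && nlevels(cd$donor) > 1)
    model.matrix(~ 0 + condition + donor, cd)
  else
    model.matrix(~ 0 + condition, cd)
  colnames(X) <- sub("^condition", "", colnames(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) - ncol(X) < 1)
    stop("no residual degrees of freedom left by the design")
  xtxi <- chol2inv(chol(crossprod(X)))
  dimnames(xtxi) <- list(colnames(X), colnames(X))
  beta <- y %*% X %*% xtxi
  colnames(beta) <- colnames(X)
  resid <- y - beta %*% t(X)
  df <- nrow(X) - ncol(X)
  new("GeneWiseFit", coefficients = beta, covUnscaled = xtxi,
      sigma2 = rowSums(resid^2) / df, df = df, design = X)
}

# Newton solve of trigamma(y) = x, vectorized; used by the closed-form
# moment estimator of the variance prior.
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior `(d0, s0^2)` of the scaled inverse chi-square variance
#' model by closed-form moment matching on the log residual variances: with
#' `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`, the prior satisfies
#' `E[e] = log(s0^2) + digamma(d0/2) - log(d0/2)` and
#' `Var[e] = trigamma(d/2) + trigamma(d0/2)`, so `d0` follows from a
#' trigamma inverse and `s0^2` from the mean. Posterior variances shrink
#' each `s_g^2` towards `s0^2` with weight `d0 / (d0 + d)`.
#'
#' @param fit a [GeneWiseFit-class] with at least 10 genes.
#' @return A [ModeratedFit-class].
#' @export
eBayesModerate <- function(fit) {
  s2 <- fit@sigma2
  if (length(s2) < 10)
    stop("need >= 10 genes to estimate the variance prior")
  d <- fit@df
  if (all(s2 == 0)) {
    warning("all residual variances are zero; falling back to ordinary t")
    return(new("ModeratedFit", fit, d0 = 0, s02 = NA_real_, s2Post = s2))
  }
  if (any(s2 == 0)) {
    floor <- min(s2[s2 > 0]) * 1e-8
    warning(sum(s2 == 0), " zero residual variances floored at ",
            format(floor))
    s2[s2 == 0] <- floor
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + d * fit@sigma2) / (d0 + d)
  } else {
    # no excess dispersion of log-variances beyond sampling noise: the
    # prior is effectively infinitely informative and the pooled variance
    # is the posterior for every gene
    d0 <- Inf
    s02 <- mean(fit@sigma2)
    s2post <- rep(s02, length(s2))
  }
  names(s2post) <- names(fit@sigma2)
  new("ModeratedFit", fit, d0 = d0, s02 = s02, s2Post = s2post)
}

#' Moderated-t contrast between two conditions
#'
#' @param fit a [ModeratedFit-class] (or a plain [GeneWiseFit-class], in
#'   which case ordinary t-statistics are returned).
#' @param contrast length-2 character `c(numerator, denominator)` naming two
#'   condition coefficients, or a full numeric contrast vector over the
#'   design coefficients.
#' @param label optional contrast label stored in the result.
#' @return data.frame `gene`, `logFC`, `t`, `p`, `fdr` (Benjamini-Hochberg),
#'   with attribute `"contrast"`.
#' @export
contrastResult <- function(fit, contrast, label = NULL) {
  cn <- colnames(fit@coefficients)
  if (is.character(contrast)) {
    stopifnot(length(contrast) == 2)
    if (!all(contrast %in% cn))
      stop("unknown condition coefficients: ",
           paste(setdiff(contrast, cn), collapse = ", "))
    cv <- setNames(numeric(length(cn)), cn)
    cv[contrast[1]] <- 1
    cv[contrast[2]] <- -1
    if (is.null(label)) label <- paste0(contrast[1], "_vs_", contrast[2])
  } else {
    stopifnot(length(contrast) == length(cn))
    cv <- contrast
    if (is.null(label)) label <- "contrast"
  }
  logFC <- drop(fit@coefficients %*% cv)
  vc <- drop(t(cv) %*% fit@covUnscaled %*% cv)
  if (is(fit, "ModeratedFit") && fit@d0 > 0 && !is.na(fit@s02)) {
    s2 <- fit@s2Post
    dfTotal <- fit@df + fit@d0
  } else {
    s2 <- fit@sigma2
    dfTotal <- fit@df
  }
  tstat <- logFC / sqrt(s2 * vc)
  tstat[s2 == 0 & logFC == 0] <- 0
  p <- 2 * pt(-abs(tstat), df = dfTotal)
  out <- data.frame(gene = rownames(fit@coefficients), logFC = logFC,
                    t = tstat, p = p, fdr = adjustBH(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- label
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (FDR), monotone and capped at 1.
#' @export
adjustBH <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1L) * p[o]))[ro]
}

#' Select differentially expressed genes at strict cutoffs
#'
#' Keeps genes with `fdr < fdrCut` and `logFC` strictly above `lfcCut` or
#' strictly below `-lfcCut`; both inequalities are strict. `lfcCut = 0`
#' reduces the rule to the FDR threshold alone (a sensitivity mode that
#' selects any gene with nonzero fold change and significant FDR).
#'
#' @param result a [contrastResult()] table.
#' @param fdrCut FDR threshold (default 0.05).
#' @param lfcCut absolute log2-fold-change threshold (default 0.58).
#' @return subset of `result` with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
selectDEG <- function(result, fdrCut = 0.05, lfcCut = 0.58) {
  stopifnot(all(c("gene", "logFC", "fdr") %in% colnames(result)))
  keep <- result$fdr < fdrCut & (result$logFC > lfcCut |
                                 result$logFC < -lfcCut)
  out <- result[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(result, "contrast")
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons per gene
#'
#' Targeted comparison of selected genes across the condition groups:
#' one-way ANOVA F-test per gene followed by Tukey's honest significant
#' difference adjusted p-values for all pairwise condition comparisons
#' (studentized-range distribution).
#'
#' @param experiment a [MacrophageExperiment-class].
#' @param genes gene symbols to test (must exist in the experiment).
#' @return data.frame `gene`, `comparison`, `diff`, `p_adj`, `anova_F`,
#'   `anova_p`.
#' @export
anovaTukey <- function(experiment, genes) {
  y <- exprMatrix(experiment)
  missing <- setdiff(genes, rownames(y))
  if (length(missing))
    stop("genes absent from the experiment: ",
         paste(missing, collapse = ", "))
  grp <- factor(conditionLabels(experiment))
  if (nlevels(grp) < 2) stop("need >= 2 condition groups")
  if (any(table(grp) < 2))
    stop("every condition group needs >= 2 samples")
  out <- lapply(genes, function(g) {
    d <- data.frame(value = y[g, ], group = grp)
    fit <- aov(value ~ group, data = d)
    sm <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    data.frame(gene = g, comparison = rownames(tk),
               diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]),
               anova_F = sm[1, "F value"], anova_p = sm[1, "Pr(>F)"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run moderated differential expression for all design contrasts
#'
#' Convenience wrapper: fit, moderate, and tabulate every contrast in
#' [designContrasts()] that is estimable from the experiment's conditions.
#'
#' @param experiment a [MacrophageExperiment-class].
#' @param donorBlocking passed to [fitLinearModel()].
#' @return named list of [contrastResult()] tables.
#' @export
runDifferentialExpression <- function(experiment, donorBlocking = TRUE) {
  fit <- eBayesModerate(fitLinearModel(experiment, donorBlocking))
  conds <- unique(conditionLabels(experiment))
  use <- Filter(function(p) all(p %in% conds), designContrasts())
  lapply(use, function(pair) contrastResult(fit, pair))
}
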