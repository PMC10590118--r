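test_that("quantile normalization matches the definition and limma", {
  # identical columns are already normalized
  m <- matrix(c(1, 5, 3, 1, 5, 3), 3, 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(quantileNormalize(m), m)
  # constant matrix unchanged
  k <- matrix(2, 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  expect_equal(quantileNormalize(k), k)
  # 3x2 hand computation: sorted columns (1,3,5) and (2,4,8),
  # reference = (1.5, 3.5, 6.5)
  h <- matrix(c(5, 1, 3, 2, 8, 4), 3, 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(unname(quantileNormalize(h)),
               matrix(c(6.5, 1.5, 3.5, 1.5, 6.5, 3.5), 3, 2))
  # tied values receive the mean of the tied reference quantiles:
  # ref = (1.5, 2.5, 5.5); the tie (1, 1) spans quantiles 1-2 -> 2.0
  tie <- matrix(c(1, 1, 5, 2, 4, 6), 3, 2,
                dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(unname(quantileNormalize(tie)),
               matrix(c(2, 2, 5.5, 1.5, 2.5, 5.5), 3, 2))
  # agreement with the reference implementation on tie-free data
  set.seed(42)
  r <- matrix(rnorm(60), 12, 5)
  dimnames(r) <- list(paste0("g", 1:12), paste0("s", 1:5))
  expect_equal(unname(quantileNormalize(r)),
               unname(limma::normalizeQuantiles(r)), tolerance = 1e-12)
  expect_error(quantileNormalize(matrix(c(1, NA), 1, 2)), "missing|2 samples")
})

test_that("gene-wise least squares matches closed forms and lm()", {
  # two groups, no donor term: coefficient difference = mean difference
  m <- matrix(c(1, 2, 3, 5, 2, 4, 6, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  me <- MacrophageExperiment(m, condition = c("a", "a", "b", "b"),
                             donor = paste0("d", 1:4))
  fit <- fitLinearModel(me, donorBlocking = FALSE)
  expect_equal(unname(fit@coefficients[, "b"] - fit@coefficients[, "a"]),
               c(mean(m[1, 3:4]) - mean(m[1, 1:2]),
                 mean(m[2, 3:4]) - mean(m[2, 1:2])))
  # constant response: zero residual variance, exact coefficients
  mc <- matrix(7, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  mec <- MacrophageExperiment(mc, condition = c("a", "a", "b", "b"),
                              donor = paste0("d", 1:4))
  fc <- fitLinearModel(mec, donorBlocking = FALSE)
  expect_equal(unname(fc@sigma2), 0)
  expect_equal(unname(fc@coefficients[1, ]), c(a = 7, b = 7),
               ignore_attr = TRUE)
  # paired 4-condition, 4-donor design on 5 genes vs lm() oracle
  sim <- toyExperiment(nGenes = 5, seed = 3)
  fitP <- fitLinearModel(sim$experiment)
  cond <- factor(conditionLabels(sim$experiment))
  donor <- factor(donorLabels(sim$experiment))
  for (g in rownames(sim$experiment)) {
    o <- lm(exprMatrix(sim$experiment)[g, ] ~ 0 + cond + donor)
    expect_equal(unname(fitP@coefficients[g, seq_len(nlevels(cond))]),
                 unname(coef(o)[seq_len(nlevels(cond))]),
                 tolerance = 1e-10)
    expect_equal(unname(fitP@sigma2[g]), summary(o)$sigma^2,
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  # donor nested in condition: condition is collinear with donors
  m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3),
                                               paste0("s", 1:4)))
  me <- MacrophageExperiment(m, condition = c("a", "a", "b", "b"),
                             donor = c("d1", "d1", "d2", "d2"))
  expect_error(fitLinearModel(me), "rank deficient.*donor")
})

test_that("eBayes moderation satisfies the posterior-variance identity", {
  # heterogeneous gene variances so the prior df is finite
  sim <- toyExperiment(nGenes = 80, seed = 5)
  m <- exprMatrix(sim$experiment)
  scale <- exp(seq(-1, 1, length.out = nrow(m)))
  m2 <- (m - rowMeans(m)) * scale + rowMeans(m)
  me <- MacrophageExperiment(m2, conditionLabels(sim$experiment),
                             donorLabels(sim$experiment))
  mod <- eBayesModerate(fitLinearModel(me))
  expect_true(is.finite(mod@d0))
  expect_equal(mod@s2Post,
               (mod@d0 * mod@s02 + mod@df * mod@sigma2) / (mod@d0 + mod@df),
               tolerance = 1e-12)
  lo <- pmin(mod@sigma2, mod@s02); hi <- pmax(mod@sigma2, mod@s02)
  expect_true(all(mod@s2Post >= lo - 1e-12 & mod@s2Post <= hi + 1e-12))
})

test_that("moderated statistics agree with the reference eBayes", {
  sim <- toyExperiment(nGenes = 200, seed = 8)
  # heterogeneous per-gene variances keep the prior df moderate
  m <- exprMatrix(sim$experiment)
  scale <- exp(seq(-1.5, 1.5, length.out = nrow(m)))
  m <- (m - rowMeans(m)) * scale + rowMeans(m)
  sim$experiment <- MacrophageExperiment(
    m, conditionLabels(sim$experiment), donorLabels(sim$experiment))
  cond <- factor(conditionLabels(sim$experiment),
                 levels = designConditions())
  donor <- factor(donorLabels(sim$experiment))
  design <- model.matrix(~ 0 + cond + donor)
  colnames(design) <- sub("^cond", "", colnames(design))
  lfit <- limma::lmFit(exprMatrix(sim$experiment), design)
  cm <- limma::makeContrasts(hlf - uM, levels = design)
  lfit <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  mod <- eBayesModerate(fitLinearModel(sim$experiment))
  res <- contrastResult(mod, c("hlf", "uM"))
  expect_equal(mod@d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod@s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(res$logFC, unname(lfit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(res$t, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(lfit$p.value[, 1]), tolerance = 1e-8)
})

test_that("degenerate and limiting moderation cases behave", {
  # all residual variances equal -> d0 = Inf, s2Post = common value
  m <- matrix(rnorm(16 * 12), 12, 16)
  dimnames(m) <- list(paste0("g", 1:12), paste0("s", 1:16))
  cond <- rep(c("a", "b"), each = 8)
  donor <- rep(paste0("d", 1:8), 2)
  me <- MacrophageExperiment(m, cond, donor)
  fit <- fitLinearModel(me, donorBlocking = FALSE)
  fit@sigma2 <- rep(0.5, 12)
  names(fit@sigma2) <- rownames(m)
  mod <- eBayesModerate(fit)
  expect_equal(mod@d0, Inf)
  expect_equal(unname(mod@s2Post), rep(0.5, 12), tolerance = 1e-9)
  # gene with logFC exactly 0 -> t = 0, p = 1
  fit2 <- fitLinearModel(me, donorBlocking = FALSE)
  fit2@coefficients[1, ] <- c(2, 2)
  res <- contrastResult(eBayesModerate(fit2), c("b", "a"))
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  # all variances zero -> ordinary t fallback with warning
  fit3 <- fit
  fit3@sigma2 <- rep(0, 12); names(fit3@sigma2) <- rownames(m)
  expect_warning(eBayesModerate(fit3), "ordinary t")
})

test_that("variance prior hyperparameters are recovered by simulation", {
  d0True <- 6; s02True <- 0.2; d <- 9; nGenes <- 20
  set.seed(99)
  est <- t(vapply(1:200, function(i) {
    sigma2 <- d0True * s02True / rchisq(nGenes, d0True)
    s2 <- sigma2 * rchisq(nGenes, d) / d
    fit <- new("GeneWiseFit",
               coefficients = matrix(0, nGenes, 1,
                                     dimnames = list(paste0("g",
                                                            1:nGenes), "c")),
               covUnscaled = matrix(1, 1, 1), sigma2 = s2, df = d,
               design = matrix(0, 0, 0))
    mod <- eBayesModerate(fit)
    c(d0 = min(mod@d0, 1e4), s02 = mod@s02)
  }, numeric(2)))
  expect_lt(abs(median(est[, "d0"]) - d0True) / d0True, 0.2)
  expect_lt(abs(median(est[, "s02"]) - s02True) / s02True, 0.2)
})

test_that("moderated t reduces to the ordinary t when the prior is off", {
  sim <- toyExperiment(nGenes = 40, seed = 12)
  fit <- fitLinearModel(sim$experiment)
  plain <- contrastResult(fit, c("hlf", "uM"))
  forced <- eBayesModerate(fit)
  forced@d0 <- 0
  off <- contrastResult(forced, c("hlf", "uM"))
  expect_equal(off$t, plain$t, tolerance = 1e-12)
  expect_equal(off$p, plain$p, tolerance = 1e-12)
})

test_that("BH adjustment matches hand computation, brute force, p.adjust", {
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    a <- adjustBH(p)
    expect_equal(a, bhBrute(p), tolerance = 1e-14)
    expect_equal(a, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(a >= p - 1e-15) && all(a <= 1))
  }
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG selection applies strict cutoffs with signed partition", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(0.60, 0.58, -0.59, -3),
                    fdr = c(0.04, 0.04, 0.05, 0.01))
  deg <- selectDEG(res)
  expect_equal(deg$gene, c("a", "d"))       # 0.58 and fdr = 0.05 excluded
  expect_equal(deg$direction, c("up", "down"))
  allNull <- data.frame(gene = "a", logFC = 5, fdr = 1)
  expect_equal(nrow(selectDEG(allNull)), 0L)
})

test_that("ANOVA/Tukey matches hand-computed F and dominates pairwise t", {
  # textbook 3-group example, n = 4 each
  vals <- c(8, 9, 6, 5, 4, 6, 3, 7, 1, 2, 3, 2)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  m <- matrix(vals, 1, 12, dimnames = list("gene1", paste0("s", 1:12)))
  me <- MacrophageExperiment(m, condition = grp, donor = paste0("d", 1:12))
  out <- anovaTukey(me, "gene1")
  # hand computation of the F statistic from sums of squares
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  fHand <- (ssb / 2) / (ssw / 9)
  expect_equal(out$anova_F[1], fHand, tolerance = 1e-12)
  # Tukey adjusted p >= unadjusted pairwise t p
  for (cmp in out$comparison) {
    gs <- strsplit(cmp, "-")[[1]]
    praw <- t.test(vals[grp == gs[1]], vals[grp == gs[2]],
                   var.equal = TRUE)$p.value
    expect_gte(out$p_adj[out$comparison == cmp] + 1e-12, praw)
  }
  # identical group means with positive variance: F = 0, all p = 1
  v2 <- rep(c(1, 3, 2, 2), 3)
  m2 <- matrix(v2, 1, 12, dimnames = list("gene1", paste0("s", 1:12)))
  me2 <- MacrophageExperiment(m2, condition = grp,
                              donor = paste0("d", 1:12))
  out2 <- anovaTukey(me2, "gene1")
  expect_equal(out2$anova_F[1], 0)
  expect_true(all(out2$p_adj > 0.999))
  # group with < 2 samples errors
  me3 <- MacrophageExperiment(m2[, 1:5, drop = FALSE],
                              condition = c("a", "a", "b", "b", "c"),
                              donor = paste0("d", 1:5))
  expect_error(anovaTukey(me3, "gene1"), ">= 2 samples")
})

test_that("donor blocking removes additive per-donor offsets exactly", {
  sim <- toyExperiment(nGenes = 30, seed = 21)
  me <- sim$experiment
  res1 <- contrastResult(eBayesModerate(fitLinearModel(me)), c("hlf", "uM"))
  shift <- setNames(c(3, -1, 0.5, 2), unique(donorLabels(me)))
  m2 <- exprMatrix(me) +
    matrix(shift[donorLabels(me)], nrow(me), ncol(me), byrow = TRUE)
  me2 <- MacrophageExperiment(m2, conditionLabels(me), donorLabels(me))
  res2 <- contrastResult(eBayesModerate(fitLinearModel(me2)),
                         c("hlf", "uM"))
  expect_equal(res2$logFC, res1$logFC, tolerance = 1e-9)
})
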