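test_that("annotation filter keeps class members and preserves columns", {
  ann <- data.frame(gene = c("A", "B", "B", "C"),
                    class = c("membrane", "cytokine", "innate", "cytokine"))
  deg <- data.frame(gene = c("A", "B", "C", "D"), logFC = 1:4,
                    fdr = c(0.01, 0.02, 0.03, 0.04))
  out <- filterByAnnotation(deg, ann, "cytokine")
  expect_equal(out$gene, c("B", "C"))
  expect_true(all(c("logFC", "fdr") %in% colnames(out)))
  # gene in two classes appears under both filters
  expect_true("B" %in% filterByAnnotation(deg, ann, "innate")$gene)
  expect_equal(nrow(filterByAnnotation(deg, ann, "membrane")), 1L)
  expect_equal(nrow(filterByAnnotation(deg[deg$gene == "D", ], ann,
                                       "cytokine")), 0L)
  expect_error(filterByAnnotation(deg, ann, "nope"),
               "cytokine.*innate.*membrane")
})

test_that("standardization uses sample SD and handles degeneracies", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g", c("c1", "c2")))
  z <- standardizeExpression(m)
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # population SD variant
  zp <- standardizeExpression(m, populationSd = TRUE)
  expect_equal(unname(zp[1, ]), c(-1, 1), tolerance = 1e-12)
  # constant row -> zeros with warning
  mc <- matrix(c(2, 2, 2, 1, 5, 9), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("c", 1:3)))
  expect_warning(zc <- standardizeExpression(mc), "zero-variance")
  expect_equal(unname(zc["g1", ]), c(0, 0, 0))
  # idempotence up to FP tolerance
  set.seed(2)
  r <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3),
                                               paste0("c", 1:4)))
  z1 <- standardizeExpression(r)
  expect_equal(standardizeExpression(z1), z1, tolerance = 1e-12)
  expect_error(standardizeExpression(r[, 1, drop = FALSE]), ">= 2")
})

test_that("propensity equals the brute-force double loop on random toys", {
  for (s in 1:100) {
    toy <- randomPropensityToy(s)
    net <- InteractionNetwork(toy$edges)
    for (ch in intersect(c("physical", "soluble"), toy$edges$channel)) {
      got <- interactionPropensity(toy$macroZ, toy$cellZ, net, ch)
      want <- propensityBrute(toy$macroZ, toy$cellZ, toy$edges, ch)
      m <- matrix(got$score, nrow(want), ncol(want))
      expect_equal(m, unname(want), tolerance = 1e-12)
    }
  }
})

test_that("propensity is bilinear and additive over edge partitions", {
  toy <- randomPropensityToy(7)
  net <- InteractionNetwork(toy$edges)
  ch <- toy$edges$channel[1]
  base <- interactionPropensity(toy$macroZ, toy$cellZ, net, ch)$score
  dbl <- interactionPropensity(2 * toy$macroZ, toy$cellZ, net, ch)$score
  expect_equal(dbl, 2 * base, tolerance = 1e-12)
  # additivity over a partition of the edge set
  e <- toy$edges[toy$edges$channel == ch, ]
  if (nrow(e) >= 2) {
    half <- seq_len(floor(nrow(e) / 2))
    s1 <- interactionPropensity(toy$macroZ, toy$cellZ,
                                InteractionNetwork(e[half, ]), ch)$score
    s2 <- interactionPropensity(toy$macroZ, toy$cellZ,
                                InteractionNetwork(e[-half, ]), ch)$score
    expect_equal(s1 + s2, base, tolerance = 1e-12)
  }
  # empty edge set: zero scores with warning, not an error
  emptyNet <- InteractionNetwork(toy$edges[0, ])
  expect_warning(z <- interactionPropensity(toy$macroZ, toy$cellZ,
                                            emptyNet, "soluble"),
                 "no soluble edges")
  expect_true(all(z$score == 0))
})

test_that("single soluble edge gives the single product", {
  macroZ <- matrix(2, 1, 1 + 1, dimnames = list("CYT", c("a", "b")))
  macroZ[1, 2] <- -2
  cellZ <- matrix(0.5, 1, 1, dimnames = list("REC", "Tcell"))
  net <- InteractionNetwork(data.frame(gene_a = "CYT", gene_b = "REC",
                                       channel = "soluble", directed = TRUE))
  got <- interactionPropensity(macroZ, cellZ, net, "soluble")
  expect_equal(got$score[got$condition == "a"], 1.0)
  expect_equal(got$score[got$condition == "b"], -1.0)
})

test_that("coverage report always accounts for every channel edge", {
  for (s in 1:20) {
    toy <- randomPropensityToy(100 + s)
    net <- InteractionNetwork(toy$edges)
    for (ch in c("physical", "soluble")) {
      e <- toy$edges[toy$edges$channel == ch, ]
      if (nrow(e) == 0) next
      cov <- attr(interactionPropensity(toy$macroZ, toy$cellZ, net, ch),
                  "coverage")
      expect_equal(cov$used + cov$skipped, nrow(e))
      expect_equal(cov$total, nrow(e))
    }
  }
})

test_that("reference deltas are zero at the reference and shift-stable", {
  toy <- randomPropensityToy(11)
  net <- InteractionNetwork(toy$edges)
  ch <- toy$edges$channel[1]
  sc <- interactionPropensity(toy$macroZ, toy$cellZ, net, ch)
  ref <- sc$condition[1]
  out <- relativeToReference(sc, ref)
  expect_true(all(out$delta_vs_ref[out$condition == ref] == 0))
  # translation invariance of cross-condition ordering per cell type
  sc2 <- sc
  oneCell <- sc$cell_type[1]
  sc2$score[sc2$cell_type == oneCell] <-
    sc2$score[sc2$cell_type == oneCell] + 5
  out2 <- relativeToReference(sc2, ref)
  o1 <- order(out$delta_vs_ref[out$cell_type == oneCell])
  o2 <- order(out2$delta_vs_ref[out2$cell_type == oneCell])
  expect_equal(o1, o2)
  expect_error(relativeToReference(sc, "NOPE"), "not present")
})

test_that("driver decomposition is exact and sign-symmetric", {
  for (s in 1:25) {
    toy <- randomPropensityToy(200 + s)
    if (ncol(toy$macroZ) < 2) next
    net <- InteractionNetwork(toy$edges)
    conds <- colnames(toy$macroZ)[1:2]
    for (ch in c("physical", "soluble")) {
      if (!any(toy$edges$channel == ch)) next
      drv <- interactionDrivers(toy$macroZ, conds[1], conds[2],
                                toy$cellZ, net, ch)
      sc <- interactionPropensity(toy$macroZ, toy$cellZ, net, ch)
      totalDelta <- sum(sc$score[sc$condition == conds[1]]) -
                    sum(sc$score[sc$condition == conds[2]])
      expect_equal(sum(drv$contribution_delta), totalDelta,
                   tolerance = 1e-9)
      # swapping conditions negates every contribution
      rev <- interactionDrivers(toy$macroZ, conds[2], conds[1],
                                toy$cellZ, net, ch)
      rev <- rev[match(drv$gene, rev$gene), ]
      expect_equal(rev$contribution_delta, -drv$contribution_delta,
                   tolerance = 1e-12)
    }
  }
})

test_that("interaction count tallies distinct reachable cell types", {
  macroZ <- matrix(c(1, -1), 1, 2, dimnames = list("G", c("a", "b")))
  cellZ <- matrix(c(1, 2, 3), 1, 3,
                  dimnames = list("P", c("t1", "t2", "t3")))
  net <- InteractionNetwork(data.frame(gene_a = "G", gene_b = "P",
                                       channel = "soluble", directed = TRUE))
  drv <- interactionDrivers(macroZ, "a", "b", cellZ, net, "soluble")
  expect_equal(drv$interaction_count, 3L)
  expect_equal(drv$contribution_delta, 2 * (1 + 2 + 3))
  # gene without incident edges is absent
  macroZ2 <- rbind(macroZ, LONELY = c(5, 5))
  drv2 <- interactionDrivers(macroZ2, "a", "b", cellZ, net, "soluble")
  expect_false("LONELY" %in% drv2$gene)
  # mean expression attached when a mean matrix is supplied
  meanExpr <- matrix(c(6, 8), 1, 2, dimnames = list("G", c("a", "b")))
  drv3 <- interactionDrivers(macroZ, "a", "b", cellZ, net, "soluble",
                             meanExpr = meanExpr)
  expect_equal(drv3$mean_expr, 7)
})
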