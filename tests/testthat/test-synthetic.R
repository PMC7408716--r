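test_that("pathway generation is deterministic and honors its contracts", {
  g1 <- generatePathway(nNodes = 12, seed = 5)
  g2 <- generatePathway(nNodes = 12, seed = 5)
  expect_identical(edgeTable(g1), edgeTable(g2))
  expect_identical(nodeTable(g1), nodeTable(g2))
  g3 <- generatePathway(nNodes = 12, seed = 6)
  expect_false(identical(edgeTable(g1), edgeTable(g3)))

  # all-activation graphs when pInhibition = 0
  g0 <- generatePathway(nNodes = 10, pEdge = 0.6, pInhibition = 0,
                        seed = 3)
  expect_true(all(edgeTable(g0)$sign == "activation"))

  # forced minimal topology: one receptor, one effector, one circuit
  gm <- generatePathway(nNodes = 3, pEdge = 1, nReceptors = 1,
                        nEffectors = 1, seed = 1)
  expect_length(extractEffectorCircuits(gm), 1L)

  expect_error(generatePathway(nNodes = 3, nReceptors = 2, nEffectors = 2),
               class = "sc_input_error")
})

test_that("every generated effector is activation-reachable from a receptor", {
  for (seed in 1:12) {
    g <- generatePathway(nNodes = sample(5:14, 1), pEdge = 0.3,
                         pInhibition = 0.4, seed = seed)
    circ <- extractEffectorCircuits(g)
    expect_length(circ, sum(nodeTable(g)$effector))
    act <- suppressWarnings(
      computeActivityMatrix(circ, makeNvm(
        matrix(1, nrow(nodeTable(g)), 1,
               dimnames = list(nodeTable(g)$node_id, "s1")))))
    expect_false(any(convergenceReport(act)$starved))
  }
})

test_that("expression generation plants group effects with NB noise", {
  g <- generatePathway(nNodes = 8, seed = 2)
  genes <- unlist(nodeTable(g)$genes)
  de <- genes[3]
  ex <- generateExpression(g, nPerGroup = 50, deGenes = de,
                           effectLog2fc = 2, dispersion = 0.05,
                           baseMean = 300, seed = 4)
  m <- as.matrix(ex$expression)
  expect_equal(dim(m), c(8L, 100L))
  expect_equal(levels(ex$labels), c("G1", "G2"))
  g1 <- names(ex$labels)[ex$labels == "G1"]
  g2 <- names(ex$labels)[ex$labels == "G2"]
  ratio <- mean(m[de, g1]) / mean(m[de, g2])
  expect_gt(ratio, 2.5)  # planted 4x, NB noise
  other <- setdiff(genes, de)
  ratios <- rowMeans(m[other, g1]) / rowMeans(m[other, g2])
  expect_true(all(ratios > 0.6 & ratios < 1.6))

  # determinism and seed sensitivity
  ex2 <- generateExpression(g, nPerGroup = 50, deGenes = de,
                            effectLog2fc = 2, dispersion = 0.05,
                            baseMean = 300, seed = 4)
  expect_identical(m, as.matrix(ex2$expression))

  expect_error(generateExpression(g, deGenes = "nope"),
               class = "sc_input_error")
  expect_error(generateExpression(g, nPerGroup = 2),
               class = "sc_input_error")
})

test_that("zero dispersion approaches the Poisson mean-variance relation", {
  g <- generatePathway(nNodes = 5, seed = 8)
  ex <- generateExpression(g, nPerGroup = 500, dispersion = 0,
                           baseMean = 100, sdLog = 0, seed = 9)
  m <- as.matrix(ex$expression)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("scenario ground truth is disjoint, present, and seed-stable", {
  sc <- generateScenario(nPathways = 3, nNodes = 10, nPerGroup = 5,
                         deGenes = 6, effectLog2fc = 2, seed = 12,
                         withDrug = TRUE)
  circuits <- unlist(lapply(sc@graphs, extractEffectorCircuits),
                     recursive = FALSE)
  ids <- vapply(circuits, circuitId, character(1))
  expect_length(intersect(sc@truthGsdsa, sc@truthNull), 0L)
  expect_true(all(c(sc@truthGsdsa, sc@truthNull) %in% ids))
  expect_true(all(sc@truthGsdsa %in% sc@deCircuits))
  expect_length(sc@drugs, 1L)

  sc2 <- generateScenario(nPathways = 3, nNodes = 10, nPerGroup = 5,
                          deGenes = 6, effectLog2fc = 2, seed = 12,
                          withDrug = TRUE)
  expect_identical(as.matrix(sc@expression), as.matrix(sc2@expression))
  expect_identical(sc@truthGsdsa, sc2@truthGsdsa)

  # sub-unit planted effects leave the expected differential set empty
  weak <- generateScenario(nPathways = 2, nNodes = 8, nPerGroup = 5,
                           deGenes = 4, effectLog2fc = 0.5, seed = 12)
  expect_length(weak@truthGsdsa, 0L)
  expect_gt(length(weak@deCircuits), 0L)
})

test_that("null circuits really contain no planted gene", {
  sc <- generateScenario(nPathways = 4, nNodes = 10, nPerGroup = 5,
                         deGenes = 5, effectLog2fc = 2, seed = 31)
  circuits <- unlist(lapply(sc@graphs, extractEffectorCircuits),
                     recursive = FALSE)
  de <- sc@params$deGenes
  for (c in circuits) {
    nodeGenes <- paste0("g_", memberNodes(c))  # one gene per node
    if (circuitId(c) %in% sc@truthNull)
      expect_length(intersect(nodeGenes, de), 0L)
    if (circuitId(c) %in% sc@deCircuits)
      expect_gt(length(intersect(nodeGenes, de)), 0L)
  }
})

test_that("recovery scoring follows the declared conventions", {
  sc <- generateScenario(nPathways = 2, nNodes = 8, nPerGroup = 5,
                         deGenes = 3, effectLog2fc = 2, seed = 44)
  allIds <- union(sc@truthGsdsa, sc@truthNull)
  mk <- function(called) data.frame(
    circuit_id = allIds, fdr_p = ifelse(allIds %in% called, 0.01, 0.9))

  perfect <- evaluateRecovery(mk(sc@truthGsdsa), sc)
  expect_equal(unname(perfect), c(1, 1, 0))

  none <- evaluateRecovery(mk(character()), sc)
  expect_equal(unname(none), c(0, 1, 0))  # 0/0 FDR counted as 0

  all <- evaluateRecovery(mk(allIds), sc)
  expect_equal(unname(all["sensitivity"]), 1)
  expect_equal(unname(all["specificity"]), 0)

  expect_error(evaluateRecovery(mk(allIds)[-1, ], sc),
               class = "sc_input_error")
})

test_that("scenario files round-trip through the loaders", {
  sc <- generateScenario(nPathways = 2, nNodes = 8, nPerGroup = 4,
                         deGenes = 3, seed = 3, withDrug = TRUE)
  dir <- withr::local_tempdir()
  writeScenario(sc, dir)
  graphs <- loadPathways(file.path(dir, "nodes.tsv"),
                         file.path(dir, "edges.tsv"))
  expect_equal(names(graphs), names(sc@graphs))
  for (nm in names(graphs)) {
    expect_identical(edgeTable(graphs[[nm]]), edgeTable(sc@graphs[[nm]]))
    expect_identical(nodeTable(graphs[[nm]])$genes,
                     nodeTable(sc@graphs[[nm]])$genes)
  }
  expect_identical(as.matrix(readExpression(file.path(dir, "expr.tsv"))),
                   as.matrix(sc@expression))
  lab <- readLabels(file.path(dir, "labels.tsv"))
  expect_identical(as.character(lab), as.character(sc@labels))
  drugs <- readDrugTable(file.path(dir, "drugs.tsv"))
  expect_equal(drugTargets(drugs[[1]]), drugTargets(sc@drugs[[1]]))
})
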