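test_that("pathway loading parses tables, aliases signs, and validates", {
  nodeFile <- withr::local_tempfile(fileext = ".tsv")
  edgeFile <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tgenes", "R\tgR", "M\tgM", "E\tgE"), nodeFile)
  writeLines(c("source\ttarget\tsign",
               "R\tM\tactivation", "M\tE\tactivation"), edgeFile)
  g <- loadPathway(nodeFile, edgeFile, pathwayId = "toy")
  expect_s4_class(g, "PathwayGraph")
  expect_equal(nrow(nodeTable(g)), 3L)
  expect_equal(nrow(edgeTable(g)), 2L)

  # declared alias map, case-insensitive
  writeLines(c("source\ttarget\tsign",
               "R\tM\tACTIVATES", "M\tE\tblocks"), edgeFile)
  g2 <- loadPathway(nodeFile, edgeFile, pathwayId = "toy",
                    signAliases = c(activates = "activation",
                                    blocks = "inhibition"))
  expect_equal(edgeTable(g2)$sign, c("activation", "inhibition"))

  # unknown sign token without alias
  expect_error(loadPathway(nodeFile, edgeFile), class = "sc_format_error")

  # missing required column
  writeLines(c("source\ttarget", "R\tM"), edgeFile)
  expect_error(loadPathway(nodeFile, edgeFile), class = "sc_format_error")
})

test_that("graph construction rejects self-loops, unknown nodes and sign conflicts", {
  nodes <- data.frame(node_id = c("R", "E"), genes = c("gR", "gE"))
  err <- expect_error(
    pathwayGraph(nodes, data.frame(source = "R", target = "R",
                                   sign = "activation")),
    class = "sc_integrity_error")
  expect_match(conditionMessage(err), "R")  # names the offending node

  expect_error(
    pathwayGraph(nodes, data.frame(source = "R", target = "X",
                                   sign = "activation")),
    class = "sc_integrity_error")

  # identical duplicates collapse with a warning
  expect_warning(
    g <- pathwayGraph(nodes, data.frame(source = c("R", "R"),
                                        target = c("E", "E"),
                                        sign = "activation")),
    "duplicated")
  expect_equal(nrow(edgeTable(g)), 1L)

  # conflicting signs on the same edge have no combination rule
  expect_error(
    pathwayGraph(nodes, data.frame(source = c("R", "R"),
                                   target = c("E", "E"),
                                   sign = c("activation", "inhibition"))),
    class = "sc_integrity_error")
})

test_that("receptors and effectors follow topology with annotation override", {
  g <- chainGraph(3)
  expect_equal(findReceptors(g), "R")
  expect_equal(findEffectors(g), "E")

  two <- pathwayGraph(
    nodes = data.frame(node_id = c("R1", "R2", "E"),
                       genes = c("g1", "g2", "g3")),
    edges = data.frame(source = c("R1", "R2"), target = "E",
                       sign = "activation"))
  expect_equal(findReceptors(two), c("R1", "R2"))

  split2 <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "E1", "E2"),
                       genes = c("g1", "g2", "g3")),
    edges = data.frame(source = "R", target = c("E1", "E2"),
                       sign = "activation"))
  expect_equal(findEffectors(split2), c("E1", "E2"))

  # pure cycle, no annotations: nothing derivable
  cyc <- pathwayGraph(
    nodes = data.frame(node_id = c("A", "B", "C"),
                       genes = c("gA", "gB", "gC")),
    edges = data.frame(source = c("A", "B", "C"),
                       target = c("B", "C", "A"), sign = "activation"))
  expect_error(findReceptors(cyc), class = "sc_structural_error")
  expect_error(findEffectors(cyc), class = "sc_structural_error")

  # same cycle with explicit flags resolves
  cyc2 <- pathwayGraph(
    nodes = data.frame(node_id = c("A", "B", "C"),
                       genes = c("gA", "gB", "gC"),
                       receptor = c(1, 0, 0), effector = c(0, 0, 1)),
    edges = data.frame(source = c("A", "B", "C"),
                       target = c("B", "C", "A"), sign = "activation"))
  expect_equal(findReceptors(cyc2), "A")
  expect_equal(findEffectors(cyc2), "C")
})

test_that("effector circuits contain exactly the nodes on receptor-effector paths", {
  # diamond: one effector, both branches in
  circ <- extractEffectorCircuits(diamondGraph())
  expect_length(circ, 1L)
  expect_equal(memberNodes(circ[[1]]), c("A", "B", "E", "R"))
  expect_equal(nrow(memberEdges(circ[[1]])), 4L)

  # R->E1, R->M->E2: circuit(E1) excludes M (brute-force path oracle)
  g <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "M", "E1", "E2"),
                       genes = paste0("g", 1:4)),
    edges = data.frame(source = c("R", "R", "M"),
                       target = c("E1", "M", "E2"), sign = "activation"))
  circ <- extractEffectorCircuits(g)
  expect_length(circ, 2L)
  expect_equal(circuitId(circ[[1]]), "pathway:E1")
  for (c in circ) {
    oracle <- pathMembership(g, findReceptors(g), effector(c))
    expect_equal(memberNodes(c), oracle$nodes)
    got <- sort(paste(memberEdges(c)$source, memberEdges(c)$target,
                      sep = "->"))
    expect_equal(got, oracle$edges)
  }
  expect_false("M" %in% memberNodes(circ[[1]]))

  # isolated node belongs to no circuit
  iso <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "E", "X"),
                       genes = paste0("g", 1:3)),
    edges = data.frame(source = "R", target = "E", sign = "activation"))
  circ <- suppressWarnings(extractEffectorCircuits(iso))
  expect_false(any(vapply(circ, function(c) "X" %in% memberNodes(c),
                          logical(1))))
})

test_that("circuit extraction matches exhaustive path enumeration on random graphs", {
  for (seed in 1:8) {
    g <- generatePathway(nNodes = 8, pEdge = 0.4, pInhibition = 0.2,
                         nReceptors = 2, nEffectors = 2,
                         pathwayId = "rnd", seed = seed)
    recs <- findReceptors(g)
    for (c in extractEffectorCircuits(g)) {
      oracle <- pathMembership(g, recs, effector(c))
      expect_equal(memberNodes(c), oracle$nodes,
                   info = sprintf("seed %d, effector %s", seed,
                                  effector(c)))
      got <- sort(paste(memberEdges(c)$source, memberEdges(c)$target,
                        sep = "->"))
      expect_equal(got, oracle$edges)
    }
  }
})

test_that("circuit extraction is invariant to node/edge table row order", {
  g <- generatePathway(nNodes = 10, pEdge = 0.35, seed = 5,
                       pathwayId = "shuf")
  base <- extractEffectorCircuits(g)
  set.seed(99)
  nd <- nodeTable(g)[sample(nrow(nodeTable(g))), , drop = FALSE]
  ed <- edgeTable(g)[sample(nrow(edgeTable(g))), , drop = FALSE]
  g2 <- pathwayGraph(nd, ed, pathwayId = "shuf")
  shuffled <- extractEffectorCircuits(g2)
  expect_equal(vapply(base, circuitId, character(1)),
               vapply(shuffled, circuitId, character(1)))
  for (i in seq_along(base)) {
    expect_equal(memberNodes(base[[i]]), memberNodes(shuffled[[i]]))
    eb <- memberEdges(base[[i]]); es <- memberEdges(shuffled[[i]])
    expect_setequal(paste(eb$source, eb$target, eb$sign),
                    paste(es$source, es$target, es$sign))
  }
})

test_that("display names disambiguate repeated effector genes", {
  g <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "E1", "E2", "E3"),
                       genes = c("gR", "VEGFA", "VEGFA", "KDR")),
    edges = data.frame(source = "R", target = c("E1", "E2", "E3"),
                       sign = "activation"),
    pathwayId = "pw")
  nm <- vapply(extractEffectorCircuits(g), displayName, character(1))
  expect_setequal(nm, c("pw: VEGFA", "pw: VEGFA *", "pw: KDR"))
})

test_that("circuit table export round-trips", {
  circ <- extractEffectorCircuits(diamondGraph())
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- circuitTable(circ, f)
  back <- read.delim(f)
  expect_equal(back$circuit_id, df$circuit_id)
  expect_equal(back$n_member_nodes, 4L)
  expect_equal(back$receptors, "R")
})
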