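test_that("node update evaluates the product rule and guards its domain", {
  expect_equal(nodeUpdate(1, A = 0.5), 0.5)
  expect_equal(nodeUpdate(0.8, A = c(0.5, 0.5), I = 0.2), 0.48)
  expect_equal(nodeUpdate(0.7, A = 1), 0.7)        # receptor convention
  expect_equal(nodeUpdate(0.7), 0.7)               # empty A -> factor 1
  expect_equal(nodeUpdate(0.9, A = 0.4, I = 1), 0) # full inhibition
  expect_error(nodeUpdate(1.2, A = 0.5), class = "sc_domain_error")
  expect_error(nodeUpdate(0.5, A = -0.1), class = "sc_domain_error")
})

test_that("node update matches the direct formula on a random grid", {
  set.seed(42)
  for (i in 1:300) {
    v <- runif(1)
    A <- runif(sample(0:4, 1))
    I <- runif(sample(0:4, 1))
    expected <- v * (if (length(A)) 1 - prod(1 - A) else 1) *
      prod(1 - I)
    expect_equal(nodeUpdate(v, A, I), expected, tolerance = 1e-15)
  }
})

test_that("activation chains propagate the closed-form product", {
  g <- chainGraph(3)
  circ <- extractEffectorCircuits(g)[[1]]
  st <- propagateCircuit(circ, c(R = 1, M = 1, E = 1))
  expect_equal(unname(st@nodeSignal["E"]), 1)
  expect_true(st@converged)
  expect_equal(st@iterations, 1L)

  st <- propagateCircuit(circ, c(R = 0.9, M = 0.8, E = 0.7))
  expect_equal(unname(st@nodeSignal["E"]), 0.504, tolerance = 1e-12)

  # random lengths and values: effector = prod(v) to 1e-12
  set.seed(8)
  for (n in c(2, 5, 10)) {
    g <- chainGraph(n)
    circ <- extractEffectorCircuits(g)[[1]]
    v <- setNames(runif(n), memberNodes(circ))
    st <- propagateCircuit(circ, v)
    expect_equal(unname(st@nodeSignal[effector(circ)]), prod(v),
                 tolerance = 1e-12)
  }
})

test_that("activation-starved effectors yield zero activity and a flag", {
  g <- chainGraph(3, signs = c("activation", "inhibition"))
  circ <- extractEffectorCircuits(g)[[1]]
  expect_warning(st <- propagateCircuit(circ, c(R = 1, M = 1, E = 1)),
                 "unreachable by activation")
  expect_true(st@starved)
  expect_equal(unname(st@nodeSignal["E"]), 0)
})

test_that("converging branches combine through the OR-like activation factor", {
  circ <- extractEffectorCircuits(diamondGraph())[[1]]
  st <- propagateCircuit(circ, c(R = 1, A = 1, B = 1, E = 1))
  expect_equal(unname(st@nodeSignal["E"]), 1)  # 1 - (1-1)(1-1)

  v <- c(R = 1, A = 0.5, B = 0.5, E = 1)
  st <- propagateCircuit(circ, v)
  expect_equal(unname(st@nodeSignal["E"]), 1 - (1 - 0.5) * (1 - 0.5))
})

test_that("inhibition attenuates by the complement product", {
  # R -> M (activation), R2 -> M (inhibition), M -> E
  g <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "R2", "M", "E"),
                       genes = paste0("g", 1:4)),
    edges = data.frame(source = c("R", "R2", "M"),
                       target = c("M", "M", "E"),
                       sign = c("activation", "inhibition", "activation")))
  circ <- extractEffectorCircuits(g)[[1]]
  v <- c(R = 0.9, R2 = 0.6, M = 1, E = 1)
  st <- propagateCircuit(circ, v)
  # S_M = 1 * (1 - (1-0.9)) * (1 - 0.6); S_E = S_M
  expect_equal(unname(st@nodeSignal["E"]), 0.9 * 0.4, tolerance = 1e-12)
})

test_that("propagation preserves the unit range on random circuits", {
  for (seed in 1:10) {
    g <- generatePathway(nNodes = 10, pEdge = 0.4, pInhibition = 0.3,
                         seed = seed, pathwayId = "rng")
    circ <- extractEffectorCircuits(g)
    set.seed(seed)
    v <- setNames(runif(10), nodeTable(g)$node_id)
    for (c in circ) {
      st <- suppressWarnings(propagateCircuit(c, v))
      expect_true(all(st@nodeSignal >= 0 & st@nodeSignal <= 1))
    }
  }
})

test_that("topological evaluation agrees with the fixed-point oracle on DAGs", {
  nChecked <- 0L
  for (seed in 1:25) {
    g <- generatePathway(nNodes = sample(6:12, 1), pEdge = 0.4,
                         pInhibition = 0.25, seed = seed,
                         pathwayId = "dag")
    set.seed(seed + 500)
    v <- setNames(runif(nrow(nodeTable(g))), nodeTable(g)$node_id)
    for (c in extractEffectorCircuits(g)) {
      st <- suppressWarnings(propagateCircuit(c, v))
      oracle <- fixedPointOracle(c, v)
      expect_equal(st@nodeSignal[memberNodes(c)],
                   oracle[memberNodes(c)], tolerance = 1e-6)
      nChecked <- nChecked + 1L
    }
  }
  expect_gte(nChecked, 25L)
})

test_that("cyclic circuits reach the synchronous fixed point", {
  # R -> A -> B -> A feedback, A -> E
  g <- pathwayGraph(
    nodes = data.frame(node_id = c("R", "A", "B", "E"),
                       genes = paste0("g", 1:4)),
    edges = data.frame(source = c("R", "A", "B", "A"),
                       target = c("A", "B", "A", "E"),
                       sign = "activation"))
  circ <- extractEffectorCircuits(g)[[1]]
  v <- c(R = 0.8, A = 0.9, B = 0.7, E = 0.95)
  st <- propagateCircuit(circ, v)
  expect_true(st@converged)
  expect_gt(st@iterations, 1L)
  oracle <- fixedPointOracle(circ, v, tol = 1e-12)
  expect_equal(st@nodeSignal[memberNodes(circ)],
               oracle[memberNodes(circ)], tolerance = 1e-5)

  # non-convergence within a tiny iteration budget is flagged, not fatal
  expect_warning(st2 <- propagateCircuit(circ, v, maxIter = 1L),
                 "did not converge")
  expect_false(st2@converged)
})

test_that("raising a node value never lowers effector activity on activation-only circuits", {
  for (seed in 1:10) {
    g <- generatePathway(nNodes = 10, pEdge = 0.4, pInhibition = 0,
                         seed = seed, pathwayId = "mono")
    set.seed(seed + 900)
    v <- setNames(runif(10, 0.05, 0.95), nodeTable(g)$node_id)
    for (c in extractEffectorCircuits(g)) {
      base <- propagateCircuit(c, v)@nodeSignal[effector(c)]
      for (n in memberNodes(c)) {
        v2 <- v
        v2[n] <- min(1, v2[n] + 0.3)
        up <- propagateCircuit(c, v2)@nodeSignal[effector(c)]
        expect_gte(up, base - 1e-12)
        v3 <- v
        v3[n] <- 0.001  # knockdown never raises the signal
        down <- propagateCircuit(c, v3)@nodeSignal[effector(c)]
        expect_lte(down, base + 1e-12)
      }
    }
  }
})

test_that("the activity matrix is deterministic and column-separable", {
  g <- generatePathway(nNodes = 8, pEdge = 0.4, seed = 2,
                       pathwayId = "mat")
  circ <- extractEffectorCircuits(g)
  set.seed(2)
  V <- matrix(runif(8 * 4), 8, 4,
              dimnames = list(nodeTable(g)$node_id, paste0("s", 1:4)))
  V[, 2] <- V[, 1]  # identical samples
  nv <- makeNvm(V)
  act <- computeActivityMatrix(circ, nv)
  A <- as.matrix(act)
  expect_identical(unname(A[, 1]), unname(A[, 2]))

  # matrix equals column-wise concatenation of single-sample runs
  for (s in colnames(V)) {
    for (c in circ) {
      st <- propagateCircuit(c, V[, s])
      expect_equal(A[circuitId(c), s],
                   unname(st@nodeSignal[effector(c)]), tolerance = 1e-15)
    }
  }

  # all-zero node values give all-zero activity
  z <- computeActivityMatrix(circ, makeNvm(V * 0))
  expect_true(all(as.matrix(z) == 0))

  rep <- convergenceReport(act)
  expect_equal(rep$circuit_id, rownames(A))
  expect_true(all(rep$converged))
})
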