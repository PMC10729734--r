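test_that("jaccard handles identity, disjoint sets, and counted overlap", {
  expect_equal(jaccard(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard(letters[1:3], letters[10:12]), 0)
  expect_equal(jaccard(letters[1:4], letters[3:8]), 2 / 8)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("edge_weight multiplies Jaccard by the median overlap DE score", {
  de <- setNames(c(1.0, 3.0, 1.7, 0, 0), paste0("g", 1:5))
  # |d|=4, |g|=6, overlap {g1,g2}: J = 0.25, median(1,3) = 2
  d <- c("g1", "g2", "x1", "x2")
  g <- c("g1", "g2", "y1", "y2", "y3", "y4")
  expect_equal(edge_weight(d, g, de), 0.25 * 2.0)
  # single overlap gene, J = 0.1
  d2 <- c("g3", paste0("x", 1:3))
  g2 <- c("g3", paste0("y", 1:6))
  expect_equal(edge_weight(d2, g2, de), 0.1 * 1.7)
  # all-zero overlap scores give zero weight
  expect_equal(edge_weight(c("g4", "g5"), c("g4", "g5", "y1"), de), 0)
  # no measured overlap gene: weight 0 even though the sets intersect
  expect_equal(edge_weight(c("u1", "u2"), c("u1", "z1"), de), 0)
  # disjoint sets: no edge
  expect_equal(edge_weight(c("x1"), c("y1"), de), 0)
})

test_that("bipartite matrix equals elementwise edge_weight calls", {
  for (seed in 1:5) {
    inst <- random_instance(4, 5, 40, seed)
    bw <- build_bipartite(inst$cat, inst$sets, inst$de)
    expect_equal(dim(bw$W), c(4L, 5L))
    for (a in seq_along(inst$cat$targets))
      for (j in seq_along(inst$sets$sets))
        expect_equal(bw$W[a, j],
                     edge_weight(inst$cat$targets[[a]],
                                 inst$sets$sets[[j]], inst$de),
                     tolerance = 1e-14)
  }
  # all-zero DE gives the zero matrix
  inst <- random_instance(3, 4, 30, 99)
  zero_de <- setNames(rep(0, length(inst$de)), names(inst$de))
  expect_true(all(build_bipartite(inst$cat, inst$sets, zero_de)$W == 0))
})

test_that("projection equals the explicit pairwise-sum oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    W <- matrix(runif(6 * 8), 6, 8,
                dimnames = list(paste0("D", 1:6), paste0("S", 1:8)))
    W[sample(48, 20)] <- 0
    A <- project_similarity(structure(list(W = W), class = "BipartiteWeights"))$A
    for (a in 1:6) for (b in 1:6) {
      expected <- if (a == b) 0 else sum(W[a, ] * W[b, ])
      expect_equal(A[a, b], expected, tolerance = 1e-12)
    }
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
  }
  expect_error(project_similarity(
    structure(list(W = matrix(1, 1, 3)), class = "BipartiteWeights")),
    "at least 2")
})

test_that("two drugs sharing one weighted term multiply their weights", {
  W <- matrix(c(0.5, 0.4), 2, 1, dimnames = list(c("Da", "Db"), "S1"))
  A <- project_similarity(structure(list(W = W),
                                    class = "BipartiteWeights"))$A
  expect_equal(A["Da", "Db"], 0.2)
  # no shared term: zero similarity
  W2 <- diag(c(0.5, 0.4)); dimnames(W2) <- list(c("Da", "Db"), c("S1", "S2"))
  A2 <- project_similarity(structure(list(W = W2),
                                     class = "BipartiteWeights"))$A
  expect_equal(A2["Da", "Db"], 0)
})

test_that("raising a shared gene's DE score never lowers similarity", {
  inst <- random_instance(5, 6, 30, seed = 13)
  A0 <- project_similarity(build_bipartite(inst$cat, inst$sets, inst$de))$A
  for (g in sample(names(inst$de), 5)) {
    de2 <- inst$de
    de2[g] <- de2[g] + 5
    A1 <- project_similarity(build_bipartite(inst$cat, inst$sets, de2))$A
    expect_true(all(A1 - A0 >= -1e-12))
  }
})

test_that("scaling all DE scores by c scales similarities by c^2", {
  inst <- random_instance(5, 6, 30, seed = 17)
  A1 <- project_similarity(build_bipartite(inst$cat, inst$sets, inst$de))$A
  A3 <- project_similarity(build_bipartite(inst$cat, inst$sets,
                                           3 * inst$de))$A
  expect_equal(A3, 9 * A1, tolerance = 1e-12)
})
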