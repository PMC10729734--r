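test_that("empirical p-values equal naive counting, including boundaries", {
  set.seed(8)
  for (rep in 1:5) {
    B <- 40; n <- 7
    null <- matrix(runif(B * n), B, n,
                   dimnames = list(NULL, paste0("D", 1:n)))
    v <- setNames(runif(n), colnames(null))
    p <- empirical_pvalues(v, null)
    naive <- sapply(seq_len(n), function(i)
      sum(null[, i] >= v[i]) / B)
    expect_equal(unname(p), naive)
  }
  null <- matrix(c(rep(0.5, 10)), 10, 1, dimnames = list(NULL, "Da"))
  expect_equal(unname(empirical_pvalues(c(Da = 0.9), null)), 0)   # all below
  expect_equal(unname(empirical_pvalues(c(Da = 0.5), null)), 1)   # all tied
  expect_equal(unname(empirical_pvalues(c(Da = 0.9), null,
                                        pseudocount = TRUE)), 1 / 11)
  expect_error(empirical_pvalues(c(Dx = 0.5), null), "Dx")
})

test_that("BH adjustment matches the step-up oracle on random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH output never decreases when an input p decreases", {
  set.seed(4)
  for (i in 1:50) {
    p <- runif(10)
    j <- sample(10, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_true(all(bh_fdr(p2) <= bh_fdr(p) + 1e-12))
  }
})

test_that("bootstrap null is seed-deterministic and constant pools are no-ops", {
  inst <- random_instance(6, 10, 50, seed = 12)
  n1 <- bootstrap_null(inst$cat, inst$sets, inst$de, B = 5, seed = 7)
  n2 <- bootstrap_null(inst$cat, inst$sets, inst$de, B = 5, seed = 7)
  expect_identical(n1, n2)
  n3 <- bootstrap_null(inst$cat, inst$sets, inst$de, B = 5, seed = 8)
  expect_false(identical(n1, n3))
  expect_error(bootstrap_null(inst$cat, inst$sets, inst$de, B = 0, seed = 1),
               ">= 1")
  # every replicate row is a probability vector (or all-zero if isolated)
  rs <- rowSums(n1)
  expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
  # constant DE pool: resampling cannot change anything, every replicate
  # equals the observed centrality vector
  const_de <- setNames(rep(2, length(inst$de)), names(inst$de))
  obs <- random_walk_restart(column_normalize(project_similarity(
    build_bipartite(inst$cat, inst$sets, const_de))))
  nc <- bootstrap_null(inst$cat, inst$sets, const_de, B = 3, seed = 1)
  for (k in 1:3)
    expect_equal(nc[k, names(obs$v)], obs$v, tolerance = 1e-12)
})

test_that("rank_drugs ranks by centrality with drug_id tie-break and strict FDR cutoff", {
  v <- setNames(c(0.4, 0.1, 0.4, 0.3), c("Db", "Dd", "Da", "Dc"))
  p <- setNames(c(0.01, 0.5, 0.02, 0.1), names(v))
  fdr <- setNames(c(0.04, 0.5, 0.1, 0.2), names(v))
  tab <- rank_drugs(v, p, fdr, threshold = 0.1)
  expect_equal(tab$drug_id, c("Da", "Db", "Dc", "Dd"))
  expect_equal(tab$rank, 1:4)
  # fdr exactly at the threshold is NOT a candidate
  expect_equal(tab$candidate, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(rank_drugs(v, p[1:2], fdr), "p-values")
})
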