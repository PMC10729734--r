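test_that("zscore_normalize standardizes rows and zeroes constant rows", {
  ds <- tiny_dataset(6)
  ds$values[3, ] <- 5                       # constant row
  out <- zscore_normalize(ds)
  expect_equal(unname(rowMeans(out$values)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(out$values[-3, ], 1, sd)), rep(1, 5),
               tolerance = 1e-12)
  expect_equal(unname(out$values[3, ]), rep(0, 6))
  # idempotent up to floating tolerance
  expect_equal(zscore_normalize(out)$values, out$values, tolerance = 1e-12)
  # explicit row (1,2,3)
  r <- zscore_normalize(expression_dataset(
    matrix(c(1, 2, 3, 4, 0, 1, 0, 1), nrow = 2, byrow = TRUE,
           dimnames = list(c("a", "b"), paste0("s", 1:4))),
    c("case", "case", "control", "control")))
  expect_equal(unname(r$values["a", ]),
               (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)))
})

test_that("vectorized t-test matches stats::t.test for Welch and pooled", {
  ds <- tiny_dataset(30, 5, 7, seed = 9)
  case <- ds$group == "case"
  for (ve in c(FALSE, TRUE)) {
    de <- compute_de_scores(ds, var_equal = ve)
    ref <- apply(ds$values, 1, function(row)
      t.test(row[case], row[!case], var.equal = ve)$p.value)
    expect_equal(de$p, unname(ref), tolerance = 1e-12)
  }
})

test_that("DE score is |inverse-normal of 1 - p| with clamping", {
  # frozen quantile values: qnorm(0.95) and qnorm(0.5)
  de <- data.frame(p = c(0.5, 0.05, 0.95))
  z <- qnorm(1 - de$p)
  expect_equal(z[1], 0)
  expect_equal(abs(z[2]), 1.6448536269514722, tolerance = 1e-12)
  # through the pipeline: a gene identical in both groups has p = 1 and a
  # finite DE score after clamping
  x <- tiny_matrix(3, 4, 4, seed = 5)
  x[2, ] <- rep(c(1, 2, 3, 4), 2)
  ds <- expression_dataset(x, rep(c("case", "control"), each = 4))
  prof <- compute_de_scores(ds)
  expect_true(all(is.finite(prof$de_score)))
  expect_equal(prof$p[2], 1)
  expect_equal(prof$de_score, abs(prof$z))
  expect_true(all(prof$de_score >= 0))
  # symmetric variant halves the tail
  sym <- compute_de_scores(ds, symmetric = TRUE)
  expect_equal(sym$z, qnorm(pmin(pmax(prof$p, 1e-300), 1 - 1e-16) / 2,
                            lower.tail = FALSE))
})

test_that("DE score is monotone in p on both sides of 0.5", {
  p <- c(1e-8, 1e-4, 0.01, 0.2, 0.5)
  z <- abs(qnorm(1 - p))
  expect_true(all(diff(z) < 0))             # decreasing towards 0.5
  p_hi <- c(0.5, 0.8, 0.99, 0.9999)
  expect_true(all(diff(abs(qnorm(1 - p_hi))) > 0))  # increasing beyond 0.5
})

test_that("DE scores are invariant to sample order", {
  ds <- tiny_dataset(20, 6, 6, seed = 21)
  perm <- sample(ncol(ds$values))
  ds2 <- expression_dataset(ds$values[, perm],
                            as.character(ds$group)[perm])
  expect_equal(compute_de_scores(ds)$de_score,
               compute_de_scores(ds2)$de_score, tolerance = 1e-12)
})

test_that("shifted genes recover higher DE scores than null genes", {
  set.seed(1)
  gaps <- sapply(c(0, 1, 2, 3), function(delta) {
    mean(replicate(20, {
      x <- matrix(rnorm(100 * 40), 100,
                  dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:40)))
      x[1:20, 1:20] <- x[1:20, 1:20] + delta
      ds <- expression_dataset(x, rep(c("case", "control"), each = 20))
      de <- compute_de_scores(ds)
      mean(de$de_score[1:20]) - mean(de$de_score[21:100])
    }))
  })
  expect_equal(gaps[1], 0, tolerance = 0.3)      # no shift, no gap
  expect_true(all(diff(gaps) > 0))               # gap grows with effect
  expect_gt(gaps[3], 1)                          # clear at delta = 2 sd
})
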