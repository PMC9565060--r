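test_that("min-max normalization follows the direction conventions", {
  expect_equal(normalize_column(c(2, 4, 6), "positive"), c(0, 0.5, 1))
  expect_equal(normalize_column(c(2, 4, 6), "negative"), c(1, 0.5, 0))
  expect_equal(normalize_column(c(7, 7, 7), "positive"), c(1, 1, 1))
  ## bidirectional columns fold around the ideal-band center (27.5 for C16)
  X <- matrix(3, nrow = 3, ncol = 22,
              dimnames = list(NULL, indicator_ids(SYS)))
  X[, "C4"] <- c(1, 3, 5)
  X[, "C16"] <- c(27.5, 17.5, 47.5)   # distances 0, 10, 20 from the center
  R <- normalize_matrix(X, SYS)
  expect_equal(unname(R[, "C16"]), c(1, 0.5, 0))
  expect_equal(unname(R[, "C4"]), c(0, 0.5, 1))  # categorical: higher better
})

test_that("shifted-proportion entropy matches hand-computed values", {
  ## constant normalized column: uniform proportions, maximal entropy
  ev <- entropy_values(cbind(a = c(1, 1, 1), b = c(0, 0.5, 1)))
  expect_equal(unname(ev$entropy["a"]), 1, tolerance = 1e-12)
  expect_equal(colSums(ev$proportions), c(a = 1, b = 1), tolerance = 1e-12)
  ## n = 2, column (0, 1): f = (1/3, 2/3)
  ev <- entropy_values(cbind(x = c(0, 1)))
  expect_equal(unname(ev$proportions[, "x"]), c(1, 2) / 3)
  expect_equal(unname(ev$entropy["x"]), 0.9182958, tolerance = 1e-6)
  ## n = 5, column (1,1,1,1,0): f = (2,2,2,2,1)/9
  ev <- entropy_values(cbind(y = c(1, 1, 1, 1, 0)))
  expect_equal(unname(ev$proportions[, "y"]), c(2, 2, 2, 2, 1) / 9)
  expect_equal(unname(ev$entropy["y"]), 0.9823882, tolerance = 1e-6)
  expect_error(entropy_values(matrix(0.5, 1, 3)), "fewer than 2")
})

test_that("entropy weights follow the 1 - H' formula", {
  expect_equal(entropy_weights(c(1, 0.5)), c(0, 1))
  expect_equal(entropy_weights(c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(entropy_weights(c(1, 1)), "constant")
  set.seed(3)
  H <- runif(22, 0.2, 0.99)
  w <- entropy_weights(H)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
})

test_that("identical ecological-flow values give that indicator zero weight", {
  ## emulates a river meeting its ecological flow in every segment: the C2
  ## column is constant, carries no information, and must weigh exactly 0
  sc <- make_scenario(SYS, seed = 5, placement = "midpoint")
  expect_true(all(sc$values[, "C2"] == sc$values[1, "C2"]))
  ent <- entropy_weighting(sc$values, SYS)
  expect_identical(unname(ent$weights["C2"]), 0)
  expect_equal(sum(ent$weights), 1, tolerance = 1e-12)
})

test_that("entropy weights are scale- and direction-invariant", {
  set.seed(17)
  ids <- indicator_ids(SYS)
  for (k in 1:10) {
    X <- matrix(runif(5 * 22, 1, 9), 5, 22, dimnames = list(NULL, ids))
    base <- entropy_weighting(X, SYS)$weights
    expect_equal(sum(base), 1, tolerance = 1e-12)
    ## positive affine rescale of one column changes nothing
    X2 <- X
    X2[, "C6"] <- 3.7 * X2[, "C6"] + 11
    expect_equal(entropy_weighting(X2, SYS)$weights, base,
                 tolerance = 1e-10)
    ## negating a positive column and flagging it negative is a no-op
    pos <- X[, "C6"]
    expect_equal(normalize_column(-pos, "negative"),
                 normalize_column(pos, "positive"), tolerance = 1e-12)
  }
})

test_that("contracting a column toward its mean never lowers the entropy", {
  ## r2 = a*r + (1-a)*mean(r) mixes the proportion vector toward uniform,
  ## which majorizes downward, so H' must not decrease (Schur concavity)
  set.seed(23)
  for (k in 1:20) {
    r <- runif(5)
    H1 <- unname(entropy_values(cbind(r))$entropy)
    for (a in c(0.75, 0.5, 0.25, 0)) {
      r2 <- a * r + (1 - a) * mean(r)
      H2 <- unname(entropy_values(cbind(r2))$entropy)
      expect_gte(H2 + 1e-12, H1)
    }
  }
})

test_that("data matrix validation catches structural problems", {
  ids <- indicator_ids(SYS)
  X <- matrix(3, 2, 22, dimnames = list(NULL, ids))
  Xm <- X[, -5]
  expect_error(normalize_matrix(Xm, SYS), "missing indicators")
  Xn <- X; Xn[1, 2] <- NA
  expect_error(normalize_matrix(Xn, SYS), "missing cells")
  Xu <- cbind(X, C99 = 1)
  expect_error(normalize_matrix(Xu, SYS), "unknown indicators")
})
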