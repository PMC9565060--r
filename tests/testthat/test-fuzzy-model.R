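test_that("Cauchy parameters follow the interval geometry", {
  c11 <- SYS$indicators$C11
  p4 <- cauchy_params(c11, "IV")            # (80, 90]: interior
  expect_equal(p4$branches[[1]]$a1, 85)
  expect_equal(p4$branches[[1]]$a2, 0.04)
  expect_identical(p4$branches[[1]]$saturate, "none")
  p5 <- cauchy_params(c11, "V")             # (90, 100]: worst pole at 100
  expect_equal(p5$branches[[1]]$a1, 100)
  expect_equal(p5$branches[[1]]$a2, 0.04)
  expect_identical(p5$branches[[1]]$saturate, "above")
  p1 <- cauchy_params(SYS$indicators$C2, "I")  # [98, 100]: ideal pole at 100
  expect_equal(p1$branches[[1]]$a1, 100)
  expect_equal(p1$branches[[1]]$a2, 1)
  expect_identical(p1$branches[[1]]$saturate, "above")
  ## unbounded extreme grade borrows the adjacent width (C6 I, width 2.5)
  p6 <- cauchy_params(SYS$indicators$C6, "I")
  expect_equal(p6$branches[[1]]$a1, 10)
  expect_equal(p6$branches[[1]]$a2, 4 / 2.5^2)
  ## single-point extreme grade (C9 V = {0}) borrows from IV (width 1)
  p9 <- cauchy_params(SYS$indicators$C9, "V")
  expect_equal(p9$branches[[1]]$a1, 0)
  expect_equal(p9$branches[[1]]$a2, 4)
  expect_identical(p9$branches[[1]]$saturate, "below")
  ## bidirectional: grade V has a pole branch on each side
  p16 <- cauchy_params(SYS$indicators$C16, "V")
  expect_equal(vapply(p16$branches, `[[`, numeric(1), "a1"), c(0, 100))
  expect_identical(vapply(p16$branches, `[[`, character(1), "saturate"),
                   c("below", "above"))
})

test_that("membership values match direct Cauchy evaluation", {
  c11 <- SYS$indicators$C11
  expect_equal(unname(membership_vector(85, c11)["IV"]), 1)
  m80 <- membership_vector(80, c11)         # III/IV shared boundary
  expect_equal(unname(m80[c("III", "IV")]), c(0.5, 0.5), tolerance = 1e-12)
  m <- membership_vector(81.2, c11)
  expect_equal(unname(m["IV"]), 1 / (1 + 0.04 * 3.8^2), tolerance = 1e-12)
  expect_equal(unname(m["IV"]), 0.6339, tolerance = 1e-4)
  expect_equal(unname(m["III"]), 0.4436, tolerance = 1e-4)
  expect_identical(names(which.max(m)), "IV")
  ## saturation beyond the pole of an unbounded grade
  expect_equal(unname(membership_vector(500, SYS$indicators$C6)["I"]), 1)
})

test_that("affiliation matrices stack per-indicator memberships", {
  ids <- indicator_ids(SYS)
  ## all values at grade-III placements: every row peaks at III
  planted <- matrix("III", 1, 22, dimnames = list(NULL, ids))
  v <- generate_values(planted, SYS, placement = "midpoint")[1, ]
  R <- build_affiliation(v, SYS)
  expect_equal(dim(R), c(22, 5))
  expect_true(all(R > 0 & R <= 1))
  expect_true(all(apply(R, 1, which.max) == 3))
  expect_error(build_affiliation(v[-3], SYS), "missing values")
  ## one boundary value gives exactly one 0.5/0.5 adjacent tie
  v["C11"] <- 80
  R <- build_affiliation(v, SYS)
  expect_equal(unname(R["C11", c("III", "IV")]), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("composition is the weighted matrix product with worse-grade ties", {
  R <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  colnames(R) <- ALL_GRADES
  ## one-hot weights pick out a row
  ev <- fuzzy_compose(c(0, 1), R)
  expect_equal(unname(ev$memberships), c(0, 1, 0, 0, 0))
  expect_identical(ev$grade, "II")
  ## exact tie resolves to the worse grade
  ev <- fuzzy_compose(c(0.5, 0.5), R)
  expect_equal(unname(ev$memberships), c(0.5, 0.5, 0, 0, 0))
  expect_identical(ev$grade, "II")
  ## random W, R against an elementwise loop oracle
  set.seed(31)
  for (k in 1:20) {
    n <- sample(2:10, 1)
    W <- runif(n); W <- W / sum(W)
    R <- matrix(runif(n * 5, 0.01, 1), n, 5,
                dimnames = list(NULL, ALL_GRADES))
    D <- numeric(5)
    for (g in 1:5) for (i in 1:n) D[g] <- D[g] + W[i] * R[i, g]
    expect_equal(unname(fuzzy_compose(W, R)$memberships), D,
                 tolerance = 1e-12)
    ## max-min operator oracle
    Dmm <- vapply(1:5, function(g) max(pmin(W, R[, g])), numeric(1))
    expect_equal(unname(fuzzy_compose(W, R, operator = "max_min")$memberships),
                 Dmm, tolerance = 1e-12)
  }
  expect_error(fuzzy_compose(c(0.5, 0.5), matrix(1, 3, 5)), "match")
})

test_that("composition is linear in the affiliation matrix", {
  set.seed(37)
  W <- runif(6); W <- W / sum(W)
  R1 <- matrix(runif(30), 6, 5); R2 <- matrix(runif(30), 6, 5)
  for (alpha in c(0, 0.3, 0.7, 1)) {
    lhs <- fuzzy_compose(W, alpha * R1 + (1 - alpha) * R2)$memberships
    rhs <- alpha * fuzzy_compose(W, R1)$memberships +
      (1 - alpha) * fuzzy_compose(W, R2)$memberships
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("grade assignment is invariant to positive rescaling", {
  set.seed(41)
  for (k in 1:10) {
    D <- runif(5); names(D) <- ALL_GRADES
    g1 <- ALL_GRADES[max(which(D == max(D)))]
    D2 <- D * runif(1, 0.1, 10)
    expect_identical(ALL_GRADES[max(which(D2 == max(D2)))], g1)
  }
})

test_that("layer-wise evaluation composes criteria and target coherently", {
  ids <- indicator_ids(SYS)
  fused <- fuse_weights(REF_AHP, REF_ENT)
  ## all indicators at grade-II placements: grade II at all three layers
  planted <- matrix("II", 1, 22, dimnames = list(NULL, ids))
  v <- generate_values(planted, SYS, placement = "midpoint")[1, ]
  ev <- evaluate_layers(v, fused, SYS)
  expect_true(all(ev$indicator$grade == "II"))
  expect_true(all(vapply(ev$criterion, `[[`, character(1), "grade") == "II"))
  expect_identical(ev$target$grade, "II")
  ## excellent A1-A3, poor A4: the economic criterion grades V but its
  ## weight (~0.2) cannot drag the target below good
  planted <- matrix("I", 1, 22, dimnames = list(NULL, ids))
  planted[, SYS$hierarchy$criteria$A4$indicators] <- "V"
  v <- generate_values(planted, SYS, placement = "midpoint")[1, ]
  ev <- evaluate_layers(v, fused, SYS)
  expect_identical(ev$criterion$A4$grade, "V")
  expect_true(ev$target$grade %in% c("I", "II"))
})

test_that("fuzzy argmax agrees with crisp classification at interior midpoints", {
  for (spec in SYS$indicators) {
    if (spec$direction == "categorical") next
    for (g in c("II", "III", "IV"))
      for (iv in spec$grades[[g]]) {
        x <- (iv$lower + iv$upper) / 2
        expect_identical(fuzzy_grade(x, spec), g,
                         label = paste(spec$id, g))
        expect_identical(classify_crisp(x, spec), g)
      }
  }
})
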