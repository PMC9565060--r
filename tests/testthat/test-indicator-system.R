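test_that("packaged system defines the full hierarchy", {
  expect_length(SYS$hierarchy$criteria, 4)
  expect_length(SYS$hierarchy$subcriteria, 12)
  expect_length(SYS$indicators, 22)
  expect_identical(indicator_ids(SYS), paste0("C", 1:22))
  expect_identical(criterion_ids(SYS), paste0("A", 1:4))
  ## every indicator has exactly one sub-criterion and matching criterion
  for (spec in SYS$indicators) {
    sub <- SYS$hierarchy$subcriteria[[spec$subcriterion]]
    expect_identical(sub$criterion, spec$criterion)
    expect_true(spec$id %in% sub$indicators)
  }
})

test_that("special indicator forms load as specified", {
  c16 <- SYS$indicators$C16
  expect_identical(c16$direction, "bidirectional")
  expect_length(c16$grades$I, 1)
  expect_length(c16$grades$II, 2)
  b <- c16$grades$II
  expect_equal(c(b[[1]]$lower, b[[1]]$upper), c(20, 25))
  expect_equal(c(b[[2]]$lower, b[[2]]$upper), c(30, 40))
  expect_equal(c(c16$grades$I[[1]]$lower, c16$grades$I[[1]]$upper), c(25, 30))

  c4 <- SYS$indicators$C4
  expect_identical(c4$direction, "categorical")
  expect_equal(vapply(ALL_GRADES, function(g) c4$grades[[g]][[1]]$lower,
                      numeric(1)),
               c(I = 5, II = 4, III = 3, IV = 2, V = 1))

  ## inverted printed notation is normalized to an ascending interval
  c18_ii <- SYS$indicators$C18$grades$II[[1]]
  expect_equal(c(c18_ii$lower, c18_ii$upper), c(12, 15))
  expect_false(c18_ii$lower_closed)
  expect_true(c18_ii$upper_closed)
})

test_that("interval parser handles all notations", {
  iv <- parse_interval("(0.2, 0.4]")
  expect_equal(c(iv$lower, iv$upper), c(0.2, 0.4))
  expect_false(iv$lower_closed); expect_true(iv$upper_closed)
  iv <- parse_interval("> 0.8")
  expect_equal(iv$lower, 0.8); expect_true(is.infinite(iv$upper))
  expect_false(iv$lower_closed)
  iv <- parse_interval(">= 5")
  expect_true(iv$lower_closed)
  iv <- parse_interval("0")
  expect_equal(c(iv$lower, iv$upper), c(0, 0))
  expect_true(iv$lower_closed && iv$upper_closed)
  iv <- parse_interval("(15, 12]")   # reversed printing
  expect_equal(c(iv$lower, iv$upper), c(12, 15))
  expect_error(parse_interval("nonsense"), "cannot parse")
})

test_that("crisp classification matches the grade ladder", {
  expect_identical(classify_crisp(2.72, SYS$indicators$C6), "IV")
  expect_identical(classify_crisp(0, SYS$indicators$C9), "V")
  expect_identical(classify_crisp(81.2, SYS$indicators$C11), "IV")
  expect_identical(classify_crisp(99, SYS$indicators$C2), "I")
  expect_identical(classify_crisp(35, SYS$indicators$C16), "II")
  expect_identical(classify_crisp(3, SYS$indicators$C4), "III")
  ## beyond the outermost finite boundary: unbounded extreme grade
  expect_identical(classify_crisp(1e6, SYS$indicators$C12), "V")
  expect_identical(classify_crisp(250, SYS$indicators$C6), "I")
  ## bounded ladder: out-of-domain raises
  expect_error(classify_crisp(101, SYS$indicators$C11), "outside")
  expect_error(classify_crisp(3.5, SYS$indicators$C4), "outside")
})

test_that("every interior point classifies to its own grade (round trip)", {
  for (spec in SYS$indicators)
    for (g in ALL_GRADES)
      for (iv in spec$grades[[g]]) {
        x <- if (is.infinite(iv$upper)) iv$lower + 1
             else if (is.infinite(iv$lower)) iv$upper - 1
             else (iv$lower + iv$upper) / 2
        expect_identical(classify_crisp(x, spec), g,
                         label = paste(spec$id, g))
      }
})

test_that("load-time validation names the offending indicator", {
  ## overlap: C7 grade III widened into grade IV's range
  p <- corrupt_system_yaml(function(cfg) {
    cfg$indicators[[7]]$grades$III <- "(0.5, 2]"
    cfg
  })
  expect_error(load_system(p), "C7.*overlap")
  ## gap between adjacent grades
  p <- corrupt_system_yaml(function(cfg) {
    cfg$indicators[[7]]$grades$III <- "(1.5, 2]"
    cfg
  })
  expect_error(load_system(p), "C7.*gap")
  ## missing indicator definition
  p <- corrupt_system_yaml(function(cfg) {
    cfg$indicators[[22]] <- NULL
    cfg
  })
  expect_error(load_system(p), "C22")
  ## dangling parent reference
  p <- corrupt_system_yaml(function(cfg) {
    cfg$indicators[[1]]$subcriterion <- "B99"
    cfg
  })
  expect_error(load_system(p), "C1")
})
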