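test_that("complete separation gives U = 0 and exact p = 2/C(6,3)", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@statistic, 0)
  expect_true(r@exact)
  expect_equal(r@pValue, 2 / choose(6, 3))
})

test_that("U matches brute-force pair counting, with ties", {
  set.seed(12)
  for (i in 1:50) {
    case <- sample(0:8, sample(2:6, 1), TRUE)
    control <- sample(0:8, sample(2:6, 1), TRUE)
    r <- suppressWarnings(mannWhitneyU(case, control))
    expect_equal(r@statistic, bruteForceU(case, control))
  }
})

test_that("exact MWU p equals full enumeration on small integer samples", {
  set.seed(2024)
  for (i in 1:200) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:(8 - n1), 1)
    case <- sample(1:6, n1, TRUE)
    control <- sample(1:6, n2, TRUE)
    if (length(unique(c(case, control))) == 1L) next
    for (side in c("two_sided", "greater", "less")) {
      got <- mannWhitneyU(case, control, side)@pValue
      expect_equal(got, bruteForceMWUp(case, control, side),
                   info = sprintf("case=%s control=%s %s",
                                  paste(case, collapse = ","),
                                  paste(control, collapse = ","), side))
    }
  }
})

test_that("exact MWU agrees with wilcox.test when there are no ties", {
  set.seed(8)
  for (i in 1:25) {
    case <- runif(sample(3:6, 1))
    control <- runif(sample(3:6, 1))
    got <- mannWhitneyU(case, control)
    ref <- wilcox.test(case, control, exact = TRUE)
    expect_equal(got@statistic, unname(ref$statistic))
    expect_equal(got@pValue, ref$p.value)
  }
})

test_that("large-sample MWU uses the corrected normal approximation", {
  set.seed(15)
  case <- round(rnorm(25, 1), 1)
  control <- round(rnorm(30), 1)
  got <- mannWhitneyU(case, control)
  ref <- wilcox.test(case, control, exact = FALSE, correct = TRUE)
  expect_false(got@exact)
  expect_equal(got@pValue, ref$p.value, tolerance = 1e-10)
})

test_that("identical constant samples yield p = 1 with a warning", {
  expect_warning(r <- mannWhitneyU(rep(2, 3), rep(2, 4)), "identical")
  expect_equal(r@pValue, 1)
})

test_that("permutation test enumerates small splits exactly", {
  r <- permutationTest(c(3, 4), c(1, 2))
  expect_true(r@exact)
  expect_equal(r@observedDifference, 2)
  expect_equal(r@sidedness, "greater")
  expect_equal(r@pValue, 1 / 6)
  expect_equal(r@nPermutations, 6)
  # swapped labels: same magnitude, direction flips, p identical
  r2 <- permutationTest(c(1, 2), c(3, 4))
  expect_equal(r2@sidedness, "less")
  expect_equal(r2@pValue, 1 / 6)
  expect_equal(r2@observedDifference, -2)
})

test_that("identical multisets give a large permutation p", {
  r <- permutationTest(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r@pValue, 1)
  expect_equal(r@detail, "degenerate: zero observed difference")
  expect_equal(r@sidedness, "two_sided")
})

test_that("exact permutation p is invariant under adding a constant", {
  set.seed(5)
  for (i in 1:20) {
    case <- rnorm(4); control <- rnorm(5)
    a <- permutationTest(case, control)
    b <- permutationTest(case + 17.3, control + 17.3)
    expect_equal(a@pValue, b@pValue)
    expect_equal(a@pTwoSided, b@pTwoSided)
    expect_gt(a@pValue, 0)   # observed arrangement always counted
  }
})

test_that("Monte-Carlo permutation path is seeded and reproducible", {
  set.seed(3)
  case <- rnorm(12); control <- rnorm(12)   # C(24,12) > 20000 -> MC
  a <- permutationTest(case, control, nPermutations = 2000L, seed = 7L)
  b <- permutationTest(case, control, nPermutations = 2000L, seed = 7L)
  expect_false(a@exact)
  expect_equal(a@nPermutations, 2001)
  expect_identical(a@pValue, b@pValue)
  expect_error(permutationTest(case, control, seed = NULL), "seed")
})

test_that("permutation and MWU agree on clearly separated samples", {
  set.seed(41)
  for (i in 1:10) {
    case <- rnorm(6, 10); control <- rnorm(6, 0)
    pm <- permutationTest(case, control)@pValue
    mw <- mannWhitneyU(case, control)@pValue
    expect_lt(pm, 0.05); expect_lt(mw, 0.05)
  }
})

test_that("t-test switches to Welch only when variances differ", {
  r <- tTestAuto(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r@statistic, 0)
  expect_equal(r@pValue, 1)
  # Welch statistic matches the Satterthwaite closed form by hand
  case <- c(1, 2, 3, 4, 100)
  control <- c(10, 10.1, 9.9, 10.05, 9.95)
  r <- tTestAuto(case, control)
  expect_equal(r@method, "t_welch")
  m1 <- mean(case); m2 <- mean(control)
  se <- sqrt(var(case) / 5 + var(control) / 5)
  expect_equal(r@statistic, (m1 - m2) / se)
  df <- se^4 / ((var(case) / 5)^2 / 4 + (var(control) / 5)^2 / 4)
  expect_equal(r@pValue, 2 * pt(abs(r@statistic), df, lower.tail = FALSE))
})

test_that("the F gate keeps the pooled branch for equal variances", {
  set.seed(19)
  chosen <- vapply(1:400, function(i) {
    tTestAuto(rnorm(8), rnorm(8))@method
  }, character(1))
  # the gate fires at its nominal 5% level
  expect_gte(mean(chosen == "t_student"), 0.90)
})

test_that("variance comparison: F ratio and Levene match hand computation", {
  r <- varianceCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r@statistic, 1)
  expect_equal(r@pValue, 1)
  case <- c(2, 4, 9, 1); control <- c(5, 6, 5.5, 5.2)
  rf <- varianceCompare(case, control, "F")
  expect_equal(rf@statistic, var(case) / var(control))
  # Levene (median-centered) is a one-way ANOVA on |x - median|
  rl <- varianceCompare(case, control, "levene")
  z <- c(abs(case - median(case)), abs(control - median(control)))
  g <- factor(rep(1:2, each = 4))
  ref <- anova(lm(z ~ g))
  expect_equal(rl@statistic, ref$`F value`[1])
  expect_equal(rl@pValue, ref$`Pr(>F)`[1])
})

test_that("significance stars follow the ns > 0.05 convention", {
  expect_equal(significanceStars(c(0.2, 0.051, 0.049, 0.009, 0.0009, 5e-5)),
               c("ns", "ns", "*", "**", "***", "****"))
})
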