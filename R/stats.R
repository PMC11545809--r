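# Case-vs-control battery: Mann-Whitney U (exact enumeration for small
# samples, midrank ties; normal approximation with tie and continuity
# correction otherwise), mean-difference permutation test with the
# sign-of-observed-difference sidedness rule, variance-gated t-test, and
# variance comparison (F / Levene).

# U statistic of `case` against `control` from pooled midranks
uStatistic <- function(case, control) {
  n1 <- length(case)
  r <- rank(c(case, control))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Tests whether one sample tends to have larger values than the other. U is
#' computed from pooled midranks (so U = number of (case > control) pairs plus
#' half the ties). For pooled sample sizes n1 + n2 <= 12 the null distribution
#' is enumerated exactly over all \code{choose(n1 + n2, n1)} label splits
#' (ties handled by enumeration); larger samples use the normal approximation
#' with tie correction and a 0.5 continuity correction.
#'
#' @param case,control numeric vectors, both nonempty
#' @param sidedness \code{"two_sided"} (default), \code{"greater"} (case
#'   tends larger) or \code{"less"}
#' @return A [TestResult-class] with \code{statistic} = U(case).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # exact two-sided p = 0.1
#' @export
mannWhitneyU <- function(case, control,
                         sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(case) >= 1L, length(control) >= 1L)
  n1 <- length(case); n2 <- length(control); n <- n1 + n2
  u <- uStatistic(case, control)
  pooled <- c(case, control)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(newTestResult("mann_whitney_u", u, 1, sidedness, n1, n2,
                         pTwoSided = 1, exact = TRUE,
                         detail = "degenerate: constant data"))
  }
  if (n <= 12L) {
    splits <- utils::combn(n, n1)
    r <- rank(pooled)
    uNull <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    pGe <- mean(uNull >= u - 1e-9)
    pLe <- mean(uNull <= u + 1e-9)
    p <- switch(sidedness,
                greater = pGe, less = pLe,
                two_sided = min(1, 2 * min(pGe, pLe)))
    p2 <- min(1, 2 * min(pGe, pLe))
    return(newTestResult("mann_whitney_u", u, p, sidedness, n1, n2,
                         pTwoSided = p2, nPermutations = ncol(splits),
                         exact = TRUE))
  }
  # normal approximation, tie correction + continuity correction
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm))
  zG <- (u - mu - 0.5) / sigma
  zL <- (u - mu + 0.5) / sigma
  pGe <- stats::pnorm(zG, lower.tail = FALSE)
  pLe <- stats::pnorm(zL)
  p <- switch(sidedness,
              greater = pGe, less = pLe,
              two_sided = min(1, 2 * min(pGe, pLe)))
  newTestResult("mann_whitney_u", u, p, sidedness, n1, n2,
                pTwoSided = min(1, 2 * min(pGe, pLe)), exact = FALSE,
                detail = "normal approximation, tie + continuity correction")
}

#' Mean-difference permutation test
#'
#' Statistic: \code{mean(case) - mean(control)}. Group labels are permuted;
#' the p-value is the proportion of label arrangements whose difference is at
#' least as extreme as observed, counting the observed arrangement in both
#' numerator and denominator (so p >= 1/N). All \code{choose(n, n1)}
#' arrangements are enumerated when that count is at most \code{exactCutoff};
#' otherwise \code{nPermutations} Monte-Carlo draws are used (seeded).
#'
#' Sidedness follows the rule used in the source analyses: the alternative's
#' direction is set by the sign of the observed difference (positive = case
#' greater). That choice is anti-conservative, so the two-sided p
#' (\code{P(|diff| >= |observed|)}) is always reported alongside in
#' \code{pTwoSided}; a zero observed difference degenerates to the two-sided
#' convention with p = 1.
#'
#' @param case,control numeric vectors, both nonempty
#' @param nPermutations Monte-Carlo permutations when enumeration is off
#'   (default 10000)
#' @param seed integer seed, mandatory for the Monte-Carlo path
#' @param exactCutoff max arrangements for exact enumeration (default 20000)
#' @return A [TestResult-class]; \code{statistic} and
#'   \code{observedDifference} hold the observed mean difference.
#' @examples
#' permutationTest(c(3, 4), c(1, 2))   # exact one-sided p = 1/6
#' @export
permutationTest <- function(case, control, nPermutations = 10000L,
                            seed = NULL, exactCutoff = 20000) {
  stopifnot(length(case) >= 1L, length(control) >= 1L)
  n1 <- length(case); n2 <- length(control); n <- n1 + n2
  pooled <- c(case, control)
  obs <- mean(case) - mean(control)
  tol <- 1e-9 * max(1, abs(obs))
  exact <- choose(n, n1) <= exactCutoff
  if (exact) {
    splits <- utils::combn(n, n1)
    tot <- sum(pooled)
    mCase <- colSums(matrix(pooled[splits], nrow = n1)) / n1
    diffs <- mCase - (tot - mCase * n1) / n2
    nArr <- ncol(splits)
    usedSeed <- NA_real_
  } else {
    if (is.null(seed)) stop("seed is required for Monte-Carlo permutations")
    diffs <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(nPermutations), function(i) {
        idx <- sample.int(n, n1)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1))
    })
    diffs <- c(obs, diffs)   # include the observed arrangement
    nArr <- nPermutations + 1L
    usedSeed <- as.numeric(seed)
  }
  pTwo <- mean(abs(diffs) >= abs(obs) - tol)
  if (obs == 0) {
    return(newTestResult("permutation", obs, 1, "two_sided", n1, n2,
                         pTwoSided = pTwo, nPermutations = nArr,
                         exact = exact, observedDifference = obs,
                         seed = usedSeed,
                         detail = "degenerate: zero observed difference"))
  }
  if (obs > 0) {
    p1 <- mean(diffs >= obs - tol)
    side <- "greater"
  } else {
    p1 <- mean(diffs <= obs + tol)
    side <- "less"
  }
  newTestResult("permutation", obs, p1, side, n1, n2, pTwoSided = pTwo,
                nPermutations = nArr, exact = exact,
                observedDifference = obs, seed = usedSeed)
}

#' Variance-gated two-sample t-test
#'
#' Unpaired Student t-test with pooled variance, unless an F-test of variance
#' equality is significant at \code{alpha}, in which case Welch's t-test
#' (Satterthwaite degrees of freedom) is used. The chosen branch is recorded
#' in \code{detail}.
#'
#' @param case,control numeric vectors with n >= 2 each
#' @param alpha significance level of the variance gate (default 0.05)
#' @return A [TestResult-class] (\code{method} "t_student" or "t_welch").
#' @export
tTestAuto <- function(case, control, alpha = 0.05) {
  stopifnot(length(case) >= 2L, length(control) >= 2L)
  v1 <- stats::var(case); v2 <- stats::var(control)
  if (v1 == 0 && v2 == 0) {
    if (mean(case) == mean(control))
      return(newTestResult("t_student", 0, 1, "two_sided", length(case),
                           length(control), pTwoSided = 1,
                           detail = "degenerate: zero variance, equal means"))
    stop("zero variance in both groups with unequal means")
  }
  fp <- stats::var.test(case, control)$p.value
  welch <- is.finite(fp) && fp < alpha
  tt <- stats::t.test(case, control, var.equal = !welch)
  newTestResult(if (welch) "t_welch" else "t_student",
                unname(tt$statistic), tt$p.value, "two_sided",
                length(case), length(control), pTwoSided = tt$p.value,
                detail = sprintf("variance F-test p = %.4g -> %s", fp,
                                 if (welch) "Welch" else "pooled"))
}

#' Variance comparison between case and control
#'
#' Either the F ratio of sample variances (\code{statistic} =
#' var(case)/var(control); two-sided p from the F distribution, via
#' \code{stats::var.test}) or the Brown-Forsythe/Levene test: a one-way ANOVA
#' on absolute deviations from each group's median.
#'
#' @param case,control numeric vectors with n >= 2 each
#' @param method \code{"F"} (default) or \code{"levene"}
#' @return A [TestResult-class].
#' @export
varianceCompare <- function(case, control, method = c("F", "levene")) {
  method <- match.arg(method)
  stopifnot(length(case) >= 2L, length(control) >= 2L)
  if (stats::var(case) == 0 && stats::var(control) == 0) {
    return(newTestResult(paste0("var_", method), 1, 1, "two_sided",
                         length(case), length(control), pTwoSided = 1,
                         detail = "degenerate: zero variance in both groups"))
  }
  if (method == "F") {
    ft <- stats::var.test(case, control)
    return(newTestResult("var_F", unname(ft$statistic), ft$p.value,
                         "two_sided", length(case), length(control),
                         pTwoSided = ft$p.value,
                         detail = "F = var(case)/var(control)"))
  }
  z <- c(abs(case - stats::median(case)), abs(control - stats::median(control)))
  g <- factor(rep(c("case", "control"), c(length(case), length(control))))
  an <- stats::anova(stats::lm(z ~ g))
  newTestResult("var_levene", an$`F value`[1L], an$`Pr(>F)`[1L], "two_sided",
                length(case), length(control), pTwoSided = an$`Pr(>F)`[1L],
                detail = "Brown-Forsythe: ANOVA on |x - median|")
}

#' Significance stars
#'
#' Star convention used in the figures: ns for p > 0.05, then *, **, ***,
#' **** at 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p numeric vector of p-values
#' @return character vector
#' @export
significanceStars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", "ns")))
}
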