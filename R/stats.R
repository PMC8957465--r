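# Tail probabilities from first principles. The t and F distribution tails
# both reduce to the regularized incomplete beta function I_x(a, b), which is
# evaluated with the standard continued-fraction expansion (modified Lentz
# algorithm) after the usual symmetry switch for fast convergence.

# log Beta(a, b)
lbeta_ab <- function(a, b) lgamma(a) + lgamma(b) - lgamma(a + b)

betacf <- function(x, a, b, tol = 1e-12, maxit = 500L) {
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c_ <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < 1e-30) d <- 1e-30
  d <- 1 / d
  h <- d
  for (m in seq_len(maxit)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
    c_ <- 1 + aa / c_; if (abs(c_) < 1e-30) c_ <- 1e-30
    d <- 1 / d
    h <- h * d * c_
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
    c_ <- 1 + aa / c_; if (abs(c_) < 1e-30) c_ <- 1e-30
    d <- 1 / d
    del <- d * c_
    h <- h * del
    if (abs(del - 1) < tol) return(h)
  }
  warning("incomplete beta continued fraction did not fully converge",
          call. = FALSE)
  h
}

#' Regularized incomplete beta function
#'
#' `I_x(a, b)`, computed by continued fraction with relative tolerance
#' 1e-12; the backbone of every p-value in the package (t and F tails both
#' reduce to it), so no external statistics routine is involved.
#'
#' @param x in `[0, 1]`.
#' @param a,b positive shape parameters.
#' @return `I_x(a, b)` in `[0, 1]`.
#' @export
inc_beta <- function(x, a, b) {
  if (length(x) > 1L) return(vapply(x, inc_beta, numeric(1), a = a, b = b))
  if (is.na(x)) return(NA_real_)
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  front <- exp(a * log(x) + b * log1p(-x) - lbeta_ab(a, b))
  if (x < (a + 1) / (a + b + 2)) {
    front * betacf(x, a, b) / a
  } else {
    1 - exp(b * log1p(-x) + a * log(x) - lbeta_ab(a, b)) *
      betacf(1 - x, b, a) / b
  }
}

# two-sided p for a t statistic with df degrees of freedom:
# P(|T| >= |t|) = I_{df/(df + t^2)}(df/2, 1/2)
t_p_two_sided <- function(t, df) inc_beta(df / (df + t^2), df / 2, 0.5)

# upper tail of F(d1, d2): P(F >= f) = I_{d2/(d2 + d1 f)}(d2/2, d1/2)
f_p_upper <- function(f, d1, d2) inc_beta(d2 / (d2 + d1 * f), d2 / 2, d1 / 2)

# upper tail of chi-square(df) via F limit: chi2/df ~ F(df, inf) would need
# the gamma; use the series/CF through the incomplete gamma instead.
# P(X >= x) for X ~ chi-square(1) equals 2 * (1 - Phi(sqrt(x))); for general
# df it is Q(df/2, x/2), the regularized upper incomplete gamma.
gamma_q <- function(s, x, tol = 1e-12, maxit = 1000L) {
  if (x < 0) return(1)
  if (x == 0) return(1)
  if (x < s + 1) {
    # lower series P(s, x), return 1 - P
    term <- 1 / s
    sum <- term
    for (n in seq_len(maxit)) {
      term <- term * x / (s + n)
      sum <- sum + term
      if (abs(term) < abs(sum) * tol) break
    }
    1 - sum * exp(-x + s * log(x) - lgamma(s))
  } else {
    # continued fraction for Q(s, x) (Lentz)
    b <- x + 1 - s
    c_ <- 1e300
    d <- 1 / b
    h <- d
    for (i in seq_len(maxit)) {
      an <- -i * (i - s)
      b <- b + 2
      d <- an * d + b; if (abs(d) < 1e-30) d <- 1e-30
      c_ <- b + an / c_; if (abs(c_) < 1e-30) c_ <- 1e-30
      d <- 1 / d
      del <- d * c_
      h <- h * del
      if (abs(del - 1) < tol) break
    }
    h * exp(-x + s * log(x) - lgamma(s))
  }
}

chisq_p_upper <- function(x, df) gamma_q(df / 2, x / 2)

new_ha_test <- function(test_name, statistic, df, p_value, n, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, n = n), extra),
            class = "ha_test")
}

#' @export
print.ha_test <- function(x, ...) {
  cat(sprintf("<ha_test> %s: statistic %.4g, df %s, p = %.4g (n = %s)\n",
              x$test_name, x$statistic,
              paste(format(x$df), collapse = ", "), x$p_value,
              paste(x$n, collapse = ", ")))
  if (!is.null(x$table)) {
    cat("  2x2 table:\n")
    print(x$table)
  }
  invisible(x)
}

#' Paired two-sample t-test
#'
#' Pre/post comparison on the same joints: `t = mean(d) / (sd(d) / sqrt(n))`
#' on the differences `d = pre - post`, `df = n - 1`, two-sided p-value from
#' the t distribution via the incomplete beta function.
#'
#' @param pre,post numeric vectors of equal length (n >= 2); pairs with a
#'   missing value are dropped.
#' @return an object of class `ha_test`.
#' @examples
#' paired_t_test(c(10, 12, 14), c(9, 10, 12))  # t = 5, df = 2
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre and post must pair up")
  keep <- !(is.na(pre) | is.na(post))
  d <- pre[keep] - post[keep]
  n <- length(d)
  if (n < 2L) stopf("need at least 2 complete pairs")
  s <- stats::sd(d)
  if (s == 0)
    stopf("degenerate: all differences equal (zero variance)")
  t <- mean(d) / (s / sqrt(n))
  new_ha_test("paired t-test", t, n - 1L, t_p_two_sided(t, n - 1), n)
}

#' One-way (one-factor) analysis of variance
#'
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with the between/within sums of
#' squares; the p-value is the upper F tail via the incomplete beta function.
#'
#' @param groups list of 2 or more numeric vectors, each with 2 or more
#'   values.
#' @return an `ha_test` with a two-element `df`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5, df (1, 4)
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need a list of at least 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stopf("every group needs at least 2 values")
  k <- length(groups); N <- sum(sizes)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) stopf("degenerate: zero within-group variance")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  new_ha_test("one-way ANOVA", f, c(k - 1L, N - k),
              f_p_upper(f, k - 1, N - k), sizes)
}

#' Per-level detection-rate comparison against pathology
#'
#' Compares the proportion of joints a method arm grades at `level` with the
#' proportion pathology assigns to that level, over the same joints. The 2x2
#' table has one row per rater (method, pathology) and columns "graded at
#' level / graded otherwise"; equality of the two detection rates is tested
#' with the df-1 chi-square statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` where `n` counts all `2 * m`
#' gradings (Yates continuity correction available but off by default).
#' Identical raters give a row-symmetric table and a statistic of exactly 0.
#' Joints lacking a grade in either rater are dropped from both.
#'
#' @param method_grades,pathology_grades aligned per-joint integer grades.
#' @param level grade level in 0:3 to compare detection rates at.
#' @param yates logical; apply the continuity correction.
#' @return an `ha_test` carrying the 2x2 `table` (rows = rater, columns =
#'   level yes/no).
#' @examples
#' m <- rep(c(1, 0), c(30, 70)); p <- rep(c(1, 0), c(50, 50))
#' detection_rate_comparison(m, p, level = 1)   # chi-square 8.333
#' @export
detection_rate_comparison <- function(method_grades, pathology_grades, level,
                                      yates = FALSE) {
  if (length(method_grades) != length(pathology_grades))
    stopf("grade vectors must align per joint")
  if (!level %in% 0:3) stopf("level must be one of 0, 1, 2, 3")
  keep <- !(is.na(method_grades) | is.na(pathology_grades))
  m <- sum(keep)
  if (m == 0L) stopf("no jointly graded joints")
  a <- sum(method_grades[keep] == level)       # method at level
  b <- m - a
  c_ <- sum(pathology_grades[keep] == level)   # pathology at level
  d <- m - c_
  tab <- matrix(c(a, c_, b, d), 2L, 2L,
                dimnames = list(rater = c("method", "pathology"),
                                grade = c("level", "other")))
  n <- a + b + c_ + d                          # 2 * m gradings
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    stopf("level %d absent (or universal) in both raters; test undefined",
          level)
  num <- abs(a * d - b * c_)
  if (yates) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  new_ha_test("detection-rate chi-square", stat, 1L,
              chisq_p_upper(stat, 1), m, extra = list(table = tab,
                                                      level = level))
}

#' Per-level agreement summary for one lesion
#'
#' For each score level, the joint counts in the pathology, conventional-MRI
#' and Canny-MRI arms, with the detection-rate chi-square of each MRI arm
#' against pathology.
#'
#' @param cohort a `cohort_table` carrying all three arms.
#' @param lesion lesion name.
#' @param levels grade levels (default 0:3).
#' @param yates passed to [detection_rate_comparison()].
#' @return list of class `agreement_summary`: `counts` data.frame (level,
#'   pathology, conventional, canny), `tests` list (per level, per arm; `NA`
#'   where the test is undefined), `lesion`.
#' @export
agreement_summary <- function(cohort, lesion, levels = 0:3, yates = FALSE) {
  for (arm in arm_names) {
    if (!paste0(lesion, "_", arm) %in% names(cohort))
      stopf("cohort lacks the %s arm for '%s'", arm, lesion)
  }
  path <- cohort[[paste0(lesion, "_pathology")]]
  counts <- data.frame(level = levels)
  for (arm in arm_names) {
    counts[[arm]] <- as.integer(grade_counts(cohort, lesion, arm, levels))
  }
  tests <- lapply(levels, function(l) {
    lapply(c(conventional = "conventional", canny = "canny"), function(arm) {
      tryCatch(detection_rate_comparison(cohort[[paste0(lesion, "_", arm)]],
                                         path, l, yates),
               error = function(e) NA)
    })
  })
  names(tests) <- as.character(levels)
  structure(list(counts = counts, tests = tests, lesion = lesion),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s\n", x$lesion))
  tab <- x$counts
  tab$p_conventional <- vapply(as.character(tab$level), function(l) {
    t <- x$tests[[l]]$conventional
    if (inherits(t, "ha_test")) t$p_value else NA_real_
  }, numeric(1))
  tab$p_canny <- vapply(as.character(tab$level), function(l) {
    t <- x$tests[[l]]$canny
    if (inherits(t, "ha_test")) t$p_value else NA_real_
  }, numeric(1))
  print(tab, row.names = FALSE)
  invisible(x)
}
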