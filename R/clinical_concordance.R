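# Concordance between PDO drug-sensitivity calls and patient outcomes:
# confusion metrics on the 2x2 table, Fisher's exact test, and the one-sided
# Cochran-Armitage trend test over the four ordered response categories.

#' Construct a 2x2 concordance table
#'
#' Cell layout: `a` = OS-PDO patients who responded, `b` = OS-PDO
#' non-responders, `c` = OR-PDO responders, `d` = OR-PDO non-responders.
#'
#' @param a,b,c,d nonnegative cell counts, total > 0.
#' @return A `cohort_2x2` object.
#' @export
cohort_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stopf("the table must contain at least one patient")
  structure(as.list(cells), class = "cohort_2x2")
}

#' Collapse a patient cohort to its 2x2 table
#'
#' @param cohort data frame with columns `pdo_class` (OS/OR) and `outcome`
#'   (responder/non_responder), as produced by [gen_cohort()].
#' @return A [cohort_2x2()].
#' @export
as_cohort_2x2 <- function(cohort) {
  stopifnot(all(c("pdo_class", "outcome") %in% names(cohort)))
  cohort_2x2(
    a = sum(cohort$pdo_class == "OS" & cohort$outcome == "responder"),
    b = sum(cohort$pdo_class == "OS" & cohort$outcome == "non_responder"),
    c = sum(cohort$pdo_class == "OR" & cohort$outcome == "responder"),
    d = sum(cohort$pdo_class == "OR" & cohort$outcome == "non_responder"))
}

#' @export
print.cohort_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("OS PDO", "OR PDO"),
                              c("responder", "non-responder")))
  print(m)
  invisible(x)
}

#' Confusion metrics of PDO-based outcome prediction
#'
#' Treats the OS PDO class as the prediction "patient will respond" and
#' computes, in percent: sensitivity `a/(a+c)`, specificity `d/(b+d)`,
#' positive predictive value `a/(a+b)`, negative predictive value `d/(c+d)`,
#' and accuracy `(a+d)/total`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0. Values
#' are stored at full precision; the print method rounds to 1 decimal.
#'
#' @param t a [cohort_2x2()].
#' @return A `concordance_metrics` list: `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percent), plus `n` (total patients) and
#'   `n_concordant` (`a + d`).
#' @examples
#' confusion_metrics(cohort_2x2(7, 2, 3, 5))
#' @export
confusion_metrics <- function(t) {
  stopifnot(inherits(t, "cohort_2x2"))
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  total <- t$a + t$b + t$c + t$d
  structure(
    list(sensitivity = frac(t$a, t$a + t$c),
         specificity = frac(t$d, t$b + t$d),
         ppv = frac(t$a, t$a + t$b),
         npv = frac(t$d, t$c + t$d),
         accuracy = frac(t$a + t$d, total),
         n = total, n_concordant = t$a + t$d),
    class = "concordance_metrics")
}

#' @export
print.concordance_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf(paste0("<concordance_metrics> n = %d\n",
                     "  sensitivity %s  specificity %s\n",
                     "  PPV %s  NPV %s  accuracy %s (%d/%d)\n"),
              x$n, fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv), fmt(x$accuracy), x$n_concordant, x$n))
  invisible(x)
}

#' Fisher's exact test on the concordance table
#'
#' Two-sided exact test of association between PDO class and patient
#' outcome: the p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one.
#'
#' @param t a [cohort_2x2()].
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(cohort_2x2(7, 2, 3, 5))  # 0.1534
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "cohort_2x2"))
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Cochran-Armitage trend test
#'
#' Tests for a monotone trend in event proportions across ordered
#' categories. With events \eqn{e_i}, sizes \eqn{n_i} and scores \eqn{x_i},
#' the statistic is \eqn{T = \sum e_i x_i} with
#' \eqn{E[T] = \bar p \sum n_i x_i},
#' \eqn{Var(T) = \bar p (1 - \bar p) [\sum n_i x_i^2 - (\sum n_i x_i)^2 / N]}
#' (\eqn{\bar p} the pooled event rate), and
#' \eqn{Z = (T - E[T]) / \sqrt{Var(T)}} is referred to the standard normal.
#' The `N`-denominator variance convention, without continuity correction,
#' is the default; `variance = "N-1"` applies the finite-population
#' correction \eqn{N/(N-1)}. `Z` and the p-value are invariant to affine
#' rescaling of the scores.
#'
#' `method = "permutation"` instead draws `n_permutations` random
#' reassignments of the events to the N units and reports the tail
#' proportion `P(T* <= T)` (for `alternative = "decreasing"`); note the
#' permutation null is discrete, so it brackets rather than matches the
#' asymptotic value.
#'
#' @param events,n events and totals per ordered category (>= 2 categories,
#'   `events <= n`).
#' @param scores numeric scores per category, strictly monotone; default
#'   equally spaced integers `0, 1, 2, ...`.
#' @param alternative `"decreasing"` (event rate falls as the score rises),
#'   `"increasing"`, or `"two.sided"`.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param variance `"N"` (default) or `"N-1"` denominator convention.
#' @param n_permutations,seed Monte-Carlo settings for the permutation
#'   method.
#' @return A `trend_test` list: `statistic` (Z), `p_value`, `T`, `expected`,
#'   `variance`, `alternative`, `method`.
#' @examples
#' cochran_armitage(events = c(3, 2, 1, 1), n = c(4, 4, 5, 4))  # p = 0.047
#' @export
cochran_armitage <- function(events, n, scores = NULL,
                             alternative = c("decreasing", "increasing",
                                             "two.sided"),
                             method = c("asymptotic", "permutation"),
                             variance = c("N", "N-1"),
                             n_permutations = 1e5, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  variance <- match.arg(variance)
  if (length(events) != length(n) || length(n) < 2L)
    stopf("'events' and 'n' must be equal-length vectors with >= 2 categories")
  if (any(events < 0) || any(events > n))
    stopf("each 'events' must satisfy 0 <= events <= n")
  if (is.null(scores)) scores <- seq_along(n) - 1
  if (length(scores) != length(n))
    stopf("'scores' must match the number of categories")
  if (!(all(diff(scores) > 0) || all(diff(scores) < 0)))
    stopf("'scores' must be strictly monotone")

  N <- sum(n); E <- sum(events)
  T_obs <- sum(events * scores)
  pbar <- E / N
  v <- pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  if (variance == "N-1") v <- v * N / (N - 1)
  ET <- pbar * sum(n * scores)
  if (E == 0 || E == N) {
    return(structure(list(statistic = 0, p_value = 1, T = T_obs,
                          expected = ET, variance = v,
                          alternative = alternative, method = method),
                     class = "trend_test"))
  }
  if (v <= 0) stopf("degenerate variance: the trend statistic has no spread")
  Z <- (T_obs - ET) / sqrt(v)

  if (method == "asymptotic") {
    p <- switch(alternative,
                decreasing = pnorm(Z),
                increasing = pnorm(Z, lower.tail = FALSE),
                two.sided = 2 * pnorm(-abs(Z)))
  } else {
    unit_scores <- rep(scores, n)
    Ts <- with_rng(seed, {
      vapply(seq_len(n_permutations),
             function(i) sum(sample(unit_scores, E)), numeric(1))
    })
    p <- switch(alternative,
                decreasing = mean(Ts <= T_obs),
                increasing = mean(Ts >= T_obs),
                two.sided = mean(abs(Ts - ET) >= abs(T_obs - ET)))
  }
  structure(list(statistic = Z, p_value = p, T = T_obs, expected = ET,
                 variance = v, alternative = alternative, method = method),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("<trend_test> Z = %.3f, one-sided (%s) p = %.3g [%s]\n",
              x$statistic, x$alternative, x$p_value, x$method))
  invisible(x)
}

#' Ordered trend table from a categorized cohort
#'
#' Builds the (events, n) table over the four ordered response categories
#' (non, minor, moderate, strong), counting clinical non-response
#' (recurrence) as the event, for use with [cochran_armitage()] with the
#' `"decreasing"` alternative: recurrence is expected to fall as PDO
#' sensitivity rises.
#'
#' @param cohort data frame with columns `category` and `outcome`.
#' @return Data frame with columns `category`, `events`, `n`.
#' @export
build_trend_table <- function(cohort) {
  stopifnot(all(c("category", "outcome") %in% names(cohort)))
  lev <- c("non", "minor", "moderate", "strong")
  cat4 <- factor(cohort$category, levels = lev)
  if (anyNA(cat4)) stopf("'category' must be one of %s",
                         paste(lev, collapse = ", "))
  data.frame(
    category = lev,
    events = as.vector(tapply(cohort$outcome == "non_responder", cat4, sum,
                              default = 0)),
    n = as.vector(table(cat4)))
}
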