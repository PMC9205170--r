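# Four-parameter logistic dose-response analysis.
#
# The viability model is
#   V(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
# with V in percent viability and d in uM; hill > 0 gives a decreasing curve.
# IC50 is the inflection dose, Emax the percent inhibition at the highest
# tested dose, and AUC a normalized area under the curve on the log10 dose
# axis. Fits that never reach 50% inhibition at the top dose are censored at
# the maximum tested concentration, mirroring how screening IC50s are
# conventionally capped.

#' Four-parameter logistic curve
#'
#' @param dose dose(s), uM.
#' @param top,bottom asymptotic viability percent at zero / infinite dose
#'   (`0 <= bottom < top`).
#' @param hill Hill slope (> 0 for a decreasing viability curve).
#' @param ic50 inflection dose, uM.
#' @return Predicted percent viability.
#' @export
fourpl <- function(dose, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a 4PL dose-response curve
#'
#' Least-squares fit of the four-parameter logistic to the replicate-mean
#' viabilities of a plate, with box constraints that stabilize 8-point fits:
#' `0 <= bottom < top <= top_max`, `hill` in `hill_bounds`, `ic50` in
#' `[min(dose)/10, max(dose)*10]`. Derived quantities:
#'
#' * `emax`: percent inhibition at the maximum tested dose,
#'   `100 - mean viability at max dose`, floored at 0;
#' * `auc`: trapezoidal area of `viability / top` (clipped to `[0, 1]`) over
#'   the log10 dose axis rescaled to `[0, 1]`, so curves measured on
#'   different grids are comparable;
#' * censoring: when the curve never reaches 50% inhibition at the top dose
#'   (`emax < 50`) or the optimizer fails, the fit is flagged
#'   `converged = FALSE`, `censored = TRUE` and `ic50` is set to the maximum
#'   tested dose.
#'
#' @param plate a [dose_plate()] with at least 4 distinct doses.
#' @param hill_bounds,top_max box constraints for the optimizer.
#' @return A `dose_response_fit`: list with `pdo_id`, `drug`, `top`,
#'   `bottom`, `hill`, `ic50`, `log10_ic50`, `emax`, `auc`, `converged`,
#'   `censored`.
#' @examples
#' sc <- screen_scenario(data.frame(top = 100, bottom = 5, hill = 1.2,
#'                                  ic50 = 3), noise_sd = 0)
#' fit_4pl(gen_dose_plate(sc, 1))
#' @export
fit_4pl <- function(plate, hill_bounds = c(0.1, 10), top_max = 120) {
  stopifnot(inherits(plate, "dose_plate"))
  doses <- plate$doses
  if (length(unique(doses)) < 4L)
    stopf("insufficient data: at least 4 distinct doses are required")
  means <- rowMeans(plate$viability, na.rm = TRUE)
  if (all(is.na(means)) || !any(is.finite(means)))
    stopf("all viability values are missing")

  emax <- max(0, 100 - means[length(means)])

  top0 <- max(means); bottom0 <- min(means)
  mid <- (top0 + bottom0) / 2
  start <- c(top = top0, bottom = bottom0, hill = 1,
             ic50 = unname(doses[which.min(abs(means - mid))]))
  lower <- c(top = 1e-6, bottom = 0, hill = hill_bounds[1],
             ic50 = min(doses) / 10)
  upper <- c(top = top_max, bottom = top_max, hill = hill_bounds[2],
             ic50 = max(doses) * 10)
  resid_fn <- function(p) means - fourpl(doses, p[1], p[2], p[3], p[4])
  # Levenberg-Marquardt on the residuals directly (robust to exact,
  # zero-residual data), best of a few IC50 starts
  ic50_starts <- unique(c(start[["ic50"]], exp(mean(log(range(doses))))))
  best <- NULL
  for (s in ic50_starts) {
    st <- start; st[["ic50"]] <- s
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best) || !(best$info %in% 1:4)) {
    par <- start
    converged <- FALSE
  } else {
    par <- best$par
    converged <- TRUE
  }
  censored <- FALSE
  if (emax < 50 || !converged) {
    censored <- TRUE
    converged <- FALSE
    par[["ic50"]] <- max(doses)
  }
  if (par[["bottom"]] > par[["top"]])   # degenerate flat fits
    par[c("top", "bottom")] <- par[c("bottom", "top")]

  lx <- log10(doses)
  xs <- (lx - lx[1]) / (lx[length(lx)] - lx[1])
  ys <- pmin(1, pmax(0, means / par[["top"]]))
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)

  structure(
    list(pdo_id = plate$pdo_id, drug = plate$drug,
         top = unname(par[["top"]]), bottom = unname(par[["bottom"]]),
         hill = unname(par[["hill"]]), ic50 = unname(par[["ic50"]]),
         log10_ic50 = log10(unname(par[["ic50"]])),
         emax = unname(emax), auc = auc,
         converged = converged, censored = censored),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> %s / %s\n  IC50 %.4g uM (log10 %.3f)%s  Emax %.1f%%  AUC %.3f\n  top %.1f  bottom %.1f  hill %.2f\n",
    x$pdo_id, x$drug, x$ic50, x$log10_ic50,
    if (x$censored) " [censored]" else "", x$emax, x$auc,
    x$top, x$bottom, x$hill))
  invisible(x)
}

#' Classify drug response from log10 IC50
#'
#' Maps log10 IC50 (uM) to the four response categories and the
#' sensitive/resistant grouping. The five boundaries delimit, on the log10
#' IC50 axis, strong (`[b1, b2)`), moderate (`[b2, b3)`), minor (`[b3, b4)`)
#' and non-responders (`[b4, b5)`). Intervals are half-open on the right;
#' values below the first boundary fall in `strong` and values at or above
#' the fourth in `non`, so shared endpoints are resolved toward the more
#' resistant category. Strong and moderate responders form the sensitive
#' (OS) group; minor and non-responders the resistant (OR) group.
#'
#' @param log10_ic50 numeric vector of log10 IC50 values (uM).
#' @param boundaries five increasing category boundaries; default
#'   `c(0.14, 0.57, 0.98, 1.24, 2.00)`.
#' @return Data frame with columns `log10_ic50`, `category` (factor
#'   strong/moderate/minor/non) and `group` (factor OS/OR).
#' @examples
#' classify_response(c(0.30, 0.80, 1.10, 1.50))
#' @export
classify_response <- function(log10_ic50,
                              boundaries = c(0.14, 0.57, 0.98, 1.24, 2.00)) {
  if (length(boundaries) != 5L)
    stopf("'boundaries' must contain exactly 5 increasing values")
  assert_increasing(boundaries, "boundaries")
  if (length(log10_ic50) < 1L || anyNA(log10_ic50) ||
      !all(is.finite(log10_ic50)))
    stopf("'log10_ic50' must be finite and non-missing")
  lev <- c("strong", "moderate", "minor", "non")
  category <- cut(log10_ic50, breaks = c(-Inf, boundaries[2:4], Inf),
                  labels = lev, right = FALSE)
  group <- factor(ifelse(category %in% c("strong", "moderate"), "OS", "OR"),
                  levels = c("OS", "OR"))
  data.frame(log10_ic50 = log10_ic50, category = category, group = group)
}

#' Invert a fitted 4PL for the ICx dose
#'
#' Returns the dose at which the fitted curve reaches `x` percent inhibition
#' relative to its top plateau, i.e. the dose where viability equals
#' `top * (1 - x/100)`. Used, e.g., to pick a minimum effective dose in the
#' IC10--IC40 range for combination treatments.
#'
#' @param fit a converged [fit_4pl()] result.
#' @param x target percent inhibition, `0 < x < 100`.
#' @return Dose in uM.
#' @examples
#' sc <- screen_scenario(data.frame(top = 100, bottom = 0, hill = 1,
#'                                  ic50 = 3), noise_sd = 0)
#' invert_icx(fit_4pl(gen_dose_plate(sc, 1)), 10)  # 0.3333 uM
#' @export
invert_icx <- function(fit, x) {
  stopifnot(inherits(fit, "dose_response_fit"))
  assert_number(x, "x")
  if (x <= 0 || x >= 100) stopf("'x' must be strictly between 0 and 100")
  if (!fit$converged)
    stopf("cannot invert a censored or non-converged fit")
  v_target <- fit$top * (1 - x / 100)
  if (v_target <= fit$bottom)
    stopf("unattainable effect: %g%% inhibition is below the bottom plateau (max attainable %.1f%%)",
          x, 100 * (1 - fit$bottom / fit$top))
  u <- (fit$top - v_target) / (v_target - fit$bottom)
  fit$ic50 * u^(1 / fit$hill)
}

#' Potency/efficacy shift of a combination over monotherapy
#'
#' Quantifies how a combination treatment shifts the dose-response of the
#' base drug: `relative_ic50 = combo IC50 / mono IC50` (values << 1 mean
#' sensitization), `orders_of_magnitude = -log10(relative_ic50)`, and
#' `delta_emax = combo Emax - mono Emax` in percentage points.
#'
#' @param mono,combo [fit_4pl()] results for the same PDO and base drug.
#' @return List with `relative_ic50`, `orders_of_magnitude`, `delta_emax`,
#'   and `censored_mono` (TRUE, with a warning, when the monotherapy IC50 was
#'   censored and the shift is therefore a lower bound).
#' @export
combination_shift <- function(mono, combo) {
  stopifnot(inherits(mono, "dose_response_fit"),
            inherits(combo, "dose_response_fit"))
  censored_mono <- isTRUE(mono$censored)
  if (censored_mono)
    warning("monotherapy IC50 is censored; the reported shift is a lower bound",
            call. = FALSE)
  rel <- combo$ic50 / mono$ic50
  list(relative_ic50 = rel,
       orders_of_magnitude = -log10(rel),
       delta_emax = combo$emax - mono$emax,
       censored_mono = censored_mono)
}

#' Fit and classify a set of plates
#'
#' Runs [fit_4pl()] and [classify_response()] over a list of plates and
#' assembles the per-PDO fit table.
#'
#' @param plates list of [dose_plate()] objects.
#' @param boundaries passed to [classify_response()].
#' @return Data frame with one row per plate: `pdo_id`, `drug`, `top`,
#'   `bottom`, `hill`, `ic50_uM`, `log10_ic50`, `emax_pct`, `auc`,
#'   `category`, `group`, `censored`.
#' @export
fit_plates <- function(plates, boundaries = c(0.14, 0.57, 0.98, 1.24, 2.00)) {
  fits <- lapply(plates, fit_4pl)
  do.call(rbind, lapply(fits, function(f) {
    cl <- classify_response(f$log10_ic50, boundaries)
    data.frame(pdo_id = f$pdo_id, drug = f$drug, top = f$top,
               bottom = f$bottom, hill = f$hill, ic50_uM = f$ic50,
               log10_ic50 = f$log10_ic50, emax_pct = f$emax, auc = f$auc,
               category = as.character(cl$category),
               group = as.character(cl$group), censored = f$censored)
  }))
}
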