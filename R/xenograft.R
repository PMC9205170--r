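# Xenograft tumor-growth-inhibition scoring.

#' Per-arm per-day median tumor volumes
#'
#' @param course a [tumor_course()].
#' @return Data frame with columns `arm`, `day`, `median_volume_mm3`, `n`
#'   (mice measured). The median of an even mouse count is the midpoint of
#'   the two central values.
#' @export
summarize_arms <- function(course) {
  stopifnot(inherits(course, "tumor_course"))
  x <- as.data.frame(course)
  med <- aggregate(volume_mm3 ~ arm + day, data = x, FUN = median)
  n <- aggregate(volume_mm3 ~ arm + day, data = x, FUN = length)
  out <- data.frame(arm = med$arm, day = med$day,
                    median_volume_mm3 = med$volume_mm3, n = n$volume_mm3)
  out[order(out$arm, out$day), , drop = FALSE]
}

#' Percent tumor growth inhibition (%TGI)
#'
#' Computes the treated-vs-control growth inhibition statistic
#' \deqn{\%TGI = \frac{1 - (T_t/T_0)/(C_t/C_0)}{1 - C_0/C_t} \times 100}
#' where \eqn{T_t, T_0} are the median treated-arm volumes at day `day` and
#' day 0, and \eqn{C_t, C_0} the control-arm medians. Treated stasis
#' (\eqn{T_t = T_0}) gives exactly 100%; equal growth factors in both arms
#' give 0%. A course is called a responder when %TGI is at least
#' `responder_threshold` (default 50%).
#'
#' @param course a [tumor_course()].
#' @param day endpoint day; default is the last day measured in both arms.
#' @param responder_threshold %TGI cutoff for the responder call.
#' @return A `tgi_result`: list with `tgi_pct`, `responder`, `endpoint_day`
#'   and the four medians `T0`, `Tt`, `C0`, `Ct`.
#' @examples
#' sc <- xeno_scenario(noise_cv = 0)
#' compute_tgi(gen_xeno_course(sc))
#' @export
compute_tgi <- function(course, day = NULL, responder_threshold = 50) {
  stopifnot(inherits(course, "tumor_course"))
  x <- as.data.frame(course)
  ctrl <- x[x$arm == "control", ]
  trt <- x[x$arm == "treated", ]
  shared <- intersect(unique(ctrl$day), unique(trt$day))
  if (is.null(day)) day <- max(shared)
  if (!(day %in% ctrl$day) || !(day %in% trt$day))
    stopf("missing timepoint: day %s is not measured in both arms", day)
  med <- function(d, at) median(d$volume_mm3[d$day == at])
  C0 <- med(ctrl, 0); Ct <- med(ctrl, day)
  T0 <- med(trt, 0); Tt <- med(trt, day)
  if (Ct == C0)
    stopf("degenerate control arm: median volume unchanged between day 0 and day %s",
          day)
  tgi <- (1 - (Tt / T0) / (Ct / C0)) / (1 - C0 / Ct) * 100
  structure(
    list(tgi_pct = tgi, responder = tgi >= responder_threshold,
         endpoint_day = day, T0 = T0, Tt = Tt, C0 = C0, Ct = Ct),
    class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("<tgi_result> day %s: %%TGI = %.2f%% (%s)\n",
              x$endpoint_day, x$tgi_pct,
              if (x$responder) "responder" else "non-responder"))
  invisible(x)
}
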