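# Connectivity scoring of up/down query signatures against reference rank
# profiles, in the style of the Connectivity Map's signed Kolmogorov-Smirnov
# statistic: a perturbagen whose profile places the query's up-features at
# its bottom and the down-features at its top "reverses" the query and
# scores strongly negative.

#' Construct a query signature
#'
#' @param up,down disjoint, non-empty sets of feature ids: the features up-
#'   and down-regulated in the phenotype of interest.
#' @return A `query_signature` list.
#' @export
query_signature <- function(up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (!length(up) || !length(down))
    stopf("'up' and 'down' must both be non-empty")
  if (length(intersect(up, down)))
    stopf("'up' and 'down' must be disjoint")
  structure(list(up = up, down = down), class = "query_signature")
}

#' Signed KS enrichment of a tag set in a rank profile
#'
#' Computes the signed maximum deviation between the empirical CDF of the
#' tag positions in the profile and the uniform CDF over all positions:
#' positive when the tags concentrate at the top of the profile, negative at
#' the bottom. Tags occupying the top `t` of `n` ranks score exactly
#' `+(1 - t/n)`; tags at the bottom score the exact mirror `-(1 - t/n)`.
#'
#' @param tag_set non-empty set of feature ids, all present in the profile.
#' @param profile ranked feature vector (most up-regulated first).
#' @return Signed KS statistic in `[-1, 1]`.
#' @export
ks_enrichment <- function(tag_set, profile) {
  tag_set <- unique(as.character(tag_set))
  if (!length(tag_set)) stopf("'tag_set' must be non-empty")
  r <- match(tag_set, profile)
  if (anyNA(r))
    stopf("tag(s) missing from profile: %s",
          paste(tag_set[is.na(r)], collapse = ", "))
  r <- sort(r)
  n <- length(profile); t <- length(r)
  j <- seq_len(t)
  # compare the deviation suprema on the common denominator n*t so that
  # ties and signs are resolved exactly, not at floating-point mercy
  dp_num <- max(0, j * n - r * t)
  dm_num <- max(0, (c(r, n + 1) - 1) * t - (0:t) * n)
  if (dp_num > dm_num) dp_num / (n * t)
  else if (dm_num > dp_num) -dm_num / (n * t)
  else 0
}

#' Connectivity scores of a query against a profile collection
#'
#' For each reference profile, computes the signed KS enrichment of the
#' query's up- and down-sets; when the two enrichments have opposite signs
#' the raw connectivity is `(up - down) / 2`, otherwise 0 (the profile does
#' not coherently match or reverse the query). Raw values are rescaled to
#' `[-100, 100]` by the largest |raw| in the scored collection, mirroring
#' the reporting scale of connectivity tools; a score of -100 marks the
#' strongest reversal in the collection.
#'
#' Query features absent from a profile are dropped with a warning; if more
#' than `1 - min_coverage` of either tag set is missing the profile is not
#' scored (`NA`). Profiles sharing a perturbagen name are treated as
#' replicate instances: the hit reports their mean score, `n_instances` and
#' `score_sd`.
#'
#' @param query a [query_signature()] (or list with `up`, `down`).
#' @param profiles a `reference_profiles` list of ranked feature vectors
#'   (names = perturbagen ids; duplicated names = instances).
#' @param min_coverage minimum retained fraction of each tag set.
#' @return A `connectivity_hits` data frame sorted by ascending score:
#'   `perturbagen`, `score`, `n_instances`, `score_sd`.
#' @export
connectivity_scores <- function(query, profiles, min_coverage = 0.5) {
  if (!inherits(query, "query_signature"))
    query <- query_signature(query$up, query$down)
  if (!length(profiles) || is.null(names(profiles)))
    stopf("'profiles' must be a non-empty named list of ranked feature vectors")
  raw <- vapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    up <- intersect(query$up, prof)
    down <- intersect(query$down, prof)
    n_drop <- (length(query$up) - length(up)) +
      (length(query$down) - length(down))
    if (n_drop > 0)
      warning(sprintf("profile '%s': %d query feature(s) absent and dropped",
                      names(profiles)[i], n_drop), call. = FALSE)
    if (length(up) < min_coverage * length(query$up) ||
        length(down) < min_coverage * length(query$down))
      return(NA_real_)
    a <- ks_enrichment(up, prof)
    b <- ks_enrichment(down, prof)
    if (sign(a) == sign(b)) 0 else (a - b) / 2
  }, numeric(1))
  max_abs <- suppressWarnings(max(abs(raw), na.rm = TRUE))
  score <- if (is.finite(max_abs) && max_abs > 0) 100 * raw / max_abs
           else raw * 0
  out <- do.call(rbind, lapply(split(seq_along(score), names(profiles)),
                               function(idx) {
    s <- score[idx]
    data.frame(perturbagen = names(profiles)[idx[1]],
               score = mean(s),
               n_instances = length(idx),
               score_sd = if (length(idx) > 1) stats::sd(s) else 0)
  }))
  out <- out[order(out$score, out$perturbagen), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("connectivity_hits", "data.frame")
  out
}

#' Intersect candidate perturbagens from two queries
#'
#' Returns the perturbagens whose connectivity score is at or below
#' `threshold` in **both** hit lists — i.e. compounds predicted to reverse
#' both query signatures — sorted by ascending mean score, then id.
#'
#' @param hits_a,hits_b [connectivity_scores()] results.
#' @param threshold selection cutoff in `[-100, 0]`; default -95.
#' @return Data frame: `perturbagen`, `score_a`, `score_b`, `mean_score`.
#' @export
select_candidates <- function(hits_a, hits_b, threshold = -95) {
  assert_number(threshold, "threshold", lower = -100, upper = 0)
  pass_a <- hits_a[!is.na(hits_a$score) & hits_a$score <= threshold, ]
  pass_b <- hits_b[!is.na(hits_b$score) & hits_b$score <= threshold, ]
  ids <- intersect(pass_a$perturbagen, pass_b$perturbagen)
  out <- data.frame(
    perturbagen = ids,
    score_a = pass_a$score[match(ids, pass_a$perturbagen)],
    score_b = pass_b$score[match(ids, pass_b$perturbagen)])
  out$mean_score <- (out$score_a + out$score_b) / 2
  out <- out[order(out$mean_score, out$perturbagen), , drop = FALSE]
  rownames(out) <- NULL
  out
}
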