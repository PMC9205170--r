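# Expression-signature discovery: median-of-ratios normalization, two-group
# differential expression, leave-one-out consensus selection, and
# single-feature logistic-regression predictors scored by LOOCV.

#' Construct a labeled count matrix
#'
#' @param counts nonnegative integer matrix, features x samples, with
#'   dimnames.
#' @param labels per-sample group labels, `"OS"` (sensitive) or `"OR"`
#'   (resistant); both groups need at least 2 samples.
#' @return A `count_matrix`: list with elements `counts` and `labels`
#'   (factor with levels OS, OR).
#' @export
count_matrix <- function(counts, labels) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE) ||
      any(counts != round(counts), na.rm = TRUE))
    stopf("'counts' must be nonnegative integers")
  if (length(labels) != ncol(counts))
    stopf("'labels' must have one entry per sample (%d != %d)",
          length(labels), ncol(counts))
  if (!all(labels %in% c("OS", "OR")))
    stopf("'labels' must be 'OS' or 'OR'")
  labels <- factor(labels, levels = c("OS", "OR"))
  if (any(table(labels) < 2L))
    stopf("both labels must be represented by at least 2 samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("FEAT%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  structure(list(counts = counts, labels = labels), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples (%d OS, %d OR)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$labels == "OS"), sum(x$labels == "OR")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' with positive counts in every sample, of the ratio of the sample's count
#' to the feature's geometric mean across samples. This is the
#' median-of-ratios scheme commonly used to normalize RNA-seq counts for
#' library size and composition.
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @examples
#' size_factors(matrix(c(2, 2, 8, 2), 2,
#'                     dimnames = list(c("f1", "f2"), c("s1", "s2"))))
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf("normalization infeasible: no feature has positive counts in every sample")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub / geo, 2, median)
}

# log2 of size-factor-normalized counts with a pseudocount
normalized_log_expression <- function(x, pseudocount = 1) {
  sf <- size_factors(x)
  log2(sweep(x$counts, 2, sf, `/`) + pseudocount)
}

#' Two-group differential-expression ranking
#'
#' Normalizes by [size_factors()], drops features whose mean normalized
#' count falls below `expression_floor`, and tests each remaining feature
#' for an OR-vs-OS difference with a pooled-variance Wald t statistic on
#' `log2(normalized count + pseudocount)`. P-values are Benjamini-Hochberg
#' adjusted across the tested features.
#'
#' Features with zero pooled variance get `stat = 0, p = 1` when the group
#' means agree and `p = 0` when they differ deterministically.
#'
#' @param x a [count_matrix()].
#' @param expression_floor minimum mean normalized count for a feature to be
#'   tested (default 5).
#' @param pseudocount added before the log2 transform (default 1).
#' @return Data frame with one row per tested feature: `feature_id`,
#'   `base_mean` (mean normalized count), `log2fc` (OR minus OS on the log2
#'   scale), `stat`, `p_value`, `adj_p`.
#' @seealso [top_features()], [loocv_consensus()]
#' @export
de_rank <- function(x, expression_floor = 5, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(table(x$labels) < 2L))
    stopf("each group needs at least 2 samples")
  sf <- size_factors(x)
  norm <- sweep(x$counts, 2, sf, `/`)
  keep <- rowMeans(norm) >= expression_floor
  if (!any(keep)) stopf("no feature passes the expression floor")
  lg <- log2(norm[keep, , drop = FALSE] + pseudocount)
  a <- x$labels == "OR"; b <- x$labels == "OS"
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(lg[, a, drop = FALSE])
  mb <- rowMeans(lg[, b, drop = FALSE])
  va <- apply(lg[, a, drop = FALSE], 1, var)
  vb <- apply(lg[, b, drop = FALSE], 1, var)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  lfc <- ma - mb
  se <- sqrt(sp * (1 / na + 1 / nb))
  stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- ifelse(is.finite(stat), 2 * pt(-abs(stat), df = na + nb - 2),
              0)
  p[stat == 0] <- 1
  data.frame(feature_id = rownames(lg),
             base_mean = rowMeans(norm[keep, , drop = FALSE]),
             log2fc = lfc, stat = stat, p_value = p,
             adj_p = p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Top differential features of a DE table
#'
#' Orders features by ascending adjusted p-value (or raw p-value), breaking
#' ties by descending |log2 fold change| and then feature id, and returns the
#' top `k`. By default the ranking is restricted to features passing the
#' differential-expression filter (fold change >= `min_fold_change` and
#' adjusted p < `max_adj_p`), so fewer than `k` features may be returned;
#' set `filter_significant = FALSE` to rank all tested features.
#'
#' @param de a [de_rank()] table.
#' @param k number of features to return.
#' @param filter_significant apply the DE filter before ranking?
#' @param min_fold_change,max_adj_p DE filter thresholds (fold change on the
#'   natural scale; `min_fold_change = 2` keeps `|log2fc| >= 1`).
#' @param rank_by `"adj_p"` (default) or `"p_value"`.
#' @return Character vector of feature ids, at most `k` long.
#' @export
top_features <- function(de, k = 100, filter_significant = TRUE,
                         min_fold_change = 2, max_adj_p = 0.05,
                         rank_by = c("adj_p", "p_value")) {
  rank_by <- match.arg(rank_by)
  if (filter_significant)
    de <- de[abs(de$log2fc) >= log2(min_fold_change) &
               de$adj_p < max_adj_p, , drop = FALSE]
  ord <- order(de[[rank_by]], -abs(de$log2fc), de$feature_id)
  head(de$feature_id[ord], k)
}

#' Leave-one-out consensus signature
#'
#' Implements leave-one-out consensus feature selection: for each of the
#' `n` samples, drop that sample, rerun [de_rank()] on the remaining `n - 1`,
#' and take the top `k` differential features; the consensus signature is
#' the set of features present in every fold's list. Because each pair of
#' folds shares all but two samples, only features whose differential signal
#' is robust to any single sample survive the intersection.
#'
#' @param x a [count_matrix()] with at least 4 samples; dropping any sample
#'   must leave both groups with >= 2 members.
#' @param k per-fold list size.
#' @param ... passed to [de_rank()] and [top_features()]
#'   (`expression_floor`, `filter_significant`, `min_fold_change`,
#'   `max_adj_p`, `rank_by`).
#' @return A `consensus_signature`: list with `fold_top` (named list of
#'   per-fold feature vectors, keyed by the left-out sample), `consensus`
#'   (sorted feature ids present in all folds), `k` and `n_folds`.
#' @export
loocv_consensus <- function(x, k = 100, ...) {
  stopifnot(inherits(x, "count_matrix"))
  n <- ncol(x$counts)
  if (n < 4L) stopf("at least 4 samples are required")
  dots <- list(...)
  de_args <- dots[names(dots) %in% c("expression_floor", "pseudocount")]
  top_args <- dots[names(dots) %in%
                     c("filter_significant", "min_fold_change", "max_adj_p",
                       "rank_by")]
  fold_top <- lapply(seq_len(n), function(i) {
    lab <- x$labels[-i]
    if (any(table(lab) < 2L))
      stopf("dropping sample '%s' leaves group '%s' with fewer than 2 samples",
            colnames(x$counts)[i], setdiff(levels(lab), lab[table(lab) >= 2]))
    sub <- count_matrix(x$counts[, -i, drop = FALSE], lab)
    de <- do.call(de_rank, c(list(sub), de_args))
    do.call(top_features, c(list(de, k = k), top_args))
  })
  names(fold_top) <- colnames(x$counts)
  consensus <- sort(Reduce(intersect, fold_top))
  structure(list(fold_top = fold_top, consensus = consensus, k = k,
                 n_folds = n),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("<consensus_signature> %d folds, top-%d lists; consensus: %d features\n",
              x$n_folds, x$k, length(x$consensus)))
  invisible(x)
}

# Ridge-penalized logistic regression by BFGS on the penalized deviance.
# The mild default penalty keeps coefficients finite under complete
# separation, which is the expected regime for perfect predictors.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 500) {
  X <- cbind(1, as.matrix(X))
  log1pexp <- function(e) ifelse(e > 30, e, log1p(exp(e)))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1pexp(eta)) + lambda / 2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    g <- -drop(crossprod(X, y - plogis(eta)))
    g[-1] <- g[-1] + lambda * b[-1]
    g
  }
  fit <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  fit$par
}

#' Single-feature logistic-regression predictor search
#'
#' For each candidate feature, fits a one-feature logistic regression of the
#' OR/OS label on the log2 normalized expression (with a mild ridge penalty
#' so completely separating features keep finite coefficients) and scores it
#' by leave-one-out cross-validated classification accuracy. A feature whose
#' held-out predictions are correct in every fold scores 1.0.
#'
#' @param x a [count_matrix()].
#' @param candidates feature ids to evaluate (e.g. a consensus signature).
#' @param lambda ridge penalty (default `1e-4`).
#' @param pseudocount for the log2 transform.
#' @return Data frame sorted by decreasing `loocv_score`, then feature id:
#'   `feature_id`, `intercept`, `coefficient` (full-data fit), `loocv_score`.
#'   Constant features are skipped with a warning.
#' @export
single_feature_lr_search <- function(x, candidates, lambda = 1e-4,
                                     pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  miss <- setdiff(candidates, rownames(x$counts))
  if (length(miss))
    stopf("unknown candidate feature(s): %s", paste(miss, collapse = ", "))
  expr <- normalized_log_expression(x, pseudocount)
  y <- as.integer(x$labels == "OR")
  n <- length(y)
  rows <- lapply(candidates, function(f) {
    v <- expr[f, ]
    if (var(x$counts[f, ]) == 0 || var(v) < 1e-12) {
      warning(sprintf("feature '%s' is constant; model skipped", f),
              call. = FALSE)
      return(NULL)
    }
    correct <- vapply(seq_len(n), function(i) {
      b <- ridge_logistic(v[-i], y[-i], lambda)
      pred <- plogis(b[1] + b[2] * v[i]) > 0.5
      as.integer(pred == (y[i] == 1L))
    }, integer(1))
    b_full <- ridge_logistic(v, y, lambda)
    data.frame(feature_id = f, intercept = b_full[1], coefficient = b_full[2],
               loocv_score = mean(correct))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(feature_id = character(), intercept = numeric(),
                      coefficient = numeric(), loocv_score = numeric()))
  out[order(-out$loocv_score, out$feature_id), , drop = FALSE]
}

#' LOOCV accuracy of a panel of classifiers
#'
#' Validates a feature signature by leave-one-out cross-validation with a
#' panel of standard classifiers on the log2 normalized expression
#' sub-matrix: logistic regression (mild ridge), random forest, k-nearest
#' neighbors, naive Bayes, decision tree, a single-hidden-layer neural
#' network, and a support vector machine. Features that are constant within
#' a training fold are dropped there; if none remain, the fold predicts the
#' training-set majority class.
#'
#' @param x a [count_matrix()].
#' @param features non-empty feature id vector.
#' @param classifiers subset of `c("logistic", "random_forest", "knn",
#'   "naive_bayes", "decision_tree", "neural_net", "svm")`.
#' @param seed seed for the stochastic learners (random forest, neural net),
#'   so the panel is reproducible.
#' @param knn_k neighbors for the k-NN classifier.
#' @return Data frame with columns `classifier` and `loocv_accuracy`.
#' @export
classifier_panel <- function(x, features,
                             classifiers = c("logistic", "random_forest",
                                             "knn", "naive_bayes",
                                             "decision_tree", "neural_net",
                                             "svm"),
                             seed = 1L, knn_k = 3L) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(features) < 1L) stopf("'features' must be non-empty")
  known <- c("logistic", "random_forest", "knn", "naive_bayes",
             "decision_tree", "neural_net", "svm")
  bad <- setdiff(classifiers, known)
  if (length(bad))
    stopf("unknown classifier: %s", paste(bad, collapse = ", "))
  miss <- setdiff(features, rownames(x$counts))
  if (length(miss))
    stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  expr <- t(normalized_log_expression(x)[features, , drop = FALSE])
  y <- x$labels
  n <- nrow(expr)
  acc <- with_rng(seed, vapply(classifiers, function(cl) {
    correct <- vapply(seq_len(n), function(i) {
      Xtr <- expr[-i, , drop = FALSE]; ytr <- droplevels(y[-i])
      keep <- apply(Xtr, 2, var) > 1e-12
      if (!any(keep) || nlevels(ytr) < 2L) {
        tab <- table(ytr)
        pred <- names(tab)[which.max(tab)]
      } else {
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- expr[i, keep, drop = FALSE]
        pred <- predict_one(cl, Xtr, ytr, Xte, knn_k)
      }
      as.integer(pred == as.character(y[i]))
    }, integer(1))
    mean(correct)
  }, numeric(1)))
  data.frame(classifier = classifiers, loocv_accuracy = unname(acc))
}

# train on (Xtr, ytr), predict the single row Xte; returns a label string
predict_one <- function(classifier, Xtr, ytr, Xte, knn_k) {
  dtr <- data.frame(Xtr, check.names = FALSE)
  dte <- data.frame(Xte, check.names = FALSE)
  switch(
    classifier,
    logistic = {
      b <- ridge_logistic(Xtr, as.integer(ytr == "OR"), lambda = 1e-4)
      if (plogis(b[1] + sum(b[-1] * as.numeric(Xte))) > 0.5) "OR" else "OS"
    },
    random_forest = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 200)
      as.character(predict(fit, Xte))
    },
    knn = {
      k <- min(knn_k, nrow(Xtr))
      as.character(class::knn(Xtr, Xte, ytr, k = k))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      as.character(predict(fit, dte))
    },
    decision_tree = {
      dtr$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(minsplit = 2,
                                                         cp = 1e-3))
      as.character(predict(fit, dte, type = "class"))
    },
    neural_net = {
      # standardize and take the best of a few random restarts: a single
      # small nnet on few samples regularly sticks in a poor local optimum
      mu <- colMeans(Xtr); sd <- apply(Xtr, 2, stats::sd)
      dtr <- data.frame(scale(Xtr, mu, sd), check.names = FALSE)
      dte <- data.frame(scale(Xte, mu, sd), check.names = FALSE)
      dtr$.y <- ytr
      fits <- lapply(1:5, function(r)
        nnet::nnet(.y ~ ., data = dtr, size = 2, decay = 1e-2,
                   maxit = 300, trace = FALSE))
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      as.character(predict(fit, dte, type = "class"))
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", scale = FALSE)
      as.character(predict(fit, Xte))
    })
}
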