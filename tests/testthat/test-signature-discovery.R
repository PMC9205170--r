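test_that("size factors implement median-of-ratios exactly", {
  # identical samples -> unit factors
  m <- matrix(rep(c(5L, 10L, 20L), 3), 3,
              dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))

  # hand enumeration: counts [[2,8],[2,2]] -> geomeans (4,2),
  # ratios s1 (0.5,1) s2 (2,1) -> medians (0.75, 1.5)
  m2 <- matrix(c(2, 2, 8, 2), 2, dimnames = list(c("f1", "f2"),
                                                 c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(0.75, 1.5))

  # scale equivariance: multiplying one sample by 10 multiplies its factor
  # tenfold relative to every other sample (the geometric-mean reference
  # shifts by the common factor 10^(1/n), so only factor ratios are
  # identified)
  x <- gen_counts(count_scenario(n_features = 200, seed = 12))
  sf1 <- size_factors(x)
  cnt <- x$counts; cnt[, 3] <- cnt[, 3] * 10L
  sf2 <- size_factors(count_matrix(cnt, x$labels))
  expect_equal(unname(sf2[3] / sf2[1]), unname(10 * sf1[3] / sf1[1]),
               tolerance = 1e-12)
  expect_equal(unname(sf2[-3] / sf2[1]), unname(sf1[-3] / sf1[1]),
               tolerance = 1e-12)

  # equal library sizes, no differential signal -> factors within [0.9, 1.1]
  x_eq <- gen_counts(count_scenario(n_features = 500,
                                    size_factor_range = c(1, 1 + 1e-9),
                                    seed = 14))
  expect_true(all(abs(size_factors(x_eq) - 1) <= 0.1))

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)),
               "infeasible")
})

test_that("size factors agree with the reference median-of-ratios scheme", {
  # odd feature count: the sample median is a single ratio, so the plain
  # and log-scale median-of-ratios definitions coincide exactly
  x <- gen_counts(count_scenario(n_features = 501, seed = 13))
  expect_equal(unname(size_factors(x)),
               unname(DESeq2::estimateSizeFactorsForMatrix(x$counts)),
               tolerance = 1e-12)
})

test_that("differential ranking behaves on null, planted and tied input", {
  x <- planted_counts(n_planted = 5, n_features = 300, log2fc = 3, seed = 2,
                      dispersion = 0.05)
  de <- de_rank(x)

  # planted features pass the fold-change >= 2 and adjusted p < 0.05 filter
  planted <- rownames(x$counts)[1:5]
  sub <- de[de$feature_id %in% planted, ]
  expect_true(all(abs(sub$log2fc) >= 1 & sub$adj_p < 0.05))
  expect_equal(sign(sub$log2fc), rep(c(1, -1), length.out = 5))

  # adjusted p never drops below raw p and stays in [0, 1]
  expect_true(all(de$adj_p >= de$p_value - 1e-12))
  expect_true(all(de$adj_p >= 0 & de$adj_p <= 1))

  # features with identical normalized values in both groups score
  # log2fc 0, p 1 (equal libraries so normalization leaves them identical)
  cnt <- matrix(rep(c(50L, 20L, 80L, 10L), 8), 4,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:8)))
  de2 <- de_rank(count_matrix(cnt, rep(c("OS", "OR"), each = 4)))
  expect_equal(de2$log2fc, rep(0, 4))
  expect_equal(de2$p_value, rep(1, 4))
  expect_equal(de2$stat, rep(0, 4))

  # BH adjustment matches the step-up enumeration oracle
  expect_equal(de$adj_p, bh_oracle(de$p_value), tolerance = 1e-12)
  p_seq <- seq(0.01, 0.10, by = 0.01)
  expect_equal(p.adjust(p_seq, "BH"), bh_oracle(p_seq), tolerance = 1e-12)

  expect_error(de_rank(count_matrix(x$counts[, 1:5],
                                    c("OS", "OS", "OS", "OR", "OR"))),
               NA)  # 3v2 still has >= 2 per group
})

test_that("null p-values are not anti-conservative", {
  x <- gen_counts(count_scenario(n_features = 2000, seed = 17))
  de <- de_rank(x)
  expect_lte(mean(de$p_value < 0.05), 0.07)
})

test_that("leave-one-out consensus intersects per-fold top lists", {
  x <- planted_counts(n_planted = 20, n_features = 2000, log2fc = 3, seed = 1)
  cons <- loocv_consensus(x, k = 100)
  planted <- rownames(x$counts)[1:20]

  expect_identical(cons$n_folds, 16L)
  expect_identical(length(cons$fold_top), 16L)
  # the consensus is contained in every fold list
  for (fold in cons$fold_top)
    expect_true(all(cons$consensus %in% fold))
  # strongly planted features survive every fold
  expect_gte(sum(planted %in% cons$consensus), 18)
  expect_lte(sum(!cons$consensus %in% planted), 5)

  # determinism of the whole pipeline step
  cons2 <- loocv_consensus(planted_counts(20, 2000, 3, seed = 1), k = 100)
  expect_identical(cons2$fold_top, cons$fold_top)
  expect_identical(cons2$consensus, cons$consensus)

  # with the significance filter disabled, every fold has exactly k features
  cons_all <- loocv_consensus(x, k = 100, filter_significant = FALSE)
  expect_true(all(lengths(cons_all$fold_top) == 100L))

  # dropping a sample must not empty a group
  tiny <- count_matrix(x$counts[, c(1, 2, 9, 10)],
                       c("OS", "OS", "OR", "OR"))
  expect_error(loocv_consensus(tiny, k = 10), "fewer than 2")
})

test_that("the consensus shrinks (weakly) as folds accumulate", {
  x <- planted_counts(n_planted = 10, n_features = 500, log2fc = 2, seed = 5,
                      dispersion = 0.3)
  cons <- loocv_consensus(x, k = 50, filter_significant = FALSE)
  sizes <- vapply(seq_len(cons$n_folds), function(m)
    length(Reduce(intersect, cons$fold_top[seq_len(m)])), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_identical(sizes[cons$n_folds], length(cons$consensus))
})

test_that("single-feature logistic models score separation by LOOCV", {
  x <- planted_counts(n_planted = 6, n_features = 400, log2fc = 4, seed = 3,
                      dispersion = 0.05)
  planted <- rownames(x$counts)[1:6]
  res <- single_feature_lr_search(x, planted)
  # widely separated planted features classify perfectly in every fold
  expect_equal(res$loocv_score, rep(1, 6))
  expect_identical(nrow(res), 6L)
  # coefficient sign follows the planted direction (OR vs OS)
  signs <- sign(res$coefficient[match(planted, res$feature_id)])
  expect_equal(signs, rep(c(1, -1), length.out = 6))

  # constant feature is skipped with a warning (equal libraries keep the
  # planted constant row constant after normalization)
  xc0 <- planted_counts(n_planted = 2, n_features = 100, log2fc = 4,
                        seed = 6, size_factor_range = c(1, 1 + 1e-9))
  cnt <- xc0$counts; cnt[7, ] <- 30L
  xc <- count_matrix(cnt, xc0$labels)
  expect_warning(res2 <- single_feature_lr_search(xc, rownames(cnt)[c(1, 7)]),
                 "constant")
  expect_identical(nrow(res2), 1L)

  expect_error(single_feature_lr_search(x, "NOPE"), "unknown candidate")
})

test_that("label-independent features have no predictive LOOCV score", {
  # Monte-Carlo null over 200 independent features: leave-one-out accuracy
  # of a 1-feature model on noise concentrates at or below chance (LOOCV
  # with balanced classes is pessimistic at the null, so the mean sits
  # below 0.5 rather than at it)
  x <- gen_counts(count_scenario(n_features = 200, seed = 21))
  res <- single_feature_lr_search(x, rownames(x$counts))
  expect_lt(mean(res$loocv_score), 0.55)
  expect_gt(mean(res$loocv_score), 0.15)
  expect_lt(max(res$loocv_score), 1)
})

test_that("the classifier panel validates a separable signature", {
  x <- planted_counts(n_planted = 10, n_features = 50, log2fc = 3, seed = 3)
  feats <- rownames(x$counts)[1:10]
  panel <- classifier_panel(x, feats, seed = 1)
  expect_identical(nrow(panel), 7L)
  # perfectly separable synthetic data: every classifier scores 1.0
  expect_equal(panel$loocv_accuracy, rep(1, 7))
  # reproducible under the same panel seed
  expect_identical(classifier_panel(x, feats, seed = 1), panel)

  expect_error(classifier_panel(x, feats, classifiers = "perceptron"),
               "unknown classifier")
  expect_error(classifier_panel(x, character(0)), "non-empty")
})

test_that("permuted labels destroy panel accuracy", {
  x <- gen_counts(count_scenario(n_features = 30, seed = 11))
  feats <- rownames(x$counts)[1:10]
  accs <- vapply(1:3, function(i) {
    xp <- x
    xp$labels <- withr::with_seed(100 + i, sample(x$labels))
    mean(classifier_panel(xp, feats, seed = 1)$loocv_accuracy)
  }, numeric(1))
  # chance-level or below (LOOCV is pessimistic under the null)
  expect_lt(mean(accs), 0.6)
})

test_that("a constant feature falls back to majority-class prediction", {
  cnt <- matrix(5L, 30, 16, dimnames = list(sprintf("f%02d", 1:30),
                                            sprintf("s%02d", 1:16)))
  x <- count_matrix(cnt, rep(c("OS", "OR"), c(10, 6)))
  panel <- classifier_panel(x, "f01", seed = 1)
  expect_equal(panel$loocv_accuracy, rep(10 / 16, 7))
})

test_that("signature files round-trip through the exported formats", {
  x <- planted_counts(n_planted = 6, n_features = 100, log2fc = 3, seed = 4)
  de <- de_rank(x)
  feats <- rownames(x$counts)[1:6]
  dir <- withr::local_tempdir()
  paths <- write_signature_files(de, feats, dir)
  up <- readLines(paths[["up"]]); down <- readLines(paths[["down"]])
  expect_identical(sort(c(up, down)), sort(feats))
  sub <- de[match(up, de$feature_id), ]
  expect_true(all(sub$log2fc > 0))
  rnk <- read.delim(paths[["rnk"]], header = FALSE)
  expect_identical(nrow(rnk), nrow(de))
  expect_true(all(diff(rnk[[2]]) <= 0))
})
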