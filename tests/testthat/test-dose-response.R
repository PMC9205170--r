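test_that("noiseless plates are inverted exactly by the 4PL fit", {
  truths <- data.frame(top = c(100, 95, 110), bottom = c(10, 0, 5),
                       hill = c(1.2, 0.9, 2.5), ic50 = c(3, 0.8, 12))
  sc <- noiseless_screen(truths$top, truths$bottom, truths$hill, truths$ic50)
  for (i in seq_len(nrow(truths))) {
    f <- fit_4pl(gen_dose_plate(sc, i))
    expect_true(f$converged)
    expect_false(f$censored)
    for (p in c("top", "hill", "ic50"))
      expect_lt(abs(f[[p]] / truths[[p]][i] - 1), 1e-4)
    # the bottom plateau can be 0, where relative error is undefined;
    # compare on the percent scale there
    expect_lt(abs(f$bottom - truths$bottom[i]) /
                max(truths$bottom[i], 1), 1e-4)
  }
})

test_that("flat and shallow curves are censored at the top dose", {
  # constant 100% viability: no effect at all
  plate <- dose_plate("P1", "oxaliplatin", paper_grid,
                      matrix(100, 8, 4))
  f <- fit_4pl(plate)
  expect_true(f$censored)
  expect_false(f$converged)
  expect_equal(f$ic50, 100)
  expect_equal(f$emax, 0)

  # inhibition below 50% at the max dose is censored even if a curve fits
  sc <- noiseless_screen(top = 100, bottom = 60, hill = 1, ic50 = 3)
  expect_true(fit_4pl(gen_dose_plate(sc, 1))$censored)
})

test_that("Emax is percent inhibition at the maximum tested dose", {
  v <- matrix(80, 8, 4); v[8, ] <- 20   # 20% viability at 100 uM
  f <- fit_4pl(dose_plate("P1", "oxaliplatin", paper_grid, v))
  expect_equal(f$emax, 80)
})

test_that("fitting requires at least four distinct doses", {
  expect_error(fit_4pl(dose_plate("P", "d", c(1, 3, 10), matrix(50, 3, 2))),
               "4 distinct doses")
  expect_error(fit_4pl(dose_plate("P", "d", paper_grid,
                                  matrix(NA_real_, 8, 2))),
               "missing")
})

test_that("response categories follow the half-open log10 IC50 intervals", {
  calls <- classify_response(c(0.30, 0.80, 1.10, 1.50))
  expect_identical(as.character(calls$category),
                   c("strong", "moderate", "minor", "non"))
  expect_identical(as.character(calls$group), c("OS", "OS", "OR", "OR"))

  # shared endpoints resolve to the more resistant side
  expect_identical(
    as.character(classify_response(c(0.57, 0.98, 1.24))$category),
    c("moderate", "minor", "non"))
  # open-ended outer intervals
  expect_identical(as.character(classify_response(c(-1, 5))$category),
                   c("strong", "non"))

  # strong/moderate are OS, minor/non are OR, for every category
  grid <- classify_response(seq(-0.5, 2.5, by = 0.01))
  expect_true(all((grid$category %in% c("strong", "moderate")) ==
                    (grid$group == "OS")))
  # monotone: category index never decreases as log10 IC50 increases
  expect_true(all(diff(as.integer(grid$category)) >= 0))

  expect_error(classify_response(NaN), "finite")
  expect_error(classify_response(0.5, boundaries = c(1, 2)), "5")
})

test_that("ICx inversion matches the closed-form 4PL solution", {
  sc <- noiseless_screen(top = 100, bottom = 0, hill = 1, ic50 = 3)
  f <- fit_4pl(gen_dose_plate(sc, 1))
  # IC50 is its own inverse when bottom = 0
  expect_equal(invert_icx(f, 50), f$ic50, tolerance = 1e-6)
  # closed form: dose = ic50 * (x / (100 - x))^(1/hill)
  expect_equal(invert_icx(f, 10), 3 * (10 / 90), tolerance = 1e-4)
  expect_equal(invert_icx(f, 40), 3 * (40 / 60), tolerance = 1e-4)

  # bottom plateau at 70% viability: >30% inhibition is unattainable
  sc2 <- noiseless_screen(top = 100, bottom = 70, hill = 1, ic50 = 0.3)
  f2 <- fit_4pl(gen_dose_plate(sc2, 1))
  f2$censored <- FALSE; f2$converged <- TRUE  # isolate the attainability check
  expect_error(invert_icx(f2, 40), "unattainable")
  expect_error(invert_icx(f, 0), "between 0 and 100")
})

test_that("combination shift quantifies IC50 and Emax changes", {
  sc <- noiseless_screen(top = c(100, 100), bottom = c(0, 0), hill = c(1, 1),
                         ic50 = c(30, 0.3))
  mono <- fit_4pl(gen_dose_plate(sc, 1))
  combo <- fit_4pl(gen_dose_plate(sc, 2))

  ident <- combination_shift(mono, mono)
  expect_equal(ident$relative_ic50, 1)
  expect_equal(ident$delta_emax, 0)

  shift <- combination_shift(mono, combo)
  expect_equal(shift$relative_ic50, 0.01, tolerance = 1e-4)
  expect_equal(shift$orders_of_magnitude, 2, tolerance = 1e-4)

  # generator round trip: sensitization by ic50 x 0.05 and emax +15
  sc3 <- noiseless_screen(top = c(100, 100), bottom = c(20, 5),
                          hill = c(1.5, 1.5), ic50 = c(10, 0.5))
  m <- fit_4pl(gen_dose_plate(sc3, 1)); cb <- fit_4pl(gen_dose_plate(sc3, 2))
  s <- combination_shift(m, cb)
  expect_equal(s$relative_ic50, 0.05, tolerance = 1e-3)
  expect_equal(s$delta_emax,
               (100 - fourpl(100, 100, 5, 1.5, 0.5)) -
                 (100 - fourpl(100, 100, 20, 1.5, 10)),
               tolerance = 1e-6)

  cens <- m; cens$censored <- TRUE
  expect_warning(out <- combination_shift(cens, cb), "censored")
  expect_true(out$censored_mono)
})

test_that("fitted IC50 is equivariant under dose rescaling", {
  base <- noiseless_screen(top = 100, bottom = 5, hill = 1.3, ic50 = 2)
  f1 <- fit_4pl(gen_dose_plate(base, 1))
  for (c_scale in c(0.1, 5)) {
    sc <- screen_scenario(data.frame(top = 100, bottom = 5, hill = 1.3,
                                     ic50 = 2 * c_scale),
                          dose_grid = paper_grid * c_scale, noise_sd = 0)
    f2 <- fit_4pl(gen_dose_plate(sc, 1))
    expect_equal(f2$ic50 / f1$ic50, c_scale, tolerance = 1e-6)
  }
})

test_that("refitting a fitted curve's own predictions is idempotent", {
  sc <- screen_scenario(data.frame(top = 100, bottom = 10, hill = 1.2,
                                   ic50 = 4), noise_sd = 4, seed = 11)
  f1 <- fit_4pl(gen_dose_plate(sc, 1))
  pred <- fourpl(paper_grid, f1$top, f1$bottom, f1$hill, f1$ic50)
  f2 <- fit_4pl(dose_plate("P", "oxaliplatin", paper_grid,
                           matrix(pred, 8, 1)))
  for (p in c("top", "bottom", "hill", "ic50"))
    expect_equal(f2[[p]], f1[[p]], tolerance = 1e-6)
})

test_that("AUC decreases as potency increases, other parameters fixed", {
  ic50s <- c(30, 10, 3, 1, 0.3)
  aucs <- vapply(ic50s, function(ic) {
    fit_4pl(gen_dose_plate(noiseless_screen(100, 0, 1.5, ic), 1))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("fit_plates assembles the per-PDO table with calls", {
  truths <- data.frame(top = 100, bottom = 0, hill = 1.5,
                       ic50 = c(2, 8, 12, 30))
  sc <- noiseless_screen(truths$top, truths$bottom, truths$hill, truths$ic50)
  tab <- fit_plates(lapply(1:4, function(i) gen_dose_plate(sc, i)))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$category, c("strong", "moderate", "minor", "non"))
  expect_identical(tab$group, c("OS", "OS", "OR", "OR"))
})
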