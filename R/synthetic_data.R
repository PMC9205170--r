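# Synthetic-data generators.
#
# Each scenario constructor freezes the parameters of one simulated data type
# (viability plates, RNA-seq counts, xenograft growth, patient cohort) and the
# corresponding gen_*() function draws one realization under an explicit seed.
# Generators are pure: identical scenario + seed gives identical output, and
# the global RNG state is left untouched.

#' Viability-screen scenario
#'
#' Describes a simulated oxaliplatin viability screen: the dose grid, the
#' number of replicate wells per dose, the true four-parameter logistic (4PL)
#' curve of each organoid line, and the measurement noise. Defaults follow the
#' standard 8-dose oxaliplatin grid (0.03--100 uM, half-log-ish spacing) with
#' four replicate wells.
#'
#' @param fourpl_truth data frame with one row per PDO and columns `top`,
#'   `bottom`, `hill`, `ic50`: the true 4PL parameters (viability percent for
#'   `top`/`bottom`, `ic50` in uM).
#' @param dose_grid drug concentrations in uM, strictly increasing, all > 0.
#' @param n_replicates replicate wells per dose (>= 1).
#' @param noise_sd additive Gaussian noise SD on the percent-viability scale.
#' @param seed integer seed; generation is deterministic given the scenario.
#' @return An object of class `screen_scenario`.
#' @seealso [gen_dose_plate()]
#' @export
screen_scenario <- function(fourpl_truth,
                            dose_grid = c(0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
                            n_replicates = 4,
                            noise_sd = 5,
                            seed = 1L) {
  if (!is.data.frame(fourpl_truth) ||
      !all(c("top", "bottom", "hill", "ic50") %in% names(fourpl_truth)))
    stopf("'fourpl_truth' must be a data frame with columns top, bottom, hill, ic50")
  assert_increasing(dose_grid, "dose_grid", positive = TRUE)
  n_replicates <- assert_count(n_replicates, "n_replicates")
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (any(fourpl_truth$bottom < 0) || any(fourpl_truth$bottom >= fourpl_truth$top))
    stopf("'fourpl_truth' requires 0 <= bottom < top for every PDO")
  if (any(fourpl_truth$ic50 <= 0) || any(fourpl_truth$hill <= 0))
    stopf("'fourpl_truth' requires positive ic50 and hill")
  structure(
    list(fourpl_truth = fourpl_truth, dose_grid = dose_grid,
         n_replicates = n_replicates, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "screen_scenario")
}

#' Generate one viability plate
#'
#' Draws a dose x replicate plate for one PDO: true 4PL viability plus
#' additive Gaussian noise, clipped at 0% (viability cannot be negative).
#'
#' @param scenario a [screen_scenario()].
#' @param pdo_index row of `scenario$fourpl_truth` to simulate.
#' @param pdo_id,drug identifiers stored on the plate.
#' @return A `dose_plate`: list with `pdo_id`, `drug`, `doses` (uM) and
#'   `viability`, a dose x replicate matrix of percent viability.
#' @export
gen_dose_plate <- function(scenario, pdo_index,
                           pdo_id = sprintf("PDO%02d", pdo_index),
                           drug = "oxaliplatin") {
  stopifnot(inherits(scenario, "screen_scenario"))
  pdo_index <- assert_count(pdo_index, "pdo_index")
  if (pdo_index > nrow(scenario$fourpl_truth))
    stopf("unknown pdo_index %d: fourpl_truth has %d rows",
          pdo_index, nrow(scenario$fourpl_truth))
  tr <- scenario$fourpl_truth[pdo_index, ]
  d <- scenario$dose_grid
  mu <- fourpl(d, tr$top, tr$bottom, tr$hill, tr$ic50)
  v <- with_rng(scenario$seed + pdo_index, {
    matrix(rnorm(length(d) * scenario$n_replicates, mean = mu,
                 sd = scenario$noise_sd),
           nrow = length(d))
  })
  v <- pmax(v, 0)
  dimnames(v) <- list(dose = format(d), replicate = seq_len(ncol(v)))
  dose_plate(pdo_id = pdo_id, drug = drug, doses = d, viability = v)
}

#' Construct a dose plate
#'
#' @param pdo_id,drug identifiers.
#' @param doses concentrations in uM, strictly increasing and positive.
#' @param viability dose x replicate matrix of percent viability (>= 0).
#' @return A `dose_plate` object.
#' @export
dose_plate <- function(pdo_id, drug, doses, viability) {
  assert_increasing(doses, "doses", positive = TRUE)
  viability <- as.matrix(viability)
  if (nrow(viability) != length(doses))
    stopf("'viability' must have one row per dose")
  if (any(viability < 0, na.rm = TRUE))
    stopf("'viability' must be >= 0")
  structure(list(pdo_id = pdo_id, drug = drug, doses = doses,
                 viability = viability),
            class = "dose_plate")
}

#' @export
print.dose_plate <- function(x, ...) {
  cat(sprintf("<dose_plate> %s / %s: %d doses (%g-%g uM) x %d replicates\n",
              x$pdo_id, x$drug, length(x$doses), min(x$doses), max(x$doses),
              ncol(x$viability)))
  invisible(x)
}

#' RNA-seq count scenario
#'
#' Two-group negative-binomial count matrix with planted differential
#' features, emulating the structure of a bulk RNA-seq comparison between
#' drug-sensitive (OS) and drug-resistant (OR) organoid lines. Counts for
#' feature i, sample j are NB with mean `s_j * mu_ij` and variance
#' `mu + dispersion * mu^2`; planted features have OR-group mean equal to the
#' OS-group mean times `2^planted_log2fc`.
#'
#' Defaults emulate an 8 vs 8 design. The dispersion default (0.1) is on the
#' scale typical of routine RNA-seq count variability; see the methods
#' vignette for what this does and does not emulate about patient cohorts.
#'
#' @param n_group_a,n_group_b samples per group (group A = OS, group B = OR).
#' @param n_features number of features.
#' @param planted_idx indices (1-based) of features with a true group effect.
#' @param planted_log2fc log2 fold change (OR vs OS) per planted feature;
#'   recycled to `length(planted_idx)`.
#' @param baseline_mean mean count of a feature in group A at size factor 1.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`); 0 gives
#'   Poisson counts.
#' @param size_factor_range range of per-sample library-size multipliers
#'   (drawn uniformly).
#' @param seed integer seed.
#' @return An object of class `count_scenario`.
#' @seealso [gen_counts()]
#' @export
count_scenario <- function(n_group_a = 8, n_group_b = 8, n_features = 2000,
                           planted_idx = integer(), planted_log2fc = numeric(),
                           baseline_mean = 200, dispersion = 0.1,
                           size_factor_range = c(0.7, 1.4), seed = 1L) {
  n_group_a <- assert_count(n_group_a, "n_group_a", lower = 2L)
  n_group_b <- assert_count(n_group_b, "n_group_b", lower = 2L)
  n_features <- assert_count(n_features, "n_features")
  planted_idx <- as.integer(planted_idx)
  if (length(planted_idx) &&
      (any(planted_idx < 1L) || any(planted_idx > n_features)))
    stopf("'planted_idx' must index features in [1, n_features]")
  if (anyDuplicated(planted_idx)) stopf("'planted_idx' must be unique")
  if (length(planted_idx))
    planted_log2fc <- rep_len(planted_log2fc, length(planted_idx))
  assert_number(baseline_mean, "baseline_mean", lower = .Machine$double.eps)
  assert_number(dispersion, "dispersion", lower = 0)
  assert_increasing(size_factor_range, "size_factor_range", positive = TRUE)
  if (length(size_factor_range) != 2L)
    stopf("'size_factor_range' must have length 2")
  structure(
    list(n_group_a = n_group_a, n_group_b = n_group_b, n_features = n_features,
         planted_idx = planted_idx, planted_log2fc = planted_log2fc,
         baseline_mean = baseline_mean, dispersion = dispersion,
         size_factor_range = size_factor_range, seed = as.integer(seed)),
    class = "count_scenario")
}

#' Generate a labeled count matrix
#'
#' @param scenario a [count_scenario()].
#' @return A [count_matrix()] with OS/OR labels. The true planted indices,
#'   log2 fold changes and size factors are attached as attributes
#'   `planted_idx`, `planted_log2fc` and `true_size_factors`.
#' @export
gen_counts <- function(scenario) {
  stopifnot(inherits(scenario, "count_scenario"))
  na <- scenario$n_group_a; nb <- scenario$n_group_b
  nf <- scenario$n_features
  mu_a <- rep(scenario$baseline_mean, nf)
  mu_b <- mu_a
  if (length(scenario$planted_idx))
    mu_b[scenario$planted_idx] <-
      mu_a[scenario$planted_idx] * 2^scenario$planted_log2fc
  out <- with_rng(scenario$seed, {
    sf <- runif(na + nb, scenario$size_factor_range[1],
                scenario$size_factor_range[2])
    mu <- cbind(matrix(mu_a, nf, na), matrix(mu_b, nf, nb))
    mu <- sweep(mu, 2, sf, `*`)
    cnt <- if (scenario$dispersion == 0) {
      matrix(rpois(length(mu), lambda = mu), nf)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / scenario$dispersion), nf)
    }
    list(cnt = cnt, sf = sf)
  })
  rownames(out$cnt) <- sprintf("FEAT%05d", seq_len(nf))
  colnames(out$cnt) <- c(sprintf("OS%02d", seq_len(na)),
                         sprintf("OR%02d", seq_len(nb)))
  x <- count_matrix(out$cnt, labels = rep(c("OS", "OR"), c(na, nb)))
  attr(x, "planted_idx") <- scenario$planted_idx
  attr(x, "planted_log2fc") <- scenario$planted_log2fc
  attr(x, "true_size_factors") <- out$sf
  x
}

#' Xenograft growth scenario
#'
#' Paired control/treated exponential tumor growth with per-measurement
#' multiplicative noise: `V(t) = V0 * exp(rate * t) * (1 + e)`,
#' `e ~ N(0, noise_cv)`. Defaults follow a 5-mice-per-arm design measured ten
#' times at 3-day intervals, with initial volumes uniform in 80--100 mm3.
#'
#' @param n_per_arm mice per arm (>= 1).
#' @param v0_range range (mm3) of initial tumor volumes, drawn uniformly.
#' @param growth_rate_control,growth_rate_treated exponential growth rates
#'   per day.
#' @param measurement_days sorted day offsets; the first must be 0.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed integer seed.
#' @return An object of class `xeno_scenario`.
#' @seealso [gen_xeno_course()]
#' @export
xeno_scenario <- function(n_per_arm = 5, v0_range = c(80, 100),
                          growth_rate_control = 0.10,
                          growth_rate_treated = 0.02,
                          measurement_days = seq(0, 27, by = 3),
                          noise_cv = 0.1, seed = 1L) {
  n_per_arm <- assert_count(n_per_arm, "n_per_arm")
  assert_increasing(v0_range, "v0_range", positive = TRUE)
  if (length(v0_range) != 2L) stopf("'v0_range' must have length 2")
  assert_number(growth_rate_control, "growth_rate_control")
  assert_number(growth_rate_treated, "growth_rate_treated")
  if (length(measurement_days) < 1L)
    stopf("'measurement_days' must be non-empty")
  assert_increasing(measurement_days, "measurement_days")
  if (measurement_days[1] != 0)
    stopf("'measurement_days' must start at day 0")
  assert_number(noise_cv, "noise_cv", lower = 0)
  structure(
    list(n_per_arm = n_per_arm, v0_range = v0_range,
         growth_rate_control = growth_rate_control,
         growth_rate_treated = growth_rate_treated,
         measurement_days = measurement_days, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "xeno_scenario")
}

#' Generate a paired xenograft tumor course
#'
#' @param scenario a [xeno_scenario()].
#' @return A `tumor_course` data frame with columns `mouse_id`,
#'   `arm` (control/treated), `day` and `volume_mm3`.
#' @export
gen_xeno_course <- function(scenario) {
  stopifnot(inherits(scenario, "xeno_scenario"))
  days <- scenario$measurement_days
  arms <- data.frame(
    arm = rep(c("control", "treated"), each = scenario$n_per_arm),
    rate = rep(c(scenario$growth_rate_control, scenario$growth_rate_treated),
               each = scenario$n_per_arm),
    mouse_id = c(sprintf("C%02d", seq_len(scenario$n_per_arm)),
                 sprintf("T%02d", seq_len(scenario$n_per_arm))))
  rows <- with_rng(scenario$seed, {
    v0 <- runif(nrow(arms), scenario$v0_range[1], scenario$v0_range[2])
    do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
      mu <- v0[i] * exp(arms$rate[i] * days)
      noise <- rnorm(length(days), 0, scenario$noise_cv)
      data.frame(mouse_id = arms$mouse_id[i], arm = arms$arm[i], day = days,
                 volume_mm3 = pmax(mu * (1 + noise), .Machine$double.eps))
    }))
  })
  tumor_course(rows)
}

#' Construct a tumor course
#'
#' @param x data frame with columns `mouse_id`, `arm` (control/treated),
#'   `day`, `volume_mm3`.
#' @return A `tumor_course` data frame.
#' @export
tumor_course <- function(x) {
  need <- c("mouse_id", "arm", "day", "volume_mm3")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stopf("a tumor course needs columns %s", paste(need, collapse = ", "))
  if (!all(x$arm %in% c("control", "treated")))
    stopf("'arm' must be 'control' or 'treated'")
  if (any(x$volume_mm3 <= 0)) stopf("volumes must be positive")
  for (a in c("control", "treated"))
    if (!any(x$arm == a)) stopf("arm '%s' is empty", a)
  has0 <- tapply(x$day, x$mouse_id, function(d) any(d == 0))
  if (!all(has0)) stopf("every mouse needs a day-0 measurement")
  class(x) <- c("tumor_course", "data.frame")
  x
}

#' Patient-cohort scenario
#'
#' Simulates a cohort of patients with a PDO drug-sensitivity class and a
#' binary clinical outcome, drawn independently per patient: class is OS with
#' probability `p_class_sensitive`, and the outcome is `responder` with the
#' class-conditional probability. A four-level response category is also
#' drawn uniformly within the class (strong/moderate for OS, minor/non for
#' OR) so ordered-trend analyses can be exercised.
#'
#' Defaults mirror a 17-patient validation cohort with the observed
#' class-conditional response rates (7/9 among OS, 3/8 among OR).
#'
#' @param n_patients cohort size.
#' @param p_class_sensitive probability a patient's PDO is OS.
#' @param p_respond_given_sensitive,p_respond_given_resistant conditional
#'   response probabilities.
#' @param seed integer seed.
#' @return An object of class `cohort_scenario`.
#' @seealso [gen_cohort()]
#' @export
cohort_scenario <- function(n_patients = 17, p_class_sensitive = 9 / 17,
                            p_respond_given_sensitive = 7 / 9,
                            p_respond_given_resistant = 3 / 8, seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  assert_prob(p_class_sensitive, "p_class_sensitive")
  assert_prob(p_respond_given_sensitive, "p_respond_given_sensitive")
  assert_prob(p_respond_given_resistant, "p_respond_given_resistant")
  structure(
    list(n_patients = n_patients, p_class_sensitive = p_class_sensitive,
         p_respond_given_sensitive = p_respond_given_sensitive,
         p_respond_given_resistant = p_respond_given_resistant,
         seed = as.integer(seed)),
    class = "cohort_scenario")
}

#' Generate a patient cohort
#'
#' @param scenario a [cohort_scenario()].
#' @return A `pdo_cohort` data frame with columns `patient_id`, `pdo_class`
#'   (OS/OR), `category` (strong/moderate/minor/non) and `outcome`
#'   (responder/non_responder).
#' @export
gen_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  with_rng(scenario$seed, {
    os <- rbinom(scenario$n_patients, 1, scenario$p_class_sensitive) == 1
    p_resp <- ifelse(os, scenario$p_respond_given_sensitive,
                     scenario$p_respond_given_resistant)
    resp <- rbinom(scenario$n_patients, 1, p_resp) == 1
    cat4 <- ifelse(os,
                   sample(c("strong", "moderate"), scenario$n_patients, TRUE),
                   sample(c("minor", "non"), scenario$n_patients, TRUE))
    out <- data.frame(
      patient_id = sprintf("PT%02d", seq_len(scenario$n_patients)),
      pdo_class = ifelse(os, "OS", "OR"),
      category = cat4,
      outcome = ifelse(resp, "responder", "non_responder"))
    class(out) <- c("pdo_cohort", "data.frame")
    out
  })
}

#' Generate reference rank profiles
#'
#' Builds a collection of reference expression rank profiles (one ranked
#' feature list per perturbagen instance, most up-regulated first) for
#' connectivity scoring. Most profiles are random permutations of the feature
#' universe; optionally, `n_reversers` profiles are planted that reverse a
#' query signature (its up-features pushed to the profile bottom, its
#' down-features to the top).
#'
#' @param feature_ids the feature universe.
#' @param n_perturbagens number of random (non-reverser) perturbagens.
#' @param reverse_up,reverse_down feature sets a reverser profile should
#'   invert (both required if `n_reversers > 0`).
#' @param n_reversers number of planted reverser profiles.
#' @param seed integer seed.
#' @return A named list of ranked feature vectors (class
#'   `reference_profiles`); reversers are named `REV01`, `REV02`, ...
#' @export
gen_reference_profiles <- function(feature_ids, n_perturbagens = 20,
                                   reverse_up = NULL, reverse_down = NULL,
                                   n_reversers = 0, seed = 1L) {
  n_perturbagens <- assert_count(n_perturbagens, "n_perturbagens")
  n_reversers <- assert_count(n_reversers, "n_reversers", lower = 0L)
  if (n_reversers > 0 && (is.null(reverse_up) || is.null(reverse_down)))
    stopf("'reverse_up' and 'reverse_down' are required when planting reversers")
  with_rng(seed, {
    prof <- lapply(seq_len(n_perturbagens), function(i) sample(feature_ids))
    names(prof) <- sprintf("PERT%02d", seq_len(n_perturbagens))
    if (n_reversers > 0) {
      rest <- setdiff(feature_ids, c(reverse_up, reverse_down))
      rev <- lapply(seq_len(n_reversers), function(i) {
        c(sample(reverse_down), sample(rest), sample(reverse_up))
      })
      names(rev) <- sprintf("REV%02d", seq_len(n_reversers))
      prof <- c(prof, rev)
    }
    structure(prof, class = "reference_profiles")
  })
}
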