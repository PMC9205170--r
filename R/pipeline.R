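# End-to-end orchestration: simulate -> dose-response -> xenograft ->
# signatures -> connectivity -> concordance, from one validated config.

#' Default pipeline configuration
#'
#' Returns the fully populated configuration the pipeline runs with when no
#' overrides are given. Stage parameters carry the workflow's documented
#' defaults: the 8-dose oxaliplatin grid with four replicates, the five
#' log10 IC50 category boundaries, top-k = 100 per leave-one-out fold, the
#' -95 connectivity selection threshold, and the 50% tumor-growth-inhibition
#' responder cutoff.
#'
#' @return A nested list (see [validate_config()] for the schema).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "organodx_run",
    stages = list(simulate = TRUE, dose_response = TRUE, xenograft = TRUE,
                  signatures = TRUE, connectivity = TRUE, concordance = TRUE),
    screen = list(n_pdos = 42, dose_grid = c(0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
                  n_replicates = 4, noise_sd = 5),
    counts = list(n_group_a = 8, n_group_b = 8, n_features = 2000,
                  n_planted = 20, planted_log2fc = 3, baseline_mean = 200,
                  dispersion = 0.1, size_factor_range = c(0.7, 1.4)),
    xenograft = list(n_courses = 8, n_per_arm = 5, v0_range = c(80, 100),
                     growth_rate_control = 0.10,
                     treated_rate_responder = 0.00,
                     treated_rate_nonresponder = 0.09,
                     measurement_days = seq(0, 27, by = 3), noise_cv = 0.1,
                     tgi_threshold = 50),
    cohort = list(n_patients = 17, p_class_sensitive = 9 / 17,
                  p_respond_given_sensitive = 7 / 9,
                  p_respond_given_resistant = 3 / 8),
    dose_response = list(boundaries = c(0.14, 0.57, 0.98, 1.24, 2.00)),
    signatures = list(top_k = 100, min_fold_change = 2, max_adj_p = 0.05,
                      expression_floor = 5),
    connectivity = list(n_perturbagens = 40, n_reversers = 3,
                        threshold = -95),
    concordance = list(trend_scores = c(0, 1, 2, 3),
                       alternative = "decreasing"))
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a (possibly partial) nested list, fills every
#' missing entry from [default_config()], and checks the result: stage flags
#' must be logical, seeds integral, the dose grid strictly increasing, the
#' category boundaries exactly five increasing numbers, the connectivity
#' threshold in `[-100, 0]`, probabilities in `[0, 1]`. Violations raise an
#' error naming the offending key.
#'
#' @param config path to a JSON config, a nested list, or `NULL` for the
#'   full defaults.
#' @return The validated, fully populated config (class `run_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("'config' must be a list or a JSON file path")
  merge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  known <- names(default_config())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stopf("unknown config key: %s", paste(bad, collapse = ", "))
  cfg <- merge(default_config(), config)

  if (cfg$seed != as.integer(cfg$seed)) stopf("'seed' must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  for (s in names(cfg$stages))
    if (!is.logical(cfg$stages[[s]]) || is.na(cfg$stages[[s]]))
      stopf("'stages.%s' must be TRUE or FALSE", s)
  assert_increasing(cfg$screen$dose_grid, "screen.dose_grid", positive = TRUE)
  assert_count(cfg$screen$n_replicates, "screen.n_replicates")
  assert_count(cfg$screen$n_pdos, "screen.n_pdos")
  if (length(cfg$dose_response$boundaries) != 5L ||
      any(diff(cfg$dose_response$boundaries) <= 0))
    stopf("'boundaries' must be exactly 5 strictly increasing values")
  assert_count(cfg$signatures$top_k, "signatures.top_k")
  assert_number(cfg$connectivity$threshold, "connectivity.threshold",
                lower = -100, upper = 0)
  assert_number(cfg$xenograft$tgi_threshold, "xenograft.tgi_threshold")
  for (k in c("p_class_sensitive", "p_respond_given_sensitive",
              "p_respond_given_resistant"))
    assert_prob(cfg$cohort[[k]], paste0("cohort.", k))
  if (cfg$counts$n_planted > cfg$counts$n_features)
    stopf("'counts.n_planted' cannot exceed 'counts.n_features'")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs drawn
#' from the config's scenarios, writing per-stage outputs, a run log
#' (`run.log`, ISO timestamps plus the resolved config) and a deterministic
#' machine-readable summary (`summary.json`) into `output_dir`. Re-running
#' with an identical config and seed reproduces the summary byte for byte.
#'
#' Stage outputs: `plates.csv`, `fits.csv` (per-PDO 4PL fit table with
#' category and OS/OR calls), `tgi.json` and per-course median tables,
#' `de_table.csv`, `consensus.json`, `predictors.csv`, `classifier_panel.csv`,
#' signature query files (`signature_up.txt`, `signature_down.txt`,
#' `signature.rnk`), `profiles.tsv`, `connectivity_*.csv`, `candidates.csv`,
#' `cohort.csv` and `concordance.json`.
#'
#' The connectivity stage queries the reference collection twice — once with
#' the consensus-signature up/down sets and once with the up/down split of
#' the perfect (LOOCV score 1) single-feature predictors — and intersects
#' the two candidate lists at the configured threshold.
#'
#' @param config anything [validate_config()] accepts.
#' @return Invisibly, the summary list. Stage failures abort with the stage
#'   name; outputs written before the failure are retained alongside a
#'   `FAILED` marker file.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  cat(sprintf("[%s] run started\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      file = log_path)
  logf("resolved config: %s",
       jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
  summary <- list(seed = cfg$seed)
  run_stage <- function(name, enabled, fun) {
    if (!enabled) { logf("stage %s: skipped", name); return(NULL) }
    logf("stage %s: start", name)
    out <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(cfg$output_dir, "FAILED"))
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("stage %s: done", name)
    out
  }
  st <- cfg$stages
  sim <- run_stage("simulate", st$simulate, function() {
    simulate_inputs(cfg)
  })

  if (st$dose_response) {
    fits <- run_stage("dose_response", TRUE, function() {
      if (is.null(sim)) stopf("requires the simulate stage")
      tab <- fit_plates(sim$plates, cfg$dose_response$boundaries)
      write.csv(tab, file.path(cfg$output_dir, "fits.csv"),
                row.names = FALSE)
      tab
    })
    summary$dose_response <- list(
      n_pdos = nrow(fits),
      n_censored = sum(fits$censored),
      category_counts = as.list(table(factor(fits$category,
        levels = c("strong", "moderate", "minor", "non")))),
      group_counts = as.list(table(factor(fits$group,
        levels = c("OS", "OR")))))
  }

  if (st$xenograft) {
    tgi <- run_stage("xenograft", TRUE, function() {
      if (is.null(sim)) stopf("requires the simulate stage")
      res <- lapply(sim$courses, compute_tgi,
                    responder_threshold = cfg$xenograft$tgi_threshold)
      jsonlite::write_json(
        lapply(res, function(r) r[c("tgi_pct", "responder", "endpoint_day")]),
        file.path(cfg$output_dir, "tgi.json"), auto_unbox = TRUE, digits = NA)
      res
    })
    summary$xenograft <- list(
      tgi_pct = vapply(tgi, `[[`, numeric(1), "tgi_pct"),
      responders = sum(vapply(tgi, `[[`, logical(1), "responder")))
  }

  sig <- NULL
  if (st$signatures) {
    sig <- run_stage("signatures", TRUE, function() {
      if (is.null(sim)) stopf("requires the simulate stage")
      scfg <- cfg$signatures
      de <- de_rank(sim$counts, expression_floor = scfg$expression_floor)
      write.csv(de, file.path(cfg$output_dir, "de_table.csv"),
                row.names = FALSE)
      cons <- loocv_consensus(sim$counts, k = scfg$top_k,
                              expression_floor = scfg$expression_floor,
                              min_fold_change = scfg$min_fold_change,
                              max_adj_p = scfg$max_adj_p)
      jsonlite::write_json(list(fold_top = cons$fold_top,
                                consensus = cons$consensus,
                                k = cons$k, n_folds = cons$n_folds),
                           file.path(cfg$output_dir, "consensus.json"),
                           auto_unbox = TRUE, digits = NA)
      pred <- single_feature_lr_search(sim$counts, cons$consensus)
      write.csv(pred, file.path(cfg$output_dir, "predictors.csv"),
                row.names = FALSE)
      panel <- classifier_panel(sim$counts, cons$consensus, seed = cfg$seed)
      write.csv(panel, file.path(cfg$output_dir, "classifier_panel.csv"),
                row.names = FALSE)
      paths <- write_signature_files(de, cons$consensus, cfg$output_dir)
      list(de = de, consensus = cons, predictors = pred, panel = panel,
           files = paths)
    })
    perfect <- sig$predictors$feature_id[sig$predictors$loocv_score == 1]
    summary$signatures <- list(
      n_tested = nrow(sig$de),
      consensus_size = length(sig$consensus$consensus),
      consensus = sig$consensus$consensus,
      n_perfect_predictors = length(perfect),
      panel_accuracy = setNames(as.list(sig$panel$loocv_accuracy),
                                sig$panel$classifier))
  }

  if (st$connectivity) {
    conn <- run_stage("connectivity", TRUE, function() {
      if (is.null(sig))
        stopf("requires the signatures stage: no query signature files")
      de <- sig$de
      cons_feats <- sig$consensus$consensus
      sub <- de[match(cons_feats, de$feature_id), ]
      query_a <- query_signature(up = sub$feature_id[sub$log2fc > 0],
                                 down = sub$feature_id[sub$log2fc < 0])
      perfect <- sig$predictors$feature_id[sig$predictors$loocv_score == 1]
      psub <- de[match(perfect, de$feature_id), ]
      query_b <- query_signature(up = psub$feature_id[psub$log2fc > 0],
                                 down = psub$feature_id[psub$log2fc < 0])
      profiles <- gen_reference_profiles(
        rownames(sim$counts$counts),
        n_perturbagens = cfg$connectivity$n_perturbagens,
        reverse_up = query_a$up, reverse_down = query_a$down,
        n_reversers = cfg$connectivity$n_reversers,
        seed = cfg$seed + 777L)
      write_reference_profiles(profiles,
                               file.path(cfg$output_dir, "profiles.tsv"))
      hits_a <- connectivity_scores(query_a, profiles)
      hits_b <- connectivity_scores(query_b, profiles)
      write.csv(hits_a, file.path(cfg$output_dir, "connectivity_consensus.csv"),
                row.names = FALSE)
      write.csv(hits_b, file.path(cfg$output_dir, "connectivity_predictors.csv"),
                row.names = FALSE)
      cand <- select_candidates(hits_a, hits_b, cfg$connectivity$threshold)
      write.csv(cand, file.path(cfg$output_dir, "candidates.csv"),
                row.names = FALSE)
      list(hits_a = hits_a, hits_b = hits_b, candidates = cand)
    })
    summary$connectivity <- list(
      n_profiles = nrow(conn$hits_a),
      candidates = conn$candidates$perturbagen,
      candidate_scores = conn$candidates$mean_score)
  }

  if (st$concordance) {
    conc <- run_stage("concordance", TRUE, function() {
      if (is.null(sim)) stopf("requires the simulate stage")
      t22 <- as_cohort_2x2(sim$cohort)
      met <- confusion_metrics(t22)
      trend <- build_trend_table(sim$cohort)
      ca <- cochran_armitage(trend$events, trend$n,
                             scores = cfg$concordance$trend_scores,
                             alternative = cfg$concordance$alternative)
      res <- list(table = unclass(t22)[c("a", "b", "c", "d")],
                  metrics = unclass(met),
                  fisher_p = fisher_exact(t22),
                  trend_p = ca$p_value, trend_z = ca$statistic)
      jsonlite::write_json(res, file.path(cfg$output_dir, "concordance.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
    summary$concordance <- conc
  }

  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("run finished")
  invisible(summary)
}

# draw all synthetic inputs for one pipeline run
simulate_inputs <- function(cfg) {
  # 4PL truths spanning the four response categories
  truth <- with_rng(cfg$seed, {
    b <- cfg$dose_response$boundaries
    data.frame(top = runif(cfg$screen$n_pdos, 95, 105),
               bottom = runif(cfg$screen$n_pdos, 0, 15),
               hill = runif(cfg$screen$n_pdos, 0.8, 2.5),
               ic50 = 10^runif(cfg$screen$n_pdos, b[1], b[5]))
  })
  screen <- screen_scenario(truth, dose_grid = cfg$screen$dose_grid,
                            n_replicates = cfg$screen$n_replicates,
                            noise_sd = cfg$screen$noise_sd, seed = cfg$seed)
  plates <- lapply(seq_len(cfg$screen$n_pdos),
                   function(i) gen_dose_plate(screen, i))
  write_dose_plates(plates, file.path(cfg$output_dir, "plates.csv"))

  ccfg <- cfg$counts
  planted <- seq_len(ccfg$n_planted)
  signs <- rep(c(1, -1), length.out = length(planted))
  counts <- gen_counts(count_scenario(
    n_group_a = ccfg$n_group_a, n_group_b = ccfg$n_group_b,
    n_features = ccfg$n_features, planted_idx = planted,
    planted_log2fc = signs * ccfg$planted_log2fc,
    baseline_mean = ccfg$baseline_mean, dispersion = ccfg$dispersion,
    size_factor_range = ccfg$size_factor_range, seed = cfg$seed + 101L))
  write_count_matrix(counts, file.path(cfg$output_dir, "counts.tsv"),
                     file.path(cfg$output_dir, "labels.csv"))

  xcfg <- cfg$xenograft
  n_resp <- ceiling(xcfg$n_courses / 2)
  treated_rates <- rep(c(xcfg$treated_rate_responder,
                         xcfg$treated_rate_nonresponder),
                       c(n_resp, xcfg$n_courses - n_resp))
  courses <- lapply(seq_len(xcfg$n_courses), function(i) {
    gen_xeno_course(xeno_scenario(
      n_per_arm = xcfg$n_per_arm, v0_range = xcfg$v0_range,
      growth_rate_control = xcfg$growth_rate_control,
      growth_rate_treated = treated_rates[i],
      measurement_days = xcfg$measurement_days, noise_cv = xcfg$noise_cv,
      seed = cfg$seed + 500L + i))
  })
  names(courses) <- sprintf("course%02d", seq_along(courses))

  cohort <- gen_cohort(cohort_scenario(
    n_patients = cfg$cohort$n_patients,
    p_class_sensitive = cfg$cohort$p_class_sensitive,
    p_respond_given_sensitive = cfg$cohort$p_respond_given_sensitive,
    p_respond_given_resistant = cfg$cohort$p_respond_given_resistant,
    seed = cfg$seed + 900L))
  write_cohort(cohort, file.path(cfg$output_dir, "cohort.csv"))

  list(plates = plates, counts = counts, courses = courses, cohort = cohort)
}
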