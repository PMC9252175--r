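#' Run configuration for the analysis pipeline
#'
#' Bundles the settings shared by the pipeline stages: where the cohort
#' comes from (a CSV path or a simulation spec — exactly one), which
#' measurement condition and model families to use, the bootstrap
#' budget, the seed, and the output directory.
#'
#' @param cohort_path path to an existing cohort CSV, or `NULL` to
#'   simulate.
#' @param sim_spec a [cohort_spec()], or `NULL` to read a cohort from
#'   `cohort_path`. Exactly one of `cohort_path`/`sim_spec` must be
#'   given.
#' @param model_kinds model families to evaluate, subset of
#'   `c("SC", "TTC")`.
#' @param frequencies frequencies (kHz) to evaluate.
#' @param positions electrode positions to evaluate.
#' @param agreement_frequency,agreement_position the single condition
#'   used for agreement analysis (default 50 kHz, position c, the
#'   best-performing condition).
#' @param n_boot bootstrap replicates per condition cell.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, sim_spec = NULL,
                       model_kinds = c("SC", "TTC"),
                       frequencies = c(10, 50, 100),
                       positions = c("a", "b", "c"),
                       agreement_frequency = 50,
                       agreement_position = "c",
                       n_boot = 10000L, seed = 1L, out_dir = ".") {
  if (is.null(cohort_path) == is.null(sim_spec))
    stop("exactly one of cohort_path or sim_spec must be given")
  if (!is.null(sim_spec)) stopifnot(inherits(sim_spec, "cohort_spec"))
  model_kinds <- match.arg(model_kinds, several.ok = TRUE)
  stopifnot(all(frequencies %in% c(10, 50, 100)),
            all(positions %in% c("a", "b", "c")),
            agreement_frequency %in% c(10, 50, 100),
            agreement_position %in% c("a", "b", "c"),
            n_boot >= 1)
  structure(list(cohort_path = cohort_path, sim_spec = sim_spec,
                 model_kinds = model_kinds, frequencies = frequencies,
                 positions = positions,
                 agreement_frequency = agreement_frequency,
                 agreement_position = agreement_position,
                 n_boot = as.integer(n_boot), seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; the
#' `sim_spec:` block accepts `n`, `sex_ratio`, `seed`, `ffm_rule` and
#' `noise_scale` overrides of the default [cohort_spec()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim_spec)) {
    # YAML 1.1 reads a bare `n:` key as boolean; restore it
    names(y$sim_spec)[names(y$sim_spec) %in% c("FALSE", "n_subjects")] <- "n"
    args <- y$sim_spec[intersect(names(y$sim_spec),
                                 c("n", "sex_ratio", "seed", "ffm_rule",
                                   "noise_scale", "dexa_noise_sd"))]
    sim <- do.call(cohort_spec, args)
  }
  keep <- intersect(names(y), c("cohort_path", "model_kinds",
                                "frequencies", "positions",
                                "agreement_frequency",
                                "agreement_position", "n_boot", "seed",
                                "out_dir"))
  do.call(run_config, c(y[keep], list(sim_spec = sim)))
}

load_or_simulate <- function(config) {
  if (!is.null(config$sim_spec)) generate_cohort(config$sim_spec)$cohort
  else read_cohort(config$cohort_path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `cohort.csv` (the observable table) and
#' `ground_truth.csv` (the generator's per-subject truth) to the
#' configured output directory.
#'
#' @param config a [run_config()] whose `sim_spec` is set.
#' @return Invisibly, a list with the two file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sim_spec))
    stop("run_simulate needs a config with a simulation spec")
  gen <- generate_cohort(config$sim_spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  truth_path <- file.path(config$out_dir, "ground_truth.csv")
  write_cohort(gen$cohort, cohort_path)
  utils::write.csv(gen$truth, truth_path, row.names = FALSE)
  message(sprintf("wrote %d-subject cohort to %s (truth: %s)",
                  nrow(gen$cohort), cohort_path, truth_path))
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Bootstrap-evaluate both model families over the condition grid
#'
#' Runs [condition_sweep()] on the configured cohort and writes the
#' metric table to `metrics.csv` in the output directory.
#'
#' @param config a [run_config()].
#' @return The `condition_sweep` data.frame, invisibly.
#' @export
run_evaluate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_or_simulate(config)
  if (!"ffm_dexa_kg" %in% names(cohort))
    stop("cohort lacks the reference FFM column ffm_dexa_kg")
  sweep <- condition_sweep(cohort, model_kinds = config$model_kinds,
                           frequencies = config$frequencies,
                           positions = config$positions,
                           n_boot = config$n_boot, seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "metrics.csv")
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  bc <- best_condition(sweep)
  for (i in seq_len(nrow(bc)))
    message(sprintf("best condition for %s: %g kHz position %s (MAPE %.3f)",
                    bc$model[i], bc$frequency_khz[i], bc$position[i],
                    bc$mape_mean[i]))
  invisible(sweep)
}

#' Bland-Altman agreement of the published estimators vs the reference
#'
#' Evaluates the published SC and TTC equations on the configured
#' cohort at the configured agreement condition and writes the
#' Bland-Altman report (`agreement.csv`) plus the per-subject plot
#' data (`agreement_points.csv`: subject, model, mean, difference).
#'
#' @param config a [run_config()].
#' @return The agreement report data.frame, invisibly.
#' @export
run_agreement <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_or_simulate(config)
  if (!"ffm_dexa_kg" %in% names(cohort))
    stop("cohort lacks the reference FFM column ffm_dexa_kg")
  feats <- derive_features(cohort, config$agreement_frequency,
                           config$agreement_position)
  estimates <- list()
  if ("SC" %in% config$model_kinds)
    estimates$sc_published <- predict_ffm_sc(feats$sex, feats$age,
                                             feats$tbm, feats$bi)
  if ("TTC" %in% config$model_kinds)
    estimates$ttc_published <- predict_ffm_ttc(feats$arm_volume, feats$bmi,
                                               feats$tbm, feats$bi)
  report <- agreement_report(estimates, feats$ffm_ref)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report, file.path(config$out_dir, "agreement.csv"),
                   row.names = FALSE)
  pts <- do.call(rbind, lapply(names(estimates), function(nm) {
    r <- attr(report, "results")[[nm]]
    data.frame(subject_id = feats$subject_id, model = nm,
               mean = r$means, diff = r$diffs, stringsAsFactors = FALSE)
  }))
  utils::write.csv(pts, file.path(config$out_dir, "agreement_points.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' Single-subject FFM prediction from raw measurements
#'
#' Convenience wrapper tying the anthropometric operations to the
#' published estimators for one subject.
#'
#' @param sex "M" or "F".
#' @param age years.
#' @param height_cm height, cm.
#' @param tbm_kg total body mass, kg.
#' @param shoulder_circ_cm,wrist_circ_cm,arm_length_cm per-side arm
#'   measurements, cm; length-1 values are used for both sides.
#' @param resistance_ohm measured resistance at the chosen condition,
#'   Ohm (replicate-aggregated).
#' @return A data.frame with one row per model (`sc_published`,
#'   `ttc_published`) and its FFM estimate in kg.
#' @export
predict_subject <- function(sex, age, height_cm, tbm_kg,
                            shoulder_circ_cm, wrist_circ_cm,
                            arm_length_cm, resistance_ohm) {
  stopifnot(sex %in% c("M", "F"))
  two <- function(x) if (length(x) == 1) rep(x, 2) else x
  sh <- two(shoulder_circ_cm); wr <- two(wrist_circ_cm)
  le <- two(arm_length_cm)
  vol <- total_arm_volume(arm_geometry(sh[1], wr[1], le[1]),
                          arm_geometry(sh[2], wr[2], le[2]))
  bi <- bioimpedance_index(height_cm, resistance_ohm)
  bmi <- compute_bmi(tbm_kg, height_cm)
  data.frame(model = c("sc_published", "ttc_published"),
             ffm_kg = c(predict_ffm_sc(as.numeric(sex == "M"), age,
                                       tbm_kg, bi),
                        predict_ffm_ttc(vol / 1e6, bmi, tbm_kg, bi)),
             stringsAsFactors = FALSE)
}
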