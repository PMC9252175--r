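#' Specification of a synthetic BIA study cohort
#'
#' Defines the joint distribution from which [generate_cohort()] draws
#' subjects. The defaults emulate a healthy-adult hand-to-hand BIA
#' study population: 42 subjects, half male; per-sex truncated-normal
#' age, height and body-fat-fraction marginals; BMI linked to fat
#' fraction (and total body mass derived from BMI and height, keeping
#' height, TBM and BMI mutually consistent); arm frustum geometry from
#' height/adiposity allometry with per-side jitter; and impedance
#' readings produced by the series-frustum forward model with
#' composition-linked resistivity plus per-condition and per-replicate
#' Gaussian noise.
#'
#' Noise structure per reading: the clean series resistance of the two
#' arm frusta is scaled by a per-frequency resistivity factor, shifted
#' by a per-position path offset (position a, through the fingers, is
#' the longest path and gets the largest offset; position b is the
#' noisiest; position c, the thenar, is the cleanest), then perturbed
#' by a per-subject-per-condition noise term and an independent
#' per-replicate term. `noise_scale` multiplies every noise SD at once,
#' which is how noise-free and reduced-noise cohorts are produced.
#'
#' @param n cohort size.
#' @param sex_ratio fraction of males.
#' @param seed RNG seed; the whole cohort is deterministic given the
#'   spec.
#' @param ffm_rule how true FFM is defined: `"body_comp"` (default)
#'   sets FFM = TBM x (1 - fat fraction); `"ttc_published"` sets it to
#'   the published TTC equation evaluated on the subject's noise-free
#'   derived features (used for pipeline-closure checks).
#' @param sex_sampling `"stratified"` (default) fixes the male count at
#'   `round(n * sex_ratio)` in shuffled order, mirroring a
#'   sex-balanced recruitment design; `"bernoulli"` draws each
#'   subject's sex independently.
#' @param noise_scale global multiplier on all noise SDs (condition,
#'   replicate, and reference-measurement noise).
#' @param male,female per-sex distribution parameters; see the default
#'   lists for the full field set (truncated-normal `mean`/`sd`/
#'   `min`/`max` for `age`, `height`, `fat`, plus `bmi_base`, `bmi_sd`,
#'   `arm_base` and `arm_fat_shift`).
#' @param bmi_fat_slope slope of BMI on fat fraction, kg/m^2 per unit.
#' @param bmi_range truncation bounds for BMI, kg/m^2.
#' @param allometry arm-geometry allometry coefficients (circumference
#'   and length as linear functions of height and fat fraction, with
#'   jitter SDs; `side_sd` is the per-side asymmetry jitter).
#' @param resistivity forward-model electrical parameters:
#'   `rho0` (Ohm cm at 50 kHz), `gamma` (composition exponent on
#'   1/(1 - arm fat)), `freq_scale`, `pos_offset`, `cond_noise_sd`
#'   (3 x 3 frequency-by-position matrix, Ohm), `replicate_noise_sd`
#'   (Ohm), `torso_resistance` (Ohm, 0 under the torso-neglect
#'   assumption).
#' @param dexa_noise_sd SD of the reference FFM measurement noise, kg.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 42L, sex_ratio = 0.5, seed = 1L,
                        ffm_rule = c("body_comp", "ttc_published"),
                        sex_sampling = c("stratified", "bernoulli"),
                        noise_scale = 1,
                        male = list(age = c(mean = 24.95, sd = 8.0,
                                            min = 18, max = 56),
                                    height = c(mean = 178.0, sd = 6.0,
                                               min = 156, max = 196),
                                    fat = c(mean = 0.2035, sd = 0.0755,
                                            min = 0.0832, max = 0.4839),
                                    bmi_base = 19.62, bmi_sd = 1.72,
                                    arm_base = 17.5, arm_fat_shift = 0),
                        female = list(age = c(mean = 29.1, sd = 11.65,
                                              min = 18, max = 56),
                                      height = c(mean = 165.8, sd = 6.0,
                                                 min = 156, max = 196),
                                      fat = c(mean = 0.3318, sd = 0.059,
                                              min = 0.0832, max = 0.4839),
                                      bmi_base = 16.874, bmi_sd = 4.99,
                                      arm_base = 11.25,
                                      arm_fat_shift = 0.08),
                        bmi_fat_slope = 20, bmi_range = c(18.17, 38.87),
                        allometry = list(shoulder_height = 0.03,
                                         shoulder_fat = 60,
                                         shoulder_sd = 1.2,
                                         wrist_base = 5.5,
                                         wrist_height = 0.05,
                                         wrist_fat = 5, wrist_sd = 0.6,
                                         length_height = 0.32,
                                         length_sd = 1.5,
                                         side_sd = 0.4),
                        resistivity = list(rho0 = 65, gamma = 4.5,
                                           min_arm_fat = 0.03,
                                           freq_scale = c(`10` = 1.08,
                                                          `50` = 1.0,
                                                          `100` = 0.95),
                                           pos_offset = c(a = 30, b = -10,
                                                          c = 0),
                                           cond_noise_sd = matrix(
                                             c(70, 150, 40,
                                               45, 200, 8,
                                               45, 120, 140),
                                             nrow = 3, byrow = TRUE,
                                             dimnames = list(
                                               c("10", "50", "100"),
                                               c("a", "b", "c"))),
                                           replicate_noise_sd = 3,
                                           torso_resistance = 0),
                        dexa_noise_sd = 0.5) {
  ffm_rule <- match.arg(ffm_rule)
  sex_sampling <- match.arg(sex_sampling)
  stopifnot(is.numeric(n), n >= 1, sex_ratio >= 0, sex_ratio <= 1,
            noise_scale >= 0, dexa_noise_sd >= 0)
  for (sx in list(male, female)) {
    for (f in c("age", "height", "fat")) {
      v <- sx[[f]]
      if (v["sd"] < 0) stop("negative SD in spec field ", f)
      if (v["min"] >= v["max"])
        stop("infeasible truncation bounds for ", f)
    }
    if (sx$fat["min"] <= 0 || sx$fat["max"] >= 1)
      stop("fat fraction bounds must lie strictly inside (0, 1)")
  }
  structure(list(n = as.integer(n), sex_ratio = sex_ratio, seed = seed,
                 ffm_rule = ffm_rule, sex_sampling = sex_sampling,
                 noise_scale = noise_scale,
                 male = male, female = female,
                 bmi_fat_slope = bmi_fat_slope, bmi_range = bmi_range,
                 allometry = allometry, resistivity = resistivity,
                 dexa_noise_sd = dexa_noise_sd),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, %.0f%% male, seed %s\n",
              x$n, 100 * x$sex_ratio, format(x$seed)))
  cat(sprintf("  FFM rule '%s', noise scale %g\n", x$ffm_rule,
              x$noise_scale))
  cat(sprintf("  resistivity %g Ohm cm at 50 kHz, composition exponent %g\n",
              x$resistivity$rho0, x$resistivity$gamma))
  invisible(x)
}

# inverse-CDF truncated normal draw (exact, no rejection)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a cohort from a [cohort_spec()] and returns both the
#' observable cohort table (the wide CSV layout consumed by the rest of
#' the pipeline) and the unobservable ground truth (true FFM, fat
#' fraction, per-subject resistivity, noise-free resistance), which is
#' what parameter-recovery and pipeline-closure checks compare against.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with
#'   `cohort` (data.frame, one row per subject, columns `subject_id`,
#'   `sex` (M/F), `age`, `height_cm`, `tbm_kg`,
#'   `shoulder_circ_{l,r}_cm`, `wrist_circ_{l,r}_cm`,
#'   `arm_length_{l,r}_cm`, `ffm_dexa_kg`, and one
#'   `z_{freq}khz_{pos}_rep{k}_ohm` column per reading),
#'   `truth` (data.frame with `subject_id`, `ffm_true_kg`,
#'   `fat_fraction`, `arm_fat_fraction`, `resistivity_ohm_cm`,
#'   `total_arm_volume_cm3`, `r_clean_50c_ohm`, `bi_clean_50c`), and
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  male <- if (identical(spec$sex_sampling, "bernoulli"))
    stats::runif(n) < spec$sex_ratio
  else
    sample(rep(c(TRUE, FALSE),
               c(round(n * spec$sex_ratio),
                 n - round(n * spec$sex_ratio))))
  draw <- function(field) {
    out <- numeric(n)
    for (is_m in c(TRUE, FALSE)) {
      p <- if (is_m) spec$male[[field]] else spec$female[[field]]
      k <- sum(male == is_m)
      if (k) out[male == is_m] <-
          rtruncnorm(k, p["mean"], p["sd"], p["min"], p["max"])
    }
    out
  }
  age <- draw("age")
  height <- draw("height")
  fat <- draw("fat")
  bmi_base <- ifelse(male, spec$male$bmi_base, spec$female$bmi_base)
  bmi_sd <- ifelse(male, spec$male$bmi_sd, spec$female$bmi_sd)
  bmi <- bmi_base + spec$bmi_fat_slope * fat + stats::rnorm(n, 0, bmi_sd)
  bmi <- pmin(pmax(bmi, spec$bmi_range[1]), spec$bmi_range[2])
  tbm <- bmi * (height / 100)^2
  al <- spec$allometry
  arm_base <- ifelse(male, spec$male$arm_base, spec$female$arm_base)
  c1 <- arm_base + al$shoulder_height * height + al$shoulder_fat * fat +
    stats::rnorm(n, 0, al$shoulder_sd)
  c2 <- al$wrist_base + al$wrist_height * height + al$wrist_fat * fat +
    stats::rnorm(n, 0, al$wrist_sd)
  len <- al$length_height * height + stats::rnorm(n, 0, al$length_sd)
  side <- function(x) x + stats::rnorm(n, 0, al$side_sd)
  c1_l <- side(c1); c1_r <- side(c1)
  c2_l <- pmin(side(c2), c1_l); c2_r <- pmin(side(c2), c1_r)
  len_l <- side(len); len_r <- side(len)
  vol <- frustum_volume(c1_l, c2_l, len_l) +
    frustum_volume(c1_r, c2_r, len_r)

  rs <- spec$resistivity
  shift <- ifelse(male, spec$male$arm_fat_shift, spec$female$arm_fat_shift)
  arm_fat <- pmax(fat - shift, rs$min_arm_fat)
  rho <- rs$rho0 * (1 / (1 - arm_fat))^rs$gamma
  r_clean_50 <- rho * 4 * pi * (len_l / (c1_l * c2_l) +
                                  len_r / (c1_r * c2_r)) +
    rs$torso_resistance

  freqs <- c(10, 50, 100)
  poss <- c("a", "b", "c")
  readings <- list()
  for (f in freqs) {
    for (p in poss) {
      base <- r_clean_50 * rs$freq_scale[[as.character(f)]] +
        rs$pos_offset[[p]]
      csd <- rs$cond_noise_sd[as.character(f), p] * spec$noise_scale
      cond <- base + stats::rnorm(n, 0, csd)
      for (k in 1:5) {
        rep_r <- cond + stats::rnorm(n, 0,
                                     rs$replicate_noise_sd * spec$noise_scale)
        readings[[sprintf("z_%dkhz_%s_rep%d_ohm", f, p, k)]] <- pmax(rep_r, 1)
      }
    }
  }

  bi_clean <- height^2 / r_clean_50
  ffm_true <- switch(spec$ffm_rule,
                     body_comp = tbm * (1 - fat),
                     ttc_published = predict_ffm_ttc(vol / 1e6, bmi, tbm,
                                                     bi_clean))
  ffm_dexa <- ffm_true +
    stats::rnorm(n, 0, spec$dexa_noise_sd * spec$noise_scale)

  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       sex = ifelse(male, "M", "F"),
                       age = age, height_cm = height, tbm_kg = tbm,
                       shoulder_circ_l_cm = c1_l,
                       shoulder_circ_r_cm = c1_r,
                       wrist_circ_l_cm = c2_l, wrist_circ_r_cm = c2_r,
                       arm_length_l_cm = len_l, arm_length_r_cm = len_r,
                       ffm_dexa_kg = ffm_dexa,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(readings))
  truth <- data.frame(subject_id = cohort$subject_id,
                      ffm_true_kg = ffm_true, fat_fraction = fat,
                      arm_fat_fraction = arm_fat,
                      resistivity_ohm_cm = rho,
                      total_arm_volume_cm3 = vol,
                      r_clean_50c_ohm = r_clean_50,
                      bi_clean_50c = bi_clean,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  co <- x$cohort
  cat(sprintf("Synthetic BIA cohort: %d subjects (%d male), seed %s\n",
              nrow(co), sum(co$sex == "M"), format(x$spec$seed)))
  cat(sprintf("  TBM %.2f +/- %.2f kg, height %.1f +/- %.1f cm\n",
              mean(co$tbm_kg), stats::sd(co$tbm_kg),
              mean(co$height_cm), stats::sd(co$height_cm)))
  v <- total_arm_volume_cols(co)
  r50c <- aggregate_readings(co, 50, "c")
  cat(sprintf("  total arm volume %.0f +/- %.0f cm^3, Re(Z) 50 kHz pos c %.1f +/- %.1f Ohm\n",
              mean(v), stats::sd(v), mean(r50c), stats::sd(r50c)))
  invisible(x)
}

# total arm volume from the wide cohort columns
total_arm_volume_cols <- function(cohort) {
  frustum_volume(cohort$shoulder_circ_l_cm, cohort$wrist_circ_l_cm,
                 cohort$arm_length_l_cm) +
    frustum_volume(cohort$shoulder_circ_r_cm, cohort$wrist_circ_r_cm,
                   cohort$arm_length_r_cm)
}

#' Aggregate replicate impedance readings for one condition
#'
#' Collapses the five replicate resistance readings of a
#' (frequency, position) condition to one value per subject. The
#' median is the default aggregator for robustness to single outlying
#' replicates.
#'
#' @param cohort cohort data.frame in the wide layout.
#' @param frequency 10, 50 or 100 (kHz).
#' @param position "a", "b" or "c".
#' @param agg aggregation function across replicates.
#' @return Numeric vector, one resistance (Ohm) per subject.
#' @export
aggregate_readings <- function(cohort, frequency, position, agg = stats::median) {
  stopifnot(frequency %in% c(10, 50, 100), position %in% c("a", "b", "c"))
  cols <- sprintf("z_%dkhz_%s_rep%d_ohm", frequency, position, 1:5)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort lacks reading column(s) for condition (", frequency,
         " kHz, position ", position, "): ",
         paste(missing, collapse = ", "))
  apply(as.matrix(cohort[cols]), 1, agg)
}

#' Derive model features from a cohort at one measurement condition
#'
#' Computes, per subject: sex code (1 male / 0 female), BMI, total arm
#' volume (cm^3 and m^3), the replicate-aggregated resistance of the
#' requested condition, and the bioimpedance index. The `arm_volume`
#' column is in m^3, the unit the TTC equation consumes.
#'
#' @inheritParams aggregate_readings
#' @return A data.frame with columns `subject_id`, `sex`, `age`,
#'   `height`, `tbm`, `bmi`, `arm_volume` (m^3), `arm_volume_cm3`,
#'   `resistance`, `bi`, and `ffm_ref` (NA when the cohort has no
#'   reference column).
#' @export
derive_features <- function(cohort, frequency = 50, position = "c",
                            agg = stats::median) {
  need <- c("subject_id", "sex", "age", "height_cm", "tbm_kg",
            "shoulder_circ_l_cm", "shoulder_circ_r_cm",
            "wrist_circ_l_cm", "wrist_circ_r_cm",
            "arm_length_l_cm", "arm_length_r_cm")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  r <- aggregate_readings(cohort, frequency, position, agg)
  vol <- total_arm_volume_cols(cohort)
  data.frame(subject_id = cohort$subject_id,
             sex = as.numeric(cohort$sex == "M"),
             age = cohort$age,
             height = cohort$height_cm,
             tbm = cohort$tbm_kg,
             bmi = compute_bmi(cohort$tbm_kg, cohort$height_cm),
             arm_volume = vol / 1e6,
             arm_volume_cm3 = vol,
             resistance = r,
             bi = bioimpedance_index(cohort$height_cm, r),
             ffm_ref = if ("ffm_dexa_kg" %in% names(cohort))
               cohort$ffm_dexa_kg else NA_real_,
             stringsAsFactors = FALSE)
}

#' Diagnostic validation of a cohort against its spec targets
#'
#' Compares generated marginals with the population targets implied by
#' the spec (means checked within `z_tol` standard errors at the
#' cohort's n) and checks structural invariants: FFM strictly below
#' TBM for every subject, and mean resistance ordering
#' 10 kHz >= 50 kHz >= 100 kHz (allowing a small slack for sampling
#' noise in the expectation-level ordering).
#'
#' @param cohort cohort data.frame (wide layout, reference column
#'   required for the FFM checks).
#' @param spec the [cohort_spec()] the cohort is checked against.
#' @param z_tol tolerance in standard errors for mean checks.
#' @param ordering_slack absolute slack (Ohm) for the frequency
#'   ordering check.
#' @return A data.frame with columns `check`, `observed`, `target`,
#'   `tolerance`, `pass`.
#' @export
validate_cohort <- function(cohort, spec = cohort_spec(), z_tol = 2,
                            ordering_slack = 5) {
  stopifnot(nrow(cohort) >= 1)
  n <- nrow(cohort)
  rows <- list()
  add <- function(check, observed, target, tolerance, pass) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, observed = observed, target = target,
      tolerance = tolerance, pass = pass, stringsAsFactors = FALSE)
  }
  mean_check <- function(check, x, target_mean, target_sd) {
    tol <- z_tol * target_sd / sqrt(n)
    add(check, mean(x), target_mean, tol,
        abs(mean(x) - target_mean) <= tol)
  }
  # population-level targets (mean +/- SD of the emulated study group)
  mean_check("mean TBM (kg)", cohort$tbm_kg, 69.56, 11.29)
  mean_check("mean height (cm)", cohort$height_cm, 171.89, 8.86)
  mean_check("mean total arm volume (cm^3)", total_arm_volume_cols(cohort),
             6109.06, 1505.04)
  is_m <- cohort$sex == "M"
  if ("ffm_dexa_kg" %in% names(cohort)) {
    mean_check("mean reference FFM (kg)", cohort$ffm_dexa_kg, 50.99, 10.94)
    fatp <- 100 * (1 - cohort$ffm_dexa_kg / cohort$tbm_kg)
    if (any(is_m)) {
      tol <- z_tol * spec$male$fat["sd"] * 100 / sqrt(sum(is_m))
      add("mean male fat (%)", mean(fatp[is_m]),
          100 * spec$male$fat["mean"], tol,
          abs(mean(fatp[is_m]) - 100 * spec$male$fat["mean"]) <= tol)
    }
    if (any(!is_m)) {
      tol <- z_tol * spec$female$fat["sd"] * 100 / sqrt(sum(!is_m))
      add("mean female fat (%)", mean(fatp[!is_m]),
          100 * spec$female$fat["mean"], tol,
          abs(mean(fatp[!is_m]) - 100 * spec$female$fat["mean"]) <= tol)
    }
    add("FFM < TBM for all subjects",
        sum(cohort$ffm_dexa_kg >= cohort$tbm_kg), 0, 0,
        all(cohort$ffm_dexa_kg < cohort$tbm_kg))
  }
  rbar <- vapply(c(10, 50, 100), function(f) {
    mean(vapply(c("a", "b", "c"),
                function(p) mean(aggregate_readings(cohort, f, p)),
                numeric(1)))
  }, numeric(1))
  add("resistance ordering 10 >= 50 kHz (Ohm diff)", rbar[1] - rbar[2], 0,
      ordering_slack, rbar[1] - rbar[2] >= -ordering_slack)
  add("resistance ordering 50 >= 100 kHz (Ohm diff)", rbar[2] - rbar[3], 0,
      ordering_slack, rbar[2] - rbar[3] >= -ordering_slack)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' The on-disk format is the wide one-row-per-subject CSV produced by
#' [generate_cohort()]; `read_cohort` validates the presence of the
#' anthropometric columns and at least one impedance reading column.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort`
#'   returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "height_cm", "tbm_kg",
            "shoulder_circ_l_cm", "shoulder_circ_r_cm",
            "wrist_circ_l_cm", "wrist_circ_r_cm",
            "arm_length_l_cm", "arm_length_r_cm")
  missing <- setdiff(need, names(co))
  if (length(missing))
    stop("cohort CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (!any(grepl("^z_\\d+khz_[abc]_rep\\d_ohm$", names(co))))
    stop("cohort CSV has no impedance reading columns (z_*khz_*_rep*_ohm)")
  co
}
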