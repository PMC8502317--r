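#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure the scoring schema assumes: parents
#' nested in cohort x school arms with unequal activity offerings, partial
#' uptake that falls with activity burden, and a configurable rank
#' dependence between a parent's latent engagement propensity and their
#' youth's baseline BMI percentile.
#'
#' Each parent draws a latent propensity `theta ~ Beta(propensity_shape)`.
#' An offered activity is attempted with probability
#' `plogis(qlogis(uptake_base) + propensity_scale * theta -
#' burden_slope * intensity_factor)`; attempted activities receive raw
#' counts uniform over their valid values. Youth baseline BMI percentile is
#' tied to `theta` through a Gaussian copula with correlation
#' `bmi_dependence` and a normal marginal (`bmi_mean`, `bmi_sd`) clipped to
#' (1, 99); later timepoints drift by `time_drift` per step plus
#' measurement noise.
#'
#' @param seed Integer RNG seed; a fixed seed makes the whole cohort
#'   bit-reproducible.
#' @param n_parents_per_arm Parents simulated in each arm.
#' @param propensity_shape Length-2 positive vector: Beta shape parameters
#'   of the latent propensity.
#' @param propensity_scale How strongly propensity raises the attempt
#'   log-odds.
#' @param burden_slope How strongly a higher intensity factor suppresses
#'   the attempt probability (log-odds per intensity point).
#' @param uptake_base Baseline attempt probability, in (0, 1), for a
#'   zero-burden activity at propensity 0.
#' @param bmi_dependence Target Gaussian-copula correlation, in \[-1, 1\],
#'   between propensity and baseline BMI percentile (negative values make
#'   engaged parents' youth leaner).
#' @param bmi_mean,bmi_sd Normal marginal of the baseline BMI percentile
#'   before clipping to (1, 99).
#' @param time_drift Additive drift of the BMI percentile per timepoint.
#' @param bmi_noise_sd SD of the measurement noise added at the two
#'   follow-up timepoints.
#' @param classrooms_per_school Classrooms per cohort x school cell;
#'   labels are globally unique.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_parents_per_arm = 16,
                              propensity_shape = c(2, 2),
                              propensity_scale = 4.5,
                              burden_slope = 0.6,
                              uptake_base = 0.06,
                              bmi_dependence = 0,
                              bmi_mean = 56.6,
                              bmi_sd = 30.1,
                              time_drift = 0,
                              bmi_noise_sd = 2,
                              classrooms_per_school = 2) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (length(propensity_shape) != 2 || any(propensity_shape <= 0)) {
    stop("`propensity_shape` must be two positive numbers", call. = FALSE)
  }
  if (n_parents_per_arm < 1) stop("`n_parents_per_arm` must be positive", call. = FALSE)
  if (uptake_base <= 0 || uptake_base >= 1) {
    stop("`uptake_base` must lie in (0, 1)", call. = FALSE)
  }
  if (abs(bmi_dependence) > 1) {
    stop("`bmi_dependence` must lie in [-1, 1]", call. = FALSE)
  }
  if (bmi_sd <= 0 || bmi_noise_sd < 0) {
    stop("`bmi_sd` must be positive and `bmi_noise_sd` non-negative", call. = FALSE)
  }
  if (classrooms_per_school < 1) {
    stop("`classrooms_per_school` must be positive", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_parents_per_arm = as.integer(n_parents_per_arm),
      propensity_shape = as.numeric(propensity_shape),
      propensity_scale = as.numeric(propensity_scale),
      burden_slope = as.numeric(burden_slope),
      uptake_base = as.numeric(uptake_base),
      bmi_dependence = as.numeric(bmi_dependence),
      bmi_mean = as.numeric(bmi_mean),
      bmi_sd = as.numeric(bmi_sd),
      time_drift = as.numeric(time_drift),
      bmi_noise_sd = as.numeric(bmi_noise_sd),
      classrooms_per_school = as.integer(classrooms_per_school)
    ),
    class = "simulation_config"
  )
}

#' Generate a seeded synthetic cohort
#'
#' @param config A [simulation_config()].
#' @param catalog An [engagement_catalog()]; defaults to the packaged
#'   canonical catalog.
#' @return A list with `participation` (tidy rows ready for
#'   [validate_participation()], which they pass with zero rejects),
#'   `outcomes` (one row per parent, [validate_outcomes()]-clean), and
#'   `truth` (latent propensity and per-parent generating values).
#' @export
#' @examples
#' sim <- generate_cohort(simulation_config(seed = 1, n_parents_per_arm = 4))
#' head(sim$participation)
generate_cohort <- function(config, catalog = build_default_catalogs()) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be a simulation_config", call. = FALSE)
  }
  stopifnot(inherits(catalog, "engagement_catalog"))
  set.seed(config$seed)

  part_rows <- list()
  out_rows <- list()
  truth_rows <- list()
  a <- config$propensity_shape[1]; b <- config$propensity_shape[2]
  base_logit <- stats::qlogis(config$uptake_base)

  for (i in seq_len(nrow(catalog$arms))) {
    arm <- get_arm(catalog, catalog$arms$cohort[i], catalog$arms$school[i])
    n <- config$n_parents_per_arm
    pid <- sprintf("c%ss%s_p%03d", arm$cohort, arm$school, seq_len(n))
    theta <- stats::rbeta(n, a, b)
    classroom <- sprintf("c%ss%s_cl%d", arm$cohort, arm$school,
                         sample.int(config$classrooms_per_school, n, replace = TRUE))

    for (nm in arm$offered) {
      act <- arm$activities[[nm]]
      rule <- act$frequency
      p <- stats::plogis(base_logit + config$propensity_scale * theta -
                           config$burden_slope * act$intensity_factor)
      att <- which(stats::runif(n) < p)
      if (!length(att)) next
      if (rule$kind == "per_timepoint_binned") {
        maxc <- max(rule$bins$hi)
        cts <- matrix(
          sample.int(maxc + 1L, rule$timepoints * length(att), replace = TRUE) - 1L,
          nrow = rule$timepoints
        )
        zero <- which(colSums(cts) == 0L) # an attempt implies >= 1 nonzero timepoint
        for (z in zero) {
          cts[sample.int(rule$timepoints, 1L), z] <- sample.int(maxc, 1L)
        }
        nz <- which(cts > 0L, arr.ind = TRUE)
        part_rows[[length(part_rows) + 1L]] <- tibble::tibble(
          parent_id = pid[att][nz[, "col"]], cohort = arm$cohort,
          school = arm$school, activity = nm,
          timepoint = as.integer(nz[, "row"]),
          count = as.numeric(cts[nz])
        )
      } else {
        maxc <- if (rule$kind == "per_occasion") rule$max_occasions else max(rule$bins$hi)
        part_rows[[length(part_rows) + 1L]] <- tibble::tibble(
          parent_id = pid[att], cohort = arm$cohort, school = arm$school,
          activity = nm, timepoint = NA_integer_,
          count = as.numeric(sample.int(maxc, length(att), replace = TRUE))
        )
      }
    }

    # Gaussian copula: rank of theta carried to a normal BMI marginal
    z_theta <- stats::qnorm(stats::pbeta(theta, a, b))
    rho <- config$bmi_dependence
    z_bmi <- rho * z_theta + sqrt(1 - rho^2) * stats::rnorm(n)
    clip <- function(x) pmin(pmax(x, 1), 99)
    t0 <- clip(config$bmi_mean + config$bmi_sd * z_bmi)
    t1 <- clip(t0 + config$time_drift + stats::rnorm(n, 0, config$bmi_noise_sd))
    t2 <- clip(t0 + 2 * config$time_drift + stats::rnorm(n, 0, config$bmi_noise_sd))

    out_rows[[i]] <- tibble::tibble(
      parent_id = pid, cohort = arm$cohort, school = arm$school,
      classroom = classroom, treatment = arm$treatment,
      bmi_percentile_t0 = t0, bmi_percentile_t1 = t1, bmi_percentile_t2 = t2,
      parent_bmi = stats::rnorm(n, 26.1, 5.8)
    )
    truth_rows[[i]] <- tibble::tibble(
      parent_id = pid, cohort = arm$cohort, school = arm$school,
      theta = theta, z_bmi = z_bmi
    )
  }

  participation <- if (length(part_rows)) dplyr::bind_rows(part_rows) else
    tibble::tibble(parent_id = character(), cohort = character(),
                   school = character(), activity = character(),
                   timepoint = integer(), count = numeric())
  truth <- dplyr::bind_rows(truth_rows)
  attr(truth, "config") <- config
  list(
    participation = participation,
    outcomes = validate_outcomes(dplyr::bind_rows(out_rows)),
    truth = truth
  )
}

#' Worked-example participation fixture
#'
#' The four sample parents used to illustrate the scoring arithmetic, one
#' per arm layout:
#'
#' * **A** -- control arm offering only the parent survey; completed 2
#'   surveys.
#' * **B** -- control arm offering About Eating and surveys; completed 4
#'   lessons and 1 survey.
#' * **C** -- intervention arm offering 5 activities; completed 3 surveys,
#'   youth diet assessments with 2 recalls at each of 3 timepoints, and 1
#'   About Eating lesson.
#' * **D** -- intervention arm offering all 8 activities; completed 5
#'   action packs, 4 About Eating lessons, 2 surveys, parent diet
#'   assessments with 2 recalls at 2 timepoints, and youth diet
#'   assessments with 3 recalls at 2 timepoints.
#'
#' @return A tidy participation tibble that validates against
#'   [build_default_catalogs()] with zero rejects.
#' @export
fixture_table3 <- function() {
  dplyr::bind_rows(
    tibble::tibble(parent_id = "example_A", cohort = "1", school = "2",
                   activity = "parent_survey", timepoint = NA_integer_, count = 2),
    tibble::tibble(parent_id = "example_B", cohort = "1", school = "4",
                   activity = c("about_eating", "parent_survey"),
                   timepoint = NA_integer_, count = c(4, 1)),
    tibble::tibble(parent_id = "example_C", cohort = "3", school = "5",
                   activity = c("parent_survey", rep("youth_diet_assessment", 3),
                                "about_eating"),
                   timepoint = c(NA, 1L, 2L, 3L, NA),
                   count = c(3, 2, 2, 2, 1)),
    tibble::tibble(parent_id = "example_D", cohort = "2", school = "8",
                   activity = c("action_packs", "about_eating", "parent_survey",
                                rep("parent_diet_assessment", 2),
                                rep("youth_diet_assessment", 2)),
                   timepoint = c(NA, NA, NA, 1L, 2L, 1L, 2L),
                   count = c(5, 4, 2, 2, 2, 3, 3))
  )
}
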