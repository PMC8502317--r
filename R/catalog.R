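#' Burden profile of an engagement activity
#'
#' The five effort-related attributes from which an activity's intensity
#' factor is derived: whether participation was compensated, whether the
#' parent had to leave home (activities done at home or over the internet
#' count as not away), whether the child had to be involved, the estimated
#' time per engagement episode, and whether personal information was
#' requested.
#'
#' @param incentivized Logical; was participation compensated or materially
#'   incentivized?
#' @param away_from_home Logical; did the activity require leaving home?
#'   Internet activities done at home count as `FALSE`.
#' @param involves_child Logical; did the activity require engaging with the
#'   child?
#' @param duration_hours Non-negative numeric; estimated time per episode, in
#'   hours.
#' @param personal_info Logical; was personal information requested?
#'
#' @return An object of class `burden_profile`.
#' @seealso [intensity_factor()]
#' @export
#' @examples
#' b <- burden_profile(
#'   incentivized = TRUE, away_from_home = TRUE, involves_child = TRUE,
#'   duration_hours = 2, personal_info = FALSE
#' )
#' intensity_factor(b)
burden_profile <- function(incentivized, away_from_home, involves_child,
                           duration_hours, personal_info) {
  for (flag in list(incentivized, away_from_home, involves_child, personal_info)) {
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag)) {
      stop("burden flags must be single non-missing logicals", call. = FALSE)
    }
  }
  if (!is.numeric(duration_hours) || length(duration_hours) != 1L ||
      is.na(duration_hours) || duration_hours < 0) {
    stop("`duration_hours` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(
      incentivized = incentivized,
      away_from_home = away_from_home,
      involves_child = involves_child,
      duration_hours = as.numeric(duration_hours),
      personal_info = personal_info
    ),
    class = "burden_profile"
  )
}

#' Intensity factor of an activity
#'
#' Scores the burden of an activity on a 0--5 integer scale: one point for
#' being unpaid, one for requiring the parent to leave home, one for
#' involving the child, one for taking at least 30 minutes (0.5 h), and one
#' for requesting personal information. Incentivized activities earn no
#' effort credit for the incentive attribute.
#'
#' @param burden A [burden_profile()].
#' @return Integer in 0..5.
#' @export
#' @examples
#' # family fun nights: away from home, involves child, two hours
#' intensity_factor(burden_profile(TRUE, TRUE, TRUE, 2, FALSE))
intensity_factor <- function(burden) {
  if (!inherits(burden, "burden_profile")) {
    burden <- do.call(burden_profile, burden)
  }
  as.integer(
    (!burden$incentivized) +
      burden$away_from_home +
      burden$involves_child +
      (burden$duration_hours >= 0.5) +
      burden$personal_info
  )
}

#' Frequency-point rule for an activity
#'
#' Converts raw participation counts into frequency points. Three kinds are
#' supported:
#'
#' * `per_occasion`: one point per occasion, up to `max_occasions`
#'   (e.g. one point per survey completed, maximum 3).
#' * `binned`: a count range maps to a point value (e.g. 1--3 action packs =
#'   1 point, 4--6 = 2, 7--10 = 3).
#' * `per_timepoint_binned`: a binned rule applied independently at each of
#'   `timepoints` timepoints, with the per-timepoint points summed (e.g. at
#'   each of 3 timepoints, 1 diet recall = 1 point, 2 or 3 recalls = 2).
#'
#' Bins must start at 1, be contiguous and non-overlapping, and carry
#' non-decreasing point values; this is validated at construction because a
#' silently mis-specified bin corrupts every downstream index.
#'
#' @param kind One of `"per_occasion"`, `"binned"`, `"per_timepoint_binned"`.
#' @param max_occasions Positive integer; maximum creditable occasions
#'   (`per_occasion` only).
#' @param bins Data frame with columns `lo`, `hi`, `points` (binned kinds).
#' @param timepoints Positive integer; number of timepoints
#'   (`per_timepoint_binned` only).
#'
#' @return An object of class `frequency_rule`.
#' @seealso [frequency_points()]
#' @export
frequency_rule <- function(kind = c("per_occasion", "binned", "per_timepoint_binned"),
                           max_occasions = NULL, bins = NULL, timepoints = NULL) {
  kind <- match.arg(kind)
  if (kind == "per_occasion") {
    if (is.null(max_occasions) || max_occasions < 1 ||
        max_occasions != as.integer(max_occasions)) {
      stop("`max_occasions` must be a positive integer", call. = FALSE)
    }
    rule <- list(kind = kind, max_occasions = as.integer(max_occasions))
  } else {
    bins <- as.data.frame(bins)
    if (!all(c("lo", "hi", "points") %in% names(bins)) || nrow(bins) == 0) {
      stop("`bins` must have columns lo, hi, points", call. = FALSE)
    }
    bins <- bins[order(bins$lo), c("lo", "hi", "points"), drop = FALSE]
    if (bins$lo[1] != 1L) {
      stop("bins must cover raw counts starting at 1", call. = FALSE)
    }
    if (any(bins$hi < bins$lo)) {
      stop("each bin needs lo <= hi", call. = FALSE)
    }
    if (nrow(bins) > 1 && any(bins$lo[-1] != bins$hi[-nrow(bins)] + 1L)) {
      stop("bins must be contiguous and non-overlapping", call. = FALSE)
    }
    if (any(diff(bins$points) < 0)) {
      stop("bin points must be non-decreasing with the raw count", call. = FALSE)
    }
    rule <- list(kind = kind, bins = bins)
    if (kind == "per_timepoint_binned") {
      if (is.null(timepoints) || timepoints < 1 ||
          timepoints != as.integer(timepoints)) {
        stop("`timepoints` must be a positive integer", call. = FALSE)
      }
      rule$timepoints <- as.integer(timepoints)
    }
  }
  structure(rule, class = "frequency_rule")
}

#' @rdname frequency_rule
#' @param rule A `frequency_rule`.
#' @return `rule_max_points()`: the maximum attainable frequency points;
#'   `rule_max_count()`: the maximum creditable raw count (per timepoint for
#'   `per_timepoint_binned` rules).
#' @export
rule_max_points <- function(rule) {
  switch(rule$kind,
    per_occasion = rule$max_occasions,
    binned = max(rule$bins$points),
    per_timepoint_binned = rule$timepoints * max(rule$bins$points)
  )
}

#' @rdname frequency_rule
#' @export
rule_max_count <- function(rule) {
  switch(rule$kind,
    per_occasion = rule$max_occasions,
    binned = max(rule$bins$hi),
    per_timepoint_binned = max(rule$bins$hi)
  )
}

#' Frequency points earned for raw participation counts
#'
#' @param rule A [frequency_rule()].
#' @param counts Raw counts: a single total for `per_occasion` and `binned`
#'   rules, or a vector of per-timepoint counts for `per_timepoint_binned`
#'   rules (shorter vectors are treated as zero at the remaining
#'   timepoints). A count of zero earns zero points.
#' @param activity Optional activity name used in error messages.
#' @return Non-negative integer frequency points.
#' @export
#' @examples
#' packs <- frequency_rule("binned",
#'   bins = data.frame(lo = c(1, 4, 7), hi = c(3, 6, 10), points = 1:3)
#' )
#' frequency_points(packs, 7) # top bin
frequency_points <- function(rule, counts, activity = NULL) {
  label <- if (is.null(activity)) "activity" else activity
  counts <- as.numeric(counts)
  if (length(counts) == 0) return(0L)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop(sprintf("%s: counts must be non-negative integers", label), call. = FALSE)
  }
  over <- function(x, max) {
    if (any(x > max)) {
      stop(sprintf("%s: count %s exceeds the declared maximum %s",
                   label, max(x), max), call. = FALSE)
    }
  }
  bin_points <- function(x) {
    vapply(x, function(ct) {
      if (ct == 0) return(0L)
      as.integer(rule$bins$points[rule$bins$lo <= ct & ct <= rule$bins$hi])
    }, integer(1))
  }
  switch(rule$kind,
    per_occasion = {
      total <- sum(counts)
      over(total, rule$max_occasions)
      as.integer(total)
    },
    binned = {
      total <- sum(counts)
      over(total, max(rule$bins$hi))
      as.integer(bin_points(total))
    },
    per_timepoint_binned = {
      if (length(counts) > rule$timepoints) {
        stop(sprintf("%s: %d counts supplied for %d timepoints",
                     label, length(counts), rule$timepoints), call. = FALSE)
      }
      over(counts, max(rule$bins$hi))
      as.integer(sum(bin_points(counts)))
    }
  )
}

#' Define an engagement activity type
#'
#' An activity couples a frequency rule with a burden profile. Its maximum
#' weighting -- maximum frequency points times intensity factor -- is what
#' the activity can contribute to a parent's engagement intensity; in the
#' canonical eight-activity schema every weighting equals 6.
#'
#' @param name Identifier (snake_case recommended).
#' @param category `"program"` (intervention content) or `"evaluation"`
#'   (measurement task).
#' @param frequency A [frequency_rule()].
#' @param burden A [burden_profile()].
#' @param label Optional display label; defaults to `name`.
#' @return An object of class `activity_type`.
#' @export
activity_type <- function(name, category = c("program", "evaluation"),
                          frequency, burden, label = name) {
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(frequency, "frequency_rule")) {
    stop("`frequency` must be a frequency_rule", call. = FALSE)
  }
  if (!inherits(burden, "burden_profile")) {
    stop("`burden` must be a burden_profile", call. = FALSE)
  }
  fac <- intensity_factor(burden)
  if (fac == 0L) {
    warning(sprintf(
      "activity '%s' has intensity factor 0; it will contribute nothing to the PEI",
      name
    ), call. = FALSE)
  }
  structure(
    list(
      name = name, label = label, category = category,
      frequency = frequency, burden = burden,
      intensity_factor = fac
    ),
    class = "activity_type"
  )
}

#' Maximum weighting of an activity
#'
#' The product of the maximum attainable frequency points and the intensity
#' factor: the activity's ceiling contribution to the engagement-intensity
#' index.
#'
#' @param activity An [activity_type()].
#' @return Non-negative integer.
#' @export
max_weighting <- function(activity) {
  rule_max_points(activity$frequency) * activity$intensity_factor
}

#' @export
print.activity_type <- function(x, ...) {
  cat(sprintf(
    "<activity_type> %s [%s]: max %d freq points x intensity %d = weighting %d\n",
    x$name, x$category, rule_max_points(x$frequency),
    x$intensity_factor, max_weighting(x)
  ))
  invisible(x)
}

# ---- catalogs ---------------------------------------------------------------

new_engagement_catalog <- function(activities, arms, name = "custom") {
  structure(list(name = name, activities = activities, arms = arms),
            class = "engagement_catalog")
}

#' Build an engagement catalog from activities and arms
#'
#' A catalog is the scoring context: the dictionary of activity types plus
#' the arms (cohort x school cells) of the study, each offering some subset
#' of the activities. Arms within a design need not offer the same
#' activities; the per-arm maxima derived with [arm_maxima()] are the
#' divisors that make scores comparable across arms.
#'
#' @param activities List of [activity_type()] objects.
#' @param arms Data frame with columns `cohort`, `school`, `treatment`
#'   (`"control"` or `"intervention"`) and a list-column `offered` of
#'   activity-name character vectors.
#' @param name Catalog name.
#' @return An object of class `engagement_catalog`.
#' @export
engagement_catalog <- function(activities, arms, name = "custom") {
  if (!length(activities) || !all(vapply(activities, inherits, logical(1), "activity_type"))) {
    stop("`activities` must be a non-empty list of activity_type objects", call. = FALSE)
  }
  names(activities) <- vapply(activities, `[[`, character(1), "name")
  if (anyDuplicated(names(activities))) {
    stop("duplicate activity names in catalog", call. = FALSE)
  }
  arms <- tibble::as_tibble(arms)
  required <- c("cohort", "school", "treatment", "offered")
  if (!all(required %in% names(arms))) {
    stop("`arms` needs columns cohort, school, treatment, offered", call. = FALSE)
  }
  arms$cohort <- as.character(arms$cohort)
  arms$school <- as.character(arms$school)
  if (!all(arms$treatment %in% c("control", "intervention"))) {
    stop("`treatment` must be 'control' or 'intervention'", call. = FALSE)
  }
  if (anyDuplicated(paste(arms$cohort, arms$school))) {
    stop("duplicate cohort x school arm", call. = FALSE)
  }
  for (i in seq_len(nrow(arms))) {
    off <- arms$offered[[i]]
    if (!length(off)) {
      stop(sprintf("arm (cohort %s, school %s) offers no activities",
                   arms$cohort[i], arms$school[i]), call. = FALSE)
    }
    unknown <- setdiff(off, names(activities))
    if (length(unknown)) {
      stop(sprintf("arm (cohort %s, school %s) offers unknown activities: %s",
                   arms$cohort[i], arms$school[i],
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  new_engagement_catalog(activities, arms, name)
}

#' @export
print.engagement_catalog <- function(x, ...) {
  cat(sprintf("<engagement_catalog> '%s': %d activities, %d arms\n",
              x$name, length(x$activities), nrow(x$arms)))
  invisible(x)
}

parse_frequency_rule <- function(fr) {
  if (fr$kind == "per_occasion") {
    frequency_rule("per_occasion", max_occasions = fr$max_occasions)
  } else if (fr$kind == "binned") {
    frequency_rule("binned", bins = fr$bins)
  } else {
    frequency_rule("per_timepoint_binned", bins = fr$bins,
                   timepoints = fr$timepoints)
  }
}

#' Read an engagement catalog from a JSON configuration
#'
#' The configuration carries an `activities` array (name, category,
#' frequency rule, burden attributes) and an `arms` array (cohort, school,
#' treatment, offered activity names). All structural invariants --
#' frequency-bin contiguity and coverage, arm offerings being known
#' activities -- are validated at load time.
#'
#' @param path Path to a catalog JSON file.
#' @return An `engagement_catalog`.
#' @seealso [build_default_catalogs()] for the packaged canonical catalog.
#' @export
read_catalog_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  acts <- cfg$activities
  activities <- lapply(seq_len(nrow(acts)), function(i) {
    burden <- as.list(acts$burden[i, ])
    fr <- list(
      kind = acts$frequency$kind[i],
      max_occasions = acts$frequency$max_occasions[i],
      bins = if (!is.null(acts$frequency$bins)) acts$frequency$bins[[i]],
      timepoints = if (!is.null(acts$frequency$timepoints)) acts$frequency$timepoints[i]
    )
    activity_type(
      name = acts$name[i],
      category = acts$category[i],
      frequency = parse_frequency_rule(fr),
      burden = do.call(burden_profile, burden),
      label = if (!is.null(acts$label)) acts$label[i] else acts$name[i]
    )
  })
  arms <- tibble::as_tibble(cfg$arms)
  engagement_catalog(activities, arms,
                     name = if (!is.null(cfg$name)) cfg$name else "custom")
}

#' The canonical study catalog: 8 activities, 31 arms
#'
#' Loads the packaged catalog of the eight canonical activity types (four
#' program: family fun nights, action packs, recipe preparation, About
#' Eating; four evaluation: parent survey, parent and youth diet
#' assessments, accelerometry) and the 31 cohort x school arms with their
#' offered-activity sets. Cohorts 1 and 4 are control arms; cohorts 2 and 3
#' received the intervention. Cohort 4 has no school-5 arm; looking it up
#' raises an error.
#'
#' @return An `engagement_catalog`.
#' @export
#' @examples
#' cat8 <- build_default_catalogs()
#' arm_maxima(get_arm(cat8, cohort = 2, school = 8))
build_default_catalogs <- function() {
  path <- system.file("extdata", "fff_catalog.json", package = "engage",
                      mustWork = TRUE)
  read_catalog_json(path)
}

#' Look up one arm of a catalog
#'
#' @param catalog An `engagement_catalog`.
#' @param cohort,school Arm identifiers (coerced to character).
#' @return An object of class `arm_catalog` carrying the arm's treatment
#'   label, offered activity names, and the resolved activity definitions.
#' @export
get_arm <- function(catalog, cohort, school) {
  stopifnot(inherits(catalog, "engagement_catalog"))
  i <- which(catalog$arms$cohort == as.character(cohort) &
               catalog$arms$school == as.character(school))
  if (length(i) != 1L) {
    stop(sprintf("no arm for cohort %s, school %s in catalog '%s'",
                 cohort, school, catalog$name), call. = FALSE)
  }
  offered <- catalog$arms$offered[[i]]
  structure(
    list(
      cohort = catalog$arms$cohort[i],
      school = catalog$arms$school[i],
      treatment = catalog$arms$treatment[i],
      offered = offered,
      activities = catalog$activities[offered]
    ),
    class = "arm_catalog"
  )
}

#' @export
print.arm_catalog <- function(x, ...) {
  m <- arm_maxima(x)
  cat(sprintf("<arm_catalog> cohort %s, school %s (%s)\n", x$cohort, x$school,
              x$treatment))
  cat("  offered:", paste(x$offered, collapse = ", "), "\n")
  cat(sprintf("  max PPP %d (program %d, evaluation %d); max PEI %d (program %d, evaluation %d)\n",
              m$max_ppp, m$program_max_ppp, m$evaluation_max_ppp,
              m$max_pei, m$program_max_pei, m$evaluation_max_pei))
  invisible(x)
}

#' Per-arm score maxima (standardization divisors)
#'
#' The maximum participation profile (number of offered activity types) and
#' maximum engagement intensity (sum of offered activities' maximum
#' weightings), totals and program/evaluation sub-maxima. These are the
#' divisors used to standardize raw scores to the 0--1 scale, so that
#' parents facing unequal opportunity sets are compared on the fraction of
#' their own opportunities taken.
#'
#' @param arm An `arm_catalog` from [get_arm()].
#' @return Named list with `max_ppp`, `max_pei`, `program_max_ppp`,
#'   `program_max_pei`, `evaluation_max_ppp`, `evaluation_max_pei`.
#' @export
arm_maxima <- function(arm) {
  stopifnot(inherits(arm, "arm_catalog"))
  acts <- arm$activities
  cats <- vapply(acts, `[[`, character(1), "category")
  w <- vapply(acts, max_weighting, numeric(1))
  list(
    max_ppp = length(acts),
    max_pei = as.integer(sum(w)),
    program_max_ppp = sum(cats == "program"),
    program_max_pei = as.integer(sum(w[cats == "program"])),
    evaluation_max_ppp = sum(cats == "evaluation"),
    evaluation_max_pei = as.integer(sum(w[cats == "evaluation"]))
  )
}

#' Arm maxima for every arm of a catalog
#'
#' @param catalog An `engagement_catalog`.
#' @return A tibble with one row per arm: identifiers, treatment, number of
#'   offered activities, and the six maxima of [arm_maxima()].
#' @export
catalog_maxima <- function(catalog) {
  stopifnot(inherits(catalog, "engagement_catalog"))
  rows <- lapply(seq_len(nrow(catalog$arms)), function(i) {
    arm <- get_arm(catalog, catalog$arms$cohort[i], catalog$arms$school[i])
    tibble::tibble(
      cohort = arm$cohort, school = arm$school, treatment = arm$treatment,
      !!!arm_maxima(arm)
    )
  })
  dplyr::bind_rows(rows)
}
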