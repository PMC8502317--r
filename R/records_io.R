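#' Validate tidy participation rows against a catalog
#'
#' Participation logs are long (tidy): one row per parent x activity (x
#' timepoint for per-timepoint activities) with a raw count. Validation
#' checks that each row's arm exists (an unknown cohort x school is a hard
#' error: it indicates a mis-specified study layout, not a bad row), that
#' the activity is offered in the parent's arm, and that aggregated counts
#' stay within the activity's declared maxima. Offending rows are returned
#' in a rejects table with a reason; accepted and rejected rows partition
#' the input.
#'
#' @param rows Data frame with columns `parent_id`, `cohort`, `school`,
#'   `activity`, `count` and optionally `timepoint` (1-based, required for
#'   per-timepoint activities).
#' @param catalog An [engagement_catalog()].
#' @return A list with `records` (accepted rows, aggregated to one row per
#'   parent x activity x timepoint) and `rejects` (offending input rows plus
#'   a `reason` column).
#' @export
validate_participation <- function(rows, catalog) {
  stopifnot(inherits(catalog, "engagement_catalog"))
  rows <- tibble::as_tibble(rows)
  required <- c("parent_id", "cohort", "school", "activity", "count")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols)) {
    stop("participation rows lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"timepoint" %in% names(rows)) rows$timepoint <- NA_integer_
  rows$parent_id <- as.character(rows$parent_id)
  rows$cohort <- as.character(rows$cohort)
  rows$school <- as.character(rows$school)
  rows$activity <- as.character(rows$activity)
  rows$timepoint <- suppressWarnings(as.integer(rows$timepoint))
  rows$count <- as.numeric(rows$count)

  arm_keys <- paste(catalog$arms$cohort, catalog$arms$school)
  unknown_arm <- !(paste(rows$cohort, rows$school) %in% arm_keys)
  if (any(unknown_arm)) {
    bad <- rows[unknown_arm, , drop = FALSE][1, ]
    stop(sprintf("unknown arm: cohort %s, school %s", bad$cohort, bad$school),
         call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(rows))
  flag <- function(idx, why) {
    idx <- idx & is.na(reason)
    reason[idx] <<- why
  }

  known <- rows$activity %in% names(catalog$activities)
  flag(!known, "unknown activity")

  offered_map <- stats::setNames(
    lapply(seq_len(nrow(catalog$arms)), function(i) catalog$arms$offered[[i]]),
    arm_keys
  )
  offered_ok <- vapply(seq_len(nrow(rows)), function(i) {
    known[i] && rows$activity[i] %in% offered_map[[paste(rows$cohort[i], rows$school[i])]]
  }, logical(1))
  flag(known & !offered_ok, "activity not offered in arm")

  bad_count <- is.na(rows$count) | rows$count < 0 | rows$count != floor(rows$count)
  flag(bad_count, "count must be a non-negative integer")

  # per-timepoint activities need a valid timepoint label
  for (i in which(is.na(reason))) {
    act <- catalog$activities[[rows$activity[i]]]
    rule <- act$frequency
    if (rule$kind == "per_timepoint_binned") {
      if (is.na(rows$timepoint[i]) || rows$timepoint[i] < 1 ||
          rows$timepoint[i] > rule$timepoints) {
        reason[i] <- sprintf("%s requires a timepoint in 1..%d",
                             act$name, rule$timepoints)
      }
    }
  }

  # aggregate candidate rows and check totals against declared maxima
  ok <- is.na(reason)
  if (any(ok)) {
    cand <- rows[ok, , drop = FALSE]
    cand$.row <- which(ok)
    key <- paste(cand$parent_id, cand$cohort, cand$school, cand$activity,
                 ifelse(is.na(cand$timepoint), 0L, cand$timepoint))
    totals <- tapply(cand$count, key, sum)
    for (k in names(totals)) {
      idx <- cand$.row[key == k]
      act <- catalog$activities[[rows$activity[idx[1]]]]
      maxc <- rule_max_count(act$frequency)
      if (totals[[k]] > maxc) {
        reason[idx] <- sprintf("%s: count %s exceeds the declared maximum %s",
                               act$name, totals[[k]], maxc)
      }
    }
  }

  rejects <- rows[!is.na(reason), , drop = FALSE]
  rejects$reason <- reason[!is.na(reason)]
  accepted <- rows[is.na(reason), , drop = FALSE]
  if (nrow(accepted)) {
    accepted <- dplyr::summarise(
      dplyr::group_by(accepted, .data$parent_id, .data$cohort, .data$school,
                      .data$activity, .data$timepoint),
      count = sum(.data$count), .groups = "drop"
    )
    accepted <- dplyr::arrange(accepted, .data$parent_id, .data$activity,
                               .data$timepoint)
  }
  list(records = accepted, rejects = rejects)
}

#' Read a participation log
#'
#' @param path CSV with columns `parent_id`, `cohort`, `school`, `activity`,
#'   optional `timepoint`, `count` (UTF-8).
#' @param catalog An [engagement_catalog()] the rows are validated against.
#' @return As [validate_participation()]: a list with `records` and
#'   `rejects`.
#' @export
read_participation_csv <- function(path, catalog) {
  rows <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_participation(rows, catalog)
}

#' @rdname read_participation_csv
#' @param records A records tibble as returned in `$records`.
#' @export
write_participation_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read or validate youth/parent outcome tables
#'
#' Outcome rows carry the youth BMI percentile at up to three timepoints
#' (`t0` baseline, `t1` post-program, `t2` 12 months after baseline), an
#' optional parent BMI, and the school/classroom/treatment labels used for
#' adjustment and group comparison. Percentiles must lie strictly between 0
#' and 100; missing timepoints are allowed and kept as `NA`.
#'
#' @param rows Data frame with columns `parent_id`, `school`, `classroom`,
#'   `treatment`, `bmi_percentile_t0`, `bmi_percentile_t1`,
#'   `bmi_percentile_t2`, optional `parent_bmi` and `cohort`.
#' @return A tibble of validated outcome records.
#' @export
validate_outcomes <- function(rows) {
  rows <- tibble::as_tibble(rows)
  required <- c("parent_id", "school", "classroom", "treatment")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols)) {
    stop("outcome rows lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("bmi_percentile_t0", "bmi_percentile_t1", "bmi_percentile_t2")) {
    if (!col %in% names(rows)) rows[[col]] <- NA_real_
    rows[[col]] <- as.numeric(rows[[col]])
    bad <- !is.na(rows[[col]]) & (rows[[col]] <= 0 | rows[[col]] >= 100)
    if (any(bad)) {
      stop(sprintf("%s outside (0, 100) for parent_id %s", col,
                   paste(rows$parent_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  if (!"parent_bmi" %in% names(rows)) rows$parent_bmi <- NA_real_
  rows$parent_bmi <- as.numeric(rows$parent_bmi)
  if (!"cohort" %in% names(rows)) rows$cohort <- NA_character_
  if (!all(rows$treatment %in% c("control", "intervention"))) {
    stop("`treatment` must be 'control' or 'intervention'", call. = FALSE)
  }
  if (anyDuplicated(rows$parent_id)) {
    stop("duplicate parent_id in outcomes", call. = FALSE)
  }
  rows$parent_id <- as.character(rows$parent_id)
  rows$school <- as.character(rows$school)
  rows$classroom <- as.character(rows$classroom)
  rows$cohort <- as.character(rows$cohort)
  rows
}

#' @rdname validate_outcomes
#' @param path CSV path.
#' @export
read_outcomes_csv <- function(path) {
  validate_outcomes(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname validate_outcomes
#' @param outcomes A validated outcomes tibble.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}
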