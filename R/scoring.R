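#' Score one parent's participation against their arm
#'
#' Computes the two engagement indices:
#'
#' * **PPP** (participation profile): the number of distinct activity types
#'   the parent attempted, where "attempted" means nonzero frequency
#'   points.
#' * **PEI** (engagement intensity): the sum over attempted activities of
#'   frequency points times the activity's intensity factor.
#'
#' Both are standardized by the arm's maxima ([arm_maxima()]) to a fraction
#' in \[0, 1\], so parents offered different activity sets are compared on
#' the share of their own opportunities taken. Program and evaluation
#' sub-scores partition the totals; a standardized sub-score is `NA` (not
#' zero) when the arm offers no activity of that category, since the
#' divisor is undefined.
#'
#' @param counts Named list mapping offered activity names to raw counts
#'   (a scalar total, or a per-timepoint vector for per-timepoint
#'   activities). Activities absent from the list count as zero.
#' @param arm An `arm_catalog` from [get_arm()].
#' @param pd_threshold Positive-deviance threshold on the standardized
#'   index, inclusive; default 0.75.
#' @param pd_basis Which standardized index the PD flags in the output are
#'   based on is fixed (`pd_by_ppp`, `pd_by_pei` are both reported);
#'   `pd_basis` selects which of them downstream helpers treat as *the* PD
#'   flag.
#' @return A one-row tibble with raw and standardized PPP/PEI, the
#'   program/evaluation sub-scores, and PD flags.
#' @export
#' @examples
#' cat8 <- build_default_catalogs()
#' arm <- get_arm(cat8, cohort = 1, school = 2) # surveys only
#' compute_score(list(parent_survey = 2), arm)
compute_score <- function(counts, arm, pd_threshold = 0.75,
                          pd_basis = c("ppp", "pei")) {
  stopifnot(inherits(arm, "arm_catalog"))
  pd_basis <- match.arg(pd_basis)
  counts <- as.list(counts)
  unknown <- setdiff(names(counts), arm$offered)
  if (length(unknown)) {
    stop(sprintf("counts reference activities not offered in arm (cohort %s, school %s): %s",
                 arm$cohort, arm$school, paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  per_act <- activity_points(counts, arm)
  m <- arm_maxima(arm)

  tot <- function(cat = NULL) {
    d <- if (is.null(cat)) per_act else per_act[per_act$category == cat, ]
    c(ppp = sum(d$points > 0), pei = sum(d$weighted))
  }
  std <- function(x, max) if (max > 0) x / max else NA_real_

  all_t <- tot(); prog <- tot("program"); eval_ <- tot("evaluation")
  std_ppp <- std(all_t[["ppp"]], m$max_ppp)
  std_pei <- std(all_t[["pei"]], m$max_pei)

  tibble::tibble(
    cohort = arm$cohort, school = arm$school, treatment = arm$treatment,
    ppp = as.integer(all_t[["ppp"]]), pei = as.integer(all_t[["pei"]]),
    std_ppp = std_ppp, std_pei = std_pei,
    program_ppp = as.integer(prog[["ppp"]]),
    program_pei = as.integer(prog[["pei"]]),
    evaluation_ppp = as.integer(eval_[["ppp"]]),
    evaluation_pei = as.integer(eval_[["pei"]]),
    std_program_ppp = std(prog[["ppp"]], m$program_max_ppp),
    std_program_pei = std(prog[["pei"]], m$program_max_pei),
    std_evaluation_ppp = std(eval_[["ppp"]], m$evaluation_max_ppp),
    std_evaluation_pei = std(eval_[["pei"]], m$evaluation_max_pei),
    pd_by_ppp = classify_positive_deviant(std_ppp, pd_threshold),
    pd_by_pei = classify_positive_deviant(std_pei, pd_threshold),
    pd = if (pd_basis == "ppp") pd_by_ppp else pd_by_pei
  )
}

#' Per-activity frequency points and weighted contributions
#'
#' @param counts Named list of raw counts (see [compute_score()]).
#' @param arm An `arm_catalog`.
#' @return A tibble with one row per *offered* activity: `activity`,
#'   `category`, `points` (frequency points), `weighted` (points times
#'   intensity factor).
#' @export
activity_points <- function(counts, arm) {
  rows <- lapply(arm$offered, function(nm) {
    act <- arm$activities[[nm]]
    ct <- counts[[nm]]
    pts <- if (is.null(ct)) 0L else frequency_points(act$frequency, ct, nm)
    tibble::tibble(
      activity = nm, category = act$category,
      points = pts, weighted = pts * act$intensity_factor
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify a standardized score as positive deviant
#'
#' A parent whose standardized index meets or exceeds the threshold
#' (default 75%, boundary inclusive) is a positive deviant (PD): a member
#' of the unusually highly engaged subgroup studied for transferable
#' engagement strategies.
#'
#' @param std Standardized index (fraction in \[0, 1\]); `NA` yields `FALSE`.
#' @param threshold Fraction in (0, 1\]; default 0.75.
#' @return Logical.
#' @export
classify_positive_deviant <- function(std, threshold = 0.75) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a fraction in (0, 1]", call. = FALSE)
  }
  !is.na(std) & std >= threshold
}

counts_from_records <- function(records, catalog) {
  # one parent's tidy rows -> named list of counts (per-timepoint vectors
  # for per-timepoint activities, scalars otherwise)
  out <- list()
  for (nm in unique(records$activity)) {
    act <- catalog$activities[[nm]]
    sub <- records[records$activity == nm, , drop = FALSE]
    if (act$frequency$kind == "per_timepoint_binned") {
      v <- integer(act$frequency$timepoints)
      v[sub$timepoint] <- as.integer(sub$count)
      out[[nm]] <- v
    } else {
      out[[nm]] <- sum(sub$count)
    }
  }
  out
}

#' Score a whole cohort of parents
#'
#' Joins validated participation records with outcome records and scores
#' every parent against their arm. Parents present only in the outcomes
#' table are retained with zero engagement (youth without participating
#' parents are part of the analysis population); parents present only in
#' the participation log are retained with missing outcomes.
#'
#' @param records Accepted participation rows from
#'   [validate_participation()] / [read_participation_csv()].
#' @param catalog An [engagement_catalog()].
#' @param outcomes Optional validated outcomes tibble
#'   ([validate_outcomes()]). Zero-engagement parents found there are
#'   scored against the arm given by their `cohort`/`school` columns when
#'   present.
#' @param pd_threshold,pd_basis Passed to [compute_score()].
#' @return A tibble with one row per parent: identifiers, arm metadata,
#'   all score components, per-activity frequency points (`pts_<activity>`)
#'   and weighted contributions (`pei_<activity>`), and any outcome
#'   columns.
#' @export
score_cohort <- function(records, catalog, outcomes = NULL,
                         pd_threshold = 0.75, pd_basis = c("ppp", "pei")) {
  stopifnot(inherits(catalog, "engagement_catalog"))
  pd_basis <- match.arg(pd_basis)
  records <- tibble::as_tibble(records)

  if (nrow(records)) {
    arms_per_parent <- unique(records[, c("parent_id", "cohort", "school")])
    if (anyDuplicated(arms_per_parent$parent_id)) {
      dup <- arms_per_parent$parent_id[duplicated(arms_per_parent$parent_id)]
      stop("parent_id mapped to more than one arm: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  } else {
    arms_per_parent <- tibble::tibble(parent_id = character(),
                                      cohort = character(),
                                      school = character())
  }

  # zero-engagement parents from the outcomes table
  if (!is.null(outcomes)) {
    extra <- outcomes[!(outcomes$parent_id %in% arms_per_parent$parent_id), ,
                      drop = FALSE]
    if (nrow(extra)) {
      arms_per_parent <- dplyr::bind_rows(
        arms_per_parent,
        tibble::tibble(parent_id = extra$parent_id, cohort = extra$cohort,
                       school = extra$school)
      )
    }
  }

  act_names <- names(catalog$activities)
  categories <- vapply(catalog$activities, `[[`, character(1), "category")

  # per parent x activity frequency points, vectorized per activity; this is
  # the same arithmetic as compute_score(), which tests use as the
  # one-parent reference
  bin_lookup <- function(bins, x) {
    pts <- integer(length(x))
    nz <- x > 0
    pts[nz] <- bins$points[findInterval(x[nz], bins$lo)]
    pts
  }
  pts_long <- dplyr::bind_rows(lapply(act_names, function(nm) {
    sub <- records[records$activity == nm, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    rule <- catalog$activities[[nm]]$frequency
    if (rule$kind == "per_timepoint_binned") {
      agg <- tapply(bin_lookup(rule$bins, sub$count), sub$parent_id, sum)
    } else if (rule$kind == "binned") {
      tot <- tapply(sub$count, sub$parent_id, sum)
      agg <- stats::setNames(bin_lookup(rule$bins, as.numeric(tot)), names(tot))
    } else {
      agg <- tapply(sub$count, sub$parent_id, sum)
    }
    tibble::tibble(parent_id = names(agg), activity = nm,
                   points = as.integer(agg))
  }))

  scores <- tibble::as_tibble(arms_per_parent)
  maxima <- catalog_maxima(catalog)
  scores <- dplyr::left_join(scores, maxima, by = c("cohort", "school"))

  pts_mat <- matrix(0L, nrow(scores), length(act_names),
                    dimnames = list(scores$parent_id, act_names))
  if (nrow(pts_long)) {
    pts_mat[cbind(match(pts_long$parent_id, scores$parent_id),
                  match(pts_long$activity, act_names))] <- pts_long$points
  }
  fac <- vapply(catalog$activities, `[[`, integer(1), "intensity_factor")
  pei_mat <- sweep(pts_mat, 2, fac, `*`)
  is_prog <- categories == "program"

  std <- function(x, max) ifelse(!is.na(max) & max > 0, x / max, NA_real_)
  scores$ppp <- as.integer(rowSums(pts_mat > 0))
  scores$pei <- as.integer(rowSums(pei_mat))
  scores$std_ppp <- ifelse(is.na(scores$max_ppp) & scores$ppp == 0, 0,
                           scores$ppp / scores$max_ppp)
  scores$std_pei <- ifelse(is.na(scores$max_pei) & scores$pei == 0, 0,
                           scores$pei / scores$max_pei)
  scores$program_ppp <- as.integer(rowSums(pts_mat[, is_prog, drop = FALSE] > 0))
  scores$program_pei <- as.integer(rowSums(pei_mat[, is_prog, drop = FALSE]))
  scores$evaluation_ppp <- as.integer(rowSums(pts_mat[, !is_prog, drop = FALSE] > 0))
  scores$evaluation_pei <- as.integer(rowSums(pei_mat[, !is_prog, drop = FALSE]))
  scores$std_program_ppp <- std(scores$program_ppp, scores$program_max_ppp)
  scores$std_program_pei <- std(scores$program_pei, scores$program_max_pei)
  scores$std_evaluation_ppp <- std(scores$evaluation_ppp, scores$evaluation_max_ppp)
  scores$std_evaluation_pei <- std(scores$evaluation_pei, scores$evaluation_max_pei)
  scores$pd_by_ppp <- classify_positive_deviant(scores$std_ppp, pd_threshold)
  scores$pd_by_pei <- classify_positive_deviant(scores$std_pei, pd_threshold)
  scores$pd <- if (pd_basis == "ppp") scores$pd_by_ppp else scores$pd_by_pei
  scores <- scores[, setdiff(names(scores),
                             c("max_ppp", "max_pei", "program_max_ppp",
                               "program_max_pei", "evaluation_max_ppp",
                               "evaluation_max_pei"))]
  colnames(pts_mat) <- paste0("pts_", act_names)
  colnames(pei_mat) <- paste0("pei_", act_names)
  scores <- dplyr::bind_cols(scores, tibble::as_tibble(pts_mat),
                             tibble::as_tibble(pei_mat))

  if (!is.null(outcomes)) {
    keep <- setdiff(names(outcomes), c("cohort", "school", "treatment"))
    scores <- dplyr::left_join(scores, outcomes[, keep, drop = FALSE],
                               by = "parent_id")
    # treatment for outcomes-only parents comes from the outcomes table
    fill <- match(scores$parent_id, outcomes$parent_id)
    scores$treatment <- dplyr::coalesce(scores$treatment,
                                        outcomes$treatment[fill])
    scores$cohort <- dplyr::coalesce(scores$cohort, outcomes$cohort[fill])
    scores$school <- dplyr::coalesce(scores$school, outcomes$school[fill])
  }
  scores
}

#' Cohort-level engagement summary
#'
#' Means and standard deviations of the standardized indices, positive
#' deviance counts, and per-activity participation counts, overall and by
#' PD status -- the layout used to profile which activities distinguish
#' highly engaged parents.
#'
#' @param scores A score table from [score_cohort()].
#' @param participants_only Restrict summary statistics to parents with at
#'   least one attempted activity (the engaged subsample); default `TRUE`.
#' @return A list with `overall` (one-row tibble of summary statistics) and
#'   `by_activity` (per-activity participant counts, total and by PD
#'   status).
#' @export
engagement_summary <- function(scores, participants_only = TRUE) {
  eng <- if (participants_only) scores[scores$ppp > 0, , drop = FALSE] else scores
  overall <- tibble::tibble(
    n_scored = nrow(scores),
    n_participating = sum(scores$ppp > 0),
    mean_std_ppp = mean(eng$std_ppp),
    sd_std_ppp = stats::sd(eng$std_ppp),
    mean_std_pei = mean(eng$std_pei),
    sd_std_pei = stats::sd(eng$std_pei),
    n_pd = sum(eng$pd),
    n_full_participation = sum(eng$std_ppp >= 1, na.rm = TRUE)
  )
  pts_cols <- grep("^pts_", names(scores), value = TRUE)
  by_activity <- dplyr::bind_rows(lapply(pts_cols, function(col) {
    tibble::tibble(
      activity = sub("^pts_", "", col),
      n_participating = sum(eng[[col]] > 0),
      n_pd = sum(eng[[col]] > 0 & eng$pd),
      n_non_pd = sum(eng[[col]] > 0 & !eng$pd)
    )
  }))
  list(overall = overall, by_activity = by_activity)
}
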