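#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs),
#'   neither constant.
#' @return A list with `r`, `p` (two-sided, from the t transform with
#'   n - 2 df), `n`, and `df`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Independent two-group t-test
#'
#' Pooled-variance test by default (Welch by `pooled = FALSE`). When the
#' pooled variance is exactly zero the t statistic is degenerate; the
#' comparison is still reported (t = 0, p = 1 for equal means, |t| = Inf,
#' p = 0 otherwise) with a warning, so batch comparisons over many
#' variables do not abort on a constant column.
#'
#' @param x,y Numeric vectors, each with at least 2 non-missing values.
#' @param pooled Use the pooled-variance statistic (default `TRUE`).
#' @return A list of class `group_comparison`: per-group `n`, `mean`, `sd`,
#'   plus `statistic`, `df`, `p`, and `method`.
#' @export
two_group_t <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  desc <- list(n = c(length(x), length(y)),
               mean = c(mean(x), mean(y)),
               sd = c(stats::sd(x), stats::sd(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("both groups have zero variance; t statistic is degenerate",
            call. = FALSE)
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (equal) 1 else 0,
                method = if (pooled) "pooled" else "welch")
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, method = if (pooled) "pooled" else "welch")
  }
  structure(c(desc, res), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("two-group comparison (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  cat(sprintf("  group 1: n = %d, mean = %.4g, sd = %.4g\n",
              x$n[1], x$mean[1], x$sd[1]))
  cat(sprintf("  group 2: n = %d, mean = %.4g, sd = %.4g\n",
              x$n[2], x$mean[2], x$sd[2]))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on a two-way contingency table with
#' (r - 1)(c - 1) degrees of freedom; expected counts are returned and a
#' warning is raised when any expected count falls below 5.
#'
#' @param tab Matrix or table of non-negative counts with all row and
#'   column margins positive.
#' @return A list with `statistic`, `df`, `p`, `expected`, `observed`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("table must contain non-negative finite counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("some expected counts are below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected, observed = tab)
}

#' Adjust a measurement for school and classroom enrollment
#'
#' Removes additive school and classroom effects from a numeric outcome by
#' fitting a fixed-effects linear model on the factor labels and returning
#' residuals re-centered at the grand mean. Classroom labels are treated as
#' globally unique (classroom "3" of one school is distinct from classroom
#' "3" of another); callers whose labels repeat across schools should
#' prefix them. The adjustment preserves the grand mean, removes all
#' between-group variance captured by the factor coding, and is
#' idempotent. Groups represented by a single observation contribute no
#' within-group information and are flagged with a warning.
#'
#' @param x Numeric outcome (e.g. youth BMI percentile); `NA`s pass
#'   through.
#' @param school,classroom Factor labels, one per observation. `classroom`
#'   may be `NULL` to adjust for school only.
#' @return Numeric vector of adjusted values, same length as `x`.
#' @export
adjust_for_factors <- function(x, school, classroom = NULL) {
  stopifnot(length(school) == length(x))
  ok <- !is.na(x)
  school <- factor(as.character(school))
  dat <- data.frame(x = x, school = school)
  form <- x ~ school
  if (!is.null(classroom)) {
    stopifnot(length(classroom) == length(x))
    dat$classroom <- factor(as.character(classroom))
    form <- x ~ school + classroom
    cell <- table(dat$classroom[ok])
  } else {
    cell <- table(dat$school[ok])
  }
  if (any(cell == 1)) {
    warning("groups with a single observation contribute no within-group information: ",
            paste(names(cell)[cell == 1], collapse = ", "), call. = FALSE)
  }
  if (nlevels(droplevels(dat$school[ok])) < 2 &&
      (is.null(classroom) || nlevels(droplevels(dat$classroom[ok])) < 2)) {
    return(x) # single group: centering is a no-op
  }
  fit <- stats::lm(form, data = dat, na.action = stats::na.exclude)
  unname(stats::residuals(fit) + mean(x, na.rm = TRUE))
}

#' @rdname adjust_for_factors
#' @param outcomes A validated outcomes tibble ([validate_outcomes()]).
#' @param by Factors to adjust for: `"school"`, `"classroom"`, or both
#'   (default).
#' @return `adjust_bmi_percentile()`: the outcomes tibble with the
#'   `bmi_percentile_t*` columns replaced by adjusted values.
#' @export
adjust_bmi_percentile <- function(outcomes, by = c("school", "classroom")) {
  by <- match.arg(by, several.ok = TRUE)
  sch <- if ("school" %in% by) outcomes$school else outcomes$classroom
  cls <- if (all(c("school", "classroom") %in% by)) outcomes$classroom else NULL
  for (col in c("bmi_percentile_t0", "bmi_percentile_t1", "bmi_percentile_t2")) {
    if (any(!is.na(outcomes[[col]]))) {
      outcomes[[col]] <- adjust_for_factors(outcomes[[col]], sch, cls)
    }
  }
  outcomes
}

#' Two-timepoint repeated measures by group (split plot)
#'
#' Compares the pattern of change between two groups over two timepoints
#' (e.g. adjusted BMI percentile at baseline and 12 months for youth of
#' positive-deviant vs other parents) with the standard split-plot
#' decomposition: a between-subject group effect, a within-subject time
#' effect, and the group x time interaction. Cell means with descriptive
#' standard errors are reported per group x timepoint.
#'
#' @param baseline,followup Numeric vectors, one complete pair per
#'   subject.
#' @param group Group label per subject (two levels, each with at least 2
#'   subjects).
#' @return A list of class `repeated_measures_result` with `means` (tibble
#'   of group, time, n, mean, se) and `effects` (tibble of effect, df1,
#'   df2, F, p for group, time, group:time).
#' @export
repeated_measures_by_group <- function(baseline, followup, group) {
  ok <- stats::complete.cases(baseline, followup, group)
  baseline <- baseline[ok]; followup <- followup[ok]
  group <- factor(as.character(group)[ok])
  if (nlevels(group) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  n <- length(baseline)
  long <- data.frame(
    id = factor(rep(seq_len(n), 2)),
    group = rep(group, 2),
    time = factor(rep(c("t0", "t1"), each = n)),
    y = c(baseline, followup)
  )
  fit <- stats::aov(y ~ group * time + Error(id), data = long)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: id"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  pick <- function(tabl, label) {
    i <- grep(paste0("^", label, "\\s*$"), trimws(rownames(tabl)))
    resid <- grep("Residuals", rownames(tabl))
    tibble::tibble(
      effect = label,
      df1 = tabl$Df[i], df2 = tabl$Df[resid],
      F = tabl$`F value`[i], p = tabl$`Pr(>F)`[i]
    )
  }
  effects <- dplyr::bind_rows(
    pick(between, "group"),
    pick(within, "time"),
    pick(within, "group:time")
  )
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$time),
    n = dplyr::n(), mean = mean(.data$y),
    se = stats::sd(.data$y) / sqrt(dplyr::n()), .groups = "drop"
  )
  structure(list(means = means, effects = effects),
            class = "repeated_measures_result")
}

#' @export
print.repeated_measures_result <- function(x, ...) {
  cat("repeated measures (split plot), 2 timepoints\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  cat("cell means:\n")
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

#' Full analysis surface for a scored cohort
#'
#' Reproduces the study-style report on a score table: engagement summary,
#' correlation of the standardized indices with baseline youth BMI
#' percentile among participating parents, PD vs non-PD comparison of
#' standardized intensity, per-activity PD association (chi-square on
#' participation), and the two-timepoint repeated-measures comparison of
#' school/classroom-adjusted BMI percentile by PD status.
#'
#' @param scores Score table from [score_cohort()] with outcome columns
#'   joined.
#' @return A list of analysis blocks; components that cannot be computed
#'   from the available columns are `NULL`.
#' @export
analyze_scores <- function(scores) {
  out <- list(summary = engagement_summary(scores))

  has_bmi <- "bmi_percentile_t0" %in% names(scores)
  eng <- scores[scores$ppp > 0, , drop = FALSE]
  if (has_bmi) {
    ok <- !is.na(eng$bmi_percentile_t0)
    if (sum(ok) >= 3) {
      out$bmi_correlation <- list(
        pei = pearson_correlation(eng$std_pei[ok], eng$bmi_percentile_t0[ok]),
        ppp = pearson_correlation(eng$std_ppp[ok], eng$bmi_percentile_t0[ok])
      )
    }
  }

  if (sum(eng$pd) >= 2 && sum(!eng$pd) >= 2) {
    out$pd_intensity <- two_group_t(eng$std_pei[eng$pd], eng$std_pei[!eng$pd])
    pts_cols <- grep("^pts_", names(eng), value = TRUE)
    out$pd_by_activity <- lapply(stats::setNames(pts_cols, sub("^pts_", "", pts_cols)),
      function(col) {
        tab <- table(factor(eng[[col]] > 0, c(FALSE, TRUE)),
                     factor(eng$pd, c(FALSE, TRUE)))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
        suppressWarnings(chi_square_independence(tab))[c("statistic", "df", "p")]
      })
  }

  if (has_bmi && all(c("bmi_percentile_t2", "classroom") %in% names(scores))) {
    adj <- scores
    keep <- !is.na(adj$bmi_percentile_t0) & !is.na(adj$bmi_percentile_t2) &
      !is.na(adj$classroom)
    adj <- adj[keep, , drop = FALSE]
    if (nrow(adj) >= 4 && sum(adj$pd) >= 2 && sum(!adj$pd) >= 2) {
      t0 <- adjust_for_factors(adj$bmi_percentile_t0, adj$school, adj$classroom)
      t2 <- adjust_for_factors(adj$bmi_percentile_t2, adj$school, adj$classroom)
      out$bmi_change_by_pd <- repeated_measures_by_group(t0, t2, adj$pd)
    }
  }
  out
}
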