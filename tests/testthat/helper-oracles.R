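# Frozen expectations and independent oracles used across the suite.

# canonical intensity factors (footnote order of the sample-calculation table)
canonical_factors <- c(
  family_fun_nights = 3L, action_packs = 2L, recipe_preparation = 2L,
  about_eating = 1L, parent_survey = 2L, parent_diet_assessment = 1L,
  youth_diet_assessment = 1L, accelerometry = 2L
)

# printed per-arm maxima: (PPP total/program/evaluation, PEI total/program/evaluation)
table1_expected <- tibble::tribble(
  ~cohort, ~school, ~max_ppp, ~program_max_ppp, ~evaluation_max_ppp,
  ~max_pei, ~program_max_pei, ~evaluation_max_pei,
  "1", "1", 2L, 0L, 2L, 12L, 0L, 12L,
  "1", "2", 1L, 0L, 1L, 6L, 0L, 6L,
  "1", "3", 2L, 0L, 2L, 12L, 0L, 12L,
  "1", "4", 2L, 1L, 1L, 12L, 6L, 6L,
  "1", "5", 2L, 1L, 1L, 12L, 6L, 6L,
  "1", "6", 2L, 1L, 1L, 12L, 6L, 6L,
  "1", "7", 1L, 0L, 1L, 6L, 0L, 6L,
  "1", "8", 3L, 1L, 2L, 18L, 6L, 12L,
  "2", "1", 5L, 1L, 4L, 30L, 6L, 24L,
  "2", "2", 6L, 3L, 3L, 36L, 18L, 18L,
  "2", "3", 5L, 1L, 4L, 30L, 6L, 24L,
  "2", "4", 7L, 4L, 3L, 42L, 24L, 18L,
  "2", "5", 5L, 2L, 3L, 30L, 12L, 18L,
  "2", "6", 5L, 2L, 3L, 30L, 12L, 18L,
  "2", "7", 6L, 3L, 3L, 36L, 18L, 18L,
  "2", "8", 8L, 4L, 4L, 48L, 24L, 24L,
  "3", "1", 5L, 1L, 4L, 30L, 6L, 24L,
  "3", "2", 6L, 3L, 3L, 36L, 18L, 18L,
  "3", "3", 5L, 1L, 4L, 30L, 6L, 24L,
  "3", "4", 3L, 0L, 3L, 18L, 0L, 18L,
  "3", "5", 5L, 2L, 3L, 30L, 12L, 18L,
  "3", "6", 5L, 2L, 3L, 30L, 12L, 18L,
  "3", "7", 6L, 3L, 3L, 36L, 18L, 18L,
  "3", "8", 8L, 4L, 4L, 48L, 24L, 24L,
  "4", "1", 4L, 0L, 4L, 24L, 0L, 24L,
  "4", "2", 3L, 0L, 3L, 18L, 0L, 18L,
  "4", "3", 4L, 0L, 4L, 24L, 0L, 24L,
  "4", "4", 3L, 0L, 3L, 18L, 0L, 18L,
  "4", "6", 4L, 1L, 3L, 24L, 6L, 18L,
  "4", "7", 3L, 0L, 3L, 18L, 0L, 18L,
  "4", "8", 5L, 1L, 4L, 30L, 6L, 24L
)

# Brute-force scorer for the canonical schema, written directly from the
# published frequency scales -- independent of the package's frequency_points
# and score paths.
oracle_points <- function(activity, total, per_tp = NULL) {
  bin3 <- function(x, b1, b2) if (x == 0) 0 else if (x <= b1) 1 else if (x <= b2) 2 else 3
  switch(activity,
    family_fun_nights = total,
    about_eating = total,
    parent_survey = total,
    accelerometry = total,
    action_packs = bin3(total, 3, 6),
    recipe_preparation = if (total == 0) 0 else if (total == 1) 1 else if (total <= 3) 2 else 3,
    parent_diet_assessment = ,
    youth_diet_assessment = sum(vapply(per_tp, function(x) {
      if (x == 0) 0 else if (x == 1) 1 else 2
    }, numeric(1)))
  )
}

oracle_score_parent <- function(rows) {
  # rows: tidy records of one parent under the canonical catalog
  pts <- vapply(unique(rows$activity), function(nm) {
    sub <- rows[rows$activity == nm, , drop = FALSE]
    if (nm %in% c("parent_diet_assessment", "youth_diet_assessment")) {
      per_tp <- integer(3)
      per_tp[sub$timepoint] <- sub$count
      oracle_points(nm, sum(sub$count), per_tp)
    } else {
      oracle_points(nm, sum(sub$count))
    }
  }, numeric(1))
  list(ppp = sum(pts > 0),
       pei = sum(pts * canonical_factors[unique(rows$activity)]))
}

# textbook-formula oracles for the analysis module
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# closed-form balanced split-plot decomposition (2 groups x 2 times)
oracle_split_plot <- function(baseline, followup, group) {
  g <- factor(group)
  y <- rbind(baseline, followup) # 2 x n
  grand <- mean(y)
  subj_means <- colMeans(y)
  grp_means <- tapply(subj_means, g, mean)
  time_means <- rowMeans(y)
  n_g <- table(g)
  cell <- matrix(NA_real_, 2, 2)
  for (t in 1:2) cell[t, ] <- tapply(y[t, ], g, mean)
  ss_group <- 2 * sum(n_g * (grp_means - grand)^2)
  ss_subj <- 2 * sum((subj_means - grp_means[g])^2)
  ss_time <- sum(length(group) * (time_means - grand)^2)
  ss_gt <- 0
  for (t in 1:2) for (k in 1:2) {
    ss_gt <- ss_gt + n_g[k] *
      (cell[t, k] - time_means[t] - grp_means[k] + grand)^2
  }
  ss_tot <- sum((y - grand)^2)
  ss_resid <- ss_tot - ss_group - ss_subj - ss_time - ss_gt
  df_g <- 1; df_s <- length(group) - 2; df_t <- 1; df_gt <- 1
  df_r <- df_s
  list(
    F_group = (ss_group / df_g) / (ss_subj / df_s),
    F_time = (ss_time / df_t) / (ss_resid / df_r),
    F_gt = (ss_gt / df_gt) / (ss_resid / df_r),
    p_group = stats::pf((ss_group / df_g) / (ss_subj / df_s), df_g, df_s,
                        lower.tail = FALSE),
    p_time = stats::pf((ss_time / df_t) / (ss_resid / df_r), df_t, df_r,
                       lower.tail = FALSE),
    p_gt = stats::pf((ss_gt / df_gt) / (ss_resid / df_r), df_gt, df_r,
                     lower.tail = FALSE)
  )
}

# random single-parent record generator over the canonical catalog
random_records <- function(n, catalog, seed) {
  set.seed(seed)
  arms <- catalog$arms
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- sample.int(nrow(arms), 1)
    arm <- get_arm(catalog, arms$cohort[j], arms$school[j])
    rows <- list()
    for (nm in arm$offered) {
      rule <- arm$activities[[nm]]$frequency
      if (rule$kind == "per_timepoint_binned") {
        cts <- sample(0:max(rule$bins$hi), rule$timepoints, replace = TRUE)
        nz <- which(cts > 0)
        if (length(nz)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            parent_id = sprintf("r%05d", i), cohort = arm$cohort,
            school = arm$school, activity = nm, timepoint = nz,
            count = cts[nz]
          )
        }
      } else {
        ct <- sample(0:rule_max_count(rule), 1)
        if (ct > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            parent_id = sprintf("r%05d", i), cohort = arm$cohort,
            school = arm$school, activity = nm, timepoint = NA_integer_,
            count = ct
          )
        }
      }
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
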