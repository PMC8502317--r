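cat8 <- build_default_catalogs()

test_that("the four worked examples score as published", {
  v <- validate_participation(fixture_table3(), cat8)
  expect_identical(nrow(v$rejects), 0L)
  s <- score_cohort(v$records, cat8)
  s <- s[match(paste0("example_", c("A", "B", "C", "D")), s$parent_id), ]

  # School A: surveys-only arm, 2 of 3 surveys completed
  expect_equal(s$ppp[1], 1L)
  expect_equal(s$std_ppp[1], 1)
  expect_equal(s$pei[1], 4L) # 2 points x intensity 2
  expect_equal(s$std_pei[1], 4 / 6)

  # School B: About Eating + surveys; 4 lessons and 1 survey
  expect_equal(s$std_ppp[2], 1)
  expect_equal(s$pei[2], 6L)
  expect_equal(s$std_pei[2], 6 / 12)

  # School C: 5-activity arm; 3 surveys + 3x2 youth recalls + 1 lesson
  expect_equal(s$ppp[3], 3L)
  expect_equal(s$std_ppp[3], 3 / 5)
  expect_equal(s$pei[3], 13L)
  expect_equal(s$std_pei[3], 13 / 30)

  # School D: full 8-activity arm; 5 of 8 types attempted. Scoring the
  # published counts under the published rules gives PEI 20
  # (4+4+4+4+4), i.e. 41.7% standardized.
  expect_equal(s$ppp[4], 5L)
  expect_equal(s$std_ppp[4], 5 / 8)
  expect_equal(s$pei[4], 20L)
  expect_equal(s$std_pei[4], 20 / 48)
})

test_that("positive deviance threshold is inclusive at exactly 75%", {
  expect_true(classify_positive_deviant(1.0))
  expect_true(classify_positive_deviant(0.75))
  expect_false(classify_positive_deviant(0.7499))
  expect_false(classify_positive_deviant(NA_real_))
  expect_error(classify_positive_deviant(0.8, threshold = 0), "fraction")
  expect_error(classify_positive_deviant(0.8, threshold = 1.2), "fraction")
  # basis selection flows through to the pd column
  arm <- get_arm(cat8, 1, 2)
  sc_ppp <- compute_score(list(parent_survey = 3), arm, pd_basis = "ppp")
  expect_true(sc_ppp$pd)
  sc_pei <- compute_score(list(parent_survey = 2), arm, pd_basis = "pei")
  expect_true(sc_pei$pd_by_ppp)
  expect_false(sc_pei$pd) # 4/6 < 0.75 on the intensity basis
})

test_that("empty records score zero everywhere with no PD flags", {
  arm <- get_arm(cat8, 2, 8)
  sc <- compute_score(list(), arm)
  expect_equal(sc$ppp, 0L)
  expect_equal(sc$pei, 0L)
  expect_equal(sc$std_ppp, 0)
  expect_equal(sc$std_pei, 0)
  expect_false(sc$pd_by_ppp || sc$pd_by_pei)
})

test_that("standardized sub-scores are missing when a category is not offered", {
  arm <- get_arm(cat8, 1, 2) # surveys only: no program activities
  sc <- compute_score(list(parent_survey = 1), arm)
  expect_true(is.na(sc$std_program_ppp))
  expect_true(is.na(sc$std_program_pei))
  expect_equal(sc$std_evaluation_ppp, 1)
  # program + evaluation components always sum to the totals
  expect_equal(sc$program_ppp + sc$evaluation_ppp, sc$ppp)
  expect_equal(sc$program_pei + sc$evaluation_pei, sc$pei)
})

test_that("scoring a record against the wrong arm errors", {
  arm <- get_arm(cat8, 1, 2)
  expect_error(compute_score(list(family_fun_nights = 1), arm), "not offered")
})

test_that("brute-force PEI enumeration matches the scoring output", {
  recs <- random_records(250, cat8, seed = 42)
  v <- validate_participation(recs, cat8)
  expect_identical(nrow(v$rejects), 0L)
  s <- score_cohort(v$records, cat8)
  for (pid in s$parent_id) {
    rows <- v$records[v$records$parent_id == pid, , drop = FALSE]
    if (!nrow(rows)) next
    oracle <- oracle_score_parent(rows)
    got <- s[s$parent_id == pid, ]
    expect_identical(got$ppp, as.integer(oracle$ppp))
    expect_identical(got$pei, as.integer(oracle$pei))
  }
})

test_that("score table equals per-record compute_score applied independently", {
  sim <- generate_cohort(simulation_config(seed = 11, n_parents_per_arm = 3), cat8)
  s <- score_cohort(sim$participation, cat8)
  for (pid in s$parent_id) {
    row <- s[s$parent_id == pid, ]
    arm <- get_arm(cat8, row$cohort, row$school)
    rec <- sim$participation[sim$participation$parent_id == pid, , drop = FALSE]
    counts <- engage:::counts_from_records(rec, cat8)
    ref <- compute_score(counts, arm)
    for (col in c("ppp", "pei", "std_ppp", "std_pei", "program_pei",
                  "evaluation_pei", "std_program_pei", "std_evaluation_pei")) {
      expect_equal(row[[col]], ref[[col]], info = paste(pid, col))
    }
  }
})

test_that("scores respect the canonical-catalog invariants on random records", {
  recs <- random_records(150, cat8, seed = 7)
  s <- score_cohort(validate_participation(recs, cat8)$records, cat8)
  expect_true(all(s$std_ppp >= 0 & s$std_ppp <= 1))
  expect_true(all(s$std_pei >= 0 & s$std_pei <= 1))
  # each attempted activity contributes at least one weighted point
  expect_true(all(s$pei >= s$ppp))
  # every canonical activity's ceiling is the same, so intensity share
  # can never exceed breadth share
  expect_true(all(s$std_pei <= s$std_ppp + 1e-12))
})

test_that("adding participation never decreases any score component", {
  set.seed(13)
  score_cols <- c("ppp", "pei", "std_ppp", "std_pei", "program_ppp",
                  "program_pei", "evaluation_ppp", "evaluation_pei")
  for (rep in 1:30) {
    arm_i <- sample.int(nrow(cat8$arms), 1)
    arm <- get_arm(cat8, cat8$arms$cohort[arm_i], cat8$arms$school[arm_i])
    counts <- list()
    for (nm in arm$offered) {
      rule <- arm$activities[[nm]]$frequency
      if (rule$kind == "per_timepoint_binned") {
        counts[[nm]] <- sample(0:max(rule$bins$hi), rule$timepoints, replace = TRUE)
      } else {
        counts[[nm]] <- sample(0:rule_max_count(rule), 1)
      }
    }
    base <- compute_score(counts, arm)
    # bump one activity that still has headroom
    for (nm in sample(arm$offered)) {
      rule <- arm$activities[[nm]]$frequency
      ct <- counts[[nm]]
      if (rule$kind == "per_timepoint_binned") {
        tp <- which(ct < max(rule$bins$hi))
        if (length(tp)) {
          counts[[nm]][tp[1]] <- ct[tp[1]] + 1
          break
        }
      } else if (ct < rule_max_count(rule)) {
        counts[[nm]] <- ct + 1
        break
      }
    }
    bumped <- compute_score(counts, arm)
    for (col in score_cols) {
      expect_gte(bumped[[col]], base[[col]])
    }
  }
})

test_that("score_cohort joins outcomes and keeps zero-engagement parents", {
  sim <- generate_cohort(simulation_config(seed = 3, n_parents_per_arm = 6), cat8)
  s <- score_cohort(sim$participation, cat8, outcomes = sim$outcomes)
  expect_identical(nrow(s), nrow(sim$outcomes))
  zero <- setdiff(sim$outcomes$parent_id, sim$participation$parent_id)
  expect_true(all(s$ppp[s$parent_id %in% zero] == 0L))
  expect_true(all(s$std_ppp[s$parent_id %in% zero] == 0))
  expect_false(any(is.na(s$treatment)))
  # a parent mapped to two arms is an input error
  dup <- tibble::tibble(parent_id = "dup", cohort = "1", school = c("2", "7"),
                        activity = "parent_survey", timepoint = NA_integer_,
                        count = 1)
  expect_error(score_cohort(dup, cat8), "more than one arm")
})

test_that("degenerate cohorts summarize as expected", {
  # everyone does everything in a one-arm catalog
  arm_tbl <- tibble::tibble(cohort = "1", school = "2", treatment = "control",
                            offered = list("parent_survey"))
  cat1 <- engagement_catalog(unname(build_default_catalogs()$activities[
    "parent_survey"]), arm_tbl)
  recs <- tibble::tibble(parent_id = c("a", "b"), cohort = "1", school = "2",
                         activity = "parent_survey", timepoint = NA_integer_,
                         count = 3)
  s <- score_cohort(validate_participation(recs, cat1)$records, cat1)
  sm <- engagement_summary(s)
  expect_equal(sm$overall$mean_std_ppp, 1)
  expect_equal(sm$overall$mean_std_pei, 1)
  expect_equal(sm$overall$n_pd, 2L)
  # all-zero cohort
  outc <- validate_outcomes(tibble::tibble(
    parent_id = c("a", "b"), school = "2", classroom = "x",
    treatment = "control", cohort = "1",
    bmi_percentile_t0 = c(40, 60)
  ))
  s0 <- score_cohort(recs[0, ], cat1, outcomes = outc)
  sm0 <- engagement_summary(s0, participants_only = FALSE)
  expect_equal(sm0$overall$mean_std_ppp, 0)
  expect_equal(sm0$overall$n_pd, 0L)
})
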