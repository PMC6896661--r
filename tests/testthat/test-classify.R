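test_that("delta is the post-minus-pre change and refuses missing input", {
  expect_equal(delta(139, 134), -5)
  expect_equal(delta(97.1, 97.1), 0)
  expect_equal(delta(8.9, 7.8), -1.1)
  expect_equal(delta(c(1, 2), c(3, 1)), c(2, -1))
  expect_error(delta(NA, 1), "MISSING")
  expect_error(delta(1, NA), "MISSING")
})

test_that("delta-zero rule: only an exactly-zero delta is no change", {
  expect_equal(classify_delta_zero(0, "increase_is_better"), "NO_CHANGE")
  expect_equal(classify_delta_zero(0, "decrease_is_better"), "NO_CHANGE")
  expect_equal(classify_delta_zero(-5, "decrease_is_better"), "IMPROVED")
  expect_equal(classify_delta_zero(-0.3, "increase_is_better"), "WORSENED")
  expect_equal(classify_delta_zero(1e-12, "increase_is_better"), "IMPROVED")
})

test_that("risk-threshold rule: boundary counts as a change", {
  expect_equal(classify_risk_threshold(-5, 3, "decrease_is_better"), "IMPROVED")
  expect_equal(classify_risk_threshold(-2, 3, "decrease_is_better"), "NO_CHANGE")
  expect_equal(classify_risk_threshold(1.0, 1.0, "decrease_is_better"), "WORSENED")
  expect_equal(classify_risk_threshold(-3, 3, "decrease_is_better"), "IMPROVED")
  expect_equal(classify_risk_threshold(2.9999, 3, "increase_is_better"), "NO_CHANGE")
  expect_error(classify_risk_threshold(1, 0, "increase_is_better"), "positive")
  expect_error(classify_risk_threshold(1, -2, "increase_is_better"), "positive")
})

test_that("threshold registry carries the established vascular cut-offs", {
  reg <- default_threshold_registry()
  expect_equal(registry_threshold("blood_pressure", reg), 3)
  expect_equal(registry_threshold("arterial_stiffness", reg), 1)
  expect_equal(registry_threshold("flow_mediated_dilation", reg), 1)
  expect_error(registry_threshold("serum_unobtainium", reg), "explicit threshold")
  expect_error(registry_threshold("resting_heart_rate", reg), "level")
  ext <- default_threshold_registry(extra = c(ldl_cholesterol = 10))
  expect_equal(registry_threshold("ldl_cholesterol", ext), 10)
})

test_that("quantile rule splits deltas into tertiles/quartiles as expected", {
  expect_equal(
    classify_quantile(c(-3, -2, -1, 0, 1, 2), 3, "increase_is_better"),
    c("WORSENED", "WORSENED", "NO_CHANGE", "NO_CHANGE", "IMPROVED", "IMPROVED"))
  # identical deltas: degenerate quantiles, everything is no change
  expect_equal(unique(classify_quantile(rep(0.7, 9), 3, "increase_is_better")),
               "NO_CHANGE")
  # quartiles on 8 distinct values: exactly 2 improved, 2 worsened
  st <- classify_quantile(c(5, 1, 8, 3, 7, 2, 6, 4), 4, "increase_is_better")
  expect_equal(sum(st == "IMPROVED"), 2)
  expect_equal(sum(st == "WORSENED"), 2)
  expect_error(classify_quantile(c(1, 2), 3, "increase_is_better"), "at least")
})

test_that("quantile rule matches the sort-and-slice oracle when k divides n", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(c(3, 4), 1)
    n <- k * sample(2:6, 1)
    d <- sample(seq_len(1000), n) / 10  # distinct deltas
    dir <- sample(c("increase_is_better", "decrease_is_better"), 1)
    expect_equal(classify_quantile(d, k, dir), quantile_oracle(d, k, dir),
                 info = paste("seed", seed))
  }
})

test_that("minimal detectable difference follows the z * sqrt(2) * SEM form", {
  expect_equal(mdd_threshold(2.0, 0.95), 5.543617, tolerance = 1e-6)
  expect_equal(mdd_threshold(2.0, 0.95), qnorm(0.975) * sqrt(2) * 2.0)
  # vanishing confidence gives a vanishing threshold
  expect_lt(mdd_threshold(1.0, 1e-8), 1e-7)
  # linear in the SEM
  expect_equal(mdd_threshold(2.4, 0.9), 2 * mdd_threshold(1.2, 0.9))
  expect_error(mdd_threshold(-1, 0.95), "sem")
  expect_error(mdd_threshold(1, 0), "confidence")
  expect_equal(sem_from_reliability(3, 0.91), 3 * 0.3)
})

test_that("classify_study is total: missing cells gray, everything else ruled", {
  cl <- classify_study(tiny_study())
  expect_equal(cl$statuses$bp, c("IMPROVED", "NO_CHANGE", "NO_CHANGE", "WORSENED"))
  # P3 lacks a post fmd value -> MISSING, no rule evaluated
  expect_equal(cl$statuses$fmd, c("IMPROVED", "NO_CHANGE", "MISSING", "WORSENED"))

  # empty study: empty matrix, no error
  outcomes <- list(outcome_spec("y", role = "primary",
                                benefit_direction = "increase_is_better",
                                rule = classification_rule("delta_zero")))
  empty <- study_dataset(outcomes,
                         data.frame(subject_id = character(0), arm = character(0),
                                    y_pre = numeric(0), y_post = numeric(0)))
  expect_equal(nrow(classify_study(empty)$statuses), 0)
})

test_that("quantile scope: within-arm by default, pooled on request", {
  outcomes_for <- function(scope) list(
    outcome_spec("y", role = "primary", benefit_direction = "increase_is_better",
                 rule = classification_rule("quantile", k = 3, scope = scope)))
  subjects <- data.frame(
    subject_id = sprintf("S%02d", 1:12),
    arm = rep(c("A", "B"), each = 6),
    y_pre = rep(0, 12),
    # arm A deltas all far below arm B deltas
    y_post = c(1:6, 101:106),
    stringsAsFactors = FALSE
  )
  cl_arm <- classify_study(study_dataset(outcomes_for("arm"), subjects))
  # within-arm: each arm has its own improved subjects
  expect_equal(sum(cl_arm$statuses$y[1:6] == "IMPROVED"), 2)
  expect_equal(sum(cl_arm$statuses$y[7:12] == "IMPROVED"), 2)
  cl_pool <- classify_study(study_dataset(outcomes_for("study"), subjects))
  # pooled: arm A holds all the worsened, arm B all the improved
  expect_equal(sum(cl_pool$statuses$y[1:6] == "IMPROVED"), 0)
  expect_equal(sum(cl_pool$statuses$y[7:12] == "IMPROVED"), 4)

  # too few non-missing deltas in one arm is a loud validation error
  subjects$y_post[1:4] <- NA
  expect_error(classify_study(study_dataset(outcomes_for("arm"), subjects)),
               "arm 'A'")
})

test_that("response counts: percentages over the full arm, conservation holds", {
  cl <- classify_study(cached_f5())
  rc <- response_counts(cl, "Intervention", "renal_function")
  expect_equal(rc$pct_no_change, 25.0)
  expect_equal(rc$pct_worsened, 15.0)
  expect_equal(rc$n_improved + rc$n_no_change + rc$n_worsened + rc$n_missing, 20)
  expect_error(response_counts(cl, "Placebo", "renal_function"), "unknown arm")
  expect_error(response_counts(cl, "Intervention", "qaly"), "unknown outcome")

  # an arm of all-missing cells: n_missing = arm size, all percentages zero
  outcomes <- list(outcome_spec("y", role = "primary",
                                benefit_direction = "increase_is_better",
                                rule = classification_rule("delta_zero")))
  s <- data.frame(subject_id = c("P1", "P2"), arm = "A",
                  y_pre = c(NA_real_, 1), y_post = c(2, NA_real_))
  rc0 <- response_counts(classify_study(study_dataset(outcomes, s)), "A", "y")
  expect_equal(rc0$n_missing, 2)
  expect_equal(rc0$pct_improved + rc0$pct_no_change + rc0$pct_worsened, 0)

  # observed denominator rescales the percentages
  rc_obs <- response_counts(cl, "Intervention", "renal_function",
                            denominator = "observed")
  expect_equal(rc_obs$pct_no_change, 25.0)  # F5 has no missing data
})

test_that("conservation and direction antisymmetry hold on random studies", {
  for (seed in 1:60) {
    study <- random_study(seed)
    cl <- classify_study(study)
    counts <- response_counts_table(cl)
    for (i in seq_len(nrow(counts))) {
      arm_n <- sum(study$subjects$arm == counts$arm[i])
      expect_equal(counts$n_improved[i] + counts$n_no_change[i] +
                     counts$n_worsened[i] + counts$n_missing[i], arm_n)
    }
    # flipping the benefit direction swaps IMPROVED and WORSENED cell-by-cell
    cl_f <- classify_study(flip_direction(study))
    a <- cl$statuses$y
    b <- cl_f$statuses$y
    expect_equal(b[a == "IMPROVED"], rep("WORSENED", sum(a == "IMPROVED")))
    expect_equal(b[a == "WORSENED"], rep("IMPROVED", sum(a == "WORSENED")))
    expect_equal(b[a == "MISSING"], rep("MISSING", sum(a == "MISSING")))
    # NO_CHANGE is invariant except at the threshold boundary, which has
    # measure zero for continuous data
    expect_equal(b[a == "NO_CHANGE"], rep("NO_CHANGE", sum(a == "NO_CHANGE")))
  }
})

test_that("raising the risk threshold never creates more responders", {
  set.seed(42)
  d <- rnorm(200, 0, 2)
  prev <- Inf
  for (t in c(0.25, 0.5, 1, 2, 4)) {
    st <- classify_risk_threshold(d, t, "increase_is_better")
    n_changed <- sum(st != "NO_CHANGE")
    expect_lte(n_changed, prev)
    prev <- n_changed
  }
})

test_that("the mdd rule is the risk-threshold rule at the derived threshold", {
  set.seed(7)
  d <- rnorm(500, 0, 3)
  for (sem in c(0.5, 1.5)) {
    for (conf in c(0.9, 0.95)) {
      thr <- mdd_threshold(sem, conf)
      outcomes <- list(outcome_spec("y", role = "primary",
                                    benefit_direction = "decrease_is_better",
                                    rule = classification_rule("mdd", sem = sem,
                                                               confidence = conf)))
      s <- data.frame(subject_id = sprintf("S%03d", seq_along(d)), arm = "A",
                      y_pre = rep(0, length(d)), y_post = d)
      cl <- classify_study(study_dataset(outcomes, s))
      expect_equal(cl$statuses$y,
                   classify_risk_threshold(d, thr, "decrease_is_better"))
    }
  }
})
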