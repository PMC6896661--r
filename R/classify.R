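# Cut-off rules: map each subject's pre-to-post change to a response status
# and tally responses per arm.

benefit_sign <- function(direction) {
  direction <- match.arg(direction, c("increase_is_better", "decrease_is_better"))
  if (direction == "increase_is_better") 1 else -1
}

#' Pre-to-post change score
#'
#' @param pre,post Numeric vectors of equal length, no missing values (cells
#'   with a missing pre or post value must be short-circuited to `MISSING`
#'   before any delta is computed).
#' @return `post - pre`.
#' @export
delta <- function(pre, post) {
  if (length(pre) != length(post)) stop_validation("'pre' and 'post' differ in length")
  if (anyNA(pre) || anyNA(post)) {
    stop_validation("delta() received missing values; classify those cells as MISSING instead")
  }
  post - pre
}

#' Delta-zero classification
#'
#' Any change at all counts: a delta of exactly zero is `NO_CHANGE`, a nonzero
#' delta in the benefit direction is `IMPROVED`, otherwise `WORSENED`. This is
#' the strictest reading of "any response counts" and deliberately ignores
#' measurement error (see [mdd_threshold()] for the error-aware alternative).
#'
#' @param d Numeric vector of deltas (post minus pre).
#' @param direction `"increase_is_better"` or `"decrease_is_better"`.
#' @return Character vector of statuses.
#' @export
classify_delta_zero <- function(d, direction) {
  b <- d * benefit_sign(direction)
  ifelse(b > 0, "IMPROVED", ifelse(b < 0, "WORSENED", "NO_CHANGE"))
}

#' Risk-based threshold classification
#'
#' Uses a clinically established cut-off: a change of at least `threshold`
#' (inclusive, so a delta exactly on the boundary counts as a change) in the
#' benefit direction is `IMPROVED`, at least `threshold` against it is
#' `WORSENED`, anything smaller is `NO_CHANGE`.
#'
#' @inheritParams classify_delta_zero
#' @param threshold Positive change threshold in the outcome's units.
#' @return Character vector of statuses.
#' @export
classify_risk_threshold <- function(d, threshold, direction) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0) {
    stop_validation("'threshold' must be a single positive number")
  }
  b <- d * benefit_sign(direction)
  ifelse(b >= threshold, "IMPROVED", ifelse(b <= -threshold, "WORSENED", "NO_CHANGE"))
}

#' Built-in registry of change thresholds
#'
#' Clinically established minimum changes for common vascular outcomes:
#' 3 mmHg for blood pressure, 1 m/s for arterial stiffness (pulse-wave
#' velocity), and 1 percentage point for flow-mediated dilation. Extend or
#' override via `extra`. Resting heart rate is deliberately absent: its
#' conventional 75 bpm criterion is a level, not a change score, and
#' requesting it raises an explanatory error from [registry_threshold()].
#'
#' @param extra Optional named numeric vector of additional thresholds.
#' @return Named numeric vector mapping outcome kind to threshold.
#' @export
default_threshold_registry <- function(extra = NULL) {
  reg <- c(blood_pressure = 3, arterial_stiffness = 1, flow_mediated_dilation = 1)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop_validation("'extra' thresholds must be named")
    }
    reg[names(extra)] <- as.numeric(extra)
  }
  reg
}

#' Look up a registry threshold
#'
#' @param kind Outcome kind, e.g. `"blood_pressure"`.
#' @param registry A registry from [default_threshold_registry()].
#' @return The threshold, or an error if the kind is unknown (the caller must
#'   then supply an explicit threshold).
#' @export
registry_threshold <- function(kind, registry = default_threshold_registry()) {
  if (identical(kind, "resting_heart_rate")) {
    stop_validation("the 75 bpm resting heart rate criterion is a level, not a change ",
                    "threshold, and is not supported by the delta-based registry")
  }
  if (!kind %in% names(registry)) {
    stop_validation("no registered change threshold for '", kind,
                    "'; supply an explicit threshold")
  }
  unname(registry[[kind]])
}

#' Quantile (tertile/quartile) classification
#'
#' Splits the supplied deltas into `k` equal-probability groups using sample
#' quantiles (inclusive linear interpolation, `stats::quantile` type 7). The
#' extreme group in the benefit direction is `IMPROVED`, the opposite extreme
#' `WORSENED`, the middle group(s) `NO_CHANGE`. A delta lying exactly on a cut
#' is assigned to the more central group, so that with all deltas identical
#' everything is `NO_CHANGE`.
#'
#' @param deltas Numeric vector of non-missing deltas (one arm's, or the whole
#'   study's, depending on the rule's scope).
#' @param k 3 (tertiles) or 4 (quartiles).
#' @inheritParams classify_delta_zero
#' @return Character vector of statuses, in input order.
#' @export
classify_quantile <- function(deltas, k, direction) {
  k <- as.integer(k)
  if (!k %in% c(3L, 4L)) stop_validation("'k' must be 3 or 4")
  if (anyNA(deltas)) stop_validation("classify_quantile() received missing deltas")
  if (length(deltas) < k) {
    stop_validation("quantile rule needs at least k = ", k, " deltas, got ", length(deltas))
  }
  s <- benefit_sign(direction)
  cuts <- stats::quantile(deltas, probs = c(1, k - 1) / k, type = 7, names = FALSE)
  b_lo <- cuts[1]; b_hi <- cuts[2]
  status <- rep("NO_CHANGE", length(deltas))
  status[deltas > b_hi] <- if (s > 0) "IMPROVED" else "WORSENED"
  status[deltas < b_lo] <- if (s > 0) "WORSENED" else "IMPROVED"
  status
}

#' Standard error of measurement from test-retest reliability
#'
#' @param sd_baseline Baseline (pre-intervention) standard deviation.
#' @param icc Intraclass correlation coefficient in `[0, 1)`.
#' @return `sd_baseline * sqrt(1 - icc)`.
#' @export
sem_from_reliability <- function(sd_baseline, icc) {
  if (any(sd_baseline <= 0)) stop_validation("'sd_baseline' must be > 0")
  if (any(icc < 0 | icc >= 1)) stop_validation("'icc' must lie in [0, 1)")
  sd_baseline * sqrt(1 - icc)
}

#' Minimal detectable difference for a pre/post change score
#'
#' The smallest individual change that exceeds measurement error at the given
#' confidence level: `z * sqrt(2) * sem`, with `z` the two-sided standard
#' normal quantile `qnorm((1 + confidence) / 2)`. The `sqrt(2)` reflects that
#' a change score carries the measurement error of two measurements. The
#' resulting threshold is applied via [classify_risk_threshold()].
#'
#' @param sem Standard error of measurement (> 0).
#' @param confidence Confidence level in (0, 1); conventionally 0.95.
#' @return The minimal detectable difference, same units as `sem`.
#' @export
mdd_threshold <- function(sem, confidence = 0.95) {
  if (any(sem <= 0)) stop_validation("'sem' must be > 0")
  if (any(confidence <= 0 | confidence >= 1)) {
    stop_validation("'confidence' must lie strictly between 0 and 1")
  }
  stats::qnorm((1 + confidence) / 2) * sqrt(2) * sem
}

rule_threshold <- function(rule, outcome_name) {
  switch(rule$method,
    risk_threshold = rule$threshold,
    mdd = {
      if (is.null(rule$sem)) {
        stop_validation("outcome '", outcome_name, "': mdd rule lacks parameter 'sem'")
      }
      mdd_threshold(rule$sem, rule$confidence)
    },
    stop_validation("outcome '", outcome_name, "': rule '", rule$method,
                    "' has no single threshold"))
}

#' Classify every subject on every outcome
#'
#' Applies each outcome's classification rule to every subject's delta. Cells
#' with a missing pre or post value are `MISSING` and no rule is evaluated for
#' them. Quantile rules are evaluated over the non-missing deltas within each
#' arm by default (scope `"arm"`), or pooled over the study (scope `"study"`).
#'
#' @param study A [study_dataset()].
#' @return A `classified_study`: the subject-by-outcome status matrix plus the
#'   outcome definitions, arm order and source data.
#' @export
classify_study <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  subj <- study$subjects
  n <- nrow(subj)
  statuses <- data.frame(subject_id = subj$subject_id, arm = subj$arm,
                         stringsAsFactors = FALSE)
  for (o in study$outcomes) {
    pre <- subj[[paste0(o$name, "_pre")]]
    post <- subj[[paste0(o$name, "_post")]]
    st <- rep("MISSING", n)
    obs <- !(is.na(pre) | is.na(post))
    if (any(obs)) {
      d <- delta(pre[obs], post[obs])
      st[obs] <- switch(o$rule$method,
        delta_zero = classify_delta_zero(d, o$benefit_direction),
        risk_threshold = ,
        mdd = classify_risk_threshold(d, rule_threshold(o$rule, o$name),
                                      o$benefit_direction),
        quantile = {
          out <- character(length(d))
          if (identical(o$rule$scope, "study")) {
            out <- classify_quantile(d, o$rule$k, o$benefit_direction)
          } else {
            arms_obs <- subj$arm[obs]
            for (a in unique(arms_obs)) {
              idx <- arms_obs == a
              if (sum(idx) < o$rule$k) {
                stop_validation("outcome '", o$name, "', arm '", a,
                                "': fewer non-missing deltas (", sum(idx),
                                ") than quantile groups (k = ", o$rule$k, ")")
              }
              out[idx] <- classify_quantile(d[idx], o$rule$k, o$benefit_direction)
            }
          }
          out
        })
    }
    statuses[[o$name]] <- st
  }
  new_classified_study(statuses, study$outcomes, study$arm_labels, study = study)
}

#' Tally responses for one arm and outcome
#'
#' @param classified A `classified_study`.
#' @param arm Arm label.
#' @param outcome Outcome name.
#' @param denominator `"arm"` (default): percentages are computed over all
#'   subjects in the arm, missing included; `"observed"`: over non-missing
#'   subjects only.
#' @return One-row data frame with counts `n_improved`, `n_no_change`,
#'   `n_worsened`, `n_missing` and percentages `pct_improved`,
#'   `pct_no_change`, `pct_worsened` (unrounded; round only for display).
#' @export
response_counts <- function(classified, arm, outcome,
                            denominator = c("arm", "observed")) {
  stopifnot(inherits(classified, "classified_study"))
  denominator <- match.arg(denominator)
  if (!arm %in% classified$arm_labels) stop_validation("unknown arm: ", arm)
  if (!outcome %in% names(classified$outcomes)) stop_validation("unknown outcome: ", outcome)
  st <- classified$statuses[[outcome]][classified$statuses$arm == arm]
  tab <- table(factor(st, levels = status_levels()))
  n_arm <- length(st)
  denom <- if (denominator == "arm") n_arm else n_arm - tab[["MISSING"]]
  pct <- function(k) if (denom > 0) 100 * k / denom else 0
  data.frame(arm = arm, outcome = outcome,
             n_improved = tab[["IMPROVED"]], n_no_change = tab[["NO_CHANGE"]],
             n_worsened = tab[["WORSENED"]], n_missing = tab[["MISSING"]],
             pct_improved = pct(tab[["IMPROVED"]]),
             pct_no_change = pct(tab[["NO_CHANGE"]]),
             pct_worsened = pct(tab[["WORSENED"]]),
             stringsAsFactors = FALSE)
}

#' Response counts for every arm and outcome
#'
#' @inheritParams response_counts
#' @return Data frame with one row per arm-by-outcome combination.
#' @export
response_counts_table <- function(classified, denominator = c("arm", "observed")) {
  denominator <- match.arg(denominator)
  rows <- list()
  for (a in classified$arm_labels) {
    for (nm in names(classified$outcomes)) {
      rows[[length(rows) + 1L]] <- response_counts(classified, a, nm, denominator)
    }
  }
  do.call(rbind, rows)
}
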