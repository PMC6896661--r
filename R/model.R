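# Domain types and file formats: outcome specifications, subject-level study
# data, classification results, and the CSV / YAML / JSON readers and writers.

#' Response status levels
#'
#' The four-level per-subject classification used throughout the package, in
#' canonical order: `IMPROVED`, `NO_CHANGE`, `WORSENED`, `MISSING`.
#'
#' @return Character vector of the four status levels.
#' @export
status_levels <- function() c("IMPROVED", "NO_CHANGE", "WORSENED", "MISSING")

#' Default status color mapping
#'
#' Improvement is shown green, no change yellow, worsening red and missing
#' data gray. The defaults are colorblind-checked approximations of the
#' conventional traffic-light scheme and can be overridden via [glyph_style()].
#'
#' @return Named character vector mapping every status level to a hex color.
#' @export
status_colors <- function() {
  c(IMPROVED = "#1E8F4E", NO_CHANGE = "#F2C200",
    WORSENED = "#D7301F", MISSING = "#BDBDBD")
}

# condition helpers: validation/config problems exit 2 from the CLI, I/O 3
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("vd_validation_error", "error")))
}
stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("vd_io_error", "error")))
}

#' Build a classification rule
#'
#' A rule says how a subject's pre-to-post change (delta) on one outcome is
#' mapped to a response status. Four methods are supported:
#' \describe{
#'   \item{`delta_zero`}{any nonzero delta in the benefit direction is
#'     improvement; exactly zero is no change. No parameters.}
#'   \item{`risk_threshold`}{a delta of at least `threshold` (inclusive) in
#'     the benefit direction is improvement, at least `threshold` against it
#'     is worsening, anything smaller is no change. Requires `threshold > 0`.}
#'   \item{`quantile`}{deltas are split into `k` equal-probability groups
#'     (tertiles `k = 3` or quartiles `k = 4`); the extreme group in the
#'     benefit direction is improved, the opposite extreme worsened, the
#'     middle group(s) no change. `scope` controls whether quantiles are
#'     computed within each arm (`"arm"`, default) or pooled (`"study"`).}
#'   \item{`mdd`}{minimal detectable difference: the threshold is
#'     `qnorm((1 + confidence)/2) * sqrt(2) * sem`, then applied exactly like
#'     `risk_threshold`. Supply `sem` directly or `sd_baseline` plus `icc`
#'     (test-retest reliability), from which `sem = sd_baseline * sqrt(1 - icc)`.}
#' }
#' Parameters not used by the chosen method must be absent.
#'
#' @param method One of `"delta_zero"`, `"risk_threshold"`, `"quantile"`, `"mdd"`.
#' @param threshold Positive change threshold, `risk_threshold` only.
#' @param k Number of quantile groups, 3 or 4, `quantile` only.
#' @param scope `"arm"` or `"study"`, `quantile` only (default `"arm"`).
#' @param sem Standard error of measurement (> 0), `mdd` only.
#' @param sd_baseline,icc Alternative to `sem` for `mdd`: baseline SD and
#'   intraclass correlation coefficient in `[0, 1)`.
#' @param confidence Confidence level in (0, 1) for `mdd`; default 0.95.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(method, threshold = NULL, k = NULL, scope = NULL,
                                sem = NULL, sd_baseline = NULL, icc = NULL,
                                confidence = NULL) {
  method <- match.arg(method, c("delta_zero", "risk_threshold", "quantile", "mdd"))
  given <- c(threshold = !is.null(threshold), k = !is.null(k),
             scope = !is.null(scope), sem = !is.null(sem),
             sd_baseline = !is.null(sd_baseline), icc = !is.null(icc),
             confidence = !is.null(confidence))
  allowed <- switch(method,
    delta_zero     = character(0),
    risk_threshold = "threshold",
    quantile       = c("k", "scope"),
    mdd            = c("sem", "sd_baseline", "icc", "confidence"))
  extra <- setdiff(names(given)[given], allowed)
  if (length(extra) > 0) {
    stop_validation("rule '", method, "' does not take parameter(s): ",
                    paste(extra, collapse = ", "))
  }
  rule <- list(method = method)
  if (method == "risk_threshold") {
    if (is.null(threshold)) stop_validation("rule 'risk_threshold' requires 'threshold'")
    threshold <- as.numeric(threshold)
    if (!is.finite(threshold) || threshold <= 0) {
      stop_validation("'threshold' must be a positive number, got ", threshold)
    }
    rule$threshold <- threshold
  } else if (method == "quantile") {
    if (is.null(k)) stop_validation("rule 'quantile' requires 'k' (3 or 4)")
    k <- as.integer(k)
    if (!k %in% c(3L, 4L)) stop_validation("'k' must be 3 (tertiles) or 4 (quartiles), got ", k)
    rule$k <- k
    rule$scope <- if (is.null(scope)) "arm" else match.arg(scope, c("arm", "study"))
  } else if (method == "mdd") {
    rule$confidence <- if (is.null(confidence)) 0.95 else as.numeric(confidence)
    if (!is.finite(rule$confidence) || rule$confidence <= 0 || rule$confidence >= 1) {
      stop_validation("'confidence' must lie strictly between 0 and 1")
    }
    if (is.null(sem)) {
      if (is.null(sd_baseline) || is.null(icc)) {
        stop_validation("rule 'mdd' requires 'sem', or 'sd_baseline' together with 'icc'")
      }
      sd_baseline <- as.numeric(sd_baseline); icc <- as.numeric(icc)
      if (sd_baseline <= 0) stop_validation("'sd_baseline' must be > 0")
      if (icc < 0 || icc >= 1) stop_validation("'icc' must lie in [0, 1)")
      rule$sd_baseline <- sd_baseline
      rule$icc <- icc
      rule$sem <- sem_from_reliability(sd_baseline, icc)
    } else {
      if (!is.null(sd_baseline) || !is.null(icc)) {
        stop_validation("rule 'mdd': give either 'sem' or ('sd_baseline', 'icc'), not both")
      }
      rule$sem <- as.numeric(sem)
      if (!is.finite(rule$sem) || rule$sem <= 0) stop_validation("'sem' must be > 0")
    }
  }
  structure(rule, class = "classification_rule")
}

as_classification_rule <- function(x) {
  if (inherits(x, "classification_rule")) return(x)
  if (!is.list(x) || is.null(x$method)) {
    stop_validation("a classification rule must be a list with at least a 'method' field")
  }
  do.call(classification_rule, x)
}

#' Define one trial outcome
#'
#' @param name Outcome identifier, used to find the `<name>_pre` / `<name>_post`
#'   columns in the study CSV.
#' @param units Free-text display units (e.g. `"mmHg"`, `"m/s"`, `"%"`).
#' @param role `"primary"` or `"secondary"`. Exactly one outcome per study must
#'   be primary (it is drawn as the large circle).
#' @param benefit_direction `"increase_is_better"` or `"decrease_is_better"`.
#'   Mandatory: there is no safe default for which direction is improvement.
#' @param rule A [classification_rule()] (or a plain list coercible to one).
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(name, units = "", role = c("secondary", "primary"),
                         benefit_direction, rule) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("outcome 'name' must be a non-empty string")
  }
  if (grepl("[^A-Za-z0-9_.]", name)) {
    stop_validation("outcome name '", name,
                    "' may only contain letters, digits, '_' and '.'")
  }
  role <- match.arg(role)
  if (missing(benefit_direction) || is.null(benefit_direction)) {
    stop_validation("outcome '", name, "': benefit_direction must be given (no default)")
  }
  benefit_direction <- match.arg(benefit_direction,
                                 c("increase_is_better", "decrease_is_better"))
  if (missing(rule) || is.null(rule)) {
    stop_validation("outcome '", name, "': a classification rule is required")
  }
  structure(list(name = name, units = units, role = role,
                 benefit_direction = benefit_direction,
                 rule = as_classification_rule(rule)),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("<outcome_spec> %s [%s]%s, %s, rule: %s\n", x$name,
              if (nzchar(x$units)) x$units else "unitless",
              if (x$role == "primary") " (primary)" else "",
              x$benefit_direction, x$rule$method))
  invisible(x)
}

check_outcomes <- function(outcomes) {
  if (length(outcomes) == 0) stop_validation("at least one outcome is required")
  outcomes <- lapply(outcomes, function(o) {
    if (!inherits(o, "outcome_spec")) stop_validation("outcomes must be outcome_spec objects")
    o
  })
  nms <- vapply(outcomes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_validation("duplicate outcome names: ",
                                          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  n_primary <- sum(vapply(outcomes, function(o) o$role == "primary", TRUE))
  if (n_primary != 1L) {
    stop_validation("exactly one outcome must have role = 'primary' (found ", n_primary, ")")
  }
  names(outcomes) <- nms
  outcomes
}

#' Assemble a study dataset
#'
#' Binds the outcome definitions to the wide subject-level table. `subjects`
#' must have character-compatible `subject_id` and `arm` columns plus numeric
#' `<name>_pre` / `<name>_post` columns for every outcome; `NA` marks missing
#' measurements.
#'
#' @param outcomes List of [outcome_spec()] objects (exactly one primary).
#' @param subjects Data frame, one row per subject.
#' @param arm_labels Optional character vector fixing the display order of the
#'   arms (first label = top panel in the glyph chart). Defaults to order of
#'   first appearance.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(outcomes, subjects, arm_labels = NULL) {
  outcomes <- check_outcomes(outcomes)
  if (!is.data.frame(subjects)) stop_validation("'subjects' must be a data frame")
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  for (col in c("subject_id", "arm")) {
    if (!col %in% names(subjects)) stop_validation("subjects table lacks column '", col, "'")
    subjects[[col]] <- as.character(subjects[[col]])
  }
  if (anyDuplicated(subjects$subject_id)) {
    dups <- unique(subjects$subject_id[duplicated(subjects$subject_id)])
    stop_validation("duplicate subject_id: ", paste(dups, collapse = ", "))
  }
  for (o in outcomes) {
    for (col in paste0(o$name, c("_pre", "_post"))) {
      if (!col %in% names(subjects)) {
        stop_validation("outcome '", o$name, "': column '", col,
                        "' is absent from the subject table")
      }
      if (!is.numeric(subjects[[col]])) {
        stop_validation("column '", col, "' must be numeric")
      }
    }
  }
  if (is.null(arm_labels)) arm_labels <- unique(subjects$arm)
  arm_labels <- as.character(arm_labels)
  unknown <- setdiff(subjects$arm, arm_labels)
  if (length(unknown) > 0) {
    stop_validation("subject arm(s) not in arm_labels: ", paste(unknown, collapse = ", "))
  }
  keep <- c("subject_id", "arm",
            as.vector(t(outer(names(outcomes), c("_pre", "_post"), paste0))))
  structure(list(outcomes = outcomes, subjects = subjects[keep],
                 arm_labels = arm_labels),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects, %d arm(s) [%s], %d outcome(s): %s\n",
              nrow(x$subjects), length(x$arm_labels),
              paste(x$arm_labels, collapse = ", "),
              length(x$outcomes), paste(names(x$outcomes), collapse = ", ")))
  invisible(x)
}

outcome_names <- function(study) names(study$outcomes)

primary_outcome <- function(outcomes) {
  nms <- vapply(outcomes, `[[`, "", "name")
  nms[vapply(outcomes, function(o) o$role == "primary", TRUE)][1]
}

# ---- rules config (YAML / JSON) ---------------------------------------------

#' Read a rules configuration file
#'
#' The configuration names each outcome, its role, benefit direction and
#' classification rule, and may carry a `style:` block (see [glyph_style()]),
#' an `arm_order:` list and an `options:` block (`denominator: arm|observed`).
#' Format is chosen by extension: `.json` is parsed as JSON, anything else as
#' YAML.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A list with elements `outcomes` (list of [outcome_spec()]),
#'   `style` ([glyph_style()]), `arm_order` (character or NULL) and `options`.
#' @export
read_rules_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_rules_config(raw)
}

as_rules_config <- function(raw) {
  if (is.null(raw$outcomes)) stop_validation("config has no 'outcomes' list")
  outcomes <- lapply(raw$outcomes, function(o) {
    outcome_spec(name = o$name,
                 units = if (is.null(o$units)) "" else o$units,
                 role = if (is.null(o$role)) "secondary" else o$role,
                 benefit_direction = o$benefit_direction,
                 rule = o$rule)
  })
  outcomes <- check_outcomes(outcomes)
  style <- do.call(glyph_style, if (is.null(raw$style)) list() else raw$style)
  options <- if (is.null(raw$options)) list() else raw$options
  arm_order <- if (is.null(raw$arm_order)) NULL else as.character(unlist(raw$arm_order))
  list(outcomes = outcomes, style = style, arm_order = arm_order, options = options)
}

#' Write a rules configuration file
#'
#' Serializes the outcome definitions (and arm order) of a study or config to
#' YAML or JSON, so a simulated study can be re-read with [read_study_csv()].
#'
#' @param x A `study_dataset`, or a config list as returned by
#'   [read_rules_config()].
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @export
write_rules_config <- function(x, path) {
  if (inherits(x, "study_dataset")) {
    x <- list(outcomes = x$outcomes, arm_order = x$arm_labels)
  }
  out <- list(
    outcomes = lapply(x$outcomes, function(o) {
      list(name = o$name, units = o$units, role = o$role,
           benefit_direction = o$benefit_direction,
           rule = unclass(o$rule))
    })
  )
  names(out$outcomes) <- NULL
  if (!is.null(x$arm_order)) out$arm_order <- as.list(x$arm_order)
  dir_writable(path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

dir_writable <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) stop_io("output directory does not exist: ", d)
  invisible(TRUE)
}

# ---- study CSV --------------------------------------------------------------

parse_value_column <- function(x, col) {
  x <- trimws(as.character(x))
  miss <- is.na(x) | x == "" | tolower(x) == "na"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad) > 0) {
    stop_validation("column '", col, "', data row ", bad[1],
                    ": value '", x[bad[1]],
                    "' is not numeric (use an empty cell or NA for missing)")
  }
  out[miss] <- NA_real_
  out
}

#' Read a wide-format study CSV
#'
#' Expects a header with `subject_id`, `arm`, and a `<name>_pre` /
#' `<name>_post` pair for every outcome named in the configuration. Column
#' order is irrelevant. Empty cells and the literal `NA` (case-insensitive)
#' become missing values; any other non-numeric content is an error.
#'
#' @param path Path to the CSV file.
#' @param config Path to a rules config, a parsed config list, or a list of
#'   [outcome_spec()] objects.
#' @return A [study_dataset()].
#' @export
read_study_csv <- function(path, config) {
  if (!file.exists(path)) stop_io("study CSV not found: ", path)
  cfg <- resolve_config(config)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  for (col in c("subject_id", "arm")) {
    if (!col %in% names(df)) stop_validation("study CSV lacks required column '", col, "'")
  }
  subjects <- data.frame(subject_id = df$subject_id, arm = df$arm,
                         stringsAsFactors = FALSE)
  for (o in cfg$outcomes) {
    for (col in paste0(o$name, c("_pre", "_post"))) {
      if (!col %in% names(df)) {
        stop_validation("outcome '", o$name, "' is configured but column '",
                        col, "' is absent from the CSV")
      }
      subjects[[col]] <- parse_value_column(df[[col]], col)
    }
  }
  study_dataset(cfg$outcomes, subjects, arm_labels = cfg$arm_order)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) return(read_rules_config(config))
  if (is.list(config) && !is.null(config$outcomes)) {
    if (!all(vapply(config$outcomes, inherits, TRUE, "outcome_spec"))) {
      return(as_rules_config(config))
    }
    config$outcomes <- check_outcomes(config$outcomes)
    if (is.null(config$arm_order)) config$arm_order <- NULL
    return(config)
  }
  if (is.list(config) && all(vapply(config, inherits, TRUE, "outcome_spec"))) {
    return(list(outcomes = check_outcomes(config), arm_order = NULL,
                style = glyph_style(), options = list()))
  }
  stop_validation("'config' must be a file path, a config list, or a list of outcome_spec")
}

#' Write a study dataset to CSV
#'
#' Values are written at full double precision so that
#' `read_study_csv(write_study_csv(x), ...)` reproduces `x`; missing values
#' become empty cells.
#'
#' @param study A [study_dataset()].
#' @param path Output path.
#' @export
write_study_csv <- function(study, path) {
  dir_writable(path)
  df <- study$subjects
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      v <- df[[col]]
      df[[col]] <- ifelse(is.na(v), "", sprintf("%.15g", v))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- classified-status CSV --------------------------------------------------

#' Write a classified status matrix to CSV
#'
#' One row per subject; columns `subject_id`, `arm`, then one status column
#' per outcome with the literal levels `IMPROVED` / `NO_CHANGE` / `WORSENED` /
#' `MISSING`.
#'
#' @param classified A `classified_study` from [classify_study()].
#' @param path Output path.
#' @export
write_classified_csv <- function(classified, path) {
  stopifnot(inherits(classified, "classified_study"))
  dir_writable(path)
  utils::write.csv(classified$statuses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classified status matrix from CSV
#'
#' Inverse of [write_classified_csv()]. A rules config supplies the outcome
#' roles, ordering and arm order needed to lay out a chart from the statuses
#' alone.
#'
#' @param path Path to a status CSV.
#' @param config Config path, parsed config, or list of [outcome_spec()].
#' @return A `classified_study` (without the original numeric study data).
#' @export
read_classified_csv <- function(path, config) {
  if (!file.exists(path)) stop_io("classified CSV not found: ", path)
  cfg <- resolve_config(config)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  for (col in c("subject_id", "arm")) {
    if (!col %in% names(df)) stop_validation("classified CSV lacks column '", col, "'")
  }
  statuses <- data.frame(subject_id = df$subject_id, arm = df$arm,
                         stringsAsFactors = FALSE)
  for (o in cfg$outcomes) {
    if (!o$name %in% names(df)) {
      stop_validation("classified CSV lacks status column '", o$name, "'")
    }
    v <- df[[o$name]]
    bad <- setdiff(unique(v), status_levels())
    if (length(bad) > 0) {
      stop_validation("column '", o$name, "': invalid status value(s): ",
                      paste(bad, collapse = ", "))
    }
    statuses[[o$name]] <- v
  }
  if (anyDuplicated(statuses$subject_id)) stop_validation("duplicate subject_id in classified CSV")
  arm_labels <- if (is.null(cfg$arm_order)) unique(statuses$arm) else cfg$arm_order
  new_classified_study(statuses, cfg$outcomes, arm_labels, study = NULL)
}

new_classified_study <- function(statuses, outcomes, arm_labels, study = NULL) {
  structure(list(statuses = statuses, outcomes = outcomes,
                 arm_labels = arm_labels, study = study),
            class = "classified_study")
}

#' @export
print.classified_study <- function(x, ...) {
  cat(sprintf("<classified_study> %d subjects x %d outcome(s)\n",
              nrow(x$statuses), length(x$outcomes)))
  for (nm in names(x$outcomes)) {
    tab <- table(factor(x$statuses[[nm]], levels = status_levels()))
    cat(sprintf("  %-24s %s\n", nm,
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  }
  invisible(x)
}
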