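# Conventional group x time summary: mean (SD) cells and the two-way
# mixed-design ANOVA (between factor: arm; within factor: time).

#' Mean and sample standard deviation
#'
#' @param values Numeric vector with missing values already excluded.
#' @return Named numeric vector `c(mean = ..., sd = ...)`; the SD uses the
#'   n - 1 denominator.
#' @export
mean_sd <- function(values) {
  if (anyNA(values)) stop_validation("mean_sd() received missing values; exclude them first")
  if (length(values) < 2L) {
    stop_validation("sample standard deviation is undefined for fewer than 2 values")
  }
  c(mean = mean(values), sd = stats::sd(values))
}

complete_cases_long <- function(study, outcome) {
  if (!outcome %in% names(study$outcomes)) stop_validation("unknown outcome: ", outcome)
  subj <- study$subjects
  pre <- subj[[paste0(outcome, "_pre")]]
  post <- subj[[paste0(outcome, "_post")]]
  keep <- !(is.na(pre) | is.na(post))
  list(
    subject_id = subj$subject_id[keep],
    arm = factor(subj$arm[keep], levels = study$arm_labels),
    pre = pre[keep], post = post[keep],
    n_dropped = sum(!keep)
  )
}

#' Two-way mixed-design ANOVA for one outcome
#'
#' Fits the classical split-plot decomposition with arm as the
#' between-subjects factor and time (pre/post) as the within-subjects factor,
#' via `stats::aov` with a subject error stratum. Subjects with a missing pre
#' or post value are dropped for this outcome (listwise deletion; the number
#' dropped is reported via a message and in the result).
#'
#' Degenerate data are handled explicitly: an effect with zero sum of squares
#' has F = 0 and p = 1 regardless of the error mean square.
#'
#' @param study A [study_dataset()] with at least two arms.
#' @param outcome Outcome name.
#' @return List with `p_time`, `p_group`, `p_interaction`, the matching F
#'   statistics `F_time`, `F_group`, `F_interaction`, and `n_complete`,
#'   `n_dropped`.
#' @export
mixed_anova <- function(study, outcome) {
  stopifnot(inherits(study, "study_dataset"))
  if (length(study$arm_labels) < 2L) {
    stop_validation("mixed_anova() needs at least two arms")
  }
  cc <- complete_cases_long(study, outcome)
  arm_n <- table(cc$arm)
  if (any(arm_n < 2)) {
    small <- names(arm_n)[arm_n < 2]
    stop_validation("outcome '", outcome, "': arm(s) with fewer than 2 complete cases: ",
                    paste(small, collapse = ", "))
  }
  if (cc$n_dropped > 0) {
    message("mixed_anova: outcome '", outcome, "': dropped ", cc$n_dropped,
            " subject(s) with incomplete data")
  }
  long <- data.frame(
    value = c(cc$pre, cc$post),
    arm = factor(rep(cc$arm, 2), levels = levels(cc$arm)),
    time = factor(rep(c("pre", "post"), each = length(cc$pre)),
                  levels = c("pre", "post")),
    subject = factor(rep(cc$subject_id, 2))
  )
  fit <- stats::aov(value ~ arm * time + Error(subject), data = long)
  sm <- summary(fit)
  get_effect <- function(name, stratum_name) {
    tab <- sm[[stratum_name]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(name, rn)
    j <- match("Residuals", rn)
    ss_eff <- tab[i, "Sum Sq"]; df_eff <- tab[i, "Df"]
    ss_err <- tab[j, "Sum Sq"]; df_err <- tab[j, "Df"]
    if (ss_eff <= 1e-12 * max(ss_eff + ss_err, 1)) {
      return(list(F = 0, p = 1))
    }
    ms_eff <- ss_eff / df_eff; ms_err <- ss_err / df_err
    if (ms_err <= 0) return(list(F = Inf, p = 0))
    f <- ms_eff / ms_err
    list(F = f, p = stats::pf(f, df_eff, df_err, lower.tail = FALSE))
  }
  strata <- names(sm)
  between <- strata[grepl("subject", strata)]
  within <- strata[grepl("Within", strata)]
  grp <- get_effect("arm", between)
  tim <- get_effect("time", within)
  int <- get_effect("arm:time", within)
  list(p_time = tim$p, p_group = grp$p, p_interaction = int$p,
       F_time = tim$F, F_group = grp$F, F_interaction = int$F,
       n_complete = length(cc$pre), n_dropped = cc$n_dropped)
}

arm_slug <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(x)))

#' Conventional summary table
#'
#' One row per outcome: mean and SD for each arm at each timepoint (computed
#' on the complete cases used by the ANOVA) plus the time, group and
#' interaction p-values from [mixed_anova()]. Columns follow the arm order of
#' the study, `<arm>_pre_mean, <arm>_pre_sd, <arm>_post_mean, <arm>_post_sd`.
#'
#' @param study A [study_dataset()] with two arms.
#' @return Data frame of class `summary_table`.
#' @export
summary_table <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  rows <- lapply(names(study$outcomes), function(nm) {
    cc <- complete_cases_long(study, nm)
    row <- data.frame(outcome = nm, units = study$outcomes[[nm]]$units,
                      stringsAsFactors = FALSE)
    for (a in study$arm_labels) {
      idx <- cc$arm == a
      if (sum(idx) < 2) {
        stop_validation("outcome '", nm, "': arm '", a, "' has fewer than 2 complete cases")
      }
      s <- arm_slug(a)
      mp <- mean_sd(cc$pre[idx]); mq <- mean_sd(cc$post[idx])
      row[[paste0(s, "_pre_mean")]] <- mp[["mean"]]
      row[[paste0(s, "_pre_sd")]] <- mp[["sd"]]
      row[[paste0(s, "_post_mean")]] <- mq[["mean"]]
      row[[paste0(s, "_post_sd")]] <- mq[["sd"]]
    }
    an <- suppressMessages(mixed_anova(study, nm))
    row$p_time <- an$p_time
    row$p_group <- an$p_group
    row$p_interaction <- an$p_interaction
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "arm_labels") <- study$arm_labels
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Format a p-value for display
#'
#' Values below 0.001 print as `"<0.001"`; otherwise three decimals. Stored
#' values remain exact — this affects display only.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' @export
print.summary_table <- function(x, digits = 1, ...) {
  arms <- attr(x, "arm_labels")
  hdr <- c("Outcome", unlist(lapply(arms, function(a) paste(a, c("pre", "post")))),
           "Time", "Group", "Interaction")
  lines <- lapply(seq_len(nrow(x)), function(i) {
    cells <- character(0)
    for (a in arms) {
      s <- arm_slug(a)
      cells <- c(cells,
        sprintf("%.*f (%.*f)", digits, x[[paste0(s, "_pre_mean")]][i],
                digits, x[[paste0(s, "_pre_sd")]][i]),
        sprintf("%.*f (%.*f)", digits, x[[paste0(s, "_post_mean")]][i],
                digits, x[[paste0(s, "_post_sd")]][i]))
    }
    u <- x$units[i]
    c(paste0(x$outcome[i], if (nzchar(u)) paste0(", ", u) else ""), cells,
      format_p(x$p_time[i]), format_p(x$p_group[i]), format_p(x$p_interaction[i]))
  })
  m <- rbind(hdr, do.call(rbind, lines))
  widths <- apply(nchar(m), 2, max)
  for (i in seq_len(nrow(m))) {
    padded <- mapply(formatC, m[i, ], width = widths,
                     MoreArgs = list(flag = "-"))
    cat(paste(padded, collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a summary table to CSV
#'
#' Numeric cells are written at full precision; rounding is a display concern.
#'
#' @param x A `summary_table`.
#' @param path Output path.
#' @export
write_summary_csv <- function(x, path) {
  dir_writable(path)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
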