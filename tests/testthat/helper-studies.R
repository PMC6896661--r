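# Shared builders and independent oracles for the test suite.

# cache the packaged example studies (deterministic, so safe to share)
.fx <- new.env(parent = emptyenv())
cached_f2 <- function() {
  if (is.null(.fx$f2)) .fx$f2 <- fixture_f2()
  .fx$f2
}
cached_f4 <- function() {
  if (is.null(.fx$f4)) .fx$f4 <- fixture_f4()
  .fx$f4
}
cached_f5 <- function() {
  if (is.null(.fx$f5)) .fx$f5 <- fixture_f5()
  .fx$f5
}

# tiny two-arm study built directly (no generator involved)
tiny_study <- function() {
  outcomes <- list(
    outcome_spec("bp", units = "mmHg", role = "primary",
                 benefit_direction = "decrease_is_better",
                 rule = classification_rule("risk_threshold", threshold = 3)),
    outcome_spec("fmd", units = "%",
                 benefit_direction = "increase_is_better",
                 rule = classification_rule("delta_zero"))
  )
  subjects <- data.frame(
    subject_id = c("P1", "P2", "P3", "P4"),
    arm = c("A", "A", "B", "B"),
    bp_pre = c(140, 150, 138, 142), bp_post = c(135, 149, 139, 150),
    fmd_pre = c(5, 6, 7, 8), fmd_post = c(6, 6, NA, 7),
    stringsAsFactors = FALSE
  )
  study_dataset(outcomes, subjects, arm_labels = c("A", "B"))
}

# random small study for property tests (values, arms, rules vary with seed)
random_study <- function(seed, n_per_arm = 5, rule = NULL,
                         direction = NULL) {
  set.seed(seed)
  if (is.null(direction)) {
    direction <- sample(c("increase_is_better", "decrease_is_better"), 1)
  }
  if (is.null(rule)) {
    rule <- sample(c("delta_zero", "risk_threshold", "mdd"), 1)
  }
  r <- switch(rule,
    delta_zero = classification_rule("delta_zero"),
    risk_threshold = classification_rule("risk_threshold",
                                         threshold = runif(1, 0.5, 3)),
    mdd = classification_rule("mdd", sem = runif(1, 0.5, 2),
                              confidence = runif(1, 0.8, 0.99)))
  outcomes <- list(outcome_spec("y", role = "primary",
                                benefit_direction = direction, rule = r))
  n <- 2 * n_per_arm
  pre <- rnorm(n, 10, 2)
  post <- pre + rnorm(n, 0, 2)
  miss <- runif(n) < 0.15
  post[miss] <- NA
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    arm = rep(c("Experimental", "Control"), each = n_per_arm),
    y_pre = pre, y_post = post, stringsAsFactors = FALSE
  )
  study_dataset(outcomes, subjects, arm_labels = c("Experimental", "Control"))
}

flip_direction <- function(study) {
  o <- study$outcomes[[1]]
  o$benefit_direction <- setdiff(c("increase_is_better", "decrease_is_better"),
                                 o$benefit_direction)
  study$outcomes[[1]] <- o
  study
}

# brute-force quantile oracle: sort, slice into k blocks, label extremes
quantile_oracle <- function(deltas, k, direction) {
  n <- length(deltas)
  stopifnot(n %% k == 0, !anyDuplicated(deltas))
  m <- n %/% k
  ord <- order(deltas)
  block <- integer(n)
  block[ord] <- rep(seq_len(k), each = m)
  s <- if (direction == "increase_is_better") 1 else -1
  status <- rep("NO_CHANGE", n)
  status[block == if (s > 0) k else 1] <- "IMPROVED"
  status[block == if (s > 0) 1 else k] <- "WORSENED"
  status
}

# split-plot sums-of-squares oracle for BALANCED two-arm two-time designs,
# written independently of the package (cell-mean decomposition)
anova_oracle <- function(pre, post, arm) {
  arm <- as.character(arm)
  groups <- unique(arm)
  stopifnot(length(groups) == 2, length(unique(table(arm))) == 1)
  a <- 2; b <- 2
  n <- sum(arm == groups[1])
  y <- c(pre, post)
  g_of <- rep(arm, 2)
  t_of <- rep(c("pre", "post"), each = length(pre))
  grand <- mean(y)
  subj_mean <- (pre + post) / 2
  g_mean <- tapply(y, g_of, mean)
  t_mean <- tapply(y, t_of, mean)
  cell <- tapply(y, list(g_of, t_of), mean)
  ss_between <- b * sum((subj_mean - grand)^2)
  ss_A <- b * n * sum((g_mean - grand)^2)
  ss_subj <- ss_between - ss_A
  ss_B <- a * n * sum((t_mean - grand)^2)
  ss_AB <- 0
  for (g in rownames(cell)) for (tt in colnames(cell)) {
    ss_AB <- ss_AB + n * (cell[g, tt] - g_mean[[g]] - t_mean[[tt]] + grand)^2
  }
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_between - ss_B - ss_AB
  df_subj <- a * (n - 1)
  df_err <- a * (n - 1) * (b - 1)
  F_A <- (ss_A / (a - 1)) / (ss_subj / df_subj)
  F_B <- (ss_B / (b - 1)) / (ss_err / df_err)
  F_AB <- (ss_AB / ((a - 1) * (b - 1))) / (ss_err / df_err)
  list(F_group = F_A, F_time = F_B, F_interaction = F_AB,
       p_group = pf(F_A, a - 1, df_subj, lower.tail = FALSE),
       p_time = pf(F_B, b - 1, df_err, lower.tail = FALSE),
       p_interaction = pf(F_AB, (a - 1) * (b - 1), df_err, lower.tail = FALSE))
}

status_count <- function(classified, outcome, status) {
  sum(classified$statuses[[outcome]] == status)
}
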