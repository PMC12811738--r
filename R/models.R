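# Covariate-structured linear mixed models dissecting task and sex effects.
#
# Each outcome is modelled as
#   outcome ~ task + sex + task:sex + covariates + (1 | subject)
# by REML, with the baseline task as reference. The covariate structure
# encodes a priori cardiorespiratory assumptions: e.g., heart rate controls
# for pulse wave velocity (vascular tone) and the RSA proxy (respiratory
# drive); each band power controls for RSA and the complementary band.

TASK_LEVELS <- c("baseline", "long_interval", "short_interval")
OUTCOMES <- c("hr", "ln_lf_hrv", "ln_hf_hrv", "pttv", "map",
              "ln_lf_bpv", "ln_hf_bpv")

#' A priori covariate structure for each outcome
#'
#' @param map_covariates `"pwv_hr"` (the default) or `"hr_pttv"`: which
#'   covariate pair the MAP model uses. Both appear in the source literature;
#'   the default isolates stroke-volume-driven blood-flow changes by
#'   controlling vascular tone (PWV) and heart rate.
#' @return Named list: outcome -> character vector of covariates.
#' @export
model_specs <- function(map_covariates = c("pwv_hr", "hr_pttv")) {
  map_covariates <- match.arg(map_covariates)
  list(
    hr = c("pwv", "rsa"),
    ln_lf_hrv = c("rsa", "ln_hf_hrv"),
    ln_hf_hrv = c("rsa", "ln_lf_hrv"),
    pttv = "hr",
    map = if (map_covariates == "pwv_hr") c("pwv", "hr") else c("hr", "pttv"),
    ln_lf_bpv = c("rsa", "ln_hf_bpv"),
    ln_hf_bpv = c("rsa", "ln_lf_bpv")
  )
}

#' Assemble the long modelling table from per-task summary rows
#'
#' @param summary_rows data.frame of [summarize_task()] rows (one per
#'   subject x task).
#' @return The long table with `subject`, `sex` factors and `task` an ordered
#'   reference-coded factor (baseline first). Subjects with no rows at all are
#'   dropped with a warning; rows with missing outcomes are dropped later,
#'   per model.
#' @export
build_long_table <- function(summary_rows) {
  if (is.null(summary_rows) || nrow(summary_rows) == 0L)
    stop_data("empty summary table")
  need <- c("subject", "sex", "task")
  miss <- setdiff(need, names(summary_rows))
  if (length(miss)) stop_data("summary table lacks column(s): ",
                              paste(miss, collapse = ", "))
  tab <- summary_rows
  tab$task <- factor(as.character(tab$task), levels = TASK_LEVELS)
  if (anyNA(tab$task)) stop_data("unknown task label in summary table")
  tab$sex <- factor(as.character(tab$sex), levels = c("F", "M"))
  tab$subject <- factor(tab$subject)
  dup <- duplicated(tab[, c("subject", "task")])
  if (any(dup)) stop_data("duplicated subject x task rows")
  empty <- setdiff(levels(tab$subject), unique(as.character(tab$subject)))
  if (length(empty)) {
    warning(length(empty), " subject(s) without any task rows dropped")
    tab$subject <- droplevels(tab$subject)
  }
  rownames(tab) <- NULL
  tab
}

#' Fit one covariate-structured mixed model
#'
#' REML fit of `outcome ~ task * sex + covariates + (1 | subject)` with
#' Satterthwaite-based type-III F tests for task, sex, and task x sex.
#' Rows missing the outcome or any covariate are dropped (count logged).
#' A singular fit (zero between-subject variance) is retained at the boundary
#' with a warning.
#'
#' @param table Long table from [build_long_table()].
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names (main effects).
#' @return Object of class `fivs_fit`: `fit` (the `lmerModLmerTest`), `anova`
#'   (type-III F table), `outcome`, `covariates`, `n_obs`, `n_subjects`,
#'   `n_dropped`, `data` (rows used), `singular`.
#' @export
fit_mixed_model <- function(table, outcome, covariates = character(0)) {
  if (!outcome %in% names(table)) stop_data("outcome column not found: ", outcome)
  miss_cov <- setdiff(covariates, names(table))
  if (length(miss_cov)) stop_data("covariate column(s) not found: ",
                                  paste(miss_cov, collapse = ", "))
  used <- c(outcome, covariates, "task", "sex", "subject")
  keep <- stats::complete.cases(table[, used, drop = FALSE])
  dat <- droplevels(table[keep, , drop = FALSE])
  n_dropped <- sum(!keep)
  if (nrow(dat) < 6L) stop_data("too few complete rows to fit a mixed model")
  tab_per_subj <- table(dat$subject)
  if (sum(tab_per_subj >= 2L) < 2L)
    stop_data("at least 2 subjects with 2+ tasks are required")
  if (nlevels(dat$sex) < 2L)
    stop_data("both sexes must be present to estimate sex effects")
  for (cv in covariates) {
    if (isTRUE(all.equal(dat[[cv]], dat[[outcome]])))
      stop_data("rank deficiency: covariate '", cv,
                "' is identical to the outcome")
  }
  rhs <- paste(c("task * sex", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0(outcome, " ~ ", rhs, " + (1 | subject)"))
  X <- stats::model.matrix(stats::as.formula(paste0("~", rhs)), dat)
  if (qr(X)$rank < ncol(X))
    stop_data("rank-deficient fixed-effect design for outcome ", outcome)
  fit <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular)
    warning("singular fit for ", outcome,
            ": between-subject variance at the boundary (kept at zero)")
  av <- suppressMessages(stats::anova(fit, type = 3))
  structure(list(fit = fit, anova = av, outcome = outcome,
                 covariates = covariates, n_obs = nrow(dat),
                 n_subjects = nlevels(dat$subject), n_dropped = n_dropped,
                 data = dat, singular = singular),
            class = "fivs_fit")
}

#' @export
print.fivs_fit <- function(x, ...) {
  cat(sprintf("Mixed model for %s (covariates: %s), %d obs / %d subjects (%d rows dropped)\n",
              x$outcome, paste(x$covariates, collapse = ", "),
              x$n_obs, x$n_subjects, x$n_dropped))
  print(x$anova)
  invisible(x)
}

# contrast vector over the fixed effects, averaged over sex
.contrast_vector <- function(fit, weights) {
  fe <- names(lme4::fixef(fit))
  L <- setNames(numeric(length(fe)), fe)
  for (nm in names(weights)) {
    if (!nm %in% fe) stop_data("fixed effect not found: ", nm)
    L[nm] <- weights[[nm]]
  }
  L
}

.contest_row <- function(fit, L, label) {
  res <- lmerTest::contest1D(fit, L, confint = FALSE)
  data.frame(contrast = label, estimate = res$Estimate,
             se = res$`Std. Error`, df = res$df, t = res$`t value`,
             p = res$`Pr(>|t|)`, stringsAsFactors = FALSE)
}

#' Pairwise task contrasts
#'
#' The three pairwise task comparisons (baseline vs long, baseline vs short,
#' long vs short), averaged over sex, with Satterthwaite t tests. p values are
#' uncorrected: comparisons are reported regardless of the omnibus F.
#' Estimates satisfy the linearity identity
#' `(short - BL) - (long - BL) = (short - long)`.
#'
#' @param fit A [fit_mixed_model()] result.
#' @return data.frame with `contrast`, `estimate` (second task minus first),
#'   `se`, `df`, `t`, `p`.
#' @export
task_contrasts <- function(fit) {
  m <- fit$fit
  rbind(
    .contest_row(m, .contrast_vector(m, list(
      tasklong_interval = 1, `tasklong_interval:sexM` = 0.5)),
      "BL vs long"),
    .contest_row(m, .contrast_vector(m, list(
      taskshort_interval = 1, `taskshort_interval:sexM` = 0.5)),
      "BL vs short"),
    .contest_row(m, .contrast_vector(m, list(
      taskshort_interval = 1, tasklong_interval = -1,
      `taskshort_interval:sexM` = 0.5, `tasklong_interval:sexM` = -0.5)),
      "long vs short")
  )
}

#' Sex differences in task-related change
#'
#' Difference-in-change contrasts: for each task pair, the male change minus
#' the female change (the task x sex interaction re-expressed per pair).
#'
#' @param fit A [fit_mixed_model()] result.
#' @return data.frame as in [task_contrasts()]; positive estimates mean males
#'   change more than females.
#' @export
sex_task_contrasts <- function(fit) {
  m <- fit$fit
  if (nlevels(fit$data$sex) < 2L)
    stop_data("both sexes must be present for interaction contrasts")
  rbind(
    .contest_row(m, .contrast_vector(m, list(`tasklong_interval:sexM` = 1)),
                 "sex x (BL vs long)"),
    .contest_row(m, .contrast_vector(m, list(`taskshort_interval:sexM` = 1)),
                 "sex x (BL vs short)"),
    .contest_row(m, .contrast_vector(m, list(
      `taskshort_interval:sexM` = 1, `tasklong_interval:sexM` = -1)),
      "sex x (long vs short)")
  )
}

#' Dissect all seven outcomes
#'
#' Fits the seven covariate-structured models, runs the single-pass influence
#' screen on each, recomputes contrasts on the screened fits, and assembles a
#' direction summary (one row per outcome with `<`, `=`, `>` labels for the
#' task pattern, the overall sex difference, and the task x sex interaction).
#'
#' @param long_table A [build_long_table()] table.
#' @param map_covariates Passed to [model_specs()].
#' @param alpha Significance level for the direction labels (default 0.05).
#' @param influence If `TRUE` (default), apply [influence_screen()] per model.
#' @return Object of class `fivs_dissection`: `fits`, `task_contrasts`,
#'   `sex_contrasts`, `influence`, `summary` (the direction table).
#' @export
dissect_all_outcomes <- function(long_table, map_covariates = "pwv_hr",
                                 alpha = 0.05, influence = TRUE) {
  specs <- model_specs(map_covariates)
  fits <- list(); tcon <- list(); scon <- list(); infl <- list()
  for (oc in names(specs)) {
    if (!oc %in% names(long_table)) {
      warning("outcome column missing, model skipped: ", oc)
      next
    }
    ft <- fit_mixed_model(long_table, oc, specs[[oc]])
    if (influence) {
      scr <- influence_screen(ft)
      infl[[oc]] <- scr$report
      if (!is.null(scr$refit)) ft <- scr$refit
    }
    fits[[oc]] <- ft
    tcon[[oc]] <- cbind(outcome = oc, task_contrasts(ft))
    scon[[oc]] <- cbind(outcome = oc, sex_task_contrasts(ft))
  }
  summary <- do.call(rbind, lapply(names(fits), function(oc) {
    direction_row(fits[[oc]], tcon[[oc]], scon[[oc]], alpha)
  }))
  structure(list(fits = fits,
                 task_contrasts = do.call(rbind, tcon),
                 sex_contrasts = do.call(rbind, scon),
                 influence = infl, summary = summary),
            class = "fivs_dissection")
}

direction_row <- function(ft, tc, sc, alpha) {
  lab <- function(est, p, lt, gt) {
    if (is.na(p) || p >= alpha) "=" else if (est > 0) lt else gt
  }
  # task pattern string BL ? long ? short from the two adjacent comparisons
  a <- lab(tc$estimate[tc$contrast == "BL vs long"],
           tc$p[tc$contrast == "BL vs long"], "<", ">")
  b <- lab(tc$estimate[tc$contrast == "long vs short"],
           tc$p[tc$contrast == "long vs short"], "<", ">")
  pattern <- paste("BL", a, "long", b, "short")

  av <- ft$anova
  sex_p <- if ("sex" %in% rownames(av)) av["sex", "Pr(>F)"] else NA
  sex_est <- tryCatch(lme4::fixef(ft$fit)[["sexM"]], error = function(e) NA)
  sex_lab <- if (is.na(sex_p) || sex_p >= alpha) "-" else {
    if (sex_est > 0) "F < M" else "M < F"
  }
  int_p <- if ("task:sex" %in% rownames(av)) av["task:sex", "Pr(>F)"] else NA
  base_changes <- sc$estimate[sc$contrast %in%
                                c("sex x (BL vs long)", "sex x (BL vs short)")]
  overall_change <- mean(tc$estimate[tc$contrast %in%
                                       c("BL vs long", "BL vs short")])
  # "less change" compares magnitudes: a male-minus-female difference in the
  # same direction as the overall change means females moved less
  int_lab <- if (is.na(int_p) || int_p >= alpha) "-" else {
    if (sign(mean(base_changes)) == sign(overall_change))
      "F = less change" else "F = more change"
  }
  data.frame(outcome = ft$outcome, task_pattern = pattern,
             sex_effect = sex_lab, interaction = int_lab,
             stringsAsFactors = FALSE)
}

#' @export
print.fivs_dissection <- function(x, ...) {
  cat("Task and sex effect summary (direction labels at the fitted alpha):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Simulate a long outcome table from a known linear mixed model
#'
#' Table-level generator for validating the model-dissection machinery:
#' outcome `y = mu + task effects + sex effect + task x sex interaction +
#' covariate effects + subject intercept + residual`, with covariates `c1`,
#' `c2` drawn standard normal per row.
#'
#' @param n_subjects Number of subjects (3 task rows each).
#' @param task_effects Named `c(long, short)` fixed effects vs baseline.
#' @param sex_effect Additive male offset.
#' @param interaction Named `c(long, short)` additional male change.
#' @param covariate_effects Length-2 coefficients for `c1`, `c2`.
#' @param sd_subject,sd_resid Random-intercept and residual SDs.
#' @param fraction_female Proportion female.
#' @param mu Grand mean.
#' @param seed Integer seed.
#' @return Long table (already through [build_long_table()]) with outcome `y`
#'   and covariates `c1`, `c2`; attribute `truth` carries the generating
#'   parameters.
#' @export
simulate_outcome_table <- function(n_subjects, task_effects = c(long = 0, short = 0),
                                   sex_effect = 0,
                                   interaction = c(long = 0, short = 0),
                                   covariate_effects = c(0, 0),
                                   sd_subject = 1, sd_resid = 1,
                                   fraction_female = 0.5, mu = 0, seed = 1) {
  set.seed(as.integer(seed))
  n_f <- round(n_subjects * fraction_female)
  sex <- c(rep("F", n_f), rep("M", n_subjects - n_f))
  subj <- sprintf("S%04d", seq_len(n_subjects))
  b0 <- stats::rnorm(n_subjects, 0, sd_subject)
  rows <- expand.grid(subject = subj, task = TASK_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$sex <- sex[match(rows$subject, subj)]
  rows$c1 <- stats::rnorm(nrow(rows))
  rows$c2 <- stats::rnorm(nrow(rows))
  te <- c(baseline = 0, long_interval = unname(task_effects["long"]),
          short_interval = unname(task_effects["short"]))
  ie <- c(baseline = 0, long_interval = unname(interaction["long"]),
          short_interval = unname(interaction["short"]))
  rows$y <- mu + te[rows$task] + sex_effect * (rows$sex == "M") +
    ie[rows$task] * (rows$sex == "M") +
    covariate_effects[1] * rows$c1 + covariate_effects[2] * rows$c2 +
    b0[match(rows$subject, subj)] + stats::rnorm(nrow(rows), 0, sd_resid)
  out <- build_long_table(rows)
  attr(out, "truth") <- list(task_effects = task_effects,
                             sex_effect = sex_effect,
                             interaction = interaction,
                             covariate_effects = covariate_effects,
                             sd_subject = sd_subject, sd_resid = sd_resid,
                             mu = mu)
  out
}
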