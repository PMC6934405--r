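## Study orchestration: baseline-balanced group assignment, descriptive
## statistics with 95% confidence intervals, the mixed-model contract
## (estimation delegated to lme4/lmerTest, Wald chi-square to car, contrasts
## to emmeans), and the end-to-end pipeline over a synthetic study.

#' Assign subjects to balanced groups from baseline scores
#'
#' Sequential procedure: subjects are pre-assigned in a counterbalanced
#' (round-robin) order; each subject's baseline score (percent correct on the
#' second pre-training block) is then compared with the running means of the
#' groups assigned so far. A score below every current group mean sends the
#' subject to the group with the highest mean, a score above every mean to
#' the group with the lowest; otherwise the pre-assignment stands. Moves are
#' capped so that final group sizes stay equal. A balance check warns if the
#' final spread of group means exceeds `tolerance`.
#'
#' @param scores Named numeric vector: baseline percent correct per subject,
#'   in assignment (arrival) order.
#' @param groups Group labels (default the three study groups).
#' @param pre_assignment Optional character vector of pre-assigned groups;
#'   default round-robin over `groups`.
#' @param tolerance Maximum acceptable gap between group means, in
#'   percentage points (default 5).
#' @return A list of class `"group_assignment"`: `assignment` (data frame
#'   subject/score/group), `group_means`, `balanced`.
#' @export
assign_groups <- function(scores,
                          groups = c("control", "AMD-trained", "AMRD-trained"),
                          pre_assignment = NULL, tolerance = 5) {
  n <- length(scores)
  if (n %% length(groups) != 0L) {
    warning("number of subjects is not a multiple of the number of groups")
  }
  cap <- ceiling(n / length(groups))
  if (is.null(pre_assignment)) {
    pre_assignment <- rep(groups, length.out = n)
  }
  if (is.null(names(scores))) names(scores) <- sprintf("S%02d", seq_len(n))

  assigned <- character(n)
  for (i in seq_len(n)) {
    sizes <- table(factor(assigned[seq_len(i - 1L)], levels = groups))
    means <- vapply(groups, function(g) {
      prev <- scores[seq_len(i - 1L)][assigned[seq_len(i - 1L)] == g]
      if (length(prev)) mean(prev) else NA_real_
    }, numeric(1))
    open <- groups[sizes < cap]
    target <- pre_assignment[i]
    if (!target %in% open) target <- open[1L]
    if (!any(is.na(means))) {
      if (scores[i] < min(means)) {
        cand <- open[order(means[open], decreasing = TRUE)]
        target <- cand[1L]
      } else if (scores[i] > max(means)) {
        cand <- open[order(means[open])]
        target <- cand[1L]
      }
    }
    assigned[i] <- target
  }

  gm <- tapply(scores, factor(assigned, levels = groups), mean)
  balanced <- diff(range(gm)) <= tolerance
  if (!balanced) {
    warning(sprintf("group means differ by %.1f points (> %.1f tolerance)",
                    diff(range(gm)), tolerance))
  }
  structure(list(
    assignment = data.frame(subject = names(scores), score = unname(scores),
                            group = assigned, stringsAsFactors = FALSE),
    group_means = gm, balanced = balanced
  ), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group assignment (baseline-balanced):\n")
  print(round(x$group_means, 1))
  cat(if (x$balanced) "balance check passed\n" else "balance check FAILED\n")
  invisible(x)
}

#' Descriptive statistics with 95% confidence intervals
#'
#' Mean, SD and t-based 95% CI of an outcome within each cell of a grouping.
#' Binary 0/1 outcomes are scaled to percent, in which case trial-level SDs
#' land near `100 * sqrt(p(1-p))`.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column.
#' @param by Character vector of grouping columns.
#' @param percent Multiply a 0/1 outcome by 100 (default: auto-detect).
#' @return Data frame: grouping columns plus `n`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`.
#' @export
descriptives <- function(data, outcome, by, percent = NULL) {
  v <- data[[outcome]]
  if (is.logical(v)) v <- as.numeric(v)
  if (is.null(percent)) percent <- all(v %in% c(0, 1))
  if (percent) v <- 100 * v
  key <- interaction(data[by], drop = TRUE, sep = ".")
  rows <- lapply(split(seq_along(v), key), function(ix) {
    if (length(ix) < 2L) stop("cells need at least 2 records")
    x <- v[ix]
    m <- mean(x); s <- stats::sd(x)
    half <- stats::qt(0.975, length(x) - 1L) * s / sqrt(length(x))
    cbind(data[ix[1L], by, drop = FALSE],
          data.frame(n = length(x), mean = m, sd = s,
                     ci_lo = m - half, ci_hi = m + half))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-model specification
#'
#' Declares the model the pipeline fits: outcome, fixed group-by-test
#' structure (plus phonetic feature for IT outcomes), a control covariate
#' (test block or centered trial order), and the maximal within-unit random
#' structure, with family linear or binomial. Reference levels are
#' control/pretest.
#'
#' @param outcome `"threshold_log10"`, `"trial_correct"` or `"relative_it"`.
#' @param feature_term Include phonetic feature as a crossed fixed effect
#'   (IT analyses). Default `FALSE`.
#' @param control One of `"block"`, `"trial_order"` or `"none"`.
#' @param family `"linear"` or `"binomial"`.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(outcome = c("threshold_log10", "trial_correct",
                                   "relative_it"),
                       feature_term = FALSE,
                       control = c("none", "block", "trial_order"),
                       family = c("linear", "binomial")) {
  outcome <- match.arg(outcome)
  structure(list(outcome = outcome, feature_term = feature_term,
                 control = match.arg(control), family = match.arg(family)),
            class = "model_spec")
}

spec_formula <- function(spec, maximal = TRUE) {
  fixed <- "group * test"
  if (spec$feature_term) fixed <- paste(fixed, "* feature")
  if (spec$control == "block") fixed <- paste(fixed, "+ block")
  if (spec$control == "trial_order") fixed <- paste(fixed, "+ trial_order_c")
  rand <- if (maximal) "(1 + test | subject)" else "(1 | subject)"
  stats::as.formula(paste(spec$outcome, "~", fixed, "+", rand))
}

prep_model_data <- function(spec, data) {
  data$group <- stats::relevel(factor(data$group), ref = "control")
  test_col <- if ("test" %in% names(data)) "test" else "session"
  data$test <- stats::relevel(factor(data[[test_col]]), ref = "pretest")
  if (spec$feature_term) data$feature <- factor(data$feature)
  if (spec$control == "trial_order") {
    data$trial_order_c <- scale(data$trial, scale = FALSE)[, 1]
  }
  if (spec$outcome == "trial_correct" && !"trial_correct" %in% names(data)) {
    data$trial_correct <- as.numeric(data$correct)
  }
  data
}

#' Fit the specified mixed-effects model
#'
#' Estimation is delegated: linear outcomes go to `lmerTest::lmer`
#' (Satterthwaite degrees of freedom), binary outcomes to `lme4::glmer`
#' (Wald z, asymptotic CIs), and Type-III tests to `car::Anova`. The model
#' starts with the maximal within-unit random structure (by-subject
#' intercepts and test slopes); if that fails to converge it is simplified
#' to random intercepts, and the simplification is recorded.
#'
#' @param spec A [model_spec].
#' @param data Data frame with columns `group`, `test` (or `session`),
#'   `subject`, the outcome, and any control covariate.
#' @return An object of class `"vocotrain_model"`: `fit` (the lme4 object),
#'   `effects` (EffectTable: term, estimate, se, ci_lo, ci_hi, statistic, p),
#'   `anova` (Type-III table), `spec`, `random_structure`, `converged`.
#' @export
fit_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- prep_model_data(spec, data)

  try_fit <- function(maximal) {
    form <- spec_formula(spec, maximal)
    res <- suppressMessages(suppressWarnings(tryCatch({
      if (spec$family == "linear") {
        lmerTest::lmer(form, data = data,
                       control = lme4::lmerControl(calc.derivs = FALSE))
      } else {
        lme4::glmer(form, data = data, family = stats::binomial,
                    control = lme4::glmerControl(calc.derivs = FALSE),
                    nAGQ = 0L)
      }
    }, error = function(e) e)))
    if (inherits(res, "error")) return(NULL)
    msgs <- res@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs))) return(NULL)
    if (lme4::isSingular(res, tol = 1e-5) && maximal) return(NULL)
    res
  }

  fit <- try_fit(TRUE)
  random_structure <- "maximal (1 + test | subject)"
  if (is.null(fit)) {
    fit <- try_fit(FALSE)
    random_structure <- "simplified (1 | subject)"
  }
  if (is.null(fit)) stop("mixed model failed to converge even after simplification")

  cf <- summary(fit)$coefficients
  if (spec$family == "linear") {
    eff <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"],
                      statistic = cf[, "t value"],
                      p = cf[, "Pr(>|t|)"], row.names = NULL)
    half <- stats::qt(0.975, cf[, "df"]) * cf[, "Std. Error"]
    an <- stats::anova(fit, type = 3)
  } else {
    eff <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"],
                      statistic = cf[, "z value"],
                      p = cf[, "Pr(>|z|)"], row.names = NULL)
    half <- 1.96 * cf[, "Std. Error"]   # asymptotic (Wald) intervals
    an <- car::Anova(fit, type = 3)
  }
  eff$ci_lo <- eff$estimate - half
  eff$ci_hi <- eff$estimate + half
  eff <- eff[, c("term", "estimate", "se", "ci_lo", "ci_hi", "statistic", "p")]

  structure(list(fit = fit, effects = eff, anova = an, spec = spec,
                 random_structure = random_structure, converged = TRUE),
            class = "vocotrain_model")
}

#' @export
print.vocotrain_model <- function(x, digits = 3, ...) {
  cat(sprintf("mixed model (%s, %s random effects)\n",
              x$spec$family, x$random_structure))
  eff <- x$effects
  eff[-1] <- lapply(eff[-1], round, digits)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' @export
summary.vocotrain_model <- function(object, ...) {
  list(effects = object$effects, anova = object$anova,
       random_structure = object$random_structure)
}

#' @export
coef.vocotrain_model <- function(object, ...) {
  stats::setNames(object$effects$estimate, object$effects$term)
}

#' Per-group pre-to-post contrasts
#'
#' Estimated marginal means by group and test (via emmeans), the pre-to-post
#' change within each group, and the between-group differences of those
#' changes, each with 95% CIs. For threshold outcomes the change is reported
#' as improvement (pretest minus posttest, positive = better).
#'
#' @param model A [fit_model] result.
#' @param improvement Report pre minus post (default `TRUE`; natural for
#'   thresholds, where smaller is better).
#' @return A list of class `"prepost_contrasts"`: `within` (per-group
#'   change), `between` (pairwise differences of changes).
#' @export
pre_post_contrasts <- function(model, improvement = TRUE) {
  stopifnot(inherits(model, "vocotrain_model"))
  emm <- emmeans::emmeans(model$fit, ~ test | group)
  # "pairwise" on test gives pretest - posttest: positive = lower (better)
  # post-test threshold, i.e. improvement
  within <- emmeans::contrast(emm, method = if (improvement) "pairwise"
                              else "revpairwise")
  within_df <- as.data.frame(stats::confint(within))
  emm_g <- emmeans::emmeans(model$fit, ~ test * group)
  between <- emmeans::contrast(emm_g, interaction = c("pairwise", "pairwise"))
  between_df <- as.data.frame(stats::confint(between))
  if (!improvement) {
    between_df$estimate <- -between_df$estimate
    lo <- -between_df$upper.CL; hi <- -between_df$lower.CL
    between_df$lower.CL <- lo; between_df$upper.CL <- hi
  }
  structure(list(within = within_df, between = between_df,
                 improvement = improvement),
            class = "prepost_contrasts")
}

#' @export
print.prepost_contrasts <- function(x, digits = 3, ...) {
  cat(sprintf("pre-to-post %s by group:\n",
              if (x$improvement) "improvement" else "change"))
  print(x$within, digits = digits)
  cat("\nbetween-group differences:\n")
  print(x$between, digits = digits)
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a study, fits and QCs every staircase track, screens outliers,
#' computes per-feature relative information transfer from the VCV trials,
#' and fits the group-by-test mixed models per task and for relative IT.
#' Deterministic given `seed`.
#'
#' @param design A [study_design].
#' @param seed Integer seed.
#' @param out_dir Optional directory: write `thresholds.csv`,
#'   `it_results.csv` and a JSON-lines log of QC decisions.
#' @return A list of class `"vocotrain_pipeline"`: `study`, `thresholds`
#'   (see [threshold_table]), `it` (per subject/session/feature relative IT),
#'   `models` (per-task threshold models), `it_model`, `contrasts` (per-task
#'   [pre_post_contrasts]), `log`.
#' @export
run_study_pipeline <- function(design = study_design(), seed = 1,
                               out_dir = NULL) {
  study <- generate_study(design, seed = seed, emit = "tracks")
  log <- list()

  tt <- threshold_table(study)
  log$track_discard_fraction <- tt$discard_fraction
  log$outlier_fraction <- tt$outlier_fraction
  log$excluded_subjects <- tt$excluded_subjects

  fmap <- feature_map()
  vcv <- study$vcv_trials
  it_rows <- lapply(split(vcv, interaction(vcv$subject, vcv$phase, drop = TRUE)),
                    function(d) {
    res <- it_results(d, fmap)
    res <- res[res$feature != "consonant", ]
    cbind(subject = d$subject[1], group = d$group[1], session = d$phase[1],
          res, stringsAsFactors = FALSE)
  })
  it <- do.call(rbind, it_rows)
  rownames(it) <- NULL

  models <- list(); contrasts <- list()
  for (task in design$tasks) {
    d <- tt$per_session[tt$per_session$task == task, ]
    d <- d[!d$subject %in% tt$excluded_subjects, ]
    m <- fit_model(model_spec("threshold_log10"), d)
    models[[task]] <- m
    contrasts[[task]] <- pre_post_contrasts(m, improvement = TRUE)
    log[[paste0("random_structure_", task)]] <- m$random_structure
  }
  it_model <- fit_model(model_spec("relative_it", feature_term = TRUE), it)
  log$random_structure_it <- it_model$random_structure

  out <- structure(list(study = study, thresholds = tt, it = it,
                        models = models, it_model = it_model,
                        contrasts = contrasts, log = log),
                   class = "vocotrain_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tt$records, file.path(out_dir, "thresholds.csv"),
                     row.names = FALSE)
    utils::write.csv(it, file.path(out_dir, "it_results.csv"),
                     row.names = FALSE)
    writeLines(vapply(names(log), function(k) {
      sprintf("{\"event\": \"%s\", \"value\": \"%s\"}", k,
              paste(format(log[[k]]), collapse = ","))
    }, character(1)), file.path(out_dir, "pipeline_log.jsonl"))
  }
  out
}

#' @export
print.vocotrain_pipeline <- function(x, ...) {
  cat("study pipeline result\n")
  cat(sprintf("  tracks: %d (%.1f%% discarded, %.1f%% outliers)\n",
              nrow(x$thresholds$records),
              100 * x$thresholds$discard_fraction,
              100 * x$thresholds$outlier_fraction))
  cat(sprintf("  threshold models: %s\n",
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}
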