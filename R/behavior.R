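# Trial preprocessing, demand splits, mixed-effects model families, and
# the group comparison of boundary values.

required_trial_columns <- c("subject", "group", "session", "task",
                            "trial_order", "entropy", "association",
                            "rt_ms", "is_error")

#' Preprocess a trial table
#'
#' Applies the analysis exclusions: response errors are dropped, as are
#' responses faster than 200 ms or slower than 10,000 ms.  Kept trials
#' gain a `log_rt` column (natural log of `rt_ms`, used because raw RTs
#' are right-skewed).  The exclusion report counts totals, exclusions and
#' percentages for every session x task x group cell.
#'
#' @param trials data.frame with at least the columns `subject`, `group`,
#'   `session`, `task`, `trial_order`, `entropy`, `association`, `rt_ms`,
#'   `is_error`.
#' @param rt_min,rt_max RT analysis window in ms (defaults 200 and
#'   10,000).
#' @return List of class `"preprocessed_trials"` with `trials` (kept rows
#'   plus `log_rt`) and `exclusions` (the per-cell report, including the
#'   breakdown into error / too-fast / too-slow counts).
#' @export
preprocess_trials <- function(trials, rt_min = 200, rt_max = 10000) {
  missing_cols <- setdiff(required_trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  err <- as.logical(trials$is_error)
  fast <- trials$rt_ms < rt_min
  slow <- trials$rt_ms > rt_max
  drop <- err | fast | slow

  cells <- interaction(trials$session, trials$task, trials$group,
                       sep = "\t", drop = TRUE)
  report <- do.call(rbind, lapply(levels(cells), function(cl) {
    i <- cells == cl
    parts <- strsplit(cl, "\t", fixed = TRUE)[[1L]]
    data.frame(session = parts[1L], task = parts[2L], group = parts[3L],
               n_trials = sum(i),
               n_error = sum(err[i]), n_fast = sum(fast[i] & !err[i]),
               n_slow = sum(slow[i] & !err[i]),
               n_excluded = sum(drop[i]),
               pct_excluded = 100 * sum(drop[i]) / sum(i),
               stringsAsFactors = FALSE)
  }))
  kept <- trials[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no trials left after exclusion", call. = FALSE)
  }
  kept$log_rt <- log(kept$rt_ms)
  rownames(kept) <- NULL
  structure(list(trials = kept, exclusions = report),
            class = "preprocessed_trials")
}

#' @export
print.preprocessed_trials <- function(x, ...) {
  total <- sum(x$exclusions$n_trials)
  cat(sprintf("<preprocessed_trials> kept %d of %d trials (%.2f%% excluded)\n",
              nrow(x$trials), total,
              100 * (total - nrow(x$trials)) / total))
  invisible(x)
}

#' Median-split and center an item demand covariate
#'
#' For interactions with categorical task variables the continuous demand
#' covariates are discretized by a per-task median split (values equal to
#' the median go to `"low"`); for interactions with continuous
#' controllability values they stay continuous but are centered per task.
#' Both derived columns are added: `<variable>_split` (factor low/high,
#' reference `"low"`) and `<variable>_c`.
#'
#' @param trials trial data.frame containing `variable` and `task`.
#' @param variable `"entropy"` or `"association"`.
#' @return The trial data.frame with the two extra columns.
#' @export
split_demands <- function(trials, variable = c("entropy", "association")) {
  variable <- match.arg(variable)
  x <- trials[[variable]]
  split_col <- character(nrow(trials))
  cent_col <- numeric(nrow(trials))
  for (tk in unique(trials$task)) {
    i <- trials$task == tk
    if (length(unique(x[i])) < 2L) {
      stop(sprintf("`%s` is constant within task '%s': median split undefined",
                   variable, tk), call. = FALSE)
    }
    med <- median(x[i])
    split_col[i] <- ifelse(x[i] <= med, "low", "high")
    cent_col[i] <- x[i] - mean(x[i])
  }
  trials[[paste0(variable, "_split")]] <- factor(split_col,
                                                 levels = c("low", "high"))
  trials[[paste0(variable, "_c")]] <- cent_col
  trials
}

#' The mixed-effects model registry
#'
#' Reads the family definitions (fixed-effects formula and trial subset
#' per family) shipped with the package, or from a user-supplied YAML
#' file with the same layout.
#'
#' @param path optional path to a registry YAML; default uses the
#'   installed registry.
#' @return Named list of families, each with `fixed`, `subset`,
#'   `description`.
#' @export
model_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_registry.yaml",
                        package = "connectrol", mustWork = TRUE)
  }
  reg <- yaml::read_yaml(path)$families
  if (is.null(reg)) stop("registry file has no `families` section", call. = FALSE)
  structure(reg, class = "model_registry")
}

prepare_model_frame <- function(trials) {
  d <- trials
  d$subject <- factor(d$subject)
  d$stimulation <- factor(d$group, levels = c("sham", "active"))
  d$session <- factor(d$session, levels = c("pre", "post"))
  d$task <- factor(d$task,
                   levels = c("verb_generation", "sentence_completion"))
  if (length(unique(d$trial_order)) > 1L) {
    d$trial_order_z <- as.numeric(scale(d$trial_order))
  } else {
    d$trial_order_z <- 0
  }
  d
}

#' Fit a registered mixed-effects model family
#'
#' Fits natural-log response time with the family's fixed effects and, by
#' default, a random intercept plus a random slope for (standardized)
#' trial order per subject, by maximum likelihood.  Fixed-effect tests use
#' Satterthwaite degrees of freedom; if the Satterthwaite computation
#' fails, residual degrees of freedom are used and flagged in
#' `df_method`.  A fit that does not converge is retried once with the
#' bobyqa optimizer and otherwise returned with `converged = FALSE` —
#' never silently.
#'
#' Categorical coding: treatment contrasts with reference levels sham
#' (stimulation), pre (session), verb_generation (task) and low (demand
#' splits).  Demand split/centered columns are derived on the fly via
#' [split_demands()] when a family needs them and they are absent.
#'
#' @param trials preprocessed trial data.frame (must contain `log_rt`; see
#'   [preprocess_trials()]), with `boundary` / `modal` columns when the
#'   family uses them.
#' @param model_id a family name from [model_registry()].
#' @param registry the registry to resolve `model_id` in.
#' @param drop_slope if `TRUE`, fit only the random intercept.
#' @return An object of class `"rt_model_fit"`: list with `model_id`,
#'   `fixed_effects` (data.frame term / estimate / ci_low / ci_high / df /
#'   statistic / p), `random_effect_variances`, `n_obs`, `n_subjects`,
#'   `converged`, `singular`, `df_method`, `formula`, and the underlying
#'   `fit`.
#' @export
fit_rt_model <- function(trials, model_id, registry = model_registry(),
                         drop_slope = FALSE) {
  if (!model_id %in% names(registry)) {
    stop(sprintf("unknown model id '%s'; registered families: %s",
                 model_id, paste(names(registry), collapse = ", ")),
         call. = FALSE)
  }
  fam <- registry[[model_id]]
  if (!"log_rt" %in% names(trials)) {
    stop("trials lack `log_rt`; run preprocess_trials() first", call. = FALSE)
  }
  d <- trials
  for (col in names(fam$subset)) {
    d <- d[d[[col]] %in% fam$subset[[col]], , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    stop(sprintf("no trials left for family '%s' after subsetting", model_id),
         call. = FALSE)
  }
  fixed_terms <- all.vars(stats::as.formula(paste("~", fam$fixed)))
  for (v in c("entropy", "association")) {
    needs <- paste0(v, c("_split", "_c"))
    if (any(needs %in% fixed_terms) && !all(needs %in% names(d))) {
      d <- split_demands(d, v)
    }
  }
  d <- prepare_model_frame(d)
  missing_vars <- setdiff(fixed_terms, names(d))
  if (length(missing_vars)) {
    stop(sprintf("family '%s' needs column(s) not in the trial table: %s",
                 model_id, paste(missing_vars, collapse = ", ")),
         call. = FALSE)
  }
  re <- if (drop_slope) "(1 | subject)" else "(1 + trial_order_z | subject)"
  form <- stats::as.formula(paste("log_rt ~", fam$fixed, "+", re))

  fit_once <- function(optimizer = NULL) {
    ctrl <- if (is.null(optimizer)) {
      lme4::lmerControl()
    } else {
      lme4::lmerControl(optimizer = optimizer)
    }
    warns <- character()
    fit <- withCallingHandlers(
      lmerTest::lmer(form, data = d, REML = FALSE, control = ctrl),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # e.g. lme4's singular-fit note; singularity is reported via the
        # `singular` flag instead of console noise
        invokeRestart("muffleMessage")
      })
    conv_code <- fit@optinfo$conv$opt
    failed <- conv_code != 0 || any(grepl("failed to converge", warns))
    list(fit = fit, converged = !failed, warnings = warns)
  }
  res <- fit_once()
  if (!res$converged) res <- fit_once("bobyqa")

  fit <- res$fit
  sm <- suppressMessages(summary(fit))
  co <- sm$coefficients
  df_method <- "satterthwaite"
  if (ncol(co) < 5L || any(!is.finite(co[, "df"]))) {
    # Satterthwaite failed: fall back to residual df
    co_lme4 <- summary(fit, ddf = "lme4")$coefficients
    df_res <- nrow(d) - nrow(co_lme4)
    co <- cbind(co_lme4[, 1:2, drop = FALSE], df = df_res,
                "t value" = co_lme4[, "t value"],
                "Pr(>|t|)" = 2 * stats::pt(-abs(co_lme4[, "t value"]), df_res))
    df_method <- "residual"
  }
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  df <- co[, "df"]
  half <- stats::qt(0.975, df) * se
  fixed_effects <- data.frame(term = rownames(co),
                              estimate = est,
                              ci_low = est - half,
                              ci_high = est + half,
                              df = df,
                              statistic = co[, "t value"],
                              p = co[, "Pr(>|t|)"],
                              stringsAsFactors = FALSE)
  rownames(fixed_effects) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2), , drop = FALSE]   # variances only, not covariances
  re_var <- stats::setNames(vc$vcov,
                            trimws(paste(vc$grp,
                                         ifelse(is.na(vc$var1), "", vc$var1))))
  structure(list(model_id = model_id,
                 fixed_effects = fixed_effects,
                 random_effect_variances = re_var,
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject)),
                 converged = res$converged,
                 singular = lme4::isSingular(fit),
                 df_method = df_method,
                 formula = form,
                 fit = fit),
            class = "rt_model_fit")
}

#' @export
print.rt_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<rt_model_fit> %s | %d obs, %d subjects | %s df%s%s\n",
              x$model_id, x$n_obs, x$n_subjects, x$df_method,
              if (x$converged) "" else " | NOT CONVERGED",
              if (x$singular) " | singular fit" else ""))
  fe <- x$fixed_effects
  fe[-1L] <- lapply(fe[-1L], function(col) signif(col, digits))
  print(fe, row.names = FALSE)
  invisible(x)
}

#' Write a model fit as TSV mirroring the analysis table layout
#'
#' Columns: term, estimate, ci_low, ci_high, df, statistic, p.
#'
#' @param fit an `"rt_model_fit"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_fit <- function(fit, path) {
  write_tsv_full(fit$fixed_effects, path)
}

#' Compare per-subject boundary values between stimulation groups
#'
#' Wilcoxon (Mann-Whitney) unpaired two-sample rank-sum test, two-sided.
#' The reported `W` counts pairs won by the first group (the `"active"`
#' level when present, otherwise the first factor level).
#'
#' @param values per-subject boundary-controllability values.
#' @param groups group labels, two levels, aligned with `values`.
#' @return List of class `"group_test"` with `W`, `p_value`, `groups`,
#'   `n`, `medians`.
#' @export
compare_groups_boundary <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  groups <- droplevels(groups)
  levs <- levels(groups)
  if ("active" %in% levs) levs <- c("active", setdiff(levs, "active"))
  v1 <- values[groups == levs[1L]]
  v2 <- values[groups == levs[2L]]
  if (length(v1) == 0L || length(v2) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(v1, v2, alternative = "two.sided"))
  structure(list(W = unname(wt$statistic),
                 p_value = wt$p.value,
                 groups = levs,
                 n = c(length(v1), length(v2)),
                 medians = c(median(v1), median(v2))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> Wilcoxon rank-sum %s vs %s: W = %g, p = %.4g (n = %d/%d)\n",
              x$groups[1L], x$groups[2L], x$W, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}
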