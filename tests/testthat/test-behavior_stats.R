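test_that("preprocessing applies the RT window and error exclusions exactly", {
  tr <- manual_trials(rt = c(150, 250, 9000, 12000))
  pp <- preprocess_trials(tr)
  expect_equal(nrow(pp$trials), 2L)
  expect_equal(sum(pp$exclusions$n_excluded), 2L)
  expect_equal(pp$trials$log_rt, log(c(250, 9000)))

  # 1 error trial among 11 -> 10 kept, 9.09% excluded
  tr2 <- manual_trials(rt = rep(500, 11),
                       is_error = c(TRUE, rep(FALSE, 10)))
  pp2 <- preprocess_trials(tr2)
  expect_equal(nrow(pp2$trials), 10L)
  expect_equal(pp2$exclusions$pct_excluded, 100 / 11, tolerance = 1e-12)

  # all valid: identity on rows plus the log column
  tr3 <- manual_trials(rt = c(300, 400, 500))
  pp3 <- preprocess_trials(tr3)
  expect_equal(nrow(pp3$trials), 3L)
  expect_equal(pp3$trials$rt_ms, tr3$rt_ms)

  expect_error(preprocess_trials(tr3[, -1]), "missing column")
  expect_error(preprocess_trials(manual_trials(rt = c(100, 50))),
               "no trials left")
})

test_that("preprocessing commutes with task subsetting", {
  cfg <- behavior_gen_config(n_active = 3, n_sham = 3, n_trials = 20,
                             seed = 210)
  tr <- generate_trials(cfg, boundary_values = rnorm(6))
  a <- preprocess_trials(tr)$trials
  a <- a[a$task == "verb_generation", ]
  b <- preprocess_trials(tr[tr$task == "verb_generation", ])$trials
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("median splits assign ties low and center per task", {
  tr <- manual_trials(rt = rep(500, 4))
  tr$entropy <- c(0.1, 0.2, 0.6, 0.9)
  out <- split_demands(tr, "entropy")
  expect_equal(as.character(out$entropy_split), c("low", "low", "high", "high"))
  expect_equal(levels(out$entropy_split), c("low", "high"))

  # odd count: the middle value sits at the median and goes low
  tr5 <- manual_trials(rt = rep(500, 5))
  tr5$entropy <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  out5 <- split_demands(tr5, "entropy")
  expect_equal(as.character(out5$entropy_split)[3], "low")

  # centered covariate sums to zero within each task
  cfg <- behavior_gen_config(n_active = 2, n_sham = 2, n_trials = 10,
                             seed = 211)
  tr6 <- generate_trials(cfg, boundary_values = rnorm(4))
  out6 <- split_demands(tr6, "association")
  sums <- tapply(out6$association_c, out6$task, sum)
  expect_true(all(abs(sums) < 1e-10))

  tr7 <- manual_trials(rt = rep(500, 3))
  tr7$entropy <- rep(0.4, 3)
  expect_error(split_demands(tr7, "entropy"), "constant")
})

test_that("the model registry contains every analysis family", {
  reg <- model_registry()
  expect_setequal(names(reg),
                  c("both_tasks_boundary_tms", "task_by_selection_pre",
                    "task_by_retrieval_pre", "boundary_by_entropy_SC",
                    "modal_by_entropy_SC", "boundary_by_association_VG",
                    "modal_by_association_VG", "sham_session_SC",
                    "sham_session_VG", "tms_session_SC", "tms_session_VG",
                    "tms_session_boundary_SC", "tms_session_boundary_VG",
                    "trialwise_pre", "trialwise_post"))
  for (fam in reg) {
    expect_true(is.character(fam$fixed) && nzchar(fam$fixed))
    expect_no_error(as.formula(paste("log_rt ~", fam$fixed)))
  }
})

test_that("a noiseless generator yields an exact intercept fit", {
  cfg <- behavior_gen_config(n_active = 0, n_sham = 6, n_trials = 10,
                             tasks = "sentence_completion",
                             coefficients = zero_coefs(intercept = 7),
                             subj_intercept_sd = 0, trial_slope_sd = 0,
                             residual_sd = 0, error_rate = 0,
                             fast_rate = 0, slow_rate = 0, seed = 212)
  tr <- generate_trials(cfg, boundary_values = rep(0, 6))
  pp <- preprocess_trials(tr)
  fit <- fit_rt_model(pp$trials, "sham_session_SC", drop_slope = TRUE)
  fe <- fit$fixed_effects
  expect_equal(fe$estimate[fe$term == "(Intercept)"], 7, tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "sessionpost"], 0, tolerance = 1e-6)
})

test_that("model fits recover a planted session effect and satisfy output invariants", {
  cfg <- behavior_gen_config(n_active = 0, n_sham = 60, n_trials = 50,
                             tasks = "sentence_completion",
                             coefficients = zero_coefs(intercept = 7,
                                                       session = 0.072),
                             error_rate = 0, fast_rate = 0, slow_rate = 0,
                             seed = 213)
  tr <- generate_trials(cfg, boundary_values = runif(60, -55, 55))
  pp <- preprocess_trials(tr)
  fit <- fit_rt_model(pp$trials, "sham_session_SC")
  fe <- fit$fixed_effects
  est <- fe$estimate[fe$term == "sessionpost"]
  expect_lt(abs(est - 0.072), 0.03)
  expect_true(all(fe$ci_low <= fe$estimate & fe$estimate <= fe$ci_high))
  expect_true(all(fe$p >= 0 & fe$p <= 1))
  expect_true(all(fit$random_effect_variances >= 0))
  expect_equal(fit$n_obs, nrow(pp$trials))
  expect_identical(fit$df_method, "satterthwaite")
  expect_true(fit$converged)

  expect_error(fit_rt_model(pp$trials, "nonexistent_family"), "unknown model id")
  expect_error(fit_rt_model(tr, "sham_session_SC"), "log_rt")
})

test_that("demand-split columns are derived on demand for registry families", {
  cfg <- behavior_gen_config(n_active = 4, n_sham = 4, n_trials = 20,
                             seed = 214)
  tr <- generate_trials(cfg, boundary_values = rnorm(8))
  pp <- preprocess_trials(tr)
  fit <- fit_rt_model(pp$trials, "task_by_selection_pre")
  expect_true(any(grepl("entropy_splithigh", fit$fixed_effects$term)))
  fit2 <- fit_rt_model(pp$trials, "boundary_by_entropy_SC")
  expect_true(any(grepl("entropy_c", fit2$fixed_effects$term)))
})

test_that("the Wilcoxon group comparison matches exact small-sample enumeration", {
  # identical groups: no evidence of a shift
  gt0 <- compare_groups_boundary(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                                 rep(c("active", "sham"), each = 5))
  expect_gt(gt0$p_value, 0.9)

  # complete separation at n = 5 vs 5: W = 25, two-sided p = 2/252
  gt1 <- compare_groups_boundary(c(6:10, 1:5),
                                 rep(c("active", "sham"), each = 5))
  expect_equal(gt1$W, 25)
  expect_equal(gt1$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  # null calibration: moderate-sample rejection rate near the nominal level
  set.seed(215)
  ps <- replicate(200, {
    v <- rnorm(16)
    compare_groups_boundary(v, rep(c("active", "sham"), each = 8))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)

  expect_error(compare_groups_boundary(1:4, rep("a", 4)), "two groups")
})
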