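## Crafted modeling dataset with two informative features among noise.
crafted_dataset <- function(seed = 21, n_subjects = 6, n_sections = 14) {
  rows <- crafted_feature_rows(n_subjects = n_subjects, n_sections = n_sections,
                               n_features = 20, n_informative = 2, seed = seed)
  nf <- normalize_within_subject(rows)
  sp <- split_by_subject(nf, seed = seed)
  scale_by_training(sp$train, sp$test)
}

test_that("an inactive electrode budget makes the budget models coincide", {
  ds <- crafted_dataset()
  scr <- correlation_screen(ds)
  sets <- build_threshold_sets(scr, step = 0.05)
  grid <- default_grid(C = c(0.25, 1), epsilon = 0.25)
  fam <- fit_model_family(ds, sets, screen = scr, electrode_budget = 100,
                          grid = grid, k_folds = 4, seed = 2)
  expect_equal(attr(fam$models$model1, "set")$threshold,
               attr(fam$models$model2, "set")$threshold)
  expect_equal(attr(fam$models$model3, "set")$threshold,
               attr(fam$models$model4, "set")$threshold)
  expect_equal(fam$models$model1$C, fam$models$model2$C)
  expect_identical(fam$models$model1$theta, fam$models$model2$theta)

  ## sweep bookkeeping: one row per threshold, winner consistent with table
  expect_equal(nrow(fam$sweep), length(sets))
  i1 <- which(fam$sweep$threshold == fam$thresholds[["model1"]])
  expect_equal(min(fam$sweep$rbf_mse), fam$sweep$rbf_mse[i1])
})

test_that("an unmeetable electrode budget is refused", {
  ds <- crafted_dataset()
  scr <- correlation_screen(ds)
  sets <- build_threshold_sets(scr, step = 0.05)
  expect_error(fit_model_family(ds, sets, screen = scr, electrode_budget = 0,
                                grid = default_grid(C = 1, epsilon = 0.25)),
               "electrode")
})

test_that("model 5 is plain least squares on the single best predictor", {
  ds <- crafted_dataset(seed = 5)
  scr <- correlation_screen(ds)
  sets <- build_threshold_sets(scr, step = 0.05)
  fam <- fit_model_family(ds, sets, screen = scr,
                          grid = default_grid(C = 1, epsilon = 0.25),
                          k_folds = 4, seed = 3)
  best <- names(which.max(scr))
  expect_equal(fam$single_feature, best)
  ols <- stats::lm(ds$train$y ~ ds$train$x[, best])
  expect_equal(unname(coef(fam$models$model5)), unname(coef(ols)),
               tolerance = 1e-10)
  ## family predictions work for every member on the test partition
  for (nm in names(fam$models)) {
    p <- family_predict(fam, nm, ds$test)
    expect_length(p, nrow(ds$test$x))
    expect_true(all(is.finite(p)))
  }
})

test_that("a report covers five accuracies, eight comparisons and round-trips", {
  ds <- crafted_dataset(seed = 9)
  scr <- correlation_screen(ds)
  sets <- build_threshold_sets(scr, step = 0.05)
  fam <- fit_model_family(ds, sets, screen = scr,
                          grid = default_grid(C = 1, epsilon = 0.25),
                          k_folds = 4, seed = 3)
  rep <- build_report(fam, ds)
  expect_equal(rep$accuracy$model, paste0("model", 1:5))
  expect_true(all(abs(rep$accuracy$r) <= 1))
  expect_true(all(rep$accuracy$p > 0 & rep$accuracy$p <= 1))
  expect_equal(nrow(rep$comparisons), 8)
  expect_setequal(unique(rep$comparisons$method), "dependent")

  tmp <- tempfile(fileext = ".json")
  report_write(rep, tmp)
  back <- report_read(tmp)
  expect_equal(back$accuracy$r, rep$accuracy$r, tolerance = 1e-12)
  expect_equal(back$comparisons$Z, rep$comparisons$Z, tolerance = 1e-12)
  expect_equal(back$n_test, rep$n_test)
  ## printing works
  expect_output(print(rep), "held-out accuracy")
})

test_that("null cohorts yield near-zero held-out accuracy and no significant comparisons", {
  ## all effect gains zero: the pipeline should find nothing, repeatedly
  mont <- c("F3", "F4", "Pz", "O1")
  near_zero <- 0; n_signif <- 0
  for (sd_ in 1:10) {
    cfg <- sim_config(n_subjects = 10, montage = mont, effect_linear = 0,
                      effect_secondary = 0, effect_nonlinear = 0,
                      rt_effect = 0, seed = 300 + sd_)
    z <- suppressMessages(run_mw_pipeline(cfg, seed = sd_))
    acc <- z$report$accuracy
    near_zero <- near_zero + (abs(acc$r[acc$model == "model1"]) < 0.2)
    n_signif <- n_signif + sum(z$report$comparisons$p < 0.05)
  }
  expect_gte(near_zero, 9)
  ## 80 one-sided nulls at alpha = 0.05: the significant fraction stays small
  expect_lte(n_signif / 80, 0.15)
})
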