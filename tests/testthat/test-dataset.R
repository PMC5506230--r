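test_that("flat-reporting subjects are excluded by answer range", {
  rows <- crafted_feature_rows(n_subjects = 10, n_sections = 8)
  flat <- rows$subject %in% c(2, 5, 9)
  rows$response[flat] <- 4                      # constant answers
  kept <- suppressMessages(exclude_subjects(rows, min_mw_range = 2))
  expect_setequal(attr(kept, "excluded_subjects"), c("2", "5", "9"))
  expect_false(any(kept$subject %in% c(2, 5, 9)))
  ## a subject spanning the full 1..7 range survives
  expect_true(1 %in% kept$subject)
})

test_that("the split assigns whole subjects with round-half-up sizing", {
  rows <- data.frame(subject = rep(1:43, each = 2), section = 1,
                     response = 4, n_clean_epochs = 20,
                     power_Fz_delta = rnorm(86), check.names = FALSE)
  sp <- split_by_subject(rows, test_fraction = 1 / 3, seed = 5)
  expect_equal(length(unique(sp$test$subject)), 14)   # round(43/3) = 14
  expect_equal(length(unique(sp$train$subject)), 29)
  expect_length(intersect(sp$train$subject, sp$test$subject), 0)
  ## deterministic under the seed
  sp2 <- split_by_subject(rows, test_fraction = 1 / 3, seed = 5)
  expect_identical(sp$manifest, sp2$manifest)
  expect_error(split_by_subject(rows, test_fraction = 0, seed = 1),
               "strictly between")
  expect_error(split_by_subject(rows[rows$subject <= 2, ], seed = 1),
               "at least 3")
})

test_that("outlier sections match a brute-force |z| scan", {
  rows <- crafted_feature_rows(n_subjects = 4, n_sections = 10)
  nf <- normalize_within_subject(rows)
  kept <- remove_outlier_sections(nf, z_max = 5)
  expect_equal(attr(kept, "n_dropped"), 0L)     # normalized |z| <= ~3 here

  nf2 <- nf
  nf2$power_F4_theta[7] <- 6
  expect_message(remove_outlier_sections(nf2, z_max = 5), "1 outlier")
  kept2 <- suppressMessages(remove_outlier_sections(nf2, z_max = 5))
  expect_equal(nrow(kept2), nrow(nf2) - 1)
  ## independent full scan agrees
  fcols <- setdiff(names(nf2), c("subject", "section", "response", "n_clean_epochs"))
  bad <- which(apply(abs(as.matrix(nf2[, fcols])) > 5, 1, any))
  expect_equal(bad, 7L)
})

test_that("train/test scaling uses training statistics only and round-trips", {
  rows <- crafted_feature_rows(n_subjects = 6, n_sections = 12)
  nf <- normalize_within_subject(rows)
  sp <- split_by_subject(nf, seed = 3)
  te_orig <- sp$test
  te_orig$power_F3_delta <- te_orig$power_F3_delta + 2   # distribution shift
  ds <- scale_by_training(sp$train, te_orig)
  expect_equal(unname(colMeans(ds$train$x)), rep(0, ncol(ds$train$x)),
               tolerance = 1e-9)
  expect_equal(unname(apply(ds$train$x, 2, mweeg:::sd_pop)),
               rep(1, ncol(ds$train$x)), tolerance = 1e-9)
  ## the shifted test column keeps its nonzero mean after scaling
  expect_gt(mean(ds$test$x[, "power_F3_delta"]), 1)
  ## inverse transform recovers the original test values
  back <- sweep(sweep(ds$test$x, 2, ds$scale, "*"), 2, ds$center, "+")
  expect_equal(unname(back),
               unname(as.matrix(te_orig[, ds$features])), tolerance = 1e-10)
  ## zero-variance training columns are dropped from both sides
  tr2 <- sp$train; tr2$power_F3_theta <- 1
  expect_warning(scale_by_training(tr2, te_orig), "zero-training-variance")
  ds2 <- suppressWarnings(scale_by_training(tr2, te_orig))
  expect_false("power_F3_theta" %in% ds2$features)
})

test_that("no information flows from test rows into training artifacts", {
  rows <- crafted_feature_rows(n_subjects = 6, n_sections = 10)
  nf <- normalize_within_subject(rows)
  sp <- split_by_subject(nf, seed = 9)
  run <- function(test_rows) {
    ds <- scale_by_training(sp$train, test_rows)
    scr <- correlation_screen(ds)
    sets <- build_threshold_sets(scr, step = 0.05)
    cv <- grid_search_cv(ds$train$x[, sets[[1]]$members, drop = FALSE],
                         ds$train$y, "linear",
                         grid = default_grid(C = 1, epsilon = 0.25),
                         k_folds = 4, seed = 2)
    m <- svr_fit(ds$train$x[, sets[[length(sets)]]$members, drop = FALSE],
                 ds$train$y, "linear", C = 1, epsilon = 0.25)
    list(center = ds$center, scale = ds$scale, screen = scr,
         sets = lapply(sets, `[[`, "members"), cv = cv$scores,
         theta = m$theta, b = m$b)
  }
  perturbed <- sp$test
  fcols <- setdiff(names(perturbed), c("subject", "section", "response", "n_clean_epochs"))
  perturbed[, fcols] <- perturbed[, fcols] + 3
  perturbed$response <- rev(perturbed$response)
  expect_identical(run(sp$test), run(perturbed))
})
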