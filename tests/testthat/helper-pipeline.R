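# Shared end-to-end pipeline runner for recovery and comparison tests.
# Pilot-scale defaults: small cohorts, a coarse threshold grid and a
# 4-candidate hyperparameter grid keep a single run well under a minute
# while leaving the planted orderings clearly recoverable.
pilot_grid <- function() default_grid(C = c(0.03125, 0.5), epsilon = c(0.125, 0.5))

run_mw_pipeline <- function(cfg, step = 0.05, grid = pilot_grid(), budget = 9,
                            seed = 1, k_folds = 5) {
  tab <- cohort_feature_table(cfg)
  rows <- exclude_subjects(tab$features)
  nf <- normalize_within_subject(rows)
  sp <- split_by_subject(nf, 1 / 3, seed = seed)
  tr <- remove_outlier_sections(sp$train)
  te <- remove_outlier_sections(sp$test)
  ds <- scale_by_training(tr, te)
  scr <- correlation_screen(ds)
  sets <- build_threshold_sets(scr, step = step)
  fam <- fit_model_family(ds, sets, screen = scr, electrode_budget = budget,
                          grid = grid, k_folds = k_folds, seed = seed)
  rep <- suppressWarnings(build_report(fam, ds, tab$annotations))
  list(table = tab, dataset = ds, screen = scr, sets = sets,
       family = fam, report = rep)
}

# A small crafted feature table (no EEG involved) for dataset/selection
# tests: `n_informative` features carry a linear signal, the rest are noise.
crafted_feature_rows <- function(n_subjects = 6, n_sections = 20,
                                 n_features = 30, n_informative = 2,
                                 seed = 42) {
  mont <- c("F3", "F4", "Fz", "Pz", "O1", "O2")
  stopifnot(n_features <= length(mont) * 5)
  nms <- paste0("power_", rep(mont, each = 5), "_",
                rep(c("delta", "theta", "alpha1", "beta1", "gamma"), length(mont)))
  nms <- nms[seq_len(n_features)]
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      y <- rnorm(n_sections)
      X <- matrix(rnorm(n_sections * n_features), n_sections)
      for (j in seq_len(n_informative))
        X[, j] <- 0.8 * y + sqrt(1 - 0.64) * X[, j]
      df <- data.frame(subject = s, section = seq_len(n_sections),
                       response = round(pmin(pmax(4 + 1.5 * y, 1), 7)),
                       n_clean_epochs = 20L, check.names = FALSE)
      cbind(df, as.data.frame(stats::setNames(as.data.frame(X), nms),
                              check.names = FALSE))
    }))
    rownames(out) <- NULL
    out
  })
}

# Legal feature names on a small montage, for selection tests.
feature_names_for_test <- function()
  mweeg:::feature_names(c("F3", "F4", "Fz", "Pz", "O1", "O2"))
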