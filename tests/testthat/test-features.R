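tiny_session <- function(n_sections = 3, seed = 7, ...) {
  generate_session(sim_config(n_subjects = 1, n_sections = n_sections,
                              artifact_rate = 0, seed = seed, ...), 1)
}

test_that("epoching yields one epoch per second, none spanning sections", {
  s <- tiny_session(5)
  ep <- segment_epochs(s$recording, s$annotations)
  expect_equal(dim(ep$data), c(250, 17, 5 * 20))
  expect_equal(as.vector(table(ep$section)), rep(20, 5))
  ## truncated recording -> error, not silent truncation
  short <- s$recording
  short$data <- short$data[seq_len(nrow(short$data) - 100), , drop = FALSE]
  expect_error(segment_epochs(short, s$annotations), "truncated")
  ## misaligned section boundaries -> structural error
  bad <- s$annotations
  bad$section_onsets[2] <- bad$section_onsets[2] + 0.5
  expect_error(segment_epochs(s$recording, bad), "whole seconds")
})

test_that("artifact flags respect the thresholds", {
  s <- tiny_session(2)
  ep <- segment_epochs(s$recording, s$annotations)
  clean <- reject_artifacts(ep)
  expect_false(any(clean$flagged))            # nothing exceeds defaults here
  ## a transient at 3x threshold flags exactly its epoch
  dirty <- s$recording
  dirty$data[700:720, "Pz"] <- dirty$data[700:720, "Pz"] + 600
  epd <- reject_artifacts(segment_epochs(dirty, s$annotations))
  expect_true(epd$flagged[3])                 # samples 700-720 sit in epoch 3
  expect_equal(sum(epd$flagged), 1)
  ## sections losing too many epochs are dropped
  few <- reject_artifacts(segment_epochs(dirty, s$annotations), p2p_limit = 1e-9)
  expect_equal(attr(few, "dropped_sections"), c(1L, 2L))
})

test_that("band power matches a direct DFT oracle and behaves spectrally", {
  srate <- 250
  zero <- matrix(0, srate, 2, dimnames = list(NULL, c("Fz", "Pz")))
  expect_true(all(band_power(zero, srate) == 0))

  t <- seq_len(srate) / srate
  s10 <- matrix(sin(2 * pi * 10 * t), ncol = 1, dimnames = list(NULL, "Fz"))
  bp <- band_power(s10, srate)
  expect_gt(bp["Fz", "alpha1"], 0)
  expect_lt(bp["Fz", "gamma"], 1e-6 * bp["Fz", "alpha1"])

  ## random epoch against an independent direct-summation oracle
  x <- withr::with_seed(3, matrix(rnorm(2 * srate), srate, 2,
                                  dimnames = list(NULL, c("Fz", "Pz"))))
  bp <- band_power(x, srate)
  for (ch in 1:2) {
    X <- vapply(0:(srate - 1), function(k)
      sum(x[, ch] * exp(-2i * pi * k * (seq_len(srate) - 1) / srate)), 0i)
    for (bd in seq_len(nrow(kubicki_bands()))) {
      b <- kubicki_bands()[bd, ]
      bins <- ceiling(b$low):floor(b$high)
      expect_equal(unname(bp[ch, b$band]), mean(abs(X[bins + 1])^2),
                   tolerance = 1e-9)
    }
    ## Parseval under the raw-DFT convention
    expect_equal(sum(abs(X)^2), srate * sum(x[, ch]^2), tolerance = 1e-6)
  }
})

test_that("coherence is 1 for identical or delayed signals and ~1/K for noise", {
  srate <- 250; K <- 20
  base <- withr::with_seed(4, rnorm(srate * K + 50))
  same <- array(0, c(srate, 2, K), dimnames = list(NULL, c("Fz", "Pz"), NULL))
  lag <- same
  for (k in seq_len(K)) {
    seg <- base[(k - 1) * srate + seq_len(srate)]
    same[, 1, k] <- seg; same[, 2, k] <- seg
    lag[, 1, k] <- seg
    lag[, 2, k] <- base[(k - 1) * srate + 7 + seq_len(srate)]  # pure delay
  }
  as_ep <- function(a) structure(list(data = a, section = rep(1L, K),
                                      flagged = rep(FALSE, K), srate = srate,
                                      channels = c("Fz", "Pz")),
                                 class = "mweeg_epochs")
  expect_equal(unname(band_coherence(as_ep(same), c("Fz", "Pz"))),
               rep(1, 8), tolerance = 1e-9)
  expect_true(all(band_coherence(as_ep(lag), c("Fz", "Pz")) > 0.9))

  ## independent noise: E[MSC] ~ 1/K; average over bands and replicates
  mscs <- withr::with_seed(5, replicate(8, {
    noise <- array(rnorm(srate * 2 * K), c(srate, 2, K),
                   dimnames = list(NULL, c("Fz", "Pz"), NULL))
    mean(band_coherence(as_ep(noise), c("Fz", "Pz")))
  }))
  expect_equal(mean(mscs), 1 / K, tolerance = 0.2)
  single <- structure(list(data = same[, , 1, drop = FALSE],
                           section = 1L, flagged = FALSE, srate = srate,
                           channels = c("Fz", "Pz")), class = "mweeg_epochs")
  expect_error(band_coherence(single, c("Fz", "Pz")), "clean epochs")
})

test_that("section aggregation produces the documented feature layout", {
  s <- tiny_session(3, montage = c("Fz", "Pz", "O1"))
  ep <- reject_artifacts(segment_epochs(bandpass_notch(s$recording), s$annotations))
  two_bands <- kubicki_bands()[c(1, 5), ]
  rows <- aggregate_sections(ep, s$annotations, subject = 1, bands = two_bands)
  expect_equal(ncol(rows) - 4, (3 + 3) * 2)   # (E + C(E,2)) * B
  expect_equal(rows$section, 1:3)

  full <- aggregate_sections(ep, s$annotations, subject = 1)
  expect_equal(ncol(full) - 4, (3 + 3) * 8)
  ## column order is stable across subjects and runs
  s2 <- generate_session(sim_config(n_subjects = 2, n_sections = 3,
                                    artifact_rate = 0, seed = 21,
                                    montage = c("Fz", "Pz", "O1")), 2)
  ep2 <- reject_artifacts(segment_epochs(bandpass_notch(s2$recording), s2$annotations))
  rows2 <- aggregate_sections(ep2, s2$annotations, subject = 2, bands = two_bands)
  expect_identical(names(rows), names(rows2))
  ## coherence in [0, 1], power nonnegative, pre-normalization
  co <- as.matrix(full[, grep("^coh_", names(full))])
  pw <- as.matrix(full[, grep("^power_", names(full))])
  expect_true(all(co >= 0 & co <= 1))
  expect_true(all(pw >= 0))
})

test_that("within-subject normalization is exact, warned and idempotent", {
  s1 <- tiny_session(4, seed = 31, montage = c("Fz", "Pz", "O1"))
  ep <- reject_artifacts(segment_epochs(s1$recording, s1$annotations))
  rows <- aggregate_sections(ep, s1$annotations, subject = 1)
  rows$power_Fz_delta <- 5                     # constant feature
  expect_warning(normalize_within_subject(rows), "zero-variance")
  nf <- suppressWarnings(normalize_within_subject(rows))
  fcols <- setdiff(names(nf), c("subject", "section", "n_clean_epochs"))
  for (cn in fcols) {
    expect_equal(mean(nf[[cn]]), 0, tolerance = 1e-9)
    expect_true(abs(mweeg:::sd_pop(nf[[cn]]) - 1) < 1e-9 ||
                  all(nf[[cn]] == 0))
  }
  expect_true(all(nf$power_Fz_delta == 0))
  nf2 <- suppressWarnings(normalize_within_subject(nf))
  expect_equal(nf2, nf, tolerance = 1e-12)
  ## single-section subjects are excluded
  one <- rows[1, ]
  expect_message(out <- normalize_within_subject(one), "fewer than 2")
  expect_null(out)
})
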