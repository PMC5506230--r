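#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set describing a synthetic study:
#' session geometry (sections, trials, sampling), the latent per-section
#' mind-wandering (MW) process, and the planted effect pathways that tie the
#' latent trace to measurable EEG and behavioral features.
#'
#' The generator emulates a sustained-attention session: `n_sections`
#' sections of `trials_per_section` trials lasting `trial_interval` seconds
#' each, one 7-point Likert probe answer per section. The latent MW intensity
#' follows a stationary AR(1) process across sections. Three effect pathways
#' are planted:
#' \describe{
#'   \item{linear}{the beta3 (21.5--30 Hz) content of Pz and O1 is a
#'     constant-power mixture of a private and a shared band-limited source
#'     with MW-dependent mixing weight `w = effect_linear * plogis(mw)`:
#'     their magnitude-squared coherence rises monotonically with MW while
#'     the in-band power stays flat, so the effect lives in the coherence
#'     feature alone;}
#'   \item{non-linear}{independent beta1 (12.5--18 Hz) sources added to the
#'     lateral-prefrontal channels F3 and F4 whose power follows the U-shaped
#'     link `effect_nonlinear * (mw - nonlinear_vertex)^2`, so the band power
#'     is a quadratic, not linear, function of MW;}
#'   \item{secondary linear}{a set of moderate, partially independent
#'     markers spread over the montage — midline theta power (Fz, Pz)
#'     rising with MW, posterior alpha1 power (P5, P6, O2, Oz) falling with
#'     MW, and fronto-parietal theta coherences (F3-P9, F4-P10) rising with
#'     MW — all
#'     scaled by `effect_secondary`, so that multivariate models have
#'     genuinely more to work with than any single predictor;}
#'   \item{behavioral}{per-trial reaction times are lognormal with a
#'     section-level log-scale SD of `rt_base_sd + rt_effect * plogis(mw)`,
#'     making RT variance grow with MW.}
#' }
#' Each pathway sees the latent trace through its own section-level
#' Gaussian jitter (`pathway_noise_sd`): the neural state driving an EEG
#' feature is a noisy version of the state the subject reports, so no
#' single feature is a clean readout and combining features genuinely
#' helps. Background activity is white noise of 10 microvolts SD per
#' channel; each subject's whole recording is scaled by a lognormal factor
#' (`subject_scale_sd` on the log scale) so that within-subject
#' normalization is consequential.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_sections Sections per session (default 42).
#' @param trials_per_section Trials per section (default 10).
#' @param trial_interval Trial duration in seconds (default 2).
#' @param sampling_rate Sampling rate in Hz (default 250); must exceed twice
#'   the highest band edge (44 Hz).
#' @param montage Character vector of electrode labels (default: the
#'   17-electrode montage F3 F4 F7 F8 Fz T3 T4 TP9 TP10 P5 P6 P9 P10 Pz O1
#'   O2 Oz).
#' @param mw_ar Coefficient of the AR(1) latent MW process (default 0.6).
#' @param mw_innovation_sd Innovation SD of the AR(1) process (default 0.8,
#'   giving a stationary SD of 1).
#' @param effect_linear Gain on the MW-dependent mixing weight of the
#'   shared beta3 source in Pz and O1 (default 1; 0 disables the pathway).
#' @param effect_nonlinear Coefficient of the quadratic MW to prefrontal
#'   beta1 power link (default 0.4; 0 disables).
#' @param nonlinear_vertex Vertex of the U-shaped link on the latent MW
#'   scale (default -1, one stationary SD below the mean).
#' @param effect_secondary Gain of the secondary linear markers (default
#'   1.6; 0 disables them).
#' @param pathway_noise_sd SD of the independent section-level jitter each
#'   EEG pathway adds to the latent trace before applying its link
#'   (default 0.4).
#' @param rt_effect Gain of MW on the per-section RT log-scale SD
#'   (default 0.3; 0 disables).
#' @param rt_base_sd Baseline RT log-scale SD (default 0.15).
#' @param artifact_rate Probability that any 1-s window receives a
#'   high-amplitude transient (default 0.05).
#' @param likert_noise SD of Gaussian noise added to the standardized MW
#'   trace before rounding to the 1..7 probe scale (default 0.3).
#' @param subject_scale_sd Log-scale SD of the per-subject amplitude factor
#'   (default 0.2).
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return An object of class `mweeg_sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 1)
#' cfg$n_sections
#' @export
sim_config <- function(n_subjects,
                       n_sections = 42,
                       trials_per_section = 10,
                       trial_interval = 2,
                       sampling_rate = 250,
                       montage = c("F3", "F4", "F7", "F8", "Fz", "T3", "T4",
                                   "TP9", "TP10", "P5", "P6", "P9", "P10",
                                   "Pz", "O1", "O2", "Oz"),
                       mw_ar = 0.6,
                       mw_innovation_sd = 0.8,
                       effect_linear = 1,
                       effect_nonlinear = 0.4,
                       nonlinear_vertex = -1,
                       effect_secondary = 1.6,
                       pathway_noise_sd = 0.4,
                       rt_effect = 0.3,
                       rt_base_sd = 0.15,
                       artifact_rate = 0.05,
                       likert_noise = 0.3,
                       subject_scale_sd = 0.2,
                       seed = 1L) {
  cfg <- structure(list(
    n_subjects = n_subjects, n_sections = n_sections,
    trials_per_section = trials_per_section, trial_interval = trial_interval,
    sampling_rate = sampling_rate, montage = montage,
    mw_ar = mw_ar, mw_innovation_sd = mw_innovation_sd,
    effect_linear = effect_linear, effect_nonlinear = effect_nonlinear,
    nonlinear_vertex = nonlinear_vertex, effect_secondary = effect_secondary,
    pathway_noise_sd = pathway_noise_sd,
    rt_effect = rt_effect, rt_base_sd = rt_base_sd,
    artifact_rate = artifact_rate, likert_noise = likert_noise,
    subject_scale_sd = subject_scale_sd, seed = as.integer(seed)),
    class = "mweeg_sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_subjects", "n_sections", "trials_per_section")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop_config(f, "must be an integer count >= 1")
  }
  if (cfg$trial_interval <= 0) stop_config("trial_interval", "must be positive")
  if (cfg$sampling_rate <= 2 * 44)
    stop_config("sampling_rate", "must exceed twice the highest band edge (44 Hz)")
  if (anyDuplicated(cfg$montage)) stop_config("montage", "labels must be unique")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate >= 1)
    stop_config("artifact_rate", "must lie in [0, 1)")
  if (abs(cfg$mw_ar) >= 1) stop_config("mw_ar", "must lie in (-1, 1) for stationarity")
  if (cfg$mw_innovation_sd <= 0) stop_config("mw_innovation_sd", "must be positive")
  if (cfg$likert_noise < 0) stop_config("likert_noise", "must be nonnegative")
  if (cfg$pathway_noise_sd < 0) stop_config("pathway_noise_sd", "must be nonnegative")
  if (cfg$effect_secondary < 0) stop_config("effect_secondary", "must be nonnegative")
  cfg
}

#' @export
print.mweeg_sim_config <- function(x, ...) {
  cat(sprintf("<synthetic cohort config: %d subjects, %d sections x %d x %gs trials, %g Hz, %d channels>\n",
              x$n_subjects, x$n_sections, x$trials_per_section,
              x$trial_interval, x$sampling_rate, length(x$montage)))
  cat(sprintf("  effects: linear=%g nonlinear=%g (vertex %g) rt=%g; artifact rate %g; seed %d\n",
              x$effect_linear, x$effect_nonlinear, x$nonlinear_vertex,
              x$rt_effect, x$artifact_rate, x$seed))
  invisible(x)
}

## Band-limiting by FFT masking: keep (or remove) the [low, high] Hz part.
band_component <- function(x, srate, low, high) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * srate / n
  f <- pmin(f, srate - f)                      # two-sided frequency axis
  X[f < low | f > high] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

## White noise band-limited to [low, high] Hz, unit SD.
bandlimited_noise <- function(n, srate, low, high) {
  y <- band_component(stats::rnorm(n), srate, low, high)
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Generate one synthetic session
#'
#' Produces one subject's task EEG, annotations and the latent ground truth
#' driving them. Identical `(config, subject_index)` pairs yield
#' bit-identical output; the caller's RNG stream is left untouched.
#'
#' @param config An [sim_config()] object.
#' @param subject_index Subject number, 1-based, at most `config$n_subjects`.
#' @return A list of class `mweeg_session` with elements `recording`
#'   (`mweeg_recording`), `annotations` (`mweeg_annotations`) and `truth`
#'   (list with `mw_trace`, `planted_features`, `rt_sd_trace`,
#'   `artifact_windows`, `subject_scale`).
#' @examples
#' s <- generate_session(sim_config(n_subjects = 1, n_sections = 3, seed = 1), 1)
#' nrow(s$recording$data) / s$recording$srate  # seconds of task EEG
#' @export
generate_session <- function(config, subject_index) {
  validate_sim_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop_config("n_subjects", sprintf("subject_index %d outside 1..%d",
                                      subject_index, config$n_subjects))
  sseed <- derive_seed(config$seed, subject_index)
  with_seed(sseed, generate_session_impl(config, subject_index))
}

generate_session_impl <- function(config, subject_index) {
  srate <- config$sampling_rate
  sec_s <- config$trials_per_section * config$trial_interval
  sec_n <- as.integer(sec_s * srate)
  n_sec <- config$n_sections
  n_tot <- sec_n * n_sec
  E <- length(config$montage)

  ## latent AR(1) MW trace, stationary start
  phi <- config$mw_ar; isd <- config$mw_innovation_sd
  mw <- numeric(n_sec)
  mw[1] <- stats::rnorm(1, 0, isd / sqrt(1 - phi^2))
  if (n_sec > 1)
    for (t in 2:n_sec) mw[t] <- phi * mw[t - 1] + stats::rnorm(1, 0, isd)

  subject_scale <- exp(stats::rnorm(1, 0, config$subject_scale_sd))
  base_sd <- 10                                 # background microvolts
  data <- matrix(stats::rnorm(n_tot * E, 0, base_sd), n_tot, E,
                 dimnames = list(NULL, config$montage))

  sec_gain <- function(g) rep(g, each = sec_n)  # per-section gain -> samples
  jitter <- function() mw + stats::rnorm(n_sec, 0, config$pathway_noise_sd)
  planted <- character(0)

  ## Constant-power mixing: the in-band content of both channels is replaced
  ## by sqrt(1 - w^2) * private + w * shared, so in-band power stays flat
  ## while the coherence rises monotonically with the per-section weight w.
  plant_coherence <- function(cha, chb, low, high, w) {
    gw <- sec_gain(w)
    ga <- sec_gain(sqrt(1 - w^2))
    shared <- bandlimited_noise(n_tot, srate, low, high)
    for (ch in c(cha, chb)) {
      rem <- band_component(data[, ch], srate, low, high)
      priv <- bandlimited_noise(n_tot, srate, low, high)
      data[, ch] <<- data[, ch] - rem + stats::sd(rem) * (ga * priv + gw * shared)
    }
  }
  ## Additive source scaled to the channel's own in-band SD, so amp^2 is the
  ## fractional in-band power increase.
  plant_power <- function(ch, low, high, amp) {
    band_sd <- stats::sd(band_component(data[, ch], srate, low, high))
    src <- bandlimited_noise(n_tot, srate, low, high) * band_sd
    data[, ch] <<- data[, ch] + sec_gain(amp) * src
  }

  if (config$effect_linear > 0 &&
      all(c("Pz", "O1") %in% config$montage)) {
    w <- pmin(config$effect_linear * stats::plogis(jitter()), 0.95)
    plant_coherence("Pz", "O1", 21.5, 30, w)
    planted <- c(planted, "coh_Pz_O1_beta3")
  }

  if (config$effect_secondary > 0) {
    e2 <- config$effect_secondary
    for (ch in c("Fz", "Pz")) {             # midline theta rises with MW
      if (ch %in% config$montage) {
        plant_power(ch, 6.5, 8, sqrt(e2) * stats::plogis(jitter()))
        planted <- c(planted, sprintf("power_%s_theta", ch))
      }
    }
    for (ch in c("P5", "P6", "O2", "Oz")) {  # posterior alpha1 falls with MW
      if (ch %in% config$montage) {
        plant_power(ch, 8.5, 10, sqrt(e2) * stats::plogis(-jitter()))
        planted <- c(planted, sprintf("power_%s_alpha1", ch))
      }
    }
    for (pr in list(c("F3", "P9"), c("F4", "P10"))) {  # fronto-parietal theta coupling
      if (all(pr %in% config$montage)) {
        w2 <- pmin(e2 * stats::plogis(jitter()), 0.95)
        plant_coherence(pr[1], pr[2], 6.5, 8, w2)
        planted <- c(planted, sprintf("coh_%s_%s_theta", pr[1], pr[2]))
      }
    }
  }

  if (config$effect_nonlinear > 0 &&
      all(c("F3", "F4") %in% config$montage)) {
    for (ch in c("F3", "F4")) {
      amp <- sqrt(config$effect_nonlinear) * abs(jitter() - config$nonlinear_vertex)
      plant_power(ch, 12.5, 18, amp)
      planted <- c(planted, sprintf("power_%s_beta1", ch))
    }
  }

  data <- data * subject_scale

  ## behavioral data: lognormal per-trial RTs, SD driven by MW
  rt_sd <- config$rt_base_sd + config$rt_effect * stats::plogis(mw)
  rts <- lapply(seq_len(n_sec), function(i)
    stats::rlnorm(config$trials_per_section, log(0.4), rt_sd[i]))

  ## probe answers: standardized MW + noise, affine-mapped to 1..7
  z <- (mw - mean(mw)) / max(sd_pop(mw), .Machine$double.eps)
  ans <- round(4 + 1.5 * (z + stats::rnorm(n_sec, 0, config$likert_noise)))
  ans <- pmin(7L, pmax(1L, as.integer(ans)))

  rec <- new_recording(data, srate)
  ann <- new_annotations(section_onsets = (seq_len(n_sec) - 1) * sec_s,
                         section_duration = sec_s,
                         probe_answers = ans, rts = rts)

  art_windows <- integer(0)
  if (config$artifact_rate > 0) {
    rec <- inject_artifacts(rec, ann, rate = config$artifact_rate,
                            seed = derive_seed(config$seed, subject_index + 7919L))
    art_windows <- attr(rec, "artifact_windows")
  }

  structure(list(recording = rec, annotations = ann,
                 truth = list(mw_trace = mw,
                              planted_features = planted,
                              rt_sd_trace = rt_sd,
                              artifact_windows = art_windows,
                              subject_scale = subject_scale),
                 subject = subject_index),
            class = "mweeg_session")
}

#' Generate a whole synthetic cohort
#'
#' Calls [generate_session()] for each subject with a deterministic
#' per-subject sub-seed derived from `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A list of `mweeg_session` objects, one per subject.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  lapply(seq_len(config$n_subjects), function(i) generate_session(config, i))
}

#' Inject high-amplitude artifact transients
#'
#' Adds a short half-sine transient (120 ms, 400 microvolt peak, twice
#' the default 200 microvolt peak-to-peak rejection threshold) to a random
#' channel of each selected 1-s window. Windows are selected independently
#' with probability `rate`. The contaminated window indices are recorded in
#' the `"artifact_windows"` attribute for test introspection.
#'
#' @param recording An `mweeg_recording`.
#' @param annotations Session annotations (defines the 1-s window grid).
#' @param rate Per-window contamination probability in \[0, 1).
#' @param seed Integer seed for window and channel selection.
#' @return The contaminated recording, with attribute `artifact_windows`.
#' @export
inject_artifacts <- function(recording, annotations, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop_config("artifact_rate", "must lie in [0, 1)")
  if (rate == 0) {
    attr(recording, "artifact_windows") <- integer(0)
    return(recording)
  }
  srate <- recording$srate
  n_win <- floor(nrow(recording$data) / srate)
  with_seed(seed, {
    hit <- which(stats::runif(n_win) < rate)
    pulse_len <- max(3L, as.integer(0.12 * srate))
    pulse <- 400 * sin(pi * seq_len(pulse_len) / (pulse_len + 1))
    for (w in hit) {
      ch <- sample.int(ncol(recording$data), 1)
      pos <- (w - 1) * srate + sample.int(srate - pulse_len, 1)
      sgn <- sample(c(-1, 1), 1)
      idx <- pos + seq_len(pulse_len)
      recording$data[idx, ch] <- recording$data[idx, ch] + sgn * pulse
    }
    attr(recording, "artifact_windows") <- hit
    recording
  })
}
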