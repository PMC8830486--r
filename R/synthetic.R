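#' Labelled multichannel EEG recording
#'
#' Lightweight container for a channels-by-samples matrix in microvolts with
#' 10-20 electrode labels and a sampling rate.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param channel_labels character vector, one 10-20 label per row.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id identifier used in tables and logs.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate,
                          subject_id = "S01") {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels),
            sampling_rate > 0)
  labels <- canonical_labels(channel_labels)
  unknown <- setdiff(labels, known_1020_labels())
  if (length(unknown))
    warning("labels not in the 10-20 set: ", paste(unknown, collapse = ", "),
            "; accepted names include ",
            paste(known_1020_labels()[1:19], collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, channels = labels,
                 sampling_rate = sampling_rate, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Outcome score model for synthetic cohorts
#'
#' Scores are generated as `baseline + slope * z(feature) + N(0, residual_sd)`
#' where `z(feature)` is the standardized planted per-subject feature, then
#' clipped to `range`.  With the feature standardized, the planted population
#' correlation is `slope / sqrt(slope^2 + residual_sd^2)`.
#'
#' @param baseline mean score of the cohort (composite-score scale,
#'   population mean 100).
#' @param slope score-units change per SD of the planted feature; sign sets
#'   the direction of the planted association.
#' @param residual_sd residual score SD, must be >= 0.
#' @param range score clipping range; defaults to the observed 74-145 span.
#' @export
score_model <- function(baseline = 100, slope = 0, residual_sd = 15,
                        range = c(74, 145)) {
  if (residual_sd < 0) stop("configuration error: residual_sd must be >= 0")
  list(baseline = baseline, slope = slope, residual_sd = residual_sd,
       range = range)
}

#' Score model achieving a target planted correlation
#'
#' @param rho target population correlation between the planted feature and
#'   the (unclipped) scores; sign carries through to the slope.
#' @param total_sd total score SD (slope and residual components combined).
#' @inheritParams score_model
#' @export
score_model_for_rho <- function(rho, total_sd = 15, baseline = 100,
                                range = c(74, 145)) {
  stopifnot(abs(rho) <= 1)
  score_model(baseline = baseline, slope = rho * total_sd,
              residual_sd = sqrt(1 - rho^2) * total_sd, range = range)
}

#' Specification of a synthetic EEG cohort
#'
#' Declares everything the generator needs: cohort shape, planted narrowband
#' oscillations, planted phase coupling between channel pairs, a per-subject
#' complexity gradient (the planted feature driving outcome scores), planted
#' artifacts, and the score model.  The generator is fully deterministic
#' given `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sampling_rate Hz.
#' @param duration seconds per recording; `duration * sampling_rate` must be
#'   integral.
#' @param channel_labels 10-20 electrode names.
#' @param oscillation_specs list of `list(freq, amplitude, channels)`:
#'   sinusoids (Hz, microvolts) planted on the named channels with a random
#'   per-subject/channel phase.
#' @param coupling_specs list of `list(pair, lag, strength, band, amplitude)`
#'   planted band-limited phase coupling; see [plant_coupled_pair()].
#' @param complexity_gradient `NULL` or a list with elements
#'   `noise_scale` (per-subject multiplier on the broadband noise SD),
#'   and optionally a planted narrowband complexity feature:
#'   `channel`, `freq` (Hz), `band` (Hz pair), `amplitude` (microvolts) and
#'   `mix` (per-subject tone-to-noise mixing ratio in `[0, 1]`; higher mix =
#'   more irregular = higher entropy).  `mix` is the ground-truth feature
#'   the score model couples to.
#' @param artifact_spec `NULL` or a list with `flat_channels`,
#'   `noisy_channels`, `noisy_factor`, `supra_fraction`, `supra_amplitude`,
#'   and `ocular = list(rate, amplitude, topography)` (low-frequency
#'   frontal-weighted transients).
#' @param noise_sd broadband white-noise SD in microvolts.
#' @param score_model see [score_model()].
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, sampling_rate = 512, duration = 60,
                        channel_labels = c("C3", "F3", "F7", "FZ", "O1", "O2",
                                           "P3", "P4", "T3", "T4", "T5", "T6"),
                        oscillation_specs = list(),
                        coupling_specs = list(),
                        complexity_gradient = NULL,
                        artifact_spec = NULL,
                        noise_sd = 2,
                        score_model = neoqeeg::score_model(),
                        seed = 1L) {
  if (n_subjects < 2) stop("configuration error: n_subjects must be >= 2")
  n_samp <- duration * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("configuration error: duration * sampling_rate must be integral")
  labels <- canonical_labels(channel_labels)
  check_channels <- function(ch, what) {
    bad <- setdiff(canonical_labels(ch), labels)
    if (length(bad))
      stop("configuration error: ", what, " channel(s) not in channel set: ",
           paste(bad, collapse = ", "))
  }
  for (osc in oscillation_specs) check_channels(osc$channels, "oscillation")
  for (cs in coupling_specs) {
    check_channels(cs$pair, "coupling")
    if (cs$strength < 0 || cs$strength > 1)
      stop("configuration error: coupling strength must be in [0, 1]")
    if (cs$lag <= -pi || cs$lag > pi)
      stop("configuration error: lag must be in (-pi, pi]")
  }
  if (!is.null(complexity_gradient)) {
    cg <- complexity_gradient
    if (!is.null(cg$channel)) check_channels(cg$channel, "complexity gradient")
    if (!is.null(cg$mix) && (length(cg$mix) != n_subjects ||
                             any(cg$mix < 0 | cg$mix > 1)))
      stop("configuration error: mix must be per-subject values in [0, 1]")
    if (!is.null(cg$noise_scale) && length(cg$noise_scale) != n_subjects)
      stop("configuration error: noise_scale must have one value per subject")
  }
  structure(list(n_subjects = n_subjects, sampling_rate = sampling_rate,
                 duration = duration, channel_labels = labels,
                 oscillation_specs = oscillation_specs,
                 coupling_specs = coupling_specs,
                 complexity_gradient = complexity_gradient,
                 artifact_spec = artifact_spec, noise_sd = noise_sd,
                 score_model = score_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Plant band-limited phase coupling between a channel pair
#'
#' Adds a coupling spec under which the second channel's band-limited
#' component equals the first's phase-shifted by `lag`, mixed with
#' independent same-band noise in proportion `1 - strength`.  At strength 1
#' and lag pi/2 the downstream WPLI of the pair approaches 1; at strength 0
#' the channels share no lagged coupling.
#'
#' @param spec a [cohort_spec()].
#' @param pair length-2 character, coupled channels (driver first).
#' @param lag phase lag in radians, in `(-pi, pi]`.
#' @param strength coupling strength in `[0, 1]`.
#' @param band frequency band of the coupled component, Hz.
#' @param amplitude RMS amplitude of the coupled component, microvolts.
#' @return the spec with the coupling appended.
#' @export
plant_coupled_pair <- function(spec, pair, lag, strength, band = c(8, 12),
                               amplitude = 10) {
  stopifnot(inherits(spec, "cohort_spec"))
  new_specs <- c(spec$coupling_specs,
                 list(list(pair = canonical_labels(pair), lag = lag,
                           strength = strength, band = band,
                           amplitude = amplitude)))
  cohort_spec(n_subjects = spec$n_subjects,
              sampling_rate = spec$sampling_rate, duration = spec$duration,
              channel_labels = spec$channel_labels,
              oscillation_specs = spec$oscillation_specs,
              coupling_specs = new_specs,
              complexity_gradient = spec$complexity_gradient,
              artifact_spec = spec$artifact_spec, noise_sd = spec$noise_sd,
              score_model = spec$score_model, seed = spec$seed)
}

band_noise <- function(n, fs, band) {
  x <- fft_bandpass(rnorm(n + 2 * fs), fs, band) # pad to absorb wrap-around
  x <- x[(fs + 1):(fs + n)]
  x / sd(x)
}

# Random-phase, flat-amplitude narrowband process (surrogate-data style):
# every DFT bin inside the band gets unit magnitude and an independent
# phase, so the realization's own periodogram is exactly flat across the
# band.  Used for the complexity gradient, where the planted quantity is
# spectral spread and realization-to-realization spectral variance would
# otherwise blur it.
flat_band_noise <- function(n, fs, band, exclude_freq = NULL) {
  freqs <- (seq_len(n) - 1) * fs / n
  k <- which(freqs >= band[1] & freqs <= band[2] & seq_len(n) <= n / 2)
  if (!is.null(exclude_freq))
    k <- k[abs(freqs[k] - exclude_freq) > fs / n / 2]
  X <- complex(real = rep(0, n))
  ph <- runif(length(k), 0, 2 * pi)
  X[k] <- exp(1i * ph)
  X[n - k + 2] <- Conj(X[k])
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic recording
#'
#' Deterministic given the spec's seed and the subject index: the same call
#' repeated yields bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject number, 1-based.
#' @return an [eeg_recording()].
#' @export
generate_recording <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (subject_index < 1 || subject_index > spec$n_subjects)
    stop("configuration error: subject_index out of range")
  fs <- spec$sampling_rate
  n <- as.integer(round(spec$duration * fs))
  labels <- spec$channel_labels
  nc <- length(labels)
  t_sec <- (seq_len(n) - 1) / fs
  set.seed(derive_seed(spec$seed, subject_index, salt = 1L))

  cg <- spec$complexity_gradient
  nscale <- if (!is.null(cg$noise_scale)) cg$noise_scale[subject_index] else 1
  x <- matrix(rnorm(nc * n, sd = spec$noise_sd * nscale), nrow = nc,
              dimnames = list(labels, NULL))

  for (osc in spec$oscillation_specs) {
    for (ch in canonical_labels(osc$channels)) {
      phase <- runif(1, 0, 2 * pi)
      x[ch, ] <- x[ch, ] + osc$amplitude * sin(2 * pi * osc$freq * t_sec + phase)
    }
  }

  if (!is.null(cg$channel)) {
    mix <- cg$mix[subject_index]
    tone <- sqrt(2) * sin(2 * pi * cg$freq * t_sec + runif(1, 0, 2 * pi))
    # irregular part built block-wise at the downstream epoch length so
    # each epoch sees the same flat in-band spectrum
    block <- as.integer(round((cg$epoch_s %||% 2) * fs))
    n_blocks <- ceiling(n / block)
    irregular <- unlist(lapply(seq_len(n_blocks), function(b)
      flat_band_noise(block, fs, cg$band, exclude_freq = cg$freq)))[seq_len(n)]
    # unit-variance mixture: only the regularity changes along the gradient
    comp <- ((1 - mix) * tone + mix * irregular) /
      sqrt((1 - mix)^2 + mix^2)
    x[canonical_labels(cg$channel), ] <-
      x[canonical_labels(cg$channel), ] + cg$amplitude * comp
  }

  for (cs in spec$coupling_specs) {
    a <- cs$pair[1]; b <- cs$pair[2]
    s_a <- band_noise(n, fs, cs$band)
    shifted <- Re(analytic_signal(s_a) * exp(-1i * cs$lag))
    s_ind <- band_noise(n, fs, cs$band)
    x[a, ] <- x[a, ] + cs$amplitude * s_a
    x[b, ] <- x[b, ] + cs$amplitude *
      (cs$strength * shifted + (1 - cs$strength) * s_ind)
  }

  as_ <- spec$artifact_spec
  if (!is.null(as_)) {
    for (ch in canonical_labels(as_$flat_channels %||% character()))
      x[ch, ] <- rnorm(n, sd = 1e-3)
    for (ch in canonical_labels(as_$noisy_channels %||% character()))
      x[ch, ] <- rnorm(n, sd = spec$noise_sd * (as_$noisy_factor %||% 20))
    if (!is.null(as_$supra_fraction) && as_$supra_fraction > 0) {
      epoch_len <- 2 * fs
      n_ep <- floor(n / epoch_len)
      n_bad <- ceiling(as_$supra_fraction * n_ep)
      bad_ep <- sample(n_ep, n_bad)
      amp <- as_$supra_amplitude %||% 80
      for (e in bad_ep) {
        i0 <- (e - 1) * epoch_len
        w <- exp(-((seq_len(epoch_len) - epoch_len / 2)^2) / (2 * (fs / 4)^2))
        ch <- sample(nc, 1)
        x[ch, i0 + seq_len(epoch_len)] <- x[ch, i0 + seq_len(epoch_len)] + amp * w
      }
    }
    oc <- as_$ocular
    if (!is.null(oc)) {
      topo <- oc$topography
      if (is.null(topo)) { # frontal-weighted default
        topo <- as.numeric(grepl("^(FP|F)", labels)) + 0.1
        topo <- topo / max(topo)
      }
      n_ev <- max(1L, as.integer(round((oc$rate %||% 0.2) * spec$duration)))
      src <- rep(0, n)
      for (ev in seq_len(n_ev)) {
        t0 <- runif(1, 0.5, spec$duration - 0.5)
        width <- runif(1, 0.15, 0.4) # > 0.15 s half-width: < 4 Hz content
        src <- src + (oc$amplitude %||% 40) * exp(-((t_sec - t0)^2) / (2 * width^2))
      }
      x <- x + outer(topo, src)
      attr(x, "ocular_source") <- src
    }
  }

  rec <- eeg_recording(x, labels, fs,
                       subject_id = sprintf("S%02d", subject_index))
  rec$ocular_source <- attr(x, "ocular_source")
  rec
}

#' Generate a full synthetic cohort with coupled outcome scores
#'
#' Recordings are generated per subject; scores follow the spec's
#' [score_model()] applied to the standardized planted feature (the
#' complexity-gradient `mix`, falling back to `noise_scale`), then clipped to
#' the declared range.  Ground truth (planted feature values, planted
#' population correlation, clipping fraction) is recorded for recovery
#' checks.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort` with elements `recordings`,
#'   `scores` (data.frame `subject_id`, `score`) and `ground_truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recordings <- lapply(seq_len(spec$n_subjects),
                       function(i) generate_recording(spec, i))
  cg <- spec$complexity_gradient
  g <- cg$mix %||% cg$noise_scale %||% rep(0, spec$n_subjects)
  sm <- spec$score_model
  z <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, spec$n_subjects)
  set.seed(derive_seed(spec$seed, 0L, salt = 2L))
  raw <- sm$baseline + sm$slope * z + rnorm(spec$n_subjects, 0, sm$residual_sd)
  scores <- pmin(pmax(raw, sm$range[1]), sm$range[2])
  denom <- sqrt(sm$slope^2 + sm$residual_sd^2)
  structure(list(
    recordings = recordings,
    scores = data.frame(subject_id = vapply(recordings, `[[`, "", "subject_id"),
                        score = scores),
    ground_truth = list(
      feature = g,
      planted_rho = if (denom > 0) sm$slope / denom else 0,
      slope_sign = sign(sm$slope),
      target_channel = cg$channel %||% NA_character_,
      target_band = cg$band %||% NULL,
      clip_fraction = mean(raw != scores)),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d subjects, %d channels, %g s @ %g Hz\n",
                     "  planted rho = %.3f, clip fraction = %.2f\n"),
              x$spec$n_subjects, length(x$spec$channel_labels),
              x$spec$duration, x$spec$sampling_rate,
              x$ground_truth$planted_rho, x$ground_truth$clip_fraction))
  invisible(x)
}

#' Write a cohort to an on-disk fixture
#'
#' Recordings are written as a plain array container (one TSV matrix per
#' subject, samples in rows and channels in columns, full double precision,
#' with a JSON sidecar holding labels and sampling rate); scores go to a
#' tab-separated `scores.tsv` and the planted ground truth to
#' `ground_truth.json`.  The container round-trips losslessly through
#' [read_recording()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param path directory to create/write into.
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (rec in cohort$recordings) {
    base <- file.path(path, paste0(rec$subject_id, "_eeg"))
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channels
    ok <- tryCatch({
      write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                  paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(list(subject_id = rec$subject_id,
                                sampling_rate = rec$sampling_rate,
                                channel_labels = rec$channels,
                                unit = "uV"),
                           paste0(base, ".json"), auto_unbox = TRUE)
      TRUE
    }, error = function(e) {
      stop("I/O failure writing ", base, ": ", conditionMessage(e))
    })
    files <- c(files, paste0(base, c(".tsv", ".json")))
  }
  write.table(cohort$scores, file.path(path, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, file.path(path, c("scores.tsv", "ground_truth.json"))))
}
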