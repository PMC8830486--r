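#' Sifting configuration for NA-MEMD
#'
#' @param n_directions number of direction vectors K sampled on the
#'   hypersphere (K >= 2x the dimensionality is recommended).
#' @param n_noise_channels number of independent white-noise variates
#'   appended before decomposition.
#' @param noise_sd_fraction noise SD as a fraction of the pooled signal SD.
#' @param max_sift_iterations cap on sifting iterations per mode.
#' @param stoppage_tolerance threshold of the amplitude-normalized sifting
#'   stoppage: sifting of a mode stops once the local envelope-mean-to-
#'   envelope-amplitude ratio exceeds the threshold on fewer than that
#'   fraction of samples and nowhere exceeds ten times it.
#' @param max_imfs cap on extracted modes (`Inf` = until the remainder is
#'   monotonic).
#' @param merge_ratio adjacent modes whose pooled spectral centroids differ
#'   by less than this factor are consolidated into one mode after sifting
#'   (over-decomposition repair; genuine neighbours of a dyadic cascade
#'   differ by a factor of about 2).  Set to `NULL` to disable.
#' @param seed seed of the noise realization.
#' @export
sift_config <- function(n_directions = 64, n_noise_channels = 2,
                        noise_sd_fraction = 0.1, max_sift_iterations = 10,
                        stoppage_tolerance = 0.075, max_imfs = Inf,
                        merge_ratio = 1.5, seed = 1L) {
  stopifnot(noise_sd_fraction > 0, n_directions >= 1, max_sift_iterations >= 1)
  structure(list(n_directions = as.integer(n_directions),
                 n_noise_channels = as.integer(n_noise_channels),
                 noise_sd_fraction = noise_sd_fraction,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 stoppage_tolerance = stoppage_tolerance,
                 max_imfs = max_imfs, merge_ratio = merge_ratio,
                 seed = as.integer(seed)),
            class = "sift_config")
}

radical_inverse <- function(i, base) {
  out <- 0; f <- 1 / base
  while (i > 0) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Low-discrepancy direction vectors on the unit hypersphere
#'
#' Maps a Hammersley sequence in the unit cube to uniformly distributed
#' points on the (n-1)-sphere through exact inverse-CDF transforms of the
#' hyperspherical angles.  Deterministic: repeated calls give the same set.
#'
#' @param dimensionality ambient dimension n (>= 2).
#' @param K number of directions.
#' @return a K x n matrix of unit vectors.
#' @export
hammersley_directions <- function(dimensionality, K) {
  n <- as.integer(dimensionality)
  stopifnot(n >= 2, K >= 1)
  u <- matrix(0, K, n - 1)
  u[, 1] <- (seq_len(K) - 0.5) / K
  if (n > 2) {
    bases <- first_primes(n - 2)
    for (j in seq_len(n - 2))
      u[, j + 1] <- vapply(seq_len(K), radical_inverse, 0, base = bases[j])
  }
  dirs <- matrix(0, K, n)
  # angles phi_1..phi_{n-2} on [0, pi] with sin^k density (k = n-1-j),
  # exact via the symmetric Beta inverse CDF; last angle uniform on [0, 2pi)
  for (row in seq_len(K)) {
    phi <- numeric(n - 1)
    if (n > 2) {
      for (j in seq_len(n - 2)) {
        k <- n - 1 - j
        phi[j] <- acos(1 - 2 * qbeta(u[row, j], (k + 1) / 2, (k + 1) / 2))
      }
    }
    phi[n - 1] <- 2 * pi * u[row, n - 1]
    v <- numeric(n)
    sin_prod <- 1
    for (j in seq_len(n - 1)) {
      v[j] <- sin_prod * cos(phi[j])
      sin_prod <- sin_prod * sin(phi[j])
    }
    v[n] <- sin_prod
    dirs[row, ] <- v / sqrt(sum(v^2))
  }
  dirs
}

residue_condition <- function(msg = "signal is a residue: too few extrema") {
  structure(class = c("neoqeeg_residue", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Mean envelope of a multivariate signal
#'
#' For each direction vector: project the signal, locate the projection
#' maxima, cubic-spline interpolate the multivariate signal values at those
#' instants (natural splines, extrema mirrored about both boundaries), then
#' average the K envelopes.  Signals whose projections carry fewer than two
#' maxima are residues and raise a condition of class `neoqeeg_residue`.
#'
#' @param v variates x samples matrix.
#' @param directions K x variates matrix of unit directions.
#' @return the mean envelope, same shape as `v`.
#' @export
envelope_mean <- function(v, directions) {
  res <- memd_envelope_mean_cpp(v, directions)
  if (!res$ok) stop(residue_condition())
  res$m
}

is_monotonic_rows <- function(v) {
  all(apply(v, 1, function(row) {
    d <- diff(row)
    all(d >= 0) || all(d <= 0)
  }))
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean envelope from the running detail.  The
#' stoppage rule is amplitude-normalized: with `sx(t)` the ratio of the
#' envelope-mean norm to the local envelope amplitude, sifting stops when
#' `sx` exceeds the tolerance on fewer than a `tolerance` fraction of
#' samples and never exceeds ten times it (or at the iteration cap).  This
#' sifts noisy details hard while leaving already-symmetric oscillations
#' untouched, which prevents single tones from eroding across modes.
#' `imf + remainder` reconstructs the input exactly.
#'
#' @param v variates x samples matrix (not a residue).
#' @param cfg a [sift_config()].
#' @param directions direction set; defaults to Hammersley directions of the
#'   right dimensionality.
#' @return list with elements `imf`, `remainder` and `n_sifts`.
#' @export
extract_imf <- function(v, cfg = sift_config(), directions = NULL) {
  if (is.null(directions))
    directions <- hammersley_directions(nrow(v), cfg$n_directions)
  detail <- v
  n_sifts <- 0L
  tol <- cfg$stoppage_tolerance
  for (it in seq_len(cfg$max_sift_iterations)) {
    res <- memd_envelope_mean_cpp(detail, directions)
    if (!res$ok) {
      if (it == 1L) stop(residue_condition())
      break
    }
    m_norm <- sqrt(colSums(res$m^2))
    sx <- ifelse(res$amp > 0, m_norm / res$amp, 0)
    detail <- detail - res$m
    n_sifts <- it
    if (mean(sx > tol) < tol && all(sx < 10 * tol)) break
  }
  list(imf = detail, remainder = v - detail, n_sifts = n_sifts)
}

#' Noise-assisted multivariate empirical mode decomposition
#'
#' Appends seeded independent white-noise variates (SD =
#' `noise_sd_fraction` x pooled signal SD), sifts the composite signal into
#' intrinsic mode functions until the remainder is monotonic on every
#' variate (or no projection retains two maxima), then discards the noise
#' variates.  As a final repair step, adjacent modes whose pooled spectral
#' centroids (over the original variates) differ by less than
#' `merge_ratio` are summed into one mode: sifting occasionally splits a
#' single oscillation across two spectrally indistinguishable neighbours,
#' and consolidation restores the one-scale-per-mode reading without
#' touching completeness or alignment.  All variates share one set of
#' aligned modes, and `sum(modes) + residue` reconstructs each variate
#' exactly.
#'
#' @param x variates x samples matrix (>= 2 variates, finite values).
#' @param cfg a [sift_config()].
#' @return an object of class `imf_decomposition`: `modes` (array
#'   `[mode, variate, sample]`), `residue` (matrix), `n_modes`, `config`.
#' @export
na_memd <- function(x, cfg = sift_config()) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (!all(is.finite(x))) stop("non-finite values in input")
  n_orig <- nrow(x)
  pooled_sd <- sd(as.vector(x))
  comp <- x
  if (cfg$n_noise_channels > 0 && pooled_sd > 0) {
    set.seed(cfg$seed)
    noise <- matrix(rnorm(cfg$n_noise_channels * ncol(x),
                          sd = cfg$noise_sd_fraction * pooled_sd),
                    nrow = cfg$n_noise_channels)
    comp <- rbind(x, noise)
  }
  directions <- hammersley_directions(nrow(comp), cfg$n_directions)
  modes <- list()
  r <- comp
  while (length(modes) < cfg$max_imfs && !is_monotonic_rows(r)) {
    res <- tryCatch(extract_imf(r, cfg, directions),
                    neoqeeg_residue = function(e) NULL)
    if (is.null(res)) break
    modes[[length(modes) + 1L]] <- res$imf
    r <- res$remainder
  }
  modes <- lapply(modes, function(m) m[seq_len(n_orig), , drop = FALSE])
  if (!is.null(cfg$merge_ratio) && cfg$merge_ratio > 1)
    modes <- consolidate_modes(modes, cfg$merge_ratio)
  n_modes <- length(modes)
  mode_arr <- array(0, dim = c(n_modes, n_orig, ncol(x)))
  for (m in seq_len(n_modes))
    mode_arr[m, , ] <- modes[[m]]
  structure(list(modes = mode_arr,
                 residue = r[seq_len(n_orig), , drop = FALSE],
                 n_modes = n_modes, config = cfg), class = "imf_decomposition")
}

# Pooled spectral centroid in normalized frequency (the merge criterion is
# a ratio, so the sampling rate cancels).
pooled_centroid <- function(mat) {
  n <- ncol(mat); nf <- n %/% 2
  P <- rowSums(vapply(seq_len(nrow(mat)), function(i)
    Mod(fft(mat[i, ]))[2:(nf + 1)]^2, numeric(nf)))
  if (sum(P) == 0) return(0)
  sum(seq_len(nf) * P) / sum(P)
}

consolidate_modes <- function(modes, ratio) {
  repeat {
    if (length(modes) < 2) break
    cents <- vapply(modes, pooled_centroid, 0)
    rr <- ifelse(cents[-1] > 0, cents[-length(cents)] / cents[-1], Inf)
    i <- which(rr < ratio)[1]
    if (is.na(i)) break
    modes[[i]] <- modes[[i]] + modes[[i + 1]]
    modes[[i + 1]] <- NULL
  }
  modes
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d modes x %d variates x %d samples\n",
              x$n_modes, dim(x$modes)[2], dim(x$modes)[3]))
  invisible(x)
}

#' Frequency summary of each mode
#'
#' Per mode, pooled over all variates: the periodogram spectral centroid
#' (mean frequency) and the band holding the central 90% of power.
#'
#' @param dec an `imf_decomposition`.
#' @param fs sampling rate in Hz.
#' @param exclude_variates variate indices to leave out of the pooling
#'   (e.g. known noise-only rows).
#' @return data.frame with columns `mode`, `mean_hz`, `low_hz`, `high_hz`.
#' @export
characterize_imf_frequencies <- function(dec, fs, exclude_variates = integer()) {
  stopifnot(inherits(dec, "imf_decomposition"), dec$n_modes >= 1)
  n <- dim(dec$modes)[3]
  keep <- setdiff(seq_len(dim(dec$modes)[2]), exclude_variates)
  nf <- n %/% 2
  freqs <- seq_len(nf) * fs / n
  out <- lapply(seq_len(dec$n_modes), function(m) {
    sub <- dec$modes[m, keep, , drop = FALSE]
    P <- rowMeans(vapply(seq_along(keep), function(i) {
      Mod(fft(sub[1, i, ]))[2:(nf + 1)]^2
    }, numeric(nf)))
    tot <- sum(P)
    if (tot == 0) return(data.frame(mode = m, mean_hz = 0, low_hz = 0, high_hz = 0))
    cum <- cumsum(P) / tot
    data.frame(mode = m, mean_hz = sum(freqs * P) / tot,
               low_hz = freqs[which(cum >= 0.05)[1]],
               high_hz = freqs[which(cum >= 0.95)[1]])
  })
  do.call(rbind, out)
}

#' Select the analysis modes
#'
#' The default rule mirrors retaining the middle modes of a ten-mode
#' decomposition: drop the leading `drop_head` modes (broadband/noisy) and
#' the trailing `drop_tail` modes (residue-like).  The band rule instead
#' keeps modes whose spectral centroid falls inside `band` Hz, which suits
#' small synthetic fixtures.
#'
#' @param dec an `imf_decomposition`.
#' @param rule `"default"` or `"band"`.
#' @param drop_head,drop_tail counts for the default rule.
#' @param band,fs band (Hz) and sampling rate for the band rule.
#' @return the decomposition restricted to the selected modes; attribute
#'   `selected_modes` holds the original indices.
#' @export
select_analysis_imfs <- function(dec, rule = c("default", "band"),
                                 drop_head = 3, drop_tail = 1,
                                 band = NULL, fs = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(dec, "imf_decomposition"))
  if (rule == "default") {
    if (dec$n_modes < drop_head + drop_tail + 1)
      stop("too few modes: have ", dec$n_modes, ", need at least ",
           drop_head + drop_tail + 1)
    idx <- (drop_head + 1):(dec$n_modes - drop_tail)
  } else {
    stopifnot(!is.null(band), !is.null(fs))
    fsum <- characterize_imf_frequencies(dec, fs)
    idx <- fsum$mode[fsum$mean_hz >= band[1] & fsum$mean_hz <= band[2]]
    if (!length(idx)) stop("no mode has its spectral centroid in the band")
  }
  dec$modes <- dec$modes[idx, , , drop = FALSE]
  dec$n_modes <- length(idx)
  attr(dec, "selected_modes") <- idx
  dec
}

#' Stack a cohort's clean epochs into per-channel multivariate matrices
#'
#' Builds, for every channel, one matrix with `n_subjects * n_epochs` rows
#' of `n_samples` columns (subject-major, epoch-minor row order), so a
#' single multivariate decomposition per channel yields modes aligned
#' across all subjects and epochs.
#'
#' @param epochs_list list of `clean_epochs`, one per subject, sharing
#'   channel set, epoch count and epoch length.
#' @return list with `channels` (named list of matrices) and `row_index`
#'   (data.frame `row`, `subject`, `epoch`).
#' @export
stack_cohort_per_channel <- function(epochs_list) {
  stopifnot(length(epochs_list) >= 1)
  ref <- epochs_list[[1]]
  d_ref <- dim(ref$epochs)
  for (i in seq_along(epochs_list)) {
    e <- epochs_list[[i]]
    if (!identical(e$channels, ref$channels) ||
        !identical(dim(e$epochs), d_ref))
      stop("inconsistent shapes for subject ", e$subject_id)
  }
  n_s <- length(epochs_list); n_e <- d_ref[2]; n_t <- d_ref[3]
  row_index <- data.frame(row = seq_len(n_s * n_e),
                          subject = rep(seq_len(n_s), each = n_e),
                          epoch = rep(seq_len(n_e), times = n_s))
  channels <- setNames(lapply(seq_along(ref$channels), function(ci) {
    m <- matrix(0, n_s * n_e, n_t)
    for (s in seq_len(n_s))
      m[(s - 1) * n_e + seq_len(n_e), ] <- epochs_list[[s]]$epochs[ci, , ]
    m
  }), ref$channels)
  list(channels = channels, row_index = row_index,
       fs = ref$fs, n_subjects = n_s, n_epochs = n_e)
}

#' Invert the per-channel stacking
#'
#' @param mat a stacked matrix (rows = subject-major, epoch-minor).
#' @param row_index the `row_index` of [stack_cohort_per_channel()].
#' @return array `[subject, epoch, sample]`.
#' @export
unstack_rows <- function(mat, row_index) {
  n_s <- max(row_index$subject); n_e <- max(row_index$epoch)
  out <- array(0, dim = c(n_s, n_e, ncol(mat)))
  for (r in seq_len(nrow(row_index)))
    out[row_index$subject[r], row_index$epoch[r], ] <- mat[r, ]
  out
}

#' Decompose a stacked cohort, one NA-MEMD per channel
#'
#' Channels may yield slightly different mode counts; the leading
#' `min(mode counts)` modes of each channel are retained so every channel
#' carries the same aligned mode set.
#'
#' @param stacked output of [stack_cohort_per_channel()].
#' @param cfg a [sift_config()]; the noise seed is varied per channel.
#' @return an object of class `cohort_imfs`: per-channel decompositions plus
#'   the row index and pooled frequency summary.
#' @export
decompose_cohort <- function(stacked, cfg = sift_config()) {
  decs <- lapply(seq_along(stacked$channels), function(ci) {
    cfg_ci <- cfg
    cfg_ci$seed <- derive_seed(cfg$seed, ci, salt = 3L)
    na_memd(stacked$channels[[ci]], cfg_ci)
  })
  names(decs) <- names(stacked$channels)
  n_common <- min(vapply(decs, `[[`, 0L, "n_modes"))
  if (n_common < 1) stop("a channel produced no modes")
  for (ci in seq_along(decs)) {
    decs[[ci]]$modes <- decs[[ci]]$modes[seq_len(n_common), , , drop = FALSE]
    decs[[ci]]$n_modes <- n_common
  }
  fsum <- characterize_imf_frequencies(decs[[1]], stacked$fs)
  for (ci in seq_along(decs)[-1])
    fsum[, -1] <- fsum[, -1] + characterize_imf_frequencies(decs[[ci]], stacked$fs)[, -1]
  fsum[, -1] <- fsum[, -1] / length(decs)
  structure(list(channels = decs, row_index = stacked$row_index,
                 fs = stacked$fs, n_subjects = stacked$n_subjects,
                 n_epochs = stacked$n_epochs, frequency_summary = fsum),
            class = "cohort_imfs")
}

#' @export
print.cohort_imfs <- function(x, ...) {
  cat(sprintf("<cohort_imfs> %d channels, %d aligned modes, %d subjects x %d epochs\n",
              length(x$channels), x$channels[[1]]$n_modes, x$n_subjects,
              x$n_epochs))
  print(x$frequency_summary)
  invisible(x)
}

#' Restrict a cohort decomposition to selected modes
#'
#' Selection is computed once from the pooled frequency summary and applied
#' identically to every channel.
#'
#' @inheritParams select_analysis_imfs
#' @param cimfs a `cohort_imfs` object.
#' @export
select_cohort_imfs <- function(cimfs, rule = c("default", "band"),
                               drop_head = 3, drop_tail = 1, band = NULL) {
  rule <- match.arg(rule)
  n_modes <- cimfs$channels[[1]]$n_modes
  if (rule == "default") {
    if (n_modes < drop_head + drop_tail + 1)
      stop("too few modes: have ", n_modes, ", need at least ",
           drop_head + drop_tail + 1)
    idx <- (drop_head + 1):(n_modes - drop_tail)
  } else {
    fsum <- cimfs$frequency_summary
    idx <- fsum$mode[fsum$mean_hz >= band[1] & fsum$mean_hz <= band[2]]
    if (!length(idx)) stop("no mode has its spectral centroid in the band")
  }
  for (ci in seq_along(cimfs$channels)) {
    cimfs$channels[[ci]]$modes <-
      cimfs$channels[[ci]]$modes[idx, , , drop = FALSE]
    cimfs$channels[[ci]]$n_modes <- length(idx)
  }
  cimfs$frequency_summary <- cimfs$frequency_summary[idx, , drop = FALSE]
  cimfs$selected_modes <- idx
  cimfs
}

#' Per-subject array of one mode across channels
#'
#' @param cimfs a `cohort_imfs`.
#' @param subject subject index.
#' @param mode mode index (within the retained modes).
#' @return array `[channel, epoch, sample]`.
#' @export
subject_mode_array <- function(cimfs, subject, mode) {
  rows <- cimfs$row_index$row[cimfs$row_index$subject == subject]
  n_t <- dim(cimfs$channels[[1]]$modes)[3]
  out <- array(0, dim = c(length(cimfs$channels), length(rows), n_t))
  for (ci in seq_along(cimfs$channels))
    out[ci, , ] <- cimfs$channels[[ci]]$modes[mode, rows, ]
  dimnames(out) <- list(names(cimfs$channels), NULL, NULL)
  out
}
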