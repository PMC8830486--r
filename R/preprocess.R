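#' Preprocessing configuration
#'
#' @param flat_tolerance channel-SD floor in microvolts below which a channel
#'   counts as flat.
#' @param noise_sd_multiplier robust z-score threshold on channel SDs above
#'   which a channel counts as noise-contaminated.
#' @param epoch_length epoch length in seconds.
#' @param amplitude_threshold peak-amplitude rejection threshold in
#'   microvolts; epochs strictly above it are dropped (an epoch peaking at
#'   exactly the threshold is retained).
#' @param n_keep_epochs number of leading clean epochs retained per subject.
#' @param ica_enabled run the ICA reconstruction stage.
#' @param ica_artifact_rule `NULL` (pass-through: no component removed) or a
#'   function `(mixing, channel_labels) -> integer indices` of components to
#'   zero; see [topography_rule()].
#' @param bandpass band (Hz) of the zero-phase filter applied before
#'   bad-channel detection, or `NULL` to skip.
#' @param ica_seed seed for the ICA random initialisation.
#' @export
preprocess_config <- function(flat_tolerance = 0.1, noise_sd_multiplier = 3,
                              epoch_length = 2, amplitude_threshold = 55,
                              n_keep_epochs = 30, ica_enabled = TRUE,
                              ica_artifact_rule = NULL,
                              bandpass = c(0.5, 45), ica_seed = 1L) {
  stopifnot(epoch_length > 0, amplitude_threshold > 0, n_keep_epochs >= 1)
  structure(list(flat_tolerance = flat_tolerance,
                 noise_sd_multiplier = noise_sd_multiplier,
                 epoch_length = epoch_length,
                 amplitude_threshold = amplitude_threshold,
                 n_keep_epochs = n_keep_epochs, ica_enabled = ica_enabled,
                 ica_artifact_rule = ica_artifact_rule, bandpass = bandpass,
                 ica_seed = as.integer(ica_seed)),
            class = "preprocess_config")
}

#' Construct a clean-epochs container
#'
#' Holds a subject's retained epochs as a `channels x epochs x samples`
#' array together with the channel labels, sampling rate, removed-channel
#' list and the per-epoch rejection log.
#'
#' @param subject_id identifier used in tables and diagnostics.
#' @param channels channel labels (post-removal).
#' @param epochs numeric array `[channel, epoch, sample]`, microvolts.
#' @param fs sampling rate in Hz.
#' @param removed_channels labels dropped by bad-channel detection.
#' @param rejection_log data.frame of per-epoch keep/drop decisions.
#' @export
clean_epochs <- function(subject_id, channels, epochs, fs,
                         removed_channels = character(),
                         rejection_log = NULL) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[1] == length(channels))
  structure(list(subject_id = subject_id, channels = channels,
                 epochs = epochs, fs = fs,
                 removed_channels = removed_channels,
                 rejection_log = rejection_log), class = "clean_epochs")
}

#' @export
print.clean_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<clean_epochs> %s: %d channels x %d epochs x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  if (length(x$removed_channels))
    cat("  removed channels:", paste(x$removed_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Detect flat and noise-contaminated channels
#'
#' Flags channels whose SD falls below `flat_tolerance` (flat) or whose SD
#' exceeds the cross-channel median by more than `noise_sd_multiplier`
#' robust z-units (MAD-scaled; the MAD is floored at 10% of the median SD
#' so that a homogeneous montage cannot produce spurious flags from a
#' near-zero scale estimate).  SDs are computed on the band-passed signal
#' when the config requests filtering.
#'
#' @param recording an [eeg_recording()].
#' @param cfg a [preprocess_config()].
#' @return character vector of bad-channel labels, in input order.
#' @export
detect_bad_channels <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2) stop("need at least 2 channels")
  x <- recording$data
  if (!is.null(cfg$bandpass))
    x <- fft_bandpass(x, recording$sampling_rate, cfg$bandpass)
  sds <- apply(x, 1, sd)
  flat <- sds < cfg$flat_tolerance
  med <- median(sds)
  madv <- max(mad(sds), 0.1 * med)
  noisy <- if (madv > 0) (sds - med) / madv > cfg$noise_sd_multiplier
           else rep(FALSE, length(sds))
  bad <- flat | noisy
  if (all(bad)) stop("no usable channels: all ", length(bad), " flagged bad")
  recording$channels[bad]
}

#' Drop channels from a recording
#' @param recording an [eeg_recording()].
#' @param labels channels to remove.
#' @export
remove_channels <- function(recording, labels) {
  keep <- !(recording$channels %in% canonical_labels(labels))
  if (!any(keep)) stop("no usable channels: all channels removed")
  out <- eeg_recording(recording$data[keep, , drop = FALSE],
                       recording$channels[keep], recording$sampling_rate,
                       recording$subject_id)
  out$removed_channels <- recording$channels[!keep]
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous cross-channel mean from every sample, so the
#' cross-channel mean of the output is zero everywhere.  Idempotent; defined
#' for two or more channels.
#'
#' @param x an [eeg_recording()], a `clean_epochs` object, or a channels x
#'   samples matrix.
#' @return the same type, re-referenced.
#' @export
rereference_car <- function(x) {
  car_mat <- function(m) {
    if (nrow(m) < 2) stop("CAR undefined for a single channel")
    sweep(m, 2, colMeans(m))
  }
  if (inherits(x, "eeg_recording")) {
    x$data <- car_mat(x$data); x
  } else if (inherits(x, "clean_epochs")) {
    if (dim(x$epochs)[1] < 2) stop("CAR undefined for a single channel")
    for (e in seq_len(dim(x$epochs)[2]))
      x$epochs[, e, ] <- car_mat(x$epochs[, e, , drop = TRUE])
    x
  } else car_mat(x)
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping contiguous windows of `epoch_length` seconds; a trailing
#' partial window is discarded.
#'
#' @inheritParams detect_bad_channels
#' @return a `clean_epochs` object.
#' @export
segment_epochs <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  len <- as.integer(round(cfg$epoch_length * recording$sampling_rate))
  n <- ncol(recording$data)
  n_ep <- n %/% len
  if (n_ep < 1)
    stop("recording shorter than one epoch (", n, " < ", len, " samples)")
  ep <- array(0, dim = c(nrow(recording$data), n_ep, len))
  for (e in seq_len(n_ep))
    ep[, e, ] <- recording$data[, ((e - 1) * len + 1):(e * len)]
  clean_epochs(recording$subject_id, recording$channels, ep,
               recording$sampling_rate,
               removed_channels = recording$removed_channels %||% character())
}

#' Reject epochs by peak amplitude
#'
#' Drops every epoch whose maximum absolute value across all channels
#' strictly exceeds the threshold; the rejection log records peak and
#' decision per epoch.
#'
#' @param epochs a `clean_epochs` object.
#' @param cfg a [preprocess_config()].
#' @export
reject_epochs_by_amplitude <- function(epochs, cfg = preprocess_config()) {
  stopifnot(inherits(epochs, "clean_epochs"), cfg$amplitude_threshold > 0)
  peaks <- apply(abs(epochs$epochs), 2, max)
  keep <- peaks <= cfg$amplitude_threshold
  log <- data.frame(epoch = seq_along(peaks), peak_uv = peaks, kept = keep,
                    reason = ifelse(keep, "",
                                    sprintf("peak %.1f uV > %.1f uV", peaks,
                                            cfg$amplitude_threshold)))
  if (!any(keep))
    stop("all ", length(keep), " epochs exceed the ",
         cfg$amplitude_threshold, " uV threshold for subject ",
         epochs$subject_id)
  epochs$epochs <- epochs$epochs[, keep, , drop = FALSE]
  epochs$rejection_log <- log
  epochs
}

# --- FastICA (symmetric fixed-point, tanh nonlinearity) -------------------

fast_ica <- function(x, seed = 1L, max_iter = 200, tol = 1e-8) {
  nc <- nrow(x)
  means <- rowMeans(x)
  xc <- x - means
  cv <- xc %*% t(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop("rank-deficient data: ICA needs full channel rank; ",
         "remove linearly dependent channels first")
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  z <- K %*% xc
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(nc * nc), nc)))
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W_new <- g %*% t(z) / ncol(z) - diag(rowMeans(gp)) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  unmixing <- W %*% K                    # u = unmixing %*% centered data
  mixing <- tryCatch(solve(unmixing),
                     error = function(e) stop("non-invertible unmixing matrix"))
  list(unmixing = unmixing, mixing = mixing, means = means,
       components = unmixing %*% xc)
}

#' Artifact rule: template-topography correlation
#'
#' Builds a pluggable classifier flagging independent components whose
#' scalp topography (mixing-matrix column) correlates with a spatial
#' template above `threshold` in absolute value.  The default template
#' weights frontal electrodes, targeting ocular components.
#'
#' @param template named numeric vector over channels, or `NULL` for the
#'   frontal-weighted default.
#' @param threshold absolute correlation cut-off.
#' @return a function `(mixing, channel_labels) -> integer component indices`.
#' @export
topography_rule <- function(template = NULL, threshold = 0.8) {
  force(template); force(threshold)
  function(mixing, channel_labels) {
    tpl <- template
    if (is.null(tpl)) {
      tpl <- as.numeric(grepl("^(FP|F)", channel_labels)) + 0.1
    } else if (!is.null(names(tpl))) {
      tpl <- tpl[channel_labels]
    }
    which(abs(apply(mixing, 2, function(col) cor(col, tpl))) > threshold)
  }
}

#' ICA decomposition and artifact-free reconstruction
#'
#' Estimates an unmixing matrix W on the concatenated epochs (u = W x), zeroes
#' the component activations flagged by the artifact rule, and reconstructs
#' x' = W^-1 u'.  With no component flagged the reconstruction equals the
#' input to numerical precision.  As many components are estimated as there
#' are channels.
#'
#' @inheritParams reject_epochs_by_amplitude
#' @return the `clean_epochs` object with reconstructed data; attribute
#'   `ica_flagged` lists removed component indices.
#' @export
ica_decompose_reconstruct <- function(epochs, cfg = preprocess_config()) {
  stopifnot(inherits(epochs, "clean_epochs"))
  if (!isTRUE(cfg$ica_enabled)) return(epochs)
  d <- dim(epochs$epochs)
  # concatenate epochs in time: channels x (samples * epochs)
  x <- matrix(aperm(epochs$epochs, c(1, 3, 2)), nrow = d[1])
  fit <- fast_ica(x, seed = cfg$ica_seed)
  flagged <- integer()
  if (!is.null(cfg$ica_artifact_rule))
    flagged <- cfg$ica_artifact_rule(fit$mixing, epochs$channels)
  u <- fit$components
  if (length(flagged)) u[flagged, ] <- 0
  xr <- fit$mixing %*% u + fit$means
  epochs$epochs <- aperm(array(xr, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  attr(epochs, "ica_flagged") <- flagged
  attr(epochs, "ica_n_components") <- nrow(u)
  epochs
}

#' Truncate every subject to a common leading epoch count
#'
#' Keeps the first `n_keep_epochs` retained epochs in temporal order.
#'
#' @inheritParams reject_epochs_by_amplitude
#' @export
truncate_to_common_epochs <- function(epochs, cfg = preprocess_config()) {
  stopifnot(inherits(epochs, "clean_epochs"))
  n_ep <- dim(epochs$epochs)[2]
  if (n_ep < cfg$n_keep_epochs)
    stop("subject ", epochs$subject_id, " has only ", n_ep,
         " clean epochs; ", cfg$n_keep_epochs, " required")
  epochs$epochs <- epochs$epochs[, seq_len(cfg$n_keep_epochs), , drop = FALSE]
  epochs
}

#' Full preprocessing chain for one recording
#'
#' Band-pass filter, bad-channel removal, common average reference, epoch
#' segmentation, peak-amplitude rejection, ICA reconstruction, truncation to
#' the common epoch count.
#'
#' @inheritParams detect_bad_channels
#' @return a `clean_epochs` object.
#' @export
preprocess_recording <- function(recording, cfg = preprocess_config()) {
  rec <- recording
  if (!is.null(cfg$bandpass)) {
    rec$data <- fft_bandpass(rec$data, rec$sampling_rate, cfg$bandpass)
  }
  bad <- detect_bad_channels(rec, preprocess_config_nofilter(cfg))
  if (length(bad)) rec <- remove_channels(rec, bad)
  rec <- rereference_car(rec)
  ep <- segment_epochs(rec, cfg)
  ep <- reject_epochs_by_amplitude(ep, cfg)
  ep <- ica_decompose_reconstruct(ep, cfg)
  ep <- truncate_to_common_epochs(ep, cfg)
  ep$removed_channels <- bad
  ep
}

# cfg clone with filtering off (data already filtered upstream)
preprocess_config_nofilter <- function(cfg) {
  cfg$bandpass <- NULL
  cfg
}
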