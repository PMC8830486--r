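# Shared fixture builders.  Everything is generated in code at test time.

# 19-channel montage with the seven bad channels planted (three flat, four
# high-variance), the rest carrying comparable oscillatory content.
bad_channel_spec <- function(seed = 7L) {
  labels <- c("C3", "C4", "CZ", "F3", "F4", "F7", "F8", "FZ", "FP1", "FP2",
              "O1", "O2", "P3", "P4", "PZ", "T3", "T4", "T5", "T6")
  cohort_spec(
    n_subjects = 2, sampling_rate = 128, duration = 8,
    channel_labels = labels,
    oscillation_specs = list(list(freq = 10, amplitude = 10,
                                  channels = labels)),
    artifact_spec = list(flat_channels = c("C4", "CZ", "F4"),
                         noisy_channels = c("F8", "FP1", "FP2", "PZ"),
                         noisy_factor = 25),
    noise_sd = 2, seed = seed)
}

# Hand-built cohort decomposition: one mode per channel filled from a
# generator function(subject, channel, epoch) -> numeric series.
fake_cimfs <- function(n_subjects, channels, n_epochs, n_samples, fs,
                       gen, n_modes = 1) {
  row_index <- data.frame(row = seq_len(n_subjects * n_epochs),
                          subject = rep(seq_len(n_subjects), each = n_epochs),
                          epoch = rep(seq_len(n_epochs), times = n_subjects))
  chans <- lapply(seq_along(channels), function(ci) {
    modes <- array(0, dim = c(n_modes, nrow(row_index), n_samples))
    for (r in seq_len(nrow(row_index)))
      for (m in seq_len(n_modes))
        modes[m, r, ] <- gen(row_index$subject[r], ci, row_index$epoch[r], m)
    structure(list(modes = modes,
                   residue = matrix(0, nrow(row_index), n_samples),
                   n_modes = n_modes, config = NULL),
              class = "imf_decomposition")
  })
  names(chans) <- channels
  structure(list(channels = chans, row_index = row_index, fs = fs,
                 n_subjects = n_subjects, n_epochs = n_epochs),
            class = "cohort_imfs")
}

# Epoch-averaged WPLI of a planted coupled pair, computed through the
# package path: band-pass, segment, WPLI over epochs.
coupled_wpli <- function(strength, lag = pi / 2, seed = 1L, band = c(8, 12),
                        duration = 16, fs = 128) {
  spec <- cohort_spec(n_subjects = 2, sampling_rate = fs, duration = duration,
                      channel_labels = c("O1", "O2"), noise_sd = 0.5,
                      seed = seed)
  spec <- plant_coupled_pair(spec, c("O1", "O2"), lag = lag,
                             strength = strength, band = band, amplitude = 10)
  rec <- generate_recording(spec, 1)
  # broadband epochs: the planted band component dominates the imaginary
  # cross-spectrum, and the zero-strength null stays low
  ep <- segment_epochs(rec, preprocess_config(epoch_length = 2))
  wpli_matrix(ep$epochs, ep$channels)$values["O1", "O2"]
}

# Exhaustive double-loop sample-entropy oracle (Chebyshev distance,
# self-matches excluded).
sampen_oracle <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1))
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  if (A == 0 || B == 0) log((N - m - 1) * (N - m)) else -log(A / B)
}

# Ordinal-pattern-count permutation-entropy oracle (stable ties).
pen_oracle <- function(x, n, L, normalizer = "factorial") {
  n_win <- length(x) - (n - 1) * L
  pats <- vapply(seq_len(n_win), function(i)
    paste(order(x[i + (0:(n - 1)) * L]), collapse = ""), "")
  p <- as.numeric(table(pats)) / n_win
  -sum(p * log(p)) / if (normalizer == "factorial") log(factorial(n)) else log(n)
}

# Floyd-Warshall all-pairs shortest paths.
floyd_warshall <- function(L) {
  n <- nrow(L); D <- L
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  D
}

# Exhaustive weighted-transitivity oracle: cube-root triangle intensity
# over connected triples.
transitivity_oracle <- function(W) {
  n <- nrow(W); tri <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(n))
        if (i != j && j != k && i != k)
          tri <- tri + (W[i, j] * W[i, k] * W[j, k])^(1 / 3)
  deg <- rowSums(W > 0)
  denom <- sum(deg * (deg - 1))
  if (denom == 0) 0 else tri / denom
}

random_weight_graph <- function(n, density = 0.7) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- runif(length(up)) < density
  W[up[on]] <- runif(sum(on), 0.05, 1)
  W <- W + t(W)
  diag(W) <- 0
  W
}
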