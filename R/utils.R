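`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-unit seed stream: keeps every derived seed a valid
# 32-bit integer whatever base seed the caller supplies.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((abs(as.double(seed)) * 1000003 + as.double(index) * 7919 +
                as.double(salt) * 104729) %% 2147483629) + 1L
}

#' Zero-phase band-pass filter
#'
#' Filters each row of a channels-by-samples matrix (or a single numeric
#' vector) to the frequency band `band` by zeroing out-of-band Fourier
#' coefficients.  The operation is exactly zero-phase and numerically stable
#' at arbitrarily low normalized cut-offs, which matters for the 0.5 Hz edge
#' of clinical EEG sampled at 512-1000 Hz.
#'
#' @param x numeric vector or matrix (channels x samples), in microvolts.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz (inclusive).
#' @return filtered object of the same shape.
#' @export
fft_bandpass <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1],
            band[2] <= fs / 2)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(m)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # fold negative frequencies
  keep <- freqs >= band[1] & freqs <= band[2]
  out <- t(apply(m, 1, function(row) {
    X <- fft(row)
    X[!keep] <- 0 + 0i
    Re(fft(X, inverse = TRUE)) / n
  }))
  if (vec) drop(out) else out
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Returns the complex series whose real part is the input and whose
#' imaginary part is its harmonic conjugate; the argument of the result is
#' the instantaneous phase.
#'
#' @param x real numeric vector, length >= 8.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 8, all(is.finite(x)))
  if (stats::var(x) == 0) {
    warning("constant series: zero-amplitude analytic signal, phases set to 0")
    return(complex(real = x, imaginary = rep(0, n)))
  }
  X <- fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

known_1020_labels <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "FZ", "C3", "C4", "CZ",
    "P3", "P4", "PZ", "O1", "O2", "T3", "T4", "T5", "T6",
    "A1", "A2", "FPZ", "OZ")
}

canonical_labels <- function(labels) toupper(trimws(labels))

first_primes <- function(k) {
  # simple sieve; enough primes for Hammersley bases in high dimension
  limit <- max(30L, as.integer(k * (log(k + 2) + log(log(k + 3))) * 1.3) + 10L)
  repeat {
    is_p <- rep(TRUE, limit); is_p[1] <- FALSE
    for (i in 2:floor(sqrt(limit))) if (is_p[i])
      is_p[seq(i * i, limit, by = i)] <- FALSE
    p <- which(is_p)
    if (length(p) >= k) return(p[seq_len(k)])
    limit <- limit * 2L
  }
}
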