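#' Entropy configuration
#'
#' Parameters of the three complexity measures.  The sample-entropy
#' tolerance is expressed as a fraction of the epoch SD (recommended range
#' 0.1-0.25); the permutation-entropy normalizer defaults to `ln(n!)` (the
#' maximum ordinal entropy, keeping values in `[0, 1]`), with the plain
#' `ln(n)` denominator available as an option — downstream correlations are
#' invariant to this constant.
#'
#' @param sampen_m embedding dimension (2 or 3 recommended).
#' @param sampen_r_frac tolerance as a fraction of the epoch SD.
#' @param sampen_delay template subsampling delay (default 1).
#' @param pen_order ordinal pattern order n (>= 2).
#' @param pen_delay ordinal pattern delay L.
#' @param spen_band spectral-entropy band in Hz.
#' @param pen_normalizer `"factorial"` (`ln(n!)`) or `"order"` (`ln(n)`).
#' @export
entropy_config <- function(sampen_m = 3, sampen_r_frac = 0.2,
                           sampen_delay = 1, pen_order = 3, pen_delay = 1,
                           spen_band = c(0.5, 45),
                           pen_normalizer = c("factorial", "order")) {
  stopifnot(sampen_m >= 1, sampen_r_frac > 0, pen_order >= 2, pen_delay >= 1)
  structure(list(sampen_m = as.integer(sampen_m),
                 sampen_r_frac = sampen_r_frac,
                 sampen_delay = as.integer(sampen_delay),
                 pen_order = as.integer(pen_order),
                 pen_delay = as.integer(pen_delay), spen_band = spen_band,
                 pen_normalizer = match.arg(pen_normalizer)),
            class = "entropy_config")
}

#' Sample entropy
#'
#' `-ln(A/B)` where B counts template pairs of length `m` and A the pairs
#' still matching at length `m + 1`, Chebyshev distance, tolerance `r_abs`,
#' self-matches excluded.  When A or B is zero the conditional probability
#' is undefined and the upper-bound value `ln((N - m - 1)(N - m))` is
#' returned with attribute `capped = TRUE`.
#'
#' @param x numeric series of length N > m + 1.
#' @param m embedding dimension.
#' @param r_abs absolute tolerance (same units as `x`).
#' @param delay template subsampling delay.
#' @return sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 3, r_abs, delay = 1) {
  N <- length(x)
  if (N <= m + 1) stop("series too short: need length > m + 1")
  if (r_abs < 0) stop("tolerance must be >= 0")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_abs,
                           as.integer(delay))
  if (cnt$A == 0 || cnt$B == 0) {
    out <- log((N - m - 1) * (N - m))
    attr(out, "capped") <- TRUE
    return(out)
  }
  -log(cnt$A / cnt$B)
}

#' Permutation entropy
#'
#' Normalized Shannon entropy of the ordinal patterns of windows of `n`
#' values at delay `L`; ties broken by temporal order of occurrence.
#' Smaller values mean a more regular series.
#'
#' @param x numeric series of length >= (n - 1) L + 1.
#' @param n ordinal pattern order.
#' @param L delay in samples.
#' @param normalizer `"factorial"` for `ln(n!)`, `"order"` for `ln(n)`.
#' @return normalized permutation entropy (dimensionless).
#' @export
permutation_entropy <- function(x, n = 3, L = 1,
                                normalizer = c("factorial", "order")) {
  normalizer <- match.arg(normalizer)
  N <- length(x)
  n_win <- N - (n - 1) * L
  if (n_win < 1) stop("series too short for order ", n, " at delay ", L)
  # Lehmer encoding of each window's ordinal pattern, vectorized over
  # windows; ties resolve by temporal order (a later equal value does not
  # count as smaller), matching stable order().
  E <- vapply(0:(n - 1), function(k) x[seq_len(n_win) + k * L],
              numeric(n_win))
  code <- numeric(n_win)
  for (i in seq_len(n - 1)) {
    d_i <- rowSums(E[, (i + 1):n, drop = FALSE] < E[, i])
    code <- code + d_i * factorial(n - i)
  }
  p <- as.numeric(table(code)) / n_win
  H <- -sum(p * log(p))
  H / if (normalizer == "factorial") log(factorial(n)) else log(n)
}

#' Spectral entropy
#'
#' Shannon entropy (nats) of the periodogram normalized to a probability
#' distribution over the frequency bins inside `band`.  High values mean a
#' flat spectrum; a single-tone series scores near zero.
#'
#' @param x numeric series of length >= 16.
#' @param fs sampling rate in Hz.
#' @param band analysis band in Hz, inside (0, fs/2).
#' @return spectral entropy in nats.
#' @export
spectral_entropy <- function(x, fs, band = c(0.5, 45)) {
  N <- length(x)
  stopifnot(N >= 16, band[1] >= 0, band[2] > band[1], band[2] <= fs / 2)
  nf <- N %/% 2
  P <- Mod(fft(x))[2:(nf + 1)]^2
  freqs <- seq_len(nf) * fs / N
  inband <- freqs >= band[1] & freqs <= band[2]
  if (!any(inband) || sum(P[inband]) <= 1e-12 * sum(P))
    stop("zero in-band power: spectral entropy undefined")
  p <- P[inband] / sum(P[inband])
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Epoch-averaged entropy feature table for a decomposed cohort
#'
#' Per subject, channel, retained mode and epoch: sample, permutation and
#' spectral entropy; epoch values are arithmetically averaged into one value
#' per (subject, channel, mode, measure).  A cohort with 12 channels and
#' one retained mode yields 36 feature columns after widening.
#'
#' @param cimfs a `cohort_imfs`.
#' @param cfg an [entropy_config()].
#' @param combine_modes sum the retained modes into one band-limited
#'   component per channel before computing entropies (useful when a band
#'   selection returns several modes of one canonical band).
#' @return long data.frame `subject`, `channel`, `imf`, `sampen`, `pen`,
#'   `spen`, with the config attached as attribute `config`.
#' @export
entropy_feature_table <- function(cimfs, cfg = entropy_config(),
                                  combine_modes = FALSE) {
  n_modes <- if (combine_modes) 1L else cimfs$channels[[1]]$n_modes
  labels <- names(cimfs$channels)
  rows <- list()
  for (s in seq_len(cimfs$n_subjects)) {
    ridx <- cimfs$row_index$row[cimfs$row_index$subject == s]
    for (ci in seq_along(labels))
      for (m in seq_len(n_modes)) {
        vals <- vapply(ridx, function(r) {
          x <- if (combine_modes)
            colSums(matrix(cimfs$channels[[ci]]$modes[, r, ],
                           ncol = dim(cimfs$channels[[ci]]$modes)[3]))
          else cimfs$channels[[ci]]$modes[m, r, ]
          r_abs <- cfg$sampen_r_frac * sd(x)
          c(sampen = as.numeric(sample_entropy(x, cfg$sampen_m, r_abs,
                                               cfg$sampen_delay)),
            pen = permutation_entropy(x, cfg$pen_order, cfg$pen_delay,
                                      cfg$pen_normalizer),
            spen = spectral_entropy(x, cimfs$fs,
                                    c(cfg$spen_band[1],
                                      min(cfg$spen_band[2], cimfs$fs / 2))))
        }, numeric(3))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, channel = labels[ci], imf = m,
          sampen = mean(vals["sampen", ]), pen = mean(vals["pen", ]),
          spen = mean(vals["spen", ]))
      }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  out
}

#' Widen a feature table into a subjects x features matrix
#'
#' @param table long entropy table (from [entropy_feature_table()]) or graph
#'   table (from [graph_feature_table()]).
#' @return numeric matrix, one row per subject, columns named
#'   `measure_channel_imf` (entropies) or `metric_imf` (graph metrics).
#' @export
feature_matrix <- function(table) {
  subjects <- sort(unique(table$subject))
  if ("channel" %in% names(table)) {
    measures <- c("sampen", "pen", "spen")
    cols <- expand.grid(measure = measures,
                        channel = unique(table$channel),
                        imf = sort(unique(table$imf)),
                        stringsAsFactors = FALSE)
    out <- matrix(NA_real_, length(subjects), nrow(cols),
                  dimnames = list(subjects, paste(cols$measure, cols$channel,
                                                  cols$imf, sep = "_")))
    for (k in seq_len(nrow(cols))) {
      sel <- table$channel == cols$channel[k] & table$imf == cols$imf[k]
      out[, k] <- table[[cols$measure[k]]][sel][order(table$subject[sel])]
    }
  } else {
    metrics <- setdiff(names(table), c("subject", "imf"))
    cols <- expand.grid(metric = metrics, imf = sort(unique(table$imf)),
                        stringsAsFactors = FALSE)
    out <- matrix(NA_real_, length(subjects), nrow(cols),
                  dimnames = list(subjects,
                                  paste(cols$metric, cols$imf, sep = "_")))
    for (k in seq_len(nrow(cols))) {
      sel <- table$imf == cols$imf[k]
      out[, k] <- table[[cols$metric[k]]][sel][order(table$subject[sel])]
    }
  }
  out
}
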