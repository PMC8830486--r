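#' Weighted phase-lag index of two analytic signals
#'
#' Computes `|mean(|Im X| sign(Im X))| / mean(|Im X|)` with
#' `X = z1 * Conj(z2)` per sample, the expectation running over all samples
#' supplied (one epoch).  Returns 0 when the cross-spectrum is identically
#' real (the zero-lag / volume-conduction null).
#'
#' @param z1,z2 complex vectors of equal length.
#' @return WPLI in `[0, 1]`.
#' @export
wpli_pair <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("shape mismatch between z1 and z2")
  imx <- Im(z1 * Conj(z2))
  denom <- mean(abs(imx))
  if (denom == 0) return(0)
  min(abs(mean(abs(imx) * sign(imx))) / denom, 1)
}

#' Epoch-averaged WPLI connectivity matrix
#'
#' Per epoch: analytic signal of every channel's mode series, edge taper
#' (the first and last `taper` fraction of samples dropped to suppress
#' transform edge artifacts), pairwise WPLI; matrices are then averaged
#' arithmetically over epochs.  Symmetric with zero diagonal, entries in
#' `[0, 1]`.
#'
#' @param mode_array array `[channel, epoch, sample]` of one mode.
#' @param channel_labels channel names.
#' @param imf_index mode identifier carried in the result.
#' @param taper edge fraction dropped per side (default 0.05).
#' @return object of class `wpli_matrix`.
#' @export
wpli_matrix <- function(mode_array, channel_labels = NULL, imf_index = NA,
                        taper = 0.05) {
  d <- dim(mode_array)
  if (is.null(d) || length(d) != 3) stop("mode_array must be [channel, epoch, sample]")
  if (d[1] < 2) stop("need at least 2 channels")
  labels <- channel_labels %||% dimnames(mode_array)[[1]] %||%
    paste0("ch", seq_len(d[1]))
  n_t <- d[3]
  edge <- floor(taper * n_t)
  keep <- (edge + 1):(n_t - edge)
  acc <- matrix(0, d[1], d[1])
  for (e in seq_len(d[2])) {
    z <- vapply(seq_len(d[1]), function(ci) {
      x <- mode_array[ci, e, ]
      if (var(x) == 0) complex(real = rep(0, length(keep)))
      else analytic_signal(x)[keep]
    }, complex(length(keep)))
    for (i in seq_len(d[1] - 1))
      for (j in (i + 1):d[1]) {
        w <- wpli_pair(z[, i], z[, j])
        acc[i, j] <- acc[i, j] + w
        acc[j, i] <- acc[j, i] + w
      }
  }
  vals <- acc / d[2]
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, channel_labels = labels,
                 imf_index = imf_index, n_epochs_averaged = d[2]),
            class = "wpli_matrix")
}

#' @export
print.wpli_matrix <- function(x, ...) {
  cat(sprintf("<wpli_matrix> imf %s, %d channels, %d epochs averaged\n",
              as.character(x$imf_index), length(x$channel_labels),
              x$n_epochs_averaged))
  print(round(x$values, 3))
  invisible(x)
}

#' Convert connection weights to path lengths
#'
#' Length = 1 / weight; zero weight maps to an infinite (unreachable)
#' length; the diagonal stays 0.
#'
#' @param W `wpli_matrix` or numeric weight matrix with entries in `[0, 1]`.
#' @export
weights_to_lengths <- function(W) {
  w <- if (inherits(W, "wpli_matrix")) W$values else W
  if (any(w < 0)) stop("negative weight")
  L <- 1 / w
  L[w == 0] <- Inf
  diag(L) <- 0
  L
}

#' Shortest-path graph metrics
#'
#' All-pairs shortest paths over a length matrix (igraph, Dijkstra):
#' characteristic path length (mean finite off-diagonal distance), global
#' efficiency (mean reciprocal distance, unreachable pairs contributing 0),
#' and eccentricity-based radius and diameter.  A disconnected graph yields
#' infinite radius/diameter and a warning for the path length.
#'
#' @param lengths square non-negative matrix with zero diagonal (Inf =
#'   no edge).
#' @return list with `characteristic_path_length`, `global_efficiency`,
#'   `radius`, `diameter`.
#' @export
shortest_path_metrics <- function(lengths) {
  n <- nrow(lengths)
  stopifnot(n == ncol(lengths), all(diag(lengths) == 0),
            all(lengths >= 0))
  idx <- which(upper.tri(lengths) & is.finite(lengths), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(idx))
    g <- igraph::add_edges(g, t(idx), weight = lengths[idx])
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off)))
    warning("disconnected graph: path length computed on finite entries")
  cpl <- mean(off[is.finite(off)])
  eff <- mean(ifelse(is.finite(off), 1 / off, 0))
  ecc <- apply(D, 1, max)
  list(characteristic_path_length = cpl, global_efficiency = eff,
       radius = min(ecc), diameter = max(ecc))
}

#' Weighted transitivity
#'
#' Ratio of the total weighted-triangle intensity (cube-root geometric-mean
#' weights) to the total number of connected triples: the weighted global
#' clustering of the connectivity-toolbox convention.  Graphs without
#' connected triples return 0.
#'
#' @param W symmetric weight matrix, entries in `[0, 1]`, zero diagonal.
#' @export
transitivity_weighted <- function(W) {
  w <- if (inherits(W, "wpli_matrix")) W$values else W
  stopifnot(isTRUE(all.equal(w, t(w))), all(w >= 0), all(diag(w) == 0))
  w3 <- w^(1 / 3)
  tri <- sum(diag(w3 %*% w3 %*% w3))
  k <- rowSums(w > 0)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  tri / denom
}

#' All five global graph metrics of one connectivity matrix
#'
#' @param W `wpli_matrix` or numeric weight matrix.
#' @return one-row data.frame: transitivity, global_efficiency, radius,
#'   diameter, characteristic_path_length.
#' @export
graph_metric_set <- function(W) {
  w <- if (inherits(W, "wpli_matrix")) W$values else W
  sp <- shortest_path_metrics(weights_to_lengths(w))
  data.frame(transitivity = transitivity_weighted(w),
             global_efficiency = sp$global_efficiency,
             radius = sp$radius, diameter = sp$diameter,
             characteristic_path_length = sp$characteristic_path_length)
}

#' Graph-metric feature table for a decomposed cohort
#'
#' For every subject and retained mode: epoch-averaged WPLI matrix, then the
#' five global graph metrics.
#'
#' @param cimfs a `cohort_imfs`.
#' @param taper edge fraction passed to [wpli_matrix()].
#' @return data.frame with columns `subject`, `imf` and the five metrics.
#' @export
graph_feature_table <- function(cimfs, taper = 0.05) {
  n_modes <- cimfs$channels[[1]]$n_modes
  rows <- list()
  for (s in seq_len(cimfs$n_subjects))
    for (m in seq_len(n_modes)) {
      wm <- wpli_matrix(subject_mode_array(cimfs, s, m),
                        names(cimfs$channels), imf_index = m, taper = taper)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = s, imf = m), graph_metric_set(wm))
    }
  do.call(rbind, rows)
}
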