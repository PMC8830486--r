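test_that("analytic signal reproduces phase structure of sinusoids", {
  fs <- 128; t_sec <- (0:511) / fs; f <- 7
  x <- cos(2 * pi * f * t_sec)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-10)
  interior <- 52:460
  slope <- coef(lm(unwrap ~ t, data.frame(unwrap = cumsum(c(Arg(z)[interior][1],
    diff(Arg(z)[interior]) %% (2 * pi) - ifelse(diff(Arg(z)[interior]) %% (2 * pi) > pi, 2 * pi, 0))),
    t = t_sec[interior])))[2]
  expect_equal(as.numeric(slope), 2 * pi * f, tolerance = 0.01 * 2 * pi * f)
  zs <- analytic_signal(sin(2 * pi * f * t_sec))
  dphi <- Arg(zs[interior] * Conj(z[interior]))
  expect_equal(median(dphi), -pi / 2, tolerance = 0.05)
  expect_warning(analytic_signal(rep(1, 16)), "constant")
})

test_that("WPLI matches its defining formula in the canonical limits", {
  set.seed(1)
  z <- complex(real = rnorm(64), imaginary = rnorm(64))
  expect_equal(wpli_pair(z, z), 0)           # zero-lag null
  t_sec <- (0:255) / 64
  z1 <- analytic_signal(sin(2 * pi * 5 * t_sec))
  z2 <- analytic_signal(sin(2 * pi * 5 * t_sec - pi / 2))
  expect_equal(wpli_pair(z1[20:236], z2[20:236]), 1, tolerance = 1e-6)
  # direct Eq.-style evaluation: Im X = (+1, +1, -1) -> 1/3
  expect_equal(wpli_pair(c(1, 1, 1) + 0i, c(-1i, -1i, 1i)), 1 / 3)
  expect_error(wpli_pair(z, z[1:10]), "shape")
})

test_that("WPLI is scale-invariant, symmetric and bounded", {
  set.seed(2)
  for (k in 1:20) {
    z1 <- analytic_signal(rnorm(128))
    z2 <- analytic_signal(rnorm(128))
    w <- wpli_pair(z1, z2)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(wpli_pair(3.7 * z1, z2), w, tolerance = 1e-12)
    expect_equal(wpli_pair(z2, z1), w, tolerance = 1e-12)
  }
})

test_that("epoch-averaged WPLI matrices recover planted coupling", {
  fs <- 128
  spec <- cohort_spec(n_subjects = 2, sampling_rate = fs, duration = 60,
                      channel_labels = c("C3", "O1", "O2"), noise_sd = 0.5,
                      seed = 17)
  spec <- plant_coupled_pair(spec, c("O1", "O2"), lag = pi / 2, strength = 1,
                             band = c(8, 12), amplitude = 10)
  rec <- generate_recording(spec, 1)
  # broadband epochs: the coupled band dominates the imaginary
  # cross-spectrum, while the independent pair stays near the null
  ep <- segment_epochs(rec, preprocess_config(epoch_length = 2))
  wm <- wpli_matrix(ep$epochs, ep$channels)
  expect_gte(wm$values["O1", "O2"], 0.9)
  expect_lt(wm$values["C3", "O1"], 0.3)
  expect_equal(wm$values, t(wm$values))
  expect_true(all(diag(wm$values) == 0))
  # a single epoch reduces to pairwise wpli_pair on tapered analytic series
  one <- ep$epochs[, 1, , drop = FALSE]
  wm1 <- wpli_matrix(one, ep$channels, taper = 0.05)
  n_t <- dim(one)[3]; keep <- (floor(0.05 * n_t) + 1):(n_t - floor(0.05 * n_t))
  direct <- wpli_pair(analytic_signal(one[2, 1, ])[keep],
                      analytic_signal(one[3, 1, ])[keep])
  expect_equal(wm1$values["O1", "O2"], direct, tolerance = 1e-12)
})

test_that("weight-to-length conversion is the reciprocal map", {
  W <- matrix(c(0, 0.5, 0, 0.5, 0, 0.25, 0, 0.25, 0), 3)
  L <- weights_to_lengths(W)
  expect_equal(L[1, 2], 2)
  expect_equal(L[2, 3], 4)
  expect_true(is.infinite(L[1, 3]))
  expect_true(all(diag(L) == 0))
  expect_error(weights_to_lengths(matrix(c(0, -1, -1, 0), 2)), "negative")
  w <- runif(50, 0.01, 1)
  expect_true(all(diff(1 / sort(w)) <= 0) || all(order(w) == order(1 / w, decreasing = TRUE)))
})

test_that("shortest-path metrics match hand-enumerated and brute-force values", {
  # complete unit-weight graph
  n <- 5
  W <- matrix(1, n, n); diag(W) <- 0
  sp <- shortest_path_metrics(weights_to_lengths(W))
  expect_equal(sp$characteristic_path_length, 1)
  expect_equal(sp$global_efficiency, 1)
  expect_equal(sp$radius, 1); expect_equal(sp$diameter, 1)
  # 3-node chain: lengths 1-1, no direct edge between the ends
  L <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3)
  sp <- shortest_path_metrics(L)
  expect_equal(sp$characteristic_path_length, 4 / 3)
  expect_equal(sp$radius, 1)
  expect_equal(sp$diameter, 2)
  # random graphs vs Floyd-Warshall
  set.seed(5)
  for (k in 1:100) {
    W <- random_weight_graph(6)
    L <- weights_to_lengths(W)
    D <- floyd_warshall(L)
    off <- D[row(D) != col(D)]
    sp <- suppressWarnings(shortest_path_metrics(L))
    expect_equal(sp$characteristic_path_length, mean(off[is.finite(off)]),
                 tolerance = 1e-12)
    expect_equal(sp$global_efficiency, mean(ifelse(is.finite(off), 1 / off, 0)),
                 tolerance = 1e-12)
    ecc <- apply(D, 1, max)
    expect_equal(sp$radius, min(ecc), tolerance = 1e-12)
    expect_equal(sp$diameter, max(ecc), tolerance = 1e-12)
  }
})

test_that("weighted transitivity equals exhaustive triangle enumeration", {
  n <- 5
  W <- matrix(1, n, n); diag(W) <- 0
  expect_equal(transitivity_weighted(W), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 0.8
  expect_equal(transitivity_weighted(star), 0)
  set.seed(6)
  for (k in 1:100) {
    W <- random_weight_graph(5)
    expect_equal(transitivity_weighted(W), transitivity_oracle(W),
                 tolerance = 1e-12)
  }
})

test_that("metrics scale correctly under uniform weight rescaling", {
  set.seed(7)
  W <- matrix(runif(36, 0.2, 0.9), 6); W <- (W + t(W)) / 2; diag(W) <- 0
  sp1 <- shortest_path_metrics(weights_to_lengths(W))
  c_scale <- 0.5
  sp2 <- shortest_path_metrics(weights_to_lengths(c_scale * W))
  expect_equal(sp2$characteristic_path_length,
               sp1$characteristic_path_length / c_scale, tolerance = 1e-10)
  expect_equal(sp2$global_efficiency, sp1$global_efficiency * c_scale,
               tolerance = 1e-10)
  expect_equal(sp2$radius, sp1$radius / c_scale, tolerance = 1e-10)
  expect_equal(sp2$diameter, sp1$diameter / c_scale, tolerance = 1e-10)
})

test_that("the full metric set satisfies its structural invariants", {
  set.seed(8)
  for (k in 1:20) {
    gm <- graph_metric_set(random_weight_graph(6))
    expect_lte(gm$radius, gm$diameter)
    expect_gte(gm$global_efficiency, 0); expect_lte(gm$global_efficiency, 1)
    expect_true(all(unlist(gm) >= 0))
  }
})
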