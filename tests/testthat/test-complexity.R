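test_that("sample entropy matches the exhaustive counting oracle", {
  expect_equal(sample_entropy(rep(1, 20), 2, 0), 0)
  x <- rep(c(1, 2), 5)
  expect_equal(as.numeric(sample_entropy(x, 2, 0.5)),
               sampen_oracle(x, 2, 0.5), tolerance = 1e-12)
  set.seed(1)
  for (k in 1:30) {
    x <- rnorm(sample(15:50, 1))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5) * sd(x)
    expect_equal(as.numeric(sample_entropy(x, m, r)), sampen_oracle(x, m, r),
                 tolerance = 1e-12)
  }
  expect_error(sample_entropy(1:3, 3, 0.1), "short")
})

test_that("sample entropy orders noise above tones and decreases with tolerance", {
  set.seed(2)
  n <- 200
  tone <- sin(2 * pi * 5 * (0:(n - 1)) / 64)
  se_noise <- vapply(1:50, function(s) {
    set.seed(100 + s)
    x <- rnorm(n)
    sample_entropy(x, 2, 0.2 * sd(x))
  }, 0)
  se_tone <- sample_entropy(tone, 2, 0.2 * sd(tone))
  expect_gt(median(se_noise), se_tone)
  # monotone non-increasing in r on fixed series long enough for the
  # match counts to be well populated
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(500)
    vals <- vapply(seq(0.1, 0.6, by = 0.1), function(rf)
      as.numeric(sample_entropy(x, 2, rf * sd(x))), 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("permutation entropy matches the ordinal-pattern oracle", {
  expect_equal(permutation_entropy(1:50, 3, 1), 0)
  expect_equal(permutation_entropy(50:1, 3, 1), 0)
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(x, 3, 1), pen_oracle(x, 3, 1),
               tolerance = 1e-12)
  set.seed(4)
  for (k in 1:30) {
    x <- rnorm(sample(20:50, 1))
    n <- sample(2:4, 1); L <- sample(1:2, 1)
    expect_equal(permutation_entropy(x, n, L), pen_oracle(x, n, L),
                 tolerance = 1e-12)
    expect_equal(permutation_entropy(x, n, L, "order"),
                 pen_oracle(x, n, L, "order"), tolerance = 1e-12)
  }
  expect_error(permutation_entropy(1:3, 5, 2), "short")
})

test_that("permutation entropy is invariant under monotone transforms", {
  set.seed(5)
  x <- rnorm(80)
  p0 <- permutation_entropy(x, 3, 1)
  expect_equal(permutation_entropy(exp(x), 3, 1), p0, tolerance = 1e-12)
  expect_equal(permutation_entropy(3 * x - 100, 3, 1), p0, tolerance = 1e-12)
})

test_that("spectral entropy spans the tone-to-noise range", {
  fs <- 64; n <- 256
  t_sec <- (0:(n - 1)) / fs
  expect_lt(spectral_entropy(sin(2 * pi * 8 * t_sec), fs, c(0.5, 30)), 0.05)
  two <- sin(2 * pi * 8 * t_sec) + sin(2 * pi * 12 * t_sec)
  expect_equal(spectral_entropy(two, fs, c(0.5, 30)), log(2), tolerance = 0.05 * log(2))
  n_bins <- sum((seq_len(n %/% 2) * fs / n) >= 0.5 &
                  (seq_len(n %/% 2) * fs / n) <= 30)
  se <- mean(vapply(1:20, function(s) {
    set.seed(s)
    spectral_entropy(rnorm(n), fs, c(0.5, 30))
  }, 0))
  expect_equal(se, log(n_bins), tolerance = 0.1 * log(n_bins))
  # amplitude scaling is irrelevant
  set.seed(6); x <- rnorm(n)
  expect_equal(spectral_entropy(17 * x, fs, c(0.5, 30)),
               spectral_entropy(x, fs, c(0.5, 30)), tolerance = 1e-12)
  expect_error(spectral_entropy(sin(2 * pi * 30 * t_sec), fs, c(0.5, 2)),
               "zero in-band")
})

test_that("the entropy table has 3 measures x channels columns per mode", {
  labels <- c("C3", "F3", "F7", "FZ", "O1", "O2", "P3", "P4", "T3", "T4",
              "T5", "T6")
  set.seed(7)
  cimfs <- fake_cimfs(3, labels, 2, 64, 32, function(s, ci, e, m)
    rnorm(64, sd = 1 + 0.1 * s))
  tab <- entropy_feature_table(cimfs)
  fm <- feature_matrix(tab)
  expect_equal(ncol(fm), 36)  # 3 measures x 12 channels, one mode
  expect_equal(nrow(fm), 3)
  expect_true(all(is.finite(fm)))
})

test_that("epoch averaging is exact for identical epochs and order-invariant", {
  set.seed(8)
  base <- rnorm(64)
  cimfs <- fake_cimfs(1, c("C3", "T3"), 4, 64, 32,
                      function(s, ci, e, m) base * ci)
  tab <- entropy_feature_table(cimfs)
  single <- fake_cimfs(1, c("C3", "T3"), 1, 64, 32,
                       function(s, ci, e, m) base * ci)
  tab1 <- entropy_feature_table(single)
  expect_equal(tab$sampen, tab1$sampen, tolerance = 1e-12)
  expect_equal(tab$pen, tab1$pen, tolerance = 1e-12)
  expect_equal(tab$spen, tab1$spen, tolerance = 1e-12)
  # permuting epochs leaves the averaged table unchanged
  set.seed(9)
  eps <- lapply(1:4, function(e) rnorm(64))
  c_fwd <- fake_cimfs(1, "C3", 4, 64, 32, function(s, ci, e, m) eps[[e]])
  c_rev <- fake_cimfs(1, "C3", 4, 64, 32, function(s, ci, e, m) eps[[5 - e]])
  expect_equal(entropy_feature_table(c_fwd)[, c("sampen", "pen", "spen")],
               entropy_feature_table(c_rev)[, c("sampen", "pen", "spen")],
               tolerance = 1e-12)
})

test_that("subject rankings are robust to small embedding-parameter changes", {
  # subjects span a complexity gradient: tone-noise mixtures; the grid
  # covers small moves inside the recommended parameter band
  set.seed(10)
  n_sub <- 10
  mixes <- seq(0.1, 0.9, length.out = n_sub)
  t_sec <- (0:511) / 32
  cimfs <- fake_cimfs(n_sub, "C3", 4, 512, 32, function(s, ci, e, m) {
    (1 - mixes[s]) * sqrt(2) * sin(2 * pi * 3 * t_sec + s + e) +
      mixes[s] * rnorm(512)
  })
  grid <- expand.grid(m = c(2, 3), r = c(0.15, 0.2, 0.25))
  rank_mat <- vapply(seq_len(nrow(grid)), function(g) {
    tab <- entropy_feature_table(cimfs, entropy_config(sampen_m = grid$m[g],
                                                       sampen_r_frac = grid$r[g]))
    rank(tab$sampen)
  }, numeric(n_sub))
  base_rank <- rank_mat[, 4] # m = 3, r = 0.2 (the default setting)
  rho <- apply(rank_mat, 2, function(rk) cor(rk, base_rank, method = "spearman"))
  expect_true(all(rho > 0.8))
  # permutation-entropy rankings agree across the recommended delays
  pen_ranks <- vapply(1:2, function(L)
    rank(entropy_feature_table(cimfs, entropy_config(pen_delay = L))$pen),
    numeric(n_sub))
  expect_gt(cor(pen_ranks[, 1], pen_ranks[, 2], method = "spearman"), 0.8)
})
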