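test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(1, 3, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("t-based p-values reproduce the published worked examples", {
  expect_equal(round(p_from_r(-0.46, 20)$p, 2), 0.04)
  expect_equal(round(p_from_r(0.48, 20)$p, 2), 0.03)
  expect_equal(p_from_r(0, 20)$p, 1)
  expect_equal(p_from_r(0, 20)$t, 0)
  expect_equal(p_from_r(1, 20)$p, 0)
  expect_equal(p_from_r(-0.45, 20)$t, -0.45 * sqrt(18) / sqrt(1 - 0.45^2),
               tolerance = 1e-12)
})

test_that("analytic p-values agree with a permutation null", {
  set.seed(11)
  n <- 20
  x <- rnorm(n)
  y <- 0.45 * x + rnorm(n, sd = 0.9)
  r_obs <- pearson_r(x, y)
  p_analytic <- p_from_r(r_obs, n)$p
  n_perm <- 2e5
  xc <- x - mean(x)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(y)
    sum(xc * (yp - mean(yp)))
  }, 0) / sqrt(sum(xc^2))
  r_obs_num <- sum(xc * (y - mean(y))) / sqrt(sum(xc^2))
  p_perm <- mean(abs(perm_r) >= abs(r_obs_num))
  expect_equal(p_analytic, p_perm, tolerance = 0.01)
})

test_that("the screen ranks a strongly coupled feature first and is inclusive at alpha", {
  set.seed(12)
  hits <- vapply(seq_len(200), function(s) {
    set.seed(1000 + s)
    n <- 20
    planted <- rnorm(n)
    y <- 0.8 * planted + rnorm(n, sd = sqrt(1 - 0.64))
    feats <- cbind(planted = planted,
                   matrix(rnorm(n * 35), n,
                          dimnames = list(NULL, paste0("null", 1:35))))
    scr <- screen_features(feats, y)
    scr$feature[1] == "planted"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # inclusive boundary: a feature whose p equals alpha is significant
  set.seed(13)
  f <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  scr0 <- screen_features(f, y)
  scr_at <- screen_features(f, y, alpha = scr0$p[1])
  expect_true(scr_at$significant[1])
  expect_error(screen_features(f, y[1:10]), "scores")
})

test_that("all-null screening is calibrated at the nominal level", {
  set.seed(14)
  n_sig <- 0; n_tot <- 0
  for (s in 1:400) {
    f <- matrix(rnorm(20 * 10), 20, dimnames = list(NULL, paste0("f", 1:10)))
    y <- rnorm(20)
    scr <- screen_features(f, y)
    n_sig <- n_sig + sum(scr$significant)
    n_tot <- n_tot + nrow(scr)
  }
  half <- 1.96 * sqrt(0.05 * 0.95 / n_tot)
  expect_gte(n_sig / n_tot, 0.05 - half)
  expect_lte(n_sig / n_tot, 0.05 + half)
})

test_that("tree ensembles behave as their definitions require", {
  # deep trees interpolate a step function
  x <- data.frame(f = rep(c(0, 1), each = 10))
  y <- rep(c(2, 9), each = 10)
  fit <- fit_ensemble(x, y, model_spec("bagged", n_learners = 5, min_leaf = 1,
                                       seed = 3))
  expect_equal(as.numeric(predict(fit, x)), y, tolerance = 1e-12)
  # boosted with a single tree at unit rate equals that tree
  set.seed(15)
  x2 <- data.frame(f = runif(30))
  y2 <- sin(6 * x2$f) + rnorm(30, sd = 0.1)
  spec1 <- model_spec("boosted", n_learners = 1, learning_rate = 1,
                      min_leaf = 4, seed = 5)
  fitb <- fit_ensemble(x2, y2, spec1)
  lone <- rpart::rpart(y ~ ., data = cbind(y = y2, x2), method = "anova",
                       control = rpart::rpart.control(minsplit = 8,
                                                      minbucket = 4, cp = 0,
                                                      xval = 0, maxdepth = 30,
                                                      maxsurrogate = 0,
                                                      maxcompete = 0))
  expect_equal(as.numeric(predict(fitb, x2)),
               as.numeric(predict(lone, x2)), tolerance = 1e-10)
  # bagged aggregation identity: prediction = mean over learners
  fit2 <- fit_ensemble(x2, y2, model_spec("bagged", n_learners = 7, seed = 6))
  per_tree <- vapply(fit2$trees, function(tr) predict(tr, newdata = x2),
                     numeric(30))
  expect_equal(as.numeric(predict(fit2, x2)), unname(rowMeans(per_tree)),
               tolerance = 1e-12)
  # determinism under a fixed seed
  fit3 <- fit_ensemble(x2, y2, model_spec("bagged", n_learners = 7, seed = 6))
  expect_equal(predict(fit2, x2), predict(fit3, x2), tolerance = 1e-15)
  expect_error(fit_ensemble(data.frame(f = c(1, NA)), c(1, 2), spec1),
               "non-finite")
})

test_that("regression metrics match hand computations and invariances", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, mae = 0, r_squared = 1))
  m2 <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m2$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$r_squared, 0, tolerance = 1e-12)
  set.seed(16)
  a <- rnorm(10); p <- rnorm(10)
  m3 <- regression_metrics(a, p); m4 <- regression_metrics(a + 5, p + 5)
  expect_equal(m3$rmse, m4$rmse, tolerance = 1e-12)
  expect_equal(m3$mae, m4$mae, tolerance = 1e-12)
  expect_error(regression_metrics(rep(2, 5), rnorm(5)), "zero-variance")
})

test_that("LOSOCV predicts each subject exactly once and handles degeneracy", {
  set.seed(17)
  n <- 20
  x <- data.frame(f = rnorm(n))
  y <- 3 * x$f + rnorm(n, sd = 0.5)
  rep_ <- losocv(x, y, model_spec("bagged", n_learners = 10, seed = 2))
  expect_equal(nrow(rep_$predictions), n)
  expect_equal(rep_$predictions$subject, 1:n)
  expect_gte(rep_$rmse, 0)
  # constant scores: every prediction equals the constant
  rep_c <- losocv(x, rep(7, n), model_spec("bagged", seed = 2))
  expect_equal(rep_c$predictions$predicted, rep(7, n))
  expect_equal(rep_c$rmse, 0)
  expect_error(losocv(x[1:2, , drop = FALSE], y[1:2]), "at least 3")
})

test_that("a constant-prediction learner cannot beat the grand-mean baseline", {
  set.seed(18)
  n <- 20
  x <- data.frame(f = rnorm(n))
  y <- rnorm(n, 100, 10)
  # min_leaf of n forces root-only trees: the model predicts the fold mean
  rep_ <- losocv(x, y, model_spec("bagged", n_learners = 5, min_leaf = n,
                                  seed = 4))
  expect_lte(rep_$r_squared, 0)
})

test_that("held-out skill separates planted signal from shuffled scores", {
  set.seed(19)
  r2_sig <- numeric(50); r2_null <- numeric(50)
  for (s in 1:50) {
    set.seed(2000 + s)
    n <- 20
    x <- data.frame(f = rnorm(n))
    y <- 0.8 * scale(x$f)[, 1] + rnorm(n, sd = 0.6)
    ms <- model_spec("boosted", n_learners = 15, seed = s)
    r2_sig[s] <- losocv(x, y, ms)$r_squared
    r2_null[s] <- losocv(x, sample(y), ms)$r_squared
  }
  expect_gt(median(r2_sig), 0)
  expect_lte(median(r2_null), 0.1)
})

test_that("seeded inference is end-to-end deterministic", {
  set.seed(20)
  x <- data.frame(a = rnorm(15), b = rnorm(15))
  y <- rnorm(15, 100, 10)
  r1 <- losocv(x, y, model_spec("boosted", seed = 9))
  r2 <- losocv(x, y, model_spec("boosted", seed = 9))
  expect_identical(r1$predictions, r2$predictions)
})
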