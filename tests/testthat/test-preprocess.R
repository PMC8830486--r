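test_that("the planted seven bad channels are flagged, and only those", {
  rec <- generate_recording(bad_channel_spec(), 1)
  bad <- detect_bad_channels(rec, preprocess_config())
  expect_setequal(bad, c("C4", "CZ", "F4", "F8", "FP1", "FP2", "PZ"))
  # order follows the input montage
  expect_identical(bad, rec$channels[rec$channels %in% bad])
})

test_that("a homogeneous montage yields no flags; a dead channel is caught", {
  spec <- cohort_spec(n_subjects = 2, sampling_rate = 128, duration = 4,
                      channel_labels = c("C3", "F3", "O1", "T3"),
                      oscillation_specs = list(list(freq = 9, amplitude = 10,
                                                    channels = c("C3", "F3",
                                                                 "O1", "T3"))),
                      noise_sd = 2, seed = 13)
  rec <- generate_recording(spec, 1)
  expect_length(detect_bad_channels(rec, preprocess_config()), 0)
  rec$data["O1", ] <- 0
  expect_identical(detect_bad_channels(rec, preprocess_config()), "O1")
  rec$data[] <- 0
  expect_error(detect_bad_channels(rec, preprocess_config()), "no usable")
})

test_that("common average reference matches its definition and is idempotent", {
  set.seed(4)
  x <- matrix(rnorm(500), 5)
  out <- rereference_car(x)
  expect_lt(max(abs(colMeans(out))), 1e-10)
  expect_equal(out, sweep(x, 2, colMeans(x)), tolerance = 1e-12)
  # offset invariance and idempotence
  expect_equal(rereference_car(x + 7), out, tolerance = 1e-10)
  expect_equal(rereference_car(out), out, tolerance = 1e-12)
  expect_error(rereference_car(x[1, , drop = FALSE]), "single channel")
})

test_that("epoch segmentation cuts non-overlapping windows, dropping the tail", {
  mk <- function(dur, fs) eeg_recording(matrix(rnorm(2 * dur * fs), 2),
                                        c("C3", "T3"), fs)
  cfg <- preprocess_config(epoch_length = 2)
  ep <- segment_epochs(mk(60, 512), cfg)
  expect_equal(dim(ep$epochs)[2:3], c(30, 1024))
  expect_equal(dim(segment_epochs(mk(2, 128), cfg)$epochs)[2], 1)
  ep5 <- segment_epochs(mk(5, 512), cfg)
  expect_equal(dim(ep5$epochs)[2], 2) # 512 trailing samples discarded
  expect_error(segment_epochs(mk(1, 128), cfg), "shorter")
  # windows are consecutive: epoch 2 equals the raw samples it covers
  rec <- mk(5, 512)
  ep <- segment_epochs(rec, cfg)
  expect_equal(ep$epochs[, 2, ], unname(rec$data[, 1025:2048]))
})

test_that("amplitude rejection uses a strict threshold and logs decisions", {
  set.seed(8)
  ep <- array(rnorm(2 * 40 * 64, sd = 3), dim = c(2, 40, 64))
  bad <- sample(40, 7)
  for (e in bad) ep[1, e, 10] <- 80
  ce <- clean_epochs("S01", c("C3", "T3"), ep, 32)
  cfg <- preprocess_config(amplitude_threshold = 55)
  out <- reject_epochs_by_amplitude(ce, cfg)
  expect_equal(dim(out$epochs)[2], 33)
  expect_equal(sum(!out$rejection_log$kept), 7)
  # boundary: a peak exactly at threshold is retained, just above is not
  ep2 <- array(0, dim = c(1, 2, 8))
  ep2[1, 1, 4] <- 55
  ep2[1, 2, 4] <- 56
  out2 <- reject_epochs_by_amplitude(clean_epochs("S", "C3", ep2, 4),
                                     preprocess_config(amplitude_threshold = 55,
                                                       epoch_length = 2))
  expect_equal(out2$rejection_log$kept, c(TRUE, FALSE))
  ep3 <- array(100, dim = c(1, 3, 8))
  expect_error(reject_epochs_by_amplitude(clean_epochs("S", "C3", ep3, 4), cfg),
               "epochs exceed")
})

test_that("rejection decisions are stable under channel permutation", {
  set.seed(9)
  ep <- array(rnorm(4 * 20 * 64, sd = 15), dim = c(4, 20, 64))
  ce <- clean_epochs("S01", c("C3", "F3", "O1", "T3"), ep, 32)
  cfg <- preprocess_config(amplitude_threshold = 50)
  kept1 <- reject_epochs_by_amplitude(ce, cfg)$rejection_log$kept
  perm <- c(3, 1, 4, 2)
  ce2 <- clean_epochs("S01", ce$channels[perm], ep[perm, , ], 32)
  expect_identical(reject_epochs_by_amplitude(ce2, cfg)$rejection_log$kept,
                   kept1)
})

test_that("ICA reconstruction is exact when no component is flagged", {
  set.seed(10)
  n_ch <- 12
  mixing <- matrix(rnorm(n_ch^2), n_ch)
  src <- matrix(rnorm(n_ch * 768), n_ch)
  x <- mixing %*% src
  ep <- array(x, dim = c(n_ch, 3, 256))
  labels <- c("C3", "F3", "F7", "FZ", "O1", "O2", "P3", "P4", "T3", "T4",
              "T5", "T6")
  ce <- clean_epochs("S01", labels, ep, 128)
  out <- ica_decompose_reconstruct(ce, preprocess_config(ica_enabled = TRUE))
  expect_lt(sqrt(sum((out$epochs - ce$epochs)^2) / sum(ce$epochs^2)), 1e-6)
  expect_equal(attr(out, "ica_n_components"), 12)
})

test_that("a planted frontal ocular source is removed by the topography rule", {
  labels <- c("C3", "F3", "F7", "FZ", "O1", "O2", "P3", "P4", "T3", "T4",
              "T5", "T6")
  spec <- cohort_spec(
    n_subjects = 2, sampling_rate = 128, duration = 16,
    channel_labels = labels,
    oscillation_specs = list(list(freq = 10, amplitude = 8, channels = labels)),
    artifact_spec = list(ocular = list(rate = 0.8, amplitude = 60)),
    noise_sd = 2, seed = 31)
  rec <- generate_recording(spec, 1)
  src <- rec$ocular_source
  cfg <- preprocess_config(amplitude_threshold = 1e4, ica_enabled = TRUE,
                           ica_artifact_rule = topography_rule(threshold = 0.8),
                           bandpass = NULL)
  ep <- segment_epochs(rec, cfg)
  out <- ica_decompose_reconstruct(ep, cfg)
  expect_gt(length(attr(out, "ica_flagged")), 0)
  # frontal channels no longer track the artifact time course
  n_keep <- dim(out$epochs)[2] * dim(out$epochs)[3]
  for (ch in c("FP1", "F3", "FZ")[c(FALSE, TRUE, TRUE)]) {
    cleaned <- as.vector(t(out$epochs[which(labels == ch), , ]))
    expect_lt(abs(cor(cleaned, src[seq_len(n_keep)])), 0.2)
  }
})

test_that("truncation keeps the first epochs and reports shortfalls", {
  set.seed(12)
  ep <- array(rnorm(2 * 33 * 16), dim = c(2, 33, 16))
  ce <- clean_epochs("S07", c("C3", "T3"), ep, 8)
  cfg <- preprocess_config(n_keep_epochs = 30)
  out <- truncate_to_common_epochs(ce, cfg)
  expect_equal(dim(out$epochs)[2], 30)
  expect_equal(out$epochs[, 1:30, ], ep[, 1:30, ])
  ce30 <- clean_epochs("S08", c("C3", "T3"), ep[, 1:30, ], 8)
  expect_identical(truncate_to_common_epochs(ce30, cfg)$epochs, ce30$epochs)
  ce12 <- clean_epochs("S09", c("C3", "T3"), ep[, 1:12, ], 8)
  expect_error(truncate_to_common_epochs(ce12, cfg), "S09.*12|12.*S09")
})
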