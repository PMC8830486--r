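#' Pipeline configuration
#'
#' Bundles the per-stage configurations, stage toggles, output directory and
#' run seed.  The default is a reduced demonstration profile (8 subjects, 4
#' channels, 5 retained 4-s epochs of 512 samples at 128 Hz, 16 sifting
#' directions) that completes in minutes; the full-scale study layout (20
#' subjects, 12 channels, 30 epochs of 1024 samples at 512 Hz, 64
#' directions) is obtained by passing the corresponding [cohort_spec()] and
#' [sift_config()].
#'
#' @param cohort a [cohort_spec()], used when the synthetic stage is on.
#' @param input_dir directory of an on-disk fixture (see [write_fixture()])
#'   read instead of synthesising, when `stages$synth` is off.
#' @param preprocess a [preprocess_config()].
#' @param sift a [sift_config()].
#' @param entropy an [entropy_config()].
#' @param imf_selection list: `rule` ("default" or "band"), plus
#'   `drop_head`/`drop_tail` or `band`.
#' @param models list of [model_spec()]s evaluated under LOSOCV.
#' @param alpha screening significance level.
#' @param wpli_taper edge fraction for the WPLI stage.
#' @param stages named logical list toggling `synth`, `preprocess`,
#'   `decompose`, `connectivity`, `entropy`, `screen`, `predict`.
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @param seed run seed, propagated to every stochastic stage.
#' @export
pipeline_config <- function(cohort = demo_cohort_spec(),
                            input_dir = NULL,
                            preprocess = preprocess_config(epoch_length = 4,
                                                           n_keep_epochs = 5,
                                                           ica_enabled = FALSE),
                            sift = sift_config(n_directions = 16,
                                               max_sift_iterations = 8),
                            entropy = entropy_config(),
                            imf_selection = list(rule = "band", band = c(0.5, 6)),
                            models = list(model_spec("bagged"),
                                          model_spec("boosted")),
                            alpha = 0.05, wpli_taper = 0.05,
                            stages = list(synth = TRUE, preprocess = TRUE,
                                          decompose = TRUE,
                                          connectivity = TRUE, entropy = TRUE,
                                          screen = TRUE, predict = TRUE),
                            out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, input_dir = input_dir,
                 preprocess = preprocess, sift = sift, entropy = entropy,
                 imf_selection = imf_selection, models = models,
                 alpha = alpha, wpli_taper = wpli_taper, stages = stages,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reduced demonstration cohort
#'
#' Four channels at 128 Hz, 24 s per subject.  Every channel carries a
#' delta-band component of the same amplitude (at distinct frequencies) and
#' a 16 Hz beta tone over modest broadband noise, so channel SDs are
#' homogeneous; only C3's delta component trades its 2.5 Hz tone for
#' flat-spectrum narrowband noise along the per-subject complexity
#' gradient, and that gradient is coupled to the outcome scores at
#' population correlation `-rho` (more irregular delta, lower score).
#'
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param rho planted feature-score population correlation magnitude.
#' @export
demo_cohort_spec <- function(n_subjects = 8, seed = 1L, rho = 0.6) {
  labels <- c("C3", "F3", "O1", "T3")
  cohort_spec(
    n_subjects = n_subjects, sampling_rate = 128, duration = 24,
    channel_labels = labels,
    # distinct delta frequencies per channel (all on the 0.5 Hz epoch DFT
    # grid) so the common average reference cannot interfere with C3's
    # 2.5 Hz component at its own bin
    oscillation_specs = list(
      list(freq = 16, amplitude = 6, channels = labels),
      list(freq = 2.0, amplitude = 18, channels = "F3"),
      list(freq = 3.0, amplitude = 18, channels = "O1"),
      list(freq = 3.5, amplitude = 18, channels = "T3")),
    complexity_gradient = list(
      # RMS-matched to the 18 uV peak tones on the other channels
      channel = "C3", freq = 2.5, band = c(1, 4), amplitude = 18 / sqrt(2),
      epoch_s = 4,
      mix = seq(0.2, 0.8, length.out = n_subjects),
      noise_scale = rep(1, n_subjects)),
    noise_sd = 0.75,
    score_model = score_model_for_rho(-rho, baseline = 105),
    seed = seed)
}

#' Read a recording from the on-disk array container
#'
#' Reads the TSV matrix (samples x channels, header = labels) plus its JSON
#' sidecar written by [write_fixture()].  EDF input is detected and refused
#' with a pointer to the supported container.
#'
#' @param path path to a `*_eeg.tsv` file.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    stop("EDF input is not supported; supply the TSV + JSON array container ",
         "written by write_fixture()")
  if (!grepl("\\.tsv$", path)) stop("unknown container extension: ", path)
  if (!file.exists(path)) stop("missing recording file: ", path)
  meta_path <- sub("\\.tsv$", ".json", path)
  if (!file.exists(meta_path)) stop("missing JSON sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (length(meta$sampling_rate) != 1)
    stop("mixed per-channel sampling rates are unsupported")
  df <- read.delim(path, check.names = FALSE)
  if (!setequal(names(df), meta$channel_labels))
    stop("corrupt container: header labels disagree with sidecar")
  eeg_recording(t(as.matrix(df[, meta$channel_labels, drop = FALSE])),
                meta$channel_labels, meta$sampling_rate,
                subject_id = meta$subject_id %||% basename(path))
}

read_fixture_cohort <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "_eeg\\.tsv$", full.names = TRUE))
  if (!length(tsvs)) stop("no recordings found under ", dir)
  recordings <- lapply(tsvs, read_recording)
  scores <- read.delim(file.path(dir, "scores.tsv"))
  list(recordings = recordings, scores = scores)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — synthesize (or read) the cohort,
#' preprocess every subject, stack and decompose per channel, select the
#' analysis modes, extract graph and entropy features, screen them against
#' the outcome scores, and evaluate the requested tree ensembles under
#' LOSOCV on the significant features (falling back to the single
#' smallest-p feature when nothing passes the screen).  When `out_dir` is
#' set, feature tables, screening results, per-subject predictions, the
#' report and a run manifest are written as TSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @return list with the stage outputs and a `manifest` (config snapshot,
#'   stage timings, data shapes, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  timings <- c(); shapes <- list()
  out <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[3] - t0, 3)
    val
  }

  if (isTRUE(st$synth)) {
    cohort <- tick("synth", generate_cohort(config$cohort))
    recordings <- cohort$recordings
    scores <- cohort$scores
    out$cohort <- cohort
  } else {
    if (is.null(config$input_dir))
      stop("synthetic stage disabled and no input_dir given: nothing to read")
    fx <- tick("read", read_fixture_cohort(config$input_dir))
    recordings <- fx$recordings
    scores <- fx$scores
  }
  shapes$recordings <- c(n = length(recordings),
                         channels = nrow(recordings[[1]]$data),
                         samples = ncol(recordings[[1]]$data))

  if (isTRUE(st$preprocess)) {
    clean <- tick("preprocess",
                  lapply(recordings, preprocess_recording, cfg = config$preprocess))
    out$clean <- clean
  } else stop("preprocess stage is required by the downstream stages")
  shapes$clean <- dim(clean[[1]]$epochs)

  if (!isTRUE(st$decompose))
    stop("decompose stage disabled but connectivity/entropy stages need it")
  stacked <- stack_cohort_per_channel(clean)
  cfg_sift <- config$sift
  cfg_sift$seed <- derive_seed(config$seed, cfg_sift$seed, salt = 5L)
  cimfs <- tick("decompose", decompose_cohort(stacked, cfg_sift))
  sel <- config$imf_selection
  cimfs <- if (identical(sel$rule, "band"))
    select_cohort_imfs(cimfs, "band", band = sel$band)
  else select_cohort_imfs(cimfs, "default",
                          drop_head = sel$drop_head %||% 3,
                          drop_tail = sel$drop_tail %||% 1)
  out$imfs <- cimfs
  shapes$imfs <- c(channels = length(cimfs$channels),
                   modes = cimfs$channels[[1]]$n_modes,
                   rows = nrow(cimfs$row_index),
                   samples = dim(cimfs$channels[[1]]$modes)[3])

  feats <- list()
  if (isTRUE(st$connectivity)) {
    out$graph_table <- tick("connectivity",
                            graph_feature_table(cimfs, taper = config$wpli_taper))
    feats$graph <- feature_matrix(out$graph_table)
  }
  if (isTRUE(st$entropy)) {
    out$entropy_table <- tick("entropy",
                              entropy_feature_table(cimfs, config$entropy))
    feats$entropy <- feature_matrix(out$entropy_table)
  }

  if (isTRUE(st$screen)) {
    out$screen <- tick("screen", lapply(feats, function(f)
      screen_features(f, scores$score, config$alpha)))
  }

  if (isTRUE(st$predict)) {
    if (!isTRUE(st$screen)) stop("predict stage needs the screen stage")
    out$reports <- tick("predict", {
      reports <- list()
      for (set_name in names(feats)) {
        scr <- out$screen[[set_name]]
        chosen <- scr$feature[which(scr$significant)]
        if (!length(chosen)) chosen <- scr$feature[1]
        fsel <- feats[[set_name]][, chosen, drop = FALSE]
        for (ms in config$models) {
          ms$seed <- derive_seed(config$seed, ms$seed, salt = 6L)
          rep_id <- paste(set_name, ms$kind, sep = "_")
          reports[[rep_id]] <- losocv(fsel, scores$score, ms)
          reports[[rep_id]]$features_used <- chosen
        }
      }
      reports
    })
  }

  manifest <- list(
    package_version = as.character(packageVersion("neoqeeg")),
    seed = config$seed,
    alpha = config$alpha,
    imf_selection = config$imf_selection,
    stage_timings_s = as.list(timings),
    shapes = shapes,
    n_subjects = length(recordings),
    scores_range = range(scores$score))
  out$manifest <- manifest
  out$scores <- scores

  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$entropy_table)) wt(out$entropy_table, "entropy_features.tsv")
  if (!is.null(out$graph_table)) wt(out$graph_table, "graph_features.tsv")
  if (!is.null(out$screen))
    wt(do.call(rbind, Map(function(nm, df) cbind(set = nm, df),
                          names(out$screen), out$screen)),
       "correlations.tsv")
  if (!is.null(out$reports)) {
    preds <- do.call(rbind, Map(function(nm, r) cbind(model = nm, r$fold_log),
                                names(out$reports), out$reports))
    wt(preds, "predictions.tsv")
    jsonlite::write_json(
      lapply(out$reports, function(r)
        list(rmse = r$rmse, mae = r$mae, r_squared = r$r_squared,
             model = r$model_id, features = r$features_used)),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$clean) && !is.null(out$clean[[1]]$rejection_log))
    wt(do.call(rbind, lapply(out$clean, function(ce)
      cbind(subject = ce$subject_id, ce$rejection_log))), "rejection_log.tsv")
  jsonlite::write_json(out$manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
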