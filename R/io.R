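#' Write / read a continuous recording as delimited text
#'
#' Plain-text interchange format: `#key=value` header lines carrying the
#' sampling rate and physical unit, then a tab-separated matrix with one
#' column per channel, one row per sample. Values are written in microvolts.
#'
#' @param recording an `eeg_recording`.
#' @param path recording file path.
#' @param digits significant digits written (quantization of the text
#'   format).
#' @return `read_recording` returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#rate_hz=%d", recording$rate_hz),
               sprintf("#unit=%s", recording$unit)), con)
  df <- as.data.frame(t(signif(recording$data, digits)))
  names(df) <- recording$channels
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param events_path path of the events TSV (see [write_events()]).
#' @param rate_hz expected sampling rate; a mismatch is an error.
#' @export
read_recording <- function(path, events_path, rate_hz = RATE_HZ) {
  hdr <- character(0)
  con <- file(path, "r")
  repeat {
    line <- readLines(con, 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con)
  meta <- strsplit(sub("^#", "", hdr), "=")
  meta <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  file_rate <- as.integer(meta[["rate_hz"]])
  if (!identical(file_rate, as.integer(rate_hz)))
    stop(sprintf("read_recording: file rate %d Hz does not match expected %d Hz",
                 file_rate, as.integer(rate_hz)))
  if (!identical(meta[["unit"]], "uV"))
    stop("read_recording: unit mismatch (expected uV)")
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(ALL_CHANNELS, names(df))
  if (length(missing))
    stop("read_recording: missing channels: ", paste(missing, collapse = ", "))
  data <- t(as.matrix(df[ALL_CHANNELS]))
  ev <- read_events(events_path)
  bad <- which(ev$onset_sample + EPOCH_POST > ncol(data) |
               ev$onset_sample < 0)
  if (length(bad))
    stop(sprintf("read_recording: event %d out of recording range", bad[1]))
  structure(list(data = data, rate_hz = file_rate, channels = ALL_CHANNELS,
                 events = ev, unit = "uV", provenance = list()),
            class = "eeg_recording")
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline, defaulting to the
#' standard settings: 0.1-25 Hz 2nd-order bandpass, 50/80 microvolt
#' rejection thresholds, factor-8 downsampling, 0.1 microvolt selection
#' increment, 700 ms ISI protocol.
#'
#' @param seed master seed; schedule and subject seeds derive from it.
#' @param schedule_config a [protocol_config()].
#' @param subject a [subject_model()].
#' @param channels scalp channels to decode.
#' @param n_avg averaging options.
#' @param methods feature methods to run.
#' @param classifiers classifier kinds to run.
#' @param low_hz,high_hz,filter_order bandpass settings.
#' @param eeg_thr_uV,eog_thr_uV rejection thresholds.
#' @param ds_factor downsampling factor.
#' @param fs_mode,fs_threshold,fs_increment feature-selection settings
#'   (see [loo_crossval()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       schedule_config = protocol_config(seed = seed),
                       subject = subject_model(seed = seed + 1000L),
                       channels = SCALP_CHANNELS,
                       n_avg = c(3L, 5L, 10L),
                       methods = c("F1", "F2", "FS1", "FS2"),
                       classifiers = c("svm", "lda"),
                       low_hz = 0.1, high_hz = 25, filter_order = 2,
                       eeg_thr_uV = 50, eog_thr_uV = 80,
                       ds_factor = 8,
                       fs_mode = "train", fs_threshold = "auto",
                       fs_increment = 0.1) {
  structure(list(seed = seed, schedule_config = schedule_config,
                 subject = subject, channels = channels, n_avg = n_avg,
                 methods = methods, classifiers = classifiers,
                 low_hz = low_hz, high_hz = high_hz,
                 filter_order = filter_order,
                 eeg_thr_uV = eeg_thr_uV, eog_thr_uV = eog_thr_uV,
                 ds_factor = ds_factor, fs_mode = fs_mode,
                 fs_threshold = fs_threshold, fs_increment = fs_increment),
            class = "run_config")
}

#' Run the full decoding pipeline on one (synthetic or loaded) recording
#'
#' Schedule -> simulation (unless a recording is supplied) -> bandpass ->
#' epoching -> baseline correction -> artifact rejection -> cluster
#' assignment, then leave-one-out cross-validation for every channel x
#' method x n_avg x classifier combination. Fully deterministic given the
#' seeds in the configuration.
#'
#' @param config a [run_config()].
#' @param recording optional pre-loaded `eeg_recording`; when NULL a
#'   recording is simulated from the configured schedule and subject.
#' @return list with `results` (one row per combination: channel, method,
#'   n_avg, classifier, accuracy_pct, confusion entries, n_folds), `best`
#'   (highest-accuracy row per classifier/method/n_avg), `rejection`
#'   (per-cluster kept/rejected counts), and `m_per_n_avg`.
#' @export
run_pipeline <- function(config = run_config(), recording = NULL) {
  if (is.null(recording)) {
    schedule <- generate_schedule(config$schedule_config)
    recording <- simulate_recording(schedule, config$subject)
  }
  recording <- bandpass_filter(recording, config$low_hz, config$high_hz,
                               config$filter_order)
  ep <- epoch_recording(recording)
  ep <- baseline_correct(ep)
  ep <- reject_artifacts(ep, config$eeg_thr_uV, config$eog_thr_uV)
  cs <- assign_clusters(ep)

  rows <- list()
  m_per <- integer(0)
  for (n in config$n_avg) {
    grouped <- balance_and_group(cs, n)
    m_per[as.character(n)] <- grouped$m
    for (ch in config$channels) {
      serps <- cluster_serps(grouped, ch, config$ds_factor)
      for (meth in config$methods) {
        for (clf in config$classifiers) {
          cv <- loo_crossval(serps, meth, classifier_spec(clf),
                             fs_mode = config$fs_mode,
                             fs_threshold = config$fs_threshold,
                             fs_increment = config$fs_increment)
          rows[[length(rows) + 1]] <- data.frame(
            channel = ch, method = meth, n_avg = n, classifier = clf,
            accuracy_pct = cv$accuracy_pct,
            tp_d = cv$confusion_pct[["TP_D"]],
            fp_d = cv$confusion_pct[["FP_D"]],
            fp_v = cv$confusion_pct[["FP_V"]],
            tp_v = cv$confusion_pct[["TP_V"]],
            n_folds = cv$n_folds, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  combo <- interaction(results$method, results$n_avg, results$classifier)
  best <- do.call(rbind, lapply(split(results, combo), function(d)
    d[which.max(d$accuracy_pct), ]))
  rownames(best) <- NULL
  list(results = results, best = best, rejection = ep$rejection,
       m_per_n_avg = m_per)
}

#' Write pipeline results as JSON
#'
#' @param results the `results` data.frame of [run_pipeline()] (or the full
#'   bundle).
#' @param path output path.
#' @export
write_results_json <- function(results, path) {
  if (is.list(results) && !is.data.frame(results))
    results <- results$results
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
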