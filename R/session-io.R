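#' Construct a ContinuousStreams object
#'
#' @param sbp1ms time x channel matrix of per-ms rectified sums.
#' @param rawSampleCount1ms matching integer matrix of 2 kHz sample counts.
#' @param crossingTimes per-channel list of sorted event times (ms).
#' @param fingerPosition time x 2 percent-flexion matrix at 1 kHz.
#' @param emg optional time x channel EMG matrix.
#' @param emgRateHz sampling rate of `emg`.
#' @param originMs session-clock time of the first sample.
#' @return a validated [ContinuousStreams-class] object.
#' @export
continuousStreams <- function(sbp1ms, rawSampleCount1ms, crossingTimes,
                              fingerPosition,
                              emg = matrix(numeric(0), 0, 0),
                              emgRateHz = 10000, originMs = 0L) {
  new("ContinuousStreams", sbp1ms = sbp1ms,
      rawSampleCount1ms = rawSampleCount1ms,
      crossingTimes = crossingTimes, fingerPosition = fingerPosition,
      emg = emg, emgRateHz = emgRateHz, originMs = as.integer(originMs))
}

#' Construct a SessionRecord
#'
#' @param trials data.frame of trial records (see [SessionRecord-class]).
#' @param streams a [ContinuousStreams-class] object.
#' @param monkeyId subject identifier.
#' @param nChannels number of neural channels.
#' @param contextBlockLabels per-trial block id; inferred from runs of equal
#'   context when omitted.
#' @param groundTruth optional generator ground-truth list.
#' @return a validated [SessionRecord-class] object.
#' @export
sessionRecord <- function(trials, streams, monkeyId = "synthetic",
                          nChannels = ncol(streams@sbp1ms),
                          contextBlockLabels = NULL,
                          groundTruth = list()) {
  if (is.null(contextBlockLabels)) {
    contextBlockLabels <- if (nrow(trials))
      cumsum(c(1L, diff(as.integer(factor(trials$context,
                                          levels = .CONTEXTS))) != 0L))
    else integer(0)
  }
  new("SessionRecord", monkeyId = monkeyId, nChannels = as.integer(nChannels),
      trials = trials, streams = streams,
      contextBlockLabels = as.integer(contextBlockLabels),
      groundTruth = groundTruth)
}

.SCHEMA_VERSION <- "1.0"

#' Write a session to a plain-text container
#'
#' Serializes a [SessionRecord-class] to a directory holding a CSV trial
#' table, per-stream CSV matrices, a long-format crossing-time table, and a
#' YAML metadata file. The layout is deterministic given identical input
#' and round-trips losslessly through [readSession()].
#'
#' @param session a valid SessionRecord.
#' @param path directory to create (must not be a regular file).
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "SessionRecord"))
  validObject(session)
  if (file.exists(path) && !dir.exists(path))
    .stopf("writeSession: '%s' exists and is not a directory", path)
  dir.create(file.path(path, "streams"), recursive = TRUE, showWarnings = FALSE)
  st <- session@streams

  meta <- list(schema_version = .SCHEMA_VERSION,
               monkey_id = session@monkeyId,
               n_channels = session@nChannels,
               origin_ms = st@originMs,
               emg_rate_hz = st@emgRateHz,
               context_block_labels = as.integer(session@contextBlockLabels))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))

  data.table::fwrite(session@trials, file.path(path, "trials.csv"))

  .wmat <- function(m, f) data.table::fwrite(
    data.table::as.data.table(m), file.path(path, "streams", f),
    col.names = FALSE)
  .wmat(st@sbp1ms, "sbp_1ms.csv")
  .wmat(st@rawSampleCount1ms, "raw_count_1ms.csv")
  .wmat(st@fingerPosition, "finger_pos.csv")
  if (length(st@emg)) .wmat(st@emg, "emg.csv")

  cr <- data.table::data.table(
    channel = rep(seq_along(st@crossingTimes),
                  lengths(st@crossingTimes)),
    time_ms = unlist(st@crossingTimes, use.names = FALSE))
  data.table::fwrite(cr, file.path(path, "streams", "crossings.csv"))
  invisible(path)
}

#' Read a session from a plain-text container
#'
#' Inverse of [writeSession()]; all class invariants are re-validated on
#' read and violations raise a validation error listing the failures.
#'
#' @param path directory written by [writeSession()].
#' @return a validated [SessionRecord-class] object.
#' @export
readSession <- function(path) {
  if (!dir.exists(path))
    .stopf("readSession: container '%s' not found", path)
  need <- c("meta.yaml", "trials.csv",
            file.path("streams", c("sbp_1ms.csv", "raw_count_1ms.csv",
                                   "finger_pos.csv", "crossings.csv")))
  for (f in need)
    if (!file.exists(file.path(path, f)))
      .stopf("readSession: malformed container, missing '%s'", f)

  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.csv")))
  if (nrow(trials) == 0)
    trials <- trials[, intersect(.TRIAL_COLS, names(trials)), drop = FALSE]
  missing_cols <- setdiff(.TRIAL_COLS, names(trials))
  if (length(missing_cols))
    .stopf("readSession: trial table missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  trials$success <- as.logical(trials$success)
  trials$decoder_id <- as.character(trials$decoder_id)

  .rmat <- function(f, int = FALSE) {
    m <- as.matrix(data.table::fread(file.path(path, "streams", f),
                                     header = FALSE))
    dimnames(m) <- NULL
    if (int) storage.mode(m) <- "integer"
    m
  }
  sbp <- .rmat("sbp_1ms.csv")
  cnt <- .rmat("raw_count_1ms.csv", int = TRUE)
  fp <- .rmat("finger_pos.csv")
  emg <- if (file.exists(file.path(path, "streams", "emg.csv")))
    .rmat("emg.csv") else matrix(numeric(0), 0, 0)

  cr <- data.table::fread(file.path(path, "streams", "crossings.csv"))
  crossings <- rep(list(numeric(0)), meta$n_channels)
  if (nrow(cr)) {
    sp <- split(cr$time_ms, factor(cr$channel, levels = seq_len(meta$n_channels)))
    crossings <- lapply(sp, as.numeric)
    names(crossings) <- NULL
  }

  st <- continuousStreams(sbp, cnt, crossings, fp, emg,
                          emgRateHz = meta$emg_rate_hz,
                          originMs = meta$origin_ms)
  sessionRecord(trials, st, monkeyId = meta$monkey_id,
                nChannels = meta$n_channels,
                contextBlockLabels = meta$context_block_labels %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select trials for offline analysis
#'
#' Returns successful trials, additionally excluding any trial that
#' immediately follows an unsuccessful one; input order is preserved.
#'
#' @param session a SessionRecord (or a trial data.frame).
#' @return the retained rows of the trial table.
#' @export
selectAnalysisTrials <- function(session) {
  tr <- if (is(session, "SessionRecord")) session@trials else session
  if (nrow(tr) == 0) return(tr)
  prev_failed <- c(FALSE, !tr$success[-nrow(tr)])
  tr[tr$success & !prev_failed, , drop = FALSE]
}

#' Extract the streams of one trial window
#'
#' Crops all streams to `[presentation - padBefore, end + padAfter)`.
#' Times in the result are relative to the window start; the original
#' session-clock offset is recorded in `originMs`.
#'
#' @param streams a [ContinuousStreams-class] object (session clock).
#' @param trial one row of a trial table.
#' @param padBeforeMs,padAfterMs window padding in ms.
#' @return a ContinuousStreams slice.
#' @export
sliceTrial <- function(streams, trial, padBeforeMs = 0, padAfterMs = 0) {
  t0 <- trial$presentation_time_ms - padBeforeMs
  t1 <- trial$end_time_ms + padAfterMs
  nT <- nrow(streams@sbp1ms)
  lo <- t0 - streams@originMs      # 0-based index of first ms in window
  hi <- t1 - streams@originMs
  if (lo < 0 || hi > nT)
    .stopf("sliceTrial: window [%d, %d) outside session bounds [%d, %d)",
           t0, t1, streams@originMs, streams@originMs + nT)
  idx <- seq.int(lo + 1L, hi)
  crossings <- lapply(streams@crossingTimes, function(ct)
    ct[ct >= t0 & ct < t1] - t0)
  emg <- streams@emg
  if (length(emg)) {
    r <- streams@emgRateHz / 1000        # samples per ms
    emg <- emg[seq.int(lo * r + 1L, hi * r), , drop = FALSE]
  }
  continuousStreams(streams@sbp1ms[idx, , drop = FALSE],
                    streams@rawSampleCount1ms[idx, , drop = FALSE],
                    crossings,
                    streams@fingerPosition[idx, , drop = FALSE],
                    emg, emgRateHz = streams@emgRateHz,
                    originMs = as.integer(t0))
}
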