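## Session container format: a directory holding a UTF-8 JSON manifest
## (probe, fs, per-trial epochs/conditions, performance, metadata) and one
## little-endian float32 binary per trial, channel-major.

epochsToList <- function(ep) {
  list(fsRaw = ep@fsRaw, baselineMs = ep@baselineMs,
       stimOnsetMs = ep@stimOnsetMs, staticEndMs = ep@staticEndMs,
       mcBoundsMs = ep@mcBoundsMs, leverReleaseMs = ep@leverReleaseMs,
       analysisEndMs = ep@analysisEndMs)
}

epochsFromList <- function(x) {
  new("TrialEpochs", fsRaw = x$fsRaw, baselineMs = as.numeric(x$baselineMs),
      stimOnsetMs = x$stimOnsetMs, staticEndMs = x$staticEndMs,
      mcBoundsMs = as.numeric(x$mcBoundsMs),
      leverReleaseMs = if (is.null(x$leverReleaseMs) ||
                           length(x$leverReleaseMs) == 0L) NA_real_
                       else as.numeric(x$leverReleaseMs),
      analysisEndMs = x$analysisEndMs)
}

#' Write a session to a directory
#'
#' Serializes a \linkS4class{Session} as a JSON manifest plus one
#' little-endian 32-bit float binary per trial (channel-major). The format
#' round-trips losslessly at float32 precision via \code{\link{readSession}}.
#'
#' @param session a \linkS4class{Session}
#' @param path directory to create/fill
#' @return \code{path}, invisibly
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "Session"))
  validObject(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  trials <- session@trials
  manifest <- list(
    format = "laminarGamma-session-v1",
    probe = list(nChannels = session@probe@nChannels,
                 pitchUm = session@probe@pitchUm),
    fs = if (length(trials)) trials[[1L]]@fs else NA_real_,
    performance = session@performance,
    metadata = session@metadata,
    trials = lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      list(file = sprintf("trial_%04d.f32", i),
           nChannels = nrow(tr@data), nSamples = ncol(tr@data),
           epochs = epochsToList(tr@epochs),
           condition = list(attention = tr@condition@attention,
                            rfStimPresent = tr@condition@rfStimPresent,
                            nearbyStimPresent = tr@condition@nearbyStimPresent,
                            correct = tr@condition@correct))
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  for (i in seq_along(trials)) {
    con <- file(file.path(path, sprintf("trial_%04d.f32", i)), "wb")
    ## channel-major: all samples of channel 1, then channel 2, ...
    writeBin(as.numeric(t(trials[[i]]@data)), con, size = 4L,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of \code{\link{writeSession}}; re-validates all invariants.
#'
#' @param path session directory
#' @return a \linkS4class{Session}
#' @export
readSession <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  probe <- probeGeometry(m$probe$nChannels, m$probe$pitchUm)
  trials <- lapply(m$trials, function(ti) {
    f <- file.path(path, ti$file)
    if (!file.exists(f)) stop("missing trial binary: ", ti$file)
    nval <- ti$nChannels * ti$nSamples
    if (file.size(f) != 4L * nval)
      stop("manifest/binary size mismatch for ", ti$file)
    con <- file(f, "rb")
    x <- readBin(con, numeric(), n = nval, size = 4L, endian = "little")
    close(con)
    broadbandTrial(matrix(x, nrow = ti$nChannels, byrow = TRUE),
                   fs = m$fs, epochs = epochsFromList(ti$epochs),
                   condition = condition(ti$condition$attention,
                                         ti$condition$rfStimPresent,
                                         ti$condition$nearbyStimPresent,
                                         ti$condition$correct))
  })
  s <- session(probe, trials, performance = m$performance,
               metadata = if (is.null(m$metadata)) list() else m$metadata)
  validObject(s)
  s
}

#' Epoch window lookup
#'
#' Resolves a named epoch to a half-open \code{[start, end)} interval in ms
#' from trial start. \code{"baseline"} is the baseline period; \code{"mcN"}
#' the N-th morph cycle; \code{"mc23"} runs from the start of MC2 to the
#' analysis end (150 ms before lever release when that falls inside the
#' window, else the end of MC3); \code{"onset250"} the first 250 ms after
#' stimulus onset.
#'
#' @param epochs a \linkS4class{TrialEpochs}
#' @param name epoch name
#' @return numeric length 2, c(startMs, endMs)
#' @export
epochWindow <- function(epochs, name) {
  b <- epochs@mcBoundsMs
  switch(name,
    baseline = epochs@baselineMs,
    mc1 = c(b[1L], b[2L]),
    mc2 = c(b[2L], b[3L]),
    mc3 = c(b[3L], min(b[4L], epochs@analysisEndMs)),
    mc23 = c(b[2L], epochs@analysisEndMs),
    onset250 = c(epochs@stimOnsetMs, epochs@stimOnsetMs + 250),
    stop("unknown epoch name: ", name))
}

#' Slice an epoch out of a trial
#'
#' Returns the samples within a half-open window \code{[start, end)} (ms from
#' trial start). Adjacent windows concatenate to the original samples
#' exactly. The window may be an epoch name understood by
#' \code{\link{epochWindow}} or a numeric \code{c(startMs, endMs)}.
#'
#' @param trial any trial object (broadband or derived)
#' @param window epoch name or numeric length 2 (ms)
#' @return channels x samples matrix (possibly zero columns)
#' @export
sliceEpoch <- function(trial, window) {
  if (is.character(window)) window <- epochWindow(trial@epochs, window)
  stopifnot(length(window) == 2L)
  n <- ncol(trial@data)
  durMs <- n / trial@fs * 1000
  if (window[1L] < 0 || window[2L] > durMs + 1e-9)
    stop(sprintf("window [%g, %g) outside trial duration %g ms",
                 window[1L], window[2L], durMs))
  idx <- halfOpenIdx(window[1L], window[2L], trial@fs)
  trial@data[, idx, drop = FALSE]
}
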