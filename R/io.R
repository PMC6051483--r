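# File formats.
#
# Delimited dialect: comma-separated, "." decimal, UTF-8, one header line.
# Lines starting with "#" before the header carry "key=value" metadata
# (t_start, t_stop, n_rows, ...); when n_rows is declared, readers verify it
# and reject silently-truncated files.
#
# Container format: a single versioned RDS file holding named numeric arrays
# plus scalar attributes (tagged "lfpdec-container"). Round trip is exact to
# full floating precision. An HDF5-like hierarchical layout would serve the
# same purpose; no R HDF5 bindings are declared by this package, so the
# container is realized with R's native serialization.

CONTAINER_TAG <- "lfpdec-container"
CONTAINER_VERSION <- 1L

readDelimited <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  metaIdx <- grep("^#", lines)
  metaIdx <- metaIdx[metaIdx == seq_along(metaIdx)]   # leading block only
  meta <- list()
  for (ln in lines[metaIdx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), metaIdx)]
  if (length(body) < 1L) stop("missing header line", call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (!is.null(meta$n_rows) && length(rows) != as.integer(meta$n_rows))
    stop(sprintf("truncated file: %d data rows found, %s declared",
                 length(rows), meta$n_rows), call. = FALSE)
  list(header = header, rows = rows, meta = meta,
       firstDataLine = length(metaIdx) + 2L)
}

parseNumericField <- function(x, lineNo, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & nzchar(x))
  if (length(bad))
    stop(sprintf("parse error at line %d: '%s' is not a number (column %s)",
                 lineNo[bad[1]], x[bad[1]], field), call. = FALSE)
  v
}

writeHeaderedCsv <- function(path, meta, header, body) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(sprintf("# %s=%s", names(meta), vapply(meta, as.character, "")),
             paste(header, collapse = ","), body)
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

fmtNum <- function(x) formatC(x, format = "g", digits = 17)

# ---------------------------------------------------------------------------

#' Read / write spike event times
#'
#' Delimited layout: header `unit_id,time_s`, one row per spike; a row with
#' an empty `time_s` field declares a unit with zero spikes. The recording
#' span is carried in leading `# t_start=` / `# t_stop=` metadata lines (and
#' defaults to the span of the data).
#'
#' @param path file path.
#' @param format "delimited" (CSV) or "container" (binary array container).
#' @return [readSpikes()] returns a validated [SpikeTrainSet-class].
#' @export
readSpikes <- function(path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (format == "container") {
    x <- readContainerFile(path, "spikes")
    return(SpikeTrainSet(unitIds = x$attrs$unit_ids,
                         spikeTimes = x$arrays$spike_times,
                         tStart = x$attrs$t_start, tStop = x$attrs$t_stop,
                         areaLabels = x$attrs$area_labels))
  }
  d <- readDelimited(path)
  if (!identical(d$header, c("unit_id", "time_s")))
    stop("spike file must have header 'unit_id,time_s'", call. = FALSE)
  if (length(d$rows) == 0L) {
    t0 <- as.numeric(d$meta$t_start %||% 0)
    t1 <- as.numeric(d$meta$t_stop %||% 1)
    return(SpikeTrainSet(character(), list(), t0, t1, character()))
  }
  parts <- strsplit(d$rows, ",", fixed = TRUE)
  uid <- vapply(parts, `[`, "", 1L)
  tms <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else "", "")
  lineNo <- seq_along(d$rows) + d$firstDataLine - 1L
  tt <- parseNumericField(tms, lineNo, "time_s")
  units <- unique(uid)
  st <- lapply(units, function(u) {
    v <- tt[uid == u]
    v <- v[!is.na(v)]
    v
  })
  for (i in seq_along(units))
    if (is.unsorted(st[[i]]))
      stop(sprintf("spike times of unit '%s' are not sorted", units[i]),
           call. = FALSE)
  allT <- unlist(st)
  t0 <- as.numeric(d$meta$t_start %||%
                     (if (length(allT)) floor(min(allT)) else 0))
  t1 <- as.numeric(d$meta$t_stop %||%
                     (if (length(allT)) ceiling(max(allT)) else 1))
  SpikeTrainSet(units, st, t0, t1)
}

#' @rdname readSpikes
#' @param spikes a [SpikeTrainSet-class] to write.
#' @export
writeSpikes <- function(spikes, path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (format == "container") {
    return(writeContainerFile(path, "spikes",
      arrays = list(spike_times = spikes@spikeTimes),
      attrs = list(unit_ids = spikes@unitIds, area_labels = spikes@areaLabels,
                   t_start = spikes@tStart, t_stop = spikes@tStop)))
  }
  body <- unlist(lapply(seq_along(spikes@unitIds), function(i) {
    st <- spikes@spikeTimes[[i]]
    if (length(st) == 0L) return(paste0(spikes@unitIds[i], ","))
    paste0(spikes@unitIds[i], ",", fmtNum(st))
  }))
  writeHeaderedCsv(path,
    meta = list(t_start = fmtNum(spikes@tStart), t_stop = fmtNum(spikes@tStop),
                n_rows = length(body)),
    header = c("unit_id", "time_s"), body = body)
}

#' Read / write multichannel LFP
#'
#' Delimited layout: first column `time_s`, remaining columns one per
#' channel; the header supplies channel identifiers. Sampling must be
#' uniform (successive dt within 1e-6 of the nominal dt); the sampling rate
#' is inferred from the time column.
#'
#' @param path file path.
#' @param format "delimited" or "container".
#' @return [readLfp()] returns a validated [LfpRecording-class].
#' @export
readLfp <- function(path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (format == "container") {
    x <- readContainerFile(path, "lfp")
    return(LfpRecording(x$arrays$samples, fs = x$attrs$fs,
                        channelIds = x$attrs$channel_ids,
                        areaLabels = x$attrs$area_labels,
                        tStart = x$attrs$t_start))
  }
  d <- readDelimited(path)
  if (d$header[1] != "time_s")
    stop("LFP file must have first column 'time_s'", call. = FALSE)
  if (length(d$rows) < 2L) stop("need at least 2 samples", call. = FALSE)
  parts <- strsplit(d$rows, ",", fixed = TRUE)
  ncol <- length(d$header)
  lens <- lengths(parts)
  if (any(lens != ncol))
    stop(sprintf("malformed row at line %d: %d fields, %d expected",
                 which(lens != ncol)[1] + d$firstDataLine - 1L,
                 lens[lens != ncol][1], ncol), call. = FALSE)
  lineNo <- seq_along(d$rows) + d$firstDataLine - 1L
  m <- matrix(0, length(parts), ncol)
  for (j in seq_len(ncol))
    m[, j] <- parseNumericField(vapply(parts, `[`, "", j), lineNo,
                                d$header[j])
  tt <- m[, 1]
  dt <- diff(tt)
  dtNom <- stats::median(dt)
  if (dtNom <= 0 || max(abs(dt - dtNom)) > 1e-6 * dtNom)
    stop("non-uniform sampling: time column deviates from a fixed dt",
         call. = FALSE)
  LfpRecording(m[, -1, drop = FALSE], fs = 1 / dtNom,
               channelIds = d$header[-1], tStart = tt[1])
}

#' @rdname readLfp
#' @param lfp an [LfpRecording-class] to write.
#' @export
writeLfp <- function(lfp, path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (format == "container") {
    return(writeContainerFile(path, "lfp",
      arrays = list(samples = lfp@samples),
      attrs = list(fs = lfp@fs, channel_ids = lfp@channelIds,
                   area_labels = lfp@areaLabels, t_start = lfp@tStart)))
  }
  tt <- timeAxis(lfp)
  body <- apply(cbind(tt, lfp@samples), 1L,
                function(r) paste(fmtNum(r), collapse = ","))
  writeHeaderedCsv(path, meta = list(n_rows = length(body)),
                   header = c("time_s", lfp@channelIds), body = body)
}

#' Read / write 2D cursor kinematics
#'
#' Delimited layout: header `time_s,x,y`.
#'
#' @param path file path.
#' @return [readKinematics()] returns a [KinematicsTrace-class].
#' @export
readKinematics <- function(path) {
  d <- readDelimited(path)
  if (!identical(d$header, c("time_s", "x", "y")))
    stop("kinematics file must have header 'time_s,x,y'", call. = FALSE)
  parts <- strsplit(d$rows, ",", fixed = TRUE)
  lineNo <- seq_along(d$rows) + d$firstDataLine - 1L
  tt <- parseNumericField(vapply(parts, `[`, "", 1L), lineNo, "time_s")
  x <- parseNumericField(vapply(parts, `[`, "", 2L), lineNo, "x")
  y <- parseNumericField(vapply(parts, `[`, "", 3L), lineNo, "y")
  KinematicsTrace(tt, cbind(x, y))
}

#' @rdname readKinematics
#' @param kin a [KinematicsTrace-class] to write.
#' @export
writeKinematics <- function(kin, path) {
  body <- apply(cbind(kin@times, kin@position), 1L,
                function(r) paste(fmtNum(r), collapse = ","))
  writeHeaderedCsv(path, meta = list(n_rows = length(body)),
                   header = c("time_s", "x", "y"), body = body)
}

# ---------------------------------------------------------------------------
# Container plumbing
# ---------------------------------------------------------------------------

writeContainerFile <- function(path, kind, arrays, attrs) {
  obj <- list(format = CONTAINER_TAG, version = CONTAINER_VERSION,
              kind = kind, arrays = arrays, attrs = attrs)
  saveRDS(obj, path)
  invisible(path)
}

readContainerFile <- function(path, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("corrupt container file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, CONTAINER_TAG))
    stop(sprintf("'%s' is not an lfpdec container", path), call. = FALSE)
  if (!identical(obj$version, CONTAINER_VERSION))
    stop(sprintf("container version mismatch: file has %s, package expects %d",
                 format(obj$version), CONTAINER_VERSION), call. = FALSE)
  if (!is.null(kind) && !identical(obj$kind, kind))
    stop(sprintf("container holds '%s', '%s' expected", obj$kind, kind),
         call. = FALSE)
  obj
}

#' Persist / load fitted models
#'
#' Models travel as a [ModelContainer-class] (kind + metadata + named
#' numeric arrays) in the package container format. `readModel(writeModel(m))`
#' is the identity: bit-exact for metadata, full floating precision for
#' arrays.
#'
#' @param model a [ModelContainer-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "ModelContainer"))
  validObject(model)
  writeContainerFile(path, "model",
                     arrays = model@payload,
                     attrs = list(model_kind = model@modelKind,
                                  metadata = model@metadata))
}

#' @rdname writeModel
#' @return [readModel()] returns the stored [ModelContainer-class].
#' @export
readModel <- function(path) {
  x <- readContainerFile(path, "model")
  ModelContainer(x$attrs$model_kind, payload = x$arrays,
                 metadata = x$attrs$metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write submovement event tables
#'
#' Delimited layout: header
#' `time_s,speed,direction_rad,window_start_s,window_end_s`.
#'
#' @param path file path.
#' @return [readEvents()] returns a [SubmovementEvents-class].
#' @export
readEvents <- function(path) {
  d <- readDelimited(path)
  expect <- c("time_s", "speed", "direction_rad", "window_start_s",
              "window_end_s")
  if (!identical(d$header, expect))
    stop(sprintf("events file must have header '%s'",
                 paste(expect, collapse = ",")), call. = FALSE)
  parts <- strsplit(d$rows, ",", fixed = TRUE)
  lineNo <- seq_along(d$rows) + d$firstDataLine - 1L
  col <- function(j) parseNumericField(vapply(parts, `[`, "", j), lineNo,
                                       expect[j])
  new("SubmovementEvents", times = col(1), speeds = col(2),
      directions = col(3), windowStart = col(4), windowEnd = col(5))
}

#' @rdname readEvents
#' @param events a [SubmovementEvents-class] to write.
#' @export
writeEvents <- function(events, path) {
  df <- as.data.frame(events)
  body <- apply(df, 1L, function(r) paste(fmtNum(as.numeric(r)),
                                          collapse = ","))
  writeHeaderedCsv(path, meta = list(n_rows = nrow(df)),
                   header = names(df), body = if (nrow(df)) body
                   else character())
}

# ---------------------------------------------------------------------------
# ModelContainer converters for the package's fitted-model classes
# ---------------------------------------------------------------------------

#' Convert fitted models to and from portable containers
#'
#' @param model an [SrspModel-class], [RateDecoder-class] or list of
#'   [ProjectionPlane-class] objects.
#' @param metadata extra provenance entries to store.
#' @return `asModelContainer()` returns a [ModelContainer-class];
#'   `srspFromContainer()`, `decoderFromContainer()` and
#'   `planesFromContainer()` rebuild the corresponding objects.
#' @export
asModelContainer <- function(model, metadata = list()) {
  stamp <- c(metadata, list(created = format(Sys.time(), tz = "UTC"),
                            package_version = as.character(
                              utils::packageVersion("lfpdec"))))
  if (is(model, "SrspModel")) {
    ModelContainer("srsp",
      payload = list(kernels = model@kernels, lags = model@lags,
                     offsets = model@offsets, vaf = model@vaf),
      metadata = c(stamp, list(bin_width = model@binWidth,
                               ridge = model@ridge,
                               unit_ids = model@unitIds,
                               channel_ids = model@channelIds)))
  } else if (is(model, "RateDecoder")) {
    ModelContainer("rate_decoder",
      payload = c(stats::setNames(model@filters,
                                  paste0("filter_", model@unitIds)),
                  list(lags = model@lags, offsets = model@offsets)),
      metadata = c(stamp, list(bin_width = model@binWidth, nsr = model@nsr,
                               unit_ids = model@unitIds,
                               channel_ids = model@channelIds)))
  } else if (is.list(model) && all(vapply(model, is, TRUE, "ProjectionPlane"))) {
    pay <- list()
    for (i in seq_along(model)) {
      pay[[paste0("u_", i)]] <- model[[i]]@u
      pay[[paste0("v_", i)]] <- model[[i]]@v
    }
    ModelContainer("rotation", payload = pay,
      metadata = c(stamp, list(
        n_planes = length(model),
        provenance = vapply(model, function(p) p@provenance, ""),
        freq_hz = vapply(model, function(p) p@freqHz, 0))))
  } else stop("unsupported model type", call. = FALSE)
}

#' @rdname asModelContainer
#' @param container a [ModelContainer-class].
#' @export
srspFromContainer <- function(container) {
  stopifnot(identical(container@modelKind, "srsp"))
  m <- container@metadata
  new("SrspModel", kernels = container@payload$kernels,
      lags = as.numeric(container@payload$lags), binWidth = m$bin_width,
      offsets = as.numeric(container@payload$offsets), ridge = m$ridge,
      vaf = as.numeric(container@payload$vaf),
      unitIds = m$unit_ids, channelIds = m$channel_ids)
}

#' @rdname asModelContainer
#' @export
decoderFromContainer <- function(container) {
  stopifnot(identical(container@modelKind, "rate_decoder"))
  m <- container@metadata
  new("RateDecoder",
      filters = unname(container@payload[paste0("filter_", m$unit_ids)]),
      lags = as.numeric(container@payload$lags), binWidth = m$bin_width,
      offsets = as.numeric(container@payload$offsets), nsr = m$nsr,
      unitIds = m$unit_ids, channelIds = m$channel_ids)
}

#' @rdname asModelContainer
#' @export
planesFromContainer <- function(container) {
  stopifnot(identical(container@modelKind, "rotation"))
  m <- container@metadata
  lapply(seq_len(m$n_planes), function(i)
    ProjectionPlane(container@payload[[paste0("u_", i)]],
                    container@payload[[paste0("v_", i)]],
                    provenance = m$provenance[i], freqHz = m$freq_hz[i]))
}
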