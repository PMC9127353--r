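#' Channel map for TDMS drinkometer files
#'
#' Describes where in a TDMS file the consumed-volume signal lives. Channels
#' are addressed as `"group/channel"`.
#'
#' @param volume_channel channel carrying cumulative volume.
#' @param time_channel optional channel carrying sample times in seconds; used
#'   to infer the sampling rate when the volume channel has no `wf_increment`
#'   property.
#' @param unit_scale multiplicative factor applied to the stored values to
#'   obtain ml (e.g. 1000 when the device logs litres). Must be > 0.
#' @return an object of class `channel_map`.
#' @export
channel_map <- function(volume_channel, time_channel = NULL, unit_scale = 1) {
  if (!is.numeric(unit_scale) || unit_scale <= 0) {
    stop("unit_scale must be > 0", call. = FALSE)
  }
  structure(list(volume_channel = volume_channel,
                 time_channel = time_channel,
                 unit_scale = as.numeric(unit_scale)),
            class = "channel_map")
}

# --- minimal TDMS (NI binary format) support ------------------------------
# Only the subset needed for drinkometer traces: little-endian segments,
# float64 channel data, non-interleaved layout, basic property types. The
# device's .info and .tdms_index companions are treated as opaque.

.tdms_type <- list(i32 = 3L, u32 = 7L, double = 10L, string = 32L)

.tdms_path <- function(channel) {
  parts <- strsplit(channel, "/", fixed = TRUE)[[1]]
  paste0("/", paste0("'", parts, "'", collapse = "/"))
}

.tdms_write_string <- function(con, s) {
  raw <- charToRaw(enc2utf8(s))
  writeBin(length(raw), con, size = 4, endian = "little")
  writeBin(raw, con)
}

#' Write a single-segment TDMS file (fixture writer)
#'
#' Writes one TDMS segment containing float64 channels, suitable for
#' round-trip testing of [read_trace_tdms()]. `channels` is a named list
#' mapping `"group/channel"` paths to either a numeric vector or a list with
#' elements `values` (numeric) and `props` (named list of numeric or string
#' properties, e.g. `wf_increment`).
#'
#' @param path output path (conventionally ending in `.tdms`).
#' @param channels named list of channel data (see above).
#' @return `path`, invisibly.
#' @export
write_tdms <- function(path, channels) {
  norm <- lapply(channels, function(ch) {
    if (is.numeric(ch)) list(values = as.numeric(ch), props = list())
    else list(values = as.numeric(ch$values),
              props = if (is.null(ch$props)) list() else ch$props)
  })

  meta_con <- rawConnection(raw(0), "wb")
  on.exit(tryCatch(close(meta_con), error = function(e) NULL), add = TRUE)
  n_obj <- length(norm) + 1L # root object + channels
  writeBin(n_obj, meta_con, size = 4, endian = "little")
  # root object, no raw data, no properties
  .tdms_write_string(meta_con, "/")
  writeBin(-1L, meta_con, size = 4, endian = "little") # 0xFFFFFFFF
  writeBin(0L, meta_con, size = 4, endian = "little")
  for (nm in names(norm)) {
    ch <- norm[[nm]]
    .tdms_write_string(meta_con, .tdms_path(nm))
    writeBin(20L, meta_con, size = 4, endian = "little") # raw index length
    writeBin(.tdms_type$double, meta_con, size = 4, endian = "little")
    writeBin(1L, meta_con, size = 4, endian = "little") # dimension
    nv <- length(ch$values)
    writeBin(c(as.integer(nv), 0L), meta_con, size = 4, endian = "little")
    writeBin(length(ch$props), meta_con, size = 4, endian = "little")
    for (pn in names(ch$props)) {
      pv <- ch$props[[pn]]
      .tdms_write_string(meta_con, pn)
      if (is.character(pv)) {
        writeBin(.tdms_type$string, meta_con, size = 4, endian = "little")
        .tdms_write_string(meta_con, pv)
      } else {
        writeBin(.tdms_type$double, meta_con, size = 4, endian = "little")
        writeBin(as.numeric(pv), meta_con, size = 8, endian = "little")
      }
    }
  }
  meta <- rawConnectionValue(meta_con)

  raw_con <- rawConnection(raw(0), "wb")
  on.exit(tryCatch(close(raw_con), error = function(e) NULL), add = TRUE)
  for (ch in norm) writeBin(ch$values, raw_con, size = 8, endian = "little")
  rawdata <- rawConnectionValue(raw_con)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("TDSm"), con)
  toc <- bitwOr(bitwOr(2L, 4L), 8L) # metadata + new object list + raw data
  writeBin(toc, con, size = 4, endian = "little")
  writeBin(4713L, con, size = 4, endian = "little")
  seg_len <- length(meta) + length(rawdata)
  writeBin(c(as.integer(seg_len), 0L), con, size = 4, endian = "little")
  writeBin(c(as.integer(length(meta)), 0L), con, size = 4, endian = "little")
  writeBin(meta, con)
  writeBin(rawdata, con)
  invisible(path)
}

.tdms_read_u32 <- function(con) {
  # R cannot read unsigned 32-bit directly; wrap negatives back to [0, 2^32)
  v <- readBin(con, "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.double(v)
}

.tdms_read_u64 <- function(con) {
  lo <- .tdms_read_u32(con); hi <- .tdms_read_u32(con)
  hi * 2^32 + lo
}

.tdms_read_string <- function(con) {
  n <- .tdms_read_u32(con)
  if (n == 0) return("")
  rawToChar(readBin(con, "raw", n = n))
}

.tdms_skip_property <- function(con) {
  name <- .tdms_read_string(con)
  type <- .tdms_read_u32(con)
  value <- if (type == .tdms_type$string) {
    .tdms_read_string(con)
  } else if (type == .tdms_type$double) {
    readBin(con, "double", size = 8, endian = "little")
  } else if (type %in% c(.tdms_type$i32, .tdms_type$u32)) {
    readBin(con, "integer", size = 4, endian = "little")
  } else {
    stop("I/O error: unsupported TDMS property type ", type, call. = FALSE)
  }
  list(name = name, value = value)
}

# Parse all segments of a TDMS file; returns list(channels=, properties=)
# with channel data concatenated across segments.
.tdms_parse <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  fsize <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  channels <- list()
  props <- list()
  index <- list() # per-channel persistent raw index (type, count)
  while (seek(con, where = NA) < fsize) {
    seg_start <- seek(con, where = NA)
    tag <- tryCatch(rawToChar(readBin(con, "raw", 4)), error = function(e) "")
    if (!identical(tag, "TDSm")) {
      stop("I/O error: not a TDMS segment at byte ", seg_start, call. = FALSE)
    }
    toc <- .tdms_read_u32(con)
    if (bitwAnd(toc, bitwShiftL(1L, 6L)) != 0) {
      stop("I/O error: big-endian TDMS files are not supported", call. = FALSE)
    }
    interleaved <- bitwAnd(toc, bitwShiftL(1L, 5L)) != 0
    if (interleaved) stop("I/O error: interleaved TDMS data not supported",
                          call. = FALSE)
    .tdms_read_u32(con) # version
    next_off <- .tdms_read_u64(con)
    raw_off <- .tdms_read_u64(con)
    data_start <- seg_start + 28 + raw_off
    order <- character(0)
    if (bitwAnd(toc, 2L) != 0) { # has metadata
      n_obj <- .tdms_read_u32(con)
      for (i in seq_len(n_obj)) {
        pth <- .tdms_read_string(con)
        idx <- .tdms_read_u32(con)
        if (idx == 0xFFFFFFFF) {
          # no raw data for this object
        } else if (idx == 0L) {
          order <- c(order, pth) # same index as previous segment
        } else {
          type <- .tdms_read_u32(con)
          .tdms_read_u32(con) # dimension
          count <- .tdms_read_u64(con)
          index[[pth]] <- list(type = type, count = count)
          order <- c(order, pth)
        }
        n_prop <- .tdms_read_u32(con)
        for (p in seq_len(n_prop)) {
          pr <- .tdms_skip_property(con)
          if (nchar(pth) > 1) {
            props[[pth]][[pr$name]] <- pr$value
          }
        }
      }
    }
    if (bitwAnd(toc, 8L) != 0) { # has raw data
      seek(con, data_start)
      for (pth in order) {
        ix <- index[[pth]]
        if (is.null(ix)) next
        if (ix$type != .tdms_type$double) {
          stop("I/O error: only float64 TDMS channels are supported",
               call. = FALSE)
        }
        vals <- readBin(con, "double", n = ix$count, size = 8,
                        endian = "little")
        channels[[pth]] <- c(channels[[pth]], vals)
      }
    }
    seek(con, seg_start + 28 + next_off)
  }
  list(channels = channels, properties = props)
}

#' Read a drinkometer volume trace from a TDMS file
#'
#' Reads the mapped volume channel of the device's native `.tdms` file. The
#' companion `.info` and `.tdms_index` files are accepted in `paths` but not
#' interpreted (their calibration payload is device-specific). The sampling
#' rate comes from, in order of precedence: the `fs` argument, the channel's
#' `wf_increment` property (fs = 1/increment), or the mapped time channel.
#'
#' @param paths path to the `.tdms` file, or a character vector containing the
#'   `.info`/`.tdms`/`.tdms_index` triplet (the `.tdms` entry is used).
#' @param map a [channel_map()].
#' @param fs optional sampling-rate override in Hz.
#' @param measurement_id measurement label; defaults to the file name.
#' @return a [volume_trace()], with values scaled by `map$unit_scale`.
#' @export
read_trace_tdms <- function(paths, map, fs = NULL, measurement_id = NULL) {
  tdms <- paths[grepl("\\.tdms$", paths)]
  if (length(tdms) == 0) tdms <- paths[1]
  tdms <- tdms[1]
  if (is.null(measurement_id)) measurement_id <- sub("\\.tdms$", "", basename(tdms))
  parsed <- .tdms_parse(tdms)
  key <- .tdms_path(map$volume_channel)
  if (!key %in% names(parsed$channels)) {
    stop("channel error: channel not found in TDMS file: ", map$volume_channel,
         call. = FALSE)
  }
  vol <- parsed$channels[[key]] * map$unit_scale
  if (is.null(fs)) {
    inc <- parsed$properties[[key]][["wf_increment"]]
    if (!is.null(inc) && inc > 0) {
      fs <- 1 / inc
    } else if (!is.null(map$time_channel)) {
      tkey <- .tdms_path(map$time_channel)
      if (!tkey %in% names(parsed$channels)) {
        stop("channel error: time channel not found: ", map$time_channel,
             call. = FALSE)
      }
      dt <- diff(parsed$channels[[tkey]])
      if (length(dt) == 0 || any(dt <= 0)) {
        stop("sampling error: unusable time channel", call. = FALSE)
      }
      fs <- 1 / stats::median(dt)
    } else {
      stop("sampling error: no fs override, no wf_increment property and no ",
           "time channel", call. = FALSE)
    }
  }
  volume_trace(vol, fs, measurement_id)
}

#' Write a volume trace as a TDMS fixture
#'
#' Convenience wrapper around [write_tdms()] placing the trace in a single
#' channel with a `wf_increment` property encoding the sampling rate.
#'
#' @param trace a [volume_trace()].
#' @param path output path.
#' @param channel channel path, default `"drink/volume"`.
#' @return `path`, invisibly.
#' @export
write_trace_tdms <- function(trace, path, channel = "drink/volume") {
  chans <- list()
  chans[[channel]] <- list(values = trace$volume,
                           props = list(wf_increment = 1 / trace$fs))
  write_tdms(path, chans)
}
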