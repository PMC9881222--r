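#' Write / read the native recording container
#'
#' The native container is a directory holding a JSON manifest
#' (`manifest.json`: schema version, start time, metadata, per-channel rate,
#' units, kind and sample count), one single-column CSV per channel, and the
#' event log as CSV. Round-trips are lossless to numeric precision; events
#' are preserved exactly.
#'
#' @param rec An [fp_recording()].
#' @param path Directory to create (overwritten if it exists).
#' @return `path`, invisibly (`write_recording`); an `fp_recording`
#'   (`read_recording`).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema_version = 1L,
    start_time = rec$start_time,
    metadata = rec$metadata,
    channels = lapply(names(rec$channels), function(nm) {
      c1 <- rec$channels[[nm]]
      list(name = nm, rate = c1$rate, units = c1$units, kind = c1$kind,
           n = length(c1$samples), file = paste0("channel_", nm, ".csv"))
    }),
    events_file = "events.csv"
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(rec$channels)) {
    readr::write_csv(tibble(value = rec$channels[[nm]]$samples),
                     file.path(path, paste0("channel_", nm, ".csv")))
  }
  events_to_csv(rec$events, file.path(path, "events.csv"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("no manifest.json under `%s`", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(as.integer(manifest$schema_version), 1L)) {
    abort("unsupported schema_version (expected 1)")
  }
  channels <- list()
  for (cm in manifest$channels) {
    f <- file.path(path, cm$file)
    if (!file.exists(f)) {
      abort(sprintf("schema error: channel `%s` file missing", cm$name))
    }
    vals <- readr::read_csv(f, col_types = readr::cols(value = readr::col_double()),
                            progress = FALSE)$value
    if (length(vals) != cm$n) {
      abort(sprintf("schema error: channel `%s` has %d samples, manifest says %d",
                    cm$name, length(vals), cm$n))
    }
    channels[[cm$name]] <- list(samples = vals, rate = cm$rate,
                                units = cm$units, kind = cm$kind)
  }
  events <- read_events_csv(file.path(path, manifest$events_file))
  fp_recording(channels, events = events,
               start_time = manifest$start_time,
               metadata = manifest$metadata)
}

#' Event log to/from CSV
#'
#' Columns `onset`, `duration`, `kind`, plus an `attributes` column holding
#' the remaining event fields as a JSON object, so arbitrary per-event
#' attributes survive the round-trip.
#'
#' @param events Event tibble.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_events_csv` returns the event tibble.
#' @export
events_to_csv <- function(events, path) {
  core <- c("onset", "duration", "kind")
  ev <- as_tibble(events)
  if (nrow(ev) == 0) {
    readr::write_csv(tibble(onset = numeric(), duration = numeric(),
                            kind = character(), attributes = character()),
                     path)
    return(invisible(path))
  }
  extra <- setdiff(names(ev), core)
  attrs <- vapply(seq_len(nrow(ev)), function(i) {
    as.character(jsonlite::toJSON(as.list(ev[i, extra, drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA))
  }, character(1))
  out <- dplyr::bind_cols(ev[, core], tibble(attributes = attrs))
  readr::write_csv(arrange(out, .data$onset), path)
  invisible(path)
}

#' @rdname events_to_csv
#' @export
read_events_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    onset = readr::col_double(), duration = readr::col_double(),
    kind = readr::col_character(), attributes = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) return(empty_events()[, c("onset", "duration", "kind")])
  extras <- purrr::map_dfr(raw$attributes, function(a) {
    as_tibble(jsonlite::fromJSON(a))
  })
  dplyr::bind_cols(raw[, c("onset", "duration", "kind")], extras)
}

#' Export EEG/EMG channels to EDF
#'
#' Writes a minimal EDF file (ASCII header, 1-s data records, little-endian
#' 16-bit samples scaled into each channel's physical range). All exported
#' channels must share one sampling rate, which must be a whole number per
#' second; a trailing partial second is dropped. EDF is 16-bit, so values
#' are reproduced on re-import to within one quantization step of the
#' physical range.
#'
#' @param rec An [fp_recording()].
#' @param channels Channel names to export (must be of kind eeg/emg).
#' @param path Output `.edf` path.
#' @return `path` invisibly.
#' @export
export_edf <- function(rec, channels, path) {
  chs <- rec$channels[channels]
  if (any(vapply(chs, is.null, logical(1)))) abort("unknown channel in `channels`")
  kinds <- vapply(chs, function(c1) c1$kind, character(1))
  if (!all(kinds %in% c("eeg", "emg"))) {
    abort("EDF export supports eeg/emg channels only")
  }
  rates <- vapply(chs, function(c1) c1$rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    abort("channels with non-uniform rates cannot share one EDF file")
  }
  rate <- rates[[1]]
  if (rate != round(rate)) abort("EDF export needs an integer per-second rate")
  ns <- length(chs)
  n_rec <- min(vapply(chs, function(c1) floor(length(c1$samples) / rate),
                      numeric(1)))
  if (n_rec < 1) abort("less than one full second of data to export")

  pad <- function(x, w) formatC(substr(x, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic subject", 80), pad("sleepfp export", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(as.character(256L * (ns + 1L)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(ns), 4)
  )
  # physical range is stored as 8-char ASCII; digitize against the stored
  # (rounded) values so reader and writer share one scaling
  phys_str <- lapply(chs, function(c1) {
    x <- c1$samples[seq_len(n_rec * rate)]
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    rng <- c(-1, 1) * max(abs(rng)) * 1.0001
    sprintf("%.6g", signif(rng, 6))
  })
  phys <- lapply(phys_str, as.numeric)
  fld <- function(f) paste(vapply(seq_len(ns), f, character(1)), collapse = "")
  hdr <- paste0(
    hdr,
    fld(function(i) pad(paste(toupper(kinds[i]), channels[i]), 16)),
    fld(function(i) pad("", 80)),
    fld(function(i) pad("uV", 8)),
    fld(function(i) pad(phys_str[[i]][1], 8)),
    fld(function(i) pad(phys_str[[i]][2], 8)),
    fld(function(i) pad("-32768", 8)),
    fld(function(i) pad("32767", 8)),
    fld(function(i) pad("", 80)),
    fld(function(i) pad(as.character(rate), 8)),
    fld(function(i) pad("", 32))
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  digitized <- lapply(seq_len(ns), function(i) {
    x <- chs[[i]]$samples[seq_len(n_rec * rate)]
    p <- phys[[i]]
    as.integer(round((x - p[1]) / (p[2] - p[1]) * 65535 - 32768))
  })
  for (rix in seq_len(n_rec)) {
    sel <- ((rix - 1) * rate + 1):(rix * rate)
    for (i in seq_len(ns)) {
      writeBin(digitized[[i]][sel], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname export_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  raw <- matrix(readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                        endian = "little", signed = TRUE),
                ncol = n_rec)
  offs <- cumsum(c(0, spr))
  channels <- list()
  for (i in seq_len(ns)) {
    d <- as.vector(raw[(offs[i] + 1):offs[i + 1], , drop = FALSE])
    x <- pmin_[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
    parts <- strsplit(labels[i], " ")[[1]]
    kind <- tolower(parts[1])
    nm <- if (length(parts) > 1) parts[2] else tolower(labels[i])
    channels[[nm]] <- list(samples = x, rate = spr[i] / rec_dur,
                           units = units[i],
                           kind = if (kind %in% c("eeg", "emg")) kind else "eeg")
  }
  fp_recording(channels)
}
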