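#' Read cell tracks from CSV
#'
#' Two dialects are supported and auto-detected from the header:
#' * `native`: columns `track_id, frame, x_um, y_um` (coordinates already in
#'   micrometres), as written by [write_tracks()] and the simulators;
#' * `imagej_manual_tracking`: the ImageJ Manual Tracking export with columns
#'   `Track n.`, `Slice n.`, `X`, `Y` in pixels; positions are converted with
#'   `pixel_size_um`.
#'
#' Malformed rows are rejected with their line numbers; duplicate or
#' non-monotone frames within a track are rejected.
#'
#' @param path CSV file path.
#' @param dialect `"auto"`, `"native"` or `"imagej_manual_tracking"`.
#' @param pixel_size_um px-to-um scale, used by the ImageJ dialect.
#' @param dt frame interval in seconds attached to every track.
#' @return a named list of [cil_track()]s.
#' @export
read_tracks <- function(path, dialect = c("auto", "native",
                                          "imagej_manual_tracking"),
                        pixel_size_um = 1, dt = 15) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("track file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(trimws(names(df)))
  if (dialect == "auto") {
    dialect <- if (all(c("track_id", "frame", "x_um", "y_um") %in% nm)) {
      "native"
    } else if (any(startsWith(nm, "track")) && any(startsWith(nm, "slice"))) {
      "imagej_manual_tracking"
    } else {
      stopf("cannot detect track dialect from header: %s",
            paste(names(df), collapse = ", "))
    }
  }
  if (dialect == "native") {
    need <- match(c("track_id", "frame", "x_um", "y_um"), nm)
    if (any(is.na(need))) stopf("native dialect needs columns track_id, frame, x_um, y_um")
    tab <- data.frame(id = df[[need[1]]], frame = df[[need[2]]],
                      x = df[[need[3]]], y = df[[need[4]]])
  } else {
    ti <- which(startsWith(nm, "track"))[1]
    si <- which(startsWith(nm, "slice"))[1]
    xi <- match("x", nm); yi <- match("y", nm)
    if (any(is.na(c(ti, si, xi, yi)))) {
      stopf("ImageJ dialect needs Track/Slice/X/Y columns")
    }
    tab <- data.frame(id = df[[ti]], frame = df[[si]],
                      x = df[[xi]] * pixel_size_um,
                      y = df[[yi]] * pixel_size_um)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$frame))) |
               !is.finite(suppressWarnings(as.numeric(tab$x))) |
               !is.finite(suppressWarnings(as.numeric(tab$y))))
  if (length(bad)) {
    stopf("malformed rows at line(s) %s of %s",
          paste(bad + 1L, collapse = ", "), path)  # +1 for the header line
  }
  split_tab <- split(tab, tab$id)
  out <- lapply(split_tab, function(s) {
    if (anyDuplicated(s$frame)) {
      stopf("track '%s': duplicated frame(s) %s", s$id[1],
            paste(unique(s$frame[duplicated(s$frame)]), collapse = ", "))
    }
    s <- s[order(s$frame), ]
    cil_track(s$frame, s$x, s$y, track_id = as.character(s$id[1]), dt = dt)
  })
  names(out) <- names(split_tab)
  out
}

#' Write tracks to native CSV
#'
#' @param tracks a list of [cil_track()]s (or one track).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks_to_table(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' Reads all pages into a `H x W x frames` array. If the file carries a JSON
#' sidecar (`<path>.json`, written by [write_stack()]) its intensity scale
#' and metadata are applied. Multi-channel files stored as interleaved pages
#' are split with `channels`/`channel_index`.
#'
#' @param path TIFF path.
#' @param channel channel label for the result.
#' @param channels number of interleaved channels in the file.
#' @param channel_index which channel to extract (1-based).
#' @param pixel_size_um,dt metadata used when no sidecar is present.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, channel = "YFP", channels = 1,
                       channel_index = 1, pixel_size_um = 0.25, dt = 15) {
  if (!file.exists(path)) stopf("stack file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stopf("no pages in %s", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("inconsistent page sizes in %s", path)
  }
  if (channels > 1) {
    pages <- pages[seq(channel_index, length(pages), by = channels)]
  }
  arr <- array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
  scale <- 1
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$dt_s)) dt <- meta$dt_s
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  channel_stack(arr * scale, channel = channel,
                pixel_size_um = pixel_size_um, dt = dt)
}

#' Write an image stack as multi-page float TIFF
#'
#' Intensities are stored as 32-bit floats normalized to `[0, 1]`; the
#' normalization scale and acquisition metadata go into a JSON sidecar
#' (`<path>.json`) that [read_stack()] reads back, making the round trip
#' exact up to float precision.
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  mx <- max(stack$data)
  scale <- if (mx > 1) mx else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(f) stack$data[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(scale = scale, pixel_size_um = stack$pixel_size_um,
                            dt_s = stack$dt, channel = stack$channel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analysis run configuration
#'
#' All tunable parameters of the pipeline in one list, serialized verbatim
#' into every output's metadata: pixel size, frame interval, the 5-min
#' collision window, the ratio threshold 1.2, the CIL classification angles
#' 120/60 degrees with p < 0.05, the 90-degree direction-change threshold,
#' and the image-processing settings.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.25, dt_s = 15, window_s = 300,
    ratio_threshold = 1.2, cil_angle_hi_deg = 120, cil_angle_lo_deg = 60,
    p_threshold = 0.05, direction_change_deg = 90,
    smooth_sigma_px = 1, cfp_floor = 1e-3,
    background_region = c(1, 1, 10, 10),
    closure_tol_um = 2, seed = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (nm in c("pixel_size_um", "dt_s", "window_s", "ratio_threshold",
               "cil_angle_hi_deg", "cil_angle_lo_deg", "p_threshold",
               "direction_change_deg")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stopf("config field %s must be positive", nm)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with a subset of [run_config()] fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}
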