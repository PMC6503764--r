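#' Read a frame stack
#'
#' Readers for the two plain container dialects used by the package:
#' `"tiff-series"` (one 16-bit greyscale TIFF per frame, ordered by file
#' name) and `"ascii-grid"` (one whitespace-separated integer grid per
#' file, `#` comments allowed). All frames must share one shape.
#'
#' @param paths Character vector of frame files (one file per frame), or a
#'   directory (all `*.tif`/`*.tiff` or `*.txt` inside, sorted).
#' @param dialect `"tiff-series"` or `"ascii-grid"`.
#' @param detector Optional [detector_spec()] override; otherwise inferred
#'   from the frame shape.
#' @return A [frame_stack()].
#' @export
read_frames <- function(paths, dialect = c("tiff-series", "ascii-grid"),
                        detector = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) rlang::abort(
                        sprintf("unknown frame dialect '%s'.", dialect[1]),
                        class = "edcal_invalid_input"))
  if (length(paths) == 1 && dir.exists(paths)) {
    pat <- if (dialect == "tiff-series") "\\.tiff?$" else "\\.txt$"
    paths <- sort(list.files(paths, pattern = pat, full.names = TRUE))
  }
  if (length(paths) == 0) {
    rlang::abort("no frame files found.", class = "edcal_invalid_input")
  }
  frames <- lapply(paths, function(p) {
    if (dialect == "tiff-series") {
      m <- tiff::readTIFF(p)
      if (length(dim(m)) == 3) m <- m[, , 1]
      round(m * 65535)
    } else {
      lines <- readLines(p)
      lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
      rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      ncols <- unique(lengths(rows))
      if (length(ncols) != 1) {
        rlang::abort(sprintf("ragged ascii grid in %s.", p),
                     class = "edcal_parse_error")
      }
      matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
    }
  })
  frame_stack(frames, detector = detector)
}

#' Write a frame stack
#'
#' Inverse of [read_frames()]. TIFF frames are written as 16-bit greyscale
#' (counts are clipped to 65535); ASCII grids as integer matrices. Both
#' round-trip integer counts exactly.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if needed).
#' @param dialect `"tiff-series"` or `"ascii-grid"`.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(stack, dir, dialect = c("tiff-series", "ascii-grid"),
                         prefix = "frame") {
  stopifnot(inherits(stack, "frame_stack"))
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "tiff-series") "tif" else "txt"
  paths <- file.path(dir, sprintf("%s_%05d.%s", prefix,
                                  seq_along(stack$frames), ext))
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    if (dialect == "tiff-series") {
      tiff::writeTIFF(pmin(f, 65535) / 65535, paths[i],
                      bits.per.sample = 16)
    } else {
      writeLines(apply(f, 1, paste, collapse = " "), paths[i])
    }
  }
  invisible(paths)
}

#' Read / write peak lists (SPOT.XDS dialect)
#'
#' Whitespace-separated columns `X Y Z INTENSITY`, one peak per line,
#' `!`-prefixed comment lines ignored. X/Y are pixel coordinates in the
#' 1-based pixel-centre convention of the XDS ecosystem; this package works
#' in 0-based array coordinates internally, and the conversion (subtract
#' 1 on read, add 1 on write) happens here at the boundary.
#'
#' @param path File path.
#' @return `read_peaks()`: tibble with `x`, `y` (0-based px), `frame`,
#'   `intensity`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*!", lines) & trimws(lines) != "")
  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 4 || any(is.na(vals[1:4]))) {
      rlang::abort(sprintf("malformed peak record at line %d: %s",
                           i, trimws(lines[i])),
                   class = "edcal_parse_error")
    }
    if (vals[4] < 0) {
      rlang::abort(sprintf("negative intensity at line %d.", i),
                   class = "edcal_validation_error")
    }
    vals[1:4]
  }
  recs <- t(vapply(keep, parse_one, numeric(4)))
  tibble::tibble(x = recs[, 1] - 1, y = recs[, 2] - 1,
                 frame = recs[, 3], intensity = recs[, 4])
}

#' @rdname read_peaks
#' @param peaks Tibble with columns `x`, `y`, `frame`, `intensity`
#'   (0-based pixel coordinates).
#' @export
write_peaks <- function(peaks, path) {
  if (any(peaks$intensity < 0)) {
    rlang::abort("negative intensity in peak list.",
                 class = "edcal_validation_error")
  }
  lines <- sprintf("%12.6f %12.6f %8.2f %12.4f",
                   peaks$x + 1, peaks$y + 1, peaks$frame, peaks$intensity)
  writeLines(c("! X Y Z INTENSITY (SPOT.XDS dialect)", lines), path)
  invisible(path)
}

#' Write an integration-ready geometry template
#'
#' Serialises a calibrated [geometry_model()] (plus, optionally, the
#' explicit axis candidates of an `axis_estimate`) into an XDS.INP-style
#' keyword file: detector shape and pitch, `DETECTOR_DISTANCE`,
#' `ORGX`/`ORGY` (the direct-beam position, 1-based pixel-centre
#' convention), `ROTATION_AXIS` with the second candidate of the twofold
#' ambiguity on a commented line, `OSCILLATION_RANGE` (always positive — a
#' negative calibrated width flips the emitted axis candidate instead),
#' `X-RAY_WAVELENGTH` and `INCIDENT_BEAM_DIRECTION`. Numbers are printed
#' with six significant figures so repeated writes are byte-identical.
#'
#' @param model A complete [geometry_model()].
#' @param path Output file.
#' @param axis Optional `axis_estimate`; defaults to the model's azimuth.
#' @return Invisibly, the path.
#' @export
write_xds_template <- function(model, path, axis = NULL) {
  if (!inherits(model, "geometry_model")) {
    rlang::abort("`model` must be a geometry_model.",
                 class = "edcal_invalid_input")
  }
  missing <- names(Filter(function(v) is.null(v) || anyNA(v),
                          model[c("distance", "origin", "axis_azimuth",
                                  "oscillation_width")]))
  if (length(missing) > 0) {
    rlang::abort(paste("geometry model incomplete; missing:",
                       paste(missing, collapse = ", ")),
                 class = "edcal_invalid_input")
  }
  psi <- if (!is.null(axis)) axis$azimuth else model$axis_azimuth
  cand <- axis_vector(psi)
  flipped <- model$oscillation_width < 0
  if (flipped) cand <- cand[2:1, , drop = FALSE] # reverse rotation: flip axis
  num <- function(v) paste(formatC(v, format = "g", digits = 6),
                           collapse = " ")
  det <- model$detector
  lines <- c(
    "! geometry template written by edcal",
    sprintf("NX= %d NY= %d QX= %s QY= %s", det$n_fast, det$n_slow,
            num(det$pixel_size), num(det$pixel_size)),
    sprintf("DETECTOR_DISTANCE= %s", num(model$distance)),
    sprintf("ORGX= %s ORGY= %s", num(model$origin[1] + 1),
            num(model$origin[2] + 1)),
    sprintf("ROTATION_AXIS= %s", num(cand[1, ])),
    sprintf("!ROTATION_AXIS= %s  ! other candidate of twofold ambiguity%s",
            num(cand[2, ]),
            if (flipped) " (reverse rotation folded into axis)" else ""),
    sprintf("OSCILLATION_RANGE= %s", num(abs(model$oscillation_width))),
    sprintf("X-RAY_WAVELENGTH= %s", num(model$beam$wavelength)),
    sprintf("INCIDENT_BEAM_DIRECTION= %s", num(model$beam$incident_direction))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a geometry template back into numbers
#'
#' Convenience reader for round-trip checks of [write_xds_template()].
#'
#' @param path Template file.
#' @return Named list of numeric vectors keyed by keyword.
#' @export
read_xds_template <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*!", lines)]
  out <- list()
  for (l in lines) {
    m <- gregexpr("[A-Z_X-]+=\\s*[^A-Z!]*", l)
    for (piece in regmatches(l, m)[[1]]) {
      kv <- strsplit(piece, "=")[[1]]
      out[[trimws(kv[1])]] <- as.numeric(strsplit(trimws(kv[2]), "\\s+")[[1]])
    }
  }
  out
}

#' Write / read a calibration report
#'
#' Flat `key = value` text: numeric entries carry their unit in the key
#' (e.g. `distance_mean_A_mm`). The provenance timestamp lives on a
#' comment line so that the data section is byte-stable for identical
#' inputs. The reader inverts the writer losslessly.
#'
#' @param report Named list of numbers (or short strings).
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report), !is.null(names(report)))
  fmt <- function(v) {
    if (is.numeric(v)) paste(formatC(v, format = "g", digits = 15),
                             collapse = " ")
    else as.character(v)
  }
  lines <- c(sprintf("# edcal calibration report (%s)",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(report),
                    function(k) sprintf("%s = %s", k, fmt(report[[k]])),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    out[[key]] <- if (any(is.na(num))) val else num
  }
  out
}

#' Read a flat key=value config file
#'
#' Same dialect as the calibration report; used by the command-line
#' interface, where explicit flags override config entries.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) read_report(path)
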