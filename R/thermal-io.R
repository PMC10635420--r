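#' Read a FLIR-style AOI temperature export
#'
#' Reads a two-column CSV (header + one mean AOI temperature per timestamp,
#' as exported by FLIR analysis software) into a tidy series. Rows are kept
#' in file order; no resampling is applied.
#'
#' @param path Path to the CSV (columns: time in seconds, temperature in
#'   degC; header names are not interpreted).
#' @return A tibble with columns `time_s`, `temp_C`.
#' @export
read_aoi_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("AOI file not found: %s", path), class = "thermo_io_error")
  }
  out <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    readr::col_double(), readr::col_double()
  ), col_names = TRUE)) # parse problems re-raised as errors below
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed AOI CSV %s: row %d, %s.", path,
                  probs$row[1], probs$expected[1]),
          class = "thermo_parse_error")
  }
  if (ncol(out) != 2) {
    abort(sprintf("AOI CSV %s must have exactly 2 columns, found %d.",
                  path, ncol(out)), class = "thermo_parse_error")
  }
  names(out) <- c("time_s", "temp_C")
  validate_aoi_series(out, what = path)
  out
}

validate_aoi_series <- function(series, what = "AOI series") {
  if (!all(c("time_s", "temp_C") %in% names(series))) {
    abort(sprintf("%s must have columns time_s and temp_C.", what),
          class = "thermo_input_error")
  }
  if (nrow(series) < 2) {
    abort(sprintf(
      "%s has %d sample(s); at least 2 (before/after stimulation) required.",
      what, nrow(series)), class = "thermo_insufficient_data")
  }
  if (!all(is.finite(series$temp_C))) {
    abort(sprintf("%s contains non-finite temperatures.", what),
          class = "thermo_input_error")
  }
  if (is.unsorted(series$time_s)) {
    abort(sprintf("%s timestamps must be nondecreasing.", what),
          class = "thermo_input_error")
  }
  invisible(series)
}

#' Construct a thermal frame stack
#'
#' A frame stack is a sequence of per-timestamp temperature matrices (degC),
#' e.g. raw radiometric frames converted to temperature. All frames must
#' share dimensions and at least two frames are required.
#'
#' @param frames A list of numeric matrices, or a 3-d array (row, col, frame).
#' @param times Frame times in seconds, nondecreasing, one per frame.
#' @param trial_id Optional identifier carried through.
#' @return An object of class `thermo_frames`.
#' @export
frame_stack <- function(frames, times, trial_id = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(is.list(frames))
  if (length(frames) < 2) {
    abort("A frame stack needs at least 2 frames.",
          class = "thermo_insufficient_data")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames must share dimensions.", class = "thermo_input_error")
  }
  if (length(times) != length(frames) || is.unsorted(times)) {
    abort("`times` must be nondecreasing with one entry per frame.",
          class = "thermo_input_error")
  }
  structure(list(frames = frames, times = as.numeric(times),
                 trial_id = trial_id),
            class = "thermo_frames")
}

#' Read a frame stack from per-frame CSV matrices or a multi-page TIFF
#'
#' @param paths Either a character vector of per-frame CSV matrix files (one
#'   numeric matrix per file, no header) or a single `.tif`/`.tiff` path.
#' @param times Frame times in seconds; defaults to 0, 1, 2, ... .
#' @inheritParams frame_stack
#' @return A `thermo_frames` object.
#' @export
read_frame_stack <- function(paths, times = NULL, trial_id = NULL) {
  if (length(paths) == 1 && grepl("\\.tiff?$", paths, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package `tiff` is required to read TIFF stacks.",
            class = "thermo_io_error")
    }
    frames <- tiff::readTIFF(paths, all = TRUE, as.is = TRUE)
    frames <- lapply(frames, function(f) {
      if (length(dim(f)) == 3) f <- f[, , 1]
      f
    })
  } else {
    frames <- lapply(paths, function(p) {
      as.matrix(utils::read.csv(p, header = FALSE))
    })
    frames <- lapply(frames, unname)
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  frame_stack(frames, times, trial_id = trial_id)
}

#' Define a palm area of interest (AOI)
#'
#' The AOI is a polygon in pixel coordinates, `(row, col)` 0-based with the
#' origin at the top-left of the frame; a pixel `(i, j)` occupies the unit
#' square `[i, i+1) x [j, j+1)` and has its center at `(i + 0.5, j + 0.5)`.
#'
#' @param vertices A numeric matrix (or data frame) with two columns
#'   `(row, col)` and at least three vertices.
#' @return An object of class `thermo_aoi`.
#' @export
palm_aoi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || anyNA(vertices)) {
    abort("`vertices` must be a (row, col) matrix with >= 3 vertices.",
          class = "thermo_input_error")
  }
  structure(list(vertices = unname(vertices)), class = "thermo_aoi")
}

# even-odd (ray casting) membership for pixel centers; centers exactly on a
# polygon edge follow the crossing rule's half-open convention, which keeps
# top/left boundary pixels and drops bottom/right ones.
pixels_in_polygon <- function(nrow, ncol, vertices) {
  cy <- rep(seq_len(nrow) - 0.5, times = ncol)   # row centers
  cx <- rep(seq_len(ncol) - 0.5, each = nrow)    # col centers
  vy <- vertices[, 1]; vx <- vertices[, 2]
  nv <- length(vy)
  inside <- rep(FALSE, length(cx))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- (vy[i] > cy) != (vy[j] > cy)
    xint <- (vx[j] - vx[i]) * (cy - vy[i]) / (vy[j] - vy[i]) + vx[i]
    hit <- crosses & (cx < xint)
    inside <- xor(inside, hit & !is.na(hit))
    j <- i
  }
  matrix(inside, nrow = nrow, ncol = ncol)
}

#' Average AOI temperature per frame
#'
#' Computes, for each frame of a stack, the unweighted mean of the pixels
#' whose centers fall inside the AOI polygon. Membership is computed once on
#' the first frame's grid and reused across frames, so the result is
#' unaffected by content outside the AOI.
#'
#' @param stack A [frame_stack()].
#' @param aoi A [palm_aoi()].
#' @return A tibble with columns `time_s`, `temp_C` (one row per frame).
#' @export
aoi_mean_series <- function(stack, aoi) {
  stopifnot(inherits(stack, "thermo_frames"), inherits(aoi, "thermo_aoi"))
  d <- dim(stack$frames[[1]])
  mask <- pixels_in_polygon(d[1], d[2], aoi$vertices)
  if (!any(mask)) {
    abort("AOI polygon contains no pixel centers.", class = "thermo_empty_aoi")
  }
  temps <- vapply(stack$frames, function(f) mean(f[mask]), numeric(1))
  tibble(time_s = stack$times, temp_C = temps)
}

#' Real hand temperature change of a trial
#'
#' The first and last entries of the AOI series are taken as the hand
#' temperature before and at the end of the stimulation; the real change is
#' their signed difference (`final - baseline`). The absolute value is
#' applied only later, in [standardize_changes()].
#'
#' @param series A tibble with columns `time_s` and `temp_C`. If grouping
#'   columns `participant_id` and/or `trial` are present, one row is returned
#'   per group.
#' @return A tibble with columns `baseline_temp`, `final_temp`, `delta`
#'   (plus any grouping columns).
#' @examples
#' real_change(tibble::tibble(time_s = 0:20, temp_C = seq(32, 34.2, by = 0.11)))
#' @export
real_change <- function(series) {
  idcols <- intersect(c("participant_id", "trial"), names(series))
  if (length(idcols) > 0) {
    return(
      series %>%
        group_by(across(dplyr::all_of(idcols))) %>%
        summarise(
          baseline_temp = dplyr::first(.data$temp_C),
          final_temp = dplyr::last(.data$temp_C),
          delta = dplyr::last(.data$temp_C) - dplyr::first(.data$temp_C),
          .groups = "drop"
        )
    )
  }
  validate_aoi_series(series)
  tibble(
    baseline_temp = series$temp_C[1],
    final_temp = series$temp_C[nrow(series)],
    delta = series$temp_C[nrow(series)] - series$temp_C[1]
  )
}

#' Quality-control flags for an AOI series
#'
#' Screens a series for physiologically implausible temperatures and abrupt
#' inter-sample jumps (e.g. hand movement out of the AOI). Flagged trials are
#' reported, never auto-dropped; the original study resolved these by visual
#' inspection of the recordings.
#'
#' @inheritParams real_change
#' @param limits List with `range` (plausible degC interval, default
#'   `c(20, 45)`) and `max_step` (largest plausible one-sample change in
#'   degC, default 1).
#' @return A tibble of flags (`flag`, `index`, `value`); zero rows when clean.
#' @export
qc_trial <- function(series, limits = list(range = c(20, 45), max_step = 1)) {
  validate_aoi_series(series)
  t <- series$temp_C
  out_range <- which(t < limits$range[1] | t > limits$range[2])
  steps <- abs(diff(t))
  big_step <- which(steps > limits$max_step)
  bind_rows(
    tibble(flag = "range", index = out_range, value = t[out_range]),
    tibble(flag = "step", index = big_step + 1L, value = steps[big_step])
  )
}
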