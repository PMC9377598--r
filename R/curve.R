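#' Volume-time curve of the left atrium
#'
#' Container for one patient's LA volume across the cardiac cycle. Frame 0 is
#' the R-wave trigger of the retrospectively ECG-gated acquisition; this is a
#' convention carried through the pipeline, not enforced on the data.
#'
#' @param volumes_ml numeric vector of non-negative LA volumes in ml, one per
#'   cardiac frame, in frame order.
#' @param patient_id character scalar identifying the patient.
#' @param flag_empty_frames logical; set automatically by [build_curve()] when
#'   a frame had no segmented voxels (possible segmentation failure).
#'
#' @return An object of class `la_curve`: a list with elements `patient_id`,
#'   `volumes_ml`, `n_frames` and `flag_empty_frames`.
#' @seealso [build_curve()], [detect_fiducials()], [smooth_curve()]
#' @export
#' @examples
#' la_curve(c(50, 80, 100, 80, 55), patient_id = "demo")
la_curve <- function(volumes_ml, patient_id = "patient", flag_empty_frames = FALSE) {
  if (!is.numeric(volumes_ml) || length(volumes_ml) < 1) {
    stop("`volumes_ml` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(volumes_ml)) stop("`volumes_ml` must not contain NA", call. = FALSE)
  if (any(volumes_ml < 0)) {
    stop("`volumes_ml` must be non-negative (invalid input)", call. = FALSE)
  }
  structure(
    list(
      patient_id = as.character(patient_id)[1],
      volumes_ml = as.numeric(volumes_ml),
      n_frames = length(volumes_ml),
      flag_empty_frames = isTRUE(flag_empty_frames)
    ),
    class = "la_curve"
  )
}

#' @export
print.la_curve <- function(x, ...) {
  cat(sprintf(
    "<la_curve> patient %s: %d frames, range %.1f-%.1f ml%s\n",
    x$patient_id, x$n_frames, min(x$volumes_ml), max(x$volumes_ml),
    if (x$flag_empty_frames) " [empty frame(s) flagged]" else ""
  ))
  invisible(x)
}

#' @export
plot.la_curve <- function(x, fiducials = NULL, ...) {
  graphics::plot(
    seq_len(x$n_frames) - 1L, x$volumes_ml,
    type = "b", pch = 16, cex = 0.6,
    xlab = "cardiac frame (0 = R-wave)", ylab = "LA volume [ml]",
    main = x$patient_id, ...
  )
  if (!is.null(fiducials) && inherits(fiducials, "la_fiducials") &&
      fiducials$mode != "rejected") {
    idx <- c(fiducials$i_max, fiducials$i_min, fiducials$i_preA, fiducials$i_min2)
    vol <- c(fiducials$v_max, fiducials$v_min, fiducials$v_preA, fiducials$v_min2)
    keep <- !is.na(idx)
    graphics::points(idx[keep], vol[keep], col = "red", pch = 17, cex = 1.2)
  }
  invisible(x)
}

#' Smooth a volume-time curve with a circular moving average
#'
#' The cardiac cycle is periodic, so the moving average wraps around the
#' frame axis. Used internally by [detect_fiducials()] to stabilise extremum
#' localisation; fiducial volumes are always read back from the raw curve.
#'
#' @param curve an [la_curve].
#' @param window odd integer window width in frames; `1` returns the curve
#'   unchanged.
#' @return An [la_curve] with smoothed volumes.
#' @export
#' @examples
#' smooth_curve(la_curve(c(10, 20, 10, 20)), window = 3)
smooth_curve <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "la_curve"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer (invalid config)", call. = FALSE)
  }
  if (window >= curve$n_frames) {
    stop("`window` must be smaller than the number of frames (invalid config)",
         call. = FALSE)
  }
  if (window == 1L) return(curve)
  half <- (window - 1L) %/% 2L
  v <- curve$volumes_ml
  n <- curve$n_frames
  # circular padding, then plain moving average
  padded <- c(v[(n - half + 1L):n], v, v[1L:half])
  sm <- as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))
  out <- curve
  out$volumes_ml <- sm[(half + 1L):(half + n)]
  out
}

#' Read and write volume-time curves as CSV
#'
#' The curve CSV dialect has columns `patient_id`, `frame_index` (0-based)
#' and `volume_ml`; one file can hold many patients.
#'
#' @param curves a single [la_curve] or a list of them.
#' @param path path to the CSV file.
#' @return `write_curves_csv()` returns `path` invisibly; `read_curves_csv()`
#'   returns a named list of [la_curve] objects (names = patient ids).
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "la_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cu) {
    data.frame(
      patient_id = cu$patient_id,
      frame_index = seq_len(cu$n_frames) - 1L,
      volume_ml = cu$volumes_ml,
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "frame_index", "volume_ml")
  if (!all(need %in% names(df))) {
    stop("curve CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$frame_index), ]
    la_curve(d$volume_ml, patient_id = d$patient_id[1])
  })
  # preserve file order of first appearance
  out[unique(df$patient_id)]
}
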