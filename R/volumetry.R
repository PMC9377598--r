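#' Time-resolved LA segmentation series
#'
#' Bundles a 4D binary mask (row, col, slice, frame) with its voxel geometry.
#' Acquisitions in the supported protocol use contiguous slices (no section
#' gap); a `slice_gap` parameter is exposed for other protocols and defaults
#' to 0.
#'
#' @param mask 4D array with values in \{0, 1\} (logical or numeric), indexed
#'   (row, col, slice, frame).
#' @param in_plane_spacing numeric length-2, mm per pixel (row, col); a single
#'   value is recycled to both.
#' @param slice_thickness slice thickness in mm.
#' @param patient_id character scalar.
#' @param slice_gap inter-slice gap in mm (default 0).
#' @return An object of class `la_seg_series`.
#' @export
seg_series <- function(mask, in_plane_spacing, slice_thickness,
                       patient_id = "patient", slice_gap = 0) {
  if (length(dim(mask)) != 4L) {
    stop("`mask` must be a 4D array (row, col, slice, frame)", call. = FALSE)
  }
  check_binary_mask(mask)
  if (length(in_plane_spacing) == 1L) {
    in_plane_spacing <- rep(in_plane_spacing, 2L)
  }
  if (any(!is.finite(in_plane_spacing)) || any(in_plane_spacing <= 0) ||
      !is.finite(slice_thickness) || slice_thickness <= 0 || slice_gap < 0) {
    stop("voxel spacings must be positive (invalid geometry)", call. = FALSE)
  }
  n_frames <- dim(mask)[4]
  if (n_frames < 5L) {
    stop("a segmentation series needs at least 5 cardiac frames", call. = FALSE)
  }
  structure(
    list(
      patient_id = as.character(patient_id)[1],
      mask = mask,
      in_plane_spacing = as.numeric(in_plane_spacing),
      slice_thickness = as.numeric(slice_thickness),
      slice_gap = as.numeric(slice_gap),
      n_frames = as.integer(n_frames)
    ),
    class = "la_seg_series"
  )
}

#' @export
print.la_seg_series <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<la_seg_series> patient %s: %dx%dx%d voxels x %d frames, %.2gx%.2gx%.2g mm\n",
    x$patient_id, d[1], d[2], d[3], d[4],
    x$in_plane_spacing[1], x$in_plane_spacing[2], x$slice_thickness
  ))
  invisible(x)
}

check_binary_mask <- function(mask) {
  if (is.logical(mask)) return(invisible(TRUE))
  u <- unique(as.vector(mask))
  if (anyNA(u) || !all(u %in% c(0, 1))) {
    stop("mask must be binary with values in {0, 1} (invalid input)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Volume of one segmented frame
#'
#' LA volume is the sum of all segmented voxels times the voxel volume:
#' `count * row_spacing * col_spacing * (slice_thickness + slice_gap)`,
#' converted from cubic millimetres to millilitres. No partial-volume
#' correction or surface smoothing is applied.
#'
#' @param mask_frame 3D binary array (one cardiac frame).
#' @param in_plane_spacing mm per pixel (row, col); a single value is recycled.
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm (default 0).
#' @return Volume in ml.
#' @export
#' @examples
#' m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
#' compute_frame_volume(m, c(1, 1), 1) # 1000 voxels of 1 mm^3 -> 1 ml
compute_frame_volume <- function(mask_frame, in_plane_spacing, slice_thickness,
                                 slice_gap = 0) {
  if (length(dim(mask_frame)) != 3L) {
    stop("`mask_frame` must be a 3D array", call. = FALSE)
  }
  check_binary_mask(mask_frame)
  if (length(in_plane_spacing) == 1L) in_plane_spacing <- rep(in_plane_spacing, 2L)
  if (any(in_plane_spacing <= 0) || slice_thickness <= 0 || slice_gap < 0) {
    stop("voxel spacings must be positive (invalid geometry)", call. = FALSE)
  }
  voxel_mm3 <- in_plane_spacing[1] * in_plane_spacing[2] *
    (slice_thickness + slice_gap)
  sum(mask_frame != 0) * voxel_mm3 / 1000
}

#' Build a volume-time curve from a segmentation series
#'
#' Applies [compute_frame_volume()] to every cardiac frame, preserving frame
#' order. Frames with zero segmented voxels are a sign that the upstream
#' segmentation failed; the returned curve then carries
#' `flag_empty_frames = TRUE` and a warning is raised, mirroring the
#' per-patient exclusion bookkeeping of the pipeline.
#'
#' @param series an `la_seg_series` object (see [seg_series()]).
#' @param largest_component if `TRUE`, each frame is reduced to its largest
#'   6-connected component before voxel counting. Off by default: stray
#'   components are summed as-is.
#' @return An [la_curve].
#' @export
build_curve <- function(series, largest_component = FALSE) {
  stopifnot(inherits(series, "la_seg_series"))
  vols <- vapply(seq_len(series$n_frames), function(f) {
    frame <- series$mask[, , , f, drop = TRUE]
    dim(frame) <- dim(series$mask)[1:3]
    if (largest_component) frame <- largest_component_3d(frame)
    compute_frame_volume(frame, series$in_plane_spacing,
                         series$slice_thickness, series$slice_gap)
  }, numeric(1))
  empty <- vols == 0
  if (any(empty)) {
    warning(sprintf(
      "patient %s: %d frame(s) with zero segmented voxels (possible segmentation failure)",
      series$patient_id, sum(empty)
    ), call. = FALSE)
  }
  la_curve(vols, patient_id = series$patient_id,
           flag_empty_frames = any(empty))
}

#' Largest 6-connected component of a 3D binary mask
#'
#' Simple breadth-first flood fill; intended for modest mask sizes. Exposed
#' because [build_curve()] can optionally filter stray segmented voxels.
#'
#' @param mask 3D binary array.
#' @return 3D integer array of the same shape keeping only the largest
#'   component.
#' @export
largest_component_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  idx <- which(mask != 0)
  if (length(idx) == 0) return(array(0L, d))
  current <- 0L
  sizes <- integer(0)
  nbr_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coords <- arrayInd(idx, d)
  pos_of <- function(r, c, s) (s - 1L) * d[1] * d[2] + (c - 1L) * d[1] + r
  for (k in seq_along(idx)) {
    if (lab[idx[k]] != 0L) next
    current <- current + 1L
    queue <- matrix(coords[k, ], nrow = 1)
    lab[idx[k]] <- current
    size <- 1L
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(6)) {
        q <- p + nbr_off[j, ]
        if (any(q < 1L) || any(q > d)) next
        lin <- pos_of(q[1], q[2], q[3])
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- current
          size <- size + 1L
          queue <- rbind(queue, q)
        }
      }
    }
    sizes[current] <- size
  }
  keep <- which.max(sizes)
  array(as.integer(lab == keep), d)
}

#' Read a 4D NIfTI segmentation mask
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`): the first two
#' spatial pixdims give the in-plane spacing and the third the slice
#' thickness. Values are binarised at 0.5 to tolerate masks stored as
#' floating point.
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 4D binary mask.
#' @param patient_id patient identifier; defaults to the file name without
#'   extension.
#' @return An `la_seg_series` object (see [seg_series()]).
#' @export
read_mask_nifti <- function(path, patient_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D NIfTI mask (x, y, slice, frame): ", path, call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  if (is.null(patient_id)) {
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  seg_series(
    mask = array(as.integer(arr > 0.5), dim(arr)),
    in_plane_spacing = pd[1:2],
    slice_thickness = pd[3],
    patient_id = patient_id
  )
}

#' Write a segmentation series as 4D NIfTI
#'
#' @param series an `la_seg_series` object (see [seg_series()]).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(series, path) {
  stopifnot(inherits(series, "la_seg_series"))
  img <- RNifti::asNifti(array(as.numeric(series$mask), dim(series$mask)))
  RNifti::pixdim(img) <- c(series$in_plane_spacing, series$slice_thickness, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
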