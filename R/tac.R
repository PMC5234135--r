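#' Time-activity curve
#'
#' Radioactivity concentration per acquisition frame for one ROI or voxel.
#' Activity is assumed decay-corrected, in kBq/mL. Negative frame values are
#' permitted only when `noisy = TRUE` (reconstruction noise can push low
#' frames below zero).
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, one value per frame, kBq/mL.
#' @param label curve identifier (ROI name or voxel index).
#' @param noisy logical; flags the curve as noise-bearing.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity, label = "roi", noisy = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != n_frames(schedule)) {
    stop("activity length must equal the number of frames", call. = FALSE)
  }
  if (any(!is.finite(activity))) stop("activity must be finite", call. = FALSE)
  if (!noisy && any(activity < 0)) {
    stop("negative activity requires noisy = TRUE", call. = FALSE)
  }
  structure(
    list(schedule = schedule, activity = activity,
         label = as.character(label), noisy = isTRUE(noisy)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> '%s': %d frames, peak %.3g kBq/mL\n",
              x$label, n_frames(x$schedule), max(x$activity)))
  invisible(x)
}

# sep auto-detection: tab wins if present in the header line, else comma
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read time-activity curves from a delimited table
#'
#' Expects a comma- or tab-delimited text file (auto-detected) with columns
#' `frame_start`, `frame_end` (minutes; a `_s`/`_sec` suffix declares seconds
#' and triggers conversion) followed by one activity column per ROI
#' (kBq/mL).
#'
#' @param path file path.
#' @return Named list of [tac()] objects sharing one schedule.
#' @export
read_tac_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  start_col <- grep("^frame_start", nm, value = TRUE)
  end_col <- grep("^frame_end", nm, value = TRUE)
  if (length(start_col) != 1L || length(end_col) != 1L) {
    stop("table must contain frame_start and frame_end columns", call. = FALSE)
  }
  scale <- if (grepl("_s(ec)?$", start_col)) 1 / 60 else 1
  roi_cols <- setdiff(nm, c(start_col, end_col))
  if (length(roi_cols) == 0L) stop("no ROI activity columns found", call. = FALSE)
  for (cc in roi_cols) {
    if (any(is.na(df[[cc]]))) stop("ragged or missing activity values in column ", cc, call. = FALSE)
  }
  sch <- frame_schedule(df[[start_col]] * scale, df[[end_col]] * scale)
  out <- lapply(roi_cols, function(cc) {
    tac(sch, df[[cc]], label = cc, noisy = any(df[[cc]] < 0))
  })
  names(out) <- roi_cols
  out
}

#' Write time-activity curves to a delimited table
#'
#' @param tacs a [tac()] or list of them sharing one schedule.
#' @param path output file path; extension `.tsv` selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  if (length(tacs) > 0L) {
    sch <- tacs[[1]]$schedule
    for (tc in tacs) {
      stopifnot(inherits(tc, "tac"))
      if (!schedules_equal(tc$schedule, sch)) {
        stop("all curves must share one frame schedule", call. = FALSE)
      }
    }
    df <- data.frame(frame_start = sch$frame_start, frame_end = sch$frame_end,
                     check.names = FALSE)
    for (tc in tacs) df[[tc$label]] <- tc$activity
  } else {
    df <- data.frame(frame_start = numeric(0), frame_end = numeric(0))
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  # %.10g keeps >= 6 significant digits through the round trip
  df[] <- lapply(df, function(x) formatC(x, format = "g", digits = 10))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dynamic (4D) PET image
#'
#' @param voxels 4D numeric array of activity, kBq/mL; the 4th dimension
#'   indexes frames.
#' @param schedule a [frame_schedule()] whose length matches `dim(voxels)[4]`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, schedule, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(voxels)) != 4L) stop("voxels must be a 4D array", call. = FALSE)
  if (dim(voxels)[4] != n_frames(schedule)) {
    stop("4th dimension must equal the number of frames", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive numbers (mm)", call. = FALSE)
  }
  structure(list(voxels = voxels, schedule = schedule, voxel_size = voxel_size),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels x %d frames, %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read a 4D NIfTI dynamic PET image
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param schedule a [frame_schedule()] matching the 4th dimension.
#' @return A [dynamic_image()]; voxel size is taken from the NIfTI header.
#' @export
read_dynamic_image <- function(path, schedule) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected a 4D NIfTI image, got ", length(d), " dimensions", call. = FALSE)
  }
  if (d[4] != n_frames(schedule)) {
    stop(sprintf("schedule has %d frames but image has %d volumes",
                 n_frames(schedule), d[4]), call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1:3]
  dynamic_image(array(as.numeric(img), dim = d), schedule, vs)
}

#' Write a dynamic image (or 3D array) to NIfTI
#'
#' @param image a [dynamic_image()] or 3D numeric array.
#' @param path output .nii or .nii.gz path.
#' @param voxel_size voxel size in mm; for a [dynamic_image()] taken from the
#'   object.
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(image, path, voxel_size = c(2, 2, 2)) {
  if (inherits(image, "dynamic_image")) {
    arr <- image$voxels
    voxel_size <- image$voxel_size
  } else {
    arr <- image
  }
  nif <- RNifti::asNifti(arr)
  pd <- rep(1, length(dim(arr)))
  pd[1:3] <- voxel_size
  RNifti::pixdim(nif) <- pd
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Extract the mean TAC over a region mask
#'
#' @param image a [dynamic_image()].
#' @param mask 3D logical array matching the image's spatial dimensions.
#' @param label label for the resulting curve.
#' @return A [tac()] of the per-frame mean over the mask.
#' @export
roi_tac <- function(image, mask, label = "roi") {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  if (!identical(dim(mask), d[1:3])) stop("mask shape mismatch", call. = FALSE)
  if (!any(mask)) stop("mask selects no voxels", call. = FALSE)
  m <- matrix(image$voxels, nrow = prod(d[1:3]), ncol = d[4])
  act <- colMeans(m[as.vector(mask), , drop = FALSE], na.rm = TRUE)
  tac(image$schedule, act, label = label, noisy = any(act < 0))
}
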