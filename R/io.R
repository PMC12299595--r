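# NIfTI + JSON-sidecar I/O. Offsets live in a JSON sidecar because the
# NIfTI-1 header has no standard field for saturation frequencies; the
# sidecar is a JSON object with a single key "offsets_ppm" listing the
# offsets in stack (4th-dimension) order. All voxel coordinates are plain
# array indices; no world-coordinate handling (single 2D slice).

#' Write a z-spectrum stack to NIfTI + JSON sidecar
#'
#' One 3D volume per offset along the NIfTI 4th axis (the single slice
#' occupies the 3rd axis with size 1), plus a separate S0 NIfTI and a JSON
#' sidecar listing the offsets in ppm in stack order.
#'
#' @param stack a [ZSpectrumStack-class].
#' @param image_path,offsets_path,s0_path output paths (`.nii`/`.nii.gz`
#'   for images, `.json` for the sidecar).
#' @return invisibly, the three paths.
#' @export
writeStack <- function(stack, image_path, offsets_path, s0_path) {
  stopifnot(is(stack, "ZSpectrumStack"))
  d <- dim(stack@sSat)
  arr4 <- array(stack@sSat, c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(RNifti::asNifti(arr4), image_path)
  RNifti::writeNifti(RNifti::asNifti(stack@s0), s0_path)
  jsonlite::write_json(list(offsets_ppm = stack@grid@offsets),
                       offsets_path, auto_unbox = FALSE, digits = NA)
  invisible(c(image = image_path, offsets = offsets_path, s0 = s0_path))
}

#' Read a z-spectrum stack from NIfTI + JSON sidecar
#'
#' Validates that the number of image volumes matches the sidecar offset
#' count, and — if the sidecar lists offsets out of ascending order —
#' reorders both to ascending, recording the reordering in the returned
#' object's provenance log.
#'
#' @param image_path 4D NIfTI of saturated volumes (rows x cols x 1 x
#'   offsets, or rows x cols x offsets).
#' @param offsets_path JSON sidecar with key `offsets_ppm`.
#' @param s0_path 2D/3D NIfTI of the unsaturated image.
#' @param mask optional logical matrix; S0 must be positive inside it.
#' @return a [ZSpectrumStack-class].
#' @export
readStack <- function(image_path, offsets_path, s0_path, mask = NULL) {
  for (p in c(image_path, offsets_path, s0_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- as.array(RNifti::readNifti(image_path))
  d <- dim(img)
  if (length(d) == 4L && d[3] == 1L) {
    img <- array(img, c(d[1], d[2], d[4]))
  } else if (length(d) != 3L) {
    stop("stack image must be rows x cols x 1 x offsets (or 3D)")
  }
  side <- jsonlite::read_json(offsets_path, simplifyVector = TRUE)
  off <- as.numeric(side$offsets_ppm)
  if (!length(off)) stop("sidecar has no offsets_ppm entry")
  n_img <- dim(img)[3]
  if (n_img != length(off)) {
    stop(sprintf("stack has %d volumes but sidecar lists %d offsets",
                 n_img, length(off)))
  }
  prov <- character(0)
  if (is.unsorted(off, strictly = TRUE)) {
    ord <- order(off)
    if (anyDuplicated(off)) stop("sidecar offsets contain duplicates")
    img <- img[, , ord, drop = FALSE]
    off <- off[ord]
    prov <- "volumes reordered to ascending offset order"
  }
  s0img <- as.array(RNifti::readNifti(s0_path))
  s0img <- matrix(s0img, dim(img)[1], dim(img)[2])
  if (!is.null(mask)) {
    if (any(s0img[mask] <= 0)) {
      stop("non-positive S0 inside the provided mask")
    }
  }
  new("ZSpectrumStack", sSat = img, s0 = s0img,
      grid = new("OffsetGrid", offsets = off), provenance = prov)
}

#' Write / read a 2D parameter map as NIfTI
#'
#' @param field numeric matrix (NA allowed).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `writeMap` returns the path invisibly; `readMap` returns the
#'   matrix.
#' @export
writeMap <- function(field, path) {
  stopifnot(is.matrix(field))
  RNifti::writeNifti(RNifti::asNifti(field), path)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  matrix(arr, dim(arr)[1], dim(arr)[2])
}

#' Read a set of ROI masks
#'
#' Accepts either a named vector of per-label binary mask images, or a
#' single integer label image with a `labels` map (value -> name). Masks
#' may overlap; each must be non-empty and all must share one shape.
#'
#' @param paths named character vector of NIfTI paths (names are ROI
#'   labels), or a single unnamed path to a label image.
#' @param labels for the label-image form, named integer vector mapping
#'   ROI names to label values.
#' @return named list of logical matrices.
#' @export
readMasks <- function(paths, labels = NULL) {
  if (length(paths) == 1L && is.null(names(paths)) && !is.null(labels)) {
    lab_img <- readMap(paths)
    masks <- lapply(labels, function(v) lab_img == v)
  } else {
    if (is.null(names(paths)) || any(names(paths) == "")) {
      stop("per-label mask paths must be named")
    }
    masks <- lapply(paths, function(p) readMap(p) > 0.5)
  }
  shp <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), shp)) {
      stop("mask '", nm, "' shape differs from the others")
    }
    if (!any(masks[[nm]])) stop("mask '", nm, "' is empty")
  }
  masks
}
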