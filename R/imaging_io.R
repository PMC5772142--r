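#' Volume image container
#'
#' A `volume_image` bundles a 3D or 4D intensity array with the 4x4 affine
#' that maps 0-based voxel indices to world (RAS+, MNI) millimetre
#' coordinates, and, for 4D timeseries, the repetition time in seconds.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to mm.
#' @param tr_s Repetition time in seconds (4D data only).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine, tr_s = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array, got ", nd, "D")
  if (any(dim(data)[1:3] < 1L)) stop("spatial dimensions must be >= 1")
  if (nd == 4L && dim(data)[4] < 1L) stop("4D data must contain at least one volume")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps^0.5) stop("affine must be invertible")
  if (!is.null(tr_s)) {
    stopifnot(is.numeric(tr_s), length(tr_s) == 1L, tr_s > 0)
  }
  structure(list(data = data, affine = unname(affine), tr_s = tr_s),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_image> ", paste(d, collapse = " x "),
      if (length(d) == 4L) sprintf(" (TR %.3g s)", x$tr_s %||% NA_real_) else "",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.volume_image <- function(x) dim(x$data)

is_4d <- function(img) length(dim(img$data)) == 4L

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based; world coordinates are RAS+ millimetres.
#'
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(affine))
  out[, 1:3, drop = FALSE]
}

#' Spherical ROI specification
#'
#' @param name Region label.
#' @param center_mm Length-3 world (MNI) coordinate in mm.
#' @param radius_mm Sphere radius in mm (>= 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, center_mm, radius_mm = 4) {
  stopifnot(is.character(name), length(name) == 1L,
            length(center_mm) == 3L, is.finite(center_mm),
            is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm >= 0)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm)),
            class = "roi_spec")
}

#' Build a spherical ROI mask on a voxel grid
#'
#' Includes every voxel whose world-space centre lies at Euclidean distance
#' less than or equal to `radius_mm` from the sphere centre (boundary
#' inclusive). Distances are computed in world millimetres so anisotropic
#' grids are handled correctly. On a 2 mm isotropic grid a 4 mm sphere
#' centred on a voxel centre contains 33 voxels.
#'
#' @param spec An [roi_spec()].
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @param shape Length-3 integer grid shape.
#' @return An object of class `roi_mask` with fields `voxel_indices`
#'   (n x 3 integer matrix, 0-based), `source`, `affine`, `shape`.
#' @export
build_sphere_roi <- function(spec, affine, shape) {
  stopifnot(inherits(spec, "roi_spec"), length(shape) == 3L)
  shape <- as.integer(shape)
  # search only the bounding box of the sphere in voxel space
  ctr_vox <- drop(world_to_voxel(rbind(spec$center_mm), affine))
  vox_sizes <- sqrt(colSums(affine[1:3, 1:3]^2))
  halfwidth <- ceiling(spec$radius_mm / min(vox_sizes)) + 1L
  lo <- pmax(floor(ctr_vox) - halfwidth, 0L)
  hi <- pmin(ceiling(ctr_vox) + halfwidth, shape - 1L)
  if (any(lo > hi)) {
    stop("degenerate ROI mask: centre of '", spec$name,
         "' lies outside the field of view")
  }
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  world <- voxel_to_world(grid, affine)
  d2 <- (world[, 1] - spec$center_mm[1])^2 +
        (world[, 2] - spec$center_mm[2])^2 +
        (world[, 3] - spec$center_mm[3])^2
  keep <- d2 <= spec$radius_mm^2 + 1e-9
  if (!any(keep)) {
    stop("degenerate ROI mask: sphere '", spec$name,
         "' contains no voxel centres")
  }
  idx <- grid[keep, , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  structure(list(voxel_indices = idx, source = spec,
                 affine = unname(as.matrix(affine)), shape = shape),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", nrow(x$voxel_indices), " voxels",
      if (inherits(x$source, "roi_spec")) paste0(" ('", x$source$name, "')"),
      "\n", sep = "")
  invisible(x)
}

#' Number of voxels in an ROI mask
#' @param mask An `roi_mask`.
#' @export
roi_size <- function(mask) nrow(mask$voxel_indices)

#' Construct an ROI mask directly from voxel indices
#'
#' @param voxel_indices n x 3 matrix of 0-based indices.
#' @param affine,shape Grid geometry.
#' @param name Optional label.
#' @export
roi_mask_from_indices <- function(voxel_indices, affine, shape, name = "roi") {
  idx <- matrix(as.integer(voxel_indices), ncol = 3L)
  shape <- as.integer(shape)
  if (nrow(idx) == 0L) stop("degenerate ROI mask: no voxels supplied")
  if (any(idx < 0L) || any(t(idx) >= shape)) {
    stop("voxel indices outside grid shape")
  }
  structure(list(voxel_indices = idx, source = name,
                 affine = unname(as.matrix(affine)), shape = shape),
            class = "roi_mask")
}

# linear (1-based) offsets into the array for a mask, spatial dims only
mask_linear_index <- function(mask) {
  idx <- mask$voxel_indices
  1L + idx[, 1] + mask$shape[1] * (idx[, 2] + mask$shape[2] * idx[, 3])
}

#' Extract the timeseries matrix of an ROI from a 4D volume
#'
#' @param img A 4D `volume_image`.
#' @param mask An `roi_mask` on the same grid.
#' @return A time x voxel numeric matrix.
#' @export
roi_timeseries <- function(img, mask) {
  stopifnot(inherits(img, "volume_image"), inherits(mask, "roi_mask"))
  if (!is_4d(img)) stop("a 4D volume is required")
  d <- dim(img$data)
  if (!identical(d[1:3], as.integer(mask$shape))) {
    stop("mask grid shape does not match the volume")
  }
  nt <- d[4]
  flat <- matrix(img$data, nrow = prod(d[1:3]), ncol = nt)
  t(flat[mask_linear_index(mask), , drop = FALSE])
}

#' Load the packaged fingerprint target table
#'
#' Reads a TSV of target regions (columns `label`, `region`, `x`, `y`,
#' `z`) whose X coordinates are stored as unsigned magnitudes and resolved
#' per hemisphere: left = negative X, right = positive X. The packaged
#' table holds the 13 fingerprint target ROIs.
#'
#' @param path TSV path; defaults to the packaged table.
#' @param hemisphere `"left"` or `"right"`.
#' @param radius_mm Sphere radius assigned to every target (default 4 mm).
#' @return A list of [roi_spec()] objects, one per row.
#' @export
load_target_table <- function(path = streamconn_file("fingerprint_targets.tsv"),
                              hemisphere = c("left", "right"),
                              radius_mm = 4) {
  hemisphere <- match.arg(hemisphere)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("label", "region", "x", "y", "z")
  if (!all(required %in% names(tab))) {
    stop("target table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(list())
  bad <- which(!stats::complete.cases(tab[, c("x", "y", "z")]) |
                 !is.numeric(tab$x) | !is.numeric(tab$y) | !is.numeric(tab$z))
  if (length(bad)) stop("malformed coordinate in target table row ", bad[1])
  if (anyDuplicated(tab$label)) {
    stop("duplicate target label: ", tab$label[anyDuplicated(tab$label)])
  }
  sign_x <- if (hemisphere == "left") -1 else 1
  lapply(seq_len(nrow(tab)), function(i) {
    roi_spec(tab$label[i],
             c(sign_x * abs(tab$x[i]), tab$y[i], tab$z[i]),
             radius_mm = radius_mm)
  })
}

#' Load a dorsal/ventral stream membership table
#'
#' Reads a TSV with columns `area_name` and `stream` (values `dorsal` or
#' `ventral`). The packaged table lists the 22 cortical parcels (13 dorsal,
#' 9 ventral) defining the two processing-stream training/target sets.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A `stream_table` data.frame with columns `area_name`, `stream`.
#' @export
load_stream_table <- function(path = streamconn_file("stream_regions.tsv")) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("area_name", "stream") %in% names(tab))) {
    stop("stream table must have columns area_name, stream")
  }
  bad <- setdiff(unique(tab$stream), c("dorsal", "ventral"))
  if (length(bad)) stop("unknown stream value: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$area_name)) {
    stop("duplicate area_name: ", tab$area_name[anyDuplicated(tab$area_name)])
  }
  out <- tab[, c("area_name", "stream")]
  class(out) <- c("stream_table", "data.frame")
  out
}

#' Path to a packaged data file
#' @param ... File name components under `extdata`.
#' @export
streamconn_file <- function(...) {
  system.file("extdata", ..., package = "streamconn", mustWork = TRUE)
}

#' Maximum neighbour count for the k-NN sweep implied by a stream table
#'
#' One less than the number of parcels in the smaller (ventral) class, the
#' largest `k` for which the minority class can still win a vote.
#'
#' @param streams A `stream_table`.
#' @export
max_k_from_streams <- function(streams) {
  min(table(streams$stream)) - 1L
}

#' Parcellation volume
#'
#' @param label_data 3D integer array of parcel labels (0 = unlabelled).
#' @param label_map Named integer vector mapping area names to label values.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `parcellation_volume`.
#' @export
parcellation_volume <- function(label_data, label_map, affine) {
  label_data <- as.array(label_data)
  stopifnot(length(dim(label_data)) == 3L, !is.null(names(label_map)))
  structure(list(label_data = label_data,
                 label_map = label_map,
                 affine = unname(as.matrix(affine))),
            class = "parcellation_volume")
}

#' Voxel indices of one parcel
#' @param parc A `parcellation_volume`.
#' @param area_name Parcel name in `label_map`.
#' @return `roi_mask` of the parcel's voxels.
#' @export
parcel_mask <- function(parc, area_name) {
  lab <- parc$label_map[[area_name]]
  if (is.null(lab)) stop("unknown parcel: ", area_name)
  w <- which(parc$label_data == lab, arr.ind = TRUE)
  if (nrow(w) == 0L) {
    stop("parcel '", area_name, "' resolves to no voxels")
  }
  roi_mask_from_indices(w - 1L, parc$affine, dim(parc$label_data), area_name)
}

#' Check a stream table against a parcellation
#'
#' Warns for any stream area that resolves to no voxels.
#' @param parc A `parcellation_volume`.
#' @param streams A `stream_table`.
#' @return Invisibly, the names of empty areas.
#' @export
check_parcel_coverage <- function(parc, streams) {
  counts <- table(factor(parc$label_data[parc$label_data > 0],
                         levels = parc$label_map))
  names(counts) <- names(parc$label_map)
  empty <- streams$area_name[
    !(streams$area_name %in% names(parc$label_map)) |
      counts[streams$area_name] == 0]
  empty <- empty[!is.na(empty)]
  if (length(empty)) {
    warning("stream areas with no voxels in the parcellation: ",
            paste(empty, collapse = ", "))
  }
  invisible(empty)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param expect_4d If `TRUE`, error unless the file holds a 4D timeseries.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, expect_4d = FALSE) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  nd <- length(dim(img))
  if (expect_4d && nd != 4L) {
    stop("expected a 4D volume but '", path, "' is ", nd, "D")
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  tr <- NULL
  if (nd == 4L) {
    pd <- RNifti::pixdim(img)
    if (length(pd) >= 4 && pd[4] > 0) tr <- as.numeric(pd[4])
  }
  dat <- array(as.numeric(img), dim(img))
  volume_image(dat, aff, tr_s = tr)
}

#' Write a volume to NIfTI-1
#'
#' @param img A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  nif <- RNifti::asNifti(img$data)
  vox <- sqrt(colSums(img$affine[1:3, 1:3]^2))
  pd <- if (is_4d(img)) c(vox, img$tr_s %||% 1) else vox
  RNifti::`pixdim<-`(nif, pd) -> nif
  aff <- structure(img$affine, code = 2L)
  RNifti::`sform<-`(nif, aff) -> nif
  RNifti::`qform<-`(nif, aff) -> nif
  RNifti::writeNifti(nif, path)
  invisible(path)
}
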