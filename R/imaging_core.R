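#' @useDynLib masel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3-D scalar image with physical grid geometry
#'
#' A `volume_image` holds a 3-D array of intensities (Hounsfield-unit-like for
#' the CT phantoms) together with its physical geometry: voxel spacing in mm,
#' the physical position of voxel (0,0,0), and a 3x3 direction matrix. The
#' physical position of 0-based voxel index `i` is
#' `origin + direction %*% (i * spacing)`.
#'
#' @param voxels 3-D numeric array of finite intensities.
#' @param spacing numeric length-3, voxel spacing in mm, all strictly positive.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param direction 3x3 direction cosine matrix (default identity).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array, got ", length(dim(voxels)), " dimension(s)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all three spacing components must be strictly positive")
  if (!all(is.finite(voxels)))
    stop("all intensities must be finite")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), direction = unname(direction)),
    class = "volume_image")
}

#' Integer label map aligned to a volume image
#'
#' Labels are non-negative integers; 0 is background. `label_names` maps label
#' integers to structure names, e.g. `c("1" = "bladder", "2" = "rectum")`.
#'
#' @param labels 3-D integer array.
#' @param spacing,origin,direction grid geometry, as in [volume_image()].
#' @param label_names named character vector; names are label integers.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3), label_names = character()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (is.double(labels)) {
    if (any(labels != round(labels))) stop("labels must be integers")
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0L)) stop("labels must be non-negative; 0 is background")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("all three spacing components must be strictly positive")
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), direction = unname(direction),
         label_names = label_names),
    class = "label_map")
}

#' Contoured atlas: an image paired with its structure label map
#'
#' @param id unique atlas identifier.
#' @param image a [volume_image()].
#' @param contours a [label_map()] on the same grid.
#' @param structures optional character vector of structure names that must be
#'   present (non-empty) in `contours`.
#' @return An object of class `atlas`.
#' @export
atlas <- function(id, image, contours, structures = NULL) {
  stopifnot(inherits(image, "volume_image"), inherits(contours, "label_map"))
  if (!same_grid(image, contours))
    stop("atlas '", id, "': contours and image must share grid geometry")
  if (!is.null(structures)) {
    for (s in structures) {
      lab <- label_for_structure(contours, s)
      if (!any(contours$labels == lab))
        stop("atlas '", id, "': structure '", s, "' is empty")
    }
  }
  structure(list(id = as.character(id), image = image, contours = contours),
            class = "atlas")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = "x"),
      " @ (", paste(format(x$spacing), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = "x"),
      "; labels: ", paste(sort(unique(as.vector(x$labels))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.atlas <- function(x, ...) {
  cat("<atlas> id:", x$id, "\n")
  print(x$image)
  print(x$contours)
  invisible(x)
}

grid_dim <- function(x) dim(if (inherits(x, "label_map")) x$labels else x$voxels)

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

geometry_of <- function(x) {
  list(dim = grid_dim(x), spacing = x$spacing, origin = x$origin,
       direction = x$direction)
}

# physical coordinates (n x 3, mm) of 0-based voxel indices (n x 3)
phys_from_index <- function(geom, idx) {
  m <- geom$direction %*% diag(geom$spacing)
  sweep(idx %*% t(m), 2, geom$origin, "+")
}

# continuous 0-based voxel indices of physical points (n x 3, mm)
index_from_phys <- function(geom, pts) {
  m <- diag(1 / geom$spacing) %*% t(geom$direction)
  sweep(pts, 2, geom$origin, "-") %*% t(m)
}

# physical coordinates of every voxel centre, n x 3, index (i fastest) order
grid_phys <- function(geom) {
  d <- geom$dim
  xv <- (seq_len(d[1]) - 1)
  yv <- (seq_len(d[2]) - 1)
  zv <- (seq_len(d[3]) - 1)
  idx <- cbind(rep(xv, times = d[2] * d[3]),
               rep(rep(yv, each = d[1]), times = d[3]),
               rep(zv, each = d[1] * d[2]))
  phys_from_index(geom, idx)
}

# sample a 3-D array living on `geom` at physical points (mm)
sample_grid <- function(arr, geom, pts, method = c("linear", "nearest")) {
  method <- match.arg(method)
  idx <- index_from_phys(geom, pts)
  cpp_sample3d(as.double(arr), as.integer(geom$dim), idx,
               method == "nearest")
}

label_for_structure <- function(lm, structure) {
  if (is.numeric(structure)) {
    lab <- as.integer(structure)
    if (!as.character(lab) %in% names(lm$label_names))
      stop("unknown label: ", structure)
    return(lab)
  }
  hit <- names(lm$label_names)[lm$label_names == structure]
  if (length(hit) != 1L) stop("unknown structure: '", structure, "'")
  as.integer(hit)
}

#' Read a NIfTI volume (and label sidecar, if present)
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed). Spacing, origin and
#' direction are taken from the file's affine. If a JSON sidecar
#' `<path>.labels.json` exists (as written by [write_labels()]), the voxel data
#' are additionally interpreted as a label map.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `image` (a [volume_image()]) and `labels`
#'   (a [label_map()], or `NULL` when no sidecar is present).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)),
         " dimension(s) in ", path)
  xf <- RNifti::xform(img)
  m <- unname(xf[1:3, 1:3, drop = FALSE])
  spacing <- sqrt(colSums(m^2))
  direction <- m %*% diag(1 / spacing)
  origin <- unname(xf[1:3, 4])
  attributes(arr) <- list(dim = dim(arr))
  vi <- volume_image(arr * 1.0, spacing, origin, direction)
  sidecar <- paste0(path, ".labels.json")
  lm <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    lm <- label_map(array(as.integer(round(arr)), dim(arr)), spacing, origin,
                    direction, label_names = unlist(meta$label_names))
  }
  list(image = vi, labels = lm)
}

nifti_from <- function(arr, geom, datatype) {
  aff <- diag(4)
  aff[1:3, 1:3] <- geom$direction %*% diag(geom$spacing)
  aff[1:3, 4] <- geom$origin
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a volume image as NIfTI
#'
#' @param x a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume_image"))
  RNifti::writeNifti(nifti_from(x$voxels, geometry_of(x), "double"), path)
  invisible(path)
}

#' Write a label map as NIfTI plus a JSON label-name sidecar
#'
#' The labels go into `<path>` as an integer volume; the label-integer to
#' structure-name mapping goes into `<path>.labels.json`.
#'
#' @param x a [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "label_map"))
  RNifti::writeNifti(nifti_from(x$labels, geometry_of(x), "int32"), path)
  jsonlite::write_json(list(label_names = as.list(x$label_names)),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Surface voxels of a structure, as physical points
#'
#' A voxel of the structure is a surface voxel when at least one of its six
#' face neighbours lies outside the structure; the image boundary counts as
#' outside. Returned points are voxel centres in physical mm.
#'
#' @param mask a [label_map()].
#' @param label label integer or structure name; defaults to "any non-zero".
#' @return n x 3 matrix of physical points (mm).
#' @export
extract_surface_voxels <- function(mask, label = NULL) {
  m <- structure_mask(mask, label)
  if (!any(m)) stop("empty structure: no surface to extract")
  surf <- surface_mask(m)
  idx0 <- which(surf, arr.ind = TRUE) - 1
  phys_from_index(geometry_of(mask), idx0)
}

structure_mask <- function(mask, label = NULL) {
  if (is.null(label)) mask$labels > 0L
  else mask$labels == label_for_structure(mask, label)
}

# logical 6-connectivity surface of a logical array (boundary = outside)
surface_mask <- function(m) {
  d <- dim(m)
  inside <- m
  pad_shift <- function(ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by == 1L) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  all_nb <- inside
  for (ax in 1:3) for (by in c(1L, -1L))
    all_nb <- all_nb & pad_shift(ax, by)
  m & !all_nb
}

#' Volume of one labelled structure, in cc
#'
#' Voxel count times voxel volume: `count * sx*sy*sz / 1000`.
#'
#' @param mask a [label_map()].
#' @param label label integer or structure name.
#' @return volume in cc (cm^3).
#' @export
volume_of_label <- function(mask, label) {
  lab <- label_for_structure(mask, label)
  sum(mask$labels == lab) * prod(mask$spacing) / 1000
}
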