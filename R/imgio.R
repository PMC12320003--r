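#' @keywords internal
"_PACKAGE"

# ---- core image containers ---------------------------------------------

#' Construct a 3D image
#'
#' Lightweight container for a single 3D volume: a numeric voxel array, a
#' 4x4 voxel-to-world affine (mm), and a `kind` tag describing what the
#' volume holds.
#'
#' @param data numeric 3D array (x, y, slice).
#' @param affine 4x4 voxel-to-world matrix in mm. Defaults to identity
#'   spacing of 1 mm.
#' @param kind one of `"anatomical"`, `"fieldmap_hz"`, `"mask"`, `"label"`.
#' @return An object of class `Image3D`.
#' @export
image3d <- function(data, affine = NULL,
                    kind = c("anatomical", "fieldmap_hz", "mask", "label")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L)
    stop("Image3D requires a 3D array, got ", length(dim(data)), " dims")
  if (is.null(affine)) affine <- diag(4)
  affine <- matrix(as.numeric(affine), nrow(as.matrix(affine)))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  data <- array(as.numeric(data), dim(data))   # strip foreign attributes
  if (kind == "fieldmap_hz" && any(!is.finite(data)))
    stop("field map contains non-finite voxels")
  if (kind == "label" && (any(data < 0) || any(data != round(data))))
    stop("label volume must contain non-negative integers")
  if (kind == "mask" && !all(data %in% c(0, 1)))
    stop("mask volume must be binary")
  structure(list(data = data, affine = affine, kind = kind),
            class = "Image3D")
}

#' Construct a 4D functional image series
#'
#' @param data numeric 4D array (x, y, slice, time).
#' @param affine 4x4 voxel-to-world matrix in mm.
#' @param tr_s repetition time in seconds (> 0).
#' @param pe_axis phase-encode axis index, 0 (x) or 1 (y); 0-based to match
#'   the acquisition convention.
#' @return An object of class `Image4D`.
#' @export
image4d <- function(data, affine = NULL, tr_s = 1, pe_axis = 1L) {
  if (length(dim(data)) != 4L)
    stop("Image4D requires a 4D array, got ", length(dim(data)), " dims")
  if (is.null(affine)) affine <- diag(4)
  affine <- matrix(as.numeric(affine), nrow(as.matrix(affine)))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be > 0")
  if (!pe_axis %in% c(0L, 1L)) stop("pe_axis must be 0 or 1")
  data <- array(as.numeric(data), dim(data))   # strip foreign attributes
  structure(list(data = data, affine = affine, tr_s = as.numeric(tr_s),
                 pe_axis = as.integer(pe_axis)),
            class = "Image4D")
}

#' @export
print.Image3D <- function(x, ...) {
  cat("<Image3D> ", paste(dim(x$data), collapse = " x "),
      " kind=", x$kind, "\n", sep = "")
  invisible(x)
}

#' @export
print.Image4D <- function(x, ...) {
  cat("<Image4D> ", paste(dim(x$data), collapse = " x "),
      " TR=", x$tr_s, "s pe_axis=", x$pe_axis, "\n", sep = "")
  invisible(x)
}

#' @export
dim.Image3D <- function(x) dim(x$data)

#' @export
dim.Image4D <- function(x) dim(x$data)

#' Acquisition parameters
#'
#' Bundles the EPI acquisition constants needed for distortion correction.
#' The flip angle is carried as metadata only; no computation uses it.
#'
#' @param tr_s repetition time (s).
#' @param te_s echo time (s).
#' @param matrix integer pair (n_read, n_pe).
#' @param fov_mm field of view in mm, pair.
#' @param eff_echo_spacing_s effective echo spacing (s).
#' @param flip_angle_deg nominal excitation flip angle (degrees), metadata.
#' @return An object of class `AcquisitionParams`.
#' @export
acquisition_params <- function(tr_s = 1.0, te_s = 0.016,
                               matrix = c(96L, 48L),
                               fov_mm = c(24, 12),
                               eff_echo_spacing_s = 3e-4,
                               flip_angle_deg = 55) {
  stopifnot(tr_s > 0, te_s > 0, eff_echo_spacing_s > 0,
            length(matrix) == 2L, all(matrix >= 2),
            length(fov_mm) == 2L, all(fov_mm > 0))
  structure(list(tr_s = tr_s, te_s = te_s,
                 matrix = as.integer(matrix), fov_mm = as.numeric(fov_mm),
                 eff_echo_spacing_s = eff_echo_spacing_s,
                 flip_angle_deg = flip_angle_deg),
            class = "AcquisitionParams")
}

# ---- NIfTI reading / writing -------------------------------------------

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [image3d()] or [image4d()]
#' container. Voxel data are promoted to double precision regardless of the
#' on-disk dtype; denoising SVDs need the precision.
#'
#' @param path path to the NIfTI file.
#' @param expected_kind `"4d"` for a functional series, otherwise one of
#'   the [image3d()] kinds.
#' @param pe_axis phase-encode axis for 4D series (0 or 1).
#' @return `Image3D` or `Image4D`.
#' @export
read_image <- function(path, expected_kind = "anatomical", pe_axis = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  affine <- structure(RNifti::xform(nii), class = NULL)
  nd <- length(dim(arr))
  if (identical(expected_kind, "4d")) {
    if (nd != 4L)
      stop("expected a 4D series but ", path, " has ", nd, " dimensions")
    tr <- RNifti::pixdim(nii)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    return(image4d(arr, affine = affine, tr_s = tr, pe_axis = pe_axis))
  }
  if (nd == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1L, drop = TRUE]
    nd <- length(dim(arr))
  }
  if (nd == 2L) {                  # single-slice volumes lose their
    dim(arr) <- c(dim(arr), 1L)    # trailing singleton on disk
    nd <- 3L
  }
  if (nd != 3L)
    stop("expected a 3D volume but ", path, " has ", nd, " dimensions")
  image3d(arr, affine = affine, kind = expected_kind)
}

#' Write a NIfTI volume
#'
#' Writes an `Image3D` or `Image4D` to disk as NIfTI-1, preserving the
#' affine; for 4D series the TR is stored in the time slot of `pixdim`.
#'
#' @param img an `Image3D` or `Image4D`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  arr <- img$data
  pix <- .affine_spacing(img$affine)
  if (inherits(img, "Image4D")) {
    ref <- list(pixdim = c(-1, pix, img$tr_s, 0, 0, 0))
  } else if (inherits(img, "Image3D")) {
    ref <- list(pixdim = c(-1, pix, 1, 0, 0, 0))
  } else stop("img must be Image3D or Image4D")
  nii <- RNifti::asNifti(arr, reference = ref)
  nii <- RNifti::`sform<-`(nii, structure(img$affine, code = 2L))
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

# voxel spacings (mm) from the affine columns
.affine_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# ---- atlas hierarchy ----------------------------------------------------

#' Construct an atlas hierarchy
#'
#' Combines an integer label volume with a region tree. Regions form a
#' forest: each row names a region id, an acronym, and its parent (NA for
#' roots). Depth is computed from the parentage.
#'
#' @param labels an `Image3D` with `kind = "label"`.
#' @param regions data frame with columns `region_id`, `acronym`,
#'   `parent_id` (NA for roots).
#' @return An object of class `AtlasHierarchy` with a `depth` column added.
#' @export
atlas_hierarchy <- function(labels, regions) {
  stopifnot(inherits(labels, "Image3D"), labels$kind == "label")
  regions <- as.data.frame(regions)
  need <- c("region_id", "acronym", "parent_id")
  if (!all(need %in% names(regions)))
    stop("regions table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(regions$region_id))
    stop("duplicate region ids in table")
  # depth by walking up; also detects cycles
  idx <- match(regions$parent_id, regions$region_id)
  depth <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    d <- 0L; j <- i
    while (!is.na(idx[j])) {
      j <- idx[j]; d <- d + 1L
      if (d > nrow(regions)) stop("cycle detected in region hierarchy")
    }
    depth[i] <- d
  }
  regions$depth <- depth
  present <- setdiff(unique(as.vector(labels$data)), 0)
  missing <- setdiff(present, regions$region_id)
  if (length(missing) > 0)
    stop("label values missing from region table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, regions = regions),
            class = "AtlasHierarchy")
}

#' Read a region-hierarchy table
#'
#' Flat delimited format: columns `region_id`, `acronym`, `parent_id`
#' (empty/NA for roots). A JSON tree dialect (nested objects with `id`,
#' `acronym`, `children`) is accepted as a convenience.
#'
#' @param path CSV (or JSON tree) file.
#' @return data frame with `region_id`, `acronym`, `parent_id`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tree <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- list()
    walk <- function(node, parent) {
      rows[[length(rows) + 1L]] <<- data.frame(
        region_id = as.integer(node$id),
        acronym = as.character(node$acronym),
        parent_id = if (is.null(parent)) NA_integer_ else as.integer(parent))
      for (ch in node$children) walk(ch, node$id)
    }
    if (!is.null(tree$id)) walk(tree, NULL) else for (n in tree) walk(n, NULL)
    return(do.call(rbind, rows))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$region_id <- as.integer(df$region_id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  df
}

#' Write a region-hierarchy table as CSV
#' @param regions region data frame (as in [atlas_hierarchy()]).
#' @param path output CSV path.
#' @export
write_region_table <- function(regions, path) {
  utils::write.csv(regions[c("region_id", "acronym", "parent_id")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Region ids of all descendants (including the region itself)
#' @param atlas an `AtlasHierarchy`.
#' @param region_id region id present in the table.
#' @return integer vector of region ids.
#' @export
region_descendants <- function(atlas, region_id) {
  reg <- atlas$regions
  if (!region_id %in% reg$region_id) stop("unknown region id: ", region_id)
  out <- region_id
  frontier <- region_id
  while (length(frontier) > 0) {
    kids <- reg$region_id[!is.na(reg$parent_id) & reg$parent_id %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

#' Resolve a region to voxel indices
#'
#' Returns the linear (1-based, column-major) indices of voxels carrying
#' the region's label; with `include_descendants` the union over the region
#' and every descendant in the hierarchy.
#'
#' @param atlas an `AtlasHierarchy`.
#' @param region_id region id.
#' @param include_descendants logical; default TRUE.
#' @return sorted integer vector of linear voxel indices.
#' @export
resolve_region <- function(atlas, region_id, include_descendants = TRUE) {
  ids <- if (include_descendants) region_descendants(atlas, region_id)
         else {
           if (!region_id %in% atlas$regions$region_id)
             stop("unknown region id: ", region_id)
           region_id
         }
  which(atlas$labels$data %in% ids)
}

#' Regions at a hierarchy depth
#' @param atlas an `AtlasHierarchy`.
#' @param level depth (0 = roots).
#' @return data frame of regions at that depth.
#' @export
regions_at_level <- function(atlas, level) {
  atlas$regions[atlas$regions$depth == level, , drop = FALSE]
}
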