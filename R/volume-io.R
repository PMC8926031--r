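#' Read a 3D PET volume from a NIfTI file
#'
#' Reads a `.nii` or `.nii.gz` file and returns a `pet_volume` object holding
#' the 3D intensity array, the voxel spacing (mm) and the grid-to-world
#' affine. Volumes are assumed already spatially aligned to the parcellation
#' they will be paired with; no resampling is performed.
#'
#' @param path Path to a readable NIfTI-1 file.
#' @return A `pet_volume`: list with elements `data` (3D numeric array),
#'   `voxel_dims` (length-3 numeric, mm) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("NIfTI file not found: ", path), class = "jsseconn_io_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop the niftiImage wrapping
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    abort(
      sprintf("expected a 3D volume, got %d dimensions: %s",
              length(dim(arr)), path),
      class = "jsseconn_io_error"
    )
  }
  bad <- which(!is.finite(arr))
  if (length(bad) > 0L) {
    idx <- arrayInd(bad[1L], dim(arr))
    abort(
      sprintf("non-finite voxel intensity at index [%d, %d, %d] (%d total) in %s",
              idx[1], idx[2], idx[3], length(bad), path),
      class = "jsseconn_io_error"
    )
  }
  pet_volume(arr,
             voxel_dims = RNifti::pixdim(img)[1:3],
             affine = unclass(RNifti::xform(img)))
}

#' Construct a PET volume object
#'
#' @param data 3D numeric array of voxel intensities.
#' @param voxel_dims Physical voxel spacing in mm (length 3).
#' @param affine 4x4 grid-to-world transform.
#' @return A `pet_volume` object.
#' @export
pet_volume <- function(data, voxel_dims = c(1, 1, 1), affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) {
    abort("pet_volume data must be finite", class = "jsseconn_io_error")
  }
  structure(
    list(data = data, voxel_dims = as.numeric(voxel_dims),
         affine = unname(as.matrix(affine))),
    class = "pet_volume"
  )
}

#' Write a PET volume to a NIfTI file
#'
#' Written with double-precision datatype so synthetic phantoms round-trip
#' bit-for-bit through [read_volume()].
#'
#' @param volume A `pet_volume` (or plain 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (is.array(volume)) volume <- pet_volume(volume)
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_dims
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_dims, 3), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct an atlas-labels object
#'
#' An integer parcellation on the same grid as the PET volumes: 0 marks
#' background, labels `1..n_regions` mark regions. Every region must contain
#' at least 2 voxels so a density can be estimated from it.
#'
#' @param labels 3D integer array of region labels.
#' @param region_names Character vector naming regions in ascending label
#'   order; defaults to the AAL-90 names when there are 90 regions.
#' @param n_regions Number of regions expected (default 90).
#' @return An `atlas_labels` object.
#' @export
atlas_labels <- function(labels, region_names = NULL, n_regions = 90L) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  lab <- as.integer(round(labels))
  if (any(lab < 0L | lab > n_regions)) {
    abort(sprintf("atlas labels must lie in {0..%d}", n_regions),
          class = "jsseconn_atlas_error")
  }
  counts <- tabulate(lab, nbins = n_regions)
  missing <- which(counts < 2L)
  if (length(missing) > 0L) {
    abort(
      sprintf("every region needs >= 2 voxels; deficient region(s): %s",
              paste(missing, collapse = ", ")),
      class = "jsseconn_atlas_error"
    )
  }
  if (is.null(region_names)) region_names <- default_region_names(n_regions)
  if (length(region_names) != n_regions) {
    abort(sprintf("region_names must have length %d", n_regions),
          class = "jsseconn_atlas_error")
  }
  structure(
    list(labels = array(lab, dim = dim(labels)), region_names = region_names,
         n_regions = as.integer(n_regions)),
    class = "atlas_labels"
  )
}

#' Read an atlas parcellation from NIfTI (plus optional region-name TSV)
#'
#' @param path NIfTI file of integer labels (0 background, 1..90 regions).
#' @param names_path Optional two-column TSV (`label`, `name`); defaults to
#'   the AAL-90 table shipped with the package when the atlas has 90 regions.
#' @param n_regions Number of regions expected (default 90).
#' @return An `atlas_labels` object.
#' @export
read_atlas <- function(path, names_path = NULL, n_regions = 90L) {
  vol <- read_volume(path)
  region_names <- NULL
  if (!is.null(names_path)) {
    tbl <- utils::read.delim(names_path, stringsAsFactors = FALSE)
    region_names <- tbl$name[order(tbl$label)]
  }
  atlas_labels(vol$data, region_names = region_names, n_regions = n_regions)
}

#' @export
print.atlas_labels <- function(x, ...) {
  cat("<atlas_labels> ", x$n_regions, " regions on a ",
      paste(dim(x$labels), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Globally normalize a PET volume by its in-mask grand mean
#'
#' Proportional scaling: every in-mask voxel is divided by the grand mean of
#' the in-mask intensities, so the returned in-mask mean is exactly 1.
#' Out-of-mask voxels are set to 0. The brain mask is the union of atlas
#' regions (labels > 0) when an atlas is supplied.
#'
#' @param volume A `pet_volume`.
#' @param mask Logical 3D array, or an `atlas_labels` object (mask = labels
#'   > 0).
#' @return A `pet_volume` with in-mask mean 1.
#' @export
global_normalize <- function(volume, mask) {
  if (inherits(mask, "atlas_labels")) mask <- mask$labels > 0L
  stopifnot(identical(dim(mask), dim(volume$data)))
  if (!any(mask)) {
    abort("empty brain mask", class = "jsseconn_normalize_error")
  }
  grand_mean <- mean(volume$data[mask])
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    abort("in-mask grand mean must be positive for proportional scaling",
          class = "jsseconn_normalize_error")
  }
  out <- array(0, dim = dim(volume$data))
  out[mask] <- volume$data[mask] / grand_mean
  pet_volume(out, volume$voxel_dims, volume$affine)
}

#' Extract per-region voxel-intensity samples
#'
#' Collects, for each atlas region, the (globally normalized) intensities of
#' its voxels in a fixed raster-scan order (R array linear-index order), so
#' sample vectors are reproducible across runs.
#'
#' @param volume A `pet_volume`, already globally normalized.
#' @param atlas An `atlas_labels` on the same grid.
#' @param subject_id Subject identifier string.
#' @param group Optional outcome label, `"SZF"` or `"SZR"`.
#' @return A `roi_samples` object: list of `n_regions` numeric vectors
#'   (named by region), with `subject_id` and `group` attributes.
#' @export
extract_roi_samples <- function(volume, atlas, subject_id = "subject",
                                group = NULL) {
  if (!identical(dim(volume$data), dim(atlas$labels))) {
    abort("volume and atlas grids differ in shape",
          class = "jsseconn_atlas_error")
  }
  lab <- as.vector(atlas$labels)
  vals <- as.vector(volume$data)
  keep <- lab > 0L
  samples <- split(vals[keep], factor(lab[keep], levels = seq_len(atlas$n_regions)))
  sizes <- lengths(samples)
  if (any(sizes < 2L)) {
    abort(
      sprintf("region(s) with < 2 voxels: %s",
              paste(which(sizes < 2L), collapse = ", ")),
      class = "jsseconn_atlas_error"
    )
  }
  roi_samples(setNames(samples, atlas$region_names),
              subject_id = subject_id, group = group)
}

#' Construct a per-subject ROI sample set
#'
#' @param samples List of numeric vectors, one per region, in ascending
#'   label order; each vector holds that region's normalized voxel
#'   intensities.
#' @param subject_id Subject identifier string.
#' @param group Optional outcome label, `"SZF"` or `"SZR"`.
#' @return A `roi_samples` object.
#' @export
roi_samples <- function(samples, subject_id = "subject", group = NULL) {
  stopifnot(is.list(samples))
  ok <- vapply(samples, function(v) length(v) >= 1L && all(is.finite(v)),
               logical(1))
  if (!all(ok)) {
    abort(sprintf("empty or non-finite sample vector for region(s): %s",
                  paste(which(!ok), collapse = ", ")),
          class = "jsseconn_samples_error")
  }
  if (!is.null(group)) group <- match.arg(group, .group_levels)
  structure(samples,
            subject_id = subject_id, group = group, class = "roi_samples")
}

#' @export
print.roi_samples <- function(x, ...) {
  cat("<roi_samples> subject ", attr(x, "subject_id"), ", ",
      length(x), " regions, ",
      paste(range(lengths(x)), collapse = "-"), " voxels/region",
      if (!is.null(attr(x, "group"))) paste0(", group ", attr(x, "group")),
      "\n", sep = "")
  invisible(x)
}

#' Read a subject table (CSV with subject_id, pet_path, group)
#'
#' @param path CSV path.
#' @return Tibble with columns `subject_id`, `pet_path`, `group`.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("subject table not found: ", path),
          class = "jsseconn_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "pet_path", "group")
  if (!all(need %in% names(tbl))) {
    abort(paste0("subject table needs columns: ", paste(need, collapse = ", ")),
          class = "jsseconn_io_error")
  }
  tibble::as_tibble(tbl[need])
}
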