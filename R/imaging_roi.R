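#' MRI volume container
#'
#' A light container for one modality's 3D voxel array plus spacing metadata.
#' Intensities must be finite and the array must be at least as large as the
#' 21 x 21 x 3 region of interest in every dimension.
#'
#' @param voxels 3D numeric array, (x, y, z) order.
#' @param modality `"T2"` or `"ADC"`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm (metadata only; no
#'   resampling is performed anywhere in the package).
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, modality = c("T2", "ADC"), spacing = c(1, 1, 1)) {
  modality <- match.arg(modality)
  if (length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array (got rank ", length(dim(voxels)), ")")
  }
  if (any(!is.finite(voxels))) stop("volume contains non-finite intensities")
  structure(
    list(voxels = voxels, modality = modality, spacing = as.numeric(spacing)),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s, %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Lesion record
#'
#' One lesion per patient: centroid (1-based R voxel indices in (x, y, z)
#' array order — lesion table CSVs on disk use 0-based indices and are
#' converted on read), the Gleason score string, and the derived group label.
#'
#' @param patient_id patient identifier.
#' @param centroid length-3 integer vector of 1-based voxel indices.
#' @param gleason_score score string, e.g. `"6"`, `"3+4"`, `"4+3"`, `"8"`.
#' @param scheme grouping scheme, see [gleason_to_group()].
#' @return An object of class `lesion_record` with a derived `group` field.
#' @export
lesion_record <- function(patient_id, centroid, gleason_score,
                          scheme = c("three", "five")) {
  scheme <- match.arg(scheme)
  centroid <- as.integer(centroid)
  if (length(centroid) != 3L || any(centroid < 1L)) {
    stop("centroid must be three positive (1-based) voxel indices")
  }
  structure(
    list(patient_id = as.character(patient_id),
         centroid = centroid,
         gleason_score = as.character(gleason_score),
         group = gleason_to_group(gleason_score, scheme)),
    class = "lesion_record"
  )
}

#' Map a Gleason score string to a group label
#'
#' The three-group clinical scheme maps Gleason score <= 6 to group 1,
#' 3+4 to group 2, and primary pattern 4 or higher (4+3, 8, 9, 10) to
#' group 3. The five-group scheme is the standard Gleason Grade Group
#' (GGG 1: <= 6; 2: 3+4; 3: 4+3; 4: 8; 5: 9 or 10).
#'
#' @param gleason_score score string; recognized values are `"2"`..`"6"`,
#'   `"3+3"`, `"3+4"`, `"4+3"`, `"7"` is *not* accepted (ambiguous between
#'   3+4 and 4+3), `"8"`, `"4+4"`, `"9"`, `"4+5"`, `"5+4"`, `"10"`, `"5+5"`.
#' @param scheme `"three"` (default) or `"five"`.
#' @return Integer group label.
#' @export
#' @examples
#' gleason_to_group("3+4")            # 2
#' gleason_to_group("4+3")            # 3
#' gleason_to_group("9", "five")      # 5
gleason_to_group <- function(gleason_score, scheme = c("three", "five")) {
  scheme <- match.arg(scheme)
  if (length(gleason_score) > 1L) {
    return(vapply(gleason_score, gleason_to_group, integer(1),
                  scheme = scheme, USE.NAMES = FALSE))
  }
  gs <- gsub("\\s", "", as.character(gleason_score))
  ggg <- switch(gs,
    "2" = , "3" = , "4" = , "5" = , "6" = , "3+3" = 1L,
    "3+4" = 2L,
    "4+3" = 3L,
    "8" = , "4+4" = , "3+5" = , "5+3" = 4L,
    "9" = , "10" = , "4+5" = , "5+4" = , "5+5" = 5L,
    stop("unrecognized Gleason score string: \"", gleason_score, "\"")
  )
  if (scheme == "five") ggg else min(ggg, 3L)
}

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI file (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach (`"T2"` or `"ADC"`).
#' @return An [mri_volume()] with the array in (x, y, z) order and spacing
#'   from the NIfTI header.
#' @export
read_volume <- function(path, modality = c("T2", "ADC")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("volume ", path, " has rank ", length(dim(arr)), ", expected 3")
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  mri_volume(arr, modality, spacing)
}

#' Write an [mri_volume()] as NIfTI
#'
#' @param v an [mri_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mri_volume"))
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize volume intensities
#'
#' Reduces intensity variation across acquisitions. The default linearly
#' rescales the whole volume to \[0, 1\] (min-max); `"zscore"` centers and
#' scales to unit variance. A constant volume maps to all zeros under either
#' method. Because the region-of-interest quantization in [quantize()] is
#' itself patch-local min-max, downstream texture features are invariant to
#' this step; it is retained for inspection and plotting of whole volumes.
#'
#' @param v an [mri_volume()].
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return An [mri_volume()] with rescaled intensities.
#' @export
normalize_volume <- function(v, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(v, "mri_volume"))
  x <- v$voxels
  rng <- range(x)
  out <- if (rng[1] == rng[2]) {
    array(0, dim = dim(x))
  } else if (method == "minmax") {
    (x - rng[1]) / (rng[2] - rng[1])
  } else {
    (x - mean(x)) / sd(x)
  }
  mri_volume(out, v$modality, v$spacing)
}

#' Extract the lesion-centred region of interest
#'
#' Cuts a `size` (default 21 x 21 x 3) window centred on the lesion centroid:
#' the window spans centroid +/- 10 in x and y and centroid +/- 1 in z. If
#' the centred window would cross a volume boundary it is shifted by the
#' minimal amount needed to fit, and a warning is emitted.
#'
#' @param v an [mri_volume()].
#' @param centroid length-3 vector of 1-based voxel indices.
#' @param size odd window dimensions, default `c(21, 21, 3)`.
#' @return An object of class `roi_patch`: list with `voxels` (the window),
#'   `modality`, `patient_id` (optional), and `origin` (1-based index of the
#'   window's first corner in the source volume).
#' @export
extract_roi <- function(v, centroid, size = c(21L, 21L, 3L)) {
  stopifnot(inherits(v, "mri_volume"))
  size <- as.integer(size)
  d <- dim(v$voxels)
  if (any(d < size)) {
    stop("volume (", paste(d, collapse = "x"), ") is smaller than the ",
         paste(size, collapse = "x"), " window")
  }
  centroid <- as.integer(centroid)
  half <- (size - 1L) %/% 2L
  lo <- centroid - half
  shifted <- FALSE
  for (k in 1:3) {
    if (lo[k] < 1L) { lo[k] <- 1L; shifted <- TRUE }
    if (lo[k] + size[k] - 1L > d[k]) { lo[k] <- d[k] - size[k] + 1L; shifted <- TRUE }
  }
  if (shifted) {
    warning("ROI window at centroid (", paste(centroid, collapse = ", "),
            ") shifted to fit inside the volume")
  }
  hi <- lo + size - 1L
  structure(
    list(voxels = v$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
         modality = v$modality,
         origin = lo),
    class = "roi_patch"
  )
}

#' Uniformly quantize a patch to Ng gray levels
#'
#' Equal-width binning over the patch's own intensity range:
#' `level = min(Ng, floor((v - min) / (max - min) * Ng) + 1)`. A constant
#' patch maps to all level 1. Patch-local binning makes every downstream
#' texture feature invariant to affine intensity transforms of the patch
#' (positive slope), i.e. to scanner gain and offset.
#'
#' @param patch an `roi_patch` or a bare numeric array.
#' @param n_levels number of gray levels Ng (default 32).
#' @return An object of class `quantized_patch`: list with integer array
#'   `levels` (values in 1..Ng) and `n_levels`.
#' @export
quantize <- function(patch, n_levels = 32L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be at least 2")
  x <- if (inherits(patch, "roi_patch")) patch$voxels else patch
  if (is.null(dim(x))) stop("patch must be an array")
  if (any(!is.finite(x))) stop("patch contains non-finite intensities")
  rng <- range(x)
  lv <- if (rng[1] == rng[2]) {
    array(1L, dim = dim(x))
  } else {
    array(pmin.int(n_levels,
                   as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * n_levels)) + 1L),
          dim = dim(x))
  }
  quantized_patch(lv, n_levels)
}

#' Construct a quantized patch
#'
#' @param levels integer array with values in `1..n_levels`.
#' @param n_levels number of gray levels.
#' @return An object of class `quantized_patch`.
#' @export
quantized_patch <- function(levels, n_levels) {
  n_levels <- as.integer(n_levels)
  if (is.null(dim(levels))) stop("levels must be an array")
  storage.mode(levels) <- "integer"
  if (min(levels) < 1L || max(levels) > n_levels) {
    stop("levels must lie in 1..", n_levels)
  }
  structure(list(levels = levels, n_levels = n_levels),
            class = "quantized_patch")
}

#' @export
print.quantized_patch <- function(x, ...) {
  cat(sprintf("<quantized_patch> %s voxels, %d gray levels (%d occupied)\n",
              paste(dim(x$levels), collapse = " x "), x$n_levels,
              length(unique(as.vector(x$levels)))))
  invisible(x)
}
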