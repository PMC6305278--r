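#' Specify a synthetic mpMRI cohort
#'
#' Defines the study conditions for the bundled phantom generator: three
#' Gleason-score groups whose lesions differ in the spatial scale of
#' homogeneous intensity "blobs". Group 1 lesions are built from a few large
#' blobs (large connected zones after quantization), group 3 from many small
#' ones, so that gray-level size-zone (GLSZM) statistics separate the groups
#' while first-order intensity statistics do not (blob intensities are drawn
#' from the same distribution in every group).
#'
#' @param n_per_group patients per group; a single count or a length-3 vector
#'   (groups G1, G2, G3).
#' @param volume_shape voxel dimensions of each generated volume, `(nx, ny, nz)`.
#'   The default 64 x 64 x 19 is a scaled stand-in for a clinical
#'   320 x 320 x 19 acquisition and keeps simulation fast.
#' @param lesion_radius in-plane half-width, in voxels, of the textured lesion
#'   box embedded in each volume. Must be at least 10 so the 21 x 21 x 3
#'   region of interest fits inside the lesion.
#' @param blob_scale mean blob diameter in voxels, one value per group.
#'   Strictly decreasing values (default 9, 5, 2) give the group-dependent
#'   zone-size structure; equal values give an exchangeable null cohort.
#' @param noise_sd standard deviation of additive Gaussian voxel noise,
#'   relative to the unit signal range.
#' @param seed integer seed; the whole cohort is a pure function of the spec,
#'   including this seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_lesion_texture()], [write_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = 5, seed = 42)
#' cohort <- generate_cohort(spec)
#' length(cohort)
cohort_spec <- function(n_per_group = 30L,
                        volume_shape = c(64L, 64L, 19L),
                        lesion_radius = 12L,
                        blob_scale = c(9, 5, 2),
                        noise_sd = 0.02,
                        seed = 1L) {
  n_per_group <- as.integer(rep_len(n_per_group, 3L))
  if (any(n_per_group < 2L)) {
    stop("n_per_group must be at least 2 in every group")
  }
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < c(21L, 21L, 3L))) {
    stop("volume_shape must be 3 dimensions, each large enough for a ",
         "21x21x3 region of interest")
  }
  if (length(blob_scale) != 3L || any(!is.finite(blob_scale)) ||
      any(blob_scale <= 0)) {
    stop("blob_scale must be three positive values (one per group)")
  }
  if (lesion_radius < 10L) {
    stop("lesion_radius must be >= 10 voxels so the ROI fits in the lesion")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a nonnegative number")
  }
  structure(
    list(n_per_group = n_per_group,
         volume_shape = volume_shape,
         lesion_radius = as.integer(lesion_radius),
         blob_scale = as.numeric(blob_scale),
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic mpMRI cohort specification\n")
  cat(sprintf("  patients per group : %s\n", paste(x$n_per_group, collapse = "/")))
  cat(sprintf("  volume shape       : %s voxels\n",
              paste(x$volume_shape, collapse = " x ")))
  cat(sprintf("  lesion radius      : %d voxels\n", x$lesion_radius))
  cat(sprintf("  blob scales (G1-G3): %s voxels\n",
              paste(format(x$blob_scale), collapse = ", ")))
  cat(sprintf("  noise sd           : %g\n", x$noise_sd))
  cat(sprintf("  seed               : %d\n", x$seed))
  invisible(x)
}

#' Generate one lesion texture patch
#'
#' Draws a random texture for a single lesion of the given group: homogeneous
#' spherical blobs of mean diameter `spec$blob_scale[group]`, each with an
#' intensity drawn uniformly on \[0, 1\], painted in random order over a
#' constant background (level 0.5), followed by additive Gaussian noise of
#' standard deviation `spec$noise_sd`. Intensities are clamped to \[0, 1\].
#' Blob intensities have the same distribution in every group, so groups
#' differ only in spatial zone-size structure, not in intensity histograms.
#'
#' @param group group index (1, 2 or 3).
#' @param patch_shape dimensions of the patch to draw, `(nx, ny, nz)`.
#' @param spec a [cohort_spec()].
#' @param seed optional integer; when supplied the draw is a pure function of
#'   `(group, patch_shape, spec, seed)`. When `NULL` the current RNG stream
#'   is consumed.
#' @return A numeric array of dimension `patch_shape` with values in \[0, 1\].
#' @export
generate_lesion_texture <- function(group, patch_shape, spec, seed = NULL) {
  if (length(group) != 1L || !group %in% 1:3) {
    stop("invalid group index: ", deparse(substitute(group)), " = ",
         paste(group, collapse = ","), " (must be 1, 2 or 3)")
  }
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != 3L || any(patch_shape < 1L)) {
    stop("patch_shape must be three positive dimensions")
  }
  if (!is.null(seed)) set.seed(seed)

  d <- patch_shape
  arr <- array(0.5, dim = d)
  scale <- spec$blob_scale[group]
  r_mean <- scale / 2
  # expected blob volume, truncated by the slab thickness, sets the blob
  # count needed to cover the patch with high probability
  blob_vol <- min(4 / 3 * pi * r_mean^3, pi * r_mean^2 * d[3])
  n_blobs <- max(1L, ceiling(3 * prod(d) / blob_vol))

  cx <- runif(n_blobs, 0.5, d[1] + 0.5)
  cy <- runif(n_blobs, 0.5, d[2] + 0.5)
  cz <- runif(n_blobs, 0.5, d[3] + 0.5)
  rr <- r_mean * runif(n_blobs, 0.75, 1.25)
  val <- runif(n_blobs)

  for (b in seq_len(n_blobs)) {
    xr <- max(1L, floor(cx[b] - rr[b])):min(d[1], ceiling(cx[b] + rr[b]))
    yr <- max(1L, floor(cy[b] - rr[b])):min(d[2], ceiling(cy[b] + rr[b]))
    zr <- max(1L, floor(cz[b] - rr[b])):min(d[3], ceiling(cz[b] + rr[b]))
    dx2 <- (xr - cx[b])^2
    dy2 <- (yr - cy[b])^2
    dz2 <- (zr - cz[b])^2
    mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rr[b]^2
    sub <- arr[xr, yr, zr, drop = FALSE]
    sub[mask] <- val[b]
    arr[xr, yr, zr] <- sub
  }
  if (spec$noise_sd > 0) {
    arr <- arr + rnorm(length(arr), sd = spec$noise_sd)
    arr <- pmin(pmax(arr, 0), 1)
  }
  arr
}

# gleason score strings assigned per synthetic group; group 3 cycles through
# the primary-pattern >= 4 scores
.gs_pool <- list("6", "3+4", c("4+3", "8", "9", "10"))

#' Generate a synthetic cohort of paired T2/ADC volumes
#'
#' Produces `sum(spec$n_per_group)` synthetic patients. Each patient has a
#' T2-weighted and an ADC volume of shape `spec$volume_shape`: a quiet
#' background (level 0.35 with light noise) with a textured lesion box
#' embedded at a random centroid chosen so the full 21 x 21 x 3 region of
#' interest fits inside the volume. The T2 and ADC lesion textures are
#' independent draws with the same group parameters.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `synthetic_patient` objects, each with elements
#'   `patient_id`, `t2_volume`, `adc_volume` (see [mri_volume()]),
#'   `lesion` (see [lesion_record()]) and `true_group`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$volume_shape
  hx <- spec$lesion_radius
  hz <- min(2L, (d[3] - 1L) %/% 2L)
  # centroid margins: ROI needs +/-10 in-plane and +/-1 in z; the lesion box
  # needs +/-hx and +/-hz
  mx <- max(10L, hx)
  mz <- max(1L, hz)
  if (d[1] < 2L * mx + 1L || d[2] < 2L * mx + 1L || d[3] < 2L * mz + 1L) {
    stop("volume_shape ", paste(d, collapse = "x"),
         " is too small to embed the lesion with a full ROI margin")
  }

  n <- spec$n_per_group
  groups <- rep(1:3, n)
  total <- sum(n)
  set.seed(spec$seed)
  patient_seeds <- sample.int(2147483646L, total)

  box <- c(2L * hx + 1L, 2L * hx + 1L, 2L * hz + 1L)
  idx_in_group <- unlist(lapply(n, seq_len))

  patients <- vector("list", total)
  for (i in seq_len(total)) {
    set.seed(patient_seeds[i])
    g <- groups[i]
    centroid <- c(sample((mx + 1L):(d[1] - mx), 1L),
                  sample((mx + 1L):(d[2] - mx), 1L),
                  sample((mz + 1L):(d[3] - mz), 1L))
    make_vol <- function(modality, spacing) {
      arr <- array(0.35, dim = d)
      if (spec$noise_sd > 0) {
        arr <- arr + rnorm(length(arr), sd = spec$noise_sd / 2)
      }
      tex <- generate_lesion_texture(g, box, spec)
      xr <- (centroid[1] - hx):(centroid[1] + hx)
      yr <- (centroid[2] - hx):(centroid[2] + hx)
      zr <- (centroid[3] - hz):(centroid[3] + hz)
      arr[xr, yr, zr] <- tex
      mri_volume(pmin(pmax(arr, 0), 1), modality, spacing)
    }
    t2 <- make_vol("T2", c(0.5, 0.5, 3.6))
    adc <- make_vol("ADC", c(2, 2, 3.6))
    pool <- .gs_pool[[g]]
    gs <- pool[((idx_in_group[i] - 1L) %% length(pool)) + 1L]
    pid <- sprintf("P%03d", i)
    patients[[i]] <- structure(
      list(patient_id = pid,
           t2_volume = t2,
           adc_volume = adc,
           lesion = lesion_record(pid, centroid, gs),
           true_group = g),
      class = "synthetic_patient"
    )
  }
  patients
}

#' Write a synthetic cohort to disk
#'
#' Writes one gzipped NIfTI file per modality per patient, a lesion table CSV
#' (columns `patient_id, x, y, z, gleason_score, group`; centroid coordinates
#' are 0-based voxel indices in (x, y, z) array order, as stated in the CSV
#' comment header), and a JSON manifest listing every written path.
#'
#' @param patients list of patients from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite existing files? Default `FALSE`: any collision
#'   with an existing file is an error before anything is written.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(patients, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  vol_files <- file.path(out_dir, c(paste0(ids, "_T2.nii.gz"),
                                    paste0(ids, "_ADC.nii.gz")))
  csv_file <- file.path(out_dir, "lesions.csv")
  manifest_file <- file.path(out_dir, "manifest.json")
  targets <- c(vol_files, csv_file, manifest_file)
  existing <- targets[file.exists(targets)]
  if (length(existing) && !overwrite) {
    stop("refusing to overwrite existing files (set overwrite = TRUE): ",
         paste(basename(existing), collapse = ", "))
  }

  for (p in patients) {
    write_volume(p$t2_volume,
                 file.path(out_dir, paste0(p$patient_id, "_T2.nii.gz")))
    write_volume(p$adc_volume,
                 file.path(out_dir, paste0(p$patient_id, "_ADC.nii.gz")))
  }

  tab <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id,
               x = p$lesion$centroid[1] - 1L,
               y = p$lesion$centroid[2] - 1L,
               z = p$lesion$centroid[3] - 1L,
               gleason_score = p$lesion$gleason_score,
               group = p$lesion$group,
               stringsAsFactors = FALSE)
  }))
  con <- file(csv_file, "w")
  writeLines("# centroid coordinates are 0-based voxel indices in (x, y, z) array order",
             con)
  write.csv(tab, con, row.names = FALSE)
  close(con)

  manifest <- list(
    n_patients = length(patients),
    lesion_table = basename(csv_file),
    volumes = lapply(patients, function(p) {
      list(patient_id = p$patient_id,
           t2 = paste0(p$patient_id, "_T2.nii.gz"),
           adc = paste0(p$patient_id, "_ADC.nii.gz"))
    })
  )
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_file)
}

#' Read a lesion table CSV
#'
#' Reads the lesion-table dialect written by [write_cohort()] (and used for
#' external cohorts): columns `patient_id, x, y, z, gleason_score, group` with
#' 0-based voxel centroid coordinates. Returns a list of [lesion_record()]
#' objects with 1-based centroids ready for [extract_roi()]; the `group`
#' column, if present, is checked against [gleason_to_group()].
#'
#' @param path CSV path.
#' @param scheme grouping scheme passed to [gleason_to_group()].
#' @return List of `lesion_record` objects.
#' @export
read_lesion_table <- function(path, scheme = c("three", "five")) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop("lesion table not found: ", path)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("patient_id", "x", "y", "z", "gleason_score")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("lesion table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    lesion_record(tab$patient_id[i],
                  centroid = c(tab$x[i], tab$y[i], tab$z[i]) + 1L,
                  gleason_score = as.character(tab$gleason_score[i]),
                  scheme = scheme)
  })
}
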