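# The 41 radiomic features: 6 histogram, 19 GLCM, 5 NGTDM, 11 GLSZM,
# in fixed canonical order.

#' Canonical feature names
#'
#' Returns the 41 feature names in canonical order: 6 histogram, 19 GLCM,
#' 5 NGTDM, 11 GLSZM, prefixed by family (`hist_`, `glcm_`, `ngtdm_`,
#' `glszm_`).
#'
#' @return Character vector of length 41.
#' @export
feature_names <- function() {
  c(paste0("hist_", c("mean", "variance", "skewness", "kurtosis",
                      "energy", "entropy")),
    paste0("glcm_", c("angular_second_moment", "contrast", "correlation",
                      "sum_of_squares_variance", "homogeneity",
                      "sum_average", "sum_variance", "sum_entropy",
                      "entropy", "difference_variance", "difference_entropy",
                      "information_correlation_1", "information_correlation_2",
                      "autocorrelation", "dissimilarity", "cluster_shade",
                      "cluster_prominence", "maximum_probability",
                      "inverse_difference")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")),
    paste0("glszm_", c("small_zone_size_emphasis", "large_zone_size_emphasis",
                       "low_gray_level_zone_emphasis",
                       "high_gray_level_zone_emphasis",
                       "small_zone_low_gray_emphasis",
                       "small_zone_high_gray_emphasis",
                       "large_zone_low_gray_emphasis",
                       "large_zone_high_gray_emphasis",
                       "gray_level_nonuniformity",
                       "zone_size_nonuniformity",
                       "zone_size_percentage")))
}

#' First-order histogram features
#'
#' Six intensity statistics of the quantized gray-level histogram: mean,
#' variance, skewness, kurtosis (excess), energy `sum(h^2)` and entropy
#' `-sum(h * log2(h))`, where `h` is the normalized level histogram. They
#' are computed on quantized levels (not raw intensities) so they are
#' commensurate across scanners. A zero-variance patch has skewness and
#' kurtosis defined as 0.
#'
#' @param q a [quantized_patch()].
#' @return Named numeric vector of length 6.
#' @export
histogram_features <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  lv <- as.vector(q$levels)
  h <- tabulate(lv, nbins = q$n_levels) / length(lv)
  k <- seq_len(q$n_levels)
  mu <- sum(k * h)
  v <- sum((k - mu)^2 * h)
  if (v > 0) {
    skew <- sum((k - mu)^3 * h) / v^1.5
    kurt <- sum((k - mu)^4 * h) / v^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  hp <- h[h > 0]
  out <- c(mu, v, skew, kurt, sum(h^2), -sum(hp * log2(hp)))
  names(out) <- feature_names()[1:6]
  out
}

#' GLCM texture features
#'
#' The 19 co-occurrence features (Haralick and related conventions) computed
#' from a normalized [compute_glcm()] matrix: angular second moment,
#' contrast, correlation, sum-of-squares variance, homogeneity (inverse
#' difference moment), sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, the two information measures of
#' correlation, autocorrelation, dissimilarity, cluster shade, cluster
#' prominence, maximum probability and inverse difference. All entropies use
#' base-2 logarithms. Correlation of a zero-variance matrix is defined as 0.
#'
#' @param m a `glcm` from [compute_glcm()].
#' @return Named numeric vector of length 19.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  if (abs(sum(m$P) - 1) > 1e-8) stop("GLCM is not normalized")
  P <- m$P
  ng <- m$n_levels
  i <- row(P); j <- col(P)
  lev <- seq_len(ng)
  ks <- 2:(2 * ng)          # support of p_{x+y}
  kd <- 0:(ng - 1)          # support of p_{x-y}
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (m$sigma_x > 0 && m$sigma_y > 0) {
    (sum(i * j * P) - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  } else 0
  ssq_var <- sum((i - m$mu_x)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(ks * m$p_xplusy)
  sum_var <- sum((ks - sum_avg)^2 * m$p_xplusy)
  sum_ent <- ent(m$p_xplusy)
  entropy <- m$HXY
  mu_d <- sum(kd * m$p_xminusy)
  diff_var <- sum((kd - mu_d)^2 * m$p_xminusy)
  diff_ent <- ent(m$p_xminusy)
  denom <- max(m$HX, m$HY)
  ic1 <- if (denom > 0) (m$HXY - m$HXY1) / denom else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (m$HXY2 - m$HXY))))
  autocorr <- sum(i * j * P)
  dissim <- sum(abs(i - j) * P)
  cs_base <- i + j - m$mu_x - m$mu_y
  cluster_shade <- sum(cs_base^3 * P)
  cluster_prom <- sum(cs_base^4 * P)
  max_prob <- max(P)
  inv_diff <- sum(P / (1 + abs(i - j)))

  out <- c(asm, contrast, correlation, ssq_var, homogeneity, sum_avg,
           sum_var, sum_ent, entropy, diff_var, diff_ent, ic1, ic2,
           autocorr, dissim, cluster_shade, cluster_prom, max_prob, inv_diff)
  names(out) <- feature_names()[7:25]
  out
}

#' NGTDM texture features
#'
#' The five Amadasun features from a [compute_ngtdm()] matrix: coarseness
#' `1 / (eps + sum(p_i * s_i))`, contrast, busyness, complexity and texture
#' strength. A patch with a single occupied gray level has contrast,
#' busyness, complexity and strength defined as 0 (and coarseness `1/eps`).
#'
#' @param m an `ngtdm` from [compute_ngtdm()].
#' @param eps small positive guard in the coarseness and strength
#'   denominators (default `1e-6`).
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(m, eps = 1e-6) {
  stopifnot(inherits(m, "ngtdm"))
  if (m$n == 0) stop("NGTDM has no valid voxels")
  occ <- which(m$p_i > 0)
  p <- m$p_i[occ]; s <- m$s_i[occ]; lev <- occ
  ngp <- length(occ)
  ps <- sum(p * s)

  coarseness <- 1 / (eps + ps)
  if (ngp > 1) {
    dif2 <- outer(lev, lev, function(a, b) (a - b)^2)
    pp <- outer(p, p)
    contrast <- sum(pp * dif2) / (ngp * (ngp - 1)) * sum(m$s_i) / m$n
    busy_den <- sum(abs(outer(lev * p, lev * p, `-`)))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    psum <- outer(p, p, `+`)
    pssum <- outer(p * s, p * s, `+`)
    dif <- abs(outer(lev, lev, `-`))
    complexity <- sum(dif * pssum / (m$n * psum))
    strength <- sum(psum * dif2) / (eps + sum(m$s_i))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c(coarseness, contrast, busyness, complexity, strength)
  names(out) <- feature_names()[26:30]
  out
}

#' GLSZM texture features
#'
#' The 11 size-zone features from a [compute_glszm()] matrix, each
#' normalized by the total zone count `N_z`: small/large zone size emphasis,
#' low/high gray-level zone emphasis, the four joint emphases, gray-level
#' non-uniformity, zone-size non-uniformity, and zone size percentage
#' (`N_z / N_v`, the zone count per voxel — 1 when every voxel is its own
#' zone, small when the patch is dominated by large homogeneous zones).
#'
#' @param m a `glszm` from [compute_glszm()].
#' @return Named numeric vector of length 11.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "glszm"))
  if (m$n_z < 1) stop("empty size-zone matrix")
  Z <- m$Z
  nz <- m$n_z
  i <- row(Z); s <- col(Z)
  sze <- sum(Z / s^2) / nz
  lze <- sum(Z * s^2) / nz
  lgze <- sum(Z / i^2) / nz
  hgze <- sum(Z * i^2) / nz
  szlge <- sum(Z / (i^2 * s^2)) / nz
  szhge <- sum(Z * i^2 / s^2) / nz
  lzlge <- sum(Z * s^2 / i^2) / nz
  lzhge <- sum(Z * s^2 * i^2) / nz
  gln <- sum(rowSums(Z)^2) / nz
  zsn <- sum(colSums(Z)^2) / nz
  zsp <- nz / m$n_v
  out <- c(sze, lze, lgze, hgze, szlge, szhge, lzlge, lzhge, gln, zsn, zsp)
  names(out) <- feature_names()[31:41]
  out
}

#' All 41 features of one quantized patch
#'
#' Builds the three texture matrices and assembles the full named feature
#' vector in canonical order.
#'
#' @param q a [quantized_patch()].
#' @param glcm_distance,glcm_directions,glcm_symmetric passed to
#'   [compute_glcm()].
#' @param glszm_connectivity passed to [compute_glszm()].
#' @param eps passed to [ngtdm_features()].
#' @return Named numeric vector of length 41.
#' @export
patch_features <- function(q, glcm_distance = 1L, glcm_directions = "all13",
                           glcm_symmetric = TRUE, glszm_connectivity = 26L,
                           eps = 1e-6) {
  c(histogram_features(q),
    glcm_features(compute_glcm(q, glcm_distance, glcm_directions,
                               glcm_symmetric)),
    ngtdm_features(compute_ngtdm(q), eps = eps),
    glszm_features(compute_glszm(q, glszm_connectivity)))
}

#' Per-patient feature vector across modalities
#'
#' Features are extracted separately from the T2 and ADC patches; in
#' `"mean"` mode (the default analysis) the elementwise arithmetic mean of
#' the two 41-vectors is returned, in `"T2"`/`"ADC"` mode that single
#' modality's vector.
#'
#' @param t2 [quantized_patch()] from the T2 ROI (may be `NULL` in `"ADC"`
#'   mode).
#' @param adc [quantized_patch()] from the ADC ROI (may be `NULL` in `"T2"`
#'   mode).
#' @param mode `"mean"`, `"T2"` or `"ADC"`.
#' @param ... passed to [patch_features()].
#' @return Named numeric vector of length 41 with attribute `mode`.
#' @export
extract_patient_features <- function(t2, adc, mode = c("mean", "T2", "ADC"),
                                     ...) {
  mode <- match.arg(mode)
  if (mode == "T2") {
    out <- patch_features(t2, ...)
  } else if (mode == "ADC") {
    out <- patch_features(adc, ...)
  } else {
    if (t2$n_levels != adc$n_levels) {
      stop("T2 and ADC patches are quantized with different numbers of ",
           "gray levels (", t2$n_levels, " vs ", adc$n_levels, ")")
    }
    out <- (patch_features(t2, ...) + patch_features(adc, ...)) / 2
  }
  attr(out, "mode") <- mode
  out
}

#' Cohort feature table
#'
#' Assembles a patients x 41 feature table (plus `patient_id` and `group`
#' columns) from a list of in-memory synthetic patients, applying the full
#' per-patient chain: intensity normalization, 21 x 21 x 3 ROI extraction at
#' the lesion centroid, quantization to `n_levels`, feature extraction, and
#' (in `"mean"` mode) modality averaging.
#'
#' @param patients list of `synthetic_patient` objects (or any list whose
#'   elements have `t2_volume`, `adc_volume` and `lesion` fields).
#' @param mode feature mode, see [extract_patient_features()].
#' @param n_levels gray levels for [quantize()] (default 32).
#' @param roi_size window passed to [extract_roi()].
#' @param ... passed on to [patch_features()].
#' @return A `feature_table`: a data.frame with columns `patient_id`,
#'   `group`, then the 41 features; attribute `scaled` is `FALSE`.
#' @export
cohort_features <- function(patients, mode = c("mean", "T2", "ADC"),
                            n_levels = 32L, roi_size = c(21L, 21L, 3L), ...) {
  mode <- match.arg(mode)
  rows <- lapply(patients, function(p) {
    quant <- function(vol) {
      v <- normalize_volume(vol)
      quantize(extract_roi(v, p$lesion$centroid, roi_size), n_levels)
    }
    t2 <- if (mode != "ADC") quant(p$t2_volume) else NULL
    adc <- if (mode != "T2") quant(p$adc_volume) else NULL
    extract_patient_features(t2, adc, mode, ...)
  })
  feature_table(do.call(rbind, rows),
                patient_id = vapply(patients, function(p) p$patient_id,
                                    character(1)),
                group = vapply(patients, function(p) p$lesion$group,
                               integer(1)))
}

#' Construct a feature table
#'
#' @param x numeric matrix, patients x 41, columns named as
#'   [feature_names()] (unnamed matrices are assigned the canonical names).
#' @param patient_id character vector of patient identifiers.
#' @param group integer group labels.
#' @param scaled scaling state flag.
#' @return A `feature_table` data.frame.
#' @export
feature_table <- function(x, patient_id, group, scaled = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- feature_names()
  if (any(!is.finite(x))) stop("feature table contains non-finite values")
  out <- data.frame(patient_id = as.character(patient_id),
                    group = as.integer(group),
                    x, stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "scaled") <- scaled
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param tab a `feature_table`.
#' @return Numeric matrix (patients x features) with patient IDs as row
#'   names.
#' @export
feature_matrix <- function(tab) {
  m <- as.matrix(tab[, setdiff(names(tab), c("patient_id", "group")),
                     drop = FALSE])
  rownames(m) <- tab$patient_id
  m
}

#' Min-max scale a feature table over the cohort
#'
#' Rescales each feature column linearly to \[0, 1\] over the cohort
#' (constant columns map to zeros, with a warning). The scaling parameters
#' are stored in the result so held-out patients can be mapped with the
#' training parameters via the `params` argument — in which case values may
#' legitimately fall outside \[0, 1\]; no clipping is applied. Rank-based
#' statistics (Kruskal-Wallis, Spearman) are invariant to this scaling.
#'
#' @param tab a raw `feature_table`.
#' @param params optional scaling parameters (attribute `"scaling"` of a
#'   previously scaled table) to reuse instead of recomputing.
#' @return A scaled `feature_table` with attributes `scaled = TRUE` and
#'   `"scaling"` (list of per-feature `lo` and `hi`).
#' @export
scale_features <- function(tab, params = NULL) {
  stopifnot(inherits(tab, "feature_table"))
  if (isTRUE(attr(tab, "scaled"))) {
    stop("feature table is already scaled; refusing to double-scale")
  }
  m <- feature_matrix(tab)
  if (is.null(params)) {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    if (any(hi == lo)) {
      warning("constant feature column(s) scaled to zero: ",
              paste(colnames(m)[hi == lo], collapse = ", "))
    }
    params <- list(lo = lo, hi = hi)
  }
  span <- params$hi - params$lo
  span[span == 0] <- 1   # constant columns map to 0
  scaled <- sweep(sweep(m, 2, params$lo), 2, span, "/")
  out <- feature_table(scaled, tab$patient_id, tab$group, scaled = TRUE)
  attr(out, "scaling") <- params
  out
}
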