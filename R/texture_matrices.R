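# Texture-matrix builders: gray-level co-occurrence (GLCM), neighborhood
# gray-tone difference (NGTDM) and gray-level size-zone (GLSZM) matrices
# computed from a quantized 3D patch.

# The 13 unique 3D direction offsets at unit chessboard distance (one per
# antipodal pair of the 26-neighborhood); "axial4" keeps the 4 in-plane ones.
glcm_offsets <- function(directions = c("all13", "axial4")) {
  if (is.matrix(directions)) {
    stopifnot(ncol(directions) == 3L)
    return(directions)
  }
  directions <- match.arg(directions)
  all13 <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  if (directions == "all13") all13 else all13[c(1, 2, 4, 5), , drop = FALSE]
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of gray-level pairs at the given voxel
#' distance over the 13 unique 3D direction offsets (or the 4 in-plane ones,
#' or a custom offset matrix), pools the counts across directions, and
#' normalizes to a probability matrix. With `symmetric = TRUE` (the standard
#' Haralick convention) each voxel pair is counted in both orders.
#'
#' Marginal quantities used by [glcm_features()] are precomputed and stored:
#' row/column marginals `px`, `py`, the diagonal sums `p_xplusy` (k = 2..2Ng)
#' and `p_xminusy` (k = 0..Ng-1), means/SDs `mu_x`, `mu_y`, `sigma_x`,
#' `sigma_y`, and the entropies `HX`, `HY`, `HXY`, `HXY1`, `HXY2` (base-2
#' logarithms; zero-probability terms contribute 0).
#'
#' @param q a [quantized_patch()].
#' @param distance offset length in voxels (default 1).
#' @param directions `"all13"` (default), `"axial4"`, or an n x 3 integer
#'   matrix of custom offsets.
#' @param symmetric count each pair in both orders (default `TRUE`).
#' @return An object of class `glcm`.
#' @export
compute_glcm <- function(q, distance = 1L, directions = "all13",
                         symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_patch"))
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1 voxel")
  offs <- glcm_offsets(directions) * distance
  lv <- q$levels
  ng <- q$n_levels
  d <- dim(lv)

  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    xr <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
    if (!length(xr) || !length(yr) || !length(zr)) next
    a <- lv[xr, yr, zr]
    b <- lv[xr + o[1], yr + o[2], zr + o[3]]
    code <- a + (b - 1L) * ng
    counts <- counts + matrix(tabulate(code, nbins = ng * ng), ng, ng)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) stop("no voxel pairs at distance ", distance)
  P <- counts / total

  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(ng)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sigma_x <- sqrt(sum((lev - mu_x)^2 * px))
  sigma_y <- sqrt(sum((lev - mu_y)^2 * py))
  p_xplusy <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  p_xminusy <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  pxy <- outer(px, py)
  keep <- P > 0 & pxy > 0
  structure(
    list(P = P, n_levels = ng, symmetric = symmetric,
         px = px, py = py, p_xplusy = p_xplusy, p_xminusy = p_xminusy,
         mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
         HX = ent(px), HY = ent(py), HXY = ent(P),
         HXY1 = -sum(P[keep] * log2(pxy[keep])),
         HXY2 = ent(pxy)),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d x %d, %ssymmetric, entropy %.3f bits\n",
              x$n_levels, x$n_levels, if (x$symmetric) "" else "non-",
              x$HXY))
  invisible(x)
}

#' Neighborhood gray-tone difference matrix
#'
#' For every voxel with a complete 26-neighborhood (the interior of the
#' patch; for a 21 x 21 x 3 patch this is the middle slice's interior), the
#' absolute difference between the voxel's level and the mean of its 26
#' neighbors (centre excluded) is accumulated per gray level: `s_i` is the
#' sum of differences over valid voxels at level i, `n_i` their count,
#' `p_i = n_i / n`.
#'
#' @param q a [quantized_patch()].
#' @return An object of class `ngtdm`: list with vectors `n_i`, `s_i`, `p_i`
#'   (length Ng), the valid-voxel count `n`, and `n_gp` (levels with
#'   `p_i > 0`).
#' @export
compute_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  lv <- q$levels
  ng <- q$n_levels
  d <- dim(lv)
  if (any(d < 3L)) {
    stop("no voxel has a complete 26-neighborhood in a ",
         paste(d, collapse = "x"), " patch")
  }
  xr <- 2:(d[1] - 1L); yr <- 2:(d[2] - 1L); zr <- 2:(d[3] - 1L)
  nb_sum <- array(0, dim = c(length(xr), length(yr), length(zr)))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb_sum <- nb_sum + lv[xr + dx, yr + dy, zr + dz, drop = FALSE]
  }
  centre <- lv[xr, yr, zr, drop = FALSE]
  dev <- abs(centre - nb_sum / 26)
  n_i <- tabulate(centre, nbins = ng)
  s_i <- vapply(seq_len(ng), function(l) sum(dev[centre == l]), numeric(1))
  n <- sum(n_i)
  structure(
    list(n_i = n_i, s_i = s_i, p_i = n_i / n, n = n,
         n_gp = sum(n_i > 0), n_levels = ng),
    class = "ngtdm"
  )
}

#' Gray-level size-zone matrix
#'
#' Partitions the patch into maximal connected zones of equal gray level
#' (26-connected in 3D by default, i.e. face, edge and corner neighbors) and
#' counts zones by gray level and size: `Z[i, s]` is the number of zones of
#' level i comprising s voxels. Every voxel belongs to exactly one zone, so
#' `sum(s * Z[, s]) == prod(dim(patch))`.
#'
#' @param q a [quantized_patch()].
#' @param connectivity 26 (default) or 6.
#' @return An object of class `glszm`: list with matrix `Z` (Ng x max zone
#'   size), total zone count `n_z`, and voxel count `n_v`.
#' @export
compute_glszm <- function(q, connectivity = 26L) {
  stopifnot(inherits(q, "quantized_patch"))
  zones <- .zone_list_cpp(as.integer(q$levels), dim(q$levels),
                          as.integer(connectivity))
  smax <- max(zones$size)
  Z <- matrix(0, q$n_levels, smax)
  for (r in seq_len(nrow(zones))) {
    Z[zones$level[r], zones$size[r]] <- Z[zones$level[r], zones$size[r]] + 1
  }
  structure(
    list(Z = Z, n_z = nrow(zones), n_v = length(q$levels),
         n_levels = q$n_levels),
    class = "glszm"
  )
}

#' @export
print.glszm <- function(x, ...) {
  cat(sprintf("<glszm> %d zones over %d voxels (largest %d)\n",
              x$n_z, x$n_v, ncol(x$Z)))
  invisible(x)
}
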