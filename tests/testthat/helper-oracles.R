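# Independent brute-force oracles used to validate the texture-matrix and
# feature implementations. These deliberately use naive per-voxel loops and
# literal formula transcriptions, sharing no code with the package internals.

make_patch <- function(vals, dims, ng) {
  quantized_patch(array(as.integer(vals), dim = dims), ng)
}

random_quantized_patch <- function(dims, ng, seed) {
  set.seed(seed)
  make_patch(sample.int(ng, prod(dims), replace = TRUE), dims, ng)
}

# -- GLCM: count voxel pairs one by one -------------------------------------
oracle_glcm <- function(q, offsets, symmetric = TRUE) {
  lv <- q$levels
  ng <- q$n_levels
  d <- dim(lv)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
      if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
          zz >= 1 && zz <= d[3]) {
        a <- lv[x, y, z]; b <- lv[xx, yy, zz]
        counts[a, b] <- counts[a, b] + 1
        if (symmetric) counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# -- NGTDM: explicit neighborhood loop --------------------------------------
oracle_ngtdm <- function(q) {
  lv <- q$levels
  ng <- q$n_levels
  d <- dim(lv)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    nb <- c()
    complete <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) {
        complete <- FALSE
      } else {
        nb <- c(nb, lv[xx, yy, zz])
      }
    }
    if (complete) {
      l <- lv[x, y, z]
      n_i[l] <- n_i[l] + 1
      s_i[l] <- s_i[l] + abs(l - mean(nb))
    }
  }
  list(n_i = n_i, s_i = s_i, n = sum(n_i))
}

# -- GLSZM: stack-based flood fill over coordinates -------------------------
oracle_glszm_zones <- function(q, connectivity = 26) {
  lv <- q$levels
  d <- dim(lv)
  visited <- array(FALSE, d)
  zones <- list()
  for (x0 in seq_len(d[1])) for (y0 in seq_len(d[2])) for (z0 in seq_len(d[3])) {
    if (visited[x0, y0, z0]) next
    lev <- lv[x0, y0, z0]
    stack <- list(c(x0, y0, z0))
    visited[x0, y0, z0] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
        xx <- v[1] + dx; yy <- v[2] + dy; zz <- v[3] + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        if (!visited[xx, yy, zz] && lv[xx, yy, zz] == lev) {
          visited[xx, yy, zz] <- TRUE
          stack[[length(stack) + 1L]] <- c(xx, yy, zz)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_matrix <- function(q, connectivity = 26) {
  zones <- oracle_glszm_zones(q, connectivity)
  Z <- matrix(0, q$n_levels, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) {
    Z[zones[r, 1], zones[r, 2]] <- Z[zones[r, 1], zones[r, 2]] + 1
  }
  Z
}

# -- feature-formula oracles (literal transcriptions) -----------------------
oracle_hist_features <- function(q) {
  lv <- as.numeric(q$levels)
  m <- mean(lv)
  v <- mean((lv - m)^2)
  h <- as.numeric(table(lv)) / length(lv)
  c(mean = m,
    variance = v,
    skewness = if (v > 0) mean((lv - m)^3) / v^1.5 else 0,
    kurtosis = if (v > 0) mean((lv - m)^4) / v^2 - 3 else 0,
    energy = sum(h^2),
    entropy = -sum(h * log2(h)))
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- H(px); hy <- H(py); hxy <- H(P)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (px[i] * py[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  f <- numeric(19)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f[1] <- f[1] + p^2
    f[2] <- f[2] + (i - j)^2 * p
    f[4] <- f[4] + (i - mux)^2 * p
    f[5] <- f[5] + p / (1 + (i - j)^2)
    f[14] <- f[14] + i * j * p
    f[15] <- f[15] + abs(i - j) * p
    f[16] <- f[16] + (i + j - mux - muy)^3 * p
    f[17] <- f[17] + (i + j - mux - muy)^4 * p
    f[19] <- f[19] + p / (1 + abs(i - j))
  }
  f[3] <- if (sx > 0 && sy > 0) (f[14] - mux * muy) / (sx * sy) else 0
  sa <- sum((2:(2 * ng)) * psum[2:(2 * ng)])
  f[6] <- sa
  f[7] <- sum(((2:(2 * ng)) - sa)^2 * psum[2:(2 * ng)])
  f[8] <- H(psum)
  f[9] <- hxy
  mud <- sum((0:(ng - 1)) * pdiff)
  f[10] <- sum(((0:(ng - 1)) - mud)^2 * pdiff)
  f[11] <- H(pdiff)
  f[12] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  f[13] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f[18] <- max(P)
  f
}

oracle_ngtdm_features <- function(n_i, s_i, eps = 1e-6) {
  n <- sum(n_i)
  ng <- length(n_i)
  p <- n_i / n
  occ <- which(p > 0)
  ngp <- length(occ)
  ps <- sum(p * s_i)
  coarse <- 1 / (eps + ps)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    for (i in occ) for (j in occ) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (n * (p[i] + p[j]))
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s_i) / n
    strength <- strength / (eps + sum(s_i))
  }
  busy <- if (ngp > 1 && busy_den > 0) ps / busy_den else 0
  c(coarse, contrast, busy, complexity, strength)
}

oracle_glszm_features <- function(Z, n_v) {
  nz <- sum(Z)
  ng <- nrow(Z); smax <- ncol(Z)
  f <- numeric(11)
  for (i in 1:ng) for (s in 1:smax) {
    z <- Z[i, s]
    f[1] <- f[1] + z / s^2
    f[2] <- f[2] + z * s^2
    f[3] <- f[3] + z / i^2
    f[4] <- f[4] + z * i^2
    f[5] <- f[5] + z / (i^2 * s^2)
    f[6] <- f[6] + z * i^2 / s^2
    f[7] <- f[7] + z * s^2 / i^2
    f[8] <- f[8] + z * s^2 * i^2
  }
  f[9] <- sum(sapply(1:ng, function(i) sum(Z[i, ]))^2)
  f[10] <- sum(sapply(1:smax, function(s) sum(Z[, s]))^2)
  f[1:10] <- f[1:10] / nz
  f[11] <- nz / n_v
  f
}

# -- classification oracles -------------------------------------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# tie-corrected Kruskal-Wallis statistic from the textbook formula
oracle_kw <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
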