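test_that("canonical feature order is 6 histogram + 19 GLCM + 5 NGTDM + 11 GLSZM", {
  fn <- feature_names()
  expect_length(fn, 41)
  expect_equal(sum(startsWith(fn, "hist_")), 6)
  expect_equal(sum(startsWith(fn, "glcm_")), 19)
  expect_equal(sum(startsWith(fn, "ngtdm_")), 5)
  expect_equal(sum(startsWith(fn, "glszm_")), 11)
})

test_that("histogram features on degenerate and two-level patches", {
  const <- make_patch(rep(3, 24), c(4, 3, 2), 8)
  f <- histogram_features(const)
  expect_equal(unname(f[c("hist_variance", "hist_energy", "hist_entropy",
                          "hist_skewness", "hist_kurtosis")]),
               c(0, 1, 0, 0, 0))
  half <- make_patch(rep(c(1, 2), each = 12), c(4, 3, 2), 2)
  fh <- histogram_features(half)
  expect_equal(unname(fh["hist_entropy"]), 1)
  expect_equal(unname(fh["hist_energy"]), 0.5)
})

test_that("histogram features match independent sample-moment computation", {
  for (seed in 1:20) {
    q <- random_quantized_patch(c(6, 5, 3), 8, seed)
    expect_equal(unname(histogram_features(q)),
                 unname(oracle_hist_features(q)), tolerance = 1e-12)
  }
})

test_that("GLCM features on closed-form matrices", {
  # constant patch: point-mass GLCM
  g <- compute_glcm(make_patch(rep(1, 12), c(2, 3, 2), 2))
  f <- glcm_features(g)
  expect_equal(unname(f[c("glcm_angular_second_moment", "glcm_contrast",
                          "glcm_entropy", "glcm_homogeneity",
                          "glcm_maximum_probability")]),
               c(1, 0, 0, 1, 1))
  # two equal diagonal masses: P(1,1) = P(2,2) = 0.5
  g2 <- compute_glcm(make_patch(c(1, 2, 1, 2), c(2, 2, 1), 2),
                     directions = matrix(c(0, 1, 0), 1))
  f2 <- glcm_features(g2)
  expect_equal(unname(f2["glcm_angular_second_moment"]), 0.5)
  expect_equal(unname(f2["glcm_contrast"]), 0)
  expect_equal(unname(f2["glcm_entropy"]), 1)
})

test_that("all 19 GLCM features match the literal-formula oracle", {
  for (seed in 1:20) {
    g <- compute_glcm(random_quantized_patch(c(6, 6, 3), 4, seed))
    expect_equal(unname(glcm_features(g)), oracle_glcm_features(g$P),
                 tolerance = 1e-10)
  }
})

test_that("NGTDM features: degenerate, hand-built, and oracle cases", {
  # constant patch: capped coarseness, all else zero
  f <- ngtdm_features(compute_ngtdm(make_patch(rep(1, 27), c(3, 3, 3), 4)))
  expect_equal(unname(f["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(f[c("ngtdm_contrast", "ngtdm_busyness",
                          "ngtdm_complexity", "ngtdm_strength")]),
               rep(0, 4))
  # centre-bump: sum p_i s_i = 1 so coarseness = 1 / (1 + eps)
  vals <- rep(1L, 27); vals[14] <- 2L
  fb <- ngtdm_features(compute_ngtdm(make_patch(vals, c(3, 3, 3), 2)))
  expect_equal(unname(fb["ngtdm_coarseness"]), 1 / (1 + 1e-6))
  for (seed in 1:20) {
    m <- compute_ngtdm(random_quantized_patch(c(7, 7, 3), 4, seed))
    expect_equal(unname(ngtdm_features(m)),
                 oracle_ngtdm_features(m$n_i, m$s_i), tolerance = 1e-10)
  }
})

test_that("GLSZM features on the toy three-zone matrix", {
  q <- make_patch(c(1, 1, 3, 1, 2, 3, 2, 2, 3), c(3, 3, 1), 3)
  f <- glszm_features(compute_glszm(q))
  expect_equal(unname(f["glszm_small_zone_size_emphasis"]), 1 / 9)
  expect_equal(unname(f["glszm_large_zone_size_emphasis"]), 9)
  expect_equal(unname(f["glszm_zone_size_nonuniformity"]), 3)
  expect_equal(unname(f["glszm_gray_level_nonuniformity"]), 1)
  expect_equal(unname(f["glszm_zone_size_percentage"]), 1 / 3)
})

test_that("GLSZM features on a constant patch and against the oracle", {
  fc <- glszm_features(compute_glszm(make_patch(rep(1, 1323),
                                                c(21, 21, 3), 32)))
  expect_equal(unname(fc["glszm_zone_size_percentage"]), 1 / 1323)
  expect_equal(unname(fc["glszm_large_zone_size_emphasis"]), 1323^2)
  for (seed in 1:20) {
    q <- random_quantized_patch(c(6, 6, 3), 3, seed)
    m <- compute_glszm(q)
    expect_equal(unname(glszm_features(m)),
                 oracle_glszm_features(m$Z, m$n_v), tolerance = 1e-10)
  }
})

test_that("per-patient feature assembly averages modalities correctly", {
  t2 <- random_quantized_patch(c(21, 21, 3), 32, 1)
  adc <- random_quantized_patch(c(21, 21, 3), 32, 2)
  fm <- extract_patient_features(t2, adc, "mean")
  expect_equal(as.numeric(fm),
               as.numeric((patch_features(t2) + patch_features(adc)) / 2))
  # identical patches: mean equals the single-modality vector
  expect_equal(as.numeric(extract_patient_features(t2, t2, "mean")),
               as.numeric(patch_features(t2)))
  # single-modality mode ignores the other patch entirely
  noise <- random_quantized_patch(c(21, 21, 3), 32, 3)
  expect_equal(as.numeric(extract_patient_features(t2, adc, "T2")),
               as.numeric(extract_patient_features(t2, noise, "T2")))
  # mismatched quantization depth is an error in mean mode
  adc16 <- random_quantized_patch(c(21, 21, 3), 16, 2)
  expect_error(extract_patient_features(t2, adc16, "mean"),
               "different numbers of gray levels")
})

test_that("every patient row has 41 finite values with bounded families", {
  tab <- cohort_features(small_cohort(), "mean")
  m <- feature_matrix(tab)
  expect_equal(ncol(m), 41)
  expect_true(all(is.finite(m)))
  expect_true(all(m[, "glcm_angular_second_moment"] > 0 &
                  m[, "glcm_angular_second_moment"] <= 1))
  expect_true(all(m[, "hist_energy"] > 0 & m[, "hist_energy"] <= 1))
  expect_true(all(m[, "glcm_maximum_probability"] > 0 &
                  m[, "glcm_maximum_probability"] <= 1))
  expect_true(all(m[, "glszm_zone_size_percentage"] > 0 &
                  m[, "glszm_zone_size_percentage"] <= 1))
  expect_true(all(m[, c("hist_entropy", "glcm_entropy", "glcm_sum_entropy",
                        "glcm_difference_entropy")] >= 0))
})

test_that("cohort scaling maps to [0,1], stores parameters, never clips", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  tab <- feature_table(x, c("p1", "p2", "p3"), c(1, 2, 3))
  expect_warning(sc <- scale_features(tab), "constant")
  expect_equal(sc$a, c(0, 0.5, 1))
  expect_equal(sc$b, c(0, 0, 0))
  expect_error(scale_features(sc), "already scaled")
  # held-out patients scaled with training parameters can exceed [0,1]
  held <- feature_table(cbind(a = c(10, -3), b = c(2, 0)), c("h1", "h2"),
                        c(1, 2))
  out <- scale_features(held, params = attr(sc, "scaling"))
  expect_equal(out$a, c(2, -1.25))
})

test_that("rank statistics are invariant to cohort min-max scaling", {
  tab <- cohort_features(small_cohort(), "mean")
  s1 <- screen_features(tab)
  s2 <- screen_features(suppressWarnings(scale_features(tab)))
  expect_equal(s1$table$p_kw, s2$table$p_kw, tolerance = 1e-12)
  expect_equal(s1$table$rho, s2$table$rho, tolerance = 1e-12)
})
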