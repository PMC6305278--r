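test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_per_group = 1), "at least 2")
  expect_error(cohort_spec(volume_shape = c(10, 10, 2)), "21x21x3")
  expect_error(cohort_spec(blob_scale = c(9, -5, 2)), "positive")
  expect_error(cohort_spec(noise_sd = -0.1), "nonnegative")
  expect_s3_class(cohort_spec(), "cohort_spec")
})

test_that("lesion texture generation is deterministic and validates group", {
  spec <- cohort_spec(seed = 3)
  a <- generate_lesion_texture(2, c(21, 21, 3), spec, seed = 99)
  b <- generate_lesion_texture(2, c(21, 21, 3), spec, seed = 99)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(generate_lesion_texture(4, c(21, 21, 3), spec), "invalid group")
  expect_error(generate_lesion_texture(0, c(21, 21, 3), spec), "invalid group")
})

test_that("a blob covering the whole patch gives a constant patch", {
  spec <- cohort_spec(blob_scale = c(100, 100, 100), noise_sd = 0)
  tex <- generate_lesion_texture(1, c(21, 21, 3), spec, seed = 5)
  expect_equal(var(as.vector(tex)), 0)
})

test_that("mean large-zone-size emphasis decreases with group (oracle features)", {
  spec <- cohort_spec(noise_sd = 0)   # blob scales 9 / 5 / 2
  lze <- sapply(1:3, function(g) {
    mean(sapply(1:30, function(i) {
      q <- quantize(generate_lesion_texture(g, c(21, 21, 3), spec,
                                            seed = 1000 * g + i), 32)
      Z <- oracle_glszm_matrix(q)
      oracle_glszm_features(Z, length(q$levels))[2]
    }))
  })
  expect_true(lze[1] > lze[2])
  expect_true(lze[2] > lze[3])
})

test_that("generate_cohort honours counts, balance and determinism", {
  spec <- cohort_spec(n_per_group = 3, seed = 11)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 9)
  groups <- vapply(cohort, function(p) p$true_group, integer(1))
  expect_equal(unname(table(groups)), rep(3L, 3), ignore_attr = TRUE)
  # lesion group labels agree with the gleason strings
  for (p in cohort) {
    expect_equal(p$lesion$group, gleason_to_group(p$lesion$gleason_score))
    expect_equal(p$lesion$group, p$true_group)
    expect_equal(dim(p$t2_volume$voxels), dim(p$adc_volume$voxels))
    # ADC texture is an independent draw, not a copy of T2
    expect_false(identical(p$t2_volume$voxels, p$adc_volume$voxels))
  }
  # full determinism downstream: identical feature tables from two builds
  cohort2 <- generate_cohort(cohort_spec(n_per_group = 3, seed = 11))
  expect_identical(cohort_features(cohort, "mean"),
                   cohort_features(cohort2, "mean"))
})

test_that("too-small volumes are rejected before writing anything", {
  expect_error(
    generate_cohort(cohort_spec(n_per_group = 2,
                                volume_shape = c(24, 24, 19),
                                lesion_radius = 12)),
    "too small")
})

test_that("write_cohort writes volumes, lesion table and manifest; round-trips", {
  out <- withr::local_tempdir()
  cohort <- small_cohort()
  manifest <- write_cohort(cohort, out)
  expect_true(file.exists(manifest))
  expect_length(list.files(out, pattern = "\\.nii\\.gz$"), 18)
  expect_true(file.exists(file.path(out, "lesions.csv")))

  # collision is an error unless overwrite is set
  expect_error(write_cohort(cohort, out), "refusing to overwrite")
  expect_no_error(write_cohort(cohort, out, overwrite = TRUE))

  # round-trip identity of a written volume
  p <- cohort[[4]]
  v <- read_volume(file.path(out, paste0(p$patient_id, "_T2.nii.gz")), "T2")
  expect_equal(v$voxels, p$t2_volume$voxels, ignore_attr = TRUE,
               tolerance = 1e-12)

  # lesion table dialect: 0-based centroids, "3+4" rows map to group 2
  tab <- read.csv(file.path(out, "lesions.csv"), comment.char = "#")
  expect_equal(names(tab),
               c("patient_id", "x", "y", "z", "gleason_score", "group"))
  expect_true(all(tab$group[tab$gleason_score == "3+4"] == 2))
  expect_equal(tab$x[4], p$lesion$centroid[1] - 1L)

  # read_lesion_table restores 1-based centroids and groups
  lesions <- read_lesion_table(file.path(out, "lesions.csv"))
  expect_equal(lesions[[4]]$centroid, p$lesion$centroid)
  expect_equal(lesions[[4]]$group, p$lesion$group)
})
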