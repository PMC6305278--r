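# Shared fixtures, built once per test run and cached. The "study" cohort is
# the seeded 30/30/30 synthetic cohort with blob scales 9/5/2 that the
# pipeline-level checks run on.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

study_spec <- function() cohort_spec(n_per_group = 30, seed = 7)

study_features <- function() {
  fixture("study_features", function() {
    cohort_features(generate_cohort(study_spec()), "mean")
  })
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(cohort_spec(n_per_group = 3, seed = 11))
  })
}

# feature table built directly from lesion-texture patches (no volume
# embedding), used for the null-calibration replicates at reduced patch size
patch_feature_table <- function(spec, patch_shape, n_per_group) {
  groups <- rep(1:3, n_per_group)
  rows <- lapply(groups, function(g) {
    t2 <- quantize(generate_lesion_texture(g, patch_shape, spec), 32)
    adc <- quantize(generate_lesion_texture(g, patch_shape, spec), 32)
    extract_patient_features(t2, adc, "mean")
  })
  feature_table(do.call(rbind, rows),
                patient_id = sprintf("S%03d", seq_along(groups)),
                group = groups)
}

# separable two-group table: one feature equals the binary label, the rest
# pure noise
separable_table <- function(n = 60, p_noise = 40, seed = 0) {
  set.seed(seed)
  group <- rep(1:2, each = n / 2)
  label_feature <- as.numeric(group == 1)
  x <- cbind(label_feature + rnorm(n, sd = 0.05),
             matrix(rnorm(n * p_noise), n))
  colnames(x) <- c("label_copy", paste0("noise_", seq_len(p_noise)))
  feature_table(x, sprintf("P%02d", seq_len(n)), group)
}
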