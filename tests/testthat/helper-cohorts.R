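# Shared fixtures, built in code and memoised for the session so several
# test files can reuse the same synthetic cohorts.

.cohort_cache <- new.env(parent = emptyenv())

# Generate (once) a cohort with the given parameters; returns its
# directory.  Directories live under tempdir() for the session.
cached_cohort <- function(n_ad, n_hc, n_slices, effect, seed,
                          slice_size = c(176L, 208L)) {
  key <- paste(n_ad, n_hc, n_slices, effect, seed,
               paste(slice_size, collapse = "x"), sep = "_")
  dir <- .cohort_cache[[key]]
  if (is.null(dir) || !dir.exists(dir)) {
    dir <- file.path(tempdir(), paste0("cohort_", key))
    make_cohort(n_ad = n_ad, n_hc = n_hc, n_slices = n_slices,
                slice_size = slice_size, effect_size = effect,
                seed = seed, dir = dir, force = TRUE)
    .cohort_cache[[key]] <- dir
  }
  dir
}

# Memoised feature extraction for a cached cohort.
cached_features <- function(n_ad, n_hc, n_slices, effect, seed,
                            target = c(96L, 96L), levels = 5L,
                            slice_size = c(176L, 208L)) {
  key <- paste("fm", n_ad, n_hc, n_slices, effect, seed,
               paste(target, collapse = "x"), levels, sep = "_")
  fm <- .cohort_cache[[key]]
  if (is.null(fm)) {
    dir <- cached_cohort(n_ad, n_hc, n_slices, effect, seed, slice_size)
    fm <- build_feature_matrix(read_subjects(dir), n_slices = n_slices,
                               target = target, levels = levels)
    .cohort_cache[[key]] <- fm
  }
  fm
}

# Deterministic pseudo-random image (independent of the session RNG).
fixed_image <- function(n, m = n, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

# Oriented grating helper matching make_phantom()'s convention.
grating <- function(n, angle_deg, freq) {
  make_phantom("grating", size = c(n, n), orientation = angle_deg,
               frequency = freq)
}

# Total subband magnitude energy of a plain-DWT decomposition list.
dwt_highpass_energy <- function(bands) {
  sum(bands$LH^2) + sum(bands$HL^2) + sum(bands$HH^2)
}
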