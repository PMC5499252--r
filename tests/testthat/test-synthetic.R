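test_that("phantoms are deterministic analytic images", {
  p <- make_phantom("impulse", c(64, 64))
  expect_identical(which(p != 0, arr.ind = TRUE)[1, ], c(row = 32L, col = 32L))
  expect_identical(sum(p), 1)
  ps <- make_phantom("impulse", c(64, 64), shift = c(3, -2))
  expect_identical(unname(which(ps != 0, arr.ind = TRUE)[1, ]), c(35L, 30L))

  expect_true(all(make_phantom("constant", c(5, 7), value = 0.3) == 0.3))

  # translating a grating by a full period reproduces it exactly
  g0 <- make_phantom("grating", c(64, 64), orientation = 0, frequency = 0.125)
  g1 <- make_phantom("grating", c(64, 64), orientation = 0, frequency = 0.125,
                     shift = c(0, 8))
  expect_equal(g0, g1, tolerance = 1e-12)

  expect_identical(make_phantom("noise", c(16, 16), seed = 4),
                   make_phantom("noise", c(16, 16), seed = 4))
  expect_error(make_phantom("grating", frequency = 0.7), "frequency")
  expect_error(make_phantom("wibble"), "arg")
})

test_that("cohorts are written in the documented layout", {
  td <- tempfile()
  make_cohort(n_ad = 3, n_hc = 4, n_slices = 5, slice_size = c(44, 52),
              effect_size = 1, seed = 12, dir = td)
  tab <- read.csv(file.path(td, "subjects.csv"))
  expect_identical(nrow(tab), 7L)
  expect_identical(sum(tab$label == "AD"), 3L)
  expect_true(all(c("age", "gender", "education", "ses", "mmse", "cdr")
                  %in% names(tab)))
  expect_true(all(tab$cdr[tab$label == "AD"] == 1))
  expect_true(all(tab$cdr[tab$label == "HC"] == 0))
  expect_true(all(tab$mmse >= 0 & tab$mmse <= 30))
  for (id in tab$subject_id) {
    pngs <- list.files(file.path(td, id), pattern = "\\.png$")
    expect_length(pngs, 5L)
  }
  img <- png::readPNG(file.path(td, tab$subject_id[1], "slice_001.png"))
  expect_identical(dim(img), c(44L, 52L))
  expect_true(all(img >= 0 & img <= 1))
  # refuses to clobber without force
  expect_error(make_cohort(n_ad = 1, n_hc = 1, n_slices = 1, dir = td),
               "force")
  unlink(td, recursive = TRUE)
})

test_that("the same seed writes byte-identical cohorts", {
  t1 <- tempfile(); t2 <- tempfile()
  make_cohort(n_ad = 2, n_hc = 2, n_slices = 3, slice_size = c(40, 48),
              effect_size = 1.5, seed = 31, dir = t1)
  make_cohort(n_ad = 2, n_hc = 2, n_slices = 3, slice_size = c(40, 48),
              effect_size = 1.5, seed = 31, dir = t2)
  f1 <- list.files(t1, recursive = TRUE)
  expect_identical(f1, list.files(t2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("classes are exchangeable in image distribution at zero effect", {
  # Monte-Carlo: mean image intensity per subject, two-sample t-test per
  # replicate; at effect 0 rejections at alpha = 0.01 must stay rare.
  reject <- 0
  nrep <- 100
  for (r in seq_len(nrep)) {
    td <- tempfile()
    make_cohort(n_ad = 6, n_hc = 6, n_slices = 2, slice_size = c(40, 48),
                effect_size = 0, seed = 5000 + r, dir = td)
    tab <- read.csv(file.path(td, "subjects.csv"))
    stat <- vapply(tab$subject_id, function(id) {
      mean(vapply(list.files(file.path(td, id), full.names = TRUE),
                  function(p) mean(png::readPNG(p)), numeric(1)))
    }, numeric(1))
    pv <- t.test(stat[tab$label == "AD"], stat[tab$label == "HC"])$p.value
    if (pv < 0.01) reject <- reject + 1
    unlink(td, recursive = TRUE)
  }
  expect_lte(reject, 5)
})

test_that("higher effect sizes enlarge ventricles and thin the rim", {
  # direct morphology check on matched seeds: AD minus HC central darkness
  centre_dark <- function(eff) {
    td <- tempfile()
    make_cohort(n_ad = 4, n_hc = 4, n_slices = 1, slice_size = c(88, 104),
                effect_size = eff, seed = 404, dir = td)
    tab <- read.csv(file.path(td, "subjects.csv"))
    v <- vapply(tab$subject_id, function(id) {
      img <- png::readPNG(list.files(file.path(td, id), full.names = TRUE)[1])
      mean(img[40:50, 40:64])        # ventricular neighbourhood
    }, numeric(1))
    unlink(td, recursive = TRUE)
    mean(v[tab$label == "HC"]) - mean(v[tab$label == "AD"])
  }
  gaps <- vapply(c(0, 1, 2), centre_dark, numeric(1))
  expect_lt(abs(gaps[1]), 0.05)
  expect_gt(gaps[3], gaps[2])
  expect_gt(gaps[2], 0.01)
})

test_that("pipeline accuracy rises with the effect-size dial", {
  # 3-seed averages on a reduced cohort (20 AD + 40 HC, 10 slices,
  # 96 x 96): chance at zero effect, near-perfect at effect 2,
  # non-decreasing in between.
  mean_acc <- function(eff) {
    mean(vapply(1:3, function(s) {
      fm <- cached_features(20, 40, 10, effect = eff, seed = 300 + s,
                            target = c(96, 96))
      cv <- run_cv(fm, runs = 2, k = 5, seed = 400 + s, max_iterations = 150)
      cv$mean[["accuracy"]]
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.5, 1, 2), mean_acc, numeric(1))
  expect_true(all(diff(accs) >= -0.02))      # non-decreasing up to CV noise
  expect_lt(abs(accs[1] - 0.5), 0.15)
  expect_gte(accs[4], 0.95)
})
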