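# Seeded synthetic data: analytic test phantoms for the transform and
# two-class cohorts of brain-like slice stacks with a controllable
# morphological effect size, so the whole pipeline is testable without
# downloading any imaging data.

#' Deterministic test phantoms
#'
#' @param kind One of `"impulse"` (single unit pixel at the centre plus
#'   `shift`), `"constant"`, `"grating"` (sinusoid with wavevector at
#'   `orientation` degrees anticlockwise from the column axis, row axis
#'   pointing up), `"noise"` (seeded standard Gaussian pixels).
#' @param size Integer pair `(rows, cols)`.
#' @param value Constant value / impulse amplitude (default 1).
#' @param orientation Grating wavevector angle in degrees.
#' @param frequency Grating frequency in cycles/pixel, in (0, 0.5].
#' @param phase Grating phase offset in radians.
#' @param shift Integer pair `(dy, dx)` added to the impulse position or
#'   applied as a spatial translation of the grating.
#' @param seed RNG seed for `"noise"`.
#' @return Numeric matrix of extent `size`.
#' @examples
#' p <- make_phantom("impulse", c(64, 64))
#' which(p == 1, arr.ind = TRUE)   # (32, 32)
#' @export
make_phantom <- function(kind = c("impulse", "constant", "grating", "noise"),
                         size = c(64L, 64L), value = 1,
                         orientation = 45, frequency = 0.1, phase = 0,
                         shift = c(0L, 0L), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(size) == 2L, all(size >= 1L))
  switch(kind,
    impulse = {
      m <- matrix(0, size[1], size[2])
      pos <- c(size[1] %/% 2L + shift[1], size[2] %/% 2L + shift[2])
      if (any(pos < 1L) || pos[1] > size[1] || pos[2] > size[2])
        stop("impulse position falls outside the image", call. = FALSE)
      m[pos[1], pos[2]] <- value
      m
    },
    constant = matrix(value, size[1], size[2]),
    grating = {
      if (frequency <= 0 || frequency > 0.5)
        stop("`frequency` must lie in (0, 0.5] cycles/pixel", call. = FALSE)
      a <- orientation * pi / 180
      outer(seq_len(size[1]) - shift[1], seq_len(size[2]) - shift[2],
            function(r, c) value * cos(2 * pi * frequency *
                                       (cos(a) * c - sin(a) * r) + phase))
    },
    noise = {
      if (!is.null(seed)) set.seed(seed)
      matrix(stats::rnorm(prod(size)), size[1], size[2])
    })
}

# One synthetic axial slice.  Smooth elliptical "brain" with a bright
# cortical rim and two dark para-midline ventricular lobes; `ad` scales
# the ventricles up and thins the rim in proportion to `effect`,
# mimicking the atrophy/ventricular-enlargement contrast between the
# classes.  Subject-level factors (`subj`) are perturbed by small
# slice-level acquisition jitters and a smooth random intensity field,
# so nuisance variation is spread over many independent modes, as in
# real cohorts, rather than a handful of global ones.
.cohort_slice <- function(tau, size, subj, ad, effect, noise) {
  R <- size[1]; C <- size[2]
  jit <- function(sd) exp(stats::rnorm(1, 0, sd))
  dy <- subj$dy + stats::rnorm(1, 0, 0.6)
  dx <- subj$dx + stats::rnorm(1, 0, 0.6)
  y <- (seq_len(R) - (R + 1) / 2 - dy) / (R / 2)
  x <- (seq_len(C) - (C + 1) / 2 - dx) / (C / 2)
  depth <- sqrt(max(0.15, 1 - 0.55 * tau^2))    # brain narrows towards poles
  ax <- 0.78 * depth * subj$sx * jit(0.015)
  ay <- 0.86 * depth * subj$sy * jit(0.015)
  ex <- outer(y / ay, x / ax, function(a, b) a^2 + b^2)
  r <- sqrt(ex)
  inside <- ex <= 1.15

  vent_scale <- subj$vjit * jit(0.03) * (1 + 0.36 * effect * ad)
  rim_width  <- 0.085 * subj$rjit * jit(0.03) / (1 + 0.28 * effect * ad)

  tissue <- 0.45 * subj$gain * jit(0.02)
  rim <- 0.38 * exp(-((r - 0.88) / rim_width)^2)
  vy <- 0.34 * vent_scale * depth
  vx <- 0.16 * vent_scale
  vent <- 0
  for (sgn in c(-1, 1)) {
    ev <- outer((y - 0.05) / vy, (x - sgn * 0.17) / vx, function(a, b) a^2 + b^2)
    vent <- vent + 0.32 * exp(-ev^2)
  }
  # smooth random "tissue texture" field: low-order cosine modes with
  # independent slice-level coefficients
  field <- 0
  for (p in 0:2) for (q in 0:2) {
    if (p == 0 && q == 0) next
    field <- field + stats::rnorm(1, 0, 0.028) *
      outer(cospi(p * y), cospi(q * x))
  }
  img <- ifelse(inside, tissue + rim - vent + field, 0.02)
  img <- img + matrix(stats::rnorm(R * C, 0, noise), R, C)
  pmin(pmax(img, 0), 1)
}

.sample_demographics <- function(ad) {
  if (ad) list(age = round(min(max(stats::rnorm(1, 77.75, 6.99), 60), 96), 1),
               gender = if (stats::runif(1) < 9 / 28) "M" else "F",
               education = as.integer(min(max(round(stats::rnorm(1, 2.57, 1.31)), 1), 5)),
               ses = as.integer(min(max(round(stats::rnorm(1, 2.87, 1.29)), 1), 5)),
               mmse = as.integer(min(max(round(stats::rnorm(1, 21.67, 3.75)), 0), 30)),
               cdr = 1)
  else     list(age = round(min(max(stats::rnorm(1, 75.91, 8.98), 60), 96), 1),
               gender = if (stats::runif(1) < 26 / 98) "M" else "F",
               education = as.integer(min(max(round(stats::rnorm(1, 3.26, 1.31)), 1), 5)),
               ses = as.integer(min(max(round(stats::rnorm(1, 2.51, 1.09)), 1), 5)),
               mmse = as.integer(min(max(round(stats::rnorm(1, 28.95, 1.20)), 0), 30)),
               cdr = 0)
}

#' Generate a two-class synthetic cohort of slice stacks
#'
#' Writes one directory of 8-bit grayscale PNG slices per subject plus a
#' `subjects.csv` table (`subject_id,label,age,gender,education,ses,
#' mmse,cdr`), in the layout [read_subjects()] consumes.  Every subject
#' is a smooth elliptical brain template with a bright cortical rim and
#' dark ventricular lobes, perturbed by subject-level random geometry
#' and intensity factors plus per-pixel Gaussian noise.  Subjects
#' labelled AD additionally get their ventricles enlarged and the rim
#' thinned in proportion to `effect_size`; at `effect_size = 0` the two
#' classes are exchangeable in image distribution (only the sampled
#' demographics differ).
#'
#' @param n_ad,n_hc Subject counts (defaults 28 and 98, the unbalanced
#'   cohort structure this pipeline targets).
#' @param n_slices Slices per subject (default 32).
#' @param slice_size Slice extent `(rows, cols)`, default `c(176, 208)`.
#' @param effect_size Non-negative class-separation dial (default 1).
#' @param noise_sd Per-pixel Gaussian noise standard deviation on the
#'   \[0, 1\] intensity scale (default 0.03).
#' @param seed Master RNG seed; everything (geometry, demographics,
#'   noise) derives from it, so equal calls give byte-identical PNGs.
#' @param dir Output directory (created if missing).
#' @param force Overwrite a non-empty `dir` (default `FALSE`: refuse).
#' @return Invisibly, the path of the written `subjects.csv`.
#' @export
make_cohort <- function(n_ad = 28L, n_hc = 98L, n_slices = 32L,
                        slice_size = c(176L, 208L), effect_size = 1,
                        noise_sd = 0.03, seed = 1L, dir, force = FALSE) {
  stopifnot(n_ad >= 1L, n_hc >= 1L, n_slices >= 1L, effect_size >= 0,
            noise_sd >= 0, length(slice_size) == 2L)
  if (missing(dir)) stop("`dir` is required", call. = FALSE)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE to overwrite",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  labels <- c(rep("AD", n_ad), rep("HC", n_hc))
  ids <- sprintf("%s%03d", labels, c(seq_len(n_ad), seq_len(n_hc)))
  demo <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ad <- labels[i] == "AD"
    subj <- list(sx = stats::rnorm(1, 1, 0.04), sy = stats::rnorm(1, 1, 0.04),
                 dx = stats::rnorm(1, 0, 1.5), dy = stats::rnorm(1, 0, 1.5),
                 gain = stats::rnorm(1, 1, 0.05),
                 vjit = exp(stats::rnorm(1, 0, 0.08)),
                 rjit = exp(stats::rnorm(1, 0, 0.08)))
    demo[[i]] <- .sample_demographics(ad)
    sdir <- file.path(dir, ids[i])
    dir.create(sdir, showWarnings = FALSE)
    taus <- if (n_slices == 1L) 0 else seq(-1, 1, length.out = n_slices)
    for (t in seq_len(n_slices)) {
      img <- .cohort_slice(taus[t], slice_size, subj, ad, effect_size, noise_sd)
      png::writePNG(img, file.path(sdir, sprintf("slice_%03d.png", t)))
    }
  }
  tab <- data.frame(subject_id = ids, label = labels,
                    do.call(rbind, lapply(demo, as.data.frame)))
  csv <- file.path(dir, "subjects.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}
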