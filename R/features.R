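# Per-subject feature extraction: select the centre slices of a stack,
# normalise and resize each slice, decompose with the DTCWT, and flatten
# the coarsest-level complex subbands into one numeric row per subject.

#' Select the contiguous centre window of a slice stack
#'
#' Returns the `n_slices` contiguous entries centred on the midpoint of
#' the (ordered) input, taking the lower-median start when the margin is
#' odd, so coarse mid-brain anatomy is retained in preference to the
#' extreme apical/basal slices.
#'
#' @param all_slice_paths Ordered character vector (or any vector) of
#'   slice identifiers, ascending slice order.
#' @param n_slices Number of slices to keep (default 32).
#' @return The selected subvector, order preserved.
#' @examples
#' select_center_slices(sprintf("s%03d", 1:256), 32)[1]  # "s113"
#' @export
select_center_slices <- function(all_slice_paths, n_slices = 32L) {
  n <- length(all_slice_paths)
  if (n_slices < 1L || n_slices != round(n_slices))
    stop("`n_slices` must be a positive integer", call. = FALSE)
  if (n < n_slices)
    stop(sprintf("stack has %d slices but %d were requested", n, n_slices),
         call. = FALSE)
  start <- (n - n_slices) %/% 2L
  all_slice_paths[(start + 1L):(start + n_slices)]
}

#' Normalise and resize one slice
#'
#' Rescales intensities to \[0, 1\] (values above 1 are assumed 8-bit and
#' divided by 255; above 255, 16-bit and divided by 65535; values already
#' in \[0, 1\] are left as read) and bilinearly resizes to `target`.
#'
#' @param image 2-D numeric matrix.
#' @param target Integer pair `(rows, cols)`, default `c(256, 256)`.
#' @return Numeric matrix of extent `target` with values in \[0, 1\].
#' @export
preprocess_slice <- function(image, target = c(256L, 256L)) {
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) == 0L))
    stop("`image` must be a non-empty 2-D numeric matrix", call. = FALSE)
  if (length(target) != 2L || any(target < 1L))
    stop("`target` must be two positive extents", call. = FALSE)
  mx <- max(image)
  if (mx > 255) image <- image / 65535
  else if (mx > 1) image <- image / 255
  if (!identical(dim(image), as.integer(target)))
    image <- EBImage::resize(image, w = target[1L], h = target[2L],
                             filter = "bilinear")
  image
}

#' Flatten the coarsest DTCWT subbands of one slice into a feature vector
#'
#' Runs a `levels`-deep dual-tree complex wavelet decomposition and
#' concatenates the level-`levels` oriented subbands in the canonical
#' orientation order (+15, +45, +75, -15, -45, -75), each subband
#' flattened row-major with its real parts before its imaginary parts.
#' For a 256 x 256 slice at 5 levels this gives 6 x 8 x 8 x 2 = 768
#' features.
#'
#' @param image 2-D numeric matrix (typically the output of
#'   [preprocess_slice()]).
#' @param levels Decomposition depth (default 5).
#' @param filters Filter set, default [dtcwt_filters()].
#' @param magnitude_only If `TRUE`, store coefficient magnitudes instead
#'   of real/imaginary pairs (half the features).
#' @return Numeric vector of length
#'   `6 * prod(ceiling(dim(image)/2^levels)) * 2` (or half that for
#'   magnitudes).
#' @export
slice_features <- function(image, levels = 5L, filters = dtcwt_filters(),
                           magnitude_only = FALSE) {
  pyr <- dtcwt_forward(image, levels, filters)
  top <- pyr$levels[[levels]]
  unlist(lapply(top, function(b) {
    if (magnitude_only) as.vector(t(Mod(b)))
    else c(as.vector(t(Re(b))), as.vector(t(Im(b))))
  }), use.names = FALSE)
}

# Names describing each entry of a slice-feature vector.
.slice_feature_names <- function(extent, magnitude_only = FALSE) {
  parts <- if (magnitude_only) "mod" else c("re", "im")
  unlist(lapply(.orientations, function(o) {
    cells <- as.vector(t(outer(seq_len(extent[1]), seq_len(extent[2]),
                               function(r, c) sprintf("r%dc%d", r, c))))
    unlist(lapply(parts, function(p) sprintf("o%s_%s_%s", o, cells, p)))
  }), use.names = FALSE)
}

#' Read a cohort directory into subject records
#'
#' Expects the layout written by [make_cohort()] (and consumed by the
#' `extract` command): a `subjects.csv` with columns
#' `subject_id,label,...optional demographics...` plus one directory of
#' PNG slices per subject, slice order given by file-name sort.
#'
#' @param data_dir Cohort directory.
#' @return List of subject records, each a list with `subject_id`,
#'   `label` ("AD" or "HC"), `slice_paths`, `demographics`.
#' @export
read_subjects <- function(data_dir) {
  csv <- file.path(data_dir, "subjects.csv")
  if (!file.exists(csv))
    stop("no subjects.csv found in ", data_dir, call. = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(tab)))
    stop("subjects.csv must have subject_id and label columns", call. = FALSE)
  if (!all(tab$label %in% c("AD", "HC")))
    stop("labels must be 'AD' or 'HC'", call. = FALSE)
  demo_cols <- setdiff(names(tab), c("subject_id", "label"))
  lapply(seq_len(nrow(tab)), function(i) {
    sdir <- file.path(data_dir, tab$subject_id[i])
    paths <- sort(list.files(sdir, pattern = "\\.png$", full.names = TRUE))
    if (length(paths) == 0L)
      stop("subject ", tab$subject_id[i], ": no PNG slices in ", sdir,
           call. = FALSE)
    list(subject_id = tab$subject_id[i], label = tab$label[i],
         slice_paths = paths,
         demographics = as.list(tab[i, demo_cols, drop = FALSE]))
  })
}

.read_slice <- function(path, subject_id) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop(sprintf("subject %s: cannot read slice image '%s' (%s)",
                 subject_id, path, conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale stored with channels
  img
}

#' Build the subjects-by-features matrix
#'
#' For every subject: keep the `n_slices` centre slices, normalise and
#' resize each to `target`, extract [slice_features()] at depth
#' `levels`, and concatenate in slice order into one row.  With the
#' defaults (32 slices, 256 x 256, 5 levels) each row has
#' 32 x 768 = 24,576 entries.
#'
#' @param subjects List of subject records from [read_subjects()].
#' @param n_slices Centre slices kept per subject (default 32).
#' @param target Slice extent after resizing, default `c(256, 256)`.
#' @param levels DTCWT depth (default 5).
#' @param filters Filter set.
#' @param magnitude_only Store coefficient magnitudes only.
#' @param with_demographics Append z-scored numeric demographics
#'   (`age, gender, education, ses, mmse`; gender coded M = 1, F = 0)
#'   after the wavelet block.  Off by default: the standard feature
#'   count arithmetic excludes them.
#' @return Object of class `cad_features`: list with `values`
#'   (subjects x features matrix, rownames = subject ids), `labels`
#'   (character, "AD"/"HC"), `feature_names`.
#' @export
build_feature_matrix <- function(subjects, n_slices = 32L,
                                 target = c(256L, 256L), levels = 5L,
                                 filters = dtcwt_filters(),
                                 magnitude_only = FALSE,
                                 with_demographics = FALSE) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  counts <- vapply(subjects, function(s) length(s$slice_paths), integer(1))
  if (length(unique(counts)) > 1L)
    stop(sprintf("heterogeneous slice counts across subjects (%d to %d)",
                 min(counts), max(counts)), call. = FALSE)
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sel <- tryCatch(select_center_slices(s$slice_paths, n_slices),
                    error = function(e)
                      stop(sprintf("subject %s: %s", s$subject_id,
                                   conditionMessage(e)), call. = FALSE))
    feats <- lapply(sel, function(p) {
      img <- preprocess_slice(.read_slice(p, s$subject_id), target)
      slice_features(img, levels, filters, magnitude_only)
    })
    rows[[i]] <- unlist(feats, use.names = FALSE)
  }
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(subjects, `[[`, character(1), "subject_id")
  extent <- c(ceiling(target[1] / 2^levels), ceiling(target[2] / 2^levels))
  fn <- .slice_feature_names(extent, magnitude_only)
  feature_names <- unlist(lapply(seq_len(n_slices),
                                 function(t) sprintf("s%02d_l%d_%s", t, levels, fn)),
                          use.names = FALSE)
  labels <- vapply(subjects, `[[`, character(1), "label")

  if (with_demographics) {
    dm <- .demographic_block(subjects)
    values <- cbind(values, dm)
    feature_names <- c(feature_names, colnames(dm))
  }
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = feature_names),
            class = "cad_features")
}

# z-scored numeric demographics, gender coded M=1/F=0.
.demographic_block <- function(subjects) {
  fields <- c("age", "gender", "education", "ses", "mmse")
  cols <- lapply(fields, function(f) {
    v <- vapply(subjects, function(s) {
      x <- s$demographics[[f]]
      if (is.null(x) || (length(x) == 1L && is.na(x)))
        return(NA_real_)
      if (f == "gender") return(as.numeric(identical(toupper(as.character(x)), "M")))
      as.numeric(x)
    }, numeric(1))
    v
  })
  keep <- vapply(cols, function(v) !anyNA(v), logical(1))
  if (!any(keep)) stop("no complete demographic columns available", call. = FALSE)
  m <- do.call(cbind, cols[keep])
  colnames(m) <- paste0("demo_", fields[keep])
  sds <- apply(m, 2L, stats::sd)
  scale(m, scale = ifelse(sds > 0, sds, 1))[, , drop = FALSE]
}

#' @export
print.cad_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d subjects x %d features (%d AD / %d HC)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "AD"), sum(x$labels == "HC")))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' First column `subject_id`, second `label`, then one column per
#' feature (named).  [load_feature_matrix()] reads the format back.
#' @param features A `cad_features` object.
#' @param path Output CSV path.
#' @export
save_feature_matrix <- function(features, path) {
  df <- data.frame(subject_id = rownames(features$values),
                   label = features$labels,
                   features$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_feature_matrix
#' @export
load_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values, labels = df$label,
                 feature_names = colnames(values)),
            class = "cad_features")
}
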