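# Balanced train/validation/test splitting and stratified k-folds.
#
# The 60/20/20 split uses a ceil-on-evaluation rule per class: validation
# and test each get ceiling(fraction * N) items and training the
# remainder. For N = 7696 per class this yields the canonical
# 4616/1540/1540 partition. When slide identifiers are present the test
# partition is drawn from held-out slides where an exact quota can be met.

#' Split a labeled tile set 60/20/20 per class
#'
#' @param tiles data.frame with at least a `label` column
#'   (`"positive"`/`"negative"`); a `slide_id` column enables the
#'   held-out-slide rule for the test partition.
#' @param train_fraction,val_fraction,test_fraction split fractions; must
#'   sum to 1.
#' @param seed integer seed for the random assignment.
#' @param by_slide `"auto"` (default) tries to build the test partition
#'   from whole held-out slides and falls back to a random split with a
#'   warning; `"never"` always splits at random.
#' @return `tiles` with an added `split` column
#'   (`"train"`/`"val"`/`"test"`). Per class, `|val| = |test| =
#'   ceiling(fraction * N)` and `|train| = N - |val| - |test|`.
#' @export
split_dataset <- function(tiles, train_fraction = 0.6, val_fraction = 0.2,
                          test_fraction = 0.2, seed = 1L,
                          by_slide = c("auto", "never")) {
  by_slide <- match.arg(by_slide)
  if (abs(train_fraction + val_fraction + test_fraction - 1) > 1e-9) {
    stop("split fractions must sum to 1")
  }
  if (!"label" %in% names(tiles)) stop("tiles must have a 'label' column")
  classes <- unique(tiles$label)
  counts <- table(tiles$label)
  if (any(counts < 5L)) stop("each class needs at least 5 tiles")

  tiles$split <- NA_character_
  with_seed(seed, {
    test_idx <- integer(0)
    quotas <- vapply(classes, function(cl) {
      as.integer(ceiling(test_fraction * sum(tiles$label == cl)))
    }, integer(1))
    names(quotas) <- classes

    if (by_slide == "auto" && "slide_id" %in% names(tiles) &&
        length(unique(tiles$slide_id)) >= 2L) {
      test_idx <- held_out_slide_test(tiles, classes, quotas)
      if (is.null(test_idx)) {
        warning("no combination of held-out slides meets the test quota; ",
                "falling back to a random test split")
        test_idx <- integer(0)
      }
    }
    for (cl in classes) {
      cl_idx <- which(tiles$label == cl)
      cl_test <- intersect(test_idx, cl_idx)
      need <- quotas[[cl]] - length(cl_test)
      pool <- setdiff(cl_idx, test_idx)
      if (need > 0) cl_test <- c(cl_test, sample(pool, need))
      tiles$split[cl_test] <- "test"
      remaining <- setdiff(cl_idx, cl_test)
      n_val <- as.integer(ceiling(val_fraction * length(cl_idx)))
      cl_val <- sample(remaining, n_val)
      tiles$split[cl_val] <- "val"
      tiles$split[setdiff(remaining, cl_val)] <- "train"
    }
  })
  tiles
}

# Greedy search over shuffled slide orders for a set of whole slides whose
# per-class tile counts exactly meet the test quotas. Returns tile indices
# or NULL when no sampled order works.
held_out_slide_test <- function(tiles, classes, quotas, n_tries = 25L) {
  slides <- unique(tiles$slide_id)
  for (try in seq_len(n_tries)) {
    order_try <- sample(slides)
    got <- stats::setNames(rep(0L, length(classes)), classes)
    chosen <- character(0)
    for (s in order_try) {
      s_counts <- table(factor(tiles$label[tiles$slide_id == s], levels = classes))
      if (all(got + s_counts <= quotas)) {
        got <- got + as.integer(s_counts)
        chosen <- c(chosen, s)
        if (all(got == quotas)) {
          return(which(tiles$slide_id %in% chosen))
        }
      }
    }
  }
  NULL
}

#' Stratified k-fold partition
#'
#' @param tiles data.frame with a `label` column, or a character/factor
#'   vector of labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..k), one per row/element.
#'   Folds are disjoint, near-equal in size, and each fold's class counts
#'   are within one item of the global ratio.
#' @export
stratified_kfold <- function(tiles, k = 5L, seed = 1L) {
  labels <- if (is.data.frame(tiles)) tiles$label else tiles
  n <- length(labels)
  if (k > n) stop(sprintf("k (%d) exceeds number of items (%d)", k, n))
  if (k < 2L) stop("k must be >= 2")
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Deterministic tile augmentation
#'
#' Applies the standard flip / rotate / zoom augmentations. With all
#' defaults the transform is the identity.
#'
#' @param img square raster (matrix or RGB array).
#' @param flip `"none"`, `"horizontal"`, or `"vertical"` mirror.
#' @param rotate rotation in degrees: one of 0, 90, 180, 270.
#' @param zoom zoom factor >= 1: central crop of `1/zoom` of the image,
#'   resampled back to the input size (1 = identity).
#' @return raster of the same dimensions.
#' @export
augment <- function(img, flip = c("none", "horizontal", "vertical"),
                    rotate = 0, zoom = 1) {
  flip <- match.arg(flip)
  if (!rotate %in% c(0, 90, 180, 270)) stop("rotate must be 0, 90, 180, or 270")
  if (zoom < 1) stop("zoom must be >= 1")
  per_channel <- function(img, fn) {
    if (is.matrix(img)) return(fn(img))
    for (ch in seq_len(dim(img)[3L])) img[, , ch] <- fn(img[, , ch])
    img
  }
  if (flip == "horizontal") img <- per_channel(img, function(m) m[, ncol(m):1])
  if (flip == "vertical") img <- per_channel(img, function(m) m[nrow(m):1, ])
  rot90 <- function(m) t(m)[, nrow(m):1]   # 90 degrees counter-clockwise
  for (i in seq_len(rotate / 90)) {
    if (is.matrix(img)) {
      img <- rot90(img)
    } else {
      img <- simplify2array(lapply(seq_len(dim(img)[3L]),
                                   function(ch) rot90(img[, , ch])))
    }
  }
  if (zoom > 1) {
    h <- dim(img)[1L]; w <- dim(img)[2L]
    ch_ <- max(1L, as.integer(round_half_up(h / zoom)))
    cw <- max(1L, as.integer(round_half_up(w / zoom)))
    y0 <- (h - ch_) %/% 2L; x0 <- (w - cw) %/% 2L
    crop <- if (is.matrix(img)) {
      img[(y0 + 1L):(y0 + ch_), (x0 + 1L):(x0 + cw), drop = FALSE]
    } else {
      img[(y0 + 1L):(y0 + ch_), (x0 + 1L):(x0 + cw), , drop = FALSE]
    }
    img <- area_resample(crop, h, w)
  }
  img
}

#' Random augmentation draw
#'
#' Samples a flip / rotation / zoom combination (used for on-the-fly
#' training augmentation).
#'
#' @param img square raster.
#' @param zoom_range maximum zoom factor (draws uniformly in
#'   `[1, zoom_range]`).
#' @return augmented raster.
#' @export
random_augment <- function(img, zoom_range = 1.2) {
  augment(
    img,
    flip = sample(c("none", "horizontal", "vertical"), 1L),
    rotate = sample(c(0, 90, 180, 270), 1L),
    zoom = stats::runif(1L, 1, zoom_range)
  )
}
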