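block_row <- function(col, row, mag = 10) {
  data.frame(slide_id = "s", grid_row = row, grid_col = col,
             magnification = mag, origin_x = col * 224L, origin_y = row * 224L,
             size = 224L, state = "UNSCREENED", stringsAsFactors = FALSE)
}

ann_covering <- function(..., mag = 10, id = "a") {
  annotation_set(slideroi:::region_df(...), annotator_id = id,
                 slide_id = "s", magnification = mag)
}

test_that("consensus requires all k_required annotators", {
  b <- block_row(1L, 1L)
  covering <- ann_covering(224L, 224L, 224L, 224L)
  missing <- ann_covering(integer(0), integer(0), integer(0), integer(0))
  expect_equal(consensus_label(b, list(covering, covering, covering)), "positive")
  expect_equal(consensus_label(b, list(covering, covering, missing)), "negative")
  expect_equal(consensus_label(b, list(missing, missing, missing)), "negative")
  expect_error(consensus_label(b, list(covering, covering), k_required = 3),
               "exceeds")
})

test_that("consensus respects min_overlap and annotation magnification scaling", {
  b <- block_row(0L, 0L)
  # region covering 40% of the block, annotated at 20x (twice the scale)
  partial <- ann_covering(0L, 0L, 448L, 179L, mag = 20)
  expect_equal(consensus_label(b, list(partial), k_required = 1), "negative")
  expect_equal(consensus_label(b, list(partial), k_required = 1,
                               min_overlap = 0.3), "positive")
  full <- ann_covering(0L, 0L, 448L, 448L, mag = 20)
  expect_equal(consensus_label(b, list(full), k_required = 1), "positive")
})

test_that("consensus is monotone: adding a mark never flips positive to negative", {
  set.seed(99)
  b <- block_row(0L, 0L)
  for (i in 1:15) {
    n_regions <- sample(0:2, 3, replace = TRUE)
    anns <- lapply(n_regions, function(k) {
      if (k == 0) return(ann_covering(integer(0), integer(0), integer(0), integer(0)))
      ann_covering(sample(0:200, k, TRUE), sample(0:200, k, TRUE),
                   sample(50:224, k, TRUE), sample(50:224, k, TRUE))
    })
    before <- consensus_label(b, anns, k_required = 2)
    # add a full covering mark to annotator 1
    anns[[1]]$regions <- rbind(anns[[1]]$regions,
                               slideroi:::region_df(0L, 0L, 224L, 224L))
    after <- consensus_label(b, anns, k_required = 2)
    expect_false(before == "positive" && after == "negative")
  }
})

test_that("consensus labels equal ground truth under perfect agreement", {
  gen <- fixture_slide20()
  anns <- generate_annotations(gen$truth, 3L, agreement_prob = 1,
                               false_mark_rate = 0, seed = 2L)
  blocks <- tile_grid(gen$slide, 10)
  labeled <- label_tiles(blocks, anns)
  truth <- gen$truth
  f <- 10 / truth$base_magnification
  rr <- truth$representative_regions
  expected <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    bx <- b$origin_x / f; by <- b$origin_y / f; bs <- 224 / f
    inside <- any(bx >= rr$x0 & bx + bs <= rr$x0 + rr$w &
                  by >= rr$y0 & by + bs <= rr$y0 + rr$h)
    if (inside) "positive" else "negative"
  }, character(1))
  expect_equal(labeled$label, expected)
  # label conservation: every planted region yields >= 1 positive block
  expect_equal(sum(labeled$label == "positive"), nrow(rr))
})

test_that("split_dataset reproduces the ceil-on-eval rounding per class", {
  make_tiles <- function(n_per_class) {
    data.frame(
      label = rep(c("positive", "negative"), each = n_per_class),
      stringsAsFactors = FALSE
    )
  }
  cases <- list(
    c(n = 7696L, train = 4616L, eval_ = 1540L),
    c(n = 10L, train = 6L, eval_ = 2L),
    c(n = 7L, train = 3L, eval_ = 2L)
  )
  for (cs in cases) {
    tiles <- split_dataset(make_tiles(cs[["n"]]), seed = 1L)
    for (cl in c("positive", "negative")) {
      tab <- table(tiles$split[tiles$label == cl])
      expect_equal(unname(tab[["train"]]), cs[["train"]])
      expect_equal(unname(tab[["val"]]), cs[["eval_"]])
      expect_equal(unname(tab[["test"]]), cs[["eval_"]])
    }
    # conservation + disjointness
    expect_false(any(is.na(tiles$split)))
    expect_equal(nrow(tiles), 2L * cs[["n"]])
  }
  expect_error(split_dataset(make_tiles(10L), train_fraction = 0.5), "sum to 1")
  expect_error(split_dataset(make_tiles(3L)), "at least 5")
})

test_that("split_dataset holds out whole slides for testing when it can", {
  tiles <- data.frame(
    slide_id = rep(sprintf("s%d", 1:10), each = 20L),
    label = rep(c("positive", "negative"), times = 100L),
    stringsAsFactors = FALSE
  )
  out <- split_dataset(tiles, seed = 4L)
  test_slides <- unique(out$slide_id[out$split == "test"])
  other_slides <- unique(out$slide_id[out$split != "test"])
  expect_length(intersect(test_slides, other_slides), 0L)
  expect_equal(sum(out$split == "test" & out$label == "positive"), 20L)
})

test_that("stratified k-folds are balanced within one item per class", {
  labels <- rep(c("positive", "negative"), each = 5000L)
  folds <- stratified_kfold(labels, k = 5L, seed = 1L)
  for (f in 1:5) {
    expect_equal(sum(folds == f), 2000L)
    expect_equal(sum(folds == f & labels == "positive"), 1000L)
  }
  # n == k edge: singleton folds
  expect_equal(sort(stratified_kfold(rep("x", 4L), k = 4L, seed = 1L)), 1:4)
  expect_error(stratified_kfold(rep("x", 3L), k = 5L), "exceeds")
  # k = 2 with 3+3 items: per-class balance within 1, checked exhaustively
  labs <- rep(c("positive", "negative"), each = 3L)
  for (seed in 1:10) {
    f <- stratified_kfold(labs, k = 2L, seed = seed)
    expect_setequal(unique(f), 1:2)
    for (cl in unique(labs)) {
      per_fold <- table(factor(f[labs == cl], levels = 1:2))
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
  }
})

test_that("augmentations are involutions/identities where they should be", {
  img <- matrix(runif(224 * 224, 0, 255), 224, 224)
  expect_equal(augment(augment(img, flip = "horizontal"), flip = "horizontal"), img)
  expect_equal(augment(augment(img, flip = "vertical"), flip = "vertical"), img)
  r <- img
  for (i in 1:4) r <- augment(r, rotate = 90)
  expect_equal(r, img)
  expect_equal(augment(img, rotate = 180), augment(augment(img, rotate = 90), rotate = 90))
  expect_equal(augment(img, zoom = 1), img)
  z <- augment(img, zoom = 1.15)
  expect_equal(dim(z), dim(img))
  expect_error(augment(img, rotate = 45), "rotate")
  # RGB arrays keep all channels aligned
  arr <- array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3))
  fl <- augment(arr, flip = "horizontal")
  expect_equal(fl[, , 2], augment(arr[, , 2], flip = "horizontal"))
})

test_that("annotations round-trip through GeoJSON", {
  truth <- make_region_truth(5L)
  anns <- generate_annotations(truth, 2L, seed = 3L)
  dir <- withr::local_tempdir()
  paths <- write_annotations_geojson(anns, dir)
  back <- read_annotation_geojson(paths[[1L]])
  expect_equal(back$annotator_id, anns[[1L]]$annotator_id)
  expect_equal(back$magnification, anns[[1L]]$magnification)
  expect_equal(back$regions, anns[[1L]]$regions, ignore_attr = TRUE)
})
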