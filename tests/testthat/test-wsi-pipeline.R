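test_that("detection with an oracle classifier recovers exactly the planted blocks", {
  gen <- fixture_slide20()
  oracle <- oracle_classifier(gen$truth, magnification = 10)
  map <- detect_rois(gen$slide, oracle, magnification = 10)
  blocks <- tile_grid(gen$slide, 10)
  expect_equal(nrow(map$blocks), nrow(blocks))     # stage conservation
  expect_false(any(map$blocks$state %in% c("UNSCREENED", "CANDIDATE")))
  # representative blocks = consensus-positive blocks under perfect agreement
  anns <- generate_annotations(gen$truth, 3L, agreement_prob = 1, seed = 1L)
  labeled <- label_tiles(blocks, anns)
  expect_equal(map$blocks$state == "REPRESENTATIVE",
               labeled$label == "positive")
})

test_that("the classifier is never called on screened-out blocks", {
  gen <- fixture_slide20()
  oracle <- oracle_classifier(gen$truth, magnification = 10)
  map <- detect_rois(gen$slide, oracle, magnification = 10)
  n_candidates <- sum(map$blocks$state %in%
                        c("REPRESENTATIVE", "NON_REPRESENTATIVE"))
  expect_equal(oracle$n_predict_calls, n_candidates)
  # all-white slide: zero classifier calls
  white <- slide_pyramid(
    list(list(magnification = 10, data = flat_raster(448, 448, c(255, 255, 255))),
         list(magnification = 1, data = flat_raster(45, 45, c(255, 255, 255)))),
    slide_id = "white"
  )
  oracle2 <- oracle_classifier(gen$truth, magnification = 10)
  map2 <- detect_rois(white, oracle2, magnification = 10)
  expect_true(all(map2$blocks$state == "EMPTY"))
  expect_equal(oracle2$n_predict_calls, 0L)
})

test_that("gate precedence: artifacts over representative tissue stay ARTIFACT", {
  gen <- fixture_slide10()
  ar <- gen$truth$artifact_regions[1L, ]
  blocks <- tile_grid(gen$slide, 10)
  onto <- which(blocks$origin_x >= ar$x0 & blocks$origin_x + 224 <= ar$x0 + ar$w &
                blocks$origin_y >= ar$y0 & blocks$origin_y + 224 <= ar$y0 + ar$h)
  expect_gt(length(onto), 0L)
  oracle <- oracle_classifier(gen$truth, magnification = 10)
  map <- detect_rois(gen$slide, oracle, magnification = 10)
  expect_true(all(map$blocks$state[onto] == "ARTIFACT"))
})

test_that("detection refuses a magnification mismatch", {
  gen <- fixture_slide10()
  oracle <- oracle_classifier(gen$truth, magnification = 20)
  expect_error(detect_rois(gen$slide, oracle, magnification = 10),
               "trained at 20x")
})

test_that("full pipeline has zero FP and FN under perfect agreement (integration)", {
  gen <- fixture_slide20()
  oracle <- oracle_classifier(gen$truth, magnification = 10)
  map <- detect_rois(gen$slide, oracle, magnification = 10)
  anns <- generate_annotations(gen$truth, 3L, agreement_prob = 1, seed = 2L)
  ev <- evaluate_detection(map, anns)
  expect_equal(ev$false_negatives, 0L)
  expect_equal(sum(unlist(ev$false_positives_by_type)), 0L)
  expect_equal(ev$true_positives, nrow(gen$truth$representative_regions))
  expect_error(evaluate_detection(map, anns[1:2]), "exactly 3")
})

test_that("false-positive subtypes count annotator overlap correctly", {
  blocks <- data.frame(
    slide_id = "s", grid_row = 0L, grid_col = 0:3, magnification = 10,
    origin_x = (0:3) * 224L, origin_y = 0L, size = 224L,
    state = c("REPRESENTATIVE", "REPRESENTATIVE", "REPRESENTATIVE",
              "NON_REPRESENTATIVE"),
    stringsAsFactors = FALSE
  )
  map <- roi_map(blocks, "s", 10)
  cover <- function(cols) {
    annotation_set(slideroi:::region_df(cols * 224L, rep(0L, length(cols)),
                                        rep(224L, length(cols)), rep(224L, length(cols))),
                   magnification = 10)
  }
  # block 0: all 3 annotators; block 1: one annotator; block 2: none;
  # block 3: all 3 but NOT detected
  anns <- list(cover(c(0L, 1L, 3L)), cover(c(0L, 3L)), cover(c(0L, 3L)))
  ev <- evaluate_detection(map, anns)
  expect_equal(ev$true_positives, 1L)
  expect_equal(ev$false_negatives, 1L)
  expect_equal(ev$false_positives_by_type$type1, 0L)
  expect_equal(ev$false_positives_by_type$type2, 1L)
  expect_equal(ev$false_positives_by_type$type3, 1L)
})

test_that("coordinate transfer maps origins exactly and round-trips", {
  gen <- fixture_slide10()
  oracle <- oracle_classifier(gen$truth, magnification = 10)
  map <- detect_rois(gen$slide, oracle, magnification = 10)
  ident <- transfer_coordinates(map, affine_transform())
  expect_equal(ident$blocks, map$blocks)
  shifted <- transfer_coordinates(map, affine_transform(tx = 100, ty = 50))
  expect_equal(shifted$blocks$origin_x, map$blocks$origin_x + 100L)
  expect_equal(shifted$blocks$origin_y, map$blocks$origin_y + 50L)
  expect_equal(shifted$blocks$state, map$blocks$state)
  scale2 <- affine_transform(a = 2, d = 2)
  back <- transfer_coordinates(
    transfer_coordinates(map, scale2), affine_invert(scale2)
  )
  expect_equal(back$blocks$origin_x, map$blocks$origin_x)
  expect_equal(back$blocks$origin_y, map$blocks$origin_y)
  expect_error(affine_transform(a = 1, b = 2, c = 2, d = 4), "singular")
})

test_that("the CLI wires the stages together", {
  dir <- withr::local_tempdir()
  expect_message(
    slideroi_cli(c("generate", "--out", file.path(dir, "slide"),
                   "--width", "672", "--height", "672", "--mag", "10",
                   "--seed", "3")),
    "wrote synthetic slide"
  )
  expect_true(file.exists(file.path(dir, "slide", "pyramid.json")))
  tiles_csv <- file.path(dir, "tiles.csv")
  slideroi_cli(c("tile", "--slide", file.path(dir, "slide"),
                 "--mag", "10", "--out", tiles_csv))
  expect_equal(nrow(utils::read.csv(tiles_csv)), 9L)  # 672/224 = 3 per side
  capture.output(
    expect_message(slideroi_cli(c("enumerate-heads")), "58 architectures")
  )
  expect_message(slideroi_cli(c("grid")), "1152 configurations")
  expect_output(slideroi_cli(c("agreement", "--table", "interobserver")),
                "Agreement over 12 cases")
})
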