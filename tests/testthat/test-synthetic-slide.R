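test_that("spec validation rejects bad parameters", {
  expect_error(synthetic_slide_spec(1120, 1120, fat_fraction = 1.5), "fat_fraction")
  expect_error(synthetic_slide_spec(1120, 1120, levels = c(40, 10, 1)),
               "level magnifications")
  expect_error(synthetic_slide_spec(1120, 1120, n_representative_regions = -1),
               "region counts")
  expect_error(
    generate_slide(synthetic_slide_spec(
      448, 448, base_magnification = 20, n_representative_regions = 50
    )),
    "overcrowded spec"
  )
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- synthetic_slide_spec(672L, 672L, base_magnification = 10,
                               levels = c(10, 1), n_representative_regions = 1L,
                               n_artifact_regions = 0L, n_blur_regions = 0L,
                               seed = 7L)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_identical(a$slide$levels, b$slide$levels)
  expect_identical(a$truth, b$truth)
  skip_if_not_installed("digest")
  expect_identical(digest::digest(a$slide), digest::digest(b$slide))
})

test_that("rendered tissue classes have the stated luminance profiles", {
  gen <- fixture_slide20()
  lum <- luminance(gen$slide$levels[[1L]]$data)
  region_mean <- function(r) {
    mean(lum[(r$y0 + 1):(r$y0 + r$h), (r$x0 + 1):(r$x0 + r$w)])
  }
  for (i in seq_len(nrow(gen$truth$representative_regions))) {
    expect_lt(region_mean(gen$truth$representative_regions[i, ]), 150)
  }
  er <- gen$truth$empty_regions[1L, ]
  bright <- lum[(er$y0 + 1):(er$y0 + er$h), (er$x0 + 1):(er$x0 + er$w)] > 200
  expect_gt(mean(bright), 0.9)
  ar <- gen$truth$artifact_regions[1L, ]
  expect_lt(region_mean(ar), 30)
})

test_that("ground-truth mask area matches rendered region area (pixel-scan oracle)", {
  gen <- fixture_slide20()
  mask <- representative_mask(gen$truth)
  rr <- gen$truth$representative_regions
  expect_equal(sum(mask), sum(rr$w * rr$h))
  # mutual exclusivity with artifact/empty regions at base magnification
  ar <- gen$truth$artifact_regions
  for (i in seq_len(nrow(ar))) {
    expect_false(any(mask[(ar$y0[i] + 1):(ar$y0[i] + ar$h[i]),
                          (ar$x0[i] + 1):(ar$x0[i] + ar$w[i])]))
  }
})

test_that("pyramid levels are consistent downsamplings (luminance within 2 gray levels)", {
  gen <- fixture_slide20()
  rr <- gen$truth$representative_regions[1L, ]
  base <- gen$slide$levels[[1L]]
  for (l in gen$slide$levels[-1L]) {
    f <- l$magnification / base$magnification
    sub <- l$data[(rr$y0 * f + 1):((rr$y0 + rr$h) * f),
                  (rr$x0 * f + 1):((rr$x0 + rr$w) * f), , drop = FALSE]
    base_sub <- base$data[(rr$y0 + 1):(rr$y0 + rr$h),
                          (rr$x0 + 1):(rr$x0 + rr$w), , drop = FALSE]
    expect_lt(abs(mean(luminance(sub)) - mean(luminance(base_sub))), 2)
  }
})

test_that("an all-fat slide yields only empty blocks at 10x", {
  gen <- generate_slide(synthetic_slide_spec(
    1120L, 1120L, base_magnification = 10, levels = c(10, 1),
    n_representative_regions = 0L, n_artifact_regions = 0L,
    n_blur_regions = 0L, fat_fraction = 1, seed = 3L
  ))
  blocks <- tile_grid(gen$slide, 10)
  states <- vapply(seq_len(nrow(blocks)), function(i) {
    screen_block(gen$slide, blocks[i, ])
  }, character(1))
  expect_true(all(states == "EMPTY"))
})

test_that("annotation generation honors agreement probability exactly at the ends", {
  truth <- make_region_truth(20L)
  full <- generate_annotations(truth, 3L, agreement_prob = 1,
                               false_mark_rate = 0, seed = 5L)
  expect_length(full, 3L)
  for (a in full) {
    expect_equal(a$regions, truth$representative_regions,
                 ignore_attr = TRUE)
  }
  none <- generate_annotations(truth, 3L, agreement_prob = 0,
                               false_mark_rate = 0, seed = 5L)
  for (a in none) expect_equal(nrow(a$regions), 0L)
  expect_identical(
    generate_annotations(truth, 3L, 0.6, 0.5, seed = 11L),
    generate_annotations(truth, 3L, 0.6, 0.5, seed = 11L)
  )
})

test_that("all-3 consensus counts follow the binomial oracle (1000 replicates)", {
  truth <- make_region_truth(100L)
  p <- 0.8
  counts <- vapply(seq_len(1000L), function(rep) {
    anns <- generate_annotations(truth, 3L, agreement_prob = p,
                                 false_mark_rate = 0, seed = rep)
    keys <- lapply(anns, function(a) paste(a$regions$x0, a$regions$y0))
    length(Reduce(intersect, keys))
  }, numeric(1))
  # consensus count per replicate ~ Binomial(100, 0.8^3): mean of 1000
  # replicates must sit within 3 standard errors of 51.2
  se <- sqrt(100 * p^3 * (1 - p^3)) / sqrt(1000)
  expect_lt(abs(mean(counts) - 100 * p^3), 3 * se)
})

test_that("signal tables are Poisson draws with the requested means", {
  tab <- generate_signal_table(10000L, her2_mean = 4, cep17_mean = 2, seed = 3L)
  expect_equal(nrow(tab), 10000L)
  ratio <- sum(tab$her2_count) / sum(tab$cep17_count)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
  sym <- generate_signal_table(20000L, 3, 3, seed = 4L)
  expect_lt(abs(sum(sym$her2_count) / sum(sym$cep17_count) - 1), 0.05)
  expect_identical(generate_signal_table(50L, 4, 2, seed = 9L),
                   generate_signal_table(50L, 4, 2, seed = 9L))
  expect_error(generate_signal_table(0L, 4, 2), "empty table")
})
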