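# Shared fixtures, built once per test run. All synthetic; nothing is read
# from disk except the bundled case tables.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Standard 20x-base slide: 2240^2 base, 5x5 blocks at 10x, 3 representative
# regions + 1 artifact + 1 blur + fat strip.
fixture_slide20 <- function() {
  cached("slide20", generate_slide(
    synthetic_slide_spec(2240L, 2240L, base_magnification = 20, seed = 1L)
  ))
}

# Smaller 10x-base slide for cheap pyramid/screen tests.
fixture_slide10 <- function() {
  cached("slide10", generate_slide(
    synthetic_slide_spec(1120L, 1120L, base_magnification = 10,
                         levels = c(10, 1), n_representative_regions = 2L,
                         n_artifact_regions = 1L, n_blur_regions = 1L,
                         fat_fraction = 0.25, seed = 7L),
    slide_id = "fix10"
  ))
}

# A flat-colored RGB raster.
flat_raster <- function(h, w, rgb) {
  arr <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# Separable two-class tiles: class is a luminance band (dark vs light),
# with mild noise. Linearly decodable from any luminance-preserving
# feature map.
make_band_tiles <- function(n_per_class, size = 64L, seed = 1L) {
  slideroi:::with_seed(seed, {
    imgs <- list(); labels <- character(0)
    for (i in seq_len(n_per_class)) {
      imgs[[length(imgs) + 1L]] <-
        matrix(stats::runif(size^2, 40, 110), size, size)
      labels <- c(labels, "positive")
      imgs[[length(imgs) + 1L]] <-
        matrix(stats::runif(size^2, 150, 220), size, size)
      labels <- c(labels, "negative")
    }
    list(imgs = imgs, labels = labels)
  })
}

# A hand-built ground truth with n regions on a virtual slide (no pixels),
# for annotation simulations.
make_region_truth <- function(n_regions, seed_positions = FALSE) {
  cell <- 224L
  per_row <- 20L
  idx <- seq_len(n_regions) - 1L
  ground_truth(
    "virtual", 10, per_row * cell, (n_regions %/% per_row + 2L) * cell,
    representative_regions = slideroi:::region_df(
      (idx %% per_row) * cell, (idx %/% per_row) * cell, cell, cell
    )
  )
}
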