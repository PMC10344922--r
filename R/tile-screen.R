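# Pre-classification tile screening.
#
# Blocks are screened in a fixed order before any classifier sees them:
#   1. empty/fat test on the 1x rendition of the block: rejected as EMPTY
#      when strictly more than 75% of pixels have luminance strictly above
#      gray level 200;
#   2. artifact gate on the 1x rendition (default: fraction of near-black
#      saturated pixels);
#   3. image-quality gate on the block's own 10x rendition (default:
#      variance of a Laplacian response, a standard reference-less
#      sharpness proxy). The quality method is deliberately pluggable: any
#      reference-less evaluator can be registered by name and selected in
#      the config.
# The first failing gate assigns the block's state; survivors are
# CANDIDATEs for classification.

.screen_evaluators <- new.env(parent = emptyenv())

#' Register a screening evaluator by name
#'
#' Evaluators take a raster and return a numeric score. Quality evaluators
#' must score higher for sharper images; artifact evaluators must score
#' higher for more artifact-affected images.
#'
#' @param name evaluator name.
#' @param fn function(raster) -> numeric scalar.
#' @export
register_screen_evaluator <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .screen_evaluators)
  invisible(name)
}

#' Look up a registered screening evaluator
#' @param name evaluator name.
#' @return the evaluator function.
#' @export
get_screen_evaluator <- function(name) {
  if (!exists(name, envir = .screen_evaluators, inherits = FALSE)) {
    stop("unknown screen evaluator: ", name)
  }
  get(name, envir = .screen_evaluators)
}

#' Variance-of-Laplacian sharpness score
#'
#' The default quality gate: variance of the 4-neighbor Laplacian response
#' of the luminance image. Zero for constant rasters, invariant to 90
#' degree rotation, and monotonically decreasing under Gaussian blur of
#' increasing radius.
#'
#' @param img raster (matrix or RGB array, 0..255).
#' @return non-negative sharpness score.
#' @export
default_quality_score <- function(img) {
  y <- luminance(img)
  h <- nrow(y); w <- ncol(y)
  if (h < 3L || w < 3L) return(0)
  ctr <- y[2:(h - 1), 2:(w - 1)]
  lap <- y[1:(h - 2), 2:(w - 1)] + y[3:h, 2:(w - 1)] +
    y[2:(h - 1), 1:(w - 2)] + y[2:(h - 1), 3:w] - 4 * ctr
  stats::var(as.vector(lap))
}

#' Fraction of near-black saturated pixels
#'
#' The default artifact gate: the fraction of pixels whose luminance is at
#' or below `dark_level` (default 30). Dark smudges such as ink or heavy
#' pigment deposits saturate this; ordinary nuclei-dense tissue does not.
#'
#' @param img raster.
#' @param dark_level gray level at or below which a pixel counts as
#'   saturated dark.
#' @return fraction in `[0, 1]`.
#' @export
dark_fraction_score <- function(img, dark_level = 30) {
  y <- luminance(img)
  mean(y <= dark_level)
}

register_screen_evaluator("laplacian_variance", default_quality_score)
register_screen_evaluator("dark_fraction", dark_fraction_score)

#' Screening configuration
#'
#' @param bright_threshold gray level above which a pixel counts as bright
#'   (default 200).
#' @param bright_fraction fraction of bright pixels above which a block is
#'   rejected as empty/fat (default 0.75; strict inequality).
#' @param artifact_gate name of the registered artifact evaluator.
#' @param artifact_threshold artifact score (strictly) above which a block
#'   is rejected as ARTIFACT.
#' @param quality_gate name of the registered quality evaluator.
#' @param quality_threshold quality score (strictly) below which a block is
#'   rejected as POOR_QUALITY. The default of 150 separates the sharp and
#'   Gaussian-blurred (sigma = 3 at 10x) textures of the synthetic
#'   generator by more than an order of magnitude in Laplacian variance.
#' @return an object of class `ScreenConfig`.
#' @export
screen_config <- function(bright_threshold = 200, bright_fraction = 0.75,
                          artifact_gate = "dark_fraction",
                          artifact_threshold = 0.5,
                          quality_gate = "laplacian_variance",
                          quality_threshold = 150) {
  if (bright_threshold < 0 || bright_threshold > 255) {
    stop("bright_threshold must be in [0, 255]")
  }
  if (bright_fraction < 0 || bright_fraction > 1) {
    stop("bright_fraction must be in [0, 1]")
  }
  structure(
    list(
      bright_threshold = bright_threshold, bright_fraction = bright_fraction,
      artifact_gate = artifact_gate, artifact_threshold = artifact_threshold,
      quality_gate = quality_gate, quality_threshold = quality_threshold
    ),
    class = "ScreenConfig"
  )
}

#' Load a screening configuration from a YAML or JSON file
#' @param path config file; keys mirror the [screen_config()] arguments.
#' @export
load_screen_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(screen_config, vals[intersect(names(vals), names(formals(screen_config)))])
}

#' Empty/fat test on a 1x block rendition
#'
#' @param image_1x the 1x rendition raster of a block.
#' @param config a [screen_config()].
#' @return `TRUE` iff strictly more than `bright_fraction` of pixels have
#'   luminance strictly above `bright_threshold`.
#' @export
is_empty_block <- function(image_1x, config = screen_config()) {
  y <- luminance(image_1x)
  if (length(y) == 0L) stop("empty raster")
  mean(y > config$bright_threshold) > config$bright_fraction
}

#' Screen one block through the empty, artifact, and quality gates
#'
#' @param slide a [slide_pyramid()].
#' @param block one block row from [tile_grid()].
#' @param config a [screen_config()].
#' @return one of `"EMPTY"`, `"ARTIFACT"`, `"POOR_QUALITY"`,
#'   `"CANDIDATE"`. The empty and artifact gates look at the 1x rendition
#'   of the block; the quality gate looks at the block's own magnification.
#' @export
screen_block <- function(slide, block, config = screen_config()) {
  img_1x <- tryCatch(
    read_block_image(slide, block, at_mag = 1),
    error = function(e) {
      stop(sprintf("screening failed at block (%d, %d): %s",
                   block$grid_row, block$grid_col, conditionMessage(e)))
    }
  )
  if (is_empty_block(img_1x, config)) return("EMPTY")
  artifact_fn <- get_screen_evaluator(config$artifact_gate)
  if (artifact_fn(img_1x) > config$artifact_threshold) return("ARTIFACT")
  img_native <- read_block_image(slide, block)
  quality_fn <- get_screen_evaluator(config$quality_gate)
  if (quality_fn(img_native) < config$quality_threshold) return("POOR_QUALITY")
  "CANDIDATE"
}
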