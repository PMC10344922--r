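# Multi-resolution slide pyramids and fixed-size tile grids.
#
# A whole-slide image is stored as an ordered stack of magnification levels
# (base level first, highest magnification). Pixel dimensions scale
# proportionally with magnification, so level b at half the magnification of
# level a has (approximately) half the width and height. All downstream
# stages operate on non-overlapping 224 x 224 tiles ("blocks") cut from a
# chosen magnification.

TILE_SIZE <- 224L

BLOCK_STATES <- c(
  "UNSCREENED", "EMPTY", "ARTIFACT", "POOR_QUALITY",
  "CANDIDATE", "REPRESENTATIVE", "NON_REPRESENTATIVE"
)

#' Construct a slide pyramid
#'
#' @param levels list of levels, each a list with elements `magnification`
#'   (numeric, e.g. 20), and `data`, an `h x w x 3` RGB array (0..255) or a
#'   grayscale matrix. Levels may be given in any order; they are sorted by
#'   decreasing magnification (base level first).
#' @param slide_id character identifier.
#' @return an object of class `SlidePyramid`.
#' @details Magnifications must be strictly decreasing towards the top of
#'   the pyramid and pixel dimensions must be proportional to magnification
#'   within one pixel of rounding.
#' @export
slide_pyramid <- function(levels, slide_id = "slide") {
  stopifnot(is.list(levels), length(levels) >= 1L)
  mags <- vapply(levels, function(l) as.numeric(l$magnification), numeric(1))
  if (anyDuplicated(mags)) stop("duplicate level magnifications")
  levels <- levels[order(mags, decreasing = TRUE)]
  mags <- sort(mags, decreasing = TRUE)
  if (any(mags <= 0)) stop("magnifications must be positive")
  levels <- lapply(levels, function(l) {
    d <- dim(l$data)
    list(
      magnification = as.numeric(l$magnification),
      height = as.integer(d[1L]),
      width = as.integer(d[2L]),
      data = l$data
    )
  })
  base <- levels[[1L]]
  for (l in levels[-1L]) {
    ratio <- l$magnification / base$magnification
    if (abs(l$width - base$width * ratio) > 1 ||
        abs(l$height - base$height * ratio) > 1) {
      stop(sprintf(
        "level %gx dimensions (%d x %d) are not proportional to base",
        l$magnification, l$width, l$height
      ))
    }
  }
  structure(
    list(slide_id = slide_id, levels = levels),
    class = "SlidePyramid"
  )
}

#' @export
print.SlidePyramid <- function(x, ...) {
  cat(sprintf("SlidePyramid '%s' with %d level(s):\n", x$slide_id, length(x$levels)))
  for (l in x$levels) {
    cat(sprintf("  %5gx  %d x %d px\n", l$magnification, l$width, l$height))
  }
  invisible(x)
}

slide_base_magnification <- function(slide) slide$levels[[1L]]$magnification

# Stored level with this exact magnification, or NULL.
stored_level <- function(slide, magnification) {
  for (l in slide$levels) {
    if (isTRUE(all.equal(l$magnification, magnification))) return(l)
  }
  NULL
}

# Pixel dimensions of a (possibly virtual) magnification level.
level_dimensions <- function(slide, magnification) {
  l <- stored_level(slide, magnification)
  if (!is.null(l)) return(c(height = l$height, width = l$width))
  base <- slide$levels[[1L]]
  if (magnification > base$magnification) {
    stop(sprintf("magnification unavailable: %gx exceeds base %gx",
                 magnification, base$magnification))
  }
  r <- magnification / base$magnification
  c(
    height = as.integer(round_half_up(base$height * r)),
    width = as.integer(round_half_up(base$width * r))
  )
}

#' Cut a slide into non-overlapping 224 x 224 blocks
#'
#' Divides the requested magnification level into a grid of fixed-size
#' square blocks. Partial blocks at the right/bottom edges are dropped, so
#' the grid covers `floor(W/224) * 224` by `floor(H/224) * 224` pixels.
#'
#' @param slide a [slide_pyramid()].
#' @param magnification level at which to tile; need not be a stored level
#'   (any magnification at or below the base can be derived by
#'   downsampling).
#' @return a data.frame with one row per block: `slide_id`, `grid_row`,
#'   `grid_col` (0-based), `magnification`, `origin_x`, `origin_y` (0-based
#'   pixel origin at that magnification), `size`, and `state`
#'   (all `"UNSCREENED"`), in row-major order.
#' @export
tile_grid <- function(slide, magnification) {
  stopifnot(inherits(slide, "SlidePyramid"))
  dims <- level_dimensions(slide, magnification)
  n_rows <- dims[["height"]] %/% TILE_SIZE
  n_cols <- dims[["width"]] %/% TILE_SIZE
  if (n_rows < 1L || n_cols < 1L) {
    return(empty_tile_grid(slide$slide_id, magnification))
  }
  grid_row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  grid_col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  data.frame(
    slide_id = slide$slide_id,
    grid_row = grid_row,
    grid_col = grid_col,
    magnification = magnification,
    origin_x = grid_col * TILE_SIZE,
    origin_y = grid_row * TILE_SIZE,
    size = TILE_SIZE,
    state = "UNSCREENED",
    stringsAsFactors = FALSE
  )
}

empty_tile_grid <- function(slide_id, magnification) {
  data.frame(
    slide_id = character(0), grid_row = integer(0), grid_col = integer(0),
    magnification = numeric(0), origin_x = integer(0), origin_y = integer(0),
    size = integer(0), state = character(0), stringsAsFactors = FALSE
  )
}

#' Map a block's footprint to another magnification
#'
#' @param block one row of a [tile_grid()] data.frame (or a list with
#'   `origin_x`, `origin_y`, `magnification`, `size`).
#' @param target_mag target magnification (> 0).
#' @return list with `origin_x`, `origin_y`, `width`, `height` in pixels at
#'   `target_mag`. Coordinates scale by `target_mag / block$magnification`;
#'   sizes are rounded half-up with a minimum of 1 px.
#' @export
block_at_magnification <- function(block, target_mag) {
  stopifnot_scalar(target_mag, "target_mag")
  if (target_mag <= 0) stop("target_mag must be positive")
  f <- target_mag / block$magnification
  size <- max(1L, as.integer(round_half_up(block$size * f)))
  list(
    origin_x = as.integer(round_half_up(block$origin_x * f)),
    origin_y = as.integer(round_half_up(block$origin_y * f)),
    width = size,
    height = size
  )
}

# Read a rectangular region (0-based, half-open) from a stored level.
read_level_region <- function(level, x0, y0, w, h) {
  if (x0 < 0 || y0 < 0 || x0 + w > level$width || y0 + h > level$height) {
    stop(sprintf(
      "region [%d,%d %dx%d] out of bounds for %gx level (%d x %d)",
      x0, y0, w, h, level$magnification, level$width, level$height
    ))
  }
  rows <- (y0 + 1L):(y0 + h)
  cols <- (x0 + 1L):(x0 + w)
  if (is.matrix(level$data)) {
    level$data[rows, cols, drop = FALSE]
  } else {
    level$data[rows, cols, , drop = FALSE]
  }
}

#' Read the image of a block at a chosen magnification
#'
#' If `at_mag` is not a stored level the region is read from the nearest
#' stored level with magnification >= `at_mag` and downsampled by area
#' averaging, which preserves mean luminance.
#'
#' @param slide a [slide_pyramid()].
#' @param block a block row (see [tile_grid()]).
#' @param at_mag magnification to render the block at; defaults to the
#'   block's own magnification.
#' @return an RGB array (or matrix, matching the pyramid storage) with
#'   values on the 0..255 scale.
#' @export
read_block_image <- function(slide, block, at_mag = block$magnification) {
  stopifnot(inherits(slide, "SlidePyramid"))
  target <- block_at_magnification(block, at_mag)
  src <- NULL
  for (l in rev(slide$levels)) {        # ascending magnification
    if (l$magnification >= at_mag - 1e-9) { src <- l; break }
  }
  if (is.null(src)) src <- slide$levels[[1L]]
  src_region <- block_at_magnification(block, src$magnification)
  img <- read_level_region(
    src, src_region$origin_x, src_region$origin_y,
    src_region$width, src_region$height
  )
  if (src_region$width == target$width && src_region$height == target$height) {
    return(img)
  }
  area_resample(img, target$height, target$width)
}
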