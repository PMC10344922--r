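# ROI maps: the per-block final states of a slide, their serialization,
# and a low-magnification visual overlay (green = representative, yellow =
# artifact, purple = poor quality).

ROI_COLORS <- list(
  REPRESENTATIVE = c(0, 200, 0),
  ARTIFACT = c(255, 215, 0),
  POOR_QUALITY = c(160, 32, 240)
)

#' Construct an ROI map
#'
#' @param blocks a [tile_grid()] data.frame whose `state` column holds
#'   final states only (no `UNSCREENED`/`CANDIDATE` entries).
#' @param slide_id,magnification identifiers copied from the detection run.
#' @return an object of class `ROIMap`.
#' @export
roi_map <- function(blocks, slide_id, magnification) {
  if (any(blocks$state %in% c("UNSCREENED", "CANDIDATE"))) {
    stop("ROI map states must be final (no UNSCREENED/CANDIDATE blocks)")
  }
  if (!all(blocks$state %in% BLOCK_STATES)) stop("unknown block state")
  key <- paste(blocks$grid_row, blocks$grid_col)
  if (anyDuplicated(key)) stop("duplicate grid cells in ROI map")
  structure(
    list(slide_id = slide_id, magnification = magnification, blocks = blocks),
    class = "ROIMap"
  )
}

#' @export
print.ROIMap <- function(x, ...) {
  cat(sprintf("ROIMap '%s' at %gx: %d blocks\n", x$slide_id,
              x$magnification, nrow(x$blocks)))
  print(table(x$blocks$state))
  invisible(x)
}

draw_box <- function(img, x0, y0, w, h, col, thickness = 1L) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  xs <- clamp((x0 + 1L):(x0 + w), 1L, W)
  ys <- clamp((y0 + 1L):(y0 + h), 1L, H)
  for (t in seq_len(thickness) - 1L) {
    rows <- clamp(c(y0 + 1L + t, y0 + h - t), 1L, H)
    cols <- clamp(c(x0 + 1L + t, x0 + w - t), 1L, W)
    for (ch in 1:3) {
      img[rows, xs, ch] <- col[ch]
      img[ys, cols, ch] <- col[ch]
    }
  }
  img
}

#' Render an ROI map as a colored overlay on a low-magnification rendition
#'
#' Boxes are drawn at the lowest stored magnification: green for
#' representative, yellow for artifact, purple for poor-quality blocks;
#' empty and non-representative blocks are not drawn.
#'
#' @param map an [roi_map()].
#' @param slide the [slide_pyramid()] the map was computed on.
#' @param path optional PNG output path; when given, a JSON sidecar with
#'   every block's state and coordinates is written next to it.
#' @return the overlay RGB array, invisibly when `path` is given.
#' @export
render_roi_map <- function(map, slide, path = NULL) {
  stopifnot(inherits(map, "ROIMap"), inherits(slide, "SlidePyramid"))
  overview <- slide$levels[[length(slide$levels)]]
  img <- overview$data
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  f <- overview$magnification / map$magnification
  for (i in seq_len(nrow(map$blocks))) {
    b <- map$blocks[i, ]
    col <- ROI_COLORS[[b$state]]
    if (is.null(col)) next
    img <- draw_box(
      img,
      as.integer(round_half_up(b$origin_x * f)),
      as.integer(round_half_up(b$origin_y * f)),
      max(1L, as.integer(round_half_up(b$size * f))),
      max(1L, as.integer(round_half_up(b$size * f))),
      col
    )
  }
  if (!is.null(path)) {
    write_raster_png(img, path)
    write_roi_map(map, paste0(tools::file_path_sans_ext(path), ".json"))
    return(invisible(img))
  }
  img
}

#' Serialize an ROI map to JSON or CSV
#'
#' @param map an [roi_map()].
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @export
write_roi_map <- function(map, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(
        slide_id = map$slide_id, magnification = map$magnification,
        blocks = map$blocks
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  } else if (ext == "csv") {
    utils::write.csv(
      map$blocks[, c("slide_id", "grid_row", "grid_col", "state")],
      path, row.names = FALSE
    )
  } else {
    stop("unsupported ROI map extension: ", ext)
  }
  invisible(path)
}

#' Read an ROI map serialized as JSON
#' @param path JSON file written by [write_roi_map()].
#' @return an [roi_map()].
#' @export
read_roi_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- as.data.frame(obj$blocks)
  roi_map(blocks, obj$slide_id, obj$magnification)
}
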