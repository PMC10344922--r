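# On-disk formats: PNG-per-level pyramids with a JSON sidecar, GeoJSON
# annotation files, CSV block lists and signal tables.

#' Write a raster to a PNG file
#' @param img matrix or RGB array on the 0..255 scale.
#' @param path output file.
#' @export
write_raster_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}

#' Read a PNG file as a 0..255 raster
#' @param path PNG file.
#' @return matrix (grayscale) or RGB array on the 0..255 scale.
#' @export
read_raster_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  }
  img * 255
}

#' Write a slide pyramid as one PNG per level plus a JSON sidecar
#'
#' @param slide a [slide_pyramid()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. The sidecar `pyramid.json` records slide id
#'   and per-level magnification and dimensions.
#' @export
write_pyramid <- function(slide, dir) {
  stopifnot(inherits(slide, "SlidePyramid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(slide_id = slide$slide_id, levels = list())
  for (l in slide$levels) {
    fname <- sprintf("level_%gx.png", l$magnification)
    write_raster_png(l$data, file.path(dir, fname))
    meta$levels[[length(meta$levels) + 1L]] <- list(
      magnification = l$magnification, width = l$width, height = l$height,
      file = fname
    )
  }
  jsonlite::write_json(meta, file.path(dir, "pyramid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pyramid written by [write_pyramid()]
#' @param dir directory containing `pyramid.json` and level PNGs.
#' @return a [slide_pyramid()].
#' @export
read_pyramid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pyramid.json"))
  levels <- lapply(meta$levels, function(l) {
    list(
      magnification = l$magnification,
      data = read_raster_png(file.path(dir, l$file))
    )
  })
  slide_pyramid(levels, slide_id = meta$slide_id)
}

#' Write annotation sets as GeoJSON FeatureCollections
#'
#' Each annotator's regions become Polygon features with `annotator_id`,
#' `slide_id` and `magnification` properties; one file per annotator.
#'
#' @param annotations list of annotation sets.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_annotations_geojson <- function(annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(annotations, function(a) {
    feats <- lapply(seq_len(nrow(a$regions)), function(i) {
      r <- a$regions[i, ]
      ring <- list(
        c(r$x0, r$y0), c(r$x0 + r$w, r$y0),
        c(r$x0 + r$w, r$y0 + r$h), c(r$x0, r$y0 + r$h),
        c(r$x0, r$y0)
      )
      list(
        type = "Feature",
        geometry = list(type = "Polygon", coordinates = list(ring)),
        properties = list(
          annotator_id = a$annotator_id, slide_id = a$slide_id,
          magnification = a$magnification
        )
      )
    })
    fc <- list(type = "FeatureCollection", features = feats)
    path <- file.path(dir, sprintf("%s.geojson", a$annotator_id))
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    path
  }, character(1))
  invisible(paths)
}

#' Read one GeoJSON annotation file written by [write_annotations_geojson()]
#'
#' Only axis-aligned rectangular polygons are supported; arbitrary polygons
#' are reduced to their bounding box.
#'
#' @param path GeoJSON file.
#' @return an [annotation_set()].
#' @export
read_annotation_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  regions <- region_df()
  meta <- list(annotator_id = "annotator", slide_id = "slide", magnification = 20)
  for (f in fc$features) {
    ring <- f$geometry$coordinates[[1L]]
    xs <- vapply(ring, function(p) as.numeric(p[[1L]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2L]]), numeric(1))
    regions <- rbind(regions, region_df(min(xs), min(ys),
                                        max(xs) - min(xs), max(ys) - min(ys)))
    meta$annotator_id <- f$properties$annotator_id %||% meta$annotator_id
    meta$slide_id <- f$properties$slide_id %||% meta$slide_id
    meta$magnification <- f$properties$magnification %||% meta$magnification
  }
  annotation_set(regions, meta$annotator_id, meta$slide_id, meta$magnification)
}

#' Read or write signal-count tables as CSV
#' @param table data.frame with columns `nucleus_id`, `her2_count`,
#'   `cep17_count`.
#' @param path CSV file.
#' @export
write_signal_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  tab <- utils::read.csv(path)
  required <- c("nucleus_id", "her2_count", "cep17_count")
  if (!all(required %in% names(tab))) {
    stop("signal table must have columns nucleus_id, her2_count, cep17_count")
  }
  tab
}
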