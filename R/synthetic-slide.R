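# Synthetic slide, annotation, and signal-count generators.
#
# The generator emulates the luminance and texture statistics that the
# downstream screening and classification rules actually consume, not stain
# physics. An H&E-like slide is rendered at its base magnification as:
#   * a bright "fat/empty" strip (> 90% of pixels above gray level 200),
#   * ordinary (non-representative) tissue: sparse dark nuclei-like
#     ellipses on a pink background (mean luminance between 150 and 200),
#   * representative regions: dense dark ellipses (mean luminance < 150),
#   * artifact regions: saturated near-black smudges,
#   * blur regions: tissue texture low-pass filtered with a Gaussian.
# Regions are axis-aligned rectangles snapped to the 10x classification
# block grid so that every planted region covers at least one full block.
# Lower-magnification pyramid levels are consistent area-average
# downsamplings of the base level.

# Render palette (RGB, 0..255). Chosen once so the luminance of each tissue
# class straddles the 200/75% brightness screening rule: background tissue
# pink has luminance ~195 (tissue, not bright), fat ~247 (bright), nuclei
# ~70 (dark), artifact ~11 (saturated dark).
.PALETTE <- list(
  fat = c(248, 246, 247),
  tissue = c(226, 178, 205),
  nucleus = c(90, 50, 120),
  artifact = c(12, 10, 12)
)

#' Describe a synthetic slide
#'
#' @param width_px,height_px base-level pixel dimensions.
#' @param base_magnification magnification of the base level (default 20).
#' @param levels magnifications to materialize (must be positive and at
#'   most the base; the base is always included).
#' @param n_representative_regions,n_artifact_regions,n_blur_regions number
#'   of planted regions of each kind.
#' @param fat_fraction fraction of the slide area rendered as bright
#'   fat/empty background, in `[0, 1]`.
#' @param nuclei_density_representative,nuclei_density_tissue approximate
#'   area coverage of nuclei ellipses inside representative regions and in
#'   ordinary tissue.
#' @param blur_sigma Gaussian blur radius for blur regions, in pixels at
#'   10x (scaled to the base magnification internally).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   slides.
#' @return an object of class `SyntheticSlideSpec`.
#' @export
synthetic_slide_spec <- function(width_px, height_px,
                                 base_magnification = 20,
                                 levels = c(base_magnification, 10, 1),
                                 n_representative_regions = 3L,
                                 n_artifact_regions = 1L,
                                 n_blur_regions = 1L,
                                 fat_fraction = 0.3,
                                 nuclei_density_representative = 0.65,
                                 nuclei_density_tissue = 0.03,
                                 blur_sigma = 3,
                                 seed = 1L) {
  stopifnot_scalar(width_px, "width_px", integerish = TRUE)
  stopifnot_scalar(height_px, "height_px", integerish = TRUE)
  stopifnot_scalar(base_magnification, "base_magnification")
  stopifnot_scalar(fat_fraction, "fat_fraction")
  if (fat_fraction < 0 || fat_fraction > 1) stop("fat_fraction must be in [0, 1]")
  if (any(levels <= 0) || any(levels > base_magnification)) {
    stop("all level magnifications must be > 0 and <= base_magnification")
  }
  counts <- c(n_representative_regions, n_artifact_regions, n_blur_regions)
  if (any(counts < 0)) stop("region counts must be >= 0")
  levels <- sort(unique(c(levels, base_magnification)), decreasing = TRUE)
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      base_magnification = base_magnification, levels = levels,
      n_representative_regions = as.integer(n_representative_regions),
      n_artifact_regions = as.integer(n_artifact_regions),
      n_blur_regions = as.integer(n_blur_regions),
      fat_fraction = fat_fraction,
      nuclei_density_representative = nuclei_density_representative,
      nuclei_density_tissue = nuclei_density_tissue,
      blur_sigma = blur_sigma,
      seed = as.integer(seed)
    ),
    class = "SyntheticSlideSpec"
  )
}

region_df <- function(x0 = integer(0), y0 = integer(0),
                      w = integer(0), h = integer(0)) {
  data.frame(
    x0 = as.integer(x0), y0 = as.integer(y0),
    w = as.integer(w), h = as.integer(h)
  )
}

#' Construct a ground-truth object
#'
#' Usually produced by [generate_slide()]; exposed so that annotation
#' simulations can run on hand-built truths without rendering pixels.
#' Regions are axis-aligned rectangles `(x0, y0, w, h)` in 0-based pixels
#' at the base magnification; representative, artifact, and empty regions
#' must be mutually exclusive.
#'
#' @param slide_id slide identifier.
#' @param base_magnification magnification the coordinates refer to.
#' @param width,height slide dimensions at that magnification.
#' @param representative_regions,artifact_regions,blur_regions,empty_regions
#'   region data.frames (columns `x0`, `y0`, `w`, `h`).
#' @param free_cells optional data.frame of unoccupied tissue cells used to
#'   place spurious annotator marks.
#' @return an object of class `GroundTruth`.
#' @export
ground_truth <- function(slide_id, base_magnification, width, height,
                         representative_regions = region_df(),
                         artifact_regions = region_df(),
                         blur_regions = region_df(),
                         empty_regions = region_df(),
                         free_cells = region_df()) {
  gt <- structure(
    list(
      slide_id = slide_id, base_magnification = base_magnification,
      width = as.integer(width), height = as.integer(height),
      representative_regions = representative_regions,
      artifact_regions = artifact_regions,
      blur_regions = blur_regions,
      empty_regions = empty_regions,
      free_cells = free_cells
    ),
    class = "GroundTruth"
  )
  excl <- rbind(representative_regions, artifact_regions, empty_regions)
  if (nrow(excl) > 1L) {
    for (i in seq_len(nrow(excl) - 1L)) {
      for (j in (i + 1L):nrow(excl)) {
        if (rect_overlap_area(excl[i, ], excl[j, ]) > 0) {
          stop("representative, artifact, and empty regions must be mutually exclusive")
        }
      }
    }
  }
  gt
}

rect_overlap_area <- function(a, b) {
  dx <- min(a$x0 + a$w, b$x0 + b$w) - max(a$x0, b$x0)
  dy <- min(a$y0 + a$h, b$y0 + b$h) - max(a$y0, b$y0)
  if (dx <= 0 || dy <= 0) 0 else dx * dy
}

#' Logical mask of representative pixels at base magnification
#' @param truth a [ground_truth()].
#' @return logical matrix (height x width).
#' @export
representative_mask <- function(truth) {
  m <- matrix(FALSE, truth$height, truth$width)
  rr <- truth$representative_regions
  for (i in seq_len(nrow(rr))) {
    m[(rr$y0[i] + 1L):(rr$y0[i] + rr$h[i]),
      (rr$x0[i] + 1L):(rr$x0[i] + rr$w[i])] <- TRUE
  }
  m
}

# Draw dark elliptical "nuclei" into an RGB canvas inside the rectangle
# (x0, y0, w, h); coverage is the target area fraction.
draw_nuclei <- function(canvas, x0, y0, w, h, coverage, mean_radius) {
  n <- max(0L, round(coverage * w * h / (pi * mean_radius^2)))
  if (n == 0L) return(canvas)
  cx <- runif(n, x0, x0 + w)
  cy <- runif(n, y0, y0 + h)
  rx <- runif(n, 0.6, 1.4) * mean_radius
  ry <- runif(n, 0.6, 1.4) * mean_radius
  col <- .PALETTE$nucleus
  H <- dim(canvas)[1L]; W <- dim(canvas)[2L]
  for (i in seq_len(n)) {
    xa <- max(1L, floor(cx[i] - rx[i])); xb <- min(W, ceiling(cx[i] + rx[i]))
    ya <- max(1L, floor(cy[i] - ry[i])); yb <- min(H, ceiling(cy[i] + ry[i]))
    if (xa > xb || ya > yb) next
    xs <- xa:xb; ys <- ya:yb
    dx2 <- ((xs - cx[i]) / rx[i])^2
    dy2 <- ((ys - cy[i]) / ry[i])^2
    inside <- outer(dy2, dx2, `+`) <= 1
    if (!any(inside)) next
    for (ch in 1:3) {
      sl <- canvas[ys, xs, ch]
      sl[inside] <- col[ch]
      canvas[ys, xs, ch] <- sl
    }
  }
  canvas
}

fill_rect <- function(canvas, x0, y0, w, h, col, noise_sd = 0) {
  ys <- (y0 + 1L):(y0 + h); xs <- (x0 + 1L):(x0 + w)
  for (ch in 1:3) {
    v <- matrix(col[ch], h, w)
    if (noise_sd > 0) v <- v + matrix(rnorm(h * w, 0, noise_sd), h, w)
    canvas[ys, xs, ch] <- clamp(round_half_up(v), 0, 255)
  }
  canvas
}

#' Generate a synthetic pyramidal slide with known ground truth
#'
#' @param spec a [synthetic_slide_spec()].
#' @param slide_id identifier for the generated slide.
#' @return a list with elements `slide` (a [slide_pyramid()]) and `truth`
#'   (a [ground_truth()]).
#' @details Planted regions occupy one cell each of the 10x block grid
#'   expressed in base pixels, so every representative region covers
#'   exactly one full classification block. A demand for more regions than
#'   there are available tissue cells raises an "overcrowded spec" error.
#' @export
generate_slide <- function(spec, slide_id = "synthetic") {
  stopifnot(inherits(spec, "SyntheticSlideSpec"))
  W <- spec$width_px; H <- spec$height_px
  base_mag <- spec$base_magnification
  cell <- as.integer(round_half_up(TILE_SIZE * base_mag / 10))
  fat_rows <- as.integer(round_half_up(spec$fat_fraction * H))
  tissue_h <- H - fat_rows

  n_cell_rows <- tissue_h %/% cell
  n_cell_cols <- W %/% cell
  n_cells <- n_cell_rows * n_cell_cols
  n_demand <- spec$n_representative_regions + spec$n_artifact_regions +
    spec$n_blur_regions
  if (n_demand > n_cells) {
    stop(sprintf(
      "overcrowded spec: %d regions demanded but only %d grid cells available",
      n_demand, n_cells
    ))
  }

  with_seed(spec$seed, {
    canvas <- array(0, dim = c(H, W, 3L))
    if (tissue_h > 0) {
      canvas <- fill_rect(canvas, 0L, 0L, W, tissue_h, .PALETTE$tissue, noise_sd = 2)
    }
    if (fat_rows > 0) {
      canvas <- fill_rect(canvas, 0L, tissue_h, W, fat_rows, .PALETTE$fat, noise_sd = 2)
    }
    mean_radius <- 6 * base_mag / 20

    if (tissue_h > 0 && spec$nuclei_density_tissue > 0) {
      canvas <- draw_nuclei(canvas, 0, 0, W, tissue_h,
                            spec$nuclei_density_tissue, mean_radius)
    }

    cells <- if (n_cells > 0) sample.int(n_cells, n_demand) else integer(0)
    cell_rect <- function(idx) {
      r <- (idx - 1L) %/% n_cell_cols
      c <- (idx - 1L) %% n_cell_cols
      region_df(c * cell, r * cell, cell, cell)
    }
    take <- function(n, offset) {
      if (n == 0L) return(region_df())
      do.call(rbind, lapply(cells[offset + seq_len(n)], cell_rect))
    }
    rep_regions <- take(spec$n_representative_regions, 0L)
    art_regions <- take(spec$n_artifact_regions, spec$n_representative_regions)
    blur_regions <- take(spec$n_blur_regions,
                         spec$n_representative_regions + spec$n_artifact_regions)

    for (i in seq_len(nrow(rep_regions))) {
      r <- rep_regions[i, ]
      canvas <- draw_nuclei(canvas, r$x0, r$y0, r$w, r$h,
                            spec$nuclei_density_representative, mean_radius)
    }
    for (i in seq_len(nrow(art_regions))) {
      r <- art_regions[i, ]
      canvas <- fill_rect(canvas, r$x0, r$y0, r$w, r$h, .PALETTE$artifact,
                          noise_sd = 2)
    }
    for (i in seq_len(nrow(blur_regions))) {
      r <- blur_regions[i, ]
      canvas <- draw_nuclei(canvas, r$x0, r$y0, r$w, r$h, 0.35, mean_radius)
      ys <- (r$y0 + 1L):(r$y0 + r$h); xs <- (r$x0 + 1L):(r$x0 + r$w)
      sigma <- spec$blur_sigma * base_mag / 10
      canvas[ys, xs, ] <- gaussian_blur(canvas[ys, xs, , drop = FALSE], sigma)
    }
    canvas <- clamp(canvas, 0, 255)

    levels <- lapply(spec$levels, function(mag) {
      if (isTRUE(all.equal(mag, base_mag))) {
        return(list(magnification = mag, data = canvas))
      }
      r <- mag / base_mag
      list(
        magnification = mag,
        data = area_resample(canvas,
                             as.integer(round_half_up(H * r)),
                             as.integer(round_half_up(W * r)))
      )
    })

    occupied <- if (n_demand > 0) cells else integer(0)
    free_idx <- setdiff(seq_len(n_cells), occupied)
    free_cells <- if (length(free_idx)) {
      do.call(rbind, lapply(free_idx, cell_rect))
    } else {
      region_df()
    }
    empty_regions <- if (fat_rows > 0) {
      region_df(0L, tissue_h, W, fat_rows)
    } else {
      region_df()
    }

    list(
      slide = slide_pyramid(levels, slide_id = slide_id),
      truth = ground_truth(
        slide_id, base_mag, W, H,
        representative_regions = rep_regions,
        artifact_regions = art_regions,
        blur_regions = blur_regions,
        empty_regions = empty_regions,
        free_cells = free_cells
      )
    )
  })
}

#' Simulate pathologist annotation sets
#'
#' Each simulated annotator marks every true representative region
#' independently with probability `agreement_prob` and adds a Poisson
#' (`false_mark_rate`) number of spurious marks drawn from the unoccupied
#' tissue cells of the slide.
#'
#' @param truth a [ground_truth()].
#' @param n_annotators number of annotators (default 3).
#' @param agreement_prob per-region probability each annotator marks a true
#'   representative region.
#' @param false_mark_rate expected number of spurious regions per
#'   annotator.
#' @param seed integer seed.
#' @return list of `AnnotationSet` objects, one per annotator; each has
#'   `annotator_id`, `slide_id`, `magnification`, and a `regions`
#'   data.frame.
#' @export
generate_annotations <- function(truth, n_annotators = 3L,
                                 agreement_prob = 1, false_mark_rate = 0,
                                 seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (n_annotators < 1L) stop("n_annotators must be >= 1")
  if (agreement_prob < 0 || agreement_prob > 1) {
    stop("agreement_prob must be in [0, 1]")
  }
  if (false_mark_rate < 0) stop("false_mark_rate must be >= 0")
  rr <- truth$representative_regions
  with_seed(seed, {
    lapply(seq_len(n_annotators), function(a) {
      keep <- if (nrow(rr)) runif(nrow(rr)) <= agreement_prob else logical(0)
      regions <- rr[keep, , drop = FALSE]
      n_spur <- stats::rpois(1L, false_mark_rate)
      if (n_spur > 0 && nrow(truth$free_cells) > 0) {
        idx <- sample.int(nrow(truth$free_cells), min(n_spur, nrow(truth$free_cells)))
        regions <- rbind(regions, truth$free_cells[idx, , drop = FALSE])
      }
      rownames(regions) <- NULL
      structure(
        list(
          annotator_id = sprintf("annotator_%d", a),
          slide_id = truth$slide_id,
          magnification = truth$base_magnification,
          regions = regions
        ),
        class = "AnnotationSet"
      )
    })
  })
}

#' Construct an annotation set directly
#' @param regions data.frame with columns `x0`, `y0`, `w`, `h`.
#' @param annotator_id,slide_id identifiers.
#' @param magnification magnification the region coordinates refer to.
#' @export
annotation_set <- function(regions, annotator_id = "annotator",
                           slide_id = "slide", magnification = 20) {
  structure(
    list(annotator_id = annotator_id, slide_id = slide_id,
         magnification = magnification, regions = regions),
    class = "AnnotationSet"
  )
}

#' Simulate a per-nucleus biomarker signal-count table
#'
#' HER2 and CEP17 signal counts per nucleus are modeled as independent
#' Poisson draws.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param her2_mean,cep17_mean Poisson means of the per-nucleus counts
#'   (> 0).
#' @param seed integer seed.
#' @return data.frame with columns `nucleus_id`, `her2_count`,
#'   `cep17_count`.
#' @export
generate_signal_table <- function(n_nuclei, her2_mean, cep17_mean, seed = 1L) {
  stopifnot_scalar(n_nuclei, "n_nuclei", integerish = TRUE)
  if (n_nuclei < 1L) stop("empty table: n_nuclei must be >= 1")
  if (her2_mean <= 0 || cep17_mean <= 0) stop("signal means must be > 0")
  with_seed(seed, {
    data.frame(
      nucleus_id = seq_len(n_nuclei),
      her2_count = stats::rpois(n_nuclei, her2_mean),
      cep17_count = stats::rpois(n_nuclei, cep17_mean)
    )
  })
}
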