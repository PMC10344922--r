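# End-to-end slide-level ROI detection and its evaluation against
# pathologist annotations.
#
# Stage order on a slide: tile the chosen magnification into 224 x 224
# blocks, screen every block (empty -> artifact -> quality), then classify
# only the surviving CANDIDATE blocks. Screened-out blocks are never shown
# to the classifier.

#' Detect ROIs on a whole slide
#'
#' @param slide a [slide_pyramid()].
#' @param classifier a trained [build_classifier()] handle or an
#'   [oracle_classifier()]; its `magnification` must match the requested
#'   one.
#' @param magnification magnification at which to tile and classify
#'   (default 10).
#' @param config a [screen_config()].
#' @param threshold decision threshold on the positive-class probability.
#' @return an [roi_map()] in which every block carries a final state.
#' @export
detect_rois <- function(slide, classifier, magnification = 10,
                        config = screen_config(), threshold = 0.5) {
  stopifnot(inherits(slide, "SlidePyramid"))
  cls_mag <- classifier$magnification
  if (!isTRUE(all.equal(cls_mag, magnification))) {
    stop(sprintf(
      "classifier was trained at %gx but detection was requested at %gx",
      cls_mag, magnification
    ))
  }
  blocks <- tile_grid(slide, magnification)
  for (i in seq_len(nrow(blocks))) {
    blocks$state[i] <- screen_block(slide, blocks[i, ], config)
  }
  cand <- which(blocks$state == "CANDIDATE")
  if (length(cand)) {
    probs <- classify_blocks(classifier, slide, blocks[cand, , drop = FALSE])
    blocks$state[cand] <- ifelse(probs >= threshold,
                                 "REPRESENTATIVE", "NON_REPRESENTATIVE")
  }
  roi_map(blocks, slide$slide_id, magnification)
}

classify_blocks <- function(classifier, slide, blocks) {
  if (inherits(classifier, "oracle_classifier")) {
    classifier$n_predict_calls <- classifier$n_predict_calls + nrow(blocks)
    vapply(seq_len(nrow(blocks)), function(i) {
      as.numeric(
        block_coverage(blocks[i, ], classifier$aset) >= classifier$min_overlap
      )
    }, numeric(1))
  } else {
    imgs <- lapply(seq_len(nrow(blocks)), function(i) {
      read_block_image(slide, blocks[i, ])
    })
    predict_classifier(classifier, imgs)
  }
}

#' Evaluate a detection map against three pathologist annotation sets
#'
#' A block counts as selected by an annotator when the annotator's regions
#' cover at least `min_overlap` of it (the same rule as consensus
#' labeling). Detected = final state `REPRESENTATIVE`.
#'
#' @param map an [roi_map()].
#' @param annotations list of exactly 3 annotation sets.
#' @param min_overlap coverage rule threshold (default 0.5).
#' @return a `DetectionEvaluation` list: `true_positives` (detected and
#'   selected by all 3), `false_negatives` (selected by all 3, not
#'   detected), and `false_positives_by_type` with `type1` (detected +
#'   2 annotators), `type2` (detected + 1 annotator), `type3` (detected
#'   only). Undetected blocks with fewer than 3 annotators are true
#'   negatives and are not reported.
#' @export
evaluate_detection <- function(map, annotations, min_overlap = 0.5) {
  stopifnot(inherits(map, "ROIMap"))
  if (length(annotations) != 3L) {
    stop("the false-positive taxonomy is defined for exactly 3 annotators")
  }
  blocks <- map$blocks
  n_annot <- vapply(seq_len(nrow(blocks)), function(i) {
    sum(vapply(annotations, function(a) {
      block_coverage(blocks[i, ], a) >= min_overlap
    }, logical(1)))
  }, integer(1))
  detected <- blocks$state == "REPRESENTATIVE"
  structure(
    list(
      true_positives = sum(detected & n_annot == 3L),
      false_negatives = sum(!detected & n_annot == 3L),
      false_positives_by_type = list(
        type1 = sum(detected & n_annot == 2L),
        type2 = sum(detected & n_annot == 1L),
        type3 = sum(detected & n_annot == 0L)
      )
    ),
    class = "DetectionEvaluation"
  )
}

#' @export
print.DetectionEvaluation <- function(x, ...) {
  fp <- x$false_positives_by_type
  cat(sprintf(
    "TP: %d  FN: %d  FP: %d (type1 %d, type2 %d, type3 %d)\n",
    x$true_positives, x$false_negatives,
    fp$type1 + fp$type2 + fp$type3, fp$type1, fp$type2, fp$type3
  ))
  invisible(x)
}

#' Affine coordinate transform
#'
#' @param a,b,c,d linear part (`x' = a x + b y + tx`,
#'   `y' = c x + d y + ty`).
#' @param tx,ty translation in pixels.
#' @return an object of class `AffineTransform`.
#' @export
affine_transform <- function(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0) {
  det <- a * d - b * c
  if (abs(det) < 1e-12) stop("singular transform")
  structure(list(a = a, b = b, c = c, d = d, tx = tx, ty = ty),
            class = "AffineTransform")
}

#' Invert an affine transform
#' @param t an [affine_transform()].
#' @export
affine_invert <- function(t) {
  det <- t$a * t$d - t$b * t$c
  affine_transform(
    a = t$d / det, b = -t$b / det, c = -t$c / det, d = t$a / det,
    tx = (t$b * t$ty - t$d * t$tx) / det,
    ty = (t$c * t$tx - t$a * t$ty) / det
  )
}

#' Read an affine transform from a JSON registration sidecar
#' @param path JSON file with fields a, b, c, d, tx, ty.
#' @export
read_affine_transform <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(v$a %||% 1, v$b %||% 0, v$c %||% 0, v$d %||% 1,
                   v$tx %||% 0, v$ty %||% 0)
}

#' Transfer an ROI map into a registered serial slide's frame
#'
#' Maps every block origin through the affine transform (as produced by an
#' external image registration of, e.g., the H&E slide onto its serial
#' CISH/FISH section), rounding to the nearest pixel. States are
#' preserved.
#'
#' @param map an [roi_map()].
#' @param transform an [affine_transform()].
#' @param slide_id optional new slide id for the target frame.
#' @return an [roi_map()] in the target frame.
#' @export
transfer_coordinates <- function(map, transform, slide_id = map$slide_id) {
  stopifnot(inherits(map, "ROIMap"), inherits(transform, "AffineTransform"))
  b <- map$blocks
  x <- b$origin_x; y <- b$origin_y
  b$origin_x <- as.integer(round_half_up(transform$a * x + transform$b * y + transform$tx))
  b$origin_y <- as.integer(round_half_up(transform$c * x + transform$d * y + transform$ty))
  b$slide_id <- slide_id
  out <- map
  out$blocks <- b
  out$slide_id <- slide_id
  out
}
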