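# Consensus labeling: a block is positive only when every required
# annotator ("all three" in the reference workflow) covers it. Blocks
# marked by fewer annotators are negative.

# Fraction of a block's area covered by an annotation set's regions.
# Regions are scaled from the annotation magnification to the block's
# magnification and rasterized onto the block at 1 px resolution, so
# overlapping regions are not double counted.
block_coverage <- function(block, aset) {
  f <- block$magnification / aset$magnification
  size <- block$size
  mask <- matrix(FALSE, size, size)
  rr <- aset$regions
  for (i in seq_len(nrow(rr))) {
    x0 <- rr$x0[i] * f - block$origin_x
    y0 <- rr$y0[i] * f - block$origin_y
    x1 <- (rr$x0[i] + rr$w[i]) * f - block$origin_x
    y1 <- (rr$y0[i] + rr$h[i]) * f - block$origin_y
    xa <- max(1L, as.integer(floor(x0)) + 1L)
    xb <- min(size, as.integer(ceiling(x1)))
    ya <- max(1L, as.integer(floor(y0)) + 1L)
    yb <- min(size, as.integer(ceiling(y1)))
    if (xa > xb || ya > yb) next
    mask[ya:yb, xa:xb] <- TRUE
  }
  mean(mask)
}

#' Consensus label for one block
#'
#' @param block one block row from [tile_grid()].
#' @param annotations list of annotation sets.
#' @param k_required number of annotators that must cover the block for a
#'   positive label (default 3: the all-three intersection rule).
#' @param min_overlap minimum fraction of the block's area an annotator's
#'   regions must cover to count as having "selected" the block (default
#'   0.5).
#' @return `"positive"` or `"negative"`.
#' @export
consensus_label <- function(block, annotations, k_required = 3L,
                            min_overlap = 0.5) {
  if (k_required > length(annotations)) {
    stop(sprintf("k_required (%d) exceeds number of annotators (%d)",
                 k_required, length(annotations)))
  }
  n_cover <- sum(vapply(
    annotations,
    function(a) block_coverage(block, a) >= min_overlap,
    logical(1)
  ))
  if (n_cover >= k_required) "positive" else "negative"
}

#' Label every block of a grid by annotator consensus
#'
#' @param blocks a [tile_grid()] data.frame.
#' @param annotations list of annotation sets.
#' @inheritParams consensus_label
#' @return `blocks` with an added `label` column (`"positive"` /
#'   `"negative"`).
#' @export
label_tiles <- function(blocks, annotations, k_required = 3L,
                        min_overlap = 0.5) {
  blocks$label <- vapply(
    seq_len(nrow(blocks)),
    function(i) consensus_label(blocks[i, ], annotations, k_required, min_overlap),
    character(1)
  )
  blocks
}
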