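# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators never
#' perturb the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero ("round half up" for the non-negative pixel
# coordinates used throughout). base::round() rounds half to even.
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Convert a raster to integer luminance
#'
#' Accepts either a grayscale matrix or an `h x w x 3` RGB array with values
#' on the 0..255 scale. RGB is collapsed with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114) and rounded to the nearest integer gray level.
#'
#' @param img matrix or 3-d array, values in 0..255.
#' @return integer-valued matrix of gray levels.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) {
    return(round_half_up(img))
  }
  if (length(dim(img)) == 3L) {
    y <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    return(round_half_up(y))
  }
  stop("raster must be a matrix or an h x w x 3 array")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Area-average resampling weight matrix mapping n_in samples to n_out.
# Rows sum to 1; entry (i, j) is the fractional overlap of output cell i
# with input cell j. Exact for integer and non-integer factors.
resample_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale
    b <- i * scale
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) w[i, j] <- ov
    }
    w[i, ] <- w[i, ] / (b - a)
  }
  w
}

# Exact block mean for integer downsampling factors (cheap path).
block_mean <- function(m, fy, fx) {
  h <- nrow(m) %/% fy; w <- ncol(m) %/% fx
  dim(m) <- c(fy, h, fx * w)
  m <- colMeans(m)              # h x (fx * w)
  dim(m) <- c(h, fx, w)
  colMeans(aperm(m, c(2L, 1L, 3L)))
}

# Area-average resample of a matrix or RGB array to (h_out, w_out).
area_resample <- function(img, h_out, w_out) {
  d <- dim(img)
  integer_factor <- d[1L] %% h_out == 0L && d[2L] %% w_out == 0L
  resample_mat <- if (integer_factor) {
    fy <- d[1L] %/% h_out; fx <- d[2L] %/% w_out
    function(m) block_mean(m, fy, fx)
  } else {
    wr <- resample_weights(d[1L], h_out)
    wc <- resample_weights(d[2L], w_out)
    function(m) wr %*% m %*% t(wc)
  }
  if (is.matrix(img)) return(resample_mat(img))
  out <- array(0, dim = c(h_out, w_out, d[3L]))
  for (k in seq_len(d[3L])) out[, , k] <- resample_mat(img[, , k])
  out
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(m) {
    pad <- function(m, r, dim) {
      if (dim == 1L) {
        rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
      } else {
        cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(ncol(m), r), drop = FALSE])
      }
    }
    p <- pad(m, r, 1L)
    s <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) s <- s + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    p <- pad(s, r, 2L)
    s <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) s <- s + k[i] * p[, i:(i + ncol(m) - 1L), drop = FALSE]
    s
  }
  if (is.matrix(img)) return(blur_mat(img))
  for (ch in seq_len(dim(img)[3L])) img[, , ch] <- blur_mat(img[, , ch])
  img
}

stopifnot_scalar <- function(x, name, integerish = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name))
  }
  if (integerish && x != trunc(x)) {
    stop(sprintf("'%s' must be an integer", name))
  }
  invisible(x)
}
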