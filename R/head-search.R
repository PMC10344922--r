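# Classification-head architecture enumeration and hyperparameter grids.
#
# A head maps a 1000-wide feature vector to 2 output classes through a
# strictly decreasing chain of hidden layers drawn from the halving pool
# (512, 256, 128, 64, 32, 16, 8, 4). Three generators produce the
# candidate set:
#   * halving chains: all prefixes of the pool (depths 0..8) -> 9 heads;
#   * skip-one variants: every single-hidden-layer omission from each
#     halving chain, deduplicated (36 raw - 8 duplicates) -> 28 new heads;
#   * contiguous-run variants: omitting every contiguous run of 2..7
#     hidden layers from the deepest chain, deduplicated (27 raw - 6
#     duplicates) -> 21 new heads;
# for a grand total of 58 distinct architectures.

HALVING_POOL <- c(512L, 256L, 128L, 64L, 32L, 16L, 8L, 4L)

#' Construct a classification-head architecture
#'
#' @param hidden_widths ordered integer vector of hidden-layer widths
#'   (possibly empty); must be strictly decreasing and drawn from the
#'   halving pool 512, 256, ..., 4.
#' @param input_width,output_width fixed at 1000 and 2 in the reference
#'   design.
#' @return an object of class `HeadArchitecture`.
#' @export
head_architecture <- function(hidden_widths = integer(0),
                              input_width = 1000L, output_width = 2L) {
  hidden_widths <- as.integer(hidden_widths)
  if (length(hidden_widths)) {
    if (any(diff(hidden_widths) >= 0)) {
      stop("hidden widths must be strictly decreasing")
    }
    if (!all(hidden_widths %in% HALVING_POOL)) {
      stop("hidden widths must be drawn from the halving pool ",
           paste(HALVING_POOL, collapse = ", "))
    }
  }
  structure(
    list(
      input_width = as.integer(input_width),
      hidden_widths = hidden_widths,
      output_width = as.integer(output_width)
    ),
    class = "HeadArchitecture"
  )
}

#' @export
format.HeadArchitecture <- function(x, ...) {
  paste(c(x$input_width, x$hidden_widths, x$output_width), collapse = "-")
}

#' @export
print.HeadArchitecture <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

arch_key <- function(arch) format(arch)

# Canonical ordering: by depth, then lexicographically on the hidden
# widths (wider first).
order_architectures <- function(archs) {
  if (!length(archs)) return(archs)
  depth <- vapply(archs, function(a) length(a$hidden_widths), integer(1))
  keys <- vapply(archs, function(a) {
    paste(sprintf("%03d", c(a$hidden_widths, rep(0L, 8L - length(a$hidden_widths)))),
          collapse = "")
  }, character(1))
  archs[order(depth, keys, method = "radix", decreasing = c(FALSE, TRUE))]
}

dedup_architectures <- function(archs, against = list()) {
  seen <- vapply(against, arch_key, character(1))
  out <- list()
  for (a in archs) {
    k <- arch_key(a)
    if (!k %in% seen) {
      out[[length(out) + 1L]] <- a
      seen <- c(seen, k)
    }
  }
  out
}

#' Halving-chain head architectures
#'
#' Heads whose hidden layers are the first `m` elements of the halving
#' pool, for `m` = 0..8 (9 architectures in total, from the bare
#' 1000-2 mapping to the full 10-layer 1000-512-...-4-2 chain).
#'
#' @return list of [head_architecture()] objects in canonical order.
#' @export
halving_chains <- function() {
  lapply(0:8, function(m) head_architecture(HALVING_POOL[seq_len(m)]))
}

#' Single-omission head variants
#'
#' For every halving chain, every architecture obtained by omitting
#' exactly one hidden layer, deduplicated against the chains themselves
#' and each other (omitting the last hidden layer of a chain reproduces
#' the next-shallower chain). Yields 28 new architectures.
#'
#' @param chains list of chains from [halving_chains()].
#' @return list of new [head_architecture()] objects in canonical order.
#' @export
skip_one_variants <- function(chains = halving_chains()) {
  raw <- list()
  for (ch in chains) {
    hw <- ch$hidden_widths
    for (i in seq_along(hw)) {
      raw[[length(raw) + 1L]] <- head_architecture(hw[-i])
    }
  }
  order_architectures(dedup_architectures(raw, against = chains))
}

#' Contiguous-run omission variants
#'
#' From the deepest halving chain, omit every contiguous run of `k`
#' hidden layers for `k` = `k_min`..`k_max`, deduplicated against the
#' halving chains, the single-omission variants, and each other. With the
#' defaults this yields 21 new architectures.
#'
#' @param k_min,k_max run lengths to omit (defaults 2 and 7).
#' @param against architectures to deduplicate against (defaults to the
#'   halving chains plus their single-omission variants).
#' @return list of new [head_architecture()] objects in canonical order.
#' @export
contiguous_skip_variants <- function(k_min = 2L, k_max = 7L,
                                     against = NULL) {
  if (is.null(against)) {
    chains <- halving_chains()
    against <- c(chains, skip_one_variants(chains))
  }
  full <- HALVING_POOL
  raw <- list()
  for (k in k_min:k_max) {
    for (start in seq_len(length(full) - k + 1L)) {
      keep <- setdiff(seq_along(full), start:(start + k - 1L))
      raw[[length(raw) + 1L]] <- head_architecture(full[keep])
    }
  }
  order_architectures(dedup_architectures(raw, against = against))
}

#' All candidate head architectures
#'
#' Union of the halving chains, single-omission variants, and
#' contiguous-run variants after global deduplication (58 architectures).
#'
#' @return list of [head_architecture()] objects.
#' @export
all_head_architectures <- function() {
  chains <- halving_chains()
  skips <- skip_one_variants(chains)
  runs <- contiguous_skip_variants(against = c(chains, skips))
  c(chains, skips, runs)
}

#' Trainable parameter count of a head
#' @param arch a [head_architecture()].
#' @return number of weights and biases in the dense chain.
#' @export
head_param_count <- function(arch) {
  widths <- c(arch$input_width, arch$hidden_widths, arch$output_width)
  sum((widths[-length(widths)] + 1L) * widths[-1L])
}

#' Hyperparameter grid
#'
#' @param epochs,batch_sizes,optimizers,loss_functions,learning_rates,dropouts
#'   non-empty vectors of candidate values.
#' @return an object of class `HyperParamGrid`.
#' @export
hyperparam_grid <- function(epochs, batch_sizes, optimizers, loss_functions,
                            learning_rates, dropouts) {
  dims <- list(
    epochs = epochs, batch_sizes = batch_sizes, optimizers = optimizers,
    loss_functions = loss_functions, learning_rates = learning_rates,
    dropouts = dropouts
  )
  for (nm in names(dims)) {
    if (!length(dims[[nm]])) stop("empty grid dimension: ", nm)
  }
  if (any(epochs <= 0) || any(batch_sizes <= 0) || any(learning_rates <= 0)) {
    stop("epochs, batch sizes, and learning rates must be positive")
  }
  structure(dims, class = "HyperParamGrid")
}

#' The reference CNN hyperparameter grid
#'
#' Four epoch counts, three batch sizes, four optimizers, two loss
#' functions, three learning rates, and four dropout rates: 1152
#' configurations per model.
#'
#' @return a [hyperparam_grid()].
#' @export
reference_cnn_grid <- function() {
  hyperparam_grid(
    epochs = c(25L, 50L, 75L, 100L),
    batch_sizes = c(8L, 16L, 32L),
    optimizers = c("SGD", "Adam", "Adamax", "RMSProp"),
    loss_functions = c("categorical_crossentropy", "kullback_leibler_divergence"),
    learning_rates = c(0.01, 0.001, 0.0001),
    dropouts = c(0.5, 0.6, 0.7, 0.8)
  )
}

#' Enumerate every configuration of a hyperparameter grid
#'
#' @param grid a [hyperparam_grid()].
#' @return data.frame with one row per configuration, in row-major order
#'   over the field order (epochs slowest, dropouts fastest).
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "HyperParamGrid"))
  # expand.grid varies the first factor fastest; reverse to get row-major
  # over the documented field order.
  g <- expand.grid(rev(unclass(grid)), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(names(g)), drop = FALSE]
  ord <- do.call(order, c(lapply(names(unclass(grid)), function(nm) {
    match(g[[nm]], unclass(grid)[[nm]])
  }), list(method = "radix")))
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  names(g) <- c("epochs", "batch_size", "optimizer", "loss_function",
                "learning_rate", "dropout")
  g
}

#' Select the top candidate from evaluation records
#'
#' @param records data.frame with at least an `accuracy` column; optional
#'   `auc` and `param_count` columns refine the tie-break.
#' @return the index (row number) of the winning record. Ties on accuracy
#'   are broken by higher AUC, then smaller head parameter count, then
#'   earlier (canonical) position.
#' @export
select_top_candidate <- function(records) {
  if (!NROW(records)) stop("no candidate records")
  if (!"accuracy" %in% names(records) || all(is.na(records$accuracy))) {
    stop("records must include an 'accuracy' column with at least one value")
  }
  acc <- records$accuracy
  auc <- if ("auc" %in% names(records)) records$auc else rep(0, NROW(records))
  auc[is.na(auc)] <- 0
  pc <- if ("param_count" %in% names(records)) records$param_count else rep(0, NROW(records))
  pc[is.na(pc)] <- 0
  ord <- order(-acc, -auc, pc, seq_len(NROW(records)), method = "radix")
  ord[1L]
}
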