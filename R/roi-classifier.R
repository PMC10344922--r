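# Backbone-agnostic tile classification.
#
# A classifier is a frozen (or partially fine-tuned) feature extractor
# plus a trainable dense head. Three fine-tuning modes mirror the
# transfer-learning designs compared in the reference workflow:
#   * HEAD_ONLY       - backbone frozen, only the head trains (the CNN
#                       transfer-learning mode);
#   * MHSA_ONLY       - only the transformer's self-attention weights
#                       train, the head stays at its initialization;
#   * MHSA_PLUS_HEAD  - attention weights and the customized head train
#                       jointly.
# The named ImageNet-scale backbones resolve to seeded random-feature
# stand-ins with the genuine models' feature widths: no pretrained weights
# ship with this package, and every test runs on the desk-scale
# `tiny_cnn` / `tiny_vit` backbones.

BACKBONE_TABLE <- list(
  tiny_cnn = list(kind = "cnn", output_width = 1000L),
  tiny_vit = list(kind = "vit", output_width = 1000L),
  VGG16 = list(kind = "cnn", output_width = 4096L, synthetic = TRUE),
  VGG19 = list(kind = "cnn", output_width = 4096L, synthetic = TRUE),
  ResNet50 = list(kind = "cnn", output_width = 2048L, synthetic = TRUE),
  ResNet152 = list(kind = "cnn", output_width = 2048L, synthetic = TRUE),
  Xception = list(kind = "cnn", output_width = 2048L, synthetic = TRUE),
  InceptionV3 = list(kind = "cnn", output_width = 2048L, synthetic = TRUE),
  DenseNet121 = list(kind = "cnn", output_width = 1024L, synthetic = TRUE),
  `ViT-B/32` = list(kind = "vit", output_width = 1000L, synthetic = TRUE,
                    patch = 32L, mhsa_ffn_pairs = 24L)
)

backbone_seed <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
}

#' Available backbone names
#' @return character vector of registered backbone names.
#' @export
list_backbones <- function() names(BACKBONE_TABLE)

#' Classifier specification
#'
#' @param backbone backbone name (see [list_backbones()]).
#' @param head a [head_architecture()] or `"cnn_fc"` for the three-dense-
#'   layer CNN transfer head with top dropout.
#' @param finetune_mode `"HEAD_ONLY"`, `"MHSA_ONLY"`, or
#'   `"MHSA_PLUS_HEAD"`; the MHSA modes require a transformer backbone.
#' @param epochs,batch_size,optimizer,loss,learning_rate,dropout training
#'   hyperparameters. Supported optimizers: SGD, Adam, AdamW, Adamax,
#'   RMSProp. Supported losses: categorical cross-entropy and (one-hot)
#'   Kullback-Leibler divergence, which share a gradient.
#' @param magnification the magnification the classifier is trained for
#'   (used to guard slide-level detection).
#' @param seed integer seed controlling initialization and training.
#' @return an object of class `ClassifierSpec`.
#' @export
classifier_spec <- function(backbone = "tiny_cnn", head = "cnn_fc",
                            finetune_mode = c("HEAD_ONLY", "MHSA_ONLY",
                                              "MHSA_PLUS_HEAD"),
                            epochs = 30L, batch_size = 32L,
                            optimizer = "adam",
                            loss = "categorical_crossentropy",
                            learning_rate = 1e-3, dropout = 0,
                            magnification = 10, seed = 0L) {
  finetune_mode <- match.arg(finetune_mode)
  if (!backbone %in% names(BACKBONE_TABLE)) {
    stop("unknown backbone: ", backbone)
  }
  info <- BACKBONE_TABLE[[backbone]]
  if (finetune_mode != "HEAD_ONLY" && info$kind != "vit") {
    stop(sprintf("%s requires a transformer backbone; '%s' is a %s",
                 finetune_mode, backbone, info$kind))
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!tolower(loss) %in% c("categorical_crossentropy", "cross_entropy",
                            "kullback_leibler_divergence", "kl_divergence")) {
    stop("unknown loss: ", loss)
  }
  structure(
    list(
      backbone = backbone, head = head, finetune_mode = finetune_mode,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      optimizer = optimizer, loss = loss, learning_rate = learning_rate,
      dropout = dropout, magnification = magnification,
      seed = as.integer(seed)
    ),
    class = "ClassifierSpec"
  )
}

head_widths <- function(spec, backbone_width) {
  if (inherits(spec$head, "HeadArchitecture")) {
    if (spec$head$input_width != backbone_width) {
      stop(sprintf(
        "head input width (%d) does not match backbone output width (%d)",
        spec$head$input_width, backbone_width
      ))
    }
    c(spec$head$input_width, spec$head$hidden_widths, spec$head$output_width)
  } else if (identical(spec$head, "cnn_fc")) {
    c(backbone_width, 256L, 64L, 2L)
  } else {
    stop("head must be a HeadArchitecture or \"cnn_fc\"")
  }
}

#' Build a classifier handle from a specification
#'
#' @param spec a [classifier_spec()].
#' @return an environment of class `roi_classifier` exposing the trained
#'   state; use [train_classifier()], [predict_classifier()],
#'   [evaluate_classifier()] on it.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  info <- BACKBONE_TABLE[[spec$backbone]]
  bseed <- backbone_seed(spec$backbone)
  backbone <- if (info$kind == "cnn") {
    list(kind = "cnn",
         params = tiny_cnn_init(bseed, output_width = info$output_width))
  } else {
    list(kind = "vit", params = tiny_vit_init(bseed))
  }
  widths <- head_widths(spec, if (info$kind == "cnn") {
    backbone$params$output_width
  } else {
    backbone$params$cfg$output_width
  })
  handle <- new.env(parent = emptyenv())
  handle$spec <- spec
  handle$backbone <- backbone
  handle$head <- mlp_init(widths, spec$seed)
  handle$magnification <- spec$magnification
  handle$trained <- FALSE
  handle$n_predict_calls <- 0L
  class(handle) <- "roi_classifier"
  handle
}

#' Number of trainable parameters of a classifier
#'
#' Depends on the fine-tuning mode: head parameters in `HEAD_ONLY`, MHSA
#' projection parameters in `MHSA_ONLY`, both in `MHSA_PLUS_HEAD`.
#'
#' @param handle a built classifier.
#' @return integer count.
#' @export
trainable_parameter_count <- function(handle) {
  widths <- handle$head$widths
  n_head <- sum((widths[-length(widths)] + 1L) * widths[-1L])
  n_mhsa <- if (handle$backbone$kind == "vit") {
    cfg <- handle$backbone$params$cfg
    4L * cfg$d^2 * cfg$layers
  } else {
    0L
  }
  switch(handle$spec$finetune_mode,
    HEAD_ONLY = n_head,
    MHSA_ONLY = n_mhsa,
    MHSA_PLUS_HEAD = n_head + n_mhsa
  )
}

#' Extract backbone features for a list of images
#' @param handle a built classifier.
#' @param imgs list of rasters.
#' @return numeric matrix, one row per image.
#' @export
backbone_features <- function(handle, imgs) {
  if (handle$backbone$kind == "cnn") {
    tiny_cnn_featurize(handle$backbone$params, imgs)
  } else {
    vit_featurize(handle$backbone$params, imgs)
  }
}

as_label_int <- function(y) {
  if (is.character(y) || is.factor(y)) {
    as.integer(as.character(y) == "positive")
  } else {
    as.integer(y)
  }
}

#' Train a classifier
#'
#' Deterministic under a fixed `spec$seed` (single-threaded execution
#' assumed). In `HEAD_ONLY` mode features are extracted once (or per epoch
#' when augmentation is on) and only the dense head is optimized; in the
#' MHSA modes gradients are backpropagated through the transformer encoder
#' into the attention projections.
#'
#' @param handle a built classifier (modified in place).
#' @param train_x list of rasters (or a precomputed feature matrix in
#'   `HEAD_ONLY` mode without augmentation).
#' @param train_y,val_y labels: `"positive"`/`"negative"` or 1/0.
#' @param val_x validation rasters/features.
#' @param augment apply random flip/rotate/zoom augmentation each epoch
#'   (rasters only).
#' @return training log data.frame (`epoch`, `loss`, `val_accuracy`),
#'   invisibly also stored as `handle$log`.
#' @export
train_classifier <- function(handle, train_x, train_y, val_x = NULL,
                             val_y = NULL, augment = FALSE) {
  stopifnot(inherits(handle, "roi_classifier"))
  spec <- handle$spec
  y <- as_label_int(train_y)
  if (!length(y)) stop("empty training set")
  mode <- spec$finetune_mode
  as_features <- function(x) {
    if (is.matrix(x) && !is.list(x)) x else backbone_features(handle, x)
  }

  log <- with_seed(spec$seed, {
    if (mode == "HEAD_ONLY") {
      train_head_only(handle, train_x, y, val_x, val_y, augment, as_features)
    } else {
      train_mhsa(handle, train_x, y, val_x, val_y)
    }
  })
  handle$trained <- TRUE
  handle$log <- log
  invisible(log)
}

train_head_only <- function(handle, train_x, y, val_x, val_y, augment,
                            as_features) {
  spec <- handle$spec
  feats <- if (!augment) as_features(train_x) else NULL
  val_feats <- if (!is.null(val_x)) as_features(val_x) else NULL
  opt <- optimizer_new(spec$optimizer, length(head_flatten(handle$head)),
                       spec$learning_rate)
  n <- length(y)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    if (augment) {
      feats <- as_features(lapply(train_x, random_augment))
    }
    perm <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = spec$batch_size)) {
      idx <- perm[start:min(start + spec$batch_size - 1L, n)]
      fwd <- mlp_forward(handle$head, feats[idx, , drop = FALSE],
                         dropout = spec$dropout, training = TRUE)
      loss <- mlp_loss(fwd$probs, y[idx])
      if (!is.finite(loss) || !all(is.finite(fwd$acts[[length(fwd$acts)]]))) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
      }
      grad <- mlp_backward(handle$head, fwd, y[idx])
      theta <- optimizer_step(
        opt, head_flatten(handle$head),
        unlist(c(grad$dW, grad$db), use.names = FALSE)
      )
      handle$head <- head_unflatten(handle$head, theta)
      epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1L
    }
    val_acc <- NA_real_
    if (!is.null(val_feats)) {
      p <- mlp_forward(handle$head, val_feats)$probs[, 2L]
      val_acc <- mean((p >= 0.5) == (as_label_int(val_y) == 1L))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss / n_batches,
                                 val_accuracy = val_acc))
  }
  log
}

train_mhsa <- function(handle, train_x, y, val_x, val_y) {
  spec <- handle$spec
  vp <- handle$backbone$params
  train_head <- spec$finetune_mode == "MHSA_PLUS_HEAD"
  n <- length(y)
  n_mhsa <- length(vit_mhsa_flatten(vp))
  opt_m <- optimizer_new(spec$optimizer, n_mhsa, spec$learning_rate)
  opt_h <- if (train_head) {
    optimizer_new(spec$optimizer, length(head_flatten(handle$head)),
                  spec$learning_rate)
  } else {
    NULL
  }
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = spec$batch_size)) {
      idx <- perm[start:min(start + spec$batch_size - 1L, n)]
      outs <- lapply(train_x[idx], function(im) vit_forward_one(vp, im, TRUE))
      feats <- do.call(rbind, lapply(outs, function(o) o$feat))
      fwd <- mlp_forward(handle$head, feats, dropout = spec$dropout,
                         training = TRUE)
      loss <- mlp_loss(fwd$probs, y[idx])
      if (!is.finite(loss) || !all(is.finite(fwd$acts[[length(fwd$acts)]]))) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
      }
      grad <- mlp_backward(handle$head, fwd, y[idx])
      mhsa_grad <- numeric(n_mhsa)
      for (j in seq_along(idx)) {
        g <- vit_backward_one(vp, outs[[j]]$caches, grad$dX[j, ])
        mhsa_grad <- mhsa_grad + vit_mhsa_grad_flatten(g)
      }
      vp <- vit_mhsa_unflatten(
        vp, optimizer_step(opt_m, vit_mhsa_flatten(vp), mhsa_grad)
      )
      if (train_head) {
        theta <- optimizer_step(
          opt_h, head_flatten(handle$head),
          unlist(c(grad$dW, grad$db), use.names = FALSE)
        )
        handle$head <- head_unflatten(handle$head, theta)
      }
      epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1L
    }
    handle$backbone$params <- vp
    val_acc <- NA_real_
    if (!is.null(val_x)) {
      p <- predict_classifier(handle, val_x)
      val_acc <- mean((p >= 0.5) == (as_label_int(val_y) == 1L))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss / n_batches,
                                 val_accuracy = val_acc))
  }
  handle$backbone$params <- vp
  log
}

#' Predict positive-class probabilities
#'
#' @param handle a classifier.
#' @param x list of rasters or a feature matrix.
#' @return numeric vector of P(representative).
#' @export
predict_classifier <- function(handle, x) {
  feats <- if (is.matrix(x) && !is.list(x)) x else backbone_features(handle, x)
  handle$n_predict_calls <- handle$n_predict_calls + nrow(feats)
  mlp_forward(handle$head, feats)$probs[, 2L]
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; tied scores receive half credit.
#'
#' @param scores predicted positive-class scores.
#' @param labels true labels (1/0 or positive/negative).
#' @return AUC in `[0, 1]`; `NaN` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  y <- as_label_int(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#' @param scores,labels as in [auc_score()].
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_label_int(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(
      fpr = sum(pred & y == 0L) / max(1L, sum(y == 0L)),
      tpr = sum(pred & y == 1L) / max(1L, sum(y == 1L))
    )
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Evaluate a classifier on a labeled set
#'
#' @param handle a classifier.
#' @param x rasters or features.
#' @param y true labels.
#' @param threshold decision threshold on P(positive) (default 0.5).
#' @return an `EvalMetrics` list: confusion counts, `accuracy`,
#'   `sensitivity` (TPR), `specificity` (TNR), `auc`. On a single-class
#'   set the undefined rate is `NaN` with a warning.
#' @export
evaluate_classifier <- function(handle, x, y, threshold = 0.5) {
  scores <- predict_classifier(handle, x)
  eval_metrics(scores, y, threshold)
}

#' Compute classification metrics from scores
#' @param scores predicted positive-class scores.
#' @param y true labels.
#' @param threshold decision threshold.
#' @return an `EvalMetrics` list (see [evaluate_classifier()]).
#' @export
eval_metrics <- function(scores, y, threshold = 0.5) {
  yi <- as_label_int(y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & yi == 1L); tn <- sum(pred == 0L & yi == 0L)
  fp <- sum(pred == 1L & yi == 0L); fn <- sum(pred == 0L & yi == 1L)
  if (tp + fn == 0L || tn + fp == 0L) {
    warning("single-class test set: sensitivity or specificity undefined")
  }
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = (tp + tn) / (tp + tn + fp + fn),
      sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NaN,
      specificity = if (tn + fp > 0L) tn / (tn + fp) else NaN,
      auc = auc_score(scores, yi)
    ),
    class = "EvalMetrics"
  )
}

#' Stratified k-fold cross-validation of a classifier spec
#'
#' @param spec a [classifier_spec()].
#' @param x list of rasters.
#' @param y labels.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `folds` (assignment vector), `metrics` (one
#'   `EvalMetrics` per fold), `accuracy` (per-fold vector), and
#'   `mean_accuracy`.
#' @export
cross_validate <- function(spec, x, y, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  folds <- stratified_kfold(as_label_vector(y), k = k, seed = seed)
  metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    handle <- build_classifier(spec)
    train_classifier(handle, x[tr], y[tr])
    metrics[[f]] <- evaluate_classifier(handle, x[!tr], y[!tr])
  }
  acc <- vapply(metrics, function(m) m$accuracy, numeric(1))
  list(folds = folds, metrics = metrics, accuracy = acc,
       mean_accuracy = mean(acc))
}

as_label_vector <- function(y) {
  if (is.character(y) || is.factor(y)) as.character(y) else as.integer(y)
}

#' An oracle classifier backed by ground truth
#'
#' Predicts 1 for blocks whose footprint lies inside a true representative
#' region and 0 otherwise; used to test the slide pipeline independently
#' of any trained model. The oracle consumes blocks, not pixels.
#'
#' @param truth a [ground_truth()].
#' @param magnification the magnification the oracle claims to operate at.
#' @param min_overlap coverage fraction above which a block counts as
#'   representative (default 0.5).
#' @return an object of class `oracle_classifier`.
#' @export
oracle_classifier <- function(truth, magnification = 10, min_overlap = 0.5) {
  handle <- new.env(parent = emptyenv())
  handle$truth <- truth
  handle$magnification <- magnification
  handle$min_overlap <- min_overlap
  handle$n_predict_calls <- 0L
  handle$aset <- annotation_set(
    truth$representative_regions, "oracle", truth$slide_id,
    truth$base_magnification
  )
  class(handle) <- "oracle_classifier"
  handle
}
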