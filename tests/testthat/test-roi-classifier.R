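# Deeper training runs live in test-acceptance.R; these tests cover the
# structural contracts and the metric definitions.

test_that("classifier specs validate backbone/head/mode compatibility", {
  expect_error(classifier_spec(backbone = "no_such_net"), "unknown backbone")
  expect_error(classifier_spec(backbone = "tiny_cnn", finetune_mode = "MHSA_ONLY"),
               "transformer backbone")
  expect_error(classifier_spec(dropout = 1), "dropout")
  expect_error(classifier_spec(loss = "hinge"), "unknown loss")
  # head input width must match the backbone feature width
  spec <- classifier_spec(backbone = "DenseNet121",
                          head = head_architecture(c(128L)))
  expect_error(build_classifier(spec), "does not match backbone output width")
  expect_true(all(c("VGG16", "ResNet152", "Xception", "ViT-B/32") %in%
                  list_backbones()))
})

test_that("trainable-parameter bookkeeping follows the finetune mode", {
  head <- head_architecture(c(128L, 64L, 32L))
  h <- build_classifier(classifier_spec(backbone = "tiny_cnn", head = head))
  expect_equal(
    trainable_parameter_count(h),
    1001L * 128L + 129L * 64L + 65L * 32L + 33L * 2L
  )
  hv <- build_classifier(classifier_spec(backbone = "tiny_vit", head = head,
                                         finetune_mode = "MHSA_ONLY"))
  cfg <- hv$backbone$params$cfg
  expect_equal(trainable_parameter_count(hv), 4L * cfg$d^2 * cfg$layers)
  hb <- build_classifier(classifier_spec(backbone = "tiny_vit", head = head,
                                         finetune_mode = "MHSA_PLUS_HEAD"))
  expect_equal(
    trainable_parameter_count(hb),
    trainable_parameter_count(h) + trainable_parameter_count(hv)
  )
})

test_that("HEAD_ONLY training never changes backbone outputs (frozen contract)", {
  d <- make_band_tiles(20L, seed = 4L)
  probe <- d$imgs[1:3]
  h <- build_classifier(classifier_spec(
    backbone = "tiny_cnn", head = head_architecture(c(32L)), epochs = 3L
  ))
  before <- backbone_features(h, probe)
  train_classifier(h, d$imgs, d$labels)
  expect_identical(backbone_features(h, probe), before)
})

test_that("MHSA fine-tuning changes attention outputs but decreases loss", {
  d <- make_band_tiles(20L, seed = 5L)
  h <- build_classifier(classifier_spec(
    backbone = "tiny_vit", head = head_architecture(c(32L)),
    finetune_mode = "MHSA_PLUS_HEAD", epochs = 4L, batch_size = 10L, seed = 1L
  ))
  before <- backbone_features(h, d$imgs[1:2])
  log <- train_classifier(h, d$imgs, d$labels)
  expect_false(identical(backbone_features(h, d$imgs[1:2]), before))
  expect_lt(log$loss[nrow(log)], log$loss[1L])
})

test_that("MHSA backprop matches finite-difference gradients", {
  vp <- slideroi:::tiny_vit_init(3L)
  img <- matrix(stats::runif(64 * 64, 0, 255), 64, 64)
  dfeat <- seq_len(1000L) / 1000
  out <- slideroi:::vit_forward_one(vp, img, keep_cache = TRUE)
  ana <- slideroi:::vit_mhsa_grad_flatten(
    slideroi:::vit_backward_one(vp, out$caches, dfeat)
  )
  loss_fn <- function(theta) {
    f <- slideroi:::vit_forward_one(
      slideroi:::vit_mhsa_unflatten(vp, theta), img
    )$feat
    sum(f * dfeat)
  }
  theta <- slideroi:::vit_mhsa_flatten(vp)
  set.seed(1)
  for (i in sample(length(theta), 10L)) {
    eps <- 1e-5
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    num <- (loss_fn(tp) - loss_fn(tm)) / (2 * eps)
    expect_lt(abs(num - ana[i]), 1e-6 + 1e-4 * abs(num))
  }
})

test_that("training is deterministic under a fixed seed", {
  d <- make_band_tiles(15L, seed = 6L)
  run <- function() {
    h <- build_classifier(classifier_spec(
      backbone = "tiny_cnn", head = head_architecture(c(32L)),
      epochs = 3L, seed = 42L
    ))
    train_classifier(h, d$imgs, d$labels)
    predict_classifier(h, d$imgs)
  }
  expect_identical(run(), run())
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  d <- make_band_tiles(10L, seed = 7L)
  d$imgs[[3L]][5, 5] <- NaN    # poisoned pixel propagates to the loss
  h <- build_classifier(classifier_spec(
    backbone = "tiny_cnn", head = head_architecture(c(32L)), epochs = 2L
  ))
  expect_error(train_classifier(h, d$imgs, d$labels), "diverged")
})

test_that("metrics satisfy their confusion-matrix identities", {
  scores <- c(0.9, 0.8, 0.4, 0.1)
  y <- c(1, 1, 0, 0)
  m <- eval_metrics(scores, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)    # all 4 pos-neg pairs correctly ordered
  # chance-level constant predictor: AUC 0.5 under the tie convention
  m2 <- eval_metrics(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$auc, 0.5)
  # identities hold on random confusion matrices
  set.seed(3)
  for (i in 1:20) {
    s <- stats::runif(40)
    yy <- sample(0:1, 40, TRUE)
    mm <- eval_metrics(s, yy)
    tp <- mm$tp; tn <- mm$tn; fp <- mm$fp; fn <- mm$fn
    expect_equal(mm$accuracy, (tp + tn) / 40)
    expect_equal(mm$sensitivity, tp / (tp + fn))
    expect_equal(mm$specificity, tn / (tn + fp))
  }
  expect_warning(eval_metrics(c(0.4, 0.6), c(1, 1)), "single-class")
})

test_that("AUC equals brute-force pairwise concordance (ties get half credit)", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    y <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(stats::runif(n), 1)  # coarse scores force ties
    pos <- s[y == 1]; neg <- s[y == 0]
    oracle <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
    expect_equal(auc_score(s, y), oracle)
  }
  expect_true(is.nan(auc_score(c(0.1, 0.9), c(1, 1))))
})

test_that("roc_curve starts at (0,0) and ends at (1,1)", {
  s <- stats::runif(30); y <- sample(0:1, 30, TRUE)
  y[1:2] <- c(0, 1)
  rc <- roc_curve(s, y)
  expect_equal(unlist(rc[1L, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("cross-validation is stratified, complete, and seed-stable", {
  d <- make_band_tiles(25L, seed = 9L)   # 50 tiles
  spec <- classifier_spec(backbone = "tiny_cnn",
                          head = head_architecture(c(32L)),
                          epochs = 50L, seed = 2L)
  cv <- cross_validate(spec, d$imgs, d$labels, k = 5L, seed = 3L)
  expect_length(cv$metrics, 5L)
  expect_equal(length(cv$accuracy), 5L)
  expect_equal(cv$mean_accuracy, mean(cv$accuracy))
  expect_gte(cv$mean_accuracy, 0.95)     # separable by construction
  cv2 <- cross_validate(spec, d$imgs, d$labels, k = 5L, seed = 3L)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$accuracy, cv2$accuracy)
})
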