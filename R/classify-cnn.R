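# Desk-scale convolutional classifier, implemented directly in R: one 3x3
# convolution (ReLU) feeding block average pooling and a softmax layer,
# trained with Adam on categorical cross-entropy.  It is deliberately tiny —
# a CPU-trainable harness for exercising the preprocessing/augmentation/
# evaluation pipeline end to end, not a competitor to ImageNet-pretrained
# backbones.

#' Training configuration for the desk-scale CNN
#'
#' Desk-scale defaults: 96 x 96 inputs and an Adam step of 1e-2, sized so a
#' few hundred images train a randomly initialised tiny network on one CPU
#' in minutes.  A clinical-scale recipe for large pretrained backbones
#' (30 epochs, batch 30, learning rate 1e-4, 543 x 475 inputs) can be
#' requested explicitly.
#'
#' @param epochs,batch_size Training schedule.
#' @param learning_rate Adam step size.
#' @param target_size `c(height, width)` images are resized to.
#' @param n_filters Convolution filters in the single 3x3 layer.
#' @param pool Average-pooling block size.
#' @param seed Integer seed fixing initialisation and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 30L, learning_rate = 1e-2,
                         target_size = c(96L, 96L), n_filters = 8L,
                         pool = 8L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            length(target_size) == 2L, all(target_size >= 8),
            n_filters >= 1, pool >= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, target_size = as.integer(target_size),
         n_filters = as.integer(n_filters), pool = as.integer(pool),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

im2col3 <- function(image) {
  d <- dim(image)
  oh <- d[1] - 2L; ow <- d[2] - 2L
  x <- matrix(0, oh * ow, 27L)
  j <- 0L
  for (c in 1:3) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        j <- j + 1L
        x[, j] <- as.vector(image[(1L + dy):(oh + dy), (1L + dx):(ow + dx), c])
      }
    }
  }
  x
}

pool_mats <- function(oh, ow, pool) {
  nbh <- oh %/% pool; nbw <- ow %/% pool
  l <- matrix(0, nbh, oh)
  for (i in seq_len(nbh)) l[i, ((i - 1L) * pool + 1L):(i * pool)] <- 1 / pool
  r <- matrix(0, ow, nbw)
  for (i in seq_len(nbw)) r[((i - 1L) * pool + 1L):(i * pool), i] <- 1 / pool
  list(l = l, r = r, nbh = nbh, nbw = nbw)
}

cnn_forward <- function(x, model, want_cache = FALSE) {
  z <- sweep(x %*% model$w_conv, 2L, model$b_conv, "+")
  a <- pmax(z, 0)
  pm <- model$pm
  feat <- numeric(pm$nbh * pm$nbw * ncol(a))
  for (f in seq_len(ncol(a))) {
    af <- matrix(a[, f], model$oh, model$ow)
    feat[((f - 1L) * pm$nbh * pm$nbw + 1L):(f * pm$nbh * pm$nbw)] <-
      as.vector(pm$l %*% af %*% pm$r)
  }
  logits <- drop(feat %*% model$w_dense) + model$b_dense
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  if (!want_cache) return(p)
  list(p = p, feat = feat, z = z)
}

cnn_backward <- function(x, cache, y_onehot, model) {
  dlogits <- cache$p - y_onehot
  dw_dense <- outer(cache$feat, dlogits)
  db_dense <- dlogits
  dfeat <- drop(model$w_dense %*% dlogits)
  pm <- model$pm
  da <- matrix(0, model$oh * model$ow, ncol(model$w_conv))
  for (f in seq_len(ncol(da))) {
    dp <- matrix(dfeat[((f - 1L) * pm$nbh * pm$nbw + 1L):(f * pm$nbh * pm$nbw)],
                 pm$nbh, pm$nbw)
    da[, f] <- as.vector(t(pm$l) %*% dp %*% t(pm$r))
  }
  dz <- da * (cache$z > 0)
  list(w_conv = crossprod(x, dz), b_conv = colSums(dz),
       w_dense = dw_dense, b_dense = db_dense)
}

prep_images <- function(images, target_size) {
  lapply(images, function(img) {
    d <- dim(img)
    if (d[1] != target_size[1] || d[2] != target_size[2]) {
      img <- resize_image(img, target_size[1], target_size[2])
    }
    img / 255 - 0.5
  })
}

#' Train the desk-scale CNN
#'
#' Expects a sample table with an `image` list-column of RGB arrays (0..255)
#' and a `label` column with at least two classes present.  Images are
#' resized to `config$target_size` and scaled to `[0, 1]`.  Training aborts
#' on divergence (non-finite loss); the per-epoch mean loss is kept in the
#' returned model's `history`.
#'
#' @param train A data frame with `image` (list of arrays) and `label`.
#' @param config A [train_config()].
#' @return A `uceis_cnn` model object with a [predict][predict.uceis_cnn]
#'   method.
#' @export
train_small_cnn <- function(train, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (!all(c("image", "label") %in% names(train))) {
    abort("`train` needs `image` and `label` columns.")
  }
  labels <- as.character(train$label)
  classes <- if (is.factor(train$label)) levels(train$label) else sort(unique(labels))
  classes <- classes[classes %in% labels]
  if (length(classes) < 2L) {
    abort("Training input must contain at least 2 classes.")
  }
  y <- match(labels, classes)
  set.seed(config$seed)

  imgs <- prep_images(train$image, config$target_size)
  oh <- config$target_size[1] - 2L
  ow <- config$target_size[2] - 2L
  nf <- config$n_filters
  pm <- pool_mats(oh, ow, config$pool)
  n_feat <- pm$nbh * pm$nbw * nf

  # random-threshold init: ReLU units with spread biases act as soft pixel
  # thresholds from the first step, so block averages immediately expose
  # "fraction of pixels beyond a colour threshold" features; the softmax
  # layer starts at zero (uninformative) and learns on top of them.
  model <- list(
    w_conv = matrix(rnorm(27 * nf, 0, sqrt(2 / 27)), 27, nf),
    b_conv = runif(nf, -0.3, 0.3),
    w_dense = matrix(0, n_feat, length(classes)),
    b_dense = numeric(length(classes)),
    oh = oh, ow = ow, pm = pm, classes = classes, config = config
  )

  adam <- list(m = lapply(model[1:4], function(p) p * 0),
               v = lapply(model[1:4], function(p) p * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- numeric(config$epochs)
  n <- length(imgs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- NULL
      for (i in batch) {
        x <- im2col3(imgs[[i]])
        cache <- cnn_forward(x, model, want_cache = TRUE)
        y1 <- replace(numeric(length(classes)), y[i], 1)
        losses <- c(losses, -log(max(cache$p[y[i]], 1e-12)))
        g <- cnn_backward(x, cache, y1, model)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(batch))
      adam$t <- adam$t + 1
      for (nm in names(grads)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
        model[[nm]] <- model[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    history[epoch] <- mean(losses)
    if (!is.finite(history[epoch])) {
      abort(sprintf("Training diverged at epoch %d (non-finite loss).", epoch))
    }
  }
  model$history <- history
  class(model) <- "uceis_cnn"
  model
}

#' @export
print.uceis_cnn <- function(x, ...) {
  cat(sprintf(
    "Desk-scale CNN: %d 3x3 filters, %d features, classes [%s]\n  final epoch loss %.4f over %d epochs\n",
    ncol(x$w_conv), nrow(x$w_dense), paste(x$classes, collapse = ", "),
    tail(x$history, 1), length(x$history)
  ))
  invisible(x)
}

#' Predict severity classes with a trained desk-scale CNN
#'
#' @param object A `uceis_cnn` model.
#' @param newdata A data frame with an `image` list-column.
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix.
#' @param ... Unused.
#' @return A factor of predicted labels, or a probability matrix.
#' @export
predict.uceis_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  imgs <- prep_images(newdata$image, object$config$target_size)
  probs <- t(vapply(imgs, function(img) {
    cnn_forward(im2col3(img), object)
  }, numeric(length(object$classes))))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' Evaluate a trained model on a labelled test set
#'
#' @param model A `uceis_cnn` (or any object with a compatible `predict`
#'   method returning class labels).
#' @param test A data frame with `image` and `label` columns.
#' @param classes Class order for the report.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, test, classes = NULL) {
  if (!nrow(test)) abort("Empty test set.")
  pred <- predict(model, test)
  classes <- classes %||% (if (is.factor(test$label)) levels(test$label)
                           else sort(unique(as.character(test$label))))
  eval_report(test$label, pred, classes = classes)
}
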