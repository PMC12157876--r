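#' Specification of the convolutional network
#'
#' Architecture and training hyper-parameters for the two network variants:
#' a two-way softmax classifier (64 px input, 128-unit hidden layer by
#' convention) and a single-output regressor (128 px input, 512-unit hidden
#' layer). Three 3x3 ReLU convolution blocks with non-decreasing filter
#' counts (default 32, 64, 128) are each followed by 2x2 max-pooling, so the
#' input side must be divisible by `2 ^ length(conv_filters)`. Training uses
#' Adam (initial learning rate 0.001), dropout 0.5 on the fully connected
#' hidden layer, L2 weight penalty 1e-4, and a scheduler that multiplies the
#' learning rate by `lr_factor` whenever the monitored loss fails to improve
#' for `lr_patience` epochs.
#'
#' @param input_side Input image side in pixels.
#' @param conv_filters Non-decreasing integer vector of per-block filter
#'   counts.
#' @param fc_units Width of the fully connected hidden layer.
#' @param dropout Dropout rate in `[0, 1)` on the hidden layer.
#' @param l2 L2 penalty coefficient on weight matrices (biases exempt).
#' @param lr Initial Adam learning rate.
#' @param lr_factor Multiplicative learning rate decay on plateau.
#' @param lr_patience Epochs without improvement before a decay step.
#' @param lr_min_delta Minimum loss improvement that resets the plateau
#'   counter.
#' @param early_stop_patience Epochs without improvement before training
#'   halts.
#' @param epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @return A list of class `"cnn_spec"`.
#' @export
cnn_spec <- function(input_side = 64, conv_filters = c(32, 64, 128),
                     fc_units = 128, dropout = 0.5, l2 = 1e-4,
                     lr = 1e-3, lr_factor = 0.1, lr_patience = 5,
                     lr_min_delta = 1e-4, early_stop_patience = 15,
                     epochs = 100, batch_size = 32) {
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) < 1L || any(diff(conv_filters) < 0))
    stop("conv_filters must be a non-decreasing sequence")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (l2 < 0) stop("l2 must be non-negative")
  pool_div <- 2^length(conv_filters)
  if (input_side %% pool_div != 0)
    stop("input_side ", input_side, " is incompatible with ",
         length(conv_filters), " pooling layers (must be divisible by ",
         pool_div, ")")
  structure(list(input_side = as.integer(input_side),
                 conv_filters = conv_filters, fc_units = as.integer(fc_units),
                 dropout = dropout, l2 = l2, lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 lr_min_delta = lr_min_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "cnn_spec")
}

#' Default spec for a task
#' @param task `"classify"` or `"regress"`.
#' @param input_side Image side; defaults to 64 for classification and 128
#'   for regression.
#' @param ... Overrides passed to [cnn_spec()].
#' @export
default_cnn_spec <- function(task = c("classify", "regress"),
                             input_side = NULL, ...) {
  task <- match.arg(task)
  if (is.null(input_side)) input_side <- if (task == "classify") 64 else 128
  fc <- if (task == "classify") 128 else 512
  cnn_spec(input_side = input_side, fc_units = fc, ...)
}

.cnn_geometry <- function(spec) {
  s <- spec$input_side
  sides <- integer(0)
  for (l in seq_along(spec$conv_filters)) {
    sides[l] <- s
    s <- s %/% 2L
  }
  list(conv = spec$conv_filters, sides = sides, flat_side = s,
       flat_dim = s * s * spec$conv_filters[length(spec$conv_filters)])
}

.cnn_init_pars <- function(spec, task) {
  geom <- .cnn_geometry(spec)
  pars <- list()
  cin <- 3L
  for (l in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[l]
    fan_in <- 9L * cin
    pars[[paste0("Wc", l)]] <-
      matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f)
    pars[[paste0("bc", l)]] <- numeric(f)
    cin <- f
  }
  pars$Wf <- matrix(stats::rnorm(geom$flat_dim * spec$fc_units, 0,
                                 sqrt(2 / geom$flat_dim)),
                    geom$flat_dim, spec$fc_units)
  pars$bf <- numeric(spec$fc_units)
  n_out <- if (task == "classify") 2L else 1L
  pars$Wo <- matrix(stats::rnorm(spec$fc_units * n_out, 0,
                                 sqrt(1 / spec$fc_units)),
                    spec$fc_units, n_out)
  pars$bo <- numeric(n_out)
  pars
}

.cnn_architecture <- function(spec, task) {
  geom <- .cnn_geometry(spec)
  rows <- list()
  s <- spec$input_side
  cin <- 3L
  for (l in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[l]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("conv", l), type = "conv", units = f,
      output = sprintf("%dx%dx%d", s, s, f), params = (9L * cin + 1L) * f)
    s <- s %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("pool", l), type = "maxpool", units = f,
      output = sprintf("%dx%dx%d", s, s, f), params = 0L)
    cin <- f
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "fc1", type = "dense", units = spec$fc_units,
    output = as.character(spec$fc_units),
    params = (geom$flat_dim + 1L) * spec$fc_units)
  n_out <- if (task == "classify") 2L else 1L
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "output", type = if (task == "classify") "softmax" else "linear",
    units = n_out, output = as.character(n_out),
    params = (spec$fc_units + 1L) * n_out)
  do.call(rbind, rows)
}

# Accept (n, side, side, 3) arrays, lists of gaf_image, or a single image;
# return internal layout (side, side, 3, n).
.as_image_batch <- function(x, side = NULL) {
  if (is.list(x) && !is.array(x))
    x <- abind_images(x)
  if (inherits(x, "gaf_image")) {
    d <- dim(x)
    x <- array(unclass(x), c(1L, d))
    x <- aperm(x, c(2, 3, 1, 4))
    return(x)
  }
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("images must form an (n, side, side, 3) array")
  if (!is.null(side) && dim(x)[2] != side)
    stop("image side ", dim(x)[2], " does not match the model's expected ",
         side)
  aperm(x, c(2, 3, 1, 4))
}

#' Stack a list of GAF images into an (n, side, side, 3) array
#' @param images List of `gaf_image` objects sharing one side.
#' @export
abind_images <- function(images) {
  sides <- vapply(images, function(im) dim(im)[1], integer(1))
  if (length(unique(sides)) != 1L) stop("images must share one side")
  side <- sides[1]
  out <- array(NA_real_, c(length(images), side, side, 3L))
  for (i in seq_along(images)) out[i, , , ] <- unclass(images[[i]])
  out
}

#' Build an untrained network
#'
#' Initializes weights (He initialization, seeded) without training, which
#' is useful for architecture inspection and for testing the forward pass
#' contracts (softmax rows summing to one, shape checks).
#'
#' @param spec A [cnn_spec()].
#' @param task `"classify"` or `"regress"`.
#' @param seed Seed for weight initialization.
#' @return An object of class `"gait_cnn"` with `trained = FALSE`.
#' @export
build_gait_cnn <- function(spec = cnn_spec(),
                           task = c("classify", "regress"), seed = 1) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "cnn_spec"))
  pars <- with_rng(seed, .cnn_init_pars(spec, task))
  structure(list(spec = spec, task = task, pars = pars,
                 architecture = .cnn_architecture(spec, task),
                 classes = if (task == "classify") c("control", "pd") else NULL,
                 trained = FALSE, log = NULL, seed = seed),
            class = "gait_cnn")
}

.encode_labels <- function(y) {
  if (is.factor(y)) {
    if (!all(levels(y) %in% c("control", "pd")))
      y <- factor(as.character(y), levels = sort(unique(as.character(y))))
    lv <- levels(y)
    if (setequal(lv, c("control", "pd"))) lv <- c("control", "pd")
    as.integer(factor(as.character(y), levels = lv)) - 1L
  } else if (is.character(y)) {
    if (!all(y %in% c("control", "pd")))
      stop("character labels must be 'control' or 'pd'")
    as.integer(y == "pd")
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L)))
      stop("numeric class labels must be 0 (control) or 1 (pd)")
    y
  }
}

#' Fit a convolutional network on GAF images
#'
#' The modelling entry point: trains the classifier (two-way softmax,
#' cross-entropy loss; class 1 = `"pd"` is the positive class) or the
#' regressor (single linear output, mean squared error loss) on a batch of
#' GAF images. Training is seeded and single-threaded, hence reproducible:
#' identical data, spec and seed give an identical training log and weights.
#'
#' The learning rate starts at `spec$lr` and is multiplied by
#' `spec$lr_factor` whenever the monitored loss (validation loss when
#' `validation_fraction > 0`, else training loss) fails to improve for
#' `spec$lr_patience` epochs; training stops early after
#' `spec$early_stop_patience` epochs without improvement.
#'
#' @param x Images: an `(n, side, side, 3)` array or a list of
#'   [window_to_image()] results.
#' @param y Targets: class labels (0/1, `"control"`/`"pd"`, or a factor) for
#'   classification; a numeric score for regression.
#' @param task `"classify"` or `"regress"`.
#' @param spec A [cnn_spec()]; defaults to [default_cnn_spec()] for the task
#'   at the side of `x`.
#' @param validation_fraction Fraction of samples held out (stratified for
#'   classification) to monitor the scheduler; 0 monitors training loss.
#' @param seed Seed controlling initialization, the validation split,
#'   shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"gait_cnn"` with the fitted weights, the
#'   architecture echo and a per-epoch `log` (losses, accuracy, learning
#'   rate).
#' @seealso [predict.gait_cnn()], [build_gait_cnn()]
#' @export
gait_cnn <- function(x, y, task = c("classify", "regress"), spec = NULL,
                     validation_fraction = 0.1, seed = 1, verbose = FALSE) {
  task <- match.arg(task)
  X <- .as_image_batch(x)
  side <- dim(X)[1]
  if (is.null(spec)) spec <- default_cnn_spec(task, input_side = side)
  if (side != spec$input_side)
    stop("image side ", side, " does not match spec input_side ",
         spec$input_side)
  n <- dim(X)[3]
  if (n == 0L) stop("empty training set")
  if (task == "classify") {
    yv <- .encode_labels(y)
    if (length(unique(yv)) < 2L)
      stop("classifier training requires both classes present")
  } else {
    yv <- as.numeric(y)
    if (anyNA(yv)) stop("regression targets contain NA")
  }
  if (length(yv) != n) stop("images and targets are not aligned")

  model <- build_gait_cnn(spec, task, seed = seed)
  pars <- model$pars
  if (task == "regress") pars$bo[] <- mean(yv) # start at the target mean
  geom <- .cnn_geometry(spec)

  with_rng(seed + 1L, {
    # validation split (stratified for classification)
    if (validation_fraction > 0 && n >= 5L) {
      if (task == "classify") {
        val_idx <- unlist(lapply(split(seq_len(n), yv), function(ii)
          sample(ii, max(1L, round(length(ii) * validation_fraction)))))
      } else {
        val_idx <- sample(n, max(1L, round(n * validation_fraction)))
      }
      val_idx <- sort(val_idx)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    if (task == "classify" && length(unique(yv[tr_idx])) < 2L)
      stop("validation split left a single-class training set")

    Xtr <- X[, , tr_idx, , drop = FALSE]
    ytr <- yv[tr_idx]
    Xval <- if (length(val_idx)) X[, , val_idx, , drop = FALSE] else NULL
    yval <- yv[val_idx]
    ntr <- length(tr_idx)

    adam <- adam_init(pars)
    lr <- spec$lr
    t_step <- 0L
    best <- Inf
    plateau <- 0L
    stall <- 0L
    log_rows <- list()
    weight_names <- grep("^W", names(pars), value = TRUE)

    eval_loss <- function(Xe, ye) {
      # loss without dropout, in prediction mode, batched
      ne <- dim(Xe)[3]
      tot <- 0
      correct <- 0
      bs <- max(spec$batch_size, 16L)
      for (s in seq(1L, ne, by = bs)) {
        ii <- s:min(s + bs - 1L, ne)
        out <- cnn_forward(pars, geom, Xe[, , ii, , drop = FALSE],
                           train = FALSE)$out
        if (task == "classify") {
          pr <- softmax_rows(out)
          tot <- tot + sum(-log(pmax(pr[cbind(seq_along(ii), ye[ii] + 1L)],
                                     1e-12)))
          correct <- correct + sum(max.col(pr) - 1L == ye[ii])
        } else {
          tot <- tot + sum((out[, 1] - ye[ii])^2)
        }
      }
      list(loss = tot / ne, acc = correct / ne)
    }

    for (epoch in seq_len(spec$epochs)) {
      ord <- sample(ntr)
      ep_loss <- 0
      for (s in seq(1L, ntr, by = spec$batch_size)) {
        ii <- ord[s:min(s + spec$batch_size - 1L, ntr)]
        nb <- length(ii)
        fw <- cnn_forward(pars, geom, Xtr[, , ii, , drop = FALSE],
                          train = TRUE, dropout = spec$dropout)
        if (task == "classify") {
          pr <- softmax_rows(fw$out)
          loss <- mean(-log(pmax(pr[cbind(seq_len(nb), ytr[ii] + 1L)],
                                 1e-12)))
          dOut <- pr
          dOut[cbind(seq_len(nb), ytr[ii] + 1L)] <-
            dOut[cbind(seq_len(nb), ytr[ii] + 1L)] - 1
          dOut <- dOut / nb
        } else {
          resid <- fw$out[, 1] - ytr[ii]
          loss <- mean(resid^2)
          dOut <- matrix(2 * resid / nb, ncol = 1L)
        }
        grads <- cnn_backward(pars, geom, dOut, fw$caches, fw$feat_dim)
        if (spec$l2 > 0)
          for (wn in weight_names)
            grads[[wn]] <- grads[[wn]] + 2 * spec$l2 * pars[[wn]]
        t_step <- t_step + 1L
        upd <- adam_step(pars, grads, adam, lr, t_step)
        pars <- upd$pars
        adam <- upd$state
        ep_loss <- ep_loss + loss * nb
      }
      ep_loss <- ep_loss / ntr
      if (length(val_idx)) {
        ev <- eval_loss(Xval, yval)
        monitored <- ev$loss
      } else {
        ev <- list(loss = NA_real_, acc = NA_real_)
        monitored <- ep_loss
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss,
        val_loss = ev$loss, val_acc = if (task == "classify") ev$acc else NA)
      if (verbose)
        message(sprintf("epoch %3d lr %.1e train %.4f val %.4f",
                        epoch, lr, ep_loss, ev$loss))
      if (monitored < best - spec$lr_min_delta) {
        best <- monitored
        plateau <- 0L
        stall <- 0L
      } else {
        plateau <- plateau + 1L
        stall <- stall + 1L
        if (plateau >= spec$lr_patience) {
          lr <- lr * spec$lr_factor
          plateau <- 0L
        }
      }
      if (stall >= spec$early_stop_patience) break
    }
    model$pars <- pars
    model$trained <- TRUE
    model$log <- do.call(rbind, log_rows)
    model$n_train <- ntr
    model$n_val <- length(val_idx)
  })
  model
}

#' Predict from a fitted network
#'
#' Inference is deterministic (dropout disabled): the same batch yields the
#' same output, and permuting the batch permutes the output identically.
#'
#' @param object A `gait_cnn`.
#' @param x Images as in [gait_cnn()]; the side must match the spec.
#' @param type For the classifier: `"prob"` (default, an `(n, 2)` matrix
#'   with columns `control`/`pd` summing to one) or `"class"` (a factor,
#'   argmax decision). Ignored for the regressor, which returns a numeric
#'   vector.
#' @param batch_size Prediction chunk size.
#' @param ... Unused.
#' @export
predict.gait_cnn <- function(object, x, type = c("prob", "class"),
                             batch_size = 64L, ...) {
  type <- match.arg(type)
  X <- .as_image_batch(x, side = object$spec$input_side)
  n <- dim(X)[3]
  geom <- .cnn_geometry(object$spec)
  outs <- vector("list", ceiling(n / batch_size))
  j <- 0L
  for (s in seq(1L, n, by = batch_size)) {
    ii <- s:min(s + batch_size - 1L, n)
    j <- j + 1L
    outs[[j]] <- cnn_forward(object$pars, geom, X[, , ii, , drop = FALSE],
                             train = FALSE)$out
  }
  out <- do.call(rbind, outs)
  if (object$task == "regress") return(as.numeric(out[, 1]))
  pr <- softmax_rows(out)
  colnames(pr) <- object$classes
  if (type == "prob") pr
  else factor(object$classes[max.col(pr)], levels = object$classes)
}

#' @export
print.gait_cnn <- function(x, ...) {
  cat(sprintf("<gait_cnn> %s, input %dx%dx3, conv filters (%s), fc %d%s\n",
              x$task, x$spec$input_side, x$spec$input_side,
              paste(x$spec$conv_filters, collapse = ", "), x$spec$fc_units,
              if (x$trained) sprintf(", trained %d epochs", nrow(x$log))
              else " (untrained)"))
  invisible(x)
}

#' @export
summary.gait_cnn <- function(object, ...) {
  cat("Architecture:\n")
  print(object$architecture, row.names = FALSE)
  cat(sprintf("Total parameters: %d\n", sum(object$architecture$params)))
  if (object$trained) {
    tail_log <- utils::tail(object$log, 1)
    cat(sprintf("Trained %d epochs (final lr %.2e, train loss %.4f)\n",
                nrow(object$log), tail_log$lr, tail_log$train_loss))
  }
  invisible(object)
}

#' Plot training curves
#' @param x A trained `gait_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gait_cnn <- function(x, ...) {
  if (!x$trained || is.null(x$log)) stop("model is untrained")
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
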