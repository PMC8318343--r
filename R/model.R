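#' Training configuration for the regression CNN
#'
#' Defaults follow the published recipe: RMSprop, mini-batch 16, up to 60
#' epochs, initial learning rate 1e-4 dropped by a factor of 0.09 every 10
#' epochs (piecewise schedule), validation every 50 iterations with infinite
#' patience, and reshuffling every epoch. `sq_grad_decay` and `epsilon` are
#' the RMSprop accumulator constants (toolbox defaults).
#'
#' @param solver Only `"rmsprop"` is implemented.
#' @param mini_batch Mini-batch size.
#' @param max_epochs Number of epochs.
#' @param lr0 Initial learning rate.
#' @param lr_drop_factor Multiplicative drop applied each drop period.
#' @param lr_drop_period_epochs Epochs between drops.
#' @param validation_frequency_iters Iterations between validation passes.
#' @param validation_patience `Inf` (no early stopping) or an integer number
#'   of validations without improvement tolerated before stopping.
#' @param shuffle Only `"every_epoch"` is implemented.
#' @param seed Integer seed for initial shuffling and batching.
#' @param backbone `"small"` or `"resnet_class"`.
#' @param sq_grad_decay,epsilon RMSprop accumulator decay and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(solver = "rmsprop", mini_batch = 16L, max_epochs = 60L,
                         lr0 = 1e-4, lr_drop_factor = 0.09,
                         lr_drop_period_epochs = 10L,
                         validation_frequency_iters = 50L,
                         validation_patience = Inf,
                         shuffle = "every_epoch", seed = 1L,
                         backbone = c("small", "resnet_class"),
                         sq_grad_decay = 0.9, epsilon = 1e-8) {
  backbone <- match.arg(backbone)
  stopifnot(solver == "rmsprop", shuffle == "every_epoch",
            mini_batch >= 1, lr0 > 0, lr_drop_factor > 0, lr_drop_factor <= 1,
            lr_drop_period_epochs >= 1, validation_frequency_iters >= 1)
  structure(list(
    solver = solver, mini_batch = as.integer(mini_batch),
    max_epochs = as.integer(max_epochs), lr0 = lr0,
    lr_drop_factor = lr_drop_factor,
    lr_drop_period_epochs = as.integer(lr_drop_period_epochs),
    validation_frequency_iters = as.integer(validation_frequency_iters),
    validation_patience = validation_patience, shuffle = shuffle,
    seed = as.integer(seed), backbone = backbone,
    sq_grad_decay = sq_grad_decay, epsilon = epsilon
  ), class = "train_config")
}

#' Piecewise learning-rate schedule
#'
#' `lr = lr0 * lr_drop_factor^floor((epoch - 1) / lr_drop_period_epochs)`:
#' the rate starts at `lr0` and is multiplied by the drop factor after every
#' drop period.
#'
#' @param epoch 1-based epoch number.
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @export
#' @examples
#' lr_at_epoch(1, train_config())  # 1e-4
#' lr_at_epoch(11, train_config()) # 9e-6
lr_at_epoch <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 1))
  config$lr0 * config$lr_drop_factor^floor((epoch - 1) / config$lr_drop_period_epochs)
}

#' Build a regression CNN for tip localization
#'
#' Both backbones end in a single fully connected layer with three outputs —
#' the continuous `(col, row, z)` tip coordinate — trained under a
#' mean-squared-error regression loss. `"small"` is a compact
#' four-convolution network sized for CPU training; `"resnet_class"` is a
#' deeper residual network (three stages of residual blocks) with its
#' classification head replaced by the same three-output regression layer,
#' randomly initialized.
#'
#' @param backbone `"small"` or `"resnet_class"`.
#' @param input_side_px Input side length; must be divisible by 16 (the
#'   network downsampling factor).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pipette_cnn`.
#' @export
build_model <- function(backbone = c("small", "resnet_class"),
                        input_side_px = 64L, seed = 1L) {
  backbone <- match.arg(backbone)
  s <- as.integer(input_side_px)
  if (s %% 16L != 0L || s <= 0L) {
    stop("input_side_px must be a positive multiple of 16", call. = FALSE)
  }
  layers <- with_local_seed(seed, {
    if (backbone == "small") {
      # three pooling stages only: the final 8x8 grid (for 64 px input)
      # keeps enough spatial resolution for sub-pixel coordinate regression
      list(
        new_conv_layer(1L, 12L), list(type = "pool"),
        new_conv_layer(12L, 24L), list(type = "pool"),
        new_conv_layer(24L, 48L), list(type = "pool"),
        new_conv_layer(48L, 48L),
        list(type = "flatten"),
        new_fc_layer(48L * (s %/% 8L)^2, 3L)
      )
    } else {
      list(
        new_conv_layer(1L, 16L), list(type = "pool"),
        new_res_block(16L),
        new_conv_layer(16L, 32L), list(type = "pool"),
        new_res_block(32L),
        new_conv_layer(32L, 64L), list(type = "pool"),
        new_res_block(64L),
        list(type = "pool"),
        list(type = "flatten"),
        new_fc_layer(64L * (s %/% 16L)^2, 3L)
      )
    }
  })
  structure(list(
    layers = layers, backbone = backbone, input_side_px = s, seed = seed,
    target_center = NULL, target_scale = NULL, config = NULL, log = NULL
  ), class = "pipette_cnn")
}

#' @export
print.pipette_cnn <- function(x, ...) {
  np <- sum(vapply(net_params(x$layers), length, numeric(1)))
  cat(sprintf("<pipette_cnn> backbone=%s, input %dx%d, %d parameters, %s\n",
              x$backbone, x$input_side_px, x$input_side_px, np,
              if (is.null(x$target_center)) "untrained" else "trained"))
  invisible(x)
}

#' Raw network predictions for a model-ready batch
#'
#' @param model A [build_model()] network.
#' @param x Array `side x side x 1 x n` (a single matrix is accepted).
#' @param batch_size Forward-pass batch size.
#' @return An n x 3 matrix of `(col_px, row_px, z_um)` predictions in the
#'   preprocessed frame (de-standardized when the model is trained).
#' @export
predict_cnn <- function(model, x, batch_size = 64L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, 3)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- net_forward(model$layers, x[, , , b, drop = FALSE])
    out[b, ] <- t(fw$out)
  }
  if (!is.null(model$target_center)) {
    out <- sweep(sweep(out, 2, model$target_scale, "*"), 2,
                 model$target_center, "+")
  }
  colnames(out) <- c("col_px", "row_px", "z_um")
  out
}

validation_rmse <- function(model, val) {
  pred <- predict_cnn(model, val$x)
  sqrt(mean((pred - val$y)^2))
}

#' Train the regression CNN with RMSprop
#'
#' Optimizes the mean-squared-error objective over standardized 3-vector
#' targets (each target column is centred and scaled over the training set;
#' predictions are de-standardized on output, so mixed pixel/micron units
#' cannot let one axis dominate the loss). Batches are drawn after per-epoch
#' reshuffling; validation RMSE (in original target units) is computed every
#' `validation_frequency_iters` iterations and once before training.
#'
#' @param model An untrained [build_model()] network.
#' @param train,val Model-ready sets from [build_model_set()] (`val` may be
#'   `NULL`).
#' @param config A [train_config()].
#' @return The trained model, with the append-only training log as a tibble
#'   (`iteration`, `epoch`, `lr`, `loss`, `val_rmse`) in `$log`.
#' @export
train_cnn <- function(model, train, val = NULL, config = train_config()) {
  stopifnot(inherits(model, "pipette_cnn"), dim(train$x)[4] == nrow(train$y))
  n <- dim(train$x)[4]
  ctr <- colMeans(train$y)
  sc <- apply(train$y, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  model$target_center <- ctr
  model$target_scale <- sc
  ystd <- sweep(sweep(train$y, 2, ctr, "-"), 2, sc, "/")
  layers <- model$layers
  params <- net_params(layers)
  v <- lapply(params, function(p) p * 0)
  rho <- config$sq_grad_decay
  eps <- config$epsilon
  log_rows <- list()
  best_val <- Inf
  strikes <- 0L
  iter <- 0L
  if (!is.null(val)) {
    log_rows[[1]] <- tibble::tibble(iteration = 0L, epoch = 0L, lr = NA_real_,
                                    loss = NA_real_,
                                    val_rmse = validation_rmse(model, val))
  }
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at_epoch(epoch, config)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$mini_batch))
      for (b in batches) {
        iter <- iter + 1L
        xb <- train$x[, , , b, drop = FALSE]
        yb <- t(ystd[b, , drop = FALSE])
        fw <- net_forward(layers, xb, keep_cache = TRUE)
        err <- fw$out - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at iteration %d (epoch %d); batch ids: %s",
                       iter, epoch, paste(b, collapse = ",")), call. = FALSE)
        }
        dout <- 2 * err / length(err)
        grads <- net_grads_flat(layers, net_backward(layers, fw$caches, dout))
        for (k in names(params)) {
          g <- grads[[k]]
          v[[k]] <- rho * v[[k]] + (1 - rho) * g^2
          params[[k]] <- params[[k]] - lr * g / (sqrt(v[[k]]) + eps)
        }
        layers <- net_set_params(layers, params)
        val_rmse <- NA_real_
        if (!is.null(val) && iter %% config$validation_frequency_iters == 0L) {
          model$layers <- layers
          val_rmse <- validation_rmse(model, val)
          if (val_rmse < best_val) {
            best_val <- val_rmse
            strikes <- 0L
          } else {
            strikes <- strikes + 1L
          }
        }
        log_rows[[length(log_rows) + 1L]] <-
          tibble::tibble(iteration = iter, epoch = epoch, lr = lr, loss = loss,
                         val_rmse = val_rmse)
        if (is.finite(config$validation_patience) &&
            strikes > config$validation_patience) break
      }
      if (is.finite(config$validation_patience) &&
          strikes > config$validation_patience) break
    }
  })
  model$layers <- layers
  model$config <- config
  model$log <- dplyr::bind_rows(log_rows)
  model
}

#' Predict the tip position in microns from a raw camera image
#'
#' Applies the full preprocessing chain ([contrast_stretch()] +
#' [crop_resize()]), runs the network, inverts the crop/resize coordinate
#' transform back to the camera frame, and converts to stage-frame microns.
#'
#' @param model A trained [pipette_cnn][build_model()] whose input side
#'   matches `spec$out_side_px`.
#' @param image A raw intensity matrix matching `camera`'s frame, or a list
#'   of such matrices.
#' @param camera The [camera_model()] of the raw frame.
#' @param spec The [preproc_spec()] used at training time.
#' @return A tibble with one row per image: `x`, `y`, `z` in microns and the
#'   camera-frame `col_px`, `row_px`.
#' @export
predict_tip <- function(model, image, camera = camera_model(),
                        spec = preproc_spec()) {
  if (spec$out_side_px != model$input_side_px) {
    stop("preproc out_side_px does not match the model input size", call. = FALSE)
  }
  imgs <- if (is.list(image)) image else list(image)
  side <- spec$out_side_px
  x <- array(0, dim = c(side, side, 1L, length(imgs)))
  for (i in seq_along(imgs)) {
    x[, , 1L, i] <- crop_resize(contrast_stretch(imgs[[i]]), NULL, spec, camera)
  }
  pred <- predict_cnn(model, x)
  ann <- invert_crop_resize(
    tibble::tibble(col_px = pred[, 1], row_px = pred[, 2]), spec, camera
  )
  tibble::tibble(
    x = unname((ann$col_px - (camera$cols_px - 1) / 2) * camera$um_per_px_x),
    y = unname(((camera$rows_px - 1) / 2 - ann$row_px) * camera$um_per_px_y),
    z = unname(pred[, 3]),
    col_px = unname(ann$col_px), row_px = unname(ann$row_px)
  )
}

#' Save and restore a model checkpoint
#'
#' A single-file serialized checkpoint embedding the weights, the training
#' configuration, the target standardization constants, and the training log.
#'
#' @param model A `pipette_cnn`.
#' @param path Checkpoint file path.
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pipette_cnn"))
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fitted tip-localization CNN
#'
#' @param x A trained `pipette_cnn`.
#' @param ... Unused.
#' @return The training log as a tibble (`iteration`, `epoch`, `lr`, `loss`,
#'   `val_rmse`).
#' @method tidy pipette_cnn
#' @export
tidy.pipette_cnn <- function(x, ...) {
  if (is.null(x$log)) return(tibble::tibble())
  x$log
}

#' One-row summary of a fitted tip-localization CNN
#'
#' @param x A trained `pipette_cnn`.
#' @param ... Unused.
#' @return A tibble with backbone, parameter count, epochs and iterations
#'   run, final training loss, and initial/final validation RMSE.
#' @method glance pipette_cnn
#' @export
glance.pipette_cnn <- function(x, ...) {
  np <- sum(vapply(net_params(x$layers), length, numeric(1)))
  log <- x$log
  val <- if (!is.null(log)) log$val_rmse[!is.na(log$val_rmse)] else numeric()
  tibble::tibble(
    backbone = x$backbone,
    n_parameters = np,
    epochs = if (!is.null(log)) max(log$epoch) else NA_integer_,
    iterations = if (!is.null(log)) max(log$iteration) else NA_integer_,
    final_loss = if (!is.null(log)) utils::tail(stats::na.omit(log$loss), 1) else NA_real_,
    initial_val_rmse = if (length(val)) val[1] else NA_real_,
    final_val_rmse = if (length(val)) utils::tail(val, 1) else NA_real_
  )
}
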