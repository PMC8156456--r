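# Training and prediction with the published optimiser recipe: momentum
# stochastic gradient descent (momentum 0.9, weight decay 5e-4), initial
# learning rate 0.1 decayed by 10% (multiplied by 0.9) every 50 epochs,
# mini-batches of 16.  Desk-scale runs override the numbers that only make
# sense at GPU scale (epochs, batch size, model width), never the recipe's
# structure.

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param batch_size mini-batch size (published value 16).
#' @param lr initial learning rate (published value 0.1).
#' @param lr_decay multiplicative decay factor (0.9 = decay by 10%).
#' @param lr_step epochs between decays (published value 50).
#' @param momentum SGD momentum (published value 0.9).
#' @param weight_decay L2 coefficient (published value 5e-4).
#' @param seed global seed controlling init and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, lr = 0.1,
                         lr_decay = 0.9, lr_step = 50L, momentum = 0.9,
                         weight_decay = 5e-4, seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_decay > 0,
            lr_step >= 1, momentum >= 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule: `lr * decay^floor(epoch / step)`.  With the
#' defaults: 0.1 for epochs 0..49, 0.09 for 50..99, 0.081 for 100..149.
#'
#' @param cfg a [train_config()].
#' @param epoch zero-based epoch index.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0)
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$lr_step)
}

# Stack a list of (S, S, 3) images / (S, S) masks into batch arrays.
stack_images <- function(samples, idx) {
  S <- dim(samples[[idx[1]]]$image)[1]
  x <- array(0, dim = c(S, S, 3L, length(idx)))
  y <- array(0, dim = c(S, S, length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]$image / 255
    y[, , j] <- samples[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Mini-batch momentum SGD on the multi-label loss.  Shuffling is seeded
#' from (seed, epoch); weight init from `seed` (set before calling
#' [build_model()] when a model is passed in).  Single-threaded execution
#' is deterministic given the seed.
#'
#' @param net_cfg a [net_config()] (ignored when `model` is given).
#' @param samples list of training samples, each a list with `image`
#'   ((S, S, 3), 0..255) and `mask` ((S, S), 0/1) — e.g.
#'   `generate_dataset()$samples` or `build_training_set()$samples`.
#' @param cfg a [train_config()].
#' @param model optional prebuilt/resumed model.
#' @param start_epoch zero-based epoch to resume from.
#' @param verbose print per-epoch loss and Dice to stderr.
#' @return list with `model` and `log` (data.frame epoch, lr, loss, dice).
#' @export
train <- function(net_cfg, samples, cfg = train_config(), model = NULL,
                  start_epoch = 0L, verbose = TRUE) {
  if (length(samples) == 0) stop("empty dataset")
  if (is.null(model)) {
    set.seed(cfg$seed)
    model <- build_model(net_cfg)
  }
  n <- length(samples)
  log_rows <- list()
  for (epoch in start_epoch:(cfg$epochs - 1L)) {
    set.seed(cfg$seed * 10007L + epoch)
    ord <- sample.int(n)
    lr <- lr_at_epoch(cfg, epoch)
    ep_loss <- 0; nb <- 0L
    dice_acc <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      batch <- stack_images(samples, idx)
      zero_grads(model)
      out <- segnet_forward(model, batch$x, training = TRUE)
      lg <- multi_label_loss_grad(out, batch$y)
      segnet_backward(model, lg$grads)
      sgd_step(model, lr, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      msk <- out$mask
      if (length(idx) == 1L) dim(msk) <- c(dim(msk), 1L)
      for (j in seq_along(idx))
        dice_acc <- c(dice_acc, dice_of_masks(msk[, , j], batch$y[, , j]))
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / nb,
                      dice = mean(dice_acc))
    log_rows[[length(log_rows) + 1L]] <- row
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  dice %.4f",
                      epoch, lr, row$loss, row$dice))
  }
  list(model = model, log = do.call(rbind, log_rows))
}

#' Predict lesion masks
#'
#' Runs the model in evaluation mode (batch-norm running statistics) and
#' thresholds the averaged probability map at argmax.
#'
#' @param model a trained model.
#' @param images list of (S, S, 3) images (0..255) or a single one.
#' @return list per image with `mask` (0/1 matrix), `prob` (lesion
#'   probability matrix).
#' @export
predict_masks <- function(model, images) {
  if (!is.list(images)) images <- list(images)
  lapply(images, function(im) {
    x <- array(im / 255, dim = c(dim(im)[1], dim(im)[2], 3L, 1L))
    out <- segnet_forward(model, x, training = FALSE)
    list(mask = matrix(out$mask, dim(im)[1], dim(im)[2]),
         prob = out$final_map[, , 2, 1])
  })
}

# --- checkpointing ---------------------------------------------------------
# A checkpoint is a plain list (config + parameter/buffer arrays) written
# with saveRDS; the module tree is rebuilt from the config and the arrays
# restored by name, so the file format is independent of environments.

flatten_state <- function(model, path = "root") {
  out <- list()
  out[[path]] <- list(params = as.list(model$params),
                      buffers = as.list(model$buffers))
  for (nm in names(model$children))
    out <- c(out, flatten_state(model$children[[nm]],
                                paste0(path, "/", nm)))
  out
}

restore_state <- function(model, state, path = "root") {
  st <- state[[path]]
  if (is.null(st)) stop("checkpoint/config mismatch at ", path)
  for (nm in names(st$params)) model$params[[nm]] <- st$params[[nm]]
  for (nm in names(st$buffers)) model$buffers[[nm]] <- st$buffers[[nm]]
  for (nm in names(model$children))
    restore_state(model$children[[nm]], state, paste0(path, "/", nm))
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' @param model model to save.
#' @param net_cfg its `net_config`.
#' @param path file path.
#' @param epoch epoch reached (stored for resuming).
#' @return `path` / the restored list(model, net_cfg, epoch).
#' @export
save_checkpoint <- function(model, net_cfg, path, epoch = NA_integer_) {
  saveRDS(list(version = 1L, net_cfg = net_cfg, epoch = epoch,
               state = flatten_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || is.null(ck$net_cfg))
    stop("invalid checkpoint")
  model <- build_model(ck$net_cfg)
  restore_state(model, ck$state)
  list(model = model, net_cfg = ck$net_cfg, epoch = ck$epoch)
}
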