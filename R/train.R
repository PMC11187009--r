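# ---------------------------------------------------------------------------
# Desk-scale training and validation: Adam with cosine learning-rate decay,
# optional mosaic augmentation, fully seeded.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the study's published schedule: Adam, 300 epochs,
#' batch size 4, initial learning rate 1e-3 decaying (cosine) to 1e-5,
#' first-moment coefficient 0.937, weight decay 5e-4, 640x640 inputs,
#' mosaic augmentation on.
#'
#' @param epochs,batch_size Run length and batch size.
#' @param lr_init,lr_final Cosine learning-rate schedule endpoints.
#' @param momentum Adam first-moment coefficient (beta1).
#' @param weight_decay L2 weight decay on conv kernels.
#' @param input_size Square input size, divisible by 32.
#' @param mosaic Apply mosaic augmentation to training batches.
#' @param eval_every Run validation every this many epochs (0 = never).
#' @param seed Integer seed covering init, data order and augmentation.
#' @return An object of class `cdd_train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 4L, lr_init = 1e-3,
                         lr_final = 1e-5, momentum = 0.937,
                         weight_decay = 5e-4, input_size = 640L,
                         mosaic = TRUE, eval_every = 25L, seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_final <= lr_init,
            input_size %% 32 == 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_final = lr_final, momentum = momentum,
                 weight_decay = weight_decay,
                 input_size = as.integer(input_size), mosaic = isTRUE(mosaic),
                 eval_every = as.integer(eval_every), seed = as.integer(seed)),
            class = "cdd_train_config")
}

flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(flat, template) {
  out <- template
  at <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[at + seq_len(n)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    at <- at + n
  }
  out
}

# full state (trainable params + batch-norm running stats) for checkpoints
graph_state <- function(g) {
  st <- list()
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    if (n$kind == "conv") st[[as.character(i)]] <- n[c("w", "b")]
    if (n$kind == "bn") st[[as.character(i)]] <- n[c("gamma", "beta",
                                                     "rmean", "rvar")]
  }
  st
}

graph_restore <- function(g, st) {
  for (k in names(st))
    for (f in names(st[[k]])) {
      v <- st[[k]][[f]]
      if (!is.null(v)) g$nodes[[as.integer(k)]][[f]] <- v
    }
  invisible(g)
}

# ground truths of a sample in input pixels
sample_gts <- function(sample, input_size) {
  b <- norm_to_corners(sample$boxes, input_size, input_size)
  zero <- (b$x2 - b$x1) <= 0 | (b$y2 - b$y1) <= 0
  if (any(zero)) {
    warning("dropping degenerate zero-area ground-truth box(es)",
            call. = FALSE)
    b <- b[!zero, , drop = FALSE]
  }
  b
}

prepare_sample <- function(sample, input_size) {
  d <- dim(sample$image)
  if (d[1] != input_size || d[2] != input_size)
    sample <- letterbox(sample, input_size)
  sample
}

#' Train a detector
#'
#' Wires the model, losses, data and metrics together: batches are drawn in
#' seeded shuffled order, optionally mosaic-fused, the composite loss (box +
#' classification + distribution focal) is backpropagated through the layer
#' graph, and Adam with cosine decay updates the weights. Per-epoch loss
#' components (and validation mAP when scheduled) are logged in the history.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param dataset Training samples: a list of samples, or a dataset
#'   directory created by [generate_synthetic()].
#' @param val_dataset Optional validation samples (same forms).
#' @return An object of class `cdd_fit`: the trained model, history tibble,
#'   the best state seen, and the configs.
#' @export
train <- function(model_cfg, train_cfg, dataset, val_dataset = NULL) {
  samples <- load_samples(dataset)
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  val <- if (!is.null(val_dataset)) load_samples(val_dataset)
  set.seed(train_cfg$seed)
  cfg <- model_cfg
  if (cfg$input_size != train_cfg$input_size)
    cfg <- utils::modifyList(cfg, list(input_size = train_cfg$input_size))
  class(cfg) <- "cdd_model_config"
  model <- build_model(cfg, seed = train_cfg$seed)
  g <- model$graph
  theta_t <- graph_params(g)
  decay_mask <- rep(as.numeric(attr(theta_t, "decay")),
                    vapply(theta_t, length, 0L))
  theta <- flatten_params(theta_t)
  m <- v <- numeric(length(theta))
  t_step <- 0
  history <- list()
  best <- list(map50 = -Inf, state = NULL, epoch = NA_integer_)
  n <- length(samples)
  prepped <- lapply(samples, prepare_sample, input_size = cfg$input_size)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- train_cfg$lr_final + 0.5 * (train_cfg$lr_init - train_cfg$lr_final) *
      (1 + cos(pi * (epoch - 1) / max(1, train_cfg$epochs - 1)))
    ord <- sample.int(n)
    ep_loss <- c(loss = 0, box = 0, cls = 0, dfl = 0)
    n_batches <- 0
    for (b0 in seq(1, n, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1, n)]
      batch <- lapply(idx, function(i) {
        if (train_cfg$mosaic) {
          picks <- c(i, sample.int(n, 3, replace = TRUE))
          mosaic(prepped[picks], cfg$input_size,
                 seed = stats::runif(1, 0, .Machine$integer.max / 2))
        } else prepped[[i]]
      })
      x <- array(0, c(3L, cfg$input_size, cfg$input_size, length(batch)))
      for (k in seq_along(batch)) x[, , , k] <- img_to_tensor(batch[[k]]$image)
      gts <- lapply(batch, sample_gts, input_size = cfg$input_size)
      raw <- model_forward(model, x, train = TRUE)
      ls <- total_loss(raw, gts, cfg)
      if (!is.finite(ls$loss))
        stop(sprintf(
          "non-finite loss at epoch %d (batch of samples %s): box=%g cls=%g dfl=%g",
          epoch, paste(idx, collapse = ","), ls$box, ls$cls, ls$dfl),
          call. = FALSE)
      dout <- list()
      for (l in 1:3) {
        dout[[as.character(model$reg_ids[l])]] <- ls$grads$reg[[l]]
        dout[[as.character(model$cls_ids[l])]] <- ls$grads$cls[[l]]
      }
      bw <- graph_backward(g, raw$fw, dout)
      grads <- flatten_params(graph_collect_grads(g, bw$param_grads))
      grads <- grads + train_cfg$weight_decay * theta * decay_mask
      t_step <- t_step + 1
      b1 <- train_cfg$momentum; b2 <- 0.999
      m <- b1 * m + (1 - b1) * grads
      v <- b2 * v + (1 - b2) * grads^2
      mh <- m / (1 - b1^t_step)
      vh <- v / (1 - b2^t_step)
      theta <- theta - lr * mh / (sqrt(vh) + 1e-8)
      graph_set_params(g, unflatten_params(theta, theta_t))
      ep_loss <- ep_loss + c(ls$loss, ls$box, ls$cls, ls$dfl)
      n_batches <- n_batches + 1
    }
    ep_loss <- ep_loss / n_batches
    row <- tibble::tibble(epoch = epoch, lr = lr, loss = ep_loss[1],
                          box = ep_loss[2], cls = ep_loss[3],
                          dfl = ep_loss[4], map50 = NA_real_)
    if (!is.null(val) && train_cfg$eval_every > 0 &&
        (epoch %% train_cfg$eval_every == 0 || epoch == train_cfg$epochs)) {
      ev <- evaluate_model(model, val)
      row$map50 <- ev$map50
      if (ev$map50 > best$map50)
        best <- list(map50 = ev$map50, state = graph_state(g), epoch = epoch)
    }
    history[[epoch]] <- row
  }
  if (is.null(best$state))
    best <- list(map50 = NA_real_, state = graph_state(g),
                 epoch = train_cfg$epochs)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best = best, model_cfg = cfg, train_cfg = train_cfg),
            class = "cdd_fit")
}

#' @export
print.cdd_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<cdd_fit> %d epochs, final loss %.4f (box %.4f cls %.4f dfl %.4f)\n",
              nrow(x$history), last$loss, last$box, last$cls, last$dfl))
  if (is.finite(x$best$map50))
    cat(sprintf("  best val mAP@0.5 = %.4f at epoch %d\n", x$best$map50,
                x$best$epoch))
  invisible(x)
}

load_samples <- function(dataset) {
  if (is.character(dataset) && length(dataset) == 1 && dir.exists(dataset)) {
    imgs <- list.files(file.path(dataset, "images"), full.names = TRUE,
                       pattern = "\\.png$")
    return(lapply(imgs, read_sample))
  }
  if (is.list(dataset) && !is.null(dataset$image)) return(list(dataset))
  dataset
}

#' Evaluate a model on a dataset split
#'
#' Deterministic evaluation: forward pass in inference mode, decode at
#' confidence 0.001 with class-wise NMS at IoU 0.45, then mAP over the
#' requested thresholds.
#'
#' @param model A `cdd_model` or `cdd_fit`.
#' @param dataset Samples (list or dataset directory).
#' @param conf_threshold,nms_iou Decode settings.
#' @param thresholds IoU thresholds for the mAP sweep.
#' @return A `cdd_eval` (see [map_at()]).
#' @export
evaluate_model <- function(model, dataset, conf_threshold = 0.001,
                           nms_iou = 0.45,
                           thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(model, "cdd_fit")) model <- model$model
  samples <- load_samples(dataset)
  if (length(samples) == 0) stop("empty evaluation split", call. = FALSE)
  cfg <- model$config
  dets <- list(); gts <- list()
  for (k in seq_along(samples)) {
    s <- prepare_sample(samples[[k]], cfg$input_size)
    raw <- model_forward(model, img_to_tensor(s$image), train = FALSE)
    dets[[k]] <- decode(raw, cfg, conf_threshold, nms_iou)
    gts[[k]] <- suppressWarnings(sample_gts(s, cfg$input_size))
  }
  map_at(dets, gts, thresholds, num_classes = cfg$num_classes)
}

#' Save / load a checkpoint
#'
#' A checkpoint bundles a format version, the model and training configs,
#' the full weight state (including batch-norm running statistics) and the
#' training history.
#'
#' @param fit A `cdd_fit` (or a `cdd_model` for an untrained snapshot).
#' @param path Destination file.
#' @param use_best Save the best-validation state instead of the final one.
#' @return `path` (save) / a rebuilt `cdd_fit` (load).
#' @export
save_checkpoint <- function(fit, path, use_best = FALSE) {
  if (inherits(fit, "cdd_model"))
    fit <- structure(list(model = fit, history = tibble::tibble(),
                          best = list(state = graph_state(fit$graph)),
                          model_cfg = fit$config, train_cfg = NULL),
                     class = "cdd_fit")
  state <- if (use_best && !is.null(fit$best$state)) fit$best$state
           else graph_state(fit$model$graph)
  saveRDS(list(version = 1L, model_cfg = unclass(fit$model_cfg),
               train_cfg = if (!is.null(fit$train_cfg)) unclass(fit$train_cfg),
               state = state, history = fit$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L)
    stop("unsupported checkpoint version", call. = FALSE)
  cfg <- structure(ck$model_cfg, class = "cdd_model_config")
  model <- build_model(cfg)
  graph_restore(model$graph, ck$state)
  structure(list(model = model, history = ck$history,
                 best = list(map50 = NA_real_, state = ck$state,
                             epoch = NA_integer_),
                 model_cfg = cfg,
                 train_cfg = if (!is.null(ck$train_cfg))
                   structure(ck$train_cfg, class = "cdd_train_config")),
            class = "cdd_fit")
}
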