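# Broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_step labs facet_wrap theme_minimal
NULL

#' Tidy a profile, evaluation or fit
#'
#' `tidy()` returns the underlying per-unit tibble (per layer, per class,
#' per epoch); `glance()` a one-row summary.
#'
#' @param x A `cdd_profile`, `cdd_eval` or `cdd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.cdd_profile <- function(x, ...) x$layers

#' @rdname tidy
#' @export
glance.cdd_profile <- function(x, ...) {
  tibble::tibble(total_params = x$total_params, params_m = x$total_params / 1e6,
                 gflops = x$gflops, input_size = x$input_size)
}

#' @rdname tidy
#' @export
tidy.cdd_eval <- function(x, ...) x$per_class

#' @rdname tidy
#' @export
glance.cdd_eval <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map = x$map, precision = x$precision,
                 recall = x$recall, tp = x$tp, fp = x$fp, fn = x$fn)
}

#' @rdname tidy
#' @export
tidy.cdd_fit <- function(x, ...) x$history

#' @rdname tidy
#' @export
glance.cdd_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), final_loss = last$loss,
                 best_map50 = x$best$map50, best_epoch = x$best$epoch)
}

#' Plot methods
#'
#' `autoplot()` draws the training curves of a fit, the per-class AP bars of
#' an evaluation, or the cumulative cost profile of a model.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdd_fit
#' @export
autoplot.cdd_fit <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    epoch = rep(h$epoch, 4),
    component = rep(c("total", "box", "cls", "dfl"), each = nrow(h)),
    value = c(h$loss, h$box, h$cls, h$dfl))
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$component)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "Training loss components") +
    theme_minimal()
}

#' @rdname autoplot.cdd_fit
#' @method autoplot cdd_eval
#' @export
autoplot.cdd_eval <- function(object, ...) {
  pc <- object$per_class
  pc$class <- factor(cdd_classes[pc$class_id + 1], levels = cdd_classes)
  long <- tibble::tibble(class = rep(pc$class, 2),
                         metric = rep(c("AP@0.5", "AP@0.5:0.95"),
                                      each = nrow(pc)),
                         value = c(pc$ap50, pc$ap))
  ggplot(long, aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "average precision",
         title = sprintf("mAP@0.5 = %.3f", object$map50)) +
    theme_minimal()
}

#' @rdname autoplot.cdd_fit
#' @method autoplot cdd_profile
#' @export
autoplot.cdd_profile <- function(object, ...) {
  l <- object$layers[object$layers$params > 0 | object$layers$flops > 0, ]
  l$cum_params <- cumsum(l$params) / 1e6
  l$cum_gflops <- cumsum(l$flops) / 1e9
  l$depth <- seq_len(nrow(l))
  long <- tibble::tibble(depth = rep(l$depth, 2),
                         quantity = rep(c("params (M)", "FLOPs (G)"),
                                        each = nrow(l)),
                         value = c(l$cum_params, l$cum_gflops))
  ggplot(long, aes(x = .data$depth, y = .data$value)) +
    geom_step() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "layer depth", y = "cumulative cost",
         title = "Where the cost sits in the network") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
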