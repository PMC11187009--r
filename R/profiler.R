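# ---------------------------------------------------------------------------
# Cost model. Pinned counting convention:
#   params: conv kernels K*K*(Cin/groups)*Cout, projection biases, and
#           batch-norm scale+shift (2C); pooling/upsample/concat are free.
#   FLOPs:  2 x multiply-accumulates of conv layers only, at the profiled
#           input size; elementwise, pooling and upsampling ops excluded.
# The convention was calibrated once against the baseline variant and frozen;
# residual differences with other counters are a counting dialect.
# ---------------------------------------------------------------------------

profile_graph <- function(g, input_size) {
  shp <- graph_shapes(g, input_size)
  rows <- lapply(seq_along(g$nodes), function(i) {
    n <- g$nodes[[i]]
    s <- shp[[i]]
    params <- 0; macs <- 0
    if (n$kind == "conv") {
      params <- n$k^2 * (n$cin / n$groups) * n$cout +
        (if (!is.null(n$b) || isTRUE(n$with_bias)) n$cout else 0)
      macs <- n$k^2 * (n$cin / n$groups) * n$cout * s[2] * s[3]
    } else if (n$kind == "bn") {
      params <- 2 * n$c
    }
    tibble::tibble(id = i, name = n$name, kind = n$kind, params = params,
                   flops = 2 * macs, out_c = s[1], out_h = s[2], out_w = s[3])
  })
  dplyr::bind_rows(rows)
}

#' Profile a model or block
#'
#' Walks the assembled layer graph and reports per-layer and total parameter
#' and FLOP counts under the package's pinned counting convention (see the
#' methods vignette). Parameter counts are independent of the input size;
#' FLOPs scale with the spatial grid.
#'
#' @param x A `cdd_model` (from [build_model()]) or a [block_spec()].
#' @param input_size Square input size in pixels for the FLOP count;
#'   defaults to the model config's size.
#' @return An object of class `cdd_profile`: a per-layer tibble plus totals
#'   (`total_params`, `total_flops`; `gflops` = total FLOPs / 1e9).
#' @export
profile_model <- function(x, input_size = NULL) {
  if (inherits(x, "cdd_block_spec")) {
    g <- block_graph(x, seed = 1L)
    if (is.null(input_size)) input_size <- 32L
  } else if (inherits(x, "cdd_model")) {
    g <- x$graph
    if (is.null(input_size)) input_size <- x$config$input_size
  } else if (inherits(x, "cdd_graph")) {
    g <- x
    if (is.null(input_size)) stop("input_size required for a bare graph",
                                  call. = FALSE)
  } else stop("cannot profile object of class ", class(x)[1], call. = FALSE)
  layers <- profile_graph(g, input_size)
  structure(list(layers = layers,
                 total_params = sum(layers$params),
                 total_flops = sum(layers$flops),
                 gflops = sum(layers$flops) / 1e9,
                 input_size = as.integer(input_size)),
            class = "cdd_profile")
}

#' @export
print.cdd_profile <- function(x, ...) {
  cat(sprintf("<cdd_profile> input %d: %.4f M params, %.4f GFLOPs\n",
              x$input_size, x$total_params / 1e6, x$gflops))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sum of conv kernel weights (grouped convolutions divide by groups),
#' projection biases and batch-norm scale/shift parameters.
#'
#' @param model A `cdd_model`, `cdd_block_spec` or `cdd_graph`.
#' @return Integer-valued parameter total.
#' @export
count_params <- function(model) {
  input_size <- if (inherits(model, "cdd_model")) model$config$input_size else 32L
  profile_model(model, input_size)$total_params
}

#' Count FLOPs
#'
#' 2 x conv multiply-accumulates at the given input size, in GFLOPs.
#'
#' @inheritParams count_params
#' @param input_size Square input size (divisible by 32).
#' @return GFLOPs (numeric).
#' @export
count_flops <- function(model, input_size = NULL) {
  if (!is.null(input_size) && input_size %% 32 != 0)
    stop("input_size must be divisible by 32", call. = FALSE)
  profile_model(model, input_size)$gflops
}

#' PCD / standard-convolution FLOP ratio
#'
#' Closed form `1/r^2 + 1/k^2` for the cost of a PCD unit (k x k partial
#' convolution over C/r channels followed by a 1x1 pointwise convolution)
#' relative to a single k x k standard convolution at equal channel count
#' and feature-map size.
#'
#' @param k Kernel size of the partial convolution.
#' @param r Partial ratio.
#' @param empirical If `TRUE`, additionally verify the ratio by profiling a
#'   PCD unit and a plain conv at `C = 64` on a 20x20 map and return that
#'   measured ratio.
#' @return The ratio (closed form, or measured if `empirical`).
#' @export
pcd_ratio <- function(k = 3L, r = 4L, empirical = FALSE) {
  stopifnot(k >= 1, r >= 1)
  if (!empirical) return(1 / r^2 + 1 / k^2)
  C <- 64L
  gp <- new_graph()
  i1 <- g_input(gp, C)
  p1 <- g_conv(gp, g_slice(gp, i1, 1L, C %/% r), C %/% r, C %/% r, k, 1L)
  pw <- g_conv(gp, i1, C, C, 1L, 1L)  # stands for the 1x1 pointwise stage
  gp$outputs <- c(p1, pw)
  gc_ <- new_graph()
  i2 <- g_input(gc_, C)
  cv <- g_conv(gc_, i2, C, C, k, 1L)
  gc_$outputs <- cv
  hw <- 20L  # any map size works; the ratio is size-free
  f_pcd <- sum(profile_graph(gp, hw)$flops)
  f_conv <- sum(profile_graph(gc_, hw)$flops)
  f_pcd / f_conv
}

#' Forward-pass throughput
#'
#' Wall-clock frames per second of forward + decode on synthetic frames.
#' Hardware-dependent; a development utility, never a comparison metric.
#'
#' @param model A `cdd_model`.
#' @param n_frames Number of frames (>= 1).
#' @param input_size Frame size; defaults to the model's configured size.
#' @return Frames per second (numeric), with the elapsed time as an
#'   attribute.
#' @export
measure_fps <- function(model, n_frames = 10L, input_size = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (is.null(input_size)) input_size <- model$config$input_size
  x <- array(stats::runif(3 * input_size^2), c(3L, input_size, input_size))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_frames)) {
    raw <- model_forward(model, x, train = FALSE)
    decode(raw, model$config)
  }
  el <- proc.time()[["elapsed"]] - t0
  structure(n_frames / max(el, 1e-9), elapsed = el)
}

#' Ablation cost table
#'
#' Profiles the named variants and reports parameters (M) and FLOPs (G),
#' both raw and at one-decimal table precision, plus reductions relative to
#' the baseline.
#'
#' @param variants Character vector of [variant_config()] names.
#' @param num_classes,input_size Model geometry.
#' @return A tibble with one row per variant.
#' @export
ablation_table <- function(variants = c("baseline", "c2f_faster", "slim_neck",
                                        "c2f_faster+slim_neck", "pcdetect",
                                        "cddlite"),
                           num_classes = 3L, input_size = 640L) {
  rows <- purrr::map(variants, function(v) {
    m <- build_model(variant_config(v, num_classes, input_size))
    p <- profile_model(m)
    tibble::tibble(variant = v, params = p$total_params,
                   params_m = p$total_params / 1e6, gflops = p$gflops)
  })
  out <- dplyr::bind_rows(rows)
  base <- out[out$variant == "baseline", ]
  if (nrow(base) == 1) {
    out$params_reduction_pct <- round(100 * (1 - out$params / base$params), 2)
    out$flops_reduction_pct <- round(100 * (1 - out$gflops / base$gflops), 2)
  }
  out$params_m_1dp <- round(out$params_m, 1)
  out$gflops_1dp <- round(out$gflops, 1)
  out
}

#' Profile a single block
#'
#' @param spec A [block_spec()].
#' @param input_size Spatial size of the input map.
#' @return A `cdd_profile`.
#' @export
profile_block <- function(spec, input_size = 32L) {
  profile_model(spec, input_size)
}
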