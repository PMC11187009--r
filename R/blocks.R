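# ---------------------------------------------------------------------------
# Block vocabulary: CBS, depthwise conv, partial convolution, Faster block,
# C2f / C2f-Faster, GSConv, GS bottleneck, VoVGSCSP, SPPF.
#
# Builders take a graph and the id of the feeding node and return the id of
# the block's output node, so models are assembled by chaining builders.
# Conventions pinned for the cost model: same-padding floor(K/2);
# channel-first layout; CBS = conv(no bias) + batch norm + SiLU.
# ---------------------------------------------------------------------------

#' Describe a single block
#'
#' A `block_spec` is a plain validated list naming one block of the layer
#' vocabulary and its channel geometry. It is the unit the block-level
#' forward operations and [profile_block()] consume, and the form in which
#' model layers are reported by the profiler.
#'
#' @param kind One of `"CBS"`, `"DWConv"`, `"PConv"`, `"FasterBlock"`,
#'   `"C2f"`, `"C2fFaster"`, `"GSConv"`, `"GSBottleneck"`, `"VoVGSCSP"`,
#'   `"SPPF"`, `"Upsample"`, `"Concat"`, `"PlainConv"`.
#' @param in_channels,out_channels Channel counts (positive integers).
#' @param kernel Kernel size, one of 1, 3, 5.
#' @param stride Stride, 1 or 2.
#' @param n Repeat count for composite blocks (inner units), `>= 1`.
#' @param partial_ratio Partial-convolution ratio r: only `in_channels / r`
#'   channels are convolved (PConv / FasterBlock / PCD heads). Default 4.
#' @param expansion Hidden expansion of the Faster block pointwise stage.
#' @return An object of class `cdd_block_spec`.
#' @export
block_spec <- function(kind, in_channels, out_channels = in_channels,
                       kernel = 3L, stride = 1L, n = 1L, partial_ratio = 4L,
                       expansion = 2L) {
  kinds <- c("CBS", "DWConv", "PConv", "FasterBlock", "C2f", "C2fFaster",
             "GSConv", "GSBottleneck", "VoVGSCSP", "SPPF", "Upsample",
             "Concat", "PlainConv")
  kind <- match.arg(kind, kinds)
  if (!kernel %in% c(1L, 3L, 5L)) stop("kernel must be 1, 3 or 5", call. = FALSE)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  if (in_channels < 1 || out_channels < 1) stop("channels must be >= 1", call. = FALSE)
  if (n < 1) stop("repeat n must be >= 1", call. = FALSE)
  if (kind %in% c("PConv", "FasterBlock") && in_channels %% partial_ratio != 0)
    stop(sprintf("PConv requires in_channels divisible by r = %d", partial_ratio),
         call. = FALSE)
  if (kind == "FasterBlock" && in_channels != out_channels)
    stop("FasterBlock is residual: in_channels must equal out_channels",
         call. = FALSE)
  if (kind == "GSConv" && out_channels %% 2 != 0)
    stop("GSConv requires an even out_channels", call. = FALSE)
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 n = as.integer(n), partial_ratio = as.integer(partial_ratio),
                 expansion = as.integer(expansion)),
            class = "cdd_block_spec")
}

# --- builders --------------------------------------------------------------

# conv + BN + SiLU
bld_cbs <- function(g, from, cin, cout, k = 1L, s = 1L, groups = 1L,
                    act = TRUE, name = "cbs") {
  id <- g_conv(g, from, cin, cout, k, s, groups, name = paste0(name, ".conv"))
  id <- g_bn(g, id, cout, name = paste0(name, ".bn"))
  if (act) id <- g_silu(g, id, name = paste0(name, ".silu"))
  id
}

# depthwise CBS
bld_dwconv <- function(g, from, c, k = 5L, s = 1L, act = TRUE, name = "dw") {
  bld_cbs(g, from, c, c, k, s, groups = c, act = act, name = name)
}

# partial convolution: plain k x k conv on the first C/r channels, identity
# elsewhere; no bias, no batch norm inside (those live in the following CBS)
bld_pconv <- function(g, from, c, r = 4L, k = 3L, name = "pconv") {
  if (c %% r != 0)
    stop(sprintf("layer '%s': %d channels not divisible by r = %d", name, c, r),
         call. = FALSE)
  cp <- c %/% r
  s1 <- g_slice(g, from, 1L, cp, name = paste0(name, ".take"))
  cv <- g_conv(g, s1, cp, cp, k, 1L, name = paste0(name, ".conv"))
  s2 <- g_slice(g, from, cp + 1L, c, name = paste0(name, ".pass"))
  g_concat(g, c(cv, s2), name = paste0(name, ".cat"))
}

# FasterNet block: PConv -> pointwise expand (CBS) -> pointwise project
# (plain conv, no bias/BN) + residual shortcut
bld_faster_block <- function(g, from, c, expansion = 2L, name = "faster") {
  id <- bld_pconv(g, from, c, r = 4L, k = 3L, name = paste0(name, ".pconv"))
  id <- bld_cbs(g, id, c, c * expansion, 1L, 1L, name = paste0(name, ".cv1"))
  id <- g_conv(g, id, c * expansion, c, 1L, 1L, name = paste0(name, ".cv2"))
  g_addn(g, c(id, from), name = paste0(name, ".add"))
}

# standard YOLO bottleneck (two 3x3 CBS) with optional residual
bld_bottleneck <- function(g, from, c, shortcut = TRUE, name = "bneck") {
  id <- bld_cbs(g, from, c, c, 3L, 1L, name = paste0(name, ".cv1"))
  id <- bld_cbs(g, id, c, c, 3L, 1L, name = paste0(name, ".cv2"))
  if (shortcut) g_addn(g, c(id, from), name = paste0(name, ".add")) else id
}

# C2f: 1x1 split conv -> n chained inner units (every intermediate retained)
# -> concat -> 1x1 fuse. `faster = TRUE` swaps bottlenecks for Faster blocks.
bld_c2f <- function(g, from, cin, cout, n = 1L, shortcut = TRUE,
                    faster = FALSE, name = "c2f") {
  c <- cout %/% 2L
  cv1 <- bld_cbs(g, from, cin, cout, 1L, 1L, name = paste0(name, ".cv1"))
  a <- g_slice(g, cv1, 1L, c, name = paste0(name, ".split_a"))
  b <- g_slice(g, cv1, c + 1L, cout, name = paste0(name, ".split_b"))
  parts <- c(a, b)
  cur <- b
  for (i in seq_len(n)) {
    cur <- if (faster)
      bld_faster_block(g, cur, c, name = paste0(name, ".m", i))
    else
      bld_bottleneck(g, cur, c, shortcut, name = paste0(name, ".m", i))
    parts <- c(parts, cur)
  }
  cat_id <- g_concat(g, parts, name = paste0(name, ".cat"))
  bld_cbs(g, cat_id, (2L + n) * c, cout, 1L, 1L, name = paste0(name, ".cv2"))
}

# SPPF: 1x1 reduce -> three chained 5x5 stride-1 max pools -> concat -> 1x1
bld_sppf <- function(g, from, c, k = 5L, name = "sppf") {
  ch <- c %/% 2L
  cv1 <- bld_cbs(g, from, c, ch, 1L, 1L, name = paste0(name, ".cv1"))
  p1 <- g_maxpool(g, cv1, k, name = paste0(name, ".p1"))
  p2 <- g_maxpool(g, p1, k, name = paste0(name, ".p2"))
  p3 <- g_maxpool(g, p2, k, name = paste0(name, ".p3"))
  cat_id <- g_concat(g, c(cv1, p1, p2, p3), name = paste0(name, ".cat"))
  bld_cbs(g, cat_id, 4L * ch, c, 1L, 1L, name = paste0(name, ".cv2"))
}

# GSConv: standard CBS to C2/2 (carries the stride), depthwise CBS producing
# the other C2/2 from it, concat, channel shuffle (groups = 2)
bld_gsconv <- function(g, from, cin, cout, k = 1L, s = 1L, dw_k = 5L,
                       name = "gsconv") {
  if (cout %% 2 != 0)
    stop(sprintf("layer '%s': GSConv needs even out_channels, got %d",
                 name, cout), call. = FALSE)
  ch <- cout %/% 2L
  sc <- bld_cbs(g, from, cin, ch, k, s, name = paste0(name, ".cv1"))
  dsc <- bld_dwconv(g, sc, ch, dw_k, 1L, name = paste0(name, ".cv2"))
  cat_id <- g_concat(g, c(sc, dsc), name = paste0(name, ".cat"))
  g_shuffle(g, cat_id, 2L, name = paste0(name, ".shuf"))
}

# GS bottleneck: GSConv 1x1 then GSConv 3x3, plus a depthwise + pointwise
# shortcut branch, summed
bld_gs_bottleneck <- function(g, from, cin, cout, shortcut = TRUE,
                              name = "gsb") {
  id <- bld_gsconv(g, from, cin, cout, 1L, 1L, name = paste0(name, ".g1"))
  id <- bld_gsconv(g, id, cout, cout, 3L, 1L, name = paste0(name, ".g2"))
  if (!shortcut) return(id)
  sc <- bld_dwconv(g, from, cin, 3L, 1L, act = FALSE, name = paste0(name, ".sc.dw"))
  sc <- g_conv(g, sc, cin, cout, 1L, 1L, name = paste0(name, ".sc.pw"))
  g_addn(g, c(id, sc), name = paste0(name, ".add"))
}

# VoVGSCSP: 1x1 conv -> n GS bottlenecks on one portion, a single 1x1 conv on
# the residual portion, concat, 1x1 fuse to C2
bld_vovgscsp <- function(g, from, cin, cout, n = 1L, name = "vov") {
  c <- cout %/% 2L
  a <- bld_cbs(g, from, cin, c, 1L, 1L, name = paste0(name, ".cv1"))
  for (i in seq_len(n))
    a <- bld_gs_bottleneck(g, a, c, c, name = paste0(name, ".b", i))
  b <- bld_cbs(g, from, cin, c, 1L, 1L, name = paste0(name, ".cv2"))
  cat_id <- g_concat(g, c(a, b), name = paste0(name, ".cat"))
  bld_cbs(g, cat_id, 2L * c, cout, 1L, 1L, name = paste0(name, ".cv3"))
}

# lower a block_spec onto a fresh graph (input node included)
block_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cdd_block_spec"))
  g <- new_graph()
  inp <- g_input(g, spec$in_channels)
  out <- switch(spec$kind,
    CBS = bld_cbs(g, inp, spec$in_channels, spec$out_channels, spec$kernel,
                  spec$stride),
    PlainConv = g_conv(g, inp, spec$in_channels, spec$out_channels,
                       spec$kernel, spec$stride),
    DWConv = bld_dwconv(g, inp, spec$in_channels, spec$kernel, spec$stride),
    PConv = bld_pconv(g, inp, spec$in_channels, spec$partial_ratio, spec$kernel),
    FasterBlock = bld_faster_block(g, inp, spec$in_channels, spec$expansion),
    C2f = bld_c2f(g, inp, spec$in_channels, spec$out_channels, spec$n),
    C2fFaster = bld_c2f(g, inp, spec$in_channels, spec$out_channels, spec$n,
                        faster = TRUE),
    GSConv = bld_gsconv(g, inp, spec$in_channels, spec$out_channels,
                        spec$kernel, spec$stride),
    GSBottleneck = bld_gs_bottleneck(g, inp, spec$in_channels, spec$out_channels),
    VoVGSCSP = bld_vovgscsp(g, inp, spec$in_channels, spec$out_channels, spec$n),
    SPPF = bld_sppf(g, inp, spec$in_channels, spec$kernel),
    stop("block kind has no standalone forward: ", spec$kind)
  )
  g$outputs <- out
  if (!is.null(seed)) withr_seed(seed)
  g_init(g)
  g
}

# minimal local stand-in so block_graph stays dependency-light
withr_seed <- function(seed) set.seed(seed)

run_block <- function(spec, x, seed = 1L, graph = NULL) {
  g <- if (is.null(graph)) block_graph(spec, seed = seed) else graph
  fw <- graph_forward(g, x, train = FALSE)
  y <- fw$cache[[g$outputs]]
  if (length(dim(x)) == 3L) {
    d <- dim(y)
    y <- array(y, d[1:3])
  }
  y
}

#' Block-level forward passes
#'
#' Run a single block of the layer vocabulary on a feature map. The feature
#' map is a numeric array `(C, H, W)` (or `(C, H, W, N)` for a batch); the
#' block's weights are drawn once from a seeded Kaiming-normal initialisation
#' unless a pre-built `graph` is supplied, so results are reproducible.
#'
#' * `cbs_forward()`: convolution + batch norm + SiLU.
#' * `pconv_forward()`: partial convolution — a plain `k x k` convolution over
#'   the first `C/r` channels, the remaining channels passed through
#'   untouched.
#' * `faster_block_forward()`: PConv, pointwise expansion CBS, pointwise
#'   projection, residual shortcut.
#' * `c2f_forward()` / `c2f_faster_forward()`: the cross-stage block with
#'   `n` chained inner units, every intermediate retained for the fuse conv.
#' * `gsconv_forward()`: half standard / half depthwise convolution with a
#'   channel shuffle.
#' * `gs_bottleneck_forward()` and `vovgscsp_forward()`: the slim-neck
#'   composites built on GSConv.
#' * `sppf_forward()`: spatial pyramid pooling (fast) with chained 5x5 pools.
#'
#' @param x Numeric array `(C, H, W)` or `(C, H, W, N)`.
#' @param spec A [block_spec()] whose `kind` matches the function.
#' @param seed Integer seed for weight initialisation.
#' @param graph Optionally a pre-built block graph (from internal builders)
#'   whose weights should be reused.
#' @return The output feature array, channel-first like the input.
#' @export
cbs_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "CBS")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
pconv_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "PConv")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
faster_block_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "FasterBlock")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
c2f_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "C2f")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
c2f_faster_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "C2fFaster")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
gsconv_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "GSConv")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
gs_bottleneck_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "GSBottleneck")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
vovgscsp_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "VoVGSCSP")
  run_block(spec, x, seed, graph)
}

#' @rdname cbs_forward
#' @export
sppf_forward <- function(x, spec, seed = 1L, graph = NULL) {
  stopifnot(spec$kind == "SPPF")
  run_block(spec, x, seed, graph)
}

#' Group-interleave channel shuffle
#'
#' Reorders channels by the standard group-interleave permutation: reshape the
#' channel axis to `groups x C/groups`, transpose, flatten. Values are
#' untouched; only channel order changes.
#'
#' @param x Numeric array `(C, H, W)` or `(C, H, W, N)`.
#' @param groups Number of groups; must divide `C`.
#' @return Array of the same shape with channels permuted.
#' @export
channel_shuffle <- function(x, groups) {
  x4 <- as_chwn(x)
  C <- dim(x4)[1]
  if (C %% groups != 0L)
    stop(sprintf("channel_shuffle: %d channels not divisible by %d groups",
                 C, groups), call. = FALSE)
  perm <- as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
  y <- x4[perm, , , , drop = FALSE]
  if (length(dim(x)) == 3L) dim(y) <- dim(x)
  y
}
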