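#' @useDynLib cddlite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Layer graph: a DAG of primitive nodes (conv, bn, silu, maxpool, upsample,
# concat, add, slice, shuffle). Composite blocks are lowered onto these
# primitives at build time, so a single executor serves the forward pass,
# reverse-mode gradients, and the cost profiler.
# ---------------------------------------------------------------------------

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$outputs <- integer()
  class(g) <- "cdd_graph"
  g
}

# formals are dot-prefixed so `...` fields (k, c, ...) can never partially
# match them
g_add <- function(g, .kind, .inputs, .name, ...) {
  node <- c(list(kind = .kind, inputs = as.integer(.inputs), name = .name),
            list(...))
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

# Convolution node. `w` is (Cout x (Cin/groups * K * K)); NULL until init.
g_conv <- function(g, from, cin, cout, k = 1L, s = 1L, groups = 1L,
                   bias = FALSE, name = "conv") {
  stopifnot(k %in% c(1L, 3L, 5L), s %in% c(1L, 2L), cin %% groups == 0L,
            cout %% groups == 0L)
  g_add(g, "conv", from, name, cin = as.integer(cin), cout = as.integer(cout),
        k = as.integer(k), s = as.integer(s), pad = as.integer(k %/% 2),
        groups = as.integer(groups), with_bias = isTRUE(bias), w = NULL,
        b = NULL)
}

g_bn <- function(g, from, c, name = "bn") {
  g_add(g, "bn", from, name, c = as.integer(c),
        gamma = rep(1, c), beta = rep(0, c),
        rmean = rep(0, c), rvar = rep(1, c), eps = 1e-5, momentum = 0.03)
}

g_silu <- function(g, from, name = "silu") g_add(g, "silu", from, name)
g_maxpool <- function(g, from, k = 5L, s = 1L, name = "maxpool") {
  g_add(g, "maxpool", from, name, k = as.integer(k), s = as.integer(s),
        pad = as.integer(k %/% 2))
}
g_upsample <- function(g, from, name = "upsample") g_add(g, "upsample", from, name)
g_concat <- function(g, from, name = "concat") g_add(g, "concat", from, name)
g_addn <- function(g, from, name = "add") g_add(g, "add", from, name)
g_slice <- function(g, from, ch_from, ch_to, name = "slice") {
  g_add(g, "slice", from, name, ch_from = as.integer(ch_from),
        ch_to = as.integer(ch_to))
}
g_shuffle <- function(g, from, groups, name = "shuffle") {
  g_add(g, "shuffle", from, name, groups = as.integer(groups))
}
g_input <- function(g, channels, name = "input") {
  g_add(g, "input", integer(), name, cin = as.integer(channels),
        cout = as.integer(channels))
}

# Kaiming-normal init for conv weights; biases zero unless preset by the head.
g_init <- function(g) {
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    if (n$kind == "conv" && is.null(n$w)) {
      fan_in <- n$k * n$k * n$cin / n$groups
      w <- matrix(stats::rnorm(n$cout * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = n$cout)
      g$nodes[[i]]$w <- w
      if (n$with_bias && is.null(n$b)) g$nodes[[i]]$b <- rep(0, n$cout)
    }
  }
  invisible(g)
}

as_chwn <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature input must be an array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

silu_fw <- function(x) { s <- 1 / (1 + exp(-x)); x * s }

# Forward pass; returns list(cache = per-node activations, extras for backward).
graph_forward <- function(g, x, train = FALSE) {
  x <- as_chwn(x)
  cache <- vector("list", length(g$nodes))
  aux <- vector("list", length(g$nodes))
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    out <- switch(n$kind,
      input = {
        if (dim(x)[1] != n$cin)
          stop(sprintf("layer '%s': expected %d input channels, got %d",
                       n$name, n$cin, dim(x)[1]), call. = FALSE)
        x
      },
      conv = {
        xin <- cache[[n$inputs]]
        if (dim(xin)[1] != n$cin)
          stop(sprintf("layer '%s': expected %d input channels, got %d",
                       n$name, n$cin, dim(xin)[1]), call. = FALSE)
        cpp_conv2d_fw(xin, n$w, n$b, n$k, n$s, n$pad, n$groups)
      },
      bn = {
        xin <- cache[[n$inputs]]
        d <- dim(xin)
        xm <- matrix(xin, nrow = d[1])
        if (train) {
          mu <- rowMeans(xm)
          xc <- xm - mu
          va <- rowMeans(xc * xc)
          m <- ncol(xm)
          g$nodes[[i]]$rmean <- (1 - n$momentum) * n$rmean + n$momentum * mu
          g$nodes[[i]]$rvar <- (1 - n$momentum) * n$rvar +
            n$momentum * va * m / max(1, m - 1)
        } else {
          mu <- n$rmean
          va <- n$rvar
          xc <- xm - mu
        }
        istd <- 1 / sqrt(va + n$eps)
        xhat <- xc * istd
        aux[[i]] <- list(xhat = xhat, istd = istd)
        y <- xhat * n$gamma + n$beta
        dim(y) <- d
        y
      },
      silu = silu_fw(cache[[n$inputs]]),
      maxpool = {
        r <- cpp_maxpool_fw(cache[[n$inputs]], n$k, n$s, n$pad)
        aux[[i]] <- r$idx
        r$y
      },
      upsample = {
        xin <- cache[[n$inputs]]
        d <- dim(xin)
        xin[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
            drop = FALSE]
      },
      concat = {
        parts <- cache[n$inputs]
        d1 <- dim(parts[[1]])
        out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 0)),
                          d1[2], d1[3], d1[4]))
        at <- 0L
        for (p in parts) {
          cp <- dim(p)[1]
          out[at + seq_len(cp), , , ] <- p
          at <- at + cp
        }
        out
      },
      add = cache[[n$inputs[1]]] + cache[[n$inputs[2]]],
      slice = cache[[n$inputs]][n$ch_from:n$ch_to, , , , drop = FALSE],
      shuffle = {
        xin <- cache[[n$inputs]]
        C <- dim(xin)[1]
        if (C %% n$groups != 0L)
          stop(sprintf("layer '%s': %d channels not divisible by %d groups",
                       n$name, C, n$groups), call. = FALSE)
        perm <- as.vector(matrix(seq_len(C), nrow = n$groups, byrow = TRUE))
        xin[perm, , , , drop = FALSE]
      },
      stop("unknown node kind: ", n$kind)
    )
    cache[[i]] <- out
  }
  list(cache = cache, aux = aux)
}

# Reverse-mode pass. `dout` is a list keyed by node id (character) of gradients
# w.r.t. those nodes' outputs. Returns list(param_grads, dinput).
graph_backward <- function(g, fw, dout) {
  nN <- length(g$nodes)
  dnode <- vector("list", nN)
  for (k in names(dout)) dnode[[as.integer(k)]] <- dout[[k]]
  pgrad <- vector("list", nN)
  dinput <- NULL
  for (i in rev(seq_len(nN))) {
    dy <- dnode[[i]]
    if (is.null(dy)) next
    n <- g$nodes[[i]]
    acc <- function(j, val) {
      dnode[[j]] <<- if (is.null(dnode[[j]])) val else dnode[[j]] + val
    }
    switch(n$kind,
      input = dinput <- dy,
      conv = {
        r <- cpp_conv2d_bw(fw$cache[[n$inputs]], n$w, dy, n$k, n$s, n$pad,
                           n$groups, !is.null(n$b))
        pgrad[[i]] <- list(w = r$dw, b = if (!is.null(n$b)) r$db)
        acc(n$inputs, r$dx)
      },
      bn = {
        d <- dim(fw$cache[[n$inputs]])
        a <- fw$aux[[i]]
        dym <- matrix(dy, nrow = d[1])
        dgamma <- rowSums(dym * a$xhat)
        dbeta <- rowSums(dym)
        m <- ncol(dym)
        dxhat <- dym * n$gamma
        dx <- a$istd * (dxhat - rowMeans(dxhat) - a$xhat * rowMeans(dxhat * a$xhat))
        pgrad[[i]] <- list(gamma = dgamma, beta = dbeta)
        dim(dx) <- d
        acc(n$inputs, dx)
      },
      silu = {
        x <- fw$cache[[n$inputs]]
        s <- 1 / (1 + exp(-x))
        acc(n$inputs, dy * (s * (1 + x * (1 - s))))
      },
      maxpool = acc(n$inputs,
                    cpp_maxpool_bw(dy, fw$aux[[i]], dim(fw$cache[[n$inputs]]))),
      upsample = {
        d <- dim(fw$cache[[n$inputs]])
        ih <- seq(1L, 2L * d[2], by = 2L)
        iw <- seq(1L, 2L * d[3], by = 2L)
        acc(n$inputs,
            dy[, ih, iw, , drop = FALSE] + dy[, ih + 1L, iw, , drop = FALSE] +
            dy[, ih, iw + 1L, , drop = FALSE] + dy[, ih + 1L, iw + 1L, , drop = FALSE])
      },
      concat = {
        at <- 0L
        for (j in n$inputs) {
          cp <- dim(fw$cache[[j]])[1]
          acc(j, dy[at + seq_len(cp), , , , drop = FALSE])
          at <- at + cp
        }
      },
      add = { acc(n$inputs[1], dy); acc(n$inputs[2], dy) },
      slice = {
        d <- dim(fw$cache[[n$inputs]])
        dx <- array(0, d)
        dx[n$ch_from:n$ch_to, , , ] <- dy
        acc(n$inputs, dx)
      },
      shuffle = {
        C <- dim(dy)[1]
        perm <- as.vector(matrix(seq_len(C), nrow = n$groups, byrow = TRUE))
        inv <- order(perm)
        acc(n$inputs, dy[inv, , , , drop = FALSE])
      },
      stop("unknown node kind: ", n$kind)
    )
    dnode[[i]] <- NULL  # free
  }
  list(param_grads = pgrad, dinput = dinput)
}

# Named flat list of trainable parameter arrays (and which decay).
graph_params <- function(g) {
  out <- list()
  decay <- logical()
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    if (n$kind == "conv") {
      out[[paste0(i, ".w")]] <- n$w
      decay[paste0(i, ".w")] <- TRUE
      if (!is.null(n$b)) {
        out[[paste0(i, ".b")]] <- n$b
        decay[paste0(i, ".b")] <- FALSE
      }
    } else if (n$kind == "bn") {
      out[[paste0(i, ".gamma")]] <- n$gamma
      out[[paste0(i, ".beta")]] <- n$beta
      decay[paste0(i, ".gamma")] <- FALSE
      decay[paste0(i, ".beta")] <- FALSE
    }
  }
  attr(out, "decay") <- decay
  out
}

graph_set_params <- function(g, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    slot <- parts[2]
    if (slot == "w") {
      g$nodes[[i]]$w[] <- params[[nm]]
    } else {
      g$nodes[[i]][[slot]] <- params[[nm]]
    }
  }
  invisible(g)
}

graph_collect_grads <- function(g, pgrad) {
  out <- list()
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    if (n$kind == "conv") {
      pg <- pgrad[[i]]
      out[[paste0(i, ".w")]] <- if (is.null(pg)) 0 * n$w else pg$w
      if (!is.null(n$b))
        out[[paste0(i, ".b")]] <- if (is.null(pg)) 0 * n$b else pg$b
    } else if (n$kind == "bn") {
      pg <- pgrad[[i]]
      out[[paste0(i, ".gamma")]] <- if (is.null(pg)) 0 * n$gamma else pg$gamma
      out[[paste0(i, ".beta")]] <- if (is.null(pg)) 0 * n$beta else pg$beta
    }
  }
  out
}

# Symbolic shape propagation (C, H, W) per node, for the profiler.
graph_shapes <- function(g, input_size) {
  shp <- vector("list", length(g$nodes))
  odim <- function(h, k, s, p) (h + 2 * p - k) %/% s + 1
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    shp[[i]] <- switch(n$kind,
      input = c(n$cin, input_size, input_size),
      conv = {
        s <- shp[[n$inputs]]
        c(n$cout, odim(s[2], n$k, n$s, n$pad), odim(s[3], n$k, n$s, n$pad))
      },
      maxpool = {
        s <- shp[[n$inputs]]
        c(s[1], odim(s[2], n$k, n$s, n$pad), odim(s[3], n$k, n$s, n$pad))
      },
      upsample = { s <- shp[[n$inputs]]; c(s[1], 2 * s[2], 2 * s[3]) },
      concat = {
        ss <- shp[n$inputs]
        c(sum(vapply(ss, `[`, 0, 1)), ss[[1]][2], ss[[1]][3])
      },
      slice = { s <- shp[[n$inputs]]; c(n$ch_to - n$ch_from + 1L, s[2], s[3]) },
      shp[[n$inputs[1]]]  # bn, silu, add, shuffle keep shape
    )
  }
  shp
}
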