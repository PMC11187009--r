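# ---------------------------------------------------------------------------
# Dataset I/O (YOLO-dialect text labels), the 8:1:1 split, letterboxing,
# mosaic augmentation, and the synthetic lesion-image generator that stands
# in for field imagery of the three cotton diseases.
#
# A Sample is list(image = (H, W, 3) array in [0,1], boxes = tibble with
# class_id, cx, cy, bw, bh normalised to [0,1], id = character).
# ---------------------------------------------------------------------------

#' Default class names
#'
#' The three cotton foliar diseases, in label order.
#' @export
cdd_classes <- c("verticillium_wilt", "fusarium_wilt", "anthracnose")

#' Read YOLO-dialect labels
#'
#' One text file per image, rows `class cx cy w h` with coordinates
#' normalised to `[0, 1]`. A missing file is a valid negative image (zero
#' boxes). Malformed rows raise an error naming the file and line;
#' out-of-range coordinates are clipped with a warning.
#'
#' @param path Label file path.
#' @return Tibble with columns `class_id, cx, cy, bw, bh`.
#' @export
read_labels <- function(path) {
  empty <- tibble::tibble(class_id = integer(), cx = numeric(),
                          cy = numeric(), bw = numeric(), bh = numeric())
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 5 || anyNA(vals) || vals[1] < 0 ||
        vals[1] != floor(vals[1]))
      stop(sprintf("malformed label row at %s:%d: '%s'", path, i, lines[i]),
           call. = FALSE)
    vals
  })
  m <- do.call(rbind, rows)
  coords <- m[, 2:5, drop = FALSE]
  if (any(coords < 0 | coords > 1)) {
    warning(sprintf("out-of-range coordinates clipped in %s", path),
            call. = FALSE)
    coords <- pmin(pmax(coords, 0), 1)
  }
  tibble::tibble(class_id = as.integer(m[, 1]), cx = coords[, 1],
                 cy = coords[, 2], bw = coords[, 3], bh = coords[, 4])
}

#' Write YOLO-dialect labels
#'
#' @param boxes Tibble with `class_id, cx, cy, bw, bh` (normalised).
#' @param path Output file path.
#' @param scores Optional per-box confidence column to append.
#' @return `path`, invisibly.
#' @export
write_labels <- function(boxes, path, scores = NULL) {
  fmt <- function(x) formatC(x, digits = 6, format = "f")
  lines <- sprintf("%d %s %s %s %s", boxes$class_id, fmt(boxes$cx),
                   fmt(boxes$cy), fmt(boxes$bw), fmt(boxes$bh))
  if (!is.null(scores)) lines <- paste(lines, fmt(scores))
  writeLines(lines, path)
  invisible(path)
}

# normalised centre-extent -> pixel corner boxes (and back)
norm_to_corners <- function(boxes, w, h) {
  tibble::tibble(class_id = boxes$class_id,
                 x1 = (boxes$cx - boxes$bw / 2) * w,
                 y1 = (boxes$cy - boxes$bh / 2) * h,
                 x2 = (boxes$cx + boxes$bw / 2) * w,
                 y2 = (boxes$cy + boxes$bh / 2) * h)
}

corners_to_norm <- function(boxes, w, h) {
  tibble::tibble(class_id = boxes$class_id,
                 cx = (boxes$x1 + boxes$x2) / 2 / w,
                 cy = (boxes$y1 + boxes$y2) / 2 / h,
                 bw = (boxes$x2 - boxes$x1) / w,
                 bh = (boxes$y2 - boxes$y1) / h)
}

#' Split items 8:1:1
#'
#' Seeded shuffle, then contiguous cuts at `floor(0.8 n)` and
#' `floor(0.9 n)` (for the default ratios). Deterministic per seed;
#' partitions are disjoint and exhaustive.
#'
#' @param items Vector of items (e.g. file paths).
#' @param ratios Three positive weights, default `c(8, 1, 1)`.
#' @param seed Integer seed.
#' @return `list(train, val, test)`.
#' @export
split_dataset <- function(items, ratios = c(8, 1, 1), seed = 0L) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split", call. = FALSE)
  if (length(ratios) != 3 || any(ratios <= 0))
    stop("ratios must be three positive numbers", call. = FALSE)
  set.seed(seed)
  items <- items[sample.int(n)]
  p <- cumsum(ratios) / sum(ratios)
  c1 <- floor(p[1] * n); c2 <- floor(p[2] * n)
  list(train = items[seq_len(c1)],
       val = items[setdiff(seq_len(c2), seq_len(c1))],
       test = items[setdiff(seq_len(n), seq_len(c2))])
}

# vectorised bilinear resampling of an (H, W, 3) image
resize_bilinear <- function(img, oh, ow) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sy <- (seq_len(oh) - 0.5) * (h / oh) + 0.5
  sx <- (seq_len(ow) - 0.5) * (w / ow) + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(oh, ow, 3))
  for (c in 1:3) {
    m <- img[, , c]
    out[, , c] <- (1 - wy) %o% (1 - wx) * m[y0, x0] +
                  (1 - wy) %o% wx       * m[y0, x1] +
                  wy       %o% (1 - wx) * m[y1, x0] +
                  wy       %o% wx       * m[y1, x1]
  }
  out
}

#' Letterbox a sample
#'
#' Aspect-preserving resize to fit the square target, with symmetric gray
#' padding; boxes are transformed consistently and the inverse transform is
#' recorded for decode-time un-mapping.
#'
#' @param sample A sample (list with `image`, `boxes`, `id`).
#' @param target_size Square output size, divisible by 32.
#' @return The letterboxed sample with a `transform` element
#'   (`scale, pad_x, pad_y, orig_w, orig_h`).
#' @export
letterbox <- function(sample, target_size) {
  if (target_size %% 32 != 0)
    stop("target_size must be divisible by 32", call. = FALSE)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  scale <- min(target_size / w, target_size / h)
  nw <- round(w * scale); nh <- round(h * scale)
  resized <- resize_bilinear(sample$image, nh, nw)
  canvas <- array(0.447, c(target_size, target_size, 3))
  px <- (target_size - nw) %/% 2L
  py <- (target_size - nh) %/% 2L
  canvas[py + seq_len(nh), px + seq_len(nw), ] <- resized
  boxes <- sample$boxes
  if (nrow(boxes) > 0) {
    cr <- norm_to_corners(boxes, w, h)
    cr$x1 <- cr$x1 * scale + px; cr$x2 <- cr$x2 * scale + px
    cr$y1 <- cr$y1 * scale + py; cr$y2 <- cr$y2 * scale + py
    boxes <- corners_to_norm(cr, target_size, target_size)
  }
  list(image = canvas, boxes = boxes, id = sample$id,
       transform = list(scale = scale, pad_x = px, pad_y = py,
                        orig_w = w, orig_h = h))
}

#' Undo a letterbox transform on pixel-corner boxes
#'
#' @param boxes Tibble with `x1, y1, x2, y2` in letterboxed pixels.
#' @param transform The `transform` element recorded by [letterbox()].
#' @return Boxes in original-image pixels, clipped to its bounds.
#' @export
unletterbox_boxes <- function(boxes, transform) {
  t <- transform
  boxes$x1 <- pmin(pmax((boxes$x1 - t$pad_x) / t$scale, 0), t$orig_w)
  boxes$x2 <- pmin(pmax((boxes$x2 - t$pad_x) / t$scale, 0), t$orig_w)
  boxes$y1 <- pmin(pmax((boxes$y1 - t$pad_y) / t$scale, 0), t$orig_h)
  boxes$y2 <- pmin(pmax((boxes$y2 - t$pad_y) / t$scale, 0), t$orig_h)
  boxes
}

#' Mosaic augmentation
#'
#' Fuses four samples into one canvas: a seeded centre point (jittered in
#' 0.25-0.75 of the canvas) splits the output into four quadrants, each
#' input is resized to the canvas and its quadrant crop pasted in, and
#' boxes are remapped and clipped, dropping any whose clipped area falls
#' below 2 px^2.
#'
#' @param samples List of exactly four samples.
#' @param out_size Square canvas size.
#' @param seed Integer seed for the centre jitter.
#' @return A fused sample.
#' @export
mosaic <- function(samples, out_size, seed = 0L) {
  if (length(samples) != 4) stop("mosaic needs exactly four samples",
                                 call. = FALSE)
  set.seed(seed)
  cx <- round(stats::runif(1, 0.25, 0.75) * out_size)
  cy <- round(stats::runif(1, 0.25, 0.75) * out_size)
  canvas <- array(0, c(out_size, out_size, 3))
  xr <- list(c(1, cx), c(cx + 1, out_size), c(1, cx), c(cx + 1, out_size))
  yr <- list(c(1, cy), c(1, cy), c(cy + 1, out_size), c(cy + 1, out_size))
  boxes <- NULL
  for (q in 1:4) {
    s <- samples[[q]]
    rs <- resize_bilinear(s$image, out_size, out_size)
    ys <- yr[[q]][1]:yr[[q]][2]; xs <- xr[[q]][1]:xr[[q]][2]
    canvas[ys, xs, ] <- rs[ys, xs, ]
    if (nrow(s$boxes) > 0) {
      cr <- norm_to_corners(s$boxes, out_size, out_size)
      cr$x1 <- pmin(pmax(cr$x1, xr[[q]][1] - 1), xr[[q]][2])
      cr$x2 <- pmin(pmax(cr$x2, xr[[q]][1] - 1), xr[[q]][2])
      cr$y1 <- pmin(pmax(cr$y1, yr[[q]][1] - 1), yr[[q]][2])
      cr$y2 <- pmin(pmax(cr$y2, yr[[q]][1] - 1), yr[[q]][2])
      keep <- (cr$x2 - cr$x1) * (cr$y2 - cr$y1) >= 2
      boxes <- rbind(boxes, cr[keep, , drop = FALSE])
    }
  }
  boxes <- if (is.null(boxes) || nrow(boxes) == 0) {
    tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                   bw = numeric(), bh = numeric())
  } else corners_to_norm(boxes, out_size, out_size)
  list(image = canvas, boxes = boxes,
       id = paste0("mosaic_", paste(vapply(samples, `[[`, "", "id"),
                                    collapse = "+")))
}

# --- synthetic lesion imagery ----------------------------------------------

#' Synthetic dataset configuration
#'
#' The generator emulates the three-disease field setting: cluttered
#' leaf/soil/film backgrounds with procedurally painted lesions whose
#' morphology follows the per-disease descriptions — pale-yellow interveinal
#' patches (verticillium wilt), larger yellow-brown wilted areas (fusarium
#' wilt), and small dark sunken circular spots (anthracnose). Every painted
#' lesion's exact bounding box is recorded.
#'
#' @param n_images Number of images.
#' @param image_size Square image size in pixels.
#' @param lesions_range Integer range (min, max) of lesions per image.
#' @param class_probs Sampling weights over the three classes.
#' @param clutter Background clutter level in `[0, 1]`.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return An object of class `cdd_synth_config`.
#' @export
synth_config <- function(n_images = 30L, image_size = 640L,
                         lesions_range = c(1L, 3L),
                         class_probs = c(1, 1, 1) / 3, clutter = 0.5,
                         seed = 0L) {
  stopifnot(n_images >= 1, image_size >= 32,
            length(lesions_range) == 2, lesions_range[1] >= 1,
            lesions_range[2] >= lesions_range[1],
            length(class_probs) == 3, all(class_probs >= 0),
            clutter >= 0, clutter <= 1)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 lesions_range = as.integer(lesions_range),
                 class_probs = class_probs / sum(class_probs),
                 clutter = clutter, seed = as.integer(seed)),
            class = "cdd_synth_config")
}

# paint an irregular blob; returns the logical mask
paint_blob <- function(size, cx, cy, rx, ry, wobble = 0.25) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  dx <- (xs - cx) / rx; dy <- (ys - cy) / ry
  theta <- atan2(dy, dx)
  k <- sample(2:5, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  edge <- 1 + wobble * sin(k * theta + phase)
  sqrt(dx^2 + dy^2) <= edge
}

# one synthetic sample (in memory); i indexes the image within the config
synth_sample <- function(config, i) {
  set.seed(config$seed * 100003L + i)
  sz <- config$image_size
  # cluttered background: leaf green field with soil/film patches
  base <- c(0.18, 0.35, 0.12) + stats::runif(3, -0.03, 0.03)
  img <- array(rep(base, each = sz * sz), c(sz, sz, 3))
  img <- img + array(stats::rnorm(sz * sz, sd = 0.02), c(sz, sz, 3))
  n_clutter <- 2L + round(config$clutter * 8)
  for (k in seq_len(n_clutter)) {
    style <- sample(c("leaf", "soil", "film"), 1, prob = c(0.5, 0.3, 0.2))
    col <- switch(style,
      leaf = c(0.14, 0.30, 0.10) + stats::runif(3, -0.04, 0.04),
      soil = c(0.35, 0.25, 0.15) + stats::runif(3, -0.05, 0.05),
      film = c(0.75, 0.75, 0.72) + stats::runif(3, -0.05, 0.05))
    m <- paint_blob(sz, stats::runif(1, 1, sz), stats::runif(1, 1, sz),
                    stats::runif(1, sz / 10, sz / 3),
                    stats::runif(1, sz / 10, sz / 3), wobble = 0.35)
    a <- stats::runif(1, 0.4, 0.8)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[m] <- (1 - a) * ch[m] + a * col[c]
      img[, , c] <- ch
    }
  }
  # lesions
  n_lesions <- sample(config$lesions_range[1]:config$lesions_range[2], 1)
  boxes <- NULL
  for (k in seq_len(n_lesions)) {
    cls <- sample(0:2, 1, prob = config$class_probs)
    # radii in pixels, floored at 4 px: lesions below ~8 px diameter are not
    # reliably annotatable, so the generator never paints them
    if (cls == 0L) {         # pale-yellow interveinal patch
      r <- pmax(stats::runif(2, sz / 16, sz / 7), 4)
      col <- c(0.80, 0.75, 0.30) + stats::runif(3, -0.05, 0.05)
      wob <- 0.35
    } else if (cls == 1L) {  # yellow-brown wilted area
      r <- pmax(stats::runif(2, sz / 10, sz / 5), 4)
      col <- c(0.55, 0.40, 0.12) + stats::runif(3, -0.05, 0.05)
      wob <- 0.3
    } else {                 # small dark sunken circular spot
      r0 <- max(stats::runif(1, sz / 32, sz / 14), 4)
      r <- c(r0, r0 * stats::runif(1, 0.9, 1.1))
      col <- c(0.22, 0.13, 0.08) + stats::runif(3, -0.03, 0.03)
      wob <- 0.1
    }
    cx <- stats::runif(1, r[1] + 2, sz - r[1] - 2)
    cy <- stats::runif(1, r[2] + 2, sz - r[2] - 2)
    m <- paint_blob(sz, cx, cy, r[1], r[2], wob)
    if (!any(m)) next
    for (c in 1:3) {
      ch <- img[, , c]
      ch[m] <- 0.15 * ch[m] + 0.85 * col[c]
      img[, , c] <- ch
    }
    if (cls == 2L) {  # darker rim for the sunken spot
      rim <- paint_blob(sz, cx, cy, r[1] * 1.15, r[2] * 1.15, wob) & !m
      for (c in 1:3) {
        ch <- img[, , c]
        ch[rim] <- 0.5 * ch[rim] + 0.5 * (col[c] * 0.5)
        img[, , c] <- ch
      }
    }
    ij <- which(m, arr.ind = TRUE)
    boxes <- rbind(boxes, data.frame(
      class_id = cls,
      x1 = min(ij[, 2]) - 1, y1 = min(ij[, 1]) - 1,
      x2 = max(ij[, 2]), y2 = max(ij[, 1])))
  }
  img <- pmin(pmax(img, 0), 1)
  boxes <- if (is.null(boxes)) {
    tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                   bw = numeric(), bh = numeric())
  } else corners_to_norm(tibble::as_tibble(boxes), sz, sz)
  list(image = img, boxes = boxes, id = sprintf("synth_%05d", i))
}

#' Generate a synthetic lesion dataset on disk
#'
#' Writes `n_images` PNG images with YOLO-dialect label files and a manifest
#' (`dataset.txt`: class names, then one image path per row). Deterministic
#' for a given config.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory. Must be empty or absent unless
#'   `overwrite`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest path, invisibly.
#' @export
generate_synthetic <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "cdd_synth_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", out_dir, call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
  paths <- character(config$n_images)
  for (i in seq_len(config$n_images)) {
    s <- synth_sample(config, i)
    ip <- file.path(out_dir, "images", paste0(s$id, ".png"))
    png::writePNG(s$image, ip)
    write_labels(s$boxes, file.path(out_dir, "labels", paste0(s$id, ".txt")))
    paths[i] <- file.path("images", paste0(s$id, ".png"))
  }
  manifest <- file.path(out_dir, "dataset.txt")
  writeLines(c(paste("# classes:", paste(cdd_classes, collapse = ",")),
               paths), manifest)
  invisible(manifest)
}

#' Load a sample from disk
#'
#' Reads a PNG image and its label file (`images/...` replaced by
#' `labels/...` with a `.txt` extension).
#'
#' @param image_path Path to the image.
#' @return A sample list (`image`, `boxes`, `id`).
#' @export
read_sample <- function(image_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  lp <- sub("\\.[^.]+$", ".txt", image_path)
  lp <- sub("(^|/)images(/|$)", "\\1labels\\2", lp)
  list(image = img, boxes = read_labels(lp),
       id = sub("\\.[^.]+$", "", basename(image_path)))
}

# image (H, W, 3) -> network tensor (3, H, W)
img_to_tensor <- function(img) aperm(img, c(3, 1, 2))
tensor_to_img <- function(x) aperm(x, c(2, 3, 1))
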