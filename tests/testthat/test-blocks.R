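# block vocabulary: shape laws, identity properties, pinned parameter counts

test_that("CBS obeys the channel/stride shape law and its conv cost is the Eq-style product", {
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  y1 <- cbs_forward(x, block_spec("CBS", 16, 32, kernel = 3, stride = 1))
  expect_equal(dim(y1), c(32, 8, 8))
  y2 <- cbs_forward(x, block_spec("CBS", 16, 32, kernel = 3, stride = 2))
  expect_equal(dim(y2), c(32, 4, 4))
  # conv weights only (no bias, no BN): 3*3*16*32
  p <- profile_block(block_spec("PlainConv", 16, 32, kernel = 3))
  expect_identical(p$total_params, 3 * 3 * 16 * 32)
  expect_error(cbs_forward(array(0, c(8, 4, 4)),
                           block_spec("CBS", 16, 32, kernel = 3)),
               "channels")
})

test_that("partial convolution touches only the first C/r channels", {
  set.seed(5)
  x <- array(rnorm(16 * 6 * 6), c(16, 6, 6))
  spec <- block_spec("PConv", 16, 16, kernel = 3, partial_ratio = 4)
  y <- pconv_forward(x, spec)
  expect_identical(y[5:16, , ], x[5:16, , ])   # untouched slice, bit-exact
  # identity kernel on the convolved slice reproduces the input exactly
  g <- cddlite:::block_graph(spec, seed = 1)
  ci <- which(vapply(g$nodes, function(n) n$kind == "conv", TRUE))
  idk <- matrix(0, 4, 4 * 9)
  for (c in 1:4) idk[c, (c - 1) * 9 + 5] <- 1  # centre tap of channel c
  g$nodes[[ci]]$w <- idk
  expect_equal(pconv_forward(x, spec, graph = g), x, tolerance = 1e-14)
  # cost: k*k*(C/r)*(C/r) for C = 64
  p <- profile_block(block_spec("PConv", 64, 64, kernel = 3))
  expect_identical(p$total_params, (64 / 4) * (64 / 4) * 9)
  expect_error(block_spec("PConv", 6, 6), "divisible")
})

test_that("Faster block is residual: zero weights reduce it to the identity", {
  set.seed(6)
  x <- array(rnorm(64 * 5 * 5), c(64, 5, 5))
  spec <- block_spec("FasterBlock", 64, 64)
  expect_equal(dim(faster_block_forward(x, spec)), c(64, 5, 5))
  g <- cddlite:::block_graph(spec, seed = 1)
  for (i in seq_along(g$nodes))
    if (g$nodes[[i]]$kind == "conv") g$nodes[[i]]$w[] <- 0
  expect_equal(faster_block_forward(x, spec, graph = g), x, tolerance = 1e-14)
  # pinned count: PConv 2304 + 1x1 CBS 64->128 (8192 + 256 BN) + 1x1 conv 8192
  p <- profile_block(spec)
  expect_identical(p$total_params, 2304 + 8192 + 256 + 8192)
  expect_error(block_spec("FasterBlock", 64, 32), "residual")
})

test_that("C2f keeps shape, C2f-Faster is strictly lighter, and the fuse conv sees (2+n) halves", {
  x <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
  s_c2f <- block_spec("C2f", 64, 64, n = 2)
  s_fast <- block_spec("C2fFaster", 64, 64, n = 2)
  expect_equal(dim(c2f_forward(x, s_c2f)), c(64, 16, 16))
  expect_equal(dim(c2f_faster_forward(x, s_fast)), c(64, 16, 16))
  expect_lt(profile_block(s_fast)$total_params,
            profile_block(s_c2f)$total_params)
  g <- cddlite:::block_graph(s_c2f)
  fuse <- g$nodes[[length(g$nodes) - 2L]]  # fuse conv before bn+silu
  expect_identical(fuse$cin, (2L + 2L) * 32L)
})

test_that("channel shuffle is the group-interleave permutation", {
  x <- array(0, c(4, 2, 2))
  for (c in 1:4) x[c, , ] <- c
  y <- channel_shuffle(x, 2)
  expect_equal(y[, 1, 1], c(1, 3, 2, 4))          # [a,b,c,d] -> [a,c,b,d]
  expect_identical(channel_shuffle(x, 1), x)       # groups = 1 is identity
  expect_identical(channel_shuffle(channel_shuffle(x, 2), 2), x)  # involution at C=4
  # permutation: value multiset preserved per spatial position
  set.seed(8)
  z <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  zs <- channel_shuffle(z, 4)
  expect_equal(sort(zs[, 2, 2]), sort(z[, 2, 2]))
  expect_error(channel_shuffle(z, 3), "divisible")
})

test_that("GSConv honours the channel contract and undercuts a CBS of equal geometry", {
  x <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
  expect_equal(dim(gsconv_forward(x, block_spec("GSConv", 64, 128, kernel = 3))),
               c(128, 16, 16))
  expect_equal(dim(gsconv_forward(x, block_spec("GSConv", 64, 128, kernel = 3,
                                                stride = 2))),
               c(128, 8, 8))
  expect_lt(profile_block(block_spec("GSConv", 64, 128, kernel = 3))$total_params,
            profile_block(block_spec("CBS", 64, 128, kernel = 3))$total_params)
  expect_error(block_spec("GSConv", 64, 127), "even")
})

test_that("GS bottleneck and VoVGSCSP keep shape; cost grows with n and undercuts C2f at neck widths", {
  x <- array(rnorm(128 * 8 * 8), c(128, 8, 8))
  expect_equal(dim(gs_bottleneck_forward(x, block_spec("GSBottleneck", 128, 128))),
               c(128, 8, 8))
  expect_equal(dim(vovgscsp_forward(x, block_spec("VoVGSCSP", 128, 128))),
               c(128, 8, 8))
  p1 <- profile_block(block_spec("VoVGSCSP", 128, 128, n = 1))$total_params
  p2 <- profile_block(block_spec("VoVGSCSP", 128, 128, n = 2))$total_params
  expect_lt(p1, p2)
  # the neck substitution is lighter at its actual widths
  expect_lt(profile_block(block_spec("VoVGSCSP", 384, 128, n = 1))$total_params,
            profile_block(block_spec("C2f", 384, 128, n = 1))$total_params)
})

test_that("SPPF preserves shape, maps constants to constants, concatenates four stages", {
  x <- array(rnorm(32 * 10 * 10), c(32, 10, 10))
  spec <- block_spec("SPPF", 32, 32, kernel = 5)
  expect_equal(dim(sppf_forward(x, spec)), c(32, 10, 10))
  g <- cddlite:::block_graph(spec)
  cat_node <- Find(function(n) n$kind == "concat", g$nodes)
  expect_identical(length(cat_node$inputs), 4L)
  # constant input stays constant through the pooling stages
  xc <- array(1, c(32, 10, 10))
  fw <- cddlite:::graph_forward(g, xc)
  pool_ids <- which(vapply(g$nodes, function(n) n$kind == "maxpool", TRUE))
  for (i in pool_ids) {
    per_ch <- apply(fw$cache[[i]], 1, function(m) diff(range(m)))
    expect_equal(per_ch, rep(0, length(per_ch)))
  }
})

test_that("randomised specs obey the shape law and produce finite values", {
  set.seed(9)
  kinds <- c("CBS", "PConv", "FasterBlock", "C2f", "C2fFaster", "GSConv",
             "VoVGSCSP", "SPPF")
  for (rep in 1:12) {
    kind <- sample(kinds, 1)
    cin <- sample(c(8L, 16L, 32L), 1)
    cout <- if (kind %in% c("PConv", "FasterBlock", "SPPF")) cin
            else sample(c(8L, 16L, 32L), 1)
    s <- if (kind %in% c("CBS", "GSConv")) sample(1:2, 1) else 1L
    spec <- block_spec(kind, cin, cout, kernel = 3, stride = s,
                       n = sample(1:2, 1))
    hw <- 8L
    x <- array(rnorm(cin * hw * hw), c(cin, hw, hw))
    y <- cddlite:::run_block(spec, x, seed = rep)
    expect_equal(dim(y), c(cout, hw %/% s, hw %/% s), info = kind)
    expect_true(all(is.finite(y)), info = kind)
  }
})
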